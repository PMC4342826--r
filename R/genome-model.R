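#' Genome annotation container
#'
#' A `genome_annotation` holds the features of one replicon with 1-based,
#' fully inclusive coordinates (`start` is always the leftmost base,
#' `end` the rightmost, on both strands, as in GFF3).
#'
#' @param replicon_id replicon name.
#' @param length replicon length in nt.
#' @param features data frame with columns `feature_id`, `start`, `end`,
#'   `strand` ('+'/'-'), `feature_type` (CDS, rRNA, tRNA, sRNA or novel)
#'   and optionally `product`.
#' @return an object of class `genome_annotation`: a list with elements
#'   `replicon_id`, `length` and `features` (sorted by `start`, stably).
#' @export
genome_annotation <- function(replicon_id, length, features) {
  stopifnot(is.character(replicon_id), length(replicon_id) == 1L)
  length <- as.integer(length)
  stopifnot(!is.na(length), length >= 1L)
  need <- c("feature_id", "start", "end", "strand", "feature_type")
  if (!all(need %in% names(features)))
    stop("features must have columns: ", paste(need, collapse = ", "))
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (!"product" %in% names(features)) features$product <- NA_character_
  if (anyNA(features$start) || anyNA(features$end))
    stop("non-numeric feature coordinates")
  if (any(features$end < features$start))
    stop("invalid feature coordinates: end < start for ",
         paste(features$feature_id[features$end < features$start], collapse = ", "))
  if (any(features$start < 1L) || any(features$end > length))
    stop("feature coordinates outside [1, replicon length]")
  .check_strand(features$strand)
  if (anyDuplicated(features$feature_id))
    stop("duplicate feature_id: ",
         paste(unique(features$feature_id[duplicated(features$feature_id)]), collapse = ", "))
  ord <- order(features$start)   # stable in base R
  features <- features[ord, c(need, "product"), drop = FALSE]
  rownames(features) <- NULL
  structure(list(replicon_id = replicon_id, length = length, features = features),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %s (%s nt), %d features\n",
              x$replicon_id, format(x$length, big.mark = ","), nrow(x$features)))
  print(utils::head(x$features, 6))
  invisible(x)
}

# Pre-validate a GFF3 file line by line so that errors can name the
# offending line; returns the ##sequence-region length if present.
.scan_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seqlen <- NA_integer_
  replicon <- NA_character_
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^##sequence-region", ln)) {
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) >= 4) {
        replicon <- f[2]
        seqlen <- suppressWarnings(as.integer(f[4]))
      }
      next
    }
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9)
      stop(sprintf("malformed GFF3 line %d: expected 9 tab-separated fields, got %d",
                   i, length(f)))
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e))
      stop(sprintf("malformed GFF3 line %d: non-numeric coordinates", i))
    if (e < s)
      stop(sprintf("invalid GFF3 line %d: end (%d) < start (%d)", i, e, s))
  }
  list(replicon_id = replicon, length = seqlen)
}

#' Read a genome annotation from GFF3
#'
#' Keeps CDS, rRNA, tRNA and sRNA records. The replicon length is taken
#' from the `##sequence-region` pragma unless supplied explicitly.
#'
#' @param path GFF3 file path.
#' @param replicon_length replicon length in nt; overrides the pragma.
#' @return a [genome_annotation()].
#' @export
read_gff3 <- function(path, replicon_length = NULL) {
  meta <- .scan_gff3(path)
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c("CDS", "rRNA", "tRNA", "sRNA", "novel")
  gr <- gr[keep]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  if (!is.null(gr$locus_tag)) {
    lt <- as.character(gr$locus_tag)
    ids <- ifelse(is.na(ids), lt, ids)
  }
  ids[is.na(ids)] <- sprintf("feature_%05d", which(is.na(ids)))
  prod <- if (!is.null(gr$product)) as.character(gr$product) else NA_character_
  feats <- data.frame(
    feature_id = ids,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature_type = as.character(gr$type),
    product = prod,
    stringsAsFactors = FALSE
  )
  len <- if (!is.null(replicon_length)) replicon_length else meta$length
  if (is.na(len) || is.null(len))
    stop("replicon length not found in ##sequence-region pragma; pass replicon_length=")
  rep_id <- if (nrow(feats) > 0) as.character(GenomicRanges::seqnames(gr))[1] else meta$replicon_id
  genome_annotation(rep_id, len, feats)
}

#' Write a genome annotation to GFF3
#'
#' @param annotation a [genome_annotation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  f <- annotation$features
  attr_col <- ifelse(is.na(f$product),
                     sprintf("ID=%s", f$feature_id),
                     sprintf("ID=%s;product=%s", f$feature_id, f$product))
  lines <- c(
    "##gff-version 3",
    sprintf("##sequence-region %s 1 %d", annotation$replicon_id, annotation$length),
    sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            annotation$replicon_id, "primarytx", f$feature_type, f$start, f$end,
            f$strand, ifelse(f$feature_type == "CDS", "0", "."), attr_col)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read start profile
#'
#' Sparse, stranded map from genomic position to the number of sequencing
#' reads whose 5' end maps at that position, for one replicon and one
#' library type.
#'
#' @param replicon_id replicon name.
#' @param positions,strands,counts parallel vectors describing the stored
#'   (position, strand) -> count entries; counts must be >= 1.
#' @param library `"five_prime_enriched"` or `"whole_transcriptome"`.
#' @param total_mapped number of mapped reads the profile represents;
#'   defaults to `sum(counts)`. The simulator sets this to the nominal
#'   library size so that per-million normalization is meaningful even
#'   though only reads on the simulated replicon are stored.
#' @param replicon_length optional replicon length used for bounds checks.
#' @return an object of class `read_start_profile`.
#' @export
read_start_profile <- function(replicon_id, positions = integer(), strands = character(),
                               counts = integer(),
                               library = c("five_prime_enriched", "whole_transcriptome"),
                               total_mapped = NULL, replicon_length = NA_integer_) {
  library <- match.arg(library)
  positions <- as.integer(positions); counts <- as.integer(counts)
  stopifnot(length(positions) == length(strands), length(positions) == length(counts))
  if (length(counts) && any(counts < 1L))
    stop("read-start counts must be >= 1 for stored positions")
  .check_strand(strands)
  if (!is.na(replicon_length) && length(positions) &&
      (any(positions < 1L) || any(positions > replicon_length)))
    stop("read-start positions outside [1, replicon length]")
  key <- paste(strands, positions)
  if (anyDuplicated(key))
    stop("duplicate (position, strand) entries in read-start profile")
  ord <- order(strands, positions)
  starts <- data.frame(position = positions[ord], strand = strands[ord],
                       count = counts[ord], stringsAsFactors = FALSE)
  rownames(starts) <- NULL
  if (is.null(total_mapped)) total_mapped <- sum(starts$count)
  structure(list(replicon_id = replicon_id, library = library,
                 total_mapped = as.double(total_mapped),
                 replicon_length = as.integer(replicon_length),
                 starts = starts),
            class = "read_start_profile")
}

#' @export
print.read_start_profile <- function(x, ...) {
  cat(sprintf("read_start_profile: %s [%s], %d positions, %s mapped reads\n",
              x$replicon_id, x$library, nrow(x$starts),
              format(x$total_mapped, big.mark = ",")))
  invisible(x)
}

#' Look up read-start counts
#'
#' @param profile a [read_start_profile()].
#' @param positions integer vector of positions.
#' @param strand single strand character.
#' @return integer vector of counts (0 where no reads start).
#' @export
profile_counts <- function(profile, positions, strand) {
  st <- profile$starts[profile$starts$strand == strand, , drop = FALSE]
  idx <- match(as.integer(positions), st$position)
  out <- st$count[idx]
  out[is.na(out)] <- 0L
  out
}

#' Read a read-start TSV
#'
#' Expected columns: replicon, position, strand, count. Lines starting
#' with '#' are comments.
#'
#' @param path TSV path.
#' @inheritParams read_start_profile
#' @return a [read_start_profile()].
#' @export
read_read_starts <- function(path, library = c("five_prime_enriched", "whole_transcriptome"),
                             total_mapped = NULL, replicon_length = NA_integer_) {
  library <- match.arg(library)
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(d) == 0)
    return(read_start_profile("unknown", library = library,
                              total_mapped = if (is.null(total_mapped)) 0 else total_mapped,
                              replicon_length = replicon_length))
  need <- c("replicon", "position", "strand", "count")
  if (!all(need %in% names(d))) stop("read-start TSV needs columns: ", paste(need, collapse = ", "))
  if (length(unique(d$replicon)) > 1) stop("read-start TSV mixes replicons")
  if (any(d$count <= 0)) stop("read-start TSV contains counts <= 0")
  read_start_profile(d$replicon[1], d$position, d$strand, d$count,
                     library = library, total_mapped = total_mapped,
                     replicon_length = replicon_length)
}

#' Write a read-start profile to TSV
#'
#' @param profile a [read_start_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_read_starts <- function(profile, path) {
  d <- data.frame(replicon = profile$replicon_id, profile$starts,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write interval TSVs (mappings and paired fragments)
#'
#' `mappings.tsv` has columns replicon, start, end, strand, mate_id;
#' `fragments.tsv` has replicon, start, end, strand.
#'
#' @param path TSV path.
#' @return a data frame of intervals.
#' @export
read_mappings <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("replicon", "start", "end", "strand")
  if (!all(need %in% names(d))) stop("mapping TSV needs columns: ", paste(need, collapse = ", "))
  if (!"mate_id" %in% names(d)) d$mate_id <- NA_character_
  if (any(d$end < d$start)) stop("mapping with end < start")
  .check_strand(d$strand)
  d
}

#' @rdname read_mappings
#' @export
read_fragments <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("replicon", "start", "end", "strand")
  if (!all(need %in% names(d))) stop("fragment TSV needs columns: ", paste(need, collapse = ", "))
  if (any(d$end < d$start)) stop("fragment with end < start")
  .check_strand(d$strand)
  d[, need]
}

#' @rdname read_mappings
#' @param intervals data frame of intervals to write.
#' @export
write_intervals <- function(intervals, path) {
  utils::write.table(intervals, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Combine read-pair mates into paired fragments
#'
#' Mates sharing a `mate_id` on the same replicon and in inverse
#' orientation are combined into one fragment spanning their outermost
#' coordinates, provided that span does not exceed `max_distance`
#' (default 1 kb). Wider pairs are discarded; mates without a usable
#' partner are retained as single mappings. The fragment strand is the
#' strand of the first mate record (transcript orientation).
#'
#' @param mates data frame with columns replicon, start, end, strand,
#'   mate_id (order defines which mate is "first in pair").
#' @param max_distance maximal allowed outer span in nt.
#' @return list with `fragments` (replicon, start, end, strand),
#'   `singles` (the unpaired mates) and `discarded` (number of pairs
#'   dropped for excessive span).
#' @export
combine_read_pairs <- function(mates, max_distance = 1000) {
  stopifnot(all(c("replicon", "start", "end", "strand", "mate_id") %in% names(mates)))
  if (any(mates$end < mates$start)) stop("mate with end < start")
  mates$.row <- seq_len(nrow(mates))
  has_id <- !is.na(mates$mate_id) & mates$mate_id != ""
  tab <- table(mates$mate_id[has_id])
  paired_ids <- names(tab)[tab == 2L]
  if (any(tab > 2L))
    stop("mate_id occurs more than twice: ", paste(names(tab)[tab > 2L][1], collapse = ", "))
  frag <- list(); singles_idx <- which(!has_id | !(mates$mate_id %in% paired_ids))
  discarded <- 0L
  for (id in paired_ids) {
    pr <- mates[mates$mate_id %in% id, , drop = FALSE]
    pr <- pr[order(pr$.row), , drop = FALSE]
    if (pr$replicon[1] != pr$replicon[2] || pr$strand[1] == pr$strand[2]) {
      singles_idx <- c(singles_idx, pr$.row)     # unpairable: keep as singles
      next
    }
    s <- min(pr$start); e <- max(pr$end)
    if (e - s + 1L > max_distance) { discarded <- discarded + 1L; next }
    frag[[length(frag) + 1L]] <- data.frame(
      replicon = pr$replicon[1], start = s, end = e, strand = pr$strand[1],
      stringsAsFactors = FALSE)
  }
  fragments <- if (length(frag)) do.call(rbind, frag)
  else data.frame(replicon = character(), start = integer(), end = integer(),
                  strand = character(), stringsAsFactors = FALSE)
  singles <- mates[sort(singles_idx), setdiff(names(mates), ".row"), drop = FALSE]
  rownames(singles) <- NULL
  list(fragments = fragments, singles = singles, discarded = discarded)
}

#' Per-position stranded coverage
#'
#' Builds dense per-strand coverage vectors from paired fragments (or any
#' interval data frame), or from the read starts of a profile. Coverage is
#' the number of fragments overlapping each position.
#'
#' @param fragments data frame with start, end, strand columns.
#' @param replicon_length replicon length in nt.
#' @return object of class `stranded_coverage` with integer vectors
#'   `fwd` and `rev` of length `replicon_length`.
#' @export
fragment_coverage <- function(fragments, replicon_length) {
  replicon_length <- as.integer(replicon_length)
  cov1 <- function(d) {
    if (nrow(d) == 0) return(integer(replicon_length))
    ir <- IRanges::IRanges(start = pmax(1L, as.integer(d$start)),
                           end = pmin(replicon_length, as.integer(d$end)))
    as.integer(IRanges::coverage(ir, width = replicon_length))
  }
  structure(list(length = replicon_length,
                 fwd = cov1(fragments[fragments$strand == "+", , drop = FALSE]),
                 rev = cov1(fragments[fragments$strand == "-", , drop = FALSE])),
            class = "stranded_coverage")
}

#' @rdname fragment_coverage
#' @param profile a [read_start_profile()]; its counts are used as
#'   single-position coverage (a proxy when fragment intervals are not
#'   available).
#' @export
profile_as_coverage <- function(profile, replicon_length = profile$replicon_length) {
  replicon_length <- as.integer(replicon_length)
  if (is.na(replicon_length)) stop("replicon_length required")
  out <- list(length = replicon_length,
              fwd = integer(replicon_length), rev = integer(replicon_length))
  st <- profile$starts
  fw <- st[st$strand == "+", ]; rv <- st[st$strand == "-", ]
  out$fwd[fw$position] <- fw$count
  out$rev[rv$position] <- rv$count
  structure(out, class = "stranded_coverage")
}

#' Query stranded coverage
#'
#' @param coverage a `stranded_coverage`.
#' @param positions integer positions (values outside the replicon give 0).
#' @param strand single strand character.
#' @return integer coverage values.
#' @export
coverage_at <- function(coverage, positions, strand) {
  v <- if (strand == "+") coverage$fwd else coverage$rev
  positions <- as.integer(positions)
  out <- integer(length(positions))
  ok <- positions >= 1L & positions <= coverage$length
  out[ok] <- v[positions[ok]]
  out
}

#' Read and write a genome FASTA
#'
#' @param path FASTA path.
#' @return named character vector of sequences (one element per replicon).
#' @export
read_fasta_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @rdname read_fasta_genome
#' @param genome named character vector of sequences.
#' @export
write_fasta_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
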