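#' Feature length from printed coordinates
#'
#' Default is the inclusive convention `|start - end| + 1`. Published
#' feature tables sometimes mix inclusive and exclusive conventions, so
#' a compatibility mode returning the bare coordinate difference
#' `|start - end|` is provided.
#'
#' @param start,end feature coordinates (either order).
#' @param inclusive use the inclusive convention (default TRUE).
#' @return length in nt.
#' @export
#' @examples
#' feature_length(100, 100)                      # 1
#' feature_length(2087761, 2087336, inclusive = FALSE)  # 425
feature_length <- function(start, end, inclusive = TRUE) {
  abs(start - end) + if (inclusive) 1L else 0L
}

# positions inside a same-strand CDS body? The TLS base itself does not
# count as inside: a TSS on the first base of a start codon is a
# leaderless utr-class TSS (5'-UTR length 0), not an intragenic one.
.inside_cds <- function(positions, strand, annotation) {
  f <- annotation$features
  f <- f[f$strand == strand & f$feature_type == "CDS", , drop = FALSE]
  if (nrow(f) == 0) return(rep(FALSE, length(positions)))
  q <- IRanges::IRanges(start = positions, width = 1L)
  s <- if (strand == "+")
    IRanges::IRanges(start = f$start + 1L, end = f$end)
  else
    IRanges::IRanges(start = f$start, end = f$end - 1L)
  IRanges::countOverlaps(q, s) > 0
}

.within_intervals <- function(positions, iv_start, iv_end) {
  if (length(iv_start) == 0) return(rep(FALSE, length(positions)))
  q <- IRanges::IRanges(start = positions, width = 1L)
  s <- IRanges::IRanges(start = iv_start, end = iv_end)
  IRanges::countOverlaps(q, s) > 0
}

#' Classify TSS candidates by genomic context
#'
#' Routes each verified TSS to exactly one class with precedence
#' utr > intragenic > antisense > intergenic:
#' \itemize{
#'   \item \strong{utr}: a same-strand CDS translation start lies within
#'     `X` nt downstream and the TSS is outside all same-strand CDS
#'     bodies; the gene is assigned and the 5'-UTR length recorded
#'     (TLS first base minus TSS, 0 for a TSS on the TLS itself).
#'   \item \strong{intragenic}: the TSS falls within a same-strand CDS.
#'   \item \strong{antisense}: the TSS falls within an opposite-strand
#'     feature, or within a detected 5'-UTR or estimated 3'-UTR of an
#'     opposite-strand gene.
#'   \item \strong{intergenic}: none of the above.
#' }
#'
#' @param candidates candidate data frame (from [call_tss()]`$final` or
#'   [detect_candidates()]).
#' @param annotation a [genome_annotation()].
#' @param params a [tss_params()] (supplies `X`).
#' @param utr_regions optional data frame (feature_id, start, end,
#'   strand) of detected 5'-UTR intervals consulted for the antisense
#'   class.
#' @param three_prime_utrs optional data frame of estimated 3'-UTR
#'   intervals, same shape.
#' @return the candidates with columns `class`, `assigned_feature` and
#'   `utr_length` added.
#' @export
classify_tss <- function(candidates, annotation, params = tss_params(),
                         utr_regions = NULL, three_prime_utrs = NULL) {
  n <- nrow(candidates)
  cls <- rep("intergenic", n)
  feat <- rep(NA_character_, n)
  ulen <- rep(NA_integer_, n)
  if (n == 0) {
    candidates$class <- character(); candidates$assigned_feature <- character()
    candidates$utr_length <- integer(); return(candidates)
  }
  for (s in c("+", "-")) {
    idx <- which(candidates$strand == s)
    if (!length(idx)) next
    pos <- candidates$position[idx]
    tl <- .next_tls(pos, s, annotation, types = "CDS")
    inside <- .inside_cds(pos, s, annotation)
    is_utr <- !inside & !is.na(tl$dist) & tl$dist <= params$X
    cls[idx[is_utr]] <- "utr"
    feat[idx[is_utr]] <- tl$feature_id[is_utr]
    ulen[idx[is_utr]] <- tl$dist[is_utr]
    cls[idx[!is_utr & inside]] <- "intragenic"
    # intragenic TSSs keep the containing gene as assigned feature
    if (any(!is_utr & inside)) {
      f <- annotation$features
      f <- f[f$strand == s & f$feature_type == "CDS", , drop = FALSE]
      ii <- idx[!is_utr & inside]
      for (i in ii) {
        hit <- which(f$start <= candidates$position[i] & f$end >= candidates$position[i])
        if (length(hit)) feat[i] <- f$feature_id[hit[1]]
      }
    }
    # antisense: opposite-strand features and their UTRs
    opp <- if (s == "+") "-" else "+"
    f_opp <- annotation$features[annotation$features$strand == opp, , drop = FALSE]
    iv_s <- f_opp$start; iv_e <- f_opp$end
    if (!is.null(utr_regions)) {
      u <- utr_regions[utr_regions$strand == opp, , drop = FALSE]
      iv_s <- c(iv_s, u$start); iv_e <- c(iv_e, u$end)
    }
    if (!is.null(three_prime_utrs)) {
      u <- three_prime_utrs[three_prime_utrs$strand == opp, , drop = FALSE]
      iv_s <- c(iv_s, u$start); iv_e <- c(iv_e, u$end)
    }
    anti <- .within_intervals(pos, iv_s, iv_e)
    free <- cls[idx] == "intergenic"
    cls[idx[free & anti]] <- "antisense"
  }
  candidates$class <- cls
  candidates$assigned_feature <- feat
  candidates$utr_length <- ulen
  candidates
}

#' Mark genes with single or multiple TSSs
#'
#' Among utr-class records, genes driven by two or more TSSs get
#' `multiplicity = "multiple"` on each record, others `"single"`.
#'
#' @param records classified TSS records.
#' @return records with a `multiplicity` column (NA for non-utr rows).
#' @export
assign_multiplicity <- function(records) {
  records$multiplicity <- NA_character_
  isu <- records$class == "utr"
  if (any(isu)) {
    tab <- table(records$assigned_feature[isu])
    records$multiplicity[isu] <-
      ifelse(tab[records$assigned_feature[isu]] >= 2, "multiple", "single")
  }
  records
}

#' Annotate a verified TSS set
#'
#' Two-pass classification: utr-class TSSs are found first; their 5'-UTR
#' intervals (and, when whole-transcriptome coverage is available,
#' coverage-estimated 3'-UTRs) are then consulted for the antisense
#' class. Finishes with multiplicity assignment.
#'
#' @inheritParams classify_tss
#' @param whole_coverage optional `stranded_coverage` used to estimate
#'   3'-UTRs.
#' @return annotated records.
#' @export
annotate_tss <- function(candidates, annotation, params = tss_params(),
                         whole_coverage = NULL) {
  first <- classify_tss(candidates, annotation, params)
  utr_rec <- first[first$class == "utr", , drop = FALSE]
  utr_regions <- NULL
  if (nrow(utr_rec)) {
    utr_regions <- data.frame(
      feature_id = utr_rec$assigned_feature,
      start = ifelse(utr_rec$strand == "+", utr_rec$position,
                     utr_rec$position - pmax(utr_rec$utr_length - 1L, 0L)),
      end = ifelse(utr_rec$strand == "+",
                   utr_rec$position + pmax(utr_rec$utr_length - 1L, 0L),
                   utr_rec$position),
      strand = utr_rec$strand, stringsAsFactors = FALSE)
  }
  tp_utrs <- if (!is.null(whole_coverage))
    estimate_three_prime_utrs(annotation, whole_coverage) else NULL
  rec <- classify_tss(candidates, annotation, params,
                      utr_regions = utr_regions, three_prime_utrs = tp_utrs)
  assign_multiplicity(rec)
}

#' Propose translation-start corrections from intragenic TSSs
#'
#' An intragenic sense TSS within the first half of a CDS suggests that
#' the annotated start is too far upstream. For each such TSS the
#' nearest in-frame ATG/GTG/TTG at or downstream of the TSS is proposed
#' as the corrected translation start; no proposal is made when none
#' exists before the midpoint of the CDS.
#'
#' @param records classified TSS records.
#' @param annotation a [genome_annotation()].
#' @param genome named character vector (from [read_fasta_genome()]).
#' @return data frame with feature_id, tss_position, old_tls,
#'   proposed_tls.
#' @export
propose_tls_corrections <- function(records, annotation, genome) {
  seqchar <- genome[[annotation$replicon_id]]
  if (is.null(seqchar)) seqchar <- genome[[1]]
  rec <- records[records$class == "intragenic", , drop = FALSE]
  out <- list()
  f <- annotation$features
  starts3 <- c("ATG", "GTG", "TTG")
  for (i in seq_len(nrow(rec))) {
    p <- rec$position[i]; s <- rec$strand[i]
    fid <- rec$assigned_feature[i]
    g <- f[f$feature_id == fid, , drop = FALSE]
    if (nrow(g) == 0) next
    len <- g$end - g$start + 1L
    if (s == "+") {
      if (!(p - g$start < len / 2)) next
      mid <- g$start + floor(len / 2)    # proposal must begin before the midpoint
      q <- p + (g$start - p) %% 3L
      prop <- NA_integer_
      while (q < mid) {
        cod <- substr(seqchar, q, q + 2L)
        if (cod %in% starts3) { prop <- q; break }
        q <- q + 3L
      }
      old <- g$start
    } else {
      if (!(g$end - p < len / 2)) next
      mid <- g$end - floor(len / 2)
      q <- p - (p - g$end) %% 3L
      prop <- NA_integer_
      while (q > mid) {
        cod <- .revcomp(substr(seqchar, q - 2L, q))
        if (cod %in% starts3) { prop <- q; break }
        q <- q - 3L
      }
      old <- g$end
    }
    if (!is.na(prop))
      out[[length(out) + 1L]] <- data.frame(feature_id = fid, tss_position = p,
                                            old_tls = old, proposed_tls = prop,
                                            stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(feature_id = character(), tss_position = integer(),
               old_tls = integer(), proposed_tls = integer(),
               stringsAsFactors = FALSE)
}

#' 5'-UTR length statistics
#'
#' Median (defined as the lower of the two central values for an even
#' number of observations), a histogram in 5-nt bins (1-5, 6-10, ...,
#' 496-500, plus a final >500 bin) and the count of near-leaderless
#' transcripts (5'-UTR shorter than 10 nt).
#'
#' @param records classified TSS records (utr class), or an integer
#'   vector of 5'-UTR lengths.
#' @return object of class `utr_stats`: list with `lengths`, `median`,
#'   `histogram` (data frame bin/lower/upper/count) and
#'   `leaderless_count`.
#' @export
compute_utr_stats <- function(records) {
  lengths <- if (is.data.frame(records)) {
    records$utr_length[records$class == "utr" & !is.na(records$utr_length)]
  } else as.integer(records)
  n <- length(lengths)
  med <- if (n == 0) NA_integer_ else {
    sl <- sort(lengths)
    if (n %% 2 == 1) sl[(n + 1) / 2] else sl[n / 2]
  }
  lower <- seq(1L, 496L, by = 5L); upper <- lower + 4L
  bins <- data.frame(bin = sprintf("%d-%d", lower, upper), lower = lower, upper = upper,
                     stringsAsFactors = FALSE)
  bins <- rbind(bins, data.frame(bin = ">500", lower = 501L, upper = NA_integer_))
  idx <- pmin(pmax(ceiling(lengths / 5), 1L), 101L)
  idx[lengths > 500L] <- 101L
  bins$count <- as.integer(tabulate(idx, nbins = 101L))
  structure(list(lengths = lengths, median = med, histogram = bins,
                 leaderless_count = sum(lengths < 10L)),
            class = "utr_stats")
}

#' @export
print.utr_stats <- function(x, ...) {
  cat(sprintf("utr_stats: n=%d, median=%s nt, <10 nt: %d\n",
              length(x$lengths), x$median, x$leaderless_count))
  invisible(x)
}

#' Estimate 3'-UTRs from whole-transcriptome coverage
#'
#' Extends each gene 3' end downstream while coverage stays >= 1,
#' tolerating gaps up to `max_gap` nt, capped at `max_extension`.
#'
#' @param annotation a [genome_annotation()].
#' @param coverage a `stranded_coverage`.
#' @param max_gap maximal uncovered gap in nt.
#' @param max_extension cap on the extension length.
#' @return data frame feature_id, start, end, strand of the extensions
#'   (genes with zero extension are omitted).
#' @export
estimate_three_prime_utrs <- function(annotation, coverage, max_gap = 5,
                                      max_extension = 300) {
  f <- annotation$features[annotation$features$feature_type == "CDS", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(f))) {
    s <- f$strand[i]
    from <- if (s == "+") f$end[i] + 1L else f$start[i] - 1L
    ext <- .extend_coverage(from, s, coverage, max_gap, max_extension,
                            anchored = FALSE)
    if (is.na(ext) || ext == 0L) next
    if (s == "+") {
      out[[length(out) + 1L]] <- data.frame(feature_id = f$feature_id[i],
                                            start = from, end = from + ext - 1L,
                                            strand = s, stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1L]] <- data.frame(feature_id = f$feature_id[i],
                                            start = from - ext + 1L, end = from,
                                            strand = s, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(feature_id = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)
}

# walk downstream from `from` (inclusive) while covered, tolerating
# uncovered runs of <= max_gap; returns the covered run length ending at
# the last covered position (0 if `from` region is bare). When anchored,
# the start position counts as covered (a TSS implies a transcript).
.extend_coverage <- function(from, strand, coverage, max_gap, max_len,
                             anchored = TRUE) {
  step <- if (strand == "+") 1L else -1L
  pos <- from
  last_cov <- if (anchored) from else NA_integer_
  gap <- 0L
  n <- 0L
  while (n < max_len) {
    if (pos < 1L || pos > coverage$length) break
    covd <- coverage_at(coverage, pos, strand) >= 1L
    if (covd) { last_cov <- pos; gap <- 0L }
    else {
      gap <- gap + 1L
      if (gap > max_gap) break
    }
    pos <- pos + step
    n <- n + 1L
  }
  if (is.na(last_cov)) return(0L)
  abs(last_cov - from) + 1L
}

#' Delineate novel transcripts and their 3' ends
#'
#' For TSSs of the intergenic, intragenic or antisense classes, extends
#' downstream from the TSS while whole-transcriptome coverage is >= 1
#' (gaps up to `max_gap` nt allowed) and emits a transcript when the
#' resulting length exceeds `min_len`. Antisense transcripts get a
#' subtype from their overlap geometry with the opposite-strand gene
#' (CDS only, UTR only, or both).
#'
#' @param records classified TSS records.
#' @param coverage a `stranded_coverage` from the whole-transcriptome
#'   library.
#' @param annotation a [genome_annotation()].
#' @param min_len minimal transcript length to report (default 20 nt;
#'   the emitted transcript must be strictly longer).
#' @param max_gap maximal uncovered gap in nt while extending.
#' @param max_len cap on transcript length during extension.
#' @param utr_regions optional detected 5'-UTR intervals for the
#'   antisense subtype.
#' @return data frame tss_position, strand, start, end, length,
#'   category, antisense_subtype.
#' @export
delineate_novel_transcripts <- function(records, coverage, annotation,
                                        min_len = 20, max_gap = 5,
                                        max_len = 5000, utr_regions = NULL) {
  rec <- records[records$class %in% c("intergenic", "intragenic", "antisense"), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(rec))) {
    p <- rec$position[i]; s <- rec$strand[i]
    len <- .extend_coverage(p, s, coverage, max_gap, max_len, anchored = TRUE)
    if (len <= min_len) next
    st <- if (s == "+") p else p - len + 1L
    en <- if (s == "+") p + len - 1L else p
    category <- switch(rec$class[i], intergenic = "intergenic",
                       intragenic = "intragenic_sense", antisense = "antisense")
    subtype <- NA_character_
    if (category == "antisense") {
      opp <- if (s == "+") "-" else "+"
      f_opp <- annotation$features[annotation$features$strand == opp, , drop = FALSE]
      cds_hit <- nrow(f_opp) > 0 &&
        any(f_opp$start <= en & f_opp$end >= st)
      utr_hit <- FALSE
      if (!is.null(utr_regions)) {
        u <- utr_regions[utr_regions$strand == opp, , drop = FALSE]
        utr_hit <- nrow(u) > 0 && any(u$start <= en & u$end >= st)
      }
      subtype <- if (cds_hit && utr_hit) "cds_and_utr_overlap"
      else if (cds_hit) "cds_overlap"
      else if (utr_hit) "utr_overlap"
      else NA_character_
    }
    out[[length(out) + 1L]] <- data.frame(
      tss_position = p, strand = s, start = st, end = en, length = len,
      category = category, antisense_subtype = subtype, stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(tss_position = integer(), strand = character(), start = integer(),
               end = integer(), length = integer(), category = character(),
               antisense_subtype = character(), stringsAsFactors = FALSE)
}
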