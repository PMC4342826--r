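#' Operon inference parameters
#'
#' @param bridge_threshold minimal number of paired fragments bridging
#'   an intergenic junction for the two genes to be joined (default 4).
#' @param functional_rescue_margin fragment deficit tolerated when both
#'   genes share a functional label.
#' @return object of class `operon_params`.
#' @export
operon_params <- function(bridge_threshold = 4, functional_rescue_margin = 1) {
  stopifnot(bridge_threshold >= 1, functional_rescue_margin >= 0)
  structure(list(bridge_threshold = bridge_threshold,
                 functional_rescue_margin = functional_rescue_margin),
            class = "operon_params")
}

# bridging support for each adjacent same-strand gene pair: fragments on
# the genes' strand covering both the upstream gene's last base and the
# downstream gene's first base (genomically: left gene end, right gene
# start). Returns a junction table in genomic order per strand.
.junction_support <- function(annotation, fragments) {
  f <- annotation$features[annotation$features$feature_type == "CDS", , drop = FALSE]
  out <- list()
  for (s in c("+", "-")) {
    g <- f[f$strand == s, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) < 2) next
    left <- g[-nrow(g), , drop = FALSE]; right <- g[-1, , drop = FALSE]
    fs <- fragments[fragments$strand == s, , drop = FALSE]
    jpoint_s <- pmin(left$end, right$start)       # overlapping genes: junction point
    jpoint_e <- pmax(left$end, right$start)
    supp <- if (nrow(fs)) {
      jr <- IRanges::IRanges(start = jpoint_s, end = jpoint_e)
      fr <- IRanges::IRanges(start = fs$start, end = fs$end)
      IRanges::countOverlaps(jr, fr, type = "within")
    } else integer(nrow(left))
    out[[s]] <- data.frame(strand = s, left_gene = left$feature_id,
                           right_gene = right$feature_id,
                           left_end = left$end, right_start = right$start,
                           support = as.integer(supp), stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(strand = character(), left_gene = character(),
               right_gene = character(), left_end = integer(),
               right_start = integer(), support = integer(),
               stringsAsFactors = FALSE)
}

#' Infer primary operons from paired-fragment bridging
#'
#' Adjacent same-strand genes are joined when at least
#' `bridge_threshold` paired fragments bridge their intergenic region
#' (cover the last base of the upstream gene and the first base of the
#' downstream gene); transitive joining yields maximal chains — the
#' primary operons, with members ordered in transcription direction.
#' Genes in no chain are monocistronic when at least one fragment
#' overlaps them and untranscribed otherwise. Intervening opposite-
#' strand genes neither bridge nor break a chain. When `functional_labels`
#' is supplied, junctions one fragment short of the threshold are
#' additionally joined if both genes share a label (flagged as rescued).
#'
#' @param annotation a [genome_annotation()].
#' @param fragments paired-fragment data frame (start, end, strand).
#' @param params an [operon_params()].
#' @param functional_labels optional data frame (gene_id, label).
#' @return list with `operons` (list of operon objects: members,
#'   strand, junction_support, rescued, suboperons), `monocistronic`,
#'   `untranscribed` (character vectors of gene ids) and `junctions`
#'   (the support table).
#' @export
infer_primary_operons <- function(annotation, fragments, params = operon_params(),
                                  functional_labels = NULL) {
  if (is.null(fragments) || nrow(fragments) == 0)
    fragments <- data.frame(replicon = character(), start = integer(),
                            end = integer(), strand = character(),
                            stringsAsFactors = FALSE)
  jn <- .junction_support(annotation, fragments)
  jn$joined <- jn$support >= params$bridge_threshold
  jn$rescued <- FALSE
  if (!is.null(functional_labels) && nrow(jn)) {
    resc <- rescue_functional_pairs(jn, functional_labels, params)
    if (nrow(resc)) {
      key <- paste(jn$left_gene, jn$right_gene)
      hit <- key %in% paste(resc$left_gene, resc$right_gene)
      jn$joined[hit] <- TRUE
      jn$rescued[hit] <- TRUE
    }
  }

  f <- annotation$features[annotation$features$feature_type == "CDS", , drop = FALSE]
  operons <- list()
  in_operon <- character(0)
  for (s in c("+", "-")) {
    g <- f[f$strand == s, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) == 0) next
    j <- jn[jn$strand == s, , drop = FALSE]
    joined <- if (nrow(j)) j$joined else logical(0)
    grp <- cumsum(c(TRUE, !joined))          # chain id per gene in genomic order
    for (gr in unique(grp)) {
      idx <- which(grp == gr)
      if (length(idx) < 2) next
      members <- g$feature_id[idx]
      supp <- j$support[idx[-length(idx)]]
      resc <- j$rescued[idx[-length(idx)]]
      if (s == "-") {                        # transcription order: right to left
        members <- rev(members); supp <- rev(supp); resc <- rev(resc)
      }
      operons[[length(operons) + 1L]] <- list(
        members = members, strand = s, junction_support = supp,
        rescued = resc, primary_tss = NULL, suboperons = list())
      in_operon <- c(in_operon, members)
    }
  }

  # transcription evidence for the remaining genes
  solo <- setdiff(f$feature_id, in_operon)
  solo_f <- f[match(solo, f$feature_id), , drop = FALSE]
  n_over <- if (nrow(fragments) && nrow(solo_f)) {
    gr <- IRanges::IRanges(start = solo_f$start, end = solo_f$end)
    ov <- integer(nrow(solo_f))
    for (s in c("+", "-")) {
      fs <- fragments[fragments$strand == s, , drop = FALSE]
      sel <- solo_f$strand == s
      if (any(sel) && nrow(fs))
        ov[sel] <- IRanges::countOverlaps(gr[sel], IRanges::IRanges(fs$start, fs$end))
    }
    ov
  } else integer(nrow(solo_f))
  list(operons = operons,
       monocistronic = solo[n_over >= 1L],
       untranscribed = solo[n_over < 1L],
       junctions = jn)
}

#' Rescue functionally related gene pairs
#'
#' Junctions whose support equals `bridge_threshold -
#' functional_rescue_margin` are joined when both genes carry the same
#' functional label; such joins are flagged in the output.
#'
#' @param junctions junction table from [infer_primary_operons()] (or
#'   its `.junction_support` shape).
#' @param functional_labels data frame with columns gene_id, label.
#' @param params an [operon_params()].
#' @return subset of `junctions` that qualifies for the rescue.
#' @export
rescue_functional_pairs <- function(junctions, functional_labels,
                                    params = operon_params()) {
  need <- params$bridge_threshold - params$functional_rescue_margin
  lab <- stats::setNames(functional_labels$label, functional_labels$gene_id)
  ok <- junctions$support == need &
    !is.na(lab[junctions$left_gene]) & !is.na(lab[junctions$right_gene]) &
    lab[junctions$left_gene] == lab[junctions$right_gene]
  out <- junctions[which(ok), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call suboperons from internal TSSs
#'
#' For each utr-class TSS assigned to a non-first member gene of a
#' primary operon, adds the suboperon running from that gene through the
#' operon's last gene (a suffix of the member list in transcription
#' order).
#'
#' @param operon_set result of [infer_primary_operons()].
#' @param tss_records classified TSS records (see [annotate_tss()]).
#' @return `operon_set` with `suboperons` filled in (list of lists with
#'   `first_gene`, `members`, `tss_position`) and `primary_tss` set when
#'   a utr-class TSS exists for the first gene.
#' @export
call_suboperons <- function(operon_set, tss_records) {
  utr <- tss_records[tss_records$class == "utr", , drop = FALSE]
  for (i in seq_along(operon_set$operons)) {
    op <- operon_set$operons[[i]]
    first_tss <- utr[utr$assigned_feature == op$members[1], , drop = FALSE]
    if (nrow(first_tss))
      op$primary_tss <- first_tss$position[which.max(first_tss$read_starts)]
    subs <- list()
    inner <- op$members[-1]
    hit_genes <- unique(utr$assigned_feature[utr$assigned_feature %in% inner])
    for (gid in hit_genes) {
      k <- match(gid, op$members)
      tssp <- utr$position[utr$assigned_feature == gid][1]
      subs[[length(subs) + 1L]] <- list(first_gene = gid,
                                        members = op$members[k:length(op$members)],
                                        tss_position = tssp)
    }
    # order suboperons by position of their first gene along the operon
    if (length(subs) > 1) {
      ord <- order(vapply(subs, function(x) match(x$first_gene, op$members), 1L))
      subs <- subs[ord]
    }
    op$suboperons <- subs
    operon_set$operons[[i]] <- op
  }
  operon_set
}

#' Summarize transcript organization
#'
#' @param operon_set result of [infer_primary_operons()] (after
#'   [call_suboperons()] if suboperon counts are wanted).
#' @param annotation a [genome_annotation()].
#' @return list with counts (monocistronic genes, operons, suboperons,
#'   genes in operons, untranscribed genes), the operon size histogram
#'   (table) and the percentage of annotated genes with any transcript
#'   (1 decimal, half away from zero).
#' @export
summarize_organization <- function(operon_set, annotation) {
  ops <- operon_set$operons
  sizes <- vapply(ops, function(o) length(o$members), 1L)
  n_sub <- sum(vapply(ops, function(o) length(o$suboperons), 1L))
  n_in_op <- sum(sizes)
  n_mono <- length(operon_set$monocistronic)
  n_genes <- nrow(annotation$features)
  transcribed <- n_mono + n_in_op
  list(monocistronic = n_mono,
       operons = length(ops),
       suboperons = n_sub,
       genes_in_operons = n_in_op,
       untranscribed = length(operon_set$untranscribed),
       size_histogram = if (length(sizes)) table(sizes) else table(integer()),
       n_annotated = n_genes,
       pct_transcribed = if (n_genes > 0) percent(transcribed, n_genes) else NA_real_)
}

#' Write an operon set to TSV
#'
#' @param operon_set result of [infer_primary_operons()].
#' @param path output path for the operon table.
#' @return `path`, invisibly.
#' @export
write_operons <- function(operon_set, path) {
  ops <- operon_set$operons
  d <- data.frame(
    operon_id = sprintf("operon_%03d", seq_along(ops)),
    strand = vapply(ops, `[[`, "", "strand"),
    n_genes = vapply(ops, function(o) length(o$members), 1L),
    members = vapply(ops, function(o) paste(o$members, collapse = ","), ""),
    junction_support = vapply(ops, function(o) paste(o$junction_support, collapse = ","), ""),
    rescued = vapply(ops, function(o) paste(as.integer(o$rescued), collapse = ","), ""),
    primary_tss = vapply(ops, function(o) if (is.null(o$primary_tss)) NA_integer_ else o$primary_tss, 1L),
    n_suboperons = vapply(ops, function(o) length(o$suboperons), 1L),
    stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
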