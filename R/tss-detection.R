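#' TSS detection parameters
#'
#' @param T background threshold: a candidate needs more than `T` read
#'   starts (strict).
#' @param R ratio threshold: read starts at the candidate divided by
#'   read starts at the previous position (in transcription direction)
#'   must exceed `R` (strict); a zero previous count passes.
#' @param X maximal distance in nt from the TSS to the next downstream
#'   same-strand translation start.
#' @param rescue_margin maximal read deficit (on exactly one of the
#'   `T`/`R` criteria) for which a candidate may be rescued by
#'   whole-transcriptome support.
#' @param fp_window window width in nt used by the false-positive
#'   heuristic.
#' @param fp_peak_fraction a candidate inside a window whose maximum is
#'   more than `1/fp_peak_fraction` times larger is suspect.
#' @param min_whole_tx_support minimal whole-transcriptome coverage at
#'   each of the first 20 nt downstream for a rescue.
#' @return object of class `tss_params`.
#' @export
tss_params <- function(T = 6, R = 6, X = 500, rescue_margin = 1,
                       fp_window = 50, fp_peak_fraction = 0.5,
                       min_whole_tx_support = 1) {
  stopifnot(T >= 0, R > 0, X > 0, rescue_margin >= 0,
            fp_window > 0, fp_peak_fraction > 0, fp_peak_fraction <= 1)
  structure(list(T = T, R = R, X = X, rescue_margin = rescue_margin,
                 fp_window = fp_window, fp_peak_fraction = fp_peak_fraction,
                 min_whole_tx_support = min_whole_tx_support),
            class = "tss_params")
}

# distance (in transcription direction) from each position to the next
# downstream same-strand feature start; returns list(dist, feature_id)
# with NA where no downstream feature exists. `types` filters features.
.next_tls <- function(positions, strand, annotation, types = "CDS") {
  f <- annotation$features
  f <- f[f$strand == strand & f$feature_type %in% types, , drop = FALSE]
  n <- length(positions)
  if (nrow(f) == 0)
    return(list(dist = rep(NA_integer_, n), feature_id = rep(NA_character_, n)))
  if (strand == "+") {
    tls <- f$start; ord <- order(tls)
    tls <- tls[ord]; ids <- f$feature_id[ord]
    idx <- findInterval(positions - 1L, tls) + 1L   # first tls >= position
    ok <- idx <= length(tls)
    dist <- rep(NA_integer_, n); fid <- rep(NA_character_, n)
    dist[ok] <- tls[idx[ok]] - positions[ok]
    fid[ok] <- ids[idx[ok]]
  } else {
    tls <- f$end; ord <- order(tls)
    tls <- tls[ord]; ids <- f$feature_id[ord]
    idx <- findInterval(positions, tls)             # last tls <= position
    ok <- idx >= 1L
    dist <- rep(NA_integer_, n); fid <- rep(NA_character_, n)
    dist[ok] <- positions[ok] - tls[idx[ok]]
    fid[ok] <- ids[idx[ok]]
  }
  list(dist = dist, feature_id = fid)
}

#' Detect TSS candidates from a 5'-enriched read-start profile
#'
#' A position is a candidate when (a) its read-start count exceeds `T`
#' and (b) the ratio to the previous position in transcription direction
#' exceeds `R` (a previous count of zero passes, being the sharpest
#' possible accumulation). Criterion (c) — a same-strand protein-coding
#' translation start within `X` nt downstream — is evaluated and
#' recorded in the `tls_within_X` column; candidates failing it are
#' retained for the novel-transcript path rather than dropped.
#'
#' @param profile [read_start_profile()] from the 5'-enriched library.
#' @param annotation a [genome_annotation()].
#' @param params a [tss_params()].
#' @return data frame of candidates with columns replicon, position,
#'   strand, read_starts, prev_read_starts, ratio, tls_feature,
#'   tls_distance, tls_within_X, detection_mode.
#' @export
detect_candidates <- function(profile, annotation, params = tss_params()) {
  if (profile$replicon_id != annotation$replicon_id)
    stop(sprintf("profile replicon '%s' does not match annotation replicon '%s'",
                 profile$replicon_id, annotation$replicon_id))
  out <- list()
  for (s in c("+", "-")) {
    st <- profile$starts[profile$starts$strand == s, , drop = FALSE]
    if (nrow(st) == 0) next
    prev_pos <- if (s == "+") st$position - 1L else st$position + 1L
    prev <- st$count[match(prev_pos, st$position)]
    prev[is.na(prev)] <- 0L
    ratio <- ifelse(prev == 0L, Inf, st$count / prev)
    pass <- st$count > params$T & ratio > params$R
    if (!any(pass)) next
    st <- st[pass, , drop = FALSE]; prev <- prev[pass]; ratio <- ratio[pass]
    tl <- .next_tls(st$position, s, annotation, types = "CDS")
    out[[s]] <- data.frame(
      replicon = profile$replicon_id, position = st$position, strand = s,
      read_starts = st$count, prev_read_starts = prev, ratio = ratio,
      tls_feature = tl$feature_id, tls_distance = tl$dist,
      tls_within_X = !is.na(tl$dist) & tl$dist <= params$X,
      detection_mode = "automatic", stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(replicon = character(), position = integer(), strand = character(),
               read_starts = integer(), prev_read_starts = integer(), ratio = double(),
               tls_feature = character(), tls_distance = integer(),
               tls_within_X = logical(), detection_mode = character(),
               stringsAsFactors = FALSE)
  res <- res[order(res$position, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Near misses of the automatic TSS criteria
#'
#' Positions with at least one read start that fail exactly one of the
#' background (`T`) or ratio (`R`) criteria by at most `rescue_margin`
#' reads; candidates for [rescue_candidates()].
#'
#' @inheritParams detect_candidates
#' @return candidate-style data frame with a `failed` column
#'   (`"T"` or `"R"`).
#' @export
find_near_misses <- function(profile, annotation, params = tss_params()) {
  out <- list()
  m <- params$rescue_margin
  for (s in c("+", "-")) {
    st <- profile$starts[profile$starts$strand == s, , drop = FALSE]
    if (nrow(st) == 0) next
    prev_pos <- if (s == "+") st$position - 1L else st$position + 1L
    prev <- st$count[match(prev_pos, st$position)]
    prev[is.na(prev)] <- 0L
    ratio <- ifelse(prev == 0L, Inf, st$count / prev)
    pass_a <- st$count > params$T
    pass_b <- ratio > params$R
    # deficit in reads to reach passing
    need_a <- floor(params$T) + 1L - st$count          # reads missing for (a)
    need_b <- ifelse(prev == 0L, 0L, floor(params$R * prev) + 1L - st$count)
    miss_a <- !pass_a & pass_b & need_a <= m
    miss_b <- pass_a & !pass_b & need_b <= m
    sel <- miss_a | miss_b
    if (!any(sel)) next
    st2 <- st[sel, , drop = FALSE]
    tl <- .next_tls(st2$position, s, annotation, types = "CDS")
    out[[s]] <- data.frame(
      replicon = profile$replicon_id, position = st2$position, strand = s,
      read_starts = st2$count, prev_read_starts = prev[sel], ratio = ratio[sel],
      tls_feature = tl$feature_id, tls_distance = tl$dist,
      tls_within_X = !is.na(tl$dist) & tl$dist <= params$X,
      detection_mode = "near_miss",
      failed = ifelse(miss_a[sel], "T", "R"), stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(replicon = character(), position = integer(), strand = character(),
               read_starts = integer(), prev_read_starts = integer(), ratio = double(),
               tls_feature = character(), tls_distance = integer(),
               tls_within_X = logical(), detection_mode = character(),
               failed = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Rescue near-miss candidates with whole-transcriptome support
#'
#' A near miss is rescued when the whole-transcriptome coverage is at
#' least `min_whole_tx_support` at each of the 20 positions starting at
#' the putative TSS and extending downstream, confirming a transcript.
#'
#' @param near_misses data frame from [find_near_misses()].
#' @param profile the 5'-enriched [read_start_profile()] (carried along
#'   for bookkeeping; counts already live in `near_misses`).
#' @param whole_coverage a `stranded_coverage` from the whole-
#'   transcriptome library ([fragment_coverage()] or
#'   [profile_as_coverage()]).
#' @param params a [tss_params()].
#' @return data frame of rescued candidates (`detection_mode =
#'   "rescued"`).
#' @export
rescue_candidates <- function(near_misses, profile, whole_coverage,
                              params = tss_params()) {
  if (nrow(near_misses) == 0) return(near_misses[, setdiff(names(near_misses), "failed")])
  ok <- logical(nrow(near_misses))
  for (i in seq_len(nrow(near_misses))) {
    p <- near_misses$position[i]; s <- near_misses$strand[i]
    down <- if (s == "+") p:(p + 19L) else p:(p - 19L)
    cov <- coverage_at(whole_coverage, down, s)
    ok[i] <- all(cov >= params$min_whole_tx_support)
  }
  res <- near_misses[ok, setdiff(names(near_misses), "failed"), drop = FALSE]
  res$detection_mode <- if (nrow(res)) "rescued" else character()
  rownames(res) <- NULL
  res
}

#' Flag false-positive candidates inside uneven read-start gradients
#'
#' Operationalizes the rule that a candidate without a clear isolated
#' accumulation, sitting inside a gradient of accumulated read starts,
#' is a false positive: flagged iff its count is below
#' `fp_peak_fraction` times the window maximum and at least three other
#' positions in the window also exceed the background threshold `T`.
#'
#' @param candidates data frame from [detect_candidates()].
#' @inheritParams detect_candidates
#' @return `candidates` with a logical `false_positive` column.
#' @export
flag_false_positives <- function(candidates, profile, params = tss_params()) {
  if (nrow(candidates) == 0) { candidates$false_positive <- logical(); return(candidates) }
  half <- floor(params$fp_window / 2)
  flag <- logical(nrow(candidates))
  for (s in c("+", "-")) {
    idx <- which(candidates$strand == s)
    if (!length(idx)) next
    st <- profile$starts[profile$starts$strand == s, , drop = FALSE]
    for (i in idx) {
      p <- candidates$position[i]
      w <- st[st$position >= p - half & st$position <= p + half, , drop = FALSE]
      wmax <- max(w$count, candidates$read_starts[i])
      n_other <- sum(w$count > params$T & w$position != p)
      flag[i] <- candidates$read_starts[i] < params$fp_peak_fraction * wmax &&
        n_other >= 3L
    }
  }
  candidates$false_positive <- flag
  candidates
}

#' Remove TSSs that belong to stable RNA genes
#'
#' A candidate is removed when the nearest downstream same-strand
#' feature within `X` nt is an rRNA or tRNA gene.
#'
#' @inheritParams flag_false_positives
#' @param annotation a [genome_annotation()] including rRNA/tRNA
#'   features.
#' @return list with `kept` (data frame), `removed` (data frame) and
#'   `removed_count`.
#' @export
drop_stable_rna_tss <- function(candidates, annotation, params = tss_params()) {
  if (nrow(candidates) == 0)
    return(list(kept = candidates, removed = candidates, removed_count = 0L))
  is_stable <- logical(nrow(candidates))
  for (s in c("+", "-")) {
    idx <- which(candidates$strand == s)
    if (!length(idx)) next
    tl <- .next_tls(candidates$position[idx], s, annotation,
                    types = c("CDS", "rRNA", "tRNA", "sRNA"))
    f <- annotation$features
    type <- f$feature_type[match(tl$feature_id, f$feature_id)]
    is_stable[idx] <- !is.na(tl$dist) & tl$dist <= params$X &
      type %in% c("rRNA", "tRNA")
  }
  list(kept = candidates[!is_stable, , drop = FALSE],
       removed = candidates[is_stable, , drop = FALSE],
       removed_count = sum(is_stable))
}

#' Full TSS calling pipeline
#'
#' Runs automatic detection, the false-positive heuristic, stable-RNA
#' removal and (when whole-transcriptome coverage is supplied) the
#' rescue of near misses, and returns the verified set together with the
#' bookkeeping of every removal and addition, satisfying
#' automatic - false_positive - stable_rna + rescued = final.
#'
#' @inheritParams detect_candidates
#' @param whole_coverage optional `stranded_coverage` for rescues.
#' @return list with `final` (verified candidates), `automatic`,
#'   `rescued`, `false_positive`, `stable_rna` data frames and a
#'   `summary` vector of counts.
#' @export
call_tss <- function(profile, annotation, whole_coverage = NULL,
                     params = tss_params()) {
  auto <- detect_candidates(profile, annotation, params)
  auto <- flag_false_positives(auto, profile, params)
  fps <- auto[auto$false_positive, , drop = FALSE]
  kept <- auto[!auto$false_positive, , drop = FALSE]
  sr <- drop_stable_rna_tss(kept, annotation, params)
  kept <- sr$kept
  rescued <- kept[0, setdiff(names(kept), "false_positive"), drop = FALSE]
  if (!is.null(whole_coverage)) {
    nm <- find_near_misses(profile, annotation, params)
    rescued <- rescue_candidates(nm, profile, whole_coverage, params)
    if (nrow(rescued)) {
      srr <- drop_stable_rna_tss(rescued, annotation, params)
      rescued <- srr$kept
    }
  }
  final <- rbind(kept[, setdiff(names(kept), "false_positive"), drop = FALSE], rescued)
  final <- final[order(final$position, final$strand), , drop = FALSE]
  rownames(final) <- NULL
  list(final = final, automatic = auto, rescued = rescued,
       false_positive = fps, stable_rna = sr$removed,
       summary = c(automatic = nrow(auto), false_positive = nrow(fps),
                   stable_rna = sr$removed_count, rescued = nrow(rescued),
                   final = nrow(final)))
}
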