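#' Abundance parameters
#'
#' Class boundaries on the final log-RPKM value; half-open,
#' lower-exclusive intervals: low (0, 16], middle (16, 160],
#' high (160, 1600], very_high (1600, Inf). A value of exactly 0 means
#' untranscribed.
#'
#' @param boundaries strictly increasing named vector of upper bounds
#'   for low, middle and high.
#' @param stranded count only read starts on the feature's strand
#'   (default); set FALSE for unstranded data.
#' @return object of class `abundance_params`.
#' @export
abundance_params <- function(boundaries = c(low = 16, middle = 160, high = 1600),
                             stranded = TRUE) {
  stopifnot(length(boundaries) == 3, all(diff(boundaries) > 0), all(boundaries > 0))
  structure(list(boundaries = boundaries, stranded = stranded),
            class = "abundance_params")
}

#' Geometric-mean normalized abundance (log-RPKM) of one feature
#'
#' Over the N feature positions carrying at least one read start, the
#' arithmetic mean x_bar of the natural logarithms of the per-position
#' read-start counts is taken; R_norm = exp(x_bar) * N (the geometric
#' mean count times the number of covered positions) is the normalized
#' read count, which is then scaled by feature length in kb and mapped
#' reads in millions like an ordinary RPKM. Positions with zero reads
#' contribute neither to x_bar nor to N, so log(0) never arises.
#'
#' @param feature one-row data frame (or list) with feature_id, start,
#'   end, strand.
#' @param profile whole-transcriptome [read_start_profile()].
#' @param total_mapped mapped-read total used for the per-million
#'   scaling; defaults to the profile's `total_mapped`.
#' @param params an [abundance_params()].
#' @return one-row data frame feature_id, N, x_bar, R_norm, value,
#'   class.
#' @export
log_rpkm <- function(feature, profile, total_mapped = NULL,
                     params = abundance_params()) {
  if (is.null(total_mapped)) total_mapped <- profile$total_mapped
  if (is.null(total_mapped) || total_mapped <= 0)
    stop("total_mapped must be > 0")
  if (!is.na(profile$replicon_length) &&
      (feature$start < 1L || feature$end > profile$replicon_length))
    stop("feature outside replicon")
  st <- profile$starts
  sel <- st$position >= feature$start & st$position <= feature$end
  if (params$stranded) sel <- sel & st$strand == feature$strand
  counts <- st$count[sel]
  N <- length(counts)
  if (N == 0L) {
    x_bar <- NA_real_; R_norm <- 0; value <- 0
  } else {
    x_bar <- mean(log(counts))
    R_norm <- exp(x_bar) * N
    len_kb <- (feature$end - feature$start + 1L) / 1000
    value <- R_norm / (len_kb * total_mapped / 1e6)
  }
  data.frame(feature_id = feature$feature_id, N = N, x_bar = x_bar,
             R_norm = R_norm, value = value,
             class = classify_abundance(value, params),
             stringsAsFactors = FALSE)
}

#' Classify a log-RPKM value into an abundance class
#'
#' Boundaries are lower-exclusive: a value of exactly 16 is low, 1600 is
#' high, anything above 1600 is very_high; 0 is untranscribed.
#'
#' @param value non-negative log-RPKM value(s).
#' @param params an [abundance_params()].
#' @return character vector of classes.
#' @export
#' @examples
#' classify_abundance(c(0, 16, 16.5, 1600, 12308))
classify_abundance <- function(value, params = abundance_params()) {
  stopifnot(all(value >= 0))
  b <- params$boundaries
  out <- rep("untranscribed", length(value))
  out[value > 0 & value <= b[1]] <- "low"
  out[value > b[1] & value <= b[2]] <- "middle"
  out[value > b[2] & value <= b[3]] <- "high"
  out[value > b[3]] <- "very_high"
  out
}

#' Abundance table for all annotated features
#'
#' @param annotation a [genome_annotation()].
#' @param profile whole-transcriptome [read_start_profile()].
#' @param params an [abundance_params()].
#' @param total_mapped see [log_rpkm()].
#' @return list with `records` (one row per feature) and `tally`
#'   (class counts with one-decimal percentages), plus
#'   `pct_detected` — the percentage of features with any transcript.
#' @export
abundance_table <- function(annotation, profile, params = abundance_params(),
                            total_mapped = NULL) {
  f <- annotation$features
  rows <- lapply(seq_len(nrow(f)), function(i)
    log_rpkm(f[i, ], profile, total_mapped = total_mapped, params = params))
  records <- do.call(rbind, rows)
  lev <- c("untranscribed", "low", "middle", "high", "very_high")
  tb <- table(factor(records$class, levels = lev))
  tally <- data.frame(class = names(tb), count = as.integer(tb),
                      percent = if (sum(tb) > 0) percent(as.integer(tb), sum(tb)) else NA_real_,
                      stringsAsFactors = FALSE)
  detected <- sum(records$class != "untranscribed")
  list(records = records,
       tally = tally,
       n_detected = detected,
       pct_detected = if (nrow(records) > 0) percent(detected, nrow(records)) else NA_real_)
}
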