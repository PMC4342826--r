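#' Extract upstream sequences for motif discovery
#'
#' Returns the `window` bases immediately upstream of each site on its
#' own strand (reverse-complemented for '-' sites), truncated at the
#' replicon edge.
#'
#' @param positions,strands site positions and strands.
#' @param genome named character vector of replicon sequences.
#' @param window window width in nt.
#' @param replicon_id replicon to use (default: first element).
#' @return character vector of upstream sequences.
#' @export
extract_upstream <- function(positions, strands, genome, window = 70,
                             replicon_id = NULL) {
  seqchar <- if (!is.null(replicon_id)) genome[[replicon_id]] else genome[[1]]
  L <- nchar(seqchar)
  n <- length(positions)
  out <- character(n)
  for (i in seq_len(n)) {
    p <- positions[i]
    if (strands[i] == "+") {
      a <- max(1L, p - window); b <- p - 1L
      out[i] <- if (b >= a) substr(seqchar, a, b) else ""
    } else {
      a <- p + 1L; b <- min(L, p + window)
      out[i] <- if (b >= a) .revcomp(substr(seqchar, a, b)) else ""
    }
  }
  out
}

#' Upstream sequences for RBS analysis
#'
#' One sequence per gene with an identified 5'-UTR longer than
#' `min_utr` nt: the `window` bases upstream of the translation start,
#' on the coding strand. Genes with several TSSs contribute once, via
#' their longest 5'-UTR record.
#'
#' @param records classified TSS records (utr class used).
#' @param annotation a [genome_annotation()].
#' @param genome named character vector of sequences.
#' @param window window width upstream of the TLS.
#' @param min_utr genes with 5'-UTR <= this length are excluded.
#' @return list with `sequences`, `gene_ids` and `utr_lengths`.
#' @export
rbs_upstream_sequences <- function(records, annotation, genome, window = 20,
                                   min_utr = 9) {
  rec <- records[records$class == "utr" & !is.na(records$utr_length), , drop = FALSE]
  if (nrow(rec) == 0) return(list(sequences = character(), gene_ids = character(),
                                  utr_lengths = integer()))
  # longest UTR per gene
  rec <- rec[order(rec$assigned_feature, -rec$utr_length), , drop = FALSE]
  rec <- rec[!duplicated(rec$assigned_feature), , drop = FALSE]
  rec <- rec[rec$utr_length > min_utr, , drop = FALSE]
  f <- annotation$features
  tls <- ifelse(rec$strand == "+",
                f$start[match(rec$assigned_feature, f$feature_id)],
                f$end[match(rec$assigned_feature, f$feature_id)])
  seqs <- extract_upstream(tls, rec$strand, genome, window = window)
  keep <- nchar(seqs) == window
  list(sequences = seqs[keep], gene_ids = rec$assigned_feature[keep],
       utr_lengths = rec$utr_length[keep])
}

# sequences -> integer matrix (A=1 C=2 G=3 T=4, NA for padding/ambiguity)
.seqs_to_matrix <- function(sequences) {
  lens <- nchar(sequences)
  Lmax <- max(lens)
  n <- length(sequences)
  X <- matrix(NA_integer_, n, Lmax)
  lut <- stats::setNames(1:4, c("A", "C", "G", "T"))
  for (i in seq_len(n)) {
    ch <- strsplit(toupper(sequences[i]), "")[[1]]
    X[i, seq_len(lens[i])] <- unname(lut[ch])
  }
  list(X = X, len = lens)
}

# one EM run from an initial pwm; returns model state and the trace of
# the (Dirichlet-penalized) objective, which EM increases monotonically.
# prior = "uniform": site offsets equiprobable within each sequence;
# prior = "right": a shared offset distribution indexed from the 3' end
# of each sequence is learned alongside the motif (appropriate for
# TSS- or TLS-anchored windows, where element-to-anchor spacing is the
# biologically constrained quantity).
# precompute the index structures the E/M steps reuse every iteration
.em_prepare <- function(X, len, width) {
  n <- nrow(X); Lmax <- ncol(X)
  mmax <- Lmax - width + 1L
  m <- pmax(len - width + 1L, 0L)
  valid <- outer(m, seq_len(mmax), ">=")       # offset j valid for seq i
  # distance from the sequence 3' end to the site end, 1-based index
  Didx <- outer(m, seq_len(mmax), "-") + 1L
  Didx[!valid] <- NA_integer_
  Xoff <- vector("list", width)                # lw linear indices per column
  Bidx <- vector("list", width)                # cell indices per base per column
  for (k in seq_len(width)) {
    Xk <- X[, k:(k + mmax - 1L), drop = FALSE]
    Xoff[[k]] <- Xk + (k - 1L) * 4L
    Bidx[[k]] <- lapply(1:4, function(b) which(!is.na(Xk) & Xk == b))
  }
  dvec <- as.vector(Didx); dok <- which(!is.na(dvec))
  list(n = n, mmax = mmax, m = m, valid = valid, Didx = Didx,
       Xoff = Xoff, Bidx = Bidx, dvec = dvec[dok], dok = dok,
       Wunif = sweep(valid + 0, 1, pmax(m, 1L), "/"))
}

.em_run <- function(prep, width, pwm, gamma, bg, pseudocount, tol, max_iter,
                    prior = "uniform") {
  n <- prep$n; mmax <- prep$mmax
  pi_d <- rep(1 / mmax, mmax)
  lbg <- log(bg)
  trace <- numeric(max_iter)
  obj_prev <- -Inf
  Z <- NULL
  nit <- 0L
  for (it in seq_len(max_iter)) {
    lw <- log(pwm) - lbg                        # 4 x width log-odds
    S <- matrix(0, n, mmax)
    for (k in seq_len(width)) {
      v <- lw[prep$Xoff[[k]]]
      v[is.na(v)] <- 0
      S <- S + matrix(v, n, mmax)
    }
    S[!prep$valid] <- -Inf
    A <- exp(S)
    W <- if (prior == "right") {
      w0 <- matrix(pi_d[prep$Didx], n, mmax)
      w0[is.na(w0)] <- 0
      w0 / pmax(rowSums(w0), .Machine$double.xmin)
    } else prep$Wunif
    AW <- A * W
    denom <- (1 - gamma) + gamma * rowSums(AW)
    Z <- AW * (gamma / denom)
    obj <- sum(log(denom)) + pseudocount * sum(log(pwm))
    nit <- it
    trace[it] <- obj
    # M-step
    C <- matrix(0, 4, width)
    for (k in seq_len(width))
      for (b in 1:4) C[b, k] <- sum(Z[prep$Bidx[[k]][[b]]])
    pwm_new <- sweep(C + pseudocount, 2, colSums(C + pseudocount), "/")
    gamma_new <- min(max(mean(pmin(rowSums(Z), 1)), 1e-4), 1 - 1e-4)
    if (prior == "right") {
      zd <- rowsum(Z[prep$dok], prep$dvec)
      pi_new <- rep(0, mmax)
      pi_new[as.integer(rownames(zd))] <- zd[, 1]
      pi_new <- pi_new + 0.1                    # smoothing
      pi_d <- pi_new / sum(pi_new)
    }
    if (is.finite(obj) && is.finite(obj_prev) && abs(obj - obj_prev) < tol) {
      pwm <- pwm_new; gamma <- gamma_new
      break
    }
    obj_prev <- obj
    pwm <- pwm_new; gamma <- gamma_new
  }
  list(pwm = pwm, gamma = gamma, Z = Z, objective = trace[nit],
       trace = trace[seq_len(nit)], position_prior = pi_d)
}

.pwm_from_seed <- function(seed_str, strong = 0.7) {
  cc <- strsplit(seed_str, "")[[1]]
  w <- length(cc)
  pwm <- matrix((1 - strong) / 3, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- match(cc, c("A", "C", "G", "T"))
  ok <- !is.na(idx)
  pwm[cbind(idx[ok], which(ok))] <- strong
  pwm
}

.shift_pwm <- function(pwm, s, bg) {
  w <- ncol(pwm)
  out <- matrix(bg, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
  if (s > 0) out[, seq_len(w - s)] <- pwm[, (s + 1):w]
  else out[, (1 - s):w] <- pwm[, seq_len(w + s)]
  out
}

#' ZOOPS EM motif discovery
#'
#' Finds one ungapped motif of fixed width assuming zero or one
#' occurrence per sequence, in the spirit of classical EM motif finders.
#' The expectation step computes, per sequence, posterior probabilities
#' over all site offsets (and "no site"); the maximization step
#' re-estimates the position weight matrix with a per-base pseudocount
#' and the site prior. Restarts are seeded from the most frequent
#' subsequence and from randomly sampled subsequences; the converged
#' model is refined over small column shifts and the best model by the
#' penalized objective is returned. The background is a 0-order model
#' estimated from the input.
#'
#' @param sequences character vector of DNA sequences (>= 10).
#' @param width motif width (>= 3).
#' @param n_restarts number of seeded restarts.
#' @param seed RNG seed; identical seeds give identical models.
#' @param pseudocount per-base, per-column Dirichlet pseudocount.
#' @param tol convergence tolerance on the objective.
#' @param max_iter maximal EM iterations per run.
#' @param position_prior `"uniform"` treats all site offsets within a
#'   sequence as equiprobable; `"right"` learns a shared offset
#'   distribution measured from the sequence 3' end alongside the
#'   motif, which sharpens localization in anchored windows (upstream
#'   of a TSS or TLS the element-to-anchor spacing is the conserved
#'   quantity).
#' @return object of class `motif_model`: list with `width`, `pwm`
#'   (4 x width, columns sum to 1), `background`, `site_positions`
#'   (1-based best offset per sequence, NA when the best-site posterior
#'   is < 0.5), `site_posteriors`, `gamma`, `log_likelihood` (observed
#'   data), `objective_trace` (penalized objective, non-decreasing) and
#'   `consensus` (case-coded, see [consensus_code()]).
#' @export
em_find_motif <- function(sequences, width, n_restarts = 20, seed = 1,
                          pseudocount = 0.25, tol = 1e-6, max_iter = 500,
                          position_prior = c("uniform", "right")) {
  position_prior <- match.arg(position_prior)
  stopifnot(width >= 3)
  sequences <- toupper(sequences)
  usable <- nchar(sequences) >= width
  if (!any(usable)) stop("all sequences shorter than the motif width")
  if (length(sequences) < 10) stop("need at least 10 sequences")
  sm <- .seqs_to_matrix(sequences)
  X <- sm$X; len <- sm$len
  # 0-order background from the input windows, shrunk slightly toward
  # uniform so an extreme input composition cannot absorb the motif
  tab <- tabulate(X[!is.na(X)], nbins = 4)
  bg <- 0.9 * tab / sum(tab) + 0.1 * 0.25
  prep <- .em_prepare(X, len, width)

  with_seed(seed, {
    # seed strings: most frequent w-mer first, then random subsequences
    kmers <- unlist(lapply(which(usable), function(i) {
      s <- sequences[i]
      substring(s, 1:(nchar(s) - width + 1L), width:nchar(s))
    }))
    kmers <- kmers[!grepl("[^ACGT]", kmers)]
    top <- names(sort(table(kmers), decreasing = TRUE))[1]
    seeds <- top
    for (r in seq_len(max(0L, n_restarts - 1L))) {
      i <- sample(which(usable), 1)
      o <- sample.int(len[i] - width + 1L, 1)
      seeds <- c(seeds, substr(sequences[i], o, o + width - 1L))
    }
    # quick pass, then converge the most promising runs
    quick <- lapply(seeds, function(sd)
      .em_run(prep, width, .pwm_from_seed(sd), 0.5, bg, pseudocount, tol,
              max_iter = 8L, prior = position_prior))
    top_idx <- order(vapply(quick, `[[`, 0, "objective"), decreasing = TRUE)[1:2]
    runs <- lapply(top_idx, function(i)
      .em_run(prep, width, quick[[i]]$pwm, quick[[i]]$gamma, bg, pseudocount,
              tol, max_iter, prior = position_prior))
    best <- runs[[which.max(vapply(runs, `[[`, 0, "objective"))]]
    # shift refinement around the converged motif
    for (s in c(-3:-1, 1:3)) {
      cand <- .em_run(prep, width, .shift_pwm(best$pwm, s, bg), best$gamma,
                      bg, pseudocount, tol, max_iter, prior = position_prior)
      if (cand$objective > best$objective + 1e-9) best <- cand
    }
    .finish_motif(best, X, len, width, bg, sequences, pseudocount)
  })
}

.finish_motif <- function(run, X, len, width, bg, sequences, pseudocount) {
  dimnames(run$pwm) <- list(c("A", "C", "G", "T"), NULL)
  names(bg) <- c("A", "C", "G", "T")
  Z <- run$Z
  post <- apply(Z, 1, max)
  offs <- apply(Z, 1, which.max)
  site <- ifelse(post >= 0.5, offs, NA_integer_)
  sites_chr <- ifelse(is.na(site), NA_character_,
                      substr(sequences, site, site + width - 1L))
  cons <- if (any(!is.na(sites_chr)))
    consensus_code(sites_chr[!is.na(sites_chr)], n_total = length(sequences))
  else paste(rep("n", width), collapse = "")
  ll <- run$objective - pseudocount * sum(log(run$pwm))
  structure(list(width = width, pwm = run$pwm, background = bg,
                 site_positions = site, site_posteriors = post,
                 gamma = run$gamma, log_likelihood = ll,
                 objective_trace = run$trace, consensus = cons,
                 site_sequences = sites_chr),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif_model: width %d, consensus %s, %d/%d sites\n",
              x$width, x$consensus, sum(!is.na(x$site_positions)),
              length(x$site_positions)))
  invisible(x)
}

#' Case-coded consensus from aligned sites
#'
#' Per column, the most frequent base is written in upper case when its
#' frequency exceeds `upper` (default 0.80), in lower case when it
#' exceeds `lower` (default 0.40) but not `upper`, and as 'n' otherwise.
#' Frequencies are relative to `n_total` analyzed sequences, which may
#' exceed the number of sites when some sequences carry no element.
#'
#' @param aligned_sites character vector of equal-width site sequences.
#' @param upper,lower case-coding thresholds.
#' @param n_total denominator for the column frequencies (default: the
#'   number of sites).
#' @return consensus string.
#' @export
#' @examples
#' consensus_code(c("TATAAT", "TATAAT", "TACAAT", "TTTAAT", "CATAAT"))
consensus_code <- function(aligned_sites, upper = 0.80, lower = 0.40,
                           n_total = length(aligned_sites)) {
  stopifnot(length(unique(nchar(aligned_sites))) == 1, lower < upper,
            n_total >= length(aligned_sites))
  w <- nchar(aligned_sites[1])
  out <- character(w)
  for (k in seq_len(w)) {
    ch <- toupper(substr(aligned_sites, k, k))
    tb <- table(factor(ch, levels = c("A", "C", "G", "T")))
    b <- names(tb)[which.max(tb)]
    fr <- max(tb) / n_total
    out[k] <- if (fr > upper) b else if (fr > lower) tolower(b) else "n"
  }
  paste(out, collapse = "")
}

#' Spacer statistics
#'
#' @param distances integer vector of spacer distances in nt.
#' @param range optional c(lo, hi); the fraction of distances inside it
#'   is reported.
#' @return object of class `spacer_stats`: list with `distances`,
#'   `mean` (1 decimal, half away from zero), `mean_raw`, `min`, `max`,
#'   `range` and `fraction_in_range`.
#' @export
spacer_stats <- function(distances, range = NULL) {
  distances <- distances[!is.na(distances)]
  fr <- if (!is.null(range) && length(distances))
    mean(distances >= range[1] & distances <= range[2]) else NA_real_
  structure(list(distances = distances,
                 mean = if (length(distances)) round_half_away(mean(distances), 1) else NA_real_,
                 mean_raw = if (length(distances)) mean(distances) else NA_real_,
                 min = if (length(distances)) min(distances) else NA_integer_,
                 max = if (length(distances)) max(distances) else NA_integer_,
                 range = range, fraction_in_range = fr),
            class = "spacer_stats")
}

#' @export
print.spacer_stats <- function(x, ...) {
  cat(sprintf("spacer_stats: n=%d, mean=%.1f, range [%s, %s]\n",
              length(x$distances), x$mean, x$min, x$max))
  invisible(x)
}

#' Find -10 and -35 promoter elements upstream of TSSs
#'
#' Runs the EM motif search for the -10 hexamer over full upstream
#' windows, then for the -35 hexamer over the subsequence upstream of
#' each found -10 site. Because the two elements compete for the same
#' EM objective, the first-found motif is identified geometrically:
#' when its sites sit distal to the TSS (median spacer > 14 nt, i.e.
#' outside the 4-10 nt range core -10 elements occupy) it is taken to
#' be the -35 and the -10 search is repeated on the subwindows
#' downstream of its sites. Reports the extended -10 fraction (TG
#' dinucleotide immediately upstream of the -10 hexamer), spacer
#' statistics for -10 to TSS and -35 to -10 distances (bases strictly
#' between the elements), and a descriptive discriminator report (base
#' frequencies in the first six positions downstream of the -10
#' hexamer).
#'
#' @param windows upstream windows from [extract_upstream()] (the last
#'   base of each window is the position immediately before the TSS).
#' @param width10,width35 element widths.
#' @param n_restarts,seed,pseudocount,tol EM settings, see
#'   [em_find_motif()].
#' @return list with `minus10`, `minus35` (motif models),
#'   `minus10_presence`, `minus35_presence` (fractions of windows with a
#'   site), `extended_fraction`, `spacer_tss`, `spacer_35_10`
#'   (spacer_stats) and `discriminator` (4 x 6 frequency matrix).
#' @export
find_promoter_elements <- function(windows, width10 = 6, width35 = 6,
                                   n_restarts = 20, seed = 1,
                                   pseudocount = 0.25, tol = 1e-6) {
  wlen <- unique(nchar(windows))
  stopifnot(length(wlen) == 1)
  m10 <- em_find_motif(windows, width10, n_restarts = n_restarts, seed = seed,
                       pseudocount = pseudocount, tol = tol,
                       position_prior = "right")
  o10 <- m10$site_positions
  med_sp <- stats::median(wlen - (o10 + width10 - 1L), na.rm = TRUE)
  if (!is.na(med_sp) && med_sp > 14) {
    # first-found element is distal: it is the -35; look for the -10
    # between its sites and the TSS
    down_from <- ifelse(is.na(o10), 1L, o10 + width10)
    down <- substring(windows, down_from)
    ok2 <- nchar(down) >= width10
    m10b <- em_find_motif(down[ok2], width10, n_restarts = n_restarts,
                          seed = seed + 2L, pseudocount = pseudocount,
                          tol = tol, position_prior = "right")
    o_new <- rep(NA_integer_, length(windows))
    o_new[ok2] <- down_from[ok2] - 1L + m10b$site_positions
    m10 <- m10b
    m10$site_positions <- o_new
    o10 <- o_new
  }
  spacer_tss <- wlen - (o10 + width10 - 1L)

  has10 <- !is.na(o10)
  sub <- substr(windows, 1L, ifelse(has10, o10 - 1L, 0L))
  sub_ok <- has10 & nchar(sub) >= width35
  m35 <- em_find_motif(sub[sub_ok], width35, n_restarts = n_restarts,
                       seed = seed + 1L, pseudocount = pseudocount, tol = tol,
                       position_prior = "right")
  o35 <- rep(NA_integer_, length(windows))
  o35[sub_ok] <- m35$site_positions
  spacer_35_10 <- o10 - (o35 + width35)

  ext_ok <- has10 & o10 >= 3L
  extended_fraction <- if (any(ext_ok))
    mean(substr(windows[ext_ok], o10[ext_ok] - 2L, o10[ext_ok] - 1L) == "TG") else NA_real_

  # discriminator: base usage just downstream of the -10 element
  disc <- matrix(0, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (k in 1:6) {
    p <- o10 + width10 - 1L + k
    ok <- has10 & p <= wlen
    ch <- substr(windows[ok], p[ok], p[ok])
    tb <- table(factor(ch, levels = c("A", "C", "G", "T")))
    if (sum(tb)) disc[, k] <- as.numeric(tb) / sum(tb)
  }

  list(minus10 = m10, minus35 = m35,
       minus10_presence = mean(has10),
       minus35_presence = if (sum(sub_ok)) mean(!is.na(m35$site_positions)) else NA_real_,
       extended_fraction = extended_fraction,
       spacer_tss = spacer_stats(spacer_tss[has10]),
       spacer_35_10 = spacer_stats(spacer_35_10[!is.na(spacer_35_10)]),
       discriminator = disc)
}

#' Find the ribosome binding site motif
#'
#' EM motif search over windows upstream of translation starts; the
#' spacer is the number of bases strictly between the RBS element and
#' the TLS.
#'
#' @param sequences windows from [rbs_upstream_sequences()] (last base
#'   immediately before the TLS).
#' @param width RBS element width.
#' @param spacer_range range for the reported in-range fraction.
#' @inheritParams find_promoter_elements
#' @return list with `model`, `presence` and `spacer` (spacer_stats).
#' @export
find_rbs <- function(sequences, width = 6, n_restarts = 20, seed = 1,
                     pseudocount = 0.25, tol = 1e-6, spacer_range = c(5, 10)) {
  wlen <- unique(nchar(sequences))
  stopifnot(length(wlen) == 1)
  model <- em_find_motif(sequences, width, n_restarts = n_restarts, seed = seed,
                         pseudocount = pseudocount, tol = tol,
                         position_prior = "right")
  o <- model$site_positions
  sp <- wlen - (o + width - 1L)
  list(model = model, presence = mean(!is.na(o)),
       spacer = spacer_stats(sp[!is.na(o)], range = spacer_range))
}

#' Start codon usage
#'
#' Tallies the translation start codon of the given genes and reports
#' counts and one-decimal percentages (half away from zero) for ATG,
#' GTG, TTG, CTG and anything else.
#'
#' @param annotation a [genome_annotation()].
#' @param genome named character vector of sequences.
#' @param gene_ids genes to analyze (typically those with an identified
#'   5'-UTR); default all CDS features.
#' @return data frame codon/count/percent.
#' @export
start_codon_usage <- function(annotation, genome, gene_ids = NULL) {
  f <- annotation$features[annotation$features$feature_type == "CDS", , drop = FALSE]
  if (!is.null(gene_ids)) f <- f[f$feature_id %in% gene_ids, , drop = FALSE]
  seqchar <- genome[[annotation$replicon_id]]
  if (is.null(seqchar)) seqchar <- genome[[1]]
  cods <- character(nrow(f))
  for (i in seq_len(nrow(f))) {
    cods[i] <- if (f$strand[i] == "+") substr(seqchar, f$start[i], f$start[i] + 2L)
    else .revcomp(substr(seqchar, f$end[i] - 2L, f$end[i]))
  }
  lev <- c("ATG", "GTG", "TTG", "CTG")
  codf <- ifelse(cods %in% lev, cods, "other")
  tb <- table(factor(codf, levels = c(lev, "other")))
  data.frame(codon = names(tb), count = as.integer(tb),
             percent = percent(as.integer(tb), sum(tb)),
             stringsAsFactors = FALSE)
}
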