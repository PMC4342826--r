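#' Position weight matrix from a consensus string
#'
#' @param consensus motif consensus (A/C/G/T characters).
#' @param conservation probability of the consensus base at each column
#'   (scalar or one value per column); the remainder is split equally
#'   over the other three bases.
#' @return 4 x width probability matrix with rownames A, C, G, T.
#' @export
pwm_from_consensus <- function(consensus, conservation = 0.85) {
  bases <- c("A", "C", "G", "T")
  cc <- strsplit(toupper(consensus), "")[[1]]
  w <- length(cc)
  conservation <- rep_len(conservation, w)
  stopifnot(all(cc %in% bases), all(conservation > 0.25), all(conservation <= 1))
  pwm <- matrix(rep((1 - conservation) / 3, each = 4), nrow = 4,
                dimnames = list(bases, NULL))
  pwm[cbind(match(cc, bases), seq_len(w))] <- conservation
  pwm
}

#' Simulation parameters
#'
#' Defines the synthetic study conditions: an annotated genome of
#' transcription units (operons and single genes) on both strands, a
#' 5'-enriched library with sharp read-start peaks at true TSSs over a
#' low Poisson background, a whole-transcriptome library of paired
#' fragments sampled within transcripts, and planted promoter / RBS
#' motifs with realistic spacer distributions.
#'
#' @param replicon_length replicon length in nt.
#' @param n_transcription_units number of mRNA transcription units.
#' @param operon_gene_count_probs probabilities for operon sizes 1..8.
#' @param gene_length_range CDS length range in nt (rounded to codons).
#' @param utr_mixture list controlling the 5'-UTR length distribution:
#'   a peak of short leaders at 26-35 nt plus a long right tail
#'   (log-normal), with a small fraction of near-leaderless transcripts.
#' @param tss_peak_rate mean read-start count at a true TSS (before the
#'   per-tier multiplier).
#' @param background_rate mean background read starts per transcribed
#'   position in the 5'-enriched library.
#' @param background_floor_rate residual genome-wide background rate.
#' @param fragment_size_range paired-fragment length range in nt.
#' @param bridge_depth_min,bridge_depth_extra planted bridging depth per
#'   operon junction is `bridge_depth_min + rpois(1, bridge_depth_extra)`
#'   (natural fragments already spanning the junction count toward it).
#' @param tier_probs probabilities of the four abundance tiers.
#' @param tier_whole_rates whole-transcriptome fragment 5'-start rate per
#'   transcribed position for each tier; chosen so that the log-RPKM of a
#'   gene falls inside its tier's abundance class under the nominal
#'   library size.
#' @param tier_primary_mult per-tier multiplier on `tss_peak_rate`.
#' @param whole_library_size nominal mapped-read total of the
#'   whole-transcriptome library (used for per-million normalization).
#' @param minus10_pwm,minus35_pwm,rbs_pwm motif matrices for planting.
#' @param extended_minus10_fraction fraction of promoters with a TG
#'   dinucleotide immediately upstream of the -10 hexamer.
#' @param s10_range -10 to TSS spacer range (uniform draw).
#' @param s35_support,s35_weights -35 to -10 spacer support and weights
#'   (triangular peak at 17 nt).
#' @param rbs_spacer_range RBS to TLS spacer range (uniform draw).
#' @param internal_tss_prob probability that a multi-gene unit carries an
#'   internal TSS (source of suboperons).
#' @param n_stable_rna_units number of additional tRNA units (their TSSs
#'   must be removed by the stable-RNA filter).
#' @param seed integer seed fixing all randomness.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(replicon_length = 300000,
                       n_transcription_units = 100,
                       operon_gene_count_probs = c(0.45, 0.25, 0.12, 0.08, 0.04, 0.03, 0.02, 0.01),
                       gene_length_range = c(600, 1200),
                       utr_mixture = list(p_short = 0.005, short_range = c(2, 9),
                                          p_peak = 0.22, peak_range = c(26, 35),
                                          tail_meanlog = log(55), tail_sdlog = 0.75,
                                          tail_min = 10, tail_max = 450),
                       tss_peak_rate = 50,
                       background_rate = 0.2,
                       background_floor_rate = 0.005,
                       fragment_size_range = c(100, 800),
                       bridge_depth_min = 6,
                       bridge_depth_extra = 2,
                       tier_probs = c(low = 0.15, middle = 0.45, high = 0.30, very_high = 0.10),
                       tier_whole_rates = c(low = 0.016, middle = 0.1, high = 0.8, very_high = 5),
                       tier_primary_mult = c(low = 0.5, middle = 1, high = 2, very_high = 4),
                       whole_library_size = 2e6,
                       minus10_pwm = pwm_from_consensus("TATAAT", c(0.9, 0.9, 0.65, 0.65, 0.65, 0.9)),
                       minus35_pwm = pwm_from_consensus("TTGACA", c(0.7, 0.7, 0.7, 0.46, 0.46, 0.46)),
                       rbs_pwm = pwm_from_consensus("AGGAGG", c(0.7, 0.9, 0.9, 0.7, 0.9, 0.7)),
                       extended_minus10_fraction = 0.33,
                       s10_range = c(4, 10),
                       s35_support = 15:19,
                       s35_weights = c(1, 2, 3, 2, 1),
                       rbs_spacer_range = c(5, 10),
                       internal_tss_prob = 0.15,
                       n_stable_rna_units = 3,
                       seed = 1L) {
  p <- as.list(environment())
  stopifnot(p$replicon_length > 1000, p$n_transcription_units >= 1,
            length(p$operon_gene_count_probs) == 8,
            abs(sum(p$operon_gene_count_probs) - 1) < 1e-8,
            p$gene_length_range[1] < p$gene_length_range[2],
            p$tss_peak_rate >= 0, p$background_rate >= 0,
            p$fragment_size_range[1] < p$fragment_size_range[2],
            p$bridge_depth_min >= 0,
            abs(sum(p$tier_probs) - 1) < 1e-8,
            all(p$tier_whole_rates >= 0),
            p$extended_minus10_fraction >= 0, p$extended_minus10_fraction <= 1)
  p$seed <- as.integer(seed)
  structure(p, class = "sim_params")
}

.draw_utr <- function(n, m) {
  kind <- sample(c("short", "peak", "tail"), n, replace = TRUE,
                 prob = c(m$p_short, m$p_peak, 1 - m$p_short - m$p_peak))
  out <- integer(n)
  ns <- sum(kind == "short")
  if (ns) out[kind == "short"] <- sample(m$short_range[1]:m$short_range[2], ns, replace = TRUE)
  np <- sum(kind == "peak")
  if (np) out[kind == "peak"] <- sample(m$peak_range[1]:m$peak_range[2], np, replace = TRUE)
  nt <- sum(kind == "tail")
  if (nt) out[kind == "tail"] <- pmin(m$tail_max, pmax(m$tail_min,
                round(stats::rlnorm(nt, m$tail_meanlog, m$tail_sdlog))))
  out
}

.draw_motif <- function(pwm) {
  bases <- rownames(pwm)
  paste(vapply(seq_len(ncol(pwm)),
               function(k) sample(bases, 1, prob = pwm[, k]), ""), collapse = "")
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Generate a synthetic annotated genome with ground truth
#'
#' Lays out non-overlapping transcription units sequentially on both
#' strands; each unit receives a TSS, a planted promoter (-35 element,
#' spacer, -10 element, spacer), a 5'-UTR, and per-gene RBS motifs at a
#' planted spacer upstream of each translation start. Start codons are
#' drawn with realistic usage (ATG-dominated). A few tRNA units are
#' added so the stable-RNA filter has work to do.
#'
#' @param params a [sim_params()].
#' @return list with `annotation` ([genome_annotation()]), `genome`
#'   (named character vector of length 1) and `truth` (list of tables:
#'   `units`, `genes`, `tss`, `promoters`, `junctions`, plus `params`).
#' @export
generate_genome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, .generate_genome_impl(params))
}

.generate_genome_impl <- function(p) {
  L <- p$replicon_length
  rep_id <- "synth_chr"
  seqv <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                 prob = c(0.307, 0.193, 0.193, 0.307))

  units <- list(); genes <- list(); tss <- list(); prom <- list(); junc <- list()
  put <- function(at, s) seqv[at:(at + nchar(s) - 1L)] <<- strsplit(s, "")[[1]]

  n_units <- p$n_transcription_units
  sizes <- sample(1:8, n_units, replace = TRUE, prob = p$operon_gene_count_probs)
  strands <- sample(c("+", "-"), n_units, replace = TRUE)
  tiers <- sample(names(p$tier_probs), n_units, replace = TRUE, prob = p$tier_probs)
  utrs <- .draw_utr(n_units, p$utr_mixture)

  cursor <- 200L
  gi <- 0L
  codon_pool <- c("ATG", "TTG", "GTG"); codon_probs <- c(0.755, 0.139, 0.106)

  for (u in seq_len(n_units)) {
    k <- sizes[u]; strand <- strands[u]; tier <- tiers[u]; utr <- utrs[u]
    glen <- 3L * round(stats::runif(k, p$gene_length_range[1], p$gene_length_range[2]) / 3)
    gaps <- if (k > 1) sample(20:60, k - 1, replace = TRUE) else integer()
    span_genes <- sum(glen) + sum(gaps)
    span <- 80L + utr + span_genes          # 80 nt promoter headroom
    if (cursor + span + 200L > L)
      stop(sprintf("replicon too short for %d transcription units (need > %d nt)",
                   n_units, cursor + span + 200L))

    # gene coordinates in transcription order
    if (strand == "+") {
      t_pos <- cursor + 80L
      gstart <- integer(k); gend <- integer(k)
      at <- t_pos + utr
      for (j in seq_len(k)) {
        gstart[j] <- at; gend[j] <- at + glen[j] - 1L
        at <- gend[j] + if (j < k) gaps[j] + 1L else 1L
      }
      tx_start <- t_pos; tx_end <- gend[k]
      tls <- gstart
    } else {
      # transcription right to left: first gene is rightmost
      left <- cursor
      gstart <- integer(k); gend <- integer(k)
      at <- left
      for (j in rev(seq_len(k))) {          # lay out genes left to right
        gstart[j] <- at; gend[j] <- at + glen[j] - 1L
        at <- gend[j] + if (j > 1) gaps[j - 1L] + 1L else 1L
      }
      t_pos <- gend[1] + utr
      tx_start <- gstart[k]; tx_end <- t_pos
      tls <- gend
    }

    # start codons
    codons <- sample(codon_pool, k, replace = TRUE, prob = codon_probs)
    for (j in seq_len(k)) {
      if (strand == "+") put(gstart[j], codons[j]) else put(gend[j] - 2L, .revcomp(codons[j]))
    }

    # promoter: -10 hexamer at spacer s10 from the TSS, -35 upstream of it
    s10 <- sample(p$s10_range[1]:p$s10_range[2], 1)
    s35 <- sample(p$s35_support, 1, prob = p$s35_weights)
    ext <- stats::runif(1) < p$extended_minus10_fraction
    m10 <- .draw_motif(p$minus10_pwm); m35 <- .draw_motif(p$minus35_pwm)
    if (strand == "+") {
      m10_start <- t_pos - s10 - 6L
      m35_start <- m10_start - s35 - 6L
      put(m10_start, m10); put(m35_start, m35)
      # plant (or scrub a chance) extended -10 TG so the planted
      # extended fraction is exact
      if (ext) put(m10_start - 2L, "TG")
      else if (seqv[m10_start - 2L] == "T" && seqv[m10_start - 1L] == "G")
        put(m10_start - 1L, "A")
      m10_coord <- c(m10_start, m10_start + 5L); m35_coord <- c(m35_start, m35_start + 5L)
    } else {
      m10_left <- t_pos + s10 + 1L
      m35_left <- m10_left + 6L + s35
      put(m10_left, .revcomp(m10)); put(m35_left, .revcomp(m35))
      if (ext) put(m10_left + 6L, .revcomp("TG"))
      else if (seqv[m10_left + 6L] == "C" && seqv[m10_left + 7L] == "A")
        put(m10_left + 6L, "T")
      m10_coord <- c(m10_left, m10_left + 5L); m35_coord <- c(m35_left, m35_left + 5L)
    }

    # per-gene RBS: within the 5'-UTR (first gene) or the upstream gap
    rbs_sp <- rep(NA_integer_, k); rbs_on <- logical(k)
    for (j in seq_len(k)) {
      room <- if (j == 1) utr else gaps[j - 1L]
      if (room >= p$rbs_spacer_range[1] + 6L) {
        sr <- sample(p$rbs_spacer_range[1]:min(p$rbs_spacer_range[2], room - 6L), 1)
        rbs <- .draw_motif(p$rbs_pwm)
        if (strand == "+") put(tls[j] - sr - 6L, rbs) else put(tls[j] + sr + 1L, .revcomp(rbs))
        rbs_sp[j] <- sr; rbs_on[j] <- TRUE
      }
    }

    ids <- sprintf("u%03d_g%d", u, seq_len(k))
    genes[[u]] <- data.frame(gene_id = ids, unit_id = u, ord = seq_len(k),
                             start = gstart, end = gend, strand = strand, tls = tls,
                             start_codon = codons, utr_length = c(utr, rep(NA_integer_, k - 1L)),
                             rbs = rbs_on, rbs_spacer = rbs_sp,
                             upstream_gap = c(NA_integer_, gaps),
                             stringsAsFactors = FALSE)
    units[[u]] <- data.frame(unit_id = u, strand = strand, tss = t_pos,
                             tx_start = tx_start, tx_end = tx_end,
                             n_genes = k, tier = tier, utr_length = utr,
                             stringsAsFactors = FALSE)
    tss[[length(tss) + 1L]] <- data.frame(tss_id = sprintf("tss_u%03d", u),
                                          position = t_pos, strand = strand, unit_id = u,
                                          gene_id = ids[1], kind = "primary", tier = tier,
                                          utr_length = utr, stringsAsFactors = FALSE)
    prom[[length(prom) + 1L]] <- data.frame(tss_id = sprintf("tss_u%03d", u),
                                            s10 = s10, s35 = s35, extended = ext,
                                            m10_start = m10_coord[1], m10_end = m10_coord[2],
                                            m35_start = m35_coord[1], m35_end = m35_coord[2],
                                            stringsAsFactors = FALSE)

    # internal TSS in an intergenic gap (drives a suboperon)
    if (k > 1 && stats::runif(1) < p$internal_tss_prob) {
      j <- if (k == 2) 2L else sample(2:k, 1)
      gap <- gaps[j - 1L]
      iu_max <- min(40L, gap - 1L)
      if (iu_max >= 10L) {
        iutr <- sample(10:iu_max, 1)
        ip <- if (strand == "+") tls[j] - iutr else tls[j] + iutr
        tss[[length(tss) + 1L]] <- data.frame(tss_id = sprintf("tss_u%03d_i%d", u, j),
                                              position = ip, strand = strand, unit_id = u,
                                              gene_id = ids[j], kind = "internal", tier = tier,
                                              utr_length = iutr, stringsAsFactors = FALSE)
      }
    }

    if (k > 1) {
      # genomic left/right neighbours regardless of strand
      og <- order(gstart)
      junc[[length(junc) + 1L]] <- data.frame(
        unit_id = u,
        left_gene = ids[og][seq_len(k - 1L)], right_gene = ids[og][-1L],
        left_end = gend[og][seq_len(k - 1L)], right_start = gstart[og][-1L],
        strand = strand, stringsAsFactors = FALSE)
    }
    cursor <- cursor + span + sample(150:400, 1)
  }

  # tRNA units: short stable-RNA genes with their own strong TSS
  trna_feats <- list()
  for (tn in seq_len(p$n_stable_rna_units)) {
    strand <- sample(c("+", "-"), 1)
    utr <- sample(10:30, 1)
    flen <- 76L
    if (cursor + 120L + flen > L) break
    if (strand == "+") {
      t_pos <- cursor + 40L
      fstart <- t_pos + utr; fend <- fstart + flen - 1L
    } else {
      fstart <- cursor + 40L; fend <- fstart + flen - 1L
      t_pos <- fend + utr
    }
    id <- sprintf("trna_%02d", tn)
    trna_feats[[tn]] <- data.frame(feature_id = id, start = fstart, end = fend,
                                   strand = strand, feature_type = "tRNA",
                                   product = "tRNA", stringsAsFactors = FALSE)
    tss[[length(tss) + 1L]] <- data.frame(tss_id = sprintf("tss_%s", id),
                                          position = t_pos, strand = strand, unit_id = NA_integer_,
                                          gene_id = id, kind = "stable_rna", tier = "middle",
                                          utr_length = utr, stringsAsFactors = FALSE)
    cursor <- cursor + 120L + flen + sample(150:300, 1)
  }

  genes_df <- do.call(rbind, genes)
  units_df <- do.call(rbind, units)
  tss_df <- do.call(rbind, tss)
  prom_df <- do.call(rbind, prom)
  junc_df <- if (length(junc)) do.call(rbind, junc) else
    data.frame(unit_id = integer(), left_gene = character(), right_gene = character(),
               left_end = integer(), right_start = integer(), strand = character())

  feats <- data.frame(feature_id = genes_df$gene_id, start = genes_df$start,
                      end = genes_df$end, strand = genes_df$strand,
                      feature_type = "CDS", product = NA_character_,
                      stringsAsFactors = FALSE)
  if (length(trna_feats)) feats <- rbind(feats, do.call(rbind, trna_feats))
  annotation <- genome_annotation(rep_id, L, feats)
  genome <- stats::setNames(paste(seqv, collapse = ""), rep_id)

  truth <- list(units = units_df, genes = genes_df, tss = tss_df,
                promoters = prom_df, junctions = junc_df,
                replicon_id = rep_id, replicon_length = L, params = p)
  list(annotation = annotation, genome = genome, truth = truth)
}

#' Simulate the 5'-enriched (primary transcript) library
#'
#' Read-start counts at every true TSS are Poisson with mean
#' `tss_peak_rate` times the per-tier multiplier; background read starts
#' are Poisson-placed within transcribed intervals at `background_rate`
#' per position, plus a small uniform genomic floor mimicking residual
#' processed 5' ends.
#'
#' @param truth ground truth from [generate_genome()].
#' @param params the same [sim_params()].
#' @param seed seed for this library (default derived from `params$seed`).
#' @return a [read_start_profile()] of library type `five_prime_enriched`.
#' @export
simulate_primary_library <- function(truth, params, seed = params$seed + 1L) {
  with_seed(seed, {
    L <- truth$replicon_length
    pos <- integer(); str <- character(); cnt <- integer()

    mult <- params$tier_primary_mult
    peak <- stats::rpois(nrow(truth$tss), params$tss_peak_rate * mult[truth$tss$tier])
    keep <- peak > 0
    pos <- truth$tss$position[keep]; str <- truth$tss$strand[keep]; cnt <- peak[keep]

    # background within transcribed intervals
    if (params$background_rate > 0) {
      for (i in seq_len(nrow(truth$units))) {
        un <- truth$units[i, ]
        len <- un$tx_end - un$tx_start + 1L
        nb <- stats::rpois(1, params$background_rate * len)
        if (nb > 0) {
          bp <- sample(un$tx_start:un$tx_end, nb, replace = TRUE)
          tb <- table(bp)
          pos <- c(pos, as.integer(names(tb)))
          str <- c(str, rep(un$strand, length(tb)))
          cnt <- c(cnt, as.integer(tb))
        }
      }
    }
    # genome-wide floor on both strands
    if (params$background_floor_rate > 0) {
      nf <- stats::rpois(1, params$background_floor_rate * 2 * L)
      if (nf > 0) {
        fp <- sample.int(L, nf, replace = TRUE)
        fs <- sample(c("+", "-"), nf, replace = TRUE)
        tb <- table(paste(fs, fp))
        ks <- strsplit(names(tb), " ")
        pos <- c(pos, as.integer(vapply(ks, `[`, "", 2)))
        str <- c(str, vapply(ks, `[`, "", 1))
        cnt <- c(cnt, as.integer(tb))
      }
    }
    # aggregate duplicates
    key <- paste(str, pos)
    agg <- rowsum(cnt, key)
    ks <- strsplit(rownames(agg), " ")
    read_start_profile(truth$replicon_id,
                       positions = as.integer(vapply(ks, `[`, "", 2)),
                       strands = vapply(ks, `[`, "", 1),
                       counts = as.integer(agg[, 1]),
                       library = "five_prime_enriched",
                       replicon_length = L)
  })
}

#' Simulate the whole-transcriptome paired-fragment library
#'
#' Fragments are sampled with uniform 5' positions within each
#' transcription unit and lengths uniform in `fragment_size_range`,
#' truncated at the transcript 3' end. Every operon junction is then
#' topped up with bridging fragments (fragments covering the last base
#' of the upstream gene and the first base of the downstream gene) until
#' the planted per-junction depth is reached. The returned profile
#' records fragment 5' read starts and carries the nominal library size
#' as `total_mapped`.
#'
#' @inheritParams simulate_primary_library
#' @return list with `fragments` (data frame) and `profile`
#'   (a [read_start_profile()] of type `whole_transcriptome`).
#' @export
simulate_whole_library <- function(truth, params, seed = params$seed + 2L) {
  with_seed(seed, {
    L <- truth$replicon_length
    fr <- params$fragment_size_range
    rates <- params$tier_whole_rates
    frags <- vector("list", nrow(truth$units))

    for (i in seq_len(nrow(truth$units))) {
      un <- truth$units[i, ]
      len <- un$tx_end - un$tx_start + 1L
      if (len < fr[1])
        warning(sprintf("transcription unit %d shorter (%d nt) than the minimum fragment size; fragments truncated",
                        un$unit_id, len))
      n <- stats::rpois(1, rates[[un$tier]] * len)
      if (n == 0) { frags[[i]] <- NULL; next }
      p5 <- sample(un$tx_start:un$tx_end, n, replace = TRUE)
      fl <- sample(fr[1]:fr[2], n, replace = TRUE)
      if (un$strand == "+") {
        st <- p5; en <- pmin(p5 + fl - 1L, un$tx_end)
      } else {
        en <- p5; st <- pmax(p5 - fl + 1L, un$tx_start)
      }
      frags[[i]] <- data.frame(replicon = truth$replicon_id, start = st, end = en,
                               strand = un$strand, stringsAsFactors = FALSE)
    }
    fragments <- do.call(rbind, frags[!vapply(frags, is.null, TRUE)])
    if (is.null(fragments))
      fragments <- data.frame(replicon = character(), start = integer(),
                              end = integer(), strand = character())

    # top up junction bridging to the planted depth
    jn <- truth$junctions
    if (nrow(jn)) {
      extra <- list()
      for (q in seq_len(nrow(jn))) {
        j <- jn[q, ]
        un <- truth$units[truth$units$unit_id == j$unit_id, ]
        natural <- sum(fragments$strand == j$strand &
                         fragments$start <= j$left_end & fragments$end >= j$right_start)
        target <- params$bridge_depth_min + stats::rpois(1, params$bridge_depth_extra)
        deficit <- target - natural
        if (deficit <= 0) next
        span <- j$right_start - j$left_end + 1L
        lmax <- min(fr[2], un$tx_end - un$tx_start + 1L)
        fl <- sample(max(fr[1], span):lmax, deficit, replace = TRUE)
        lo <- pmax(un$tx_start, j$right_start - fl + 1L)
        hi <- pmin(j$left_end, un$tx_end - fl + 1L)
        hi <- pmax(hi, lo)
        st <- lo + floor(stats::runif(deficit) * (hi - lo + 1L))
        en <- pmin(st + fl - 1L, un$tx_end)
        extra[[length(extra) + 1L]] <- data.frame(replicon = truth$replicon_id,
                                                  start = st, end = en, strand = j$strand,
                                                  stringsAsFactors = FALSE)
      }
      if (length(extra)) fragments <- rbind(fragments, do.call(rbind, extra))
    }
    rownames(fragments) <- NULL

    p5 <- ifelse(fragments$strand == "+", fragments$start, fragments$end)
    key <- paste(fragments$strand, p5)
    agg <- rowsum(rep(1L, length(key)), key)
    ks <- strsplit(rownames(agg), " ")
    profile <- read_start_profile(truth$replicon_id,
                                  positions = as.integer(vapply(ks, `[`, "", 2)),
                                  strands = vapply(ks, `[`, "", 1),
                                  counts = as.integer(agg[, 1]),
                                  library = "whole_transcriptome",
                                  total_mapped = params$whole_library_size,
                                  replicon_length = L)
    list(fragments = fragments, profile = profile)
  })
}

#' Plant motif instances in random windows
#'
#' Builds fixed-width sequence windows with a motif instance drawn from
#' `pwm` planted in a fraction of them, either at a uniformly random
#' offset or at an offset determined by a spacer drawn from
#' `spacer_fn` (the number of bases between the motif's last base and
#' the window's right edge, i.e. the anchored geometry of promoter or
#' RBS elements). Returns the windows together with the planting
#' record.
#'
#' @param n number of windows.
#' @param pwm 4 x width probability matrix (see [pwm_from_consensus()]).
#' @param window window width in nt.
#' @param site_freq fraction of windows that receive a motif instance.
#' @param spacer_fn either NULL (uniform random offsets) or a function
#'   `function(k)` returning `k` integer spacers.
#' @param bg background base probabilities (A, C, G, T).
#' @param seed RNG seed.
#' @return list with `windows` (character), `offsets` (1-based motif
#'   start, NA where none planted) and `spacers` (NA where none).
#' @export
plant_motif_windows <- function(n, pwm, window = 70, site_freq = 1,
                                spacer_fn = NULL,
                                bg = c(0.25, 0.25, 0.25, 0.25), seed = 1) {
  w <- ncol(pwm)
  stopifnot(window >= w, n >= 1)
  with_seed(seed, {
    windows <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), window, replace = TRUE, prob = bg),
            collapse = ""), "")
    has <- stats::runif(n) < site_freq
    offsets <- rep(NA_integer_, n); spacers <- rep(NA_integer_, n)
    k <- sum(has)
    if (k > 0) {
      if (is.null(spacer_fn)) {
        offsets[has] <- sample.int(window - w + 1L, k, replace = TRUE)
      } else {
        spacers[has] <- spacer_fn(k)
        offsets[has] <- window - spacers[has] - w + 1L
      }
      idx <- which(has)
      for (i in idx) {
        inst <- .draw_motif(pwm)
        substr(windows[i], offsets[i], offsets[i] + w - 1L) <- inst
      }
    }
    list(windows = windows, offsets = offsets, spacers = spacers)
  })
}

#' Plant full promoter geometry in random windows
#'
#' Windows anchored at the TSS (last base = position immediately before
#' the TSS) receive a -10 instance at spacer `s10` from the right edge
#' and a -35 instance at spacer `s35` upstream of the -10, with an
#' optional TG dinucleotide immediately upstream of the -10 in a given
#' fraction of windows.
#'
#' @inheritParams plant_motif_windows
#' @param pwm10,pwm35 element matrices.
#' @param s10_fn,s35_fn functions `function(k)` drawing the spacers.
#' @param extended_fraction fraction of windows with the TG dinucleotide.
#' @return list with `windows`, `s10`, `s35`, `extended` and the
#'   planted element offsets `o10`, `o35`.
#' @export
plant_promoter_windows <- function(n, pwm10, pwm35, window = 70,
                                   s10_fn = function(k) sample(4:10, k, replace = TRUE),
                                   s35_fn = function(k) sample(15:19, k, replace = TRUE,
                                                               prob = c(1, 2, 3, 2, 1)),
                                   extended_fraction = 0,
                                   bg = c(0.25, 0.25, 0.25, 0.25), seed = 1) {
  w10 <- ncol(pwm10); w35 <- ncol(pwm35)
  with_seed(seed, {
    windows <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), window, replace = TRUE, prob = bg),
            collapse = ""), "")
    s10 <- s10_fn(n); s35 <- s35_fn(n)
    ext <- stats::runif(n) < extended_fraction
    o10 <- window - s10 - w10 + 1L
    o35 <- o10 - s35 - w35
    stopifnot(all(o35 >= 1L))
    for (i in seq_len(n)) {
      substr(windows[i], o10[i], o10[i] + w10 - 1L) <- .draw_motif(pwm10)
      substr(windows[i], o35[i], o35[i] + w35 - 1L) <- .draw_motif(pwm35)
      if (ext[i]) {
        substr(windows[i], o10[i] - 2L, o10[i] - 1L) <- "TG"
      } else if (substr(windows[i], o10[i] - 2L, o10[i] - 1L) == "TG") {
        substr(windows[i], o10[i] - 1L, o10[i] - 1L) <- "A"
      }
    }
    list(windows = windows, s10 = s10, s35 = s35, extended = ext,
         o10 = o10, o35 = o35)
  })
}

#' Recovery metrics against ground truth
#'
#' A predicted TSS counts as recovered when a true TSS on the same strand
#' lies within `tolerance` nt (one-to-one matching); an operon counts as
#' recovered only when its member set matches a true multi-gene unit
#' exactly.
#'
#' @param predicted for TSSs: a data frame with `position` and `strand`
#'   columns; for operons: the list returned by [infer_primary_operons()]
#'   or a list of operon objects.
#' @param truth ground truth from [generate_genome()].
#' @param tolerance positional tolerance in nt (TSS mode only).
#' @param kinds which planted TSS kinds count as truth (default the
#'   mRNA TSSs: primary and internal).
#' @return list with tp, fp, fn, precision and recall. Precision is NaN
#'   when there are no predictions.
#' @export
evaluate_calls <- function(predicted, truth, tolerance = 0,
                           kinds = c("primary", "internal")) {
  if (is.data.frame(predicted)) {
    evaluate_tss_calls(predicted, truth, tolerance = tolerance, kinds = kinds)
  } else {
    evaluate_operon_calls(predicted, truth)
  }
}

#' @rdname evaluate_calls
#' @export
evaluate_tss_calls <- function(predicted, truth, tolerance = 0,
                               kinds = c("primary", "internal")) {
  tt <- truth$tss[truth$tss$kind %in% kinds, , drop = FALSE]
  tp <- 0L
  used <- rep(FALSE, nrow(predicted))
  for (i in seq_len(nrow(tt))) {
    cand <- which(!used & predicted$strand == tt$strand[i] &
                    abs(predicted$position - tt$position[i]) <= tolerance)
    if (length(cand)) {
      best <- cand[which.min(abs(predicted$position[cand] - tt$position[i]))]
      used[best] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- nrow(predicted) - tp
  fn <- nrow(tt) - tp
  list(tp = tp, fp = fp, fn = fn,
       precision = if (nrow(predicted) > 0) tp / nrow(predicted) else NaN,
       recall = if (nrow(tt) > 0) tp / nrow(tt) else NaN)
}

#' @rdname evaluate_calls
#' @export
evaluate_operon_calls <- function(predicted, truth) {
  ops <- if (!is.null(predicted$operons)) predicted$operons else predicted
  pred_sets <- lapply(ops, function(o) sort(o$members))
  gm <- split(truth$genes$gene_id, truth$genes$unit_id)
  true_sets <- lapply(gm[vapply(gm, length, 1L) >= 2], sort)
  matched <- vapply(true_sets, function(ts)
    any(vapply(pred_sets, identical, TRUE, y = ts)), TRUE)
  tp <- sum(matched)
  list(tp = tp, fp = length(pred_sets) - tp, fn = length(true_sets) - tp,
       precision = if (length(pred_sets)) tp / length(pred_sets) else NaN,
       recall = if (length(true_sets)) tp / length(true_sets) else NaN)
}

#' Write a simulation to disk
#'
#' Writes genome.fasta, annotation.gff3, primary.readstarts.tsv,
#' whole.fragments.tsv, whole.readstarts.tsv and the ground-truth tables.
#'
#' @param sim list from [generate_genome()].
#' @param primary profile from [simulate_primary_library()].
#' @param whole list from [simulate_whole_library()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, primary, whole, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta_genome(sim$genome, file.path(dir, "genome.fasta"))
  write_gff3(sim$annotation, file.path(dir, "annotation.gff3"))
  write_read_starts(primary, file.path(dir, "primary.readstarts.tsv"))
  write_intervals(whole$fragments, file.path(dir, "whole.fragments.tsv"))
  write_read_starts(whole$profile, file.path(dir, "whole.readstarts.tsv"))
  utils::write.table(sim$truth$tss, file.path(dir, "truth.tss.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$genes, file.path(dir, "truth.genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$units, file.path(dir, "truth.units.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
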