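test_that("upstream windows use the correct coordinates and strand", {
  base4 <- c("A", "C", "G", "T")
  set.seed(1)
  seqchar <- paste(sample(base4, 2000, replace = TRUE), collapse = "")
  genome <- c(chr = seqchar)
  w <- extract_upstream(1000, "+", genome, window = 70)
  expect_identical(w, substr(seqchar, 930, 999))
  w2 <- extract_upstream(1000, "-", genome, window = 70)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(seqchar, 1001, 1070))))
  expect_identical(w2, rc)
  # truncation at the replicon edge
  expect_identical(nchar(extract_upstream(30, "+", genome, window = 70)), 29L)
})

test_that("case coding follows the 80/40 thresholds and ignores order", {
  sites <- c(rep("AAAAAA", 9), "CCCCCC")               # A at 90%
  expect_identical(consensus_code(sites), "AAAAAA")
  sites2 <- c(rep("ACGTAC", 55), rep("CCGTAC", 45))    # col 1: A 55%
  expect_identical(substr(consensus_code(sites2), 1, 1), "a")
  mixed <- c(rep("A", 30), rep("C", 30), rep("G", 20), rep("T", 20))
  expect_identical(consensus_code(paste0(mixed, "A")),
                   paste0("n", "A"))
  # exactly 80% is lower case (strictly-greater rule)
  sites3 <- c(rep("AG", 8), rep("CG", 2))
  expect_identical(consensus_code(sites3), "aG")
  set.seed(2)
  shuffled <- sample(sites2)
  expect_identical(consensus_code(shuffled), consensus_code(sites2))
})

test_that("EM recovers a planted motif and degenerates gracefully", {
  pwm <- pwm_from_consensus("TATAAT", 0.95)
  pl <- plant_motif_windows(200, pwm, window = 70, site_freq = 1, seed = 1)
  m <- em_find_motif(pl$windows, 6, seed = 1)
  expect_identical(toupper(m$consensus), "TATAAT")
  # recovered sites match the planting record
  ok <- !is.na(m$site_positions)
  expect_gt(mean(m$site_positions[ok] == pl$offsets[ok]), 0.9)

  # pure-A input: degenerate fixed point
  pure <- rep(paste(rep("A", 30), collapse = ""), 200)
  m2 <- em_find_motif(pure, 6, seed = 1, n_restarts = 3)
  expect_true(all(m2$pwm["A", ] >= 0.99))

  # determinism under identical seed
  m3 <- em_find_motif(pl$windows, 6, seed = 1)
  expect_identical(m3$pwm, m$pwm)
  expect_identical(m3$site_positions, m$site_positions)

  # all-too-short input errors
  expect_error(em_find_motif(rep("ACG", 20), 6), "shorter")
})

test_that("the EM objective is non-decreasing on every run", {
  pwm <- pwm_from_consensus("AGGAGG", 0.85)
  pl <- plant_motif_windows(80, pwm, window = 20, site_freq = 0.8, seed = 3)
  m <- em_find_motif(pl$windows, 6, seed = 3, n_restarts = 5)
  expect_true(all(diff(m$objective_trace) >= -1e-8))
  # and on an unstructured null input
  null_w <- plant_motif_windows(60, pwm, window = 40, site_freq = 0, seed = 4)
  m0 <- em_find_motif(null_w$windows, 6, seed = 4, n_restarts = 5)
  expect_true(all(diff(m0$objective_trace) >= -1e-8))
})

test_that("promoter search separates -10 and -35 and measures spacers", {
  pl <- plant_promoter_windows(250, pwm_from_consensus("TATAAT", 0.9),
                               pwm_from_consensus("TTGACA", 0.9),
                               extended_fraction = 0.33, seed = 8)
  pe <- find_promoter_elements(pl$windows, seed = 8, n_restarts = 10)
  expect_identical(toupper(pe$minus10$consensus), "TATAAT")
  expect_identical(toupper(pe$minus35$consensus), "TTGACA")
  expect_lt(abs(pe$spacer_tss$mean_raw - mean(pl$s10)), 0.2)
  expect_lt(abs(pe$spacer_35_10$mean_raw - mean(pl$s35)), 0.2)
  expect_lt(abs(pe$extended_fraction - mean(pl$extended)), 0.06)
  expect_gt(pe$minus10_presence, 0.9)
  # discriminator report is a proper frequency matrix
  expect_true(all(abs(colSums(pe$discriminator) - 1) < 1e-9))
})

test_that("windows of unstructured sequence yield a weak consensus", {
  pl <- plant_motif_windows(200, pwm_from_consensus("TATAAT"), window = 70,
                            site_freq = 0, seed = 11)
  m <- em_find_motif(pl$windows, 6, seed = 11, n_restarts = 10)
  # no conserved motif: at least 4 of the 6 columns uncalled or weak
  n_weak <- sum(strsplit(m$consensus, "")[[1]] %in% c(letters, "n"))
  expect_gte(n_weak, 4)
})

test_that("RBS search reports spacers between element and TLS", {
  rbs_pwm <- pwm_from_consensus("AGGAGG", 0.9)
  pl <- plant_motif_windows(300, rbs_pwm, window = 20, site_freq = 1,
                            spacer_fn = function(k) sample(5:10, k, replace = TRUE),
                            seed = 12)
  rr <- find_rbs(pl$windows, seed = 12, n_restarts = 10)
  expect_identical(toupper(rr$model$consensus), "AGGAGG")
  expect_lt(abs(rr$spacer$mean_raw - mean(pl$spacers, na.rm = TRUE)), 0.2)
  expect_gt(rr$spacer$fraction_in_range, 0.95)
})

test_that("spacer statistics report mean and in-range fraction", {
  s <- spacer_stats(c(7L, 8L), range = c(5, 10))
  expect_equal(s$mean, 7.5)
  expect_equal(s$fraction_in_range, 1)
  s2 <- spacer_stats(c(5L, 10L, 12L), range = c(5, 10))
  expect_equal(s2$fraction_in_range, 2 / 3)
  expect_equal(s2$min, 5L)
  expect_equal(s2$max, 12L)
  # closed-form mean of a uniform draw on 5..10
  set.seed(9)
  d <- sample(5:10, 2000, replace = TRUE)
  expect_lt(abs(spacer_stats(d)$mean_raw - 7.5), 0.1)
})

test_that("start codon usage is tallied with one-decimal percentages", {
  ann <- genome_annotation("chr", 300, data.frame(
    feature_id = c("a", "b"), start = c(10L, 200L), end = c(60L, 250L),
    strand = c("+", "-"), feature_type = "CDS", stringsAsFactors = FALSE))
  seqv <- rep("C", 300)
  seqv[10:12] <- c("A", "T", "G")
  seqv[248:250] <- c("C", "A", "C")   # revcomp GTG
  genome <- c(chr = paste(seqv, collapse = ""))
  u <- start_codon_usage(ann, genome)
  expect_identical(u$count[u$codon == "ATG"], 1L)
  expect_identical(u$count[u$codon == "GTG"], 1L)
  expect_equal(u$percent[u$codon == "ATG"], 50.0)
  u1 <- start_codon_usage(ann, genome, gene_ids = "a")
  expect_equal(u1$percent[u1$codon == "ATG"], 100.0)
})
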