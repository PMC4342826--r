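fast_params <- function(...) {
  sim_params(replicon_length = 40000, n_transcription_units = 10,
             n_stable_rna_units = 1, seed = 5, ...)
}

test_that("generation is fully deterministic under a fixed seed", {
  a <- generate_genome(fast_params())
  b <- generate_genome(fast_params())
  expect_identical(a$genome, b$genome)
  expect_identical(a$annotation$features, b$annotation$features)
  expect_identical(a$truth$tss, b$truth$tss)
  pa <- simulate_primary_library(a$truth, fast_params())
  pb <- simulate_primary_library(b$truth, fast_params())
  expect_identical(pa$starts, pb$starts)
  wa <- simulate_whole_library(a$truth, fast_params())
  wb <- simulate_whole_library(b$truth, fast_params())
  expect_identical(wa$fragments, wb$fragments)

  c <- generate_genome(sim_params(replicon_length = 40000,
                                  n_transcription_units = 10,
                                  n_stable_rna_units = 1, seed = 6))
  expect_false(identical(a$genome, c$genome))
})

test_that("unit and gene bookkeeping matches the requested layout", {
  # 10 units of exactly 2 genes: 20 genes, 10 primary TSSs
  p <- sim_params(replicon_length = 40000, n_transcription_units = 10,
                  operon_gene_count_probs = c(0, 1, 0, 0, 0, 0, 0, 0),
                  internal_tss_prob = 0, n_stable_rna_units = 0, seed = 5)
  g <- generate_genome(p)
  expect_identical(nrow(g$truth$genes), 20L)
  expect_identical(nrow(g$truth$tss), 10L)
  expect_identical(nrow(g$truth$units), 10L)
  expect_true(all(g$truth$units$n_genes == 2L))

  # single-unit genome
  p1 <- sim_params(replicon_length = 20000, n_transcription_units = 1,
                   operon_gene_count_probs = c(1, 0, 0, 0, 0, 0, 0, 0),
                   n_stable_rna_units = 0, seed = 7)
  g1 <- generate_genome(p1)
  expect_identical(nrow(g1$truth$tss), 1L)

  # a replicon too short for the requested units errors
  expect_error(generate_genome(sim_params(replicon_length = 5000,
                                          n_transcription_units = 50, seed = 1)),
               "too short")
})

test_that("planted promoter elements lie within 70 nt upstream of their TSS", {
  g <- generate_genome(fast_params())
  pr <- merge(g$truth$promoters, g$truth$tss, by = "tss_id")
  up_dist <- ifelse(pr$strand == "+", pr$position - pr$m35_start,
                    pr$m35_end - pr$position)
  expect_true(all(up_dist >= 1 & up_dist <= 70))
  # spacer arithmetic: -10 element end sits s10 bases from the TSS
  d10 <- ifelse(pr$strand == "+", pr$position - pr$m10_end - 1L,
                pr$m10_start - pr$position - 1L)
  expect_identical(as.integer(d10), as.integer(pr$s10))
  # the planted motif instance is on the genome
  i <- which(pr$strand == "+")[1]
  hex <- substr(g$genome[[1]], pr$m10_start[i], pr$m10_end[i])
  expect_identical(nchar(hex), 6L)
})

test_that("the 5' library has peaks at every TSS over the planted background", {
  p <- fast_params()
  g <- generate_genome(p)
  prof <- simulate_primary_library(g$truth, p)
  at_tss <- profile_counts(prof, g$truth$tss$position[g$truth$tss$strand == "+"], "+")
  at_tss <- c(at_tss, profile_counts(prof, g$truth$tss$position[g$truth$tss$strand == "-"], "-"))
  expect_true(all(at_tss >= 1))

  # no background: nonzero counts only at true TSSs
  p0 <- fast_params(background_rate = 0, background_floor_rate = 0)
  prof0 <- simulate_primary_library(g$truth, p0)
  expect_true(all(prof0$starts$position %in% g$truth$tss$position))

  # doubling the peak rate doubles the mean TSS count (Monte Carlo)
  means <- vapply(c(25, 50), function(rate) {
    pr <- fast_params(tss_peak_rate = rate)
    cnt <- unlist(lapply(1:6, function(s) {
      pf <- simulate_primary_library(g$truth, pr, seed = 100 + s)
      c(profile_counts(pf, g$truth$tss$position[g$truth$tss$strand == "+"], "+"),
        profile_counts(pf, g$truth$tss$position[g$truth$tss$strand == "-"], "-"))
    }))
    mean(cnt)
  }, 0)
  expect_lt(abs(means[2] / means[1] - 2), 0.1)
})

test_that("whole-library fragments stay inside transcripts with planted bridging", {
  p <- fast_params()
  g <- generate_genome(p)
  w <- simulate_whole_library(g$truth, p)
  expect_true(all(w$fragments$end - w$fragments$start + 1 <= 800))
  # fragments never leave their transcription unit
  un <- g$truth$units
  for (i in seq_len(nrow(un))) {
    fr <- w$fragments[w$fragments$strand == un$strand[i] &
                        w$fragments$start >= un$tx_start[i] &
                        w$fragments$end <= un$tx_end[i], ]
    expect_true(nrow(fr) >= 0)
  }
  in_any_unit <- vapply(seq_len(nrow(w$fragments)), function(q) {
    any(un$strand == w$fragments$strand[q] &
          un$tx_start <= w$fragments$start[q] &
          un$tx_end >= w$fragments$end[q])
  }, TRUE)
  expect_true(all(in_any_unit))

  # every true junction carries at least the planted bridging depth
  jn <- g$truth$junctions
  for (i in seq_len(nrow(jn))) {
    supp <- sum(w$fragments$strand == jn$strand[i] &
                  w$fragments$start <= jn$left_end[i] &
                  w$fragments$end >= jn$right_start[i])
    expect_gte(supp, p$bridge_depth_min)
  }
})

test_that("recovery metrics implement one-to-one tolerant matching", {
  g <- generate_genome(fast_params())
  truth_tss <- g$truth$tss[g$truth$tss$kind != "stable_rna", ]
  perfect <- data.frame(position = truth_tss$position, strand = truth_tss$strand)
  m <- evaluate_tss_calls(perfect, g$truth)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)

  none <- perfect[0, ]
  m0 <- evaluate_tss_calls(none, g$truth)
  expect_equal(m0$recall, 0)
  expect_true(is.nan(m0$precision))

  shifted <- transform(perfect[1, ], position = position + 1L)
  m1 <- evaluate_tss_calls(shifted, g$truth, tolerance = 0)
  expect_identical(m1$tp, 0L)
  m2 <- evaluate_tss_calls(shifted, g$truth, tolerance = 1)
  expect_identical(m2$tp, 1L)
})

test_that("simulation files round-trip through the writers", {
  p <- fast_params()
  g <- generate_genome(p)
  prim <- simulate_primary_library(g$truth, p)
  whole <- simulate_whole_library(g$truth, p)
  dir <- withr::local_tempdir()
  write_simulation(g, prim, whole, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "genome.fasta", "annotation.gff3", "primary.readstarts.tsv",
    "whole.fragments.tsv", "whole.readstarts.tsv", "truth.tss.tsv")))))
  ann2 <- read_gff3(file.path(dir, "annotation.gff3"))
  expect_identical(ann2$features$feature_id, g$annotation$features$feature_id)
  prim2 <- read_read_starts(file.path(dir, "primary.readstarts.tsv"))
  expect_identical(prim2$starts, prim$starts)
  fr2 <- read_fragments(file.path(dir, "whole.fragments.tsv"))
  expect_identical(nrow(fr2), nrow(whole$fragments))
  g2 <- read_fasta_genome(file.path(dir, "genome.fasta"))
  expect_identical(g2[[1]], g$genome[[1]])
})
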