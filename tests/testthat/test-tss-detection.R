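test_that("the three calling criteria behave at their boundaries", {
  ann <- tiny_annotation()
  # TLS of g1 at 200 '+'; candidate at 150 is 50 nt upstream
  p <- tiny_profile(c(150L, 149L), c("+", "+"), c(7L, 1L))
  cand <- detect_candidates(p, ann)
  expect_identical(cand$position, 150L)
  expect_equal(cand$ratio, 7)
  expect_true(cand$tls_within_X)

  # ratio 7/2 = 3.5 <= 6: not called
  p2 <- tiny_profile(c(150L, 149L), c("+", "+"), c(7L, 2L))
  expect_identical(nrow(detect_candidates(p2, ann)), 0L)

  # count exactly T fails the strict background criterion
  p3 <- tiny_profile(150L, "+", 6L)
  expect_identical(nrow(detect_candidates(p3, ann)), 0L)

  # zero previous count passes the ratio criterion
  p4 <- tiny_profile(150L, "+", 7L)
  cand4 <- detect_candidates(p4, ann)
  expect_identical(cand4$position, 150L)
  expect_identical(cand4$ratio, Inf)

  # minus strand: previous position is p + 1
  p5 <- tiny_profile(c(1850L, 1851L), c("-", "-"), c(9L, 1L))
  cand5 <- detect_candidates(p5, ann)
  expect_identical(cand5$position, 1850L)
  expect_identical(cand5$tls_feature, "g3")   # TLS at 1800 on '-'
  expect_identical(cand5$tls_distance, 50L)

  # candidates beyond X from any TLS are retained but marked
  p6 <- tiny_profile(4500L, "+", 20L)
  cand6 <- detect_candidates(p6, ann)
  expect_identical(nrow(cand6), 1L)
  expect_false(cand6$tls_within_X)

  # replicon mismatch is an error
  p7 <- tiny_profile(100L, "+", 9L, replicon = "other")
  expect_error(detect_candidates(p7, ann), "does not match")
})

test_that("sparse caller equals the dense brute-force oracle on random profiles", {
  for (seed in c(13, 14, 15, 16, 17)) {
    prof <- random_profile(seed)
    ann <- random_annotation(seed)
    got <- detect_candidates(prof, ann, tss_params())
    got <- got[got$tls_within_X, c("position", "strand")]
    want <- oracle_detect(prof, ann)
    got <- got[order(got$strand, got$position), ]
    want <- want[order(want$strand, want$position), ]
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
  }
})

test_that("raising T or R never adds candidates", {
  prof <- random_profile(99)
  ann <- random_annotation(99)
  key <- function(d) paste(d$position, d$strand)
  base <- detect_candidates(prof, ann, tss_params(T = 4, R = 4))
  for (t in c(6, 8, 12)) {
    hi <- detect_candidates(prof, ann, tss_params(T = t, R = 4))
    expect_true(all(key(hi) %in% key(base)))
  }
  for (r in c(6, 8, 12)) {
    hi <- detect_candidates(prof, ann, tss_params(T = 4, R = r))
    expect_true(all(key(hi) %in% key(base)))
  }
})

test_that("near misses are rescued only with full downstream support", {
  ann <- tiny_annotation()
  # count 6 fails T by one read; ratio passes
  prof <- tiny_profile(150L, "+", 6L)
  nm <- find_near_misses(prof, ann)
  expect_identical(nm$position, 150L)
  expect_identical(nm$failed, "T")

  covered <- data.frame(replicon = "chr", start = 150L, end = 240L, strand = "+",
                        stringsAsFactors = FALSE)
  cov_ok <- fragment_coverage(covered, 5000)
  cov_none <- fragment_coverage(covered[0, ], 5000)
  expect_identical(rescue_candidates(nm, prof, cov_ok)$position, 150L)
  expect_identical(nrow(rescue_candidates(nm, prof, cov_none)), 0L)
  # a single uncovered base inside the first 20 nt blocks the rescue
  gap <- data.frame(replicon = "chr", start = c(150L, 161L), end = c(159L, 240L),
                    strand = "+", stringsAsFactors = FALSE)
  expect_identical(nrow(rescue_candidates(nm, prof, fragment_coverage(gap, 5000))), 0L)

  # two reads below the threshold is never a near miss
  prof5 <- tiny_profile(150L, "+", 5L)
  expect_identical(nrow(find_near_misses(prof5, ann)), 0L)

  # ratio near miss: count 12, prev 2 needs > 12; one more read would pass
  prof_r <- tiny_profile(c(150L, 149L), c("+", "+"), c(12L, 2L))
  nm_r <- find_near_misses(prof_r, ann)
  expect_identical(nm_r$failed, "R")
  # failing both criteria disqualifies
  prof_b <- tiny_profile(c(150L, 149L), c("+", "+"), c(6L, 1L))
  expect_identical(nrow(find_near_misses(prof_b, ann)), 0L)
})

test_that("candidates inside uneven gradients are flagged as false positives", {
  ann <- tiny_annotation()
  # candidate 12 at 150 within a window holding a 400 peak and 4 other
  # supra-threshold positions
  pos <- c(150L, 140L, 145L, 155L, 160L, 165L)
  cnt <- c(12L, 400L, 9L, 9L, 9L, 9L)
  prof <- tiny_profile(pos, rep("+", 6), cnt)
  cand <- detect_candidates(prof, ann)
  fl <- flag_false_positives(cand, prof)
  expect_true(fl$false_positive[fl$position == 150])

  # isolated candidate: window max is its own count
  prof2 <- tiny_profile(150L, "+", 12L)
  fl2 <- flag_false_positives(detect_candidates(prof2, ann), prof2)
  expect_false(any(fl2$false_positive))

  # exactly two other supra-threshold positions: below the gradient rule
  prof3 <- tiny_profile(c(150L, 140L, 160L, 145L), rep("+", 4),
                        c(12L, 400L, 9L, 2L))
  fl3 <- flag_false_positives(detect_candidates(prof3, ann), prof3)
  expect_false(any(fl3$false_positive[fl3$position == 150]))
})

test_that("TSSs upstream of stable RNA genes are removed", {
  ann <- tiny_annotation()    # tRNA t1 at [2500, 2576] '+'
  prof <- tiny_profile(c(2460L, 150L, 4500L), rep("+", 3), c(30L, 9L, 9L))
  cand <- detect_candidates(prof, ann)
  res <- drop_stable_rna_tss(cand, ann)
  expect_identical(res$removed_count, 1L)
  expect_identical(res$removed$position, 2460L)
  expect_true(all(c(150L, 4500L) %in% res$kept$position))
})

test_that("pipeline bookkeeping is consistent on synthetic data", {
  ss <- small_sim()
  cov <- fragment_coverage(ss$whole$fragments, ss$params$replicon_length)
  calls <- call_tss(ss$primary, ss$sim$annotation, whole_coverage = cov)
  s <- calls$summary
  expect_identical(unname(s["automatic"] - s["false_positive"] - s["stable_rna"] +
                            s["rescued"]), unname(s["final"]))
  expect_identical(as.integer(s["final"]), nrow(calls$final))
})
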