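# annotation with a same-strand gene chain A-B-C ('+') and a lone '-' gene
chain_annotation <- function() {
  genome_annotation("chr", 10000, data.frame(
    feature_id = c("A", "B", "C", "D"),
    start = c(1000L, 2100L, 3200L, 8000L),
    end = c(2000L, 3100L, 4200L, 8600L),
    strand = c("+", "+", "+", "-"),
    feature_type = "CDS", stringsAsFactors = FALSE))
}

# n fragments bridging the junction between left gene end and right gene start
bridges <- function(le, rs, n, strand = "+") {
  if (n == 0) return(NULL)
  data.frame(replicon = "chr", start = le - 50L - seq_len(n), end = rs + 50L,
             strand = strand, stringsAsFactors = FALSE)
}

test_that("four bridging fragments join a gene pair, three do not", {
  ann <- chain_annotation()
  op4 <- infer_primary_operons(ann, bridges(2000, 2100, 4))
  expect_identical(length(op4$operons), 1L)
  expect_identical(op4$operons[[1]]$members, c("A", "B"))
  expect_identical(op4$operons[[1]]$junction_support, 4L)

  op3 <- infer_primary_operons(ann, bridges(2000, 2100, 3))
  expect_identical(length(op3$operons), 0L)
  expect_setequal(op3$monocistronic, c("A", "B"))   # fragments overlap them
  expect_setequal(op3$untranscribed, c("C", "D"))
})

test_that("transitive joining yields maximal chains verified by a junction oracle", {
  ann <- chain_annotation()
  fr <- rbind(bridges(2000, 2100, 5), bridges(3100, 3200, 6))
  ops <- infer_primary_operons(ann, fr)
  expect_identical(length(ops$operons), 1L)
  expect_identical(ops$operons[[1]]$members, c("A", "B", "C"))
  expect_identical(ops$operons[[1]]$junction_support, c(5L, 6L))

  # oracle: exhaustive per-fragment overlap enumeration on random input
  set.seed(31)
  rnd <- data.frame(replicon = "chr",
                    start = sample.int(9000, 400, replace = TRUE),
                    strand = sample(c("+", "-"), 400, replace = TRUE),
                    stringsAsFactors = FALSE)
  rnd$end <- rnd$start + sample(100:800, 400, replace = TRUE)
  jn <- infer_primary_operons(ann, rnd)$junctions
  f <- ann$features
  for (i in seq_len(nrow(jn))) {
    manual <- 0L
    for (q in seq_len(nrow(rnd))) {
      if (rnd$strand[q] == jn$strand[i] &&
          rnd$start[q] <= jn$left_end[i] && rnd$end[q] >= jn$right_start[i])
        manual <- manual + 1L
    }
    expect_identical(jn$support[i], manual)
  }
})

test_that("operon members are ordered in transcription direction on '-'", {
  ann <- genome_annotation("chr", 10000, data.frame(
    feature_id = c("x", "y"), start = c(1000L, 2100L), end = c(2000L, 3000L),
    strand = "-", feature_type = "CDS", stringsAsFactors = FALSE))
  ops <- infer_primary_operons(ann, bridges(2000, 2100, 4, strand = "-"))
  expect_identical(ops$operons[[1]]$members, c("y", "x"))  # rightmost first
})

test_that("raising the bridge threshold never merges previously separate genes", {
  ann <- chain_annotation()
  fr <- rbind(bridges(2000, 2100, 4), bridges(3100, 3200, 6))
  sets <- lapply(c(4, 5, 7), function(th)
    infer_primary_operons(ann, fr, operon_params(bridge_threshold = th))$operons)
  expect_identical(lapply(sets[[1]], `[[`, "members"), list(c("A", "B", "C")))
  expect_identical(lapply(sets[[2]], `[[`, "members"), list(c("B", "C")))
  expect_identical(length(sets[[3]]), 0L)
})

test_that("suboperons are suffixes starting at internal utr TSSs", {
  ann <- chain_annotation()
  fr <- rbind(bridges(2000, 2100, 5), bridges(3100, 3200, 6))
  ops <- infer_primary_operons(ann, fr)
  recs <- data.frame(position = c(950L, 2050L, 3150L),
                     strand = "+", read_starts = c(40L, 20L, 15L),
                     class = "utr", assigned_feature = c("A", "B", "C"),
                     stringsAsFactors = FALSE)
  withsub <- call_suboperons(ops, recs)
  op <- withsub$operons[[1]]
  expect_identical(op$primary_tss, 950L)
  expect_identical(length(op$suboperons), 2L)
  expect_identical(op$suboperons[[1]]$members, c("B", "C"))
  expect_identical(op$suboperons[[2]]$members, "C")

  # no internal TSS: no suboperons
  nosub <- call_suboperons(ops, recs[1, ])
  expect_identical(length(nosub$operons[[1]]$suboperons), 0L)
})

test_that("functional labels rescue junctions one fragment short", {
  ann <- chain_annotation()
  jn <- infer_primary_operons(ann, bridges(2000, 2100, 3))$junctions
  lab_same <- data.frame(gene_id = c("A", "B"), label = "purine biosynthesis",
                         stringsAsFactors = FALSE)
  lab_diff <- data.frame(gene_id = c("A", "B"), label = c("x", "y"),
                         stringsAsFactors = FALSE)
  expect_identical(nrow(rescue_functional_pairs(jn, lab_same)), 1L)
  expect_identical(nrow(rescue_functional_pairs(jn, lab_diff)), 0L)

  jn2 <- infer_primary_operons(ann, bridges(2000, 2100, 2))$junctions
  expect_identical(nrow(rescue_functional_pairs(jn2, lab_same)), 0L)

  ops <- infer_primary_operons(ann, bridges(2000, 2100, 3),
                               functional_labels = lab_same)
  expect_identical(ops$operons[[1]]$members, c("A", "B"))
  expect_true(ops$operons[[1]]$rescued[1])
})

test_that("organization summary tallies operons, sizes and coverage", {
  ann <- chain_annotation()
  fr <- rbind(bridges(2000, 2100, 5), bridges(3100, 3200, 6))
  ops <- call_suboperons(infer_primary_operons(ann, fr), data.frame(
    position = 2050L, strand = "+", read_starts = 10L, class = "utr",
    assigned_feature = "B", stringsAsFactors = FALSE))
  s <- summarize_organization(ops, ann)
  expect_identical(s$operons, 1L)
  expect_identical(s$suboperons, 1L)
  expect_identical(s$genes_in_operons, 3L)
  expect_identical(s$monocistronic, 0L)
  expect_identical(s$untranscribed, 1L)
  expect_equal(s$pct_transcribed, 75.0)
  expect_identical(as.integer(s$size_histogram["3"]), 1L)

  none <- summarize_organization(infer_primary_operons(ann, NULL), ann)
  expect_identical(none$operons, 0L)
  expect_identical(none$monocistronic, 0L)
  expect_equal(none$pct_transcribed, 0.0)
})

test_that("each gene appears in at most one operon on synthetic data", {
  ss <- small_sim()
  ops <- infer_primary_operons(ss$sim$annotation, ss$whole$fragments)
  all_members <- unlist(lapply(ops$operons, `[[`, "members"))
  expect_identical(anyDuplicated(all_members), 0L)
  m <- evaluate_operon_calls(ops, ss$sim$truth)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
})
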