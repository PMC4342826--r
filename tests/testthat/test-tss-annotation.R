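make_cand <- function(position, strand, read_starts = 20L) {
  data.frame(replicon = "chr", position = as.integer(position), strand = strand,
             read_starts = as.integer(read_starts), prev_read_starts = 0L,
             ratio = Inf, tls_feature = NA_character_, tls_distance = NA_integer_,
             tls_within_X = NA, detection_mode = "automatic",
             stringsAsFactors = FALSE)
}

test_that("TSS classes follow genomic context with utr precedence", {
  ann <- tiny_annotation()     # g1 [200,400]+, g2 [600,900]+, g3 [1500,1800]-
  cand <- make_cand(c(150, 250, 300, 4800, 450), c("+", "+", "-", "+", "+"))
  rec <- classify_tss(cand, ann)
  expect_identical(rec$class, c("utr", "intragenic", "antisense", "intergenic", "utr"))
  expect_identical(rec$assigned_feature[1], "g1")
  expect_identical(rec$utr_length[1], 50L)
  expect_identical(rec$assigned_feature[2], "g1")
  expect_identical(rec$assigned_feature[5], "g2")
  expect_identical(rec$utr_length[5], 150L)

  # a TSS inside gene g1 but upstream of g2 is intragenic, not utr
  inside <- classify_tss(make_cand(390, "+"), ann)
  expect_identical(inside$class, "intragenic")

  # a TSS exactly on the TLS has utr length 0
  on_tls <- classify_tss(make_cand(200, "+"), ann)
  expect_identical(on_tls$class, "utr")
  expect_identical(on_tls$utr_length, 0L)

  # every record gets exactly one class
  expect_false(anyNA(rec$class))
})

test_that("antisense classification consults detected UTRs of the opposite strand", {
  ann <- tiny_annotation()
  # 1900 '+' lies over no feature but inside the 5'-UTR [1801, 1950] of g3 '-'
  utr_regions <- data.frame(feature_id = "g3", start = 1801L, end = 1950L,
                            strand = "-", stringsAsFactors = FALSE)
  plain <- classify_tss(make_cand(1900, "+"), ann)
  expect_identical(plain$class, "intergenic")
  with_utr <- classify_tss(make_cand(1900, "+"), ann, utr_regions = utr_regions)
  expect_identical(with_utr$class, "antisense")
})

test_that("multiplicity separates genes with one TSS from genes with several", {
  ann <- tiny_annotation()
  # g1: TSSs at 150 and 90; g2: one TSS
  rec <- classify_tss(make_cand(c(150, 90, 450), c("+", "+", "+")), ann)
  rec <- assign_multiplicity(rec)
  expect_identical(rec$multiplicity, c("multiple", "multiple", "single"))

  # 3 genes with {1, 1, 2} TSSs: 2 single genes, 2 multiple TSSs from 1 gene
  rec2 <- classify_tss(make_cand(c(150, 450, 1850, 1900), c("+", "+", "-", "-")), ann)
  rec2 <- assign_multiplicity(rec2)
  expect_identical(sum(rec2$multiplicity == "single"), 2L)
  expect_identical(sum(rec2$multiplicity == "multiple"), 2L)
  expect_identical(unique(rec2$assigned_feature[rec2$multiplicity == "multiple"]), "g3")
})

test_that("intragenic TSSs in the first half propose in-frame start corrections", {
  ann <- genome_annotation("chr", 1000, data.frame(
    feature_id = "g1", start = 100L, end = 400L, strand = "+",
    feature_type = "CDS", stringsAsFactors = FALSE))
  seqv <- rep("C", 1000)
  seqv[100:102] <- c("A", "T", "G")
  seqv[160:162] <- c("A", "T", "G")      # in frame: 160 = 100 + 60
  genome <- c(chr = paste(seqv, collapse = ""))

  rec <- classify_tss(make_cand(150, "+"), ann)
  prop <- propose_tls_corrections(rec, ann, genome)
  expect_identical(prop$old_tls, 100L)
  expect_identical(prop$proposed_tls, 160L)

  # TSS in the second half: no proposal
  rec2 <- classify_tss(make_cand(300, "+"), ann)
  expect_identical(nrow(propose_tls_corrections(rec2, ann, genome)), 0L)

  # no in-frame start codon before the midpoint: no proposal
  seqv[160:162] <- c("C", "C", "C")
  genome2 <- c(chr = paste(seqv, collapse = ""))
  expect_identical(nrow(propose_tls_corrections(rec, ann, genome2)), 0L)

  # out-of-frame ATG is not accepted
  seqv[161:163] <- c("A", "T", "G")
  genome3 <- c(chr = paste(seqv, collapse = ""))
  expect_identical(nrow(propose_tls_corrections(rec, ann, genome3)), 0L)
})

test_that("UTR statistics use the lower-central median and 5-nt bins", {
  s1 <- compute_utr_stats(c(50L, 51L, 52L))
  expect_identical(s1$median, 51L)
  s2 <- compute_utr_stats(c(50L, 52L))
  expect_identical(s2$median, 50L)     # lower of the two central values

  s3 <- compute_utr_stats(c(3L, 27L, 33L, 501L))
  h <- s3$histogram
  expect_identical(h$count[h$bin == "1-5"], 1L)
  expect_identical(h$count[h$bin == "26-30"], 1L)
  expect_identical(h$count[h$bin == "31-35"], 1L)
  expect_identical(h$count[h$bin == ">500"], 1L)
  expect_identical(s3$leaderless_count, 1L)
  expect_identical(sum(h$count), 4L)

  # histogram against a direct tally oracle on many draws
  set.seed(5)
  lens <- sample(1:600, 5000, replace = TRUE)
  s4 <- compute_utr_stats(lens)
  expect_identical(sum(s4$histogram$count), 5000L)
  oracle_bin <- table(cut(lens, c(seq(0, 500, by = 5), Inf)))
  expect_identical(unname(s4$histogram$count), unname(as.integer(oracle_bin)))
  expect_identical(s4$leaderless_count, sum(lens < 10))
  expect_identical(s4$median, sort(lens)[2500])
})

test_that("novel transcripts are delineated by gap-tolerant coverage extension", {
  ann <- tiny_annotation()
  rec <- classify_tss(make_cand(c(300, 4000, 4500), c("-", "+", "+")), ann)
  expect_identical(rec$class, c("antisense", "intergenic", "intergenic"))

  frs <- rbind(
    data.frame(replicon = "chr", start = 151L, end = 300L, strand = "-"),   # 150 nt
    data.frame(replicon = "chr", start = 4000L, end = 4014L, strand = "+"), # 15 nt
    data.frame(replicon = "chr", start = 4500L, end = 4529L, strand = "+"), # 30 nt
    data.frame(replicon = "chr", start = 4534L, end = 4563L, strand = "+")) # gap 4, 30 nt
  cov <- fragment_coverage(frs, 5000)
  nov <- delineate_novel_transcripts(rec, cov, ann)
  expect_identical(nrow(nov), 2L)       # the 15-nt one is suppressed
  anti <- nov[nov$category == "antisense", ]
  expect_identical(anti$length, 150L)
  expect_identical(anti$antisense_subtype, "cds_overlap")
  expect_identical(anti$start, 151L)
  gapped <- nov[nov$tss_position == 4500, ]
  expect_identical(gapped$length, 64L)  # 30 + 4 + 30

  # a gap of 6 > 5 stops the extension
  frs2 <- rbind(frs[3, ], transform(frs[4, ], start = 4536L, end = 4565L))
  nov2 <- delineate_novel_transcripts(rec[3, ], fragment_coverage(frs2, 5000), ann)
  expect_identical(nov2$length, 30L)
})

test_that("feature length supports inclusive and difference conventions", {
  expect_equal(feature_length(100, 100), 1)
  expect_equal(feature_length(2087761, 2087336, inclusive = FALSE), 425)
  expect_equal(feature_length(27291, 27628, inclusive = FALSE), 337)
  expect_equal(feature_length(10, 14), 5)
})

test_that("synthetic planted TSSs all classify as utr of their gene", {
  ss <- small_sim()
  cand <- make_cand(ss$sim$truth$tss$position[ss$sim$truth$tss$kind != "stable_rna"],
                    ss$sim$truth$tss$strand[ss$sim$truth$tss$kind != "stable_rna"])
  rec <- classify_tss(cand, ss$sim$annotation)
  expect_true(all(rec$class == "utr"))
  expect_identical(rec$assigned_feature,
                   ss$sim$truth$tss$gene_id[ss$sim$truth$tss$kind != "stable_rna"])
})
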