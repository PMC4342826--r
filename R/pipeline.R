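#' Default pipeline configuration
#'
#' A flat list with one block per stage. Every default equals the
#' study parameter where one exists (T = 6, R = 6, X = 500 for TSS
#' calling, bridging threshold 4, 70-nt promoter windows, RBS analysis
#' restricted to 5'-UTRs longer than 9 nt, 1-kb read-pair distance,
#' 20-nt minimal antisense transcript length, abundance class
#' boundaries at 16/160/1600).
#'
#' @param out_dir output directory for artifact files.
#' @param seed master seed; all stage seeds derive from it.
#' @return config list.
#' @export
pipeline_config <- function(out_dir = tempfile("primarytx_run_"), seed = 1L) {
  list(out_dir = out_dir,
       seed = as.integer(seed),
       simulate = TRUE,
       inputs = list(gff = NULL, fasta = NULL, primary_readstarts = NULL,
                     whole_fragments = NULL, whole_readstarts = NULL),
       sim = list(),                  # overrides for sim_params()
       tss = list(T = 6, R = 6, X = 500, rescue_margin = 1,
                  fp_window = 50, fp_peak_fraction = 0.5,
                  min_whole_tx_support = 1),
       operon = list(bridge_threshold = 4, functional_rescue_margin = 1),
       abundance = list(boundaries = c(low = 16, middle = 160, high = 1600),
                        stranded = TRUE),
       motif = list(window = 70, rbs_window = 20, min_utr = 9,
                    n_restarts = 20, pseudocount = 0.25, tol = 1e-6),
       novel = list(min_len = 20, max_gap = 5))
}

#' Read a pipeline configuration from YAML
#'
#' Missing keys fall back to [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  base <- pipeline_config()
  merge2 <- function(a, b) {
    for (k in names(b)) {
      a[[k]] <- if (is.list(a[[k]]) && is.list(b[[k]])) merge2(a[[k]], b[[k]]) else b[[k]]
    }
    a
  }
  cfg <- merge2(base, user)
  if (!is.null(cfg$abundance$boundaries))
    cfg$abundance$boundaries <- stats::setNames(as.numeric(cfg$abundance$boundaries),
                                               c("low", "middle", "high"))
  cfg
}

.validate_config <- function(config) {
  if (!isTRUE(config$simulate)) {
    need <- c("gff", "fasta", "primary_readstarts", "whole_fragments")
    for (k in need) {
      p <- config$inputs[[k]]
      if (is.null(p) || !file.exists(p))
        stop("config validation: missing input file for '", k, "'")
    }
  }
  invisible(config)
}

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full annotation pipeline
#'
#' Stages: ingest (or simulate) -> TSS detection -> classification and
#' 5'-UTR statistics -> motif discovery -> operons -> abundance ->
#' report. Every rescue and false-positive flag is written to the
#' decision log so a user can audit the deterministic surrogates for
#' manual curation. With `simulate = TRUE` the synthetic generator
#' provides the inputs and recovery metrics against ground truth are
#' included.
#'
#' @param config list from [pipeline_config()] /
#'   [read_pipeline_config()].
#' @return invisibly, a list with all stage results and the paths of
#'   the artifact files.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  .validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "decisions.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)

  # --- ingest ---------------------------------------------------------
  truth <- NULL
  if (isTRUE(config$simulate)) {
    sp <- do.call(sim_params, c(config$sim, list(seed = config$seed)))
    sim <- generate_genome(sp)
    primary <- simulate_primary_library(sim$truth, sp)
    whole <- simulate_whole_library(sim$truth, sp)
    write_simulation(sim, primary, whole, config$out_dir)
    annotation <- sim$annotation; genome <- sim$genome; truth <- sim$truth
    fragments <- whole$fragments; whole_profile <- whole$profile
  } else {
    annotation <- read_gff3(config$inputs$gff)
    genome <- read_fasta_genome(config$inputs$fasta)
    primary <- read_read_starts(config$inputs$primary_readstarts,
                                library = "five_prime_enriched",
                                replicon_length = annotation$length)
    fragments <- read_fragments(config$inputs$whole_fragments)
    whole_profile <- if (!is.null(config$inputs$whole_readstarts))
      read_read_starts(config$inputs$whole_readstarts,
                       library = "whole_transcriptome",
                       replicon_length = annotation$length) else NULL
  }
  whole_cov <- fragment_coverage(fragments, annotation$length)

  # --- TSS detection --------------------------------------------------
  tp <- do.call(tss_params, config$tss)
  calls <- call_tss(primary, annotation, whole_coverage = whole_cov, params = tp)
  for (i in seq_len(nrow(calls$false_positive)))
    logf("false_positive\t%d\t%s\tcount %d below %.0f%% of window max",
         calls$false_positive$position[i], calls$false_positive$strand[i],
         calls$false_positive$read_starts[i], 100 * tp$fp_peak_fraction)
  for (i in seq_len(nrow(calls$stable_rna)))
    logf("stable_rna_removed\t%d\t%s", calls$stable_rna$position[i],
         calls$stable_rna$strand[i])
  for (i in seq_len(nrow(calls$rescued)))
    logf("rescued\t%d\t%s\twhole-transcriptome support", calls$rescued$position[i],
         calls$rescued$strand[i])

  # --- classification + UTR stats ------------------------------------
  records <- annotate_tss(calls$final, annotation, params = tp,
                          whole_coverage = whole_cov)
  utr_stats <- compute_utr_stats(records)
  corrections <- propose_tls_corrections(records, annotation, genome)
  novel <- delineate_novel_transcripts(records, whole_cov, annotation,
                                       min_len = config$novel$min_len,
                                       max_gap = config$novel$max_gap)

  # --- motifs ---------------------------------------------------------
  mcfg <- config$motif
  utr_rec <- records[records$class == "utr", , drop = FALSE]
  promoters <- NULL; rbs <- NULL; codons <- NULL
  if (nrow(utr_rec) >= 10) {
    windows <- extract_upstream(utr_rec$position, utr_rec$strand, genome,
                                window = mcfg$window,
                                replicon_id = annotation$replicon_id)
    ok <- nchar(windows) == mcfg$window
    promoters <- find_promoter_elements(windows[ok],
                                        n_restarts = mcfg$n_restarts,
                                        seed = config$seed,
                                        pseudocount = mcfg$pseudocount,
                                        tol = mcfg$tol)
    rb <- rbs_upstream_sequences(records, annotation, genome,
                                 window = mcfg$rbs_window, min_utr = mcfg$min_utr)
    if (length(rb$sequences) >= 10)
      rbs <- find_rbs(rb$sequences, n_restarts = mcfg$n_restarts,
                      seed = config$seed + 1L, pseudocount = mcfg$pseudocount,
                      tol = mcfg$tol)
    codons <- start_codon_usage(annotation, genome,
                                gene_ids = unique(utr_rec$assigned_feature))
  }

  # --- operons --------------------------------------------------------
  op <- do.call(operon_params, config$operon)
  operon_set <- infer_primary_operons(annotation, fragments, params = op)
  operon_set <- call_suboperons(operon_set, records)
  organization <- summarize_organization(operon_set, annotation)

  # --- abundance ------------------------------------------------------
  ap <- abundance_params(boundaries = config$abundance$boundaries,
                         stranded = config$abundance$stranded)
  abundance <- if (!is.null(whole_profile))
    abundance_table(annotation, whole_profile, params = ap) else NULL

  # --- artifacts ------------------------------------------------------
  .write_tsv(calls$final, file.path(config$out_dir, "tss.tsv"))
  .write_tsv(records, file.path(config$out_dir, "tss_annotated.tsv"))
  .write_tsv(utr_stats$histogram, file.path(config$out_dir, "utr_histogram.tsv"))
  .write_tsv(corrections, file.path(config$out_dir, "tls_corrections.tsv"))
  .write_tsv(novel, file.path(config$out_dir, "novel_transcripts.tsv"))
  write_operons(operon_set, file.path(config$out_dir, "operons.tsv"))
  if (!is.null(abundance))
    .write_tsv(abundance$records, file.path(config$out_dir, "abundance.tsv"))
  if (!is.null(codons))
    .write_tsv(codons, file.path(config$out_dir, "start_codons.tsv"))

  # --- recovery metrics on synthetic truth ---------------------------
  recovery <- NULL
  if (!is.null(truth)) {
    tssm <- evaluate_tss_calls(calls$final, truth)
    opm <- evaluate_operon_calls(operon_set, truth)
    recovery <- data.frame(metric = c("tss_precision", "tss_recall",
                                      "operon_precision", "operon_recall"),
                           value = c(tssm$precision, tssm$recall,
                                     opm$precision, opm$recall))
    .write_tsv(recovery, file.path(config$out_dir, "recovery.tsv"))
  }

  invisible(list(annotation = annotation, calls = calls, records = records,
                 utr_stats = utr_stats, corrections = corrections, novel = novel,
                 promoters = promoters, rbs = rbs, codons = codons,
                 operons = operon_set, organization = organization,
                 abundance = abundance, recovery = recovery, truth = truth,
                 out_dir = config$out_dir))
}
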