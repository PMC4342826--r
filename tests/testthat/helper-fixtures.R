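# Shared fixture builders and independent oracles. Everything is built
# in code; no files ship with the package.

# a small annotation: two '+' CDS, one '-' CDS, one '+' tRNA
tiny_annotation <- function(length = 5000) {
  genome_annotation("chr", length, data.frame(
    feature_id = c("g1", "g2", "g3", "t1"),
    start = c(200L, 600L, 1500L, 2500L),
    end = c(400L, 900L, 1800L, 2576L),
    strand = c("+", "+", "-", "+"),
    feature_type = c("CDS", "CDS", "CDS", "tRNA"),
    stringsAsFactors = FALSE))
}

tiny_profile <- function(positions, strands, counts,
                         library = "five_prime_enriched", length = 5000,
                         replicon = "chr") {
  read_start_profile(replicon, positions, strands, counts,
                     library = library, replicon_length = length)
}

# dense, brute-force evaluation of the three TSS criteria, written
# independently of the sparse implementation: a dense count vector per
# strand, per-position shifts for the ratio, and per-gene distance
# minimization for the TLS criterion
oracle_detect <- function(profile, annotation, T = 6, R = 6, X = 500) {
  L <- annotation$length
  f <- annotation$features
  hits <- list()
  for (s in c("+", "-")) {
    cnt <- numeric(L)
    st <- profile$starts[profile$starts$strand == s, ]
    cnt[st$position] <- st$count
    prev <- if (s == "+") c(0, cnt[-L]) else c(cnt[-1], 0)
    pass_ab <- cnt > T & (prev == 0 | cnt / prev > R)
    # distance to nearest downstream TLS, via per-gene pmin
    g <- f[f$strand == s & f$feature_type == "CDS", ]
    dist <- rep(Inf, L)
    for (i in seq_len(nrow(g))) {
      tls <- if (s == "+") g$start[i] else g$end[i]
      d <- if (s == "+") tls - seq_len(L) else seq_len(L) - tls
      d[d < 0] <- Inf
      dist <- pmin(dist, d)
    }
    pos <- which(pass_ab & dist <= X)
    if (length(pos))
      hits[[s]] <- data.frame(position = pos, strand = s,
                              stringsAsFactors = FALSE)
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(position = integer(), strand = character())
}

# random sparse profile on [1, L]: background counts plus a few spikes
random_profile <- function(seed, L = 10000, n_bg = 300, n_spike = 12,
                           replicon = "chr") {
  set.seed(seed)
  pos <- sample.int(L, n_bg + n_spike)
  strand <- sample(c("+", "-"), n_bg + n_spike, replace = TRUE)
  cnt <- c(1L + stats::rpois(n_bg, 2), 5L + stats::rpois(n_spike, 20))
  read_start_profile(replicon, pos, strand, cnt,
                     library = "five_prime_enriched", replicon_length = L)
}

# random annotation with a few genes per strand for oracle tests
random_annotation <- function(seed, L = 10000) {
  set.seed(seed + 1000)
  k <- sample(2:4, 1)
  starts <- sort(sample.int(L - 900, k))
  genome_annotation("chr", L, data.frame(
    feature_id = sprintf("g%d", seq_len(k)),
    start = starts, end = starts + 600L,
    strand = sample(c("+", "-"), k, replace = TRUE),
    feature_type = "CDS", stringsAsFactors = FALSE))
}

# small simulation shared by pipeline-level tests (cached per session)
.small_sim_cache <- new.env(parent = emptyenv())
small_sim <- function() {
  if (is.null(.small_sim_cache$sim)) {
    sp <- sim_params(replicon_length = 90000, n_transcription_units = 25,
                     n_stable_rna_units = 2, seed = 421)
    sim <- generate_genome(sp)
    .small_sim_cache$sim <- list(
      params = sp, sim = sim,
      primary = simulate_primary_library(sim$truth, sp),
      whole = simulate_whole_library(sim$truth, sp))
  }
  .small_sim_cache$sim
}
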