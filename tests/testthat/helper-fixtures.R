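# Shared fixtures, built in code and cached for the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small simulated genome shared across files: 8 proviruses, recent ages
small_sim <- function() {
  cached("small_sim", {
    cfg <- sim_config(rng_seed = 421L, host_length = 250000L,
                      n_per_subgroup = c(A = 3L, B1 = 2L, B2 = 2L, C = 1L),
                      age_distribution = list(dist = "uniform",
                                              min = 0, max = 2))
    simulate_insertions(cfg)
  })
}

# mined + annotated calls for the small genome
small_calls <- function() {
  cached("small_calls", {
    sim <- small_sim()
    hits <- seed_search(sim$genome, sim$ancestors)
    loci <- extract_loci(hits, sim$genome)
    list(hits = hits, loci = loci,
         calls = annotate_loci(loci, sim$ancestors, sim$ancestor_features))
  })
}

# match an annotated call back to its truth row by genome span
truth_row <- function(call, truth) {
  g_start <- if (call$strand == "+") call$locus_start + call$provirus[1]
             else call$locus_end - call$provirus[2]
  g_end <- if (call$strand == "+") call$locus_start + call$provirus[2]
           else call$locus_end - call$provirus[1]
  hit <- which(abs(truth$start - g_start) <= 5 & abs(truth$end - g_end) <= 5)
  if (length(hit) == 1L) hit else NA_integer_
}

# uniform random DNA string
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent site-counting K2P oracle (used against k2p_distance)
oracle_k2p <- function(a, b, mask) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  keep <- setdiff(which(ca %in% c("A", "C", "G", "T") &
                          cb %in% c("A", "C", "G", "T")), mask)
  n <- length(keep)
  ts_pairs <- c("AG", "GA", "CT", "TC")
  P <- sum(paste0(ca[keep], cb[keep]) %in% ts_pairs) / n
  Q <- sum(ca[keep] != cb[keep]) / n - P
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  D <- if (w1 <= 0 || w2 <= 0) NA_real_ else -0.5 * log(w1) - 0.25 * log(w2)
  list(P = P, Q = Q, D = D, n = n)
}
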