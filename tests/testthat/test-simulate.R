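test_that("configuration invariants are enforced", {
  expect_error(sim_config(rate_M = 0), "rate_M")
  expect_error(sim_config(cpg_multiplier = 0.5), "cpg_multiplier")
  expect_error(sim_config(ltr_length = 80), "ltr_length")
  expect_error(sim_config(n_per_subgroup = c(X = 2L)), "subgroup")
  cfg <- sim_config()
  # the diagnostic deletion lengths ship by default
  expect_true(all(c(133L, 1487L, 2216L) %in% cfg$deletion_specs$length))
  expect_equal(cfg$rate_M, 0.0022)
})

test_that("ancestral proviruses carry subgroup motifs and identical LTRs", {
  cfg <- sim_config(rng_seed = 11L)
  a <- build_ancestral_provirus(cfg, "A")
  expect_true(grepl("PRPPIY", a$genes_aa$gag, fixed = TRUE))
  expect_true(grepl("PPPY", a$genes_aa$gag, fixed = TRUE))
  expect_true(grepl("CETTG", a$genes_aa$env, fixed = TRUE))
  cc <- build_ancestral_provirus(cfg, "C")
  expect_true(grepl("PQPPVL", cc$genes_aa$gag, fixed = TRUE))
  expect_true(grepl("TPPY", cc$genes_aa$gag, fixed = TRUE))
  for (sg in c("A", "B1", "B2", "C")) {
    p <- build_ancestral_provirus(cfg, sg)
    L <- nchar(p$ltr)
    expect_identical(substr(p$sequence, 1, L),
                     substr(p$sequence, nchar(p$sequence) - L + 1,
                            nchar(p$sequence)))
    # feature map tiles the provirus
    f <- p$features[!startsWith(p$features$feature, "motif"), ]
    expect_equal(f$start[1], 0)
    expect_equal(f$end[nrow(f)], nchar(p$sequence))
    expect_true(all(f$start[-1] == f$end[-nrow(f)]))
    # genes are stop-free ORFs
    for (g in c("gag", "pro", "pol", "env")) {
      aa <- p$genes_aa[[g]]
      expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
    }
  }
  expect_error(build_ancestral_provirus(cfg, "Z"), "unknown subgroup")
  # deterministic given the config
  expect_identical(build_ancestral_provirus(cfg, "A")$sequence, a$sequence)
})

test_that("sequence evolution is substitution-only with the configured rate", {
  cfg <- sim_config(rng_seed = 3L, cpg_multiplier = 1)
  set.seed(42)
  s <- rand_dna(10000)
  expect_identical(evolve_sequence(s, 0, cfg), s)
  tot <- 0
  for (i in 1:20) {
    e <- evolve_sequence(s, 2.0, cfg, detail = TRUE)
    expect_equal(nchar(e$sequence), nchar(s))
    tot <- tot + e$n_events
  }
  # Poisson expectation: 20 x 10000 x 0.0022 x 2 = 880 events
  expect_lt(abs(tot - 880), 4 * sqrt(880))
})

test_that("transition:transversion event ratio follows kappa", {
  cfg <- sim_config(rng_seed = 3L, cpg_multiplier = 1, kappa = 2)
  set.seed(7)
  s <- rand_dna(8000)
  ev <- list()
  for (i in 1:6)
    ev[[i]] <- evolve_sequence(s, 120, cfg, detail = TRUE)$events
  ev <- do.call(rbind, ev)
  expect_gt(nrow(ev), 10000)
  # kappa = 2 over two transversion targets -> half of events are transitions
  expect_lt(abs(mean(ev$transition) - 0.5), 0.03)
})

test_that("CpG sites evolve faster when the multiplier is raised", {
  set.seed(8)
  s <- paste(rep("ACGT", 500), collapse = "")   # CpG-rich template
  cfg10 <- sim_config(rng_seed = 3L, cpg_multiplier = 10)
  cfg1 <- sim_config(rng_seed = 3L, cpg_multiplier = 1)
  n10 <- sum(replicate(10, evolve_sequence(s, 2, cfg10, detail = TRUE)$n_events))
  n1 <- sum(replicate(10, evolve_sequence(s, 2, cfg1, detail = TRUE)$n_events))
  expect_gt(n10, 2 * n1)
})

test_that("simulated genomes conserve length and are reproducible", {
  sim <- small_sim()
  tr <- sim$truth
  expect_equal(nrow(tr), 8L)
  expect_equal(nchar(sim$genome[[1]]),
               sim$config$host_length + sum(tr$end - tr$start) +
                 sum(nchar(tr$tsd)))
  # byte-identical re-run from the same config
  sim2 <- simulate_insertions(sim$config)
  expect_identical(sim2$genome, sim$genome)
  expect_identical(sim2$truth, tr)
})

test_that("truth intervals slice back to proviruses delimited by LTRs", {
  sim <- small_sim()
  tr <- sim$truth
  for (i in seq_len(nrow(tr))) {
    pv <- substr(sim$genome[[1]], tr$start[i] + 1, tr$end[i])
    if (tr$strand[i] == "-") pv <- ervkit:::revcomp(pv)
    # canonical LTR termini at both ends (TG ... CA)
    expect_identical(substr(pv, 1, 2), "TG")
    expect_identical(substr(pv, nchar(pv) - 1, nchar(pv)), "CA")
    # the TSD flanks the provirus on both sides in genome coordinates
    k <- nchar(tr$tsd[i])
    expect_identical(substr(sim$genome[[1]], tr$start[i] - k + 1, tr$start[i]),
                     tr$tsd[i])
    expect_identical(substr(sim$genome[[1]], tr$end[i] + 1, tr$end[i] + k),
                     tr$tsd[i])
  }
})

test_that("zero-age insertions have identical LTR pairs", {
  cfg <- sim_config(rng_seed = 5L, host_length = 140000L,
                    n_per_subgroup = c(A = 2L, C = 1L),
                    age_distribution = list(dist = "fixed", value = 0))
  sim <- simulate_insertions(cfg)
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    pv <- substr(sim$genome[[1]], tr$start + 1, tr$end)
    if (tr$strand == "-") pv <- ervkit:::revcomp(pv)
    expect_identical(substr(pv, 1, tr$ltr5_length),
                     substr(pv, nchar(pv) - tr$ltr3_length + 1, nchar(pv)))
  }
})

test_that("LTR pair divergence is non-decreasing in true age", {
  hamming_at_age <- function(age, seed) {
    cfg <- sim_config(rng_seed = seed, host_length = 150000L,
                      n_per_subgroup = c(A = 4L),
                      age_distribution = list(dist = "fixed", value = age))
    sim <- simulate_insertions(cfg)
    mean(vapply(seq_len(nrow(sim$truth)), function(i) {
      tr <- sim$truth[i, ]
      pv <- substr(sim$genome[[1]], tr$start + 1, tr$end)
      if (tr$strand == "-") pv <- ervkit:::revcomp(pv)
      l5 <- substr(pv, 1, tr$ltr5_length)
      l3 <- substr(pv, nchar(pv) - tr$ltr3_length + 1, nchar(pv))
      sum(strsplit(l5, "")[[1]] != strsplit(l3, "")[[1]])
    }, numeric(1)))
  }
  h <- vapply(c(0, 1.5, 6), hamming_at_age, numeric(1), seed = 17L)
  expect_true(all(diff(h) >= 0))
  expect_equal(h[1], 0)
})

test_that("simulator output files round-trip", {
  cfg <- sim_config(rng_seed = 9L, host_length = 120000L,
                    n_per_subgroup = c(A = 1L, B1 = 1L))
  out <- file.path(tempdir(), "simtest")
  sim <- simulate_insertions(cfg, out_prefix = out)
  genome <- read_fasta(sim$files[["genome"]])
  expect_identical(unname(genome), unname(sim$genome))
  tr <- read.delim(sim$files[["truth"]], comment.char = "#")
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$start, sim$truth$start)
  unlink(paste0(out, "*"))
})
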