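# build a locus with a known provirus planted between random flanks
planted_locus <- function(provirus, tsd = "GATC", flank = 4000, seed = 1) {
  set.seed(seed)
  left <- rand_dna(flank)
  right <- rand_dna(flank)
  list(sequence = paste0(left, tsd, provirus, tsd, right),
       start = flank + nchar(tsd),              # 0-based provirus start
       end = flank + nchar(tsd) + nchar(provirus))
}

test_that("identical planted repeats are recovered exactly, with the TSD", {
  cfg <- sim_config(rng_seed = 21L)
  anc <- build_ancestral_provirus(cfg, "A")
  pl <- planted_locus(anc$sequence, tsd = "CATTG", seed = 5)
  lp <- detect_ltr_pair(pl$sequence)
  expect_false(is.null(lp))
  L <- nchar(anc$ltr)
  expect_equal(lp$ltr5, c(pl$start, pl$start + L))
  expect_equal(lp$ltr3, c(pl$end - L, pl$end))
  expect_identical(lp$tsd, "CATTG")
  expect_equal(lp$n_diff, 0L)
  expect_equal(lp$identity, 100)
})

test_that("detection is invariant to host flank, coordinates shift accordingly", {
  cfg <- sim_config(rng_seed = 21L)
  anc <- build_ancestral_provirus(cfg, "A")
  pl1 <- planted_locus(anc$sequence, flank = 4000, seed = 6)
  pl2 <- planted_locus(anc$sequence, flank = 6500, seed = 7)
  lp1 <- detect_ltr_pair(pl1$sequence)
  lp2 <- detect_ltr_pair(pl2$sequence)
  expect_equal(lp1$ltr5 - pl1$start, lp2$ltr5 - pl2$start)
  expect_equal(lp1$ltr3 - pl1$start, lp2$ltr3 - pl2$start)
})

test_that("random sequence yields the no-provirus outcome", {
  set.seed(9)
  expect_null(detect_ltr_pair(rand_dna(12000)))
  # repeats closer than the separation floor are not proviruses
  set.seed(10)
  ltr <- rand_dna(400)
  close_pair <- paste0(rand_dna(3000), ltr, rand_dna(1000), ltr, rand_dna(3000))
  expect_null(detect_ltr_pair(close_pair))
})

test_that("aged proviruses are recovered within tolerance on the small genome", {
  sim <- small_sim()
  sc <- small_calls()
  tr <- sim$truth
  expect_equal(length(sc$calls), nrow(tr))
  for (pc in sc$calls) {
    i <- truth_row(pc, tr)
    expect_false(is.na(i))
    # subgroup assignment is correct
    expect_identical(pc$subgroup, tr$subgroup[i])
    # LTR lengths match the planted (indel-adjusted) lengths
    expect_equal(pc$ltr5[2] - pc$ltr5[1], tr$ltr5_length[i])
    # pair difference count equals the planted substitution divergence
    pv <- substr(sim$genome[[1]], tr$start[i] + 1, tr$end[i])
    if (tr$strand[i] == "-") pv <- ervkit:::revcomp(pv)
    l5 <- substr(pv, 1, tr$ltr5_length[i])
    l3 <- substr(pv, nchar(pv) - tr$ltr3_length[i] + 1, nchar(pv))
    planted_diff <- sum(strsplit(l5, "")[[1]] != strsplit(l3, "")[[1]])
    expect_equal(pc$ltr_identity, 100 * (1 - planted_diff / nchar(l5)))
    # TSD recovered (plus-oriented loci carry the forward TSD)
    tsd_true <- if (pc$strand == "+") tr$tsd[i] else ervkit:::revcomp(tr$tsd[i])
    expect_identical(pc$tsd, tsd_true)
  }
})

test_that("gene mapping projects reference intervals through the alignment", {
  cfg <- sim_config(rng_seed = 22L)
  anc <- build_ancestral_provirus(cfg, "A")
  feats <- anc$features
  # identity projection
  mg <- map_genes(anc$sequence, anc$sequence, feats)
  expect_false(mg$flagged)
  for (g in c("gag", "pro", "pol", "env")) {
    got <- mg$features[mg$features$feature == g, ]
    want <- feats[feats$feature == g, ]
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
  # planted 1487 nt env deletion shortens the projected env interval exactly
  env <- feats[feats$feature == "env", ]
  s0 <- env$start + 300
  del <- paste0(substr(anc$sequence, 1, s0),
                substr(anc$sequence, s0 + 1488, nchar(anc$sequence)))
  mg2 <- map_genes(del, anc$sequence, feats)
  env2 <- mg2$features[mg2$features$feature == "env", ]
  expect_equal(env2$end - env2$start, (env$end - env$start) - 1487)
  # a gene removed entirely is reported absent
  gag <- feats[feats$feature == "gag", ]
  nogag <- paste0(substr(anc$sequence, 1, gag$start),
                  substr(anc$sequence, gag$end + 1, nchar(anc$sequence)))
  mg3 <- map_genes(nogag, anc$sequence, feats)
  expect_false(mg3$features$present[mg3$features$feature == "gag"])
  # identity below the floor flags the provirus
  set.seed(11)
  mg4 <- map_genes(rand_dna(nchar(anc$sequence)), anc$sequence, feats)
  expect_true(mg4$flagged)
})

test_that("motif states classify canonical, variant and altered forms", {
  cfg <- sim_config(rng_seed = 23L)
  a <- build_ancestral_provirus(cfg, "A")
  mgA <- map_genes(a$sequence, a$sequence, a$features)
  mA <- scan_motifs(mgA$features, a$sequence, a$features)
  expect_identical(mA$gag_ld1, "PRPPIY")
  expect_identical(mA$gag_ld2, "PPPY")
  expect_identical(mA$env_cettg, "CETTG")
  cc <- build_ancestral_provirus(cfg, "C")
  mgC <- map_genes(cc$sequence, cc$sequence, cc$features)
  mC <- scan_motifs(mgC$features, cc$sequence, cc$features)
  expect_identical(mC$gag_ld1, "PQPPVL")
  expect_identical(mC$gag_ld2, "TPPY")
  # single-residue CETTG -> CETAG change reads as altered
  iv <- a$features[a$features$feature == "motif_env_cettg", ]
  alt <- ervkit:::overwrite_aa(a$sequence, iv$start, "CETAG")
  mgAlt <- map_genes(alt, a$sequence, a$features)
  expect_identical(scan_motifs(mgAlt$features, alt, a$features)$env_cettg,
                   "altered")
})

test_that("ORF assessment reports stops, partials and full-length genes", {
  cfg <- sim_config(rng_seed = 24L)
  a <- build_ancestral_provirus(cfg, "A")
  mg <- map_genes(a$sequence, a$sequence, a$features)
  orfs <- assess_orfs(mg$features, a$sequence, a$features)
  expect_true(all(orfs$status == "full_length"))
  # planted TAA at codon 120 of gag
  gag <- a$features[a$features$feature == "gag", ]
  at <- gag$start + 3 * 119
  mut <- paste0(substr(a$sequence, 1, at), "TAA",
                substr(a$sequence, at + 4, nchar(a$sequence)))
  orfs2 <- assess_orfs(mg$features, mut, a$features)
  gagrow <- orfs2[orfs2$gene == "gag", ]
  expect_identical(gagrow$status, "premature_stop")
  expect_identical(gagrow$stop_positions, "120")
  # 2216 nt deletion drops pol below the length threshold -> partial
  pol <- a$features[a$features$feature == "pol", ]
  s0 <- pol$start + 500
  del <- paste0(substr(a$sequence, 1, s0),
                substr(a$sequence, s0 + 2217, nchar(a$sequence)))
  mg3 <- map_genes(del, a$sequence, a$features)
  orfs3 <- assess_orfs(mg3$features, del, a$features)
  expect_identical(orfs3$status[orfs3$gene == "pol"], "partial")
})

test_that("motif and ORF scans agree with a translation oracle in the mapped frame", {
  sim <- small_sim()
  sc <- small_calls()
  for (pc in sc$calls[1:4]) {
    gag <- pc$features[pc$features$feature == "gag", ]
    aa <- ervkit:::translate_dna(substr(pc$provirus_seq, gag$start + 1, gag$end))
    # oracle: direct translation of the mapped interval
    has_prppiy <- grepl("PRPPIY", aa, fixed = TRUE)
    expect_identical(pc$motifs$gag_ld1 == "PRPPIY", has_prppiy)
    st <- which(strsplit(aa, "")[[1]] == "*")
    st <- st[st < nchar(aa)]
    orf <- pc$orfs[pc$orfs$gene == "gag", ]
    if (orf$status %in% c("full_length", "premature_stop"))
      expect_identical(orf$stop_positions,
                       paste(st, collapse = ";"))
  }
})

test_that("deletion signatures match expected lengths within tolerance", {
  cfg <- sim_config(rng_seed = 25L)
  a <- build_ancestral_provirus(cfg, "B1")
  pol <- a$features[a$features$feature == "pol", ]
  mk_del <- function(offset, len) {
    s0 <- pol$start + offset
    paste0(substr(a$sequence, 1, s0),
           substr(a$sequence, s0 + len + 1, nchar(a$sequence)))
  }
  # exact 133 nt deletion in pol
  mg <- map_genes(mk_del(2600, 133), a$sequence, a$features)
  d <- detect_deletions(mg$ref_aln, mg$prov_aln, a$features)
  expect_equal(nrow(d), 1L)
  expect_identical(d$gene, "pol")
  expect_identical(d$expected, "133")
  expect_equal(d$observed, 133L)
  # ungapped provirus -> no signatures
  mg0 <- map_genes(a$sequence, a$sequence, a$features)
  expect_equal(nrow(detect_deletions(mg0$ref_aln, mg0$prov_aln, a$features)), 0L)
  # 1480 nt gap matches the 1487 spec within the 10 nt tolerance
  env <- a$features[a$features$feature == "env", ]
  s0 <- env$start + 300
  del1480 <- paste0(substr(a$sequence, 1, s0),
                    substr(a$sequence, s0 + 1481, nchar(a$sequence)))
  mg2 <- map_genes(del1480, a$sequence, a$features)
  d2 <- detect_deletions(mg2$ref_aln, mg2$prov_aln, a$features)
  expect_identical(d2$expected, "1487")
  expect_equal(d2$observed, 1480L)
  # an unexpected long gap is reported as "other"
  mg3 <- map_genes(mk_del(1000, 600), a$sequence, a$features)
  d3 <- detect_deletions(mg3$ref_aln, mg3$prov_aln, a$features)
  expect_identical(d3$expected, "other")
})

test_that("subgroup assignment follows nearest consensus plus the env rule", {
  cfg <- sim_config(rng_seed = 26L)
  refs <- vapply(setNames(nm = c("A", "B1", "C")), function(sg)
    build_ancestral_provirus(cfg, sg)$sequence, character(1))
  names(refs)[2] <- "B"
  b <- build_ancestral_provirus(cfg, "B1")
  feats <- build_ancestral_provirus(cfg, "B1")$features
  # B provirus with the 1487 env deletion -> B1
  env <- feats[feats$feature == "env", ]
  s0 <- env$start + 300
  bdel <- paste0(substr(b$sequence, 1, s0),
                 substr(b$sequence, s0 + 1488, nchar(b$sequence)))
  mg <- map_genes(bdel, b$sequence, feats)
  dels <- detect_deletions(mg$ref_aln, mg$prov_aln, feats)
  expect_identical(assign_subgroup(bdel, refs, dels)$subgroup, "B1")
  # without the deletion -> B2
  expect_identical(assign_subgroup(b$sequence, refs, NULL)$subgroup, "B2")
  # far from every consensus -> unassigned
  set.seed(12)
  expect_identical(assign_subgroup(rand_dna(9000), refs, NULL)$subgroup,
                   "unassigned")
  expect_error(assign_subgroup(b$sequence, character(0)), "consensus")
})
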