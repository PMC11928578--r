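test_that("shared and private indels are fingerprinted from the master alignment", {
  set.seed(61)
  base <- rand_dna(400)
  drop12 <- paste0(substr(base, 1, 100), substr(base, 113, 400))
  ins8 <- paste0(substr(base, 1, 250), "TTAACCGG", substr(base, 251, 400))
  block <- align_sequences(c(p1 = base, p2 = drop12, p3 = drop12, p4 = ins8))
  fp <- fingerprint_indels(block, min_indel_length = 5)
  expect_equal(ncol(fp$matrix), 2L)
  # the two deletion carriers share one vector, the insertion is elsewhere
  expect_identical(fp$matrix["p2", ], fp$matrix["p3", ])
  expect_false(identical(fp$matrix["p1", ], fp$matrix["p2", ]))
  # the insertion block gaps every row except its carrier
  expect_equal(sum(lengths(fp$unique_indels) > 0), 1L)
  cl <- cluster_fingerprints(fp)
  expect_identical(cl[["p2"]], cl[["p3"]])
  expect_false(cl[["p1"]] == cl[["p2"]])
})

test_that("gap-free alignments give empty vectors and a single clade", {
  set.seed(62)
  base <- rand_dna(300)
  cfg <- sim_config(rng_seed = 61L, cpg_multiplier = 1)
  seqs <- setNames(vapply(1:4, function(i) evolve_sequence(base, 1, cfg),
                          character(1)), paste0("p", 1:4))
  block <- align_sequences(seqs)
  fp <- fingerprint_indels(block)
  expect_equal(ncol(fp$matrix), 0L)
  expect_equal(length(unique(cluster_fingerprints(fp))), 1L)
})

test_that("clade labelling is deterministic and permutation-invariant", {
  set.seed(63)
  base <- rand_dna(400)
  d1 <- paste0(substr(base, 1, 50), substr(base, 61, 400))
  d2 <- paste0(substr(base, 1, 200), substr(base, 216, 400))
  seqs <- c(a = base, b = base, c = d1, d = d1, e = d2)
  part1 <- cluster_fingerprints(fingerprint_indels(align_sequences(seqs)))
  part2 <- cluster_fingerprints(fingerprint_indels(align_sequences(seqs[c(5, 3, 1, 2, 4)])))
  # same partition regardless of input order
  for (i in names(seqs)) for (j in names(seqs))
    expect_identical(part1[[i]] == part1[[j]], part2[[i]] == part2[[j]])
  # threshold 0: clades are exactly the distinct vectors
  expect_equal(length(unique(part1)), 3L)
  # a permissive Jaccard threshold merges everything that shares indels
  fp <- fingerprint_indels(align_sequences(seqs))
  merged <- cluster_fingerprints(fp, threshold = 1)
  expect_equal(length(unique(merged)), 1L)
})

test_that("fingerprint vectors round-trip the gap pattern at block resolution", {
  set.seed(64)
  base <- rand_dna(400)
  del <- paste0(substr(base, 1, 150), substr(base, 166, 400))
  block <- align_sequences(c(p1 = base, p2 = del, p3 = base))
  fp <- fingerprint_indels(block, min_indel_length = 3)
  mat <- do.call(rbind, strsplit(block$rows, ""))
  for (r in rownames(fp$matrix)) for (k in seq_len(ncol(fp$matrix))) {
    cols <- fp$blocks$col_start[k]:fp$blocks$col_end[k]
    n_gapped <- sum(mat[r, cols] == "-")
    expect_identical(unname(fp$matrix[r, k]), n_gapped >= 3L)
  }
})

test_that("neighbor joining recovers additive trees exactly", {
  # distances from the tree ((a:1,b:2):1.5,(c:3,d:4):0.5) are additive
  dm <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  dm["a", "b"] <- dm["b", "a"] <- 3
  dm["a", "c"] <- dm["c", "a"] <- 6
  dm["a", "d"] <- dm["d", "a"] <- 7
  dm["b", "c"] <- dm["c", "b"] <- 7
  dm["b", "d"] <- dm["d", "b"] <- 8
  dm["c", "d"] <- dm["d", "c"] <- 7
  tree <- nj_tree(dm)
  expect_s3_class(tree, "phylo")
  # patristic distances reproduce the input matrix exactly
  pat <- ape::cophenetic.phylo(tree)[letters[1:4], letters[1:4]]
  expect_equal(pat, dm, tolerance = 1e-10)
  # ab | cd is the internal bipartition
  expect_true(ape::is.monophyletic(ape::unroot(tree), c("a", "b")) ||
                ape::is.monophyletic(ape::unroot(tree), c("c", "d")))
})

test_that("three taxa solve the closed-form branch lengths", {
  dm <- matrix(c(0, 4, 6,
                 4, 0, 8,
                 6, 8, 0), 3, 3, dimnames = list(c("x", "y", "z"),
                                                 c("x", "y", "z")))
  tree <- nj_tree(dm)
  pat <- ape::cophenetic.phylo(tree)[c("x", "y", "z"), c("x", "y", "z")]
  expect_equal(pat, dm, tolerance = 1e-10)
  expect_error(nj_tree(dm[1:2, 1:2]), "3 taxa")
  bad <- dm; bad[1, 2] <- 5
  expect_error(nj_tree(bad), "symmetric")
})

test_that("midpoint rooting of ultrametric input matches the ultrametric root", {
  # balanced clock-like distances: root equidistant from all leaves
  dm <- matrix(c(0, 2, 6, 6,
                 2, 0, 6, 6,
                 6, 6, 0, 2,
                 6, 6, 2, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tree <- nj_tree(dm)
  depths <- ape::node.depth.edgelength(tree)[1:4]
  expect_equal(max(depths) - min(depths), 0, tolerance = 1e-10)
  expect_equal(depths[1], 3, tolerance = 1e-10)
})

test_that("planted clusters separate in the LTR tree and distance matrix", {
  cfg <- sim_config(rng_seed = 65L, cpg_multiplier = 1)
  set.seed(66)
  anc1 <- rand_dna(500)
  anc2 <- evolve_sequence(anc1, 25, cfg)
  seqs <- c(
    setNames(vapply(1:3, function(i) evolve_sequence(anc1, 1, cfg),
                    character(1)), paste0("u", 1:3)),
    setNames(vapply(1:3, function(i) evolve_sequence(anc2, 1, cfg),
                    character(1)), paste0("v", 1:3)))
  block <- align_sequences(seqs)
  dm <- block_distance_matrix(block)
  expect_true(isSymmetric(dm))
  within_u <- dm[1:3, 1:3][upper.tri(matrix(0, 3, 3))]
  between <- dm[1:3, 4:6]
  expect_lt(max(within_u), min(between))
  tree <- nj_tree(dm)
  expect_true(ape::is.monophyletic(ape::unroot(tree), paste0("u", 1:3)) ||
                ape::is.monophyletic(ape::unroot(tree), paste0("v", 1:3)))
})
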