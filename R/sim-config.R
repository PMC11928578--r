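## Simulation configuration for the germline-colonization simulator.

## run code under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1e6) * 1009 + k * 9176 + 1)
}

ltr_combo <- function(...) {
  ops <- list(...)
  if (length(ops) == 0L)
    return(data.frame(offset = integer(0), length = integer(0),
                      type = character(0), seq = character(0)))
  do.call(rbind, ops)
}

ltr_del <- function(offset, length)
  data.frame(offset = offset, length = length, type = "deletion", seq = "")

ltr_ins <- function(offset, seq)
  data.frame(offset = offset, length = nchar(seq), type = "insertion",
             seq = seq)

#' Simulation configuration
#'
#' Defines the conditions under which synthetic host genomes with
#' planted proviruses are generated.  Defaults encode the study
#' conditions: a neutral substitution rate of 0.0022 substitutions per
#' nucleotide per million years (the mammalian rate used for dating),
#' ten-fold CpG hypermutability, transition/transversion rate ratio
#' kappa = 2, insertion ages uniform on 0-7 Myr, 500 bp LTRs, 4-6 bp
#' target-site duplications, and the subgroup-diagnostic deletions of
#' 133 nt (pol/RNaseH), 1487 nt (env) and 2216 nt (pol).
#'
#' @param rng_seed integer seed; every random draw in the simulator
#'   derives from it.
#' @param host_length host background length in bp.
#' @param n_per_subgroup named integer vector of provirus counts per
#'   subgroup (names among `A`, `B1`, `B2`, `C`).
#' @param rate_M substitution rate per nt per Myr.
#' @param cpg_multiplier fold-increase of the substitution rate at CpG
#'   sites (>= 1).
#' @param kappa transition/transversion rate ratio.
#' @param age_distribution list: `list(dist = "uniform", min, max)`,
#'   `list(dist = "fixed", value)` or `list(dist = "exponential", rate)`,
#'   in Myr.
#' @param ltr_length LTR length in bp (>= 100).
#' @param tsd_length_range integer range of target-site duplication
#'   lengths in bp.
#' @param deletion_specs data frame with columns `subgroup`, `gene`,
#'   `length`, `offset` (nt within the gene), `probability`.
#' @param ltr_indel_menu per-subgroup list of LTR indel combinations
#'   (`list(combos = list(...), prob = numeric)`), each combination a
#'   data frame built with `ltr_del()` / `ltr_ins()`.
#' @param stop_codon_probability named per-gene probability of planting
#'   a premature stop codon.
#' @param gene_lengths named nt lengths of gag, pro, pol, env
#'   (multiples of 3, each including the terminal stop codon).
#' @param subgroup_divergence fraction of codons replaced by synonymous
#'   alternatives between subgroup ancestral backbones.
#' @param tppy_swap_prob,cettg_alter_prob per-subgroup probabilities of
#'   the PPPY->TPPY late-domain swap and of CETTG alteration.
#' @param min_spacing minimum distance between insertion points, bp.
#' @param contig name of the single host contig.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(rng_seed = 1L,
                       host_length = 300000L,
                       n_per_subgroup = c(A = 5L, B1 = 5L, B2 = 5L, C = 2L),
                       rate_M = 0.0022,
                       cpg_multiplier = 10,
                       kappa = 2,
                       age_distribution = list(dist = "uniform", min = 0, max = 7),
                       ltr_length = 500L,
                       tsd_length_range = c(4L, 6L),
                       deletion_specs = NULL,
                       ltr_indel_menu = NULL,
                       stop_codon_probability = c(gag = 0.05, pro = 0.02,
                                                  pol = 0.05, env = 0.05),
                       gene_lengths = c(gag = 1560L, pro = 903L,
                                        pol = 3303L, env = 1980L),
                       subgroup_divergence = 0.25,
                       tppy_swap_prob = c(A = 0, B1 = 0.8, B2 = 0.3, C = 0),
                       cettg_alter_prob = c(A = 0.13, B1 = 0, B2 = 0, C = 0),
                       min_spacing = 25000L,
                       contig = "chr1") {
  if (is.null(deletion_specs)) {
    deletion_specs <- data.frame(
      subgroup = c("B1", "B1", "B2"),
      gene     = c("env", "pol", "pol"),
      length   = c(1487L, 133L, 2216L),
      offset   = c(300L, 2600L, 500L),
      probability = c(1.0, 0.95, 0.3))
  }
  if (is.null(ltr_indel_menu)) {
    b_combos <- list(ltr_combo(),
                     ltr_combo(ltr_del(60, 8)),
                     ltr_combo(ltr_del(210, 15)),
                     ltr_combo(ltr_del(60, 8), ltr_del(210, 15)),
                     ltr_combo(ltr_del(390, 21)))
    ltr_indel_menu <- list(
      A  = list(combos = list(ltr_combo(), ltr_combo(ltr_del(100, 12))),
                prob = c(0.5, 0.5)),
      B1 = list(combos = b_combos, prob = rep(0.2, 5)),
      B2 = list(combos = b_combos, prob = rep(0.2, 5)),
      C  = list(combos = list(ltr_combo()), prob = 1))
  }
  stopifnot(rate_M > 0, cpg_multiplier >= 1, kappa > 0,
            all(n_per_subgroup >= 0), ltr_length >= 100L,
            all(tsd_length_range >= 1L),
            tsd_length_range[1] <= tsd_length_range[2],
            all(gene_lengths %% 3L == 0L))
  if (!all(names(n_per_subgroup) %in% c("A", "B1", "B2", "C")))
    stop("unknown subgroup label in n_per_subgroup")
  cfg <- list(rng_seed = as.integer(rng_seed), host_length = as.integer(host_length),
              n_per_subgroup = n_per_subgroup, rate_M = rate_M,
              cpg_multiplier = cpg_multiplier, kappa = kappa,
              age_distribution = age_distribution,
              ltr_length = as.integer(ltr_length),
              tsd_length_range = as.integer(tsd_length_range),
              deletion_specs = deletion_specs,
              ltr_indel_menu = ltr_indel_menu,
              stop_codon_probability = stop_codon_probability,
              gene_lengths = gene_lengths,
              subgroup_divergence = subgroup_divergence,
              tppy_swap_prob = tppy_swap_prob,
              cettg_alter_prob = cettg_alter_prob,
              min_spacing = as.integer(min_spacing),
              contig = contig)
  class(cfg) <- "sim_config"
  cfg
}

draw_age <- function(ad) {
  switch(ad$dist,
         uniform = runif(1, ad$min, ad$max),
         fixed = ad$value,
         exponential = rexp(1, ad$rate),
         stop("unknown age distribution: ", ad$dist))
}
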