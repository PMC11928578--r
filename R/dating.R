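## Insertion-age estimation from CpG-masked K2P divergences.
##
## At integration the two LTRs of a provirus are identical; each then
## accumulates substitutions independently, so their divergence D
## corresponds to 2 M T and the insertion age is T = D / (2 M).  For
## gene-vs-consensus dating the consensus approximates the ancestral
## sequence, so divergence accrues along one lineage and the default
## divisor is 1 (T = D / M), with the two-lineage divisor selectable.

#' Default mammalian substitution rate (substitutions/nt/Myr)
#' @export
DEFAULT_RATE_M <- 0.0022

#' LTR-pair insertion age
#'
#' Aligns a provirus's own 5' and 3' LTRs, applies the CpG mask,
#' computes the K2P distance and returns `T = D / (2 M)`.
#'
#' Because the mask is evaluated on the present-day pair, ordinary
#' substitutions that create a CpG with their neighbour are masked
#' along with the ancestrally hypermutable sites, which deflates the
#' distance.  With `mask_correction = TRUE` (default) the observed
#' transition and transversion proportions are rescaled by the
#' computable self-masking probabilities before the K2P correction, so
#' that age recovery is unbiased when CpG sites are not actually
#' hypermutable and nearly unbiased when they are.
#'
#' @param ltr5,ltr3 the two LTR sequences, or a single `provirus_call`
#'   as `ltr5` (its LTR sequences are used).
#' @param M substitution rate per nt per Myr.
#' @param cpg_mask apply CpG masking (default `TRUE`).
#' @param mask_correction rescale P and Q for mask-substitution
#'   coupling (only relevant when `cpg_mask = TRUE`).
#' @param id provirus identifier carried into the result.
#' @return an `age_estimate`: list with `id`, `method = "ltr_pair"`,
#'   `distance` ([k2p_distance] result; `D` is the coupling-corrected
#'   distance, `D_uncorrected` the plain masked one), `M`, `T` (Myr;
#'   `NA` with a `reason` when the distance is saturated or an LTR is
#'   missing).
#' @export
ltr_pair_age <- function(ltr5, ltr3 = NULL, M = DEFAULT_RATE_M,
                         cpg_mask = TRUE, mask_correction = TRUE,
                         id = NA_character_) {
  if (inherits(ltr5, "provirus_call")) {
    pc <- ltr5
    if (is.na(id)) id <- pc$locus_id
    ltr5 <- pc$ltr5_seq; ltr3 <- pc$ltr3_seq
  }
  if (is.null(ltr5) || is.null(ltr3) || !nzchar(ltr5) || !nzchar(ltr3))
    return(structure(list(id = id, method = "ltr_pair", gene = NA_character_,
                          distance = NULL, M = M, T = NA_real_,
                          reason = "missing LTR"), class = "age_estimate"))
  aln <- align_pair(ltr5, ltr3)
  d <- k2p_distance(aln[1L], aln[2L], cpg_mask = cpg_mask)
  if (cpg_mask && mask_correction && !d$saturated)
    d <- apply_mask_coupling(d, aln[1L], aln[2L])
  if (d$saturated)
    return(structure(list(id = id, method = "ltr_pair", gene = NA_character_,
                          distance = d, M = M, T = NA_real_,
                          reason = "saturated"), class = "age_estimate"))
  structure(list(id = id, method = "ltr_pair", gene = NA_character_,
                 distance = d, M = M, T = d$D / (2 * M), reason = NA_character_),
            class = "age_estimate")
}

#' Gene-vs-consensus insertion age
#'
#' Aligns a proviral gene to its subgroup consensus, applies the CpG
#' mask, and returns `T = D / (c M)` with divisor `c = 1` by default
#' (consensus treated as the ancestral proxy) or `c = 2`.
#'
#' @param gene_seq proviral gene sequence.
#' @param consensus subgroup consensus sequence for the gene.
#' @param M substitution rate per nt per Myr.
#' @param divisor 1 or 2.
#' @param cpg_mask apply CpG masking.
#' @param mask_correction rescale P and Q for mask-substitution
#'   coupling (see [ltr_pair_age]).
#' @param id,gene identifiers carried into the result.
#' @return an `age_estimate` with `method = "gene_consensus"`.
#' @export
gene_consensus_age <- function(gene_seq, consensus, M = DEFAULT_RATE_M,
                               divisor = 1, cpg_mask = TRUE,
                               mask_correction = TRUE,
                               id = NA_character_, gene = NA_character_) {
  stopifnot(divisor %in% c(1, 2))
  aln <- align_pair(gene_seq, consensus)
  d <- k2p_distance(aln[1L], aln[2L], cpg_mask = cpg_mask)
  if (cpg_mask && mask_correction && !d$saturated)
    d <- apply_mask_coupling(d, aln[1L], aln[2L])
  if (d$saturated)
    return(structure(list(id = id, method = "gene_consensus", gene = gene,
                          distance = d, M = M, divisor = divisor,
                          T = NA_real_, reason = "saturated"),
                     class = "age_estimate"))
  structure(list(id = id, method = "gene_consensus", gene = gene,
                 distance = d, M = M, divisor = divisor,
                 T = d$D / (divisor * M), reason = NA_character_),
            class = "age_estimate")
}

#' @export
print.age_estimate <- function(x, ...) {
  if (is.na(x$T)) {
    cat(sprintf("age_estimate %s (%s): none (%s)\n", x$id, x$method, x$reason))
  } else {
    cat(sprintf("age_estimate %s (%s%s): T = %.2f Myr (D = %.5f, M = %g)\n",
                x$id, x$method,
                if (!is.na(x$gene)) paste0(":", x$gene) else "",
                x$T, x$distance$D, x$M))
  }
  invisible(x)
}

## collect age_estimate objects into a data frame
ages_table <- function(estimates, subgroup = NULL) {
  rows <- lapply(estimates, function(e) {
    d <- e$distance
    data.frame(id = e$id, method = e$method,
               gene = if (is.null(e$gene)) NA_character_ else e$gene,
               P = if (is.null(d)) NA_real_ else d$P,
               Q = if (is.null(d)) NA_real_ else d$Q,
               D = if (is.null(d)) NA_real_ else d$D,
               n_sites = if (is.null(d)) NA_integer_ else d$n_sites,
               n_masked_cpg = if (is.null(d)) NA_integer_ else d$n_masked_cpg,
               M = e$M,
               divisor = if (is.null(e$divisor)) 2 else e$divisor,
               T = e$T, reason = e$reason)
  })
  out <- do.call(rbind, rows)
  if (!is.null(subgroup)) out$subgroup <- subgroup
  out
}

#' Split gene sequences into dating subgroups by sequence similarity
#'
#' Average-linkage hierarchical clustering on pairwise K2P distances,
#' cut at a distance threshold; each cluster is dated against its own
#' majority consensus, which tightens age estimates when a gene family
#' contains distinct sublineages.
#'
#' @param seqs named character vector of gene sequences (>= 2).
#' @param cut distance threshold at which the dendrogram is cut.
#' @param cpg_mask apply CpG masking to the pairwise distances.
#' @return integer cluster labels named by sequence id (deterministic;
#'   clusters numbered by first appearance).
#' @export
split_dating_subgroups <- function(seqs, cut = 0.04, cpg_mask = TRUE) {
  n <- length(seqs)
  stopifnot(n >= 2L)
  ids <- names(seqs)
  dm <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    aln <- align_pair(seqs[[i]], seqs[[j]])
    d <- k2p_distance(aln[1L], aln[2L], cpg_mask = cpg_mask)
    dm[i, j] <- dm[j, i] <- if (d$saturated) 1 else d$D
  }
  hc <- stats::hclust(stats::as.dist(dm), method = "average")
  cl <- stats::cutree(hc, h = cut)
  ## renumber by first appearance for input-order determinism
  first <- !duplicated(cl)
  remap <- setNames(seq_len(sum(first)), cl[first])
  setNames(unname(remap[as.character(cl)]), ids)
}

#' Summarize age estimates per subgroup, method and gene
#'
#' @param ages data frame of per-provirus estimates (columns
#'   `subgroup`, `method`, `gene`, `T`); rows with `NA` age are
#'   excluded and counted.
#' @return data frame: subgroup, method, gene, n, mean_T, sd_T,
#'   median_T, n_excluded, and a rendered `label` like
#'   `"~ 1.23 (+/- 0.45)"`.
#' @export
summarize_ages <- function(ages) {
  ages$gene[is.na(ages$gene)] <- ""
  key <- interaction(ages$subgroup, ages$method, ages$gene, drop = TRUE)
  out <- lapply(split(ages, key), function(g) {
    ok <- !is.na(g$T)
    x <- g$T[ok]
    if (!length(x)) return(NULL)
    data.frame(subgroup = g$subgroup[1L], method = g$method[1L],
               gene = g$gene[1L], n = length(x),
               mean_T = mean(x),
               sd_T = if (length(x) > 1L) stats::sd(x) else 0,
               median_T = stats::median(x),
               n_excluded = sum(!ok),
               label = sprintf("~ %.2f (± %.2f)", mean(x),
                               if (length(x) > 1L) stats::sd(x) else 0))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$subgroup, out$method, out$gene), , drop = FALSE]
}

#' Per-provirus age set
#'
#' Wraps a data frame of per-provirus age estimates as an `erv_ages`
#' object with print/summary methods.
#'
#' @param ages data frame from [ages_table] (with `subgroup`).
#' @return an `erv_ages` data frame.
#' @export
erv_ages <- function(ages) {
  class(ages) <- c("erv_ages", "data.frame")
  ages
}

#' @method summary erv_ages
#' @export
summary.erv_ages <- function(object, ...) summarize_ages(object)

#' @export
print.erv_ages <- function(x, ...) {
  cat(sprintf("erv_ages: %d estimates (%d ltr_pair, %d gene_consensus)\n",
              nrow(x), sum(x$method == "ltr_pair"),
              sum(x$method == "gene_consensus")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
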