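## Kimura 2-parameter distances with CpG masking -- the package's core
## dating computation.

#' CpG site mask for an aligned pair or block
#'
#' A column is masked when, in any row, the base at that column and the
#' next base of the same row's degapped sequence form a CpG dinucleotide;
#' both members of each CpG are masked.  CpG sites are hypermutable
#' (spontaneous deamination of 5-methylcytosine), so they are excluded
#' from divergence-based dating.
#'
#' @param rows character vector of aligned, equal-length sequences
#'   (gap character `-`).
#' @return sorted integer vector of masked alignment columns (1-based).
#' @export
#' @examples
#' mask_cpg(c("AACGTT", "AACGTT"))  # columns 3 and 4
mask_cpg <- function(rows) {
  nc <- unique(nchar(rows))
  if (length(nc) != 1L)
    stop("aligned rows must have equal length")
  masked <- logical(nc)
  for (r in rows) {
    ch <- seq_chars(r)
    pos <- which(ch != "-")
    if (length(pos) < 2L) next
    b <- ch[pos]
    hit <- which(b[-length(b)] == "C" & b[-1L] == "G")
    if (length(hit)) {
      masked[pos[hit]] <- TRUE
      masked[pos[hit + 1L]] <- TRUE
    }
  }
  which(masked)
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Counts transition (P) and transversion (Q) proportions over compared
#' sites and applies the K2P correction
#' \deqn{D = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q).}
#' Columns holding a gap or ambiguity code in either row are excluded
#' (complete deletion within the pair); columns in `mask` are excluded
#' and counted as masked CpG sites.  Saturation (either log argument
#' non-positive) is reported as an explicit outcome, never a silent
#' infinity.
#'
#' @param a,b aligned sequences of equal length.
#' @param mask integer vector of alignment columns to exclude
#'   (typically from [mask_cpg]); `NULL` computes the CpG mask from the
#'   pair itself.
#' @param cpg_mask logical; set `FALSE` to disable CpG masking when
#'   `mask` is `NULL`.
#' @return an object of class `k2p_dist`: list with elements `P`, `Q`,
#'   `D`, `n_sites`, `n_masked_cpg`, `n_gap_excluded`, `saturated`.
#' @export
#' @examples
#' k2p_distance("ACGT", "ACTT", mask = integer(0))  # one transversion
k2p_distance <- function(a, b, mask = NULL, cpg_mask = TRUE) {
  if (nchar(a) != nchar(b))
    stop("sequences must be aligned (equal length)")
  if (is.null(mask))
    mask <- if (cpg_mask) mask_cpg(c(a, b)) else integer(0)
  ca <- seq_chars(a)
  cb <- seq_chars(b)
  comparable <- ca %in% DNA_BASES & cb %in% DNA_BASES
  n_gap_excluded <- sum(!comparable)
  is_masked <- logical(length(ca))
  is_masked[mask] <- TRUE
  n_masked_cpg <- sum(is_masked & comparable)
  use <- comparable & !is_masked
  n <- sum(use)
  if (n == 0L)
    stop("no comparable sites left after masking")
  ua <- ca[use]
  ub <- cb[use]
  diff <- ua != ub
  ts <- diff & TRANSITION[ua] == ub
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  saturated <- w1 <= 0 || w2 <= 0
  D <- if (saturated) NA_real_ else -0.5 * log(w1) - 0.25 * log(w2)
  structure(list(P = P, Q = Q, D = D, n_sites = n,
                 n_masked_cpg = n_masked_cpg,
                 n_gap_excluded = n_gap_excluded,
                 saturated = saturated),
            class = "k2p_dist")
}

## Mask-substitution coupling factors for the CpG mask.
##
## Masking present-day CpG sites removes not only ancestrally
## hypermutable positions but also ordinary substitutions that happened
## to create a CpG with their neighbour, which deflates the distance.
## The probability that a random substitution self-masks is computable
## from the kept columns' base context, separately for transitions and
## transversions, giving multiplicative factors by which observed P and
## Q underestimate the true proportions.
mask_coupling_factors <- function(a, b) {
  rows <- list(seq_chars(a), seq_chars(b))
  nc <- length(rows[[1L]])
  mask <- mask_cpg(c(a, b))
  comparable <- rows[[1L]] %in% DNA_BASES & rows[[2L]] %in% DNA_BASES
  keep <- setdiff(which(comparable), mask)
  if (!length(keep)) return(c(ts = 1, tv = 1))
  q_ts <- 0; q_tv <- 0; cnt <- 0L
  for (r in rows) {
    pos <- which(r != "-")
    nxt <- rep(NA_character_, nc)
    prv <- rep(NA_character_, nc)
    if (length(pos) > 1L) {
      nxt[pos[-length(pos)]] <- r[pos[-1L]]
      prv[pos[-1L]] <- r[pos[-length(pos)]]
    }
    x <- r[keep]
    right_g <- !is.na(nxt[keep]) & nxt[keep] == "G"
    left_c <- !is.na(prv[keep]) & prv[keep] == "C"
    ## transition target creates CpG: A->G needs left C, T->C needs right G
    q_ts <- q_ts + sum((x == "A" & left_c) | (x == "T" & right_g))
    ## transversion targets: {C,T} for purines (C needs right G),
    ## {A,G} for pyrimidines (G needs left C); each target drawn at 1/2
    q_tv <- q_tv + 0.5 * sum(ifelse(x %in% c("A", "G"), right_g, left_c))
    cnt <- cnt + length(keep)
  }
  c(ts = max(0.5, 1 - q_ts / cnt), tv = max(0.5, 1 - q_tv / cnt))
}

## K2P closed form from proportions, with saturation guard
k2p_from_pq <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1) - 0.25 * log(w2)
}

## apply the coupling correction to a k2p_dist computed under the mask
apply_mask_coupling <- function(d, a, b) {
  cf <- mask_coupling_factors(a, b)
  P2 <- d$P / cf[["ts"]]
  Q2 <- d$Q / cf[["tv"]]
  D2 <- k2p_from_pq(P2, Q2)
  d$D_uncorrected <- d$D
  d$coupling_ts <- cf[["ts"]]
  d$coupling_tv <- cf[["tv"]]
  d$D <- D2
  d$saturated <- is.na(D2)
  d
}

#' @export
print.k2p_dist <- function(x, ...) {
  cat(sprintf("K2P distance: D = %s (P = %.4f, Q = %.4f) over %d sites",
              if (x$saturated) "saturated" else sprintf("%.6f", x$D),
              x$P, x$Q, x$n_sites))
  cat(sprintf(" [%d CpG-masked, %d gap/ambiguous excluded]\n",
              x$n_masked_cpg, x$n_gap_excluded))
  invisible(x)
}
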