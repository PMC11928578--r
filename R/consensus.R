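## Majority-rule consensus construction and outlier exclusion.

#' Majority-rule consensus of an alignment block
#'
#' Per column the most frequent symbol wins, counting the gap as a
#' symbol.  Columns won by the gap are omitted from the consensus string
#' but remain addressable through the column map.  Ties are broken by
#' the fixed base order A < C < G < T, with any base beating the gap on
#' a base-gap tie.
#'
#' @param block an `alignment_block` (see [align_sequences]), or a
#'   character vector of equal-length aligned rows.
#' @return a `consensus_profile`: list with `consensus` (gap-free
#'   string), `support` (winning-symbol fraction per consensus
#'   position), `column_map` (consensus position -> alignment column),
#'   `n_members`, and `ties` (columns decided by the tie rule).
#' @export
majority_consensus <- function(block) {
  rows <- if (inherits(block, "alignment_block")) block$rows else block
  if (length(rows) == 0L) stop("empty alignment block")
  nc <- unique(nchar(rows))
  if (length(nc) != 1L) stop("rows must have equal length")
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  symbol_order <- c(DNA_BASES, setdiff(sort(unique(as.vector(mat))),
                                       c(DNA_BASES, "-")), "-")
  cons <- character(nc)
  supp <- numeric(nc)
  tie <- logical(nc)
  nr <- nrow(mat)
  for (j in seq_len(nc)) {
    tab <- table(factor(mat[, j], levels = symbol_order))
    tab <- tab[tab > 0L]
    top <- max(tab)
    winners <- names(tab)[tab == top]
    cons[j] <- winners[1L]            # levels already encode the tie order
    supp[j] <- top / nr
    tie[j] <- length(winners) > 1L
  }
  keep <- cons != "-"
  structure(list(consensus = paste(cons[keep], collapse = ""),
                 support = supp[keep],
                 column_map = which(keep),
                 n_members = nr,
                 ties = which(tie & keep)),
            class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat(sprintf("consensus_profile: %d bp from %d members (mean support %.2f)\n",
              nchar(x$consensus), x$n_members, mean(x$support)))
  invisible(x)
}

## identity of one aligned row to the consensus, over consensus columns
row_consensus_identity <- function(row, profile) {
  ch <- seq_chars(row)[profile$column_map]
  cs <- seq_chars(profile$consensus)
  100 * sum(ch == cs) / length(cs)
}

#' Iterative consensus-identity outlier exclusion
#'
#' Members that align poorly to the family consensus distort both the
#' consensus and divergence-based ages, so they are excluded before
#' dating.  The member with the lowest identity to the current
#' consensus is removed while that identity is below the threshold, and
#' the consensus is recomputed after every removal.  Removal order is
#' deterministic (lowest identity, then id).
#'
#' @param block an `alignment_block` with >= 3 members.
#' @param min_identity percent identity threshold (default 60).
#' @return character vector of excluded member ids (possibly empty).
#' @export
flag_outliers <- function(block, min_identity = 60) {
  rows <- block$rows
  if (length(rows) < 3L) stop("need at least 3 members")
  if (min_identity > 100)
    stop("min_identity above 100 would exclude every member")
  excluded <- character(0)
  repeat {
    prof <- majority_consensus(rows)
    ids <- vapply(rows, row_consensus_identity, numeric(1), profile = prof)
    worst <- names(ids)[order(ids, names(ids))][1L]
    if (ids[[worst]] >= min_identity) break
    if (length(rows) == 1L)
      stop("outlier threshold would remove all members")
    excluded <- c(excluded, worst)
    rows <- rows[names(rows) != worst]
  }
  excluded
}
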