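## LTR indel fingerprinting, clade assignment, and a distance-based
## midpoint-rooted tree for visualization.

#' Fingerprint LTR indels from a master alignment
#'
#' Enumerates gap blocks (maximal runs of alignment columns in which at
#' least one row is gapped, with runs separated by fewer than
#' `min_indel_length` non-gap columns merged — alignment jitter can
#' shift one member's gap placement by a few columns) of at least
#' `min_indel_length` columns, left to right, and scores every LTR
#' present/absent per block (a row carries the indel when it is gapped
#' over at least `min_indel_length` block columns).  Blocks that
#' isolate exactly one LTR are flagged as unique indels.
#'
#' @param block an `alignment_block` of LTR sequences (see
#'   [align_sequences]).
#' @param min_indel_length minimum block width in columns (default 3).
#' @return an `ltr_fingerprints` object: list with `matrix` (logical,
#'   LTRs x blocks), `blocks` (data frame of column intervals),
#'   `unique_indels` (named list).
#' @export
fingerprint_indels <- function(block, min_indel_length = 3L) {
  rows <- block$rows
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  gap <- mat == "-"
  anygap <- colSums(gap) > 0L
  fp <- matrix(FALSE, nrow = length(rows), ncol = 0L,
               dimnames = list(names(rows), NULL))
  blocks <- data.frame(col_start = integer(0), col_end = integer(0))
  if (any(anygap)) {
    r <- rle(anygap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    bs <- starts[r$values]; be <- ends[r$values]
    ## merge runs split by short non-gap stretches (alignment jitter)
    if (length(bs) > 1L) {
      keep_sep <- (bs[-1L] - be[-length(be)] - 1L) >= min_indel_length
      grp <- cumsum(c(TRUE, keep_sep))
      bs <- vapply(split(bs, grp), min, integer(1))
      be <- vapply(split(be, grp), max, integer(1))
    }
    wide <- (be - bs + 1L) >= min_indel_length
    bs <- bs[wide]; be <- be[wide]
    if (length(bs)) {
      fp <- vapply(seq_along(bs), function(i) {
        rowSums(gap[, bs[i]:be[i], drop = FALSE]) >= min_indel_length
      }, logical(length(rows)))
      if (is.null(dim(fp))) fp <- matrix(fp, nrow = length(rows))
      dimnames(fp) <- list(names(rows), NULL)
      blocks <- data.frame(col_start = bs, col_end = be)
    }
  }
  ## a block is private when it isolates exactly one LTR from the rest:
  ## one gapped row (private deletion) or one ungapped row among gapped
  ## ones (private insertion)
  nr <- nrow(fp)
  cs <- colSums(fp)
  uniq_del <- cs == 1L
  uniq_ins <- nr > 2L & cs == nr - 1L
  unique_indels <- lapply(setNames(nm = names(rows)), function(id) {
    which((uniq_del & fp[id, ]) | (uniq_ins & !fp[id, ]))
  })
  structure(list(matrix = fp, blocks = blocks,
                 unique_indels = unique_indels),
            class = "ltr_fingerprints")
}

#' @export
print.ltr_fingerprints <- function(x, ...) {
  cat(sprintf("ltr_fingerprints: %d LTRs x %d indel blocks (%d unique)\n",
              nrow(x$matrix), ncol(x$matrix),
              sum(lengths(x$unique_indels) > 0L)))
  invisible(x)
}

#' Cluster LTR fingerprints into clades
#'
#' Identical indel vectors are grouped first; groups whose indel sets
#' lie within a Jaccard distance threshold are then merged by single
#' linkage.  Clade labels are deterministic: ordered by group size,
#' then by the smallest member id.
#'
#' @param fp an `ltr_fingerprints` object.
#' @param threshold Jaccard distance threshold (default 0: clades are
#'   exactly the distinct vectors).
#' @return named character vector of clade labels (`clade1`, ...).
#' @export
cluster_fingerprints <- function(fp, threshold = 0) {
  m <- fp$matrix
  if (nrow(m) == 0L) stop("no fingerprints")
  key <- apply(m, 1L, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(rownames(m), key)
  gkeys <- names(groups)
  ng <- length(groups)
  parent <- seq_len(ng)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  jacc <- function(a, b) {
    va <- which(seq_chars(a) == "1"); vb <- which(seq_chars(b) == "1")
    u <- union(va, vb)
    if (!length(u)) return(0)
    1 - length(intersect(va, vb)) / length(u)
  }
  if (ng > 1L && threshold > 0) {
    for (i in seq_len(ng - 1L)) for (j in (i + 1L):ng) {
      if (jacc(gkeys[i], gkeys[j]) <= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(ng), find, integer(1))
  merged <- lapply(split(seq_len(ng), root), function(ix)
    unlist(groups[ix], use.names = FALSE))
  ## order clades by size (desc), then smallest member id
  sizes <- lengths(merged)
  firsts <- vapply(merged, function(v) sort(v)[1L], character(1))
  ord <- order(-sizes, firsts)
  out <- character(nrow(m))
  names(out) <- rownames(m)
  for (i in seq_along(ord))
    out[merged[[ord[i]]]] <- sprintf("clade%d", i)
  out
}

#' Neighbor-joining tree with midpoint rooting
#'
#' Canonical neighbor joining on a symmetric distance matrix, with
#' negative branch lengths clamped to zero (the clamped amount moved to
#' the sibling edge) and midpoint rooting on the longest leaf-to-leaf
#' path.  The tree is diagnostic; clade assignment is fingerprint
#' based.
#'
#' @param dm symmetric numeric matrix with zero diagonal, >= 3 taxa,
#'   with dimnames.
#' @return a rooted `phylo` object (see [ape::read.tree]).
#' @export
nj_tree <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    stop("distance matrix must be square")
  if (nrow(dm) < 3L) stop("need at least 3 taxa")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix must be symmetric")
  tree <- ape::nj(stats::as.dist(dm))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    amt <- -tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1L]
    sib <- which(tree$edge[, 1L] == parent)
    sib <- setdiff(sib, e)
    if (length(sib)) tree$edge.length[sib[1L]] <-
        tree$edge.length[sib[1L]] + amt
  }
  phangorn::midpoint(tree)
}

#' Pairwise CpG-masked K2P distance matrix from an alignment block
#'
#' @param block an `alignment_block`.
#' @param cpg_mask apply CpG masking per pair.
#' @return symmetric numeric matrix of K2P distances (saturated pairs
#'   set to `NA`).
#' @export
block_distance_matrix <- function(block, cpg_mask = TRUE) {
  rows <- block$rows
  n <- length(rows)
  dm <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- k2p_distance(rows[[i]], rows[[j]], cpg_mask = cpg_mask)
    dm[i, j] <- dm[j, i] <- if (d$saturated) NA_real_ else d$D
  }
  dm
}
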