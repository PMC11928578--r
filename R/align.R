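## Pairwise and multiple alignment machinery.
##
## Pairwise global alignment delegates to Biostrings dynamic programming
## for short sequences and to an exact-k-mer anchored variant for long
## ones (anchor chain by longest increasing subsequence, DP only between
## anchors), which keeps multi-kilobase provirus-vs-reference alignments
## fast while placing large deletions exactly.

PW_MATCH <- 2; PW_MISMATCH <- -3; PW_GAP_OPEN <- 5; PW_GAP_EXT <- 2

## full-DP global alignment of two (possibly empty) sequences
pw_align <- function(a, b) {
  if (nchar(a) == 0L && nchar(b) == 0L) return(c("", ""))
  if (nchar(a) == 0L) return(c(strrep("-", nchar(b)), b))
  if (nchar(b) == 0L) return(c(a, strrep("-", nchar(a))))
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = PW_MATCH, mismatch = PW_MISMATCH, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = sm,
    gapOpening = PW_GAP_OPEN, gapExtension = PW_GAP_EXT)
  c(as.character(Biostrings::alignedPattern(aln)),
    as.character(Biostrings::alignedSubject(aln)))
}

## exact k-mers unique in both sequences -> anchor table (apos, bpos)
kmer_anchors <- function(a, b, k = 16L) {
  na <- nchar(a); nb <- nchar(b)
  if (na < k || nb < k) return(NULL)
  kma <- substring(a, seq_len(na - k + 1L), seq_len(na - k + 1L) + k - 1L)
  kmb <- substring(b, seq_len(nb - k + 1L), seq_len(nb - k + 1L) + k - 1L)
  ua <- !(duplicated(kma) | duplicated(kma, fromLast = TRUE))
  ub <- !(duplicated(kmb) | duplicated(kmb, fromLast = TRUE))
  ia <- which(ua & !grepl("N", kma, fixed = TRUE))
  hit <- match(kma[ia], kmb[which(ub)])
  keep <- !is.na(hit)
  if (!any(keep)) return(NULL)
  data.frame(apos = ia[keep], bpos = which(ub)[hit[keep]])
}

## longest increasing subsequence of y (strictly), returns kept indices
lis_indices <- function(y) {
  n <- length(y)
  if (n == 0L) return(integer(0))
  tails <- numeric(0)      # smallest tail value per LIS length
  tidx <- integer(0)       # index of that tail
  parent <- integer(n)
  for (i in seq_len(n)) {
    j <- findInterval(y[i] - 1L, tails) + 1L  # first tail >= y[i]
    parent[i] <- if (j > 1L) tidx[j - 1L] else 0L
    tails[j] <- y[i]
    tidx[j] <- i
  }
  out <- integer(length(tails))
  i <- tidx[length(tails)]
  for (j in rev(seq_along(tails))) { out[j] <- i; i <- parent[i] }
  out
}

## anchored global alignment; falls back to full DP when too few anchors
anchored_align <- function(a, b, k = 16L) {
  anc <- kmer_anchors(a, b, k)
  if (is.null(anc) || nrow(anc) < 3L) return(pw_align(a, b))
  anc <- anc[order(anc$apos), , drop = FALSE]
  keep <- lis_indices(anc$bpos)
  anc <- anc[keep, , drop = FALSE]
  ## drop anchors overlapping the previous kept anchor off-diagonal
  kept <- 1L
  for (i in seq_len(nrow(anc))[-1L]) {
    p <- anc[kept[length(kept)], ]
    same_diag <- (anc$bpos[i] - anc$apos[i]) == (p$bpos - p$apos)
    if (same_diag || (anc$apos[i] >= p$apos + k && anc$bpos[i] >= p$bpos + k))
      kept <- c(kept, i)
  }
  anc <- anc[kept, , drop = FALSE]
  ## merge same-diagonal runs into segments
  d <- anc$bpos - anc$apos
  seg_id <- cumsum(c(TRUE, d[-1L] != d[-length(d)]))
  segs <- do.call(rbind, lapply(split(seq_len(nrow(anc)), seg_id), function(ix) {
    data.frame(a1 = anc$apos[ix[1L]], a2 = anc$apos[ix[length(ix)]] + k - 1L,
               b1 = anc$bpos[ix[1L]], b2 = anc$bpos[ix[length(ix)]] + k - 1L)
  }))
  outa <- character(0); outb <- character(0)
  pa <- 1L; pb <- 1L
  for (i in seq_len(nrow(segs))) {
    ga <- substr(a, pa, segs$a1[i] - 1L)
    gb <- substr(b, pb, segs$b1[i] - 1L)
    if (nchar(ga) || nchar(gb)) {
      al <- pw_align(ga, gb)
      outa <- c(outa, al[1L]); outb <- c(outb, al[2L])
    }
    outa <- c(outa, substr(a, segs$a1[i], segs$a2[i]))
    outb <- c(outb, substr(b, segs$b1[i], segs$b2[i]))
    pa <- segs$a2[i] + 1L; pb <- segs$b2[i] + 1L
  }
  al <- pw_align(substr(a, pa, nchar(a)), substr(b, pb, nchar(b)))
  outa <- c(outa, al[1L]); outb <- c(outb, al[2L])
  c(paste(outa, collapse = ""), paste(outb, collapse = ""))
}

## dispatcher used throughout the package
align_pair <- function(a, b, k = 16L) {
  if (max(nchar(a), nchar(b)) <= 2000L) pw_align(a, b) else anchored_align(a, b, k)
}

## fraction of identical columns over the full alignment length
pair_identity <- function(aln) {
  ca <- seq_chars(aln[1L]); cb <- seq_chars(aln[2L])
  100 * sum(ca == cb & ca != "-") / length(ca)
}

#' Multiple sequence alignment
#'
#' Aligns two or more DNA sequences.  The built-in path is a
#' deterministic center-star progressive aligner: the center sequence
#' (smallest total k-mer distance to the rest) is aligned pairwise to
#' every other member and the pairwise alignments are merged on the
#' center's coordinates (once a gap, always a gap).  Alternatively an
#' external aligner command template may be supplied, e.g.
#' `"mafft --quiet {in} > {out}"`; it must read and write FASTA.
#'
#' @param seqs named character vector of >= 2 sequences.
#' @param aligner_cmd optional external command template with `{in}`
#'   and `{out}` placeholders; `NULL` (default) uses the built-in path.
#' @param k k-mer size for anchoring and center selection.
#' @param center center selection for the built-in path: `NULL` (the
#'   member with the smallest total k-mer distance), `"longest"` (the
#'   longest member — appropriate when members differ by deletions, as
#'   a deletion-free center avoids spurious insertion columns), or a
#'   member name.
#' @return an `alignment_block`: list with `ids`, `rows` (named aligned
#'   sequences, equal length), `ncol`.
#' @export
align_sequences <- function(seqs, aligner_cmd = NULL, k = 12L,
                            center = NULL) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (!is.null(aligner_cmd)) {
    fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".fasta")
    write_fasta(seqs, fin)
    cmd <- gsub("{out}", fout, gsub("{in}", fin, aligner_cmd, fixed = TRUE),
                fixed = TRUE)
    status <- system(cmd)
    if (status != 0L || !file.exists(fout))
      stop("external aligner failed: ", cmd)
    rows <- toupper(read_fasta(fout))[names(seqs)]
    return(new_alignment_block(rows))
  }
  n <- length(seqs)
  if (is.null(center)) {
    ## center selection by shared-k-mer distance
    ksets <- lapply(seqs, function(s) {
      ns <- nchar(s)
      if (ns < k) return(character(0))
      unique(substring(s, seq_len(ns - k + 1L), seq_len(ns - k + 1L) + k - 1L))
    })
    dtot <- numeric(n)
    for (i in seq_len(n)) {
      dtot[i] <- sum(vapply(seq_len(n), function(j) {
        if (i == j) return(0)
        u <- length(intersect(ksets[[i]], ksets[[j]]))
        1 - u / max(1L, min(length(ksets[[i]]), length(ksets[[j]])))
      }, numeric(1)))
    }
    ci <- which.min(dtot)
  } else if (identical(center, "longest")) {
    ci <- which.max(nchar(seqs))
  } else {
    ci <- match(center, names(seqs))
    if (is.na(ci)) stop("center not found among sequence names")
  }
  center <- seqs[[ci]]
  others <- setdiff(seq_len(n), ci)
  Lc <- nchar(center)
  pals <- lapply(others, function(j) align_pair(center, seqs[[j]], k = 16L))
  ## per pairwise alignment: member chars grouped into slots 0..Lc
  ## (slot p = columns between center base p and p+1; slot 0 precedes base 1)
  slotify <- function(al) {
    cc <- seq_chars(al[1L]); mc <- seq_chars(al[2L])
    slot_of <- cumsum(cc != "-")          # column -> center position
    ins <- tabulate(slot_of[cc == "-"] + 1L, nbins = Lc + 1L)  # gaps per slot
    aligned <- mc[cc != "-"]              # member char at each center base
    inserts <- split(mc[cc == "-"], factor(slot_of[cc == "-"], levels = 0:Lc))
    list(ins = ins, aligned = aligned, inserts = inserts)
  }
  sl <- lapply(pals, slotify)
  master_ins <- if (length(sl)) do.call(pmax, lapply(sl, `[[`, "ins")) else
    integer(Lc + 1L)
  build_row <- function(aligned, inserts) {
    out <- character(0)
    for (p in 0:Lc) {
      ins_ch <- inserts[[p + 1L]]
      if (is.null(ins_ch)) ins_ch <- character(0)
      pad <- master_ins[p + 1L] - length(ins_ch)
      out <- c(out, ins_ch, rep("-", pad))
      if (p < Lc) out <- c(out, aligned[p + 1L])
    }
    paste(out, collapse = "")
  }
  center_row <- build_row(seq_chars(center), vector("list", Lc + 1L))
  rows <- character(n)
  rows[ci] <- center_row
  for (m in seq_along(others))
    rows[others[m]] <- build_row(sl[[m]]$aligned, sl[[m]]$inserts)
  names(rows) <- names(seqs)
  new_alignment_block(rows)
}

new_alignment_block <- function(rows) {
  nc <- unique(nchar(rows))
  if (length(nc) != 1L) stop("alignment rows differ in length")
  structure(list(ids = names(rows), rows = rows, ncol = nc),
            class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf("alignment_block: %d sequences x %d columns\n",
              length(x$rows), x$ncol))
  invisible(x)
}

degap <- function(x) gsub("-", "", x, fixed = TRUE)
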