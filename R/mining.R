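## Seed-based mining of proviral loci: k-mer seeded search, tabular hit
## import, and flank extraction with clamping and merging.

## cluster exact k-mer matches of one seed (one strand) into hits
chain_kmer_hits <- function(genome_seq, seed_seq, spos, gpos, k,
                            min_identity, min_length, max_gap = 5000L) {
  o <- order(gpos, spos)
  spos <- spos[o]; gpos <- gpos[o]
  cl <- cumsum(c(TRUE, diff(gpos) > max_gap))
  hits <- list()
  for (id in unique(cl)) {
    sel <- cl == id
    s1 <- min(spos[sel]); s2 <- max(spos[sel]) + k - 1L
    g1 <- min(gpos[sel]); g2 <- max(gpos[sel]) + k - 1L
    if (g2 - g1 + 1L < min_length) next
    aln <- anchored_align(substr(seed_seq, s1, s2), substr(genome_seq, g1, g2))
    ## gap-compressed identity: long indels (> 30 nt) separate the local
    ## alignments a gapped search would report as distinct HSPs, so their
    ## columns do not dilute identity
    ca <- seq_chars(aln[1L]); cb <- seq_chars(aln[2L])
    gap <- ca == "-" | cb == "-"
    r <- rle(gap)
    long_gap <- rep(r$values & r$lengths > 30L, r$lengths)
    denom <- sum(!long_gap)
    if (denom < min_length) next
    ident <- 100 * sum(ca == cb & !gap) / denom
    if (ident < min_identity) next
    hits[[length(hits) + 1L]] <-
      data.frame(start = g1 - 1L, end = g2, identity = ident,
                 length = nchar(aln[1L]))
  }
  hits
}

#' Search a genome for seed-similar loci
#'
#' A k-mer seeded local search: exact `word_size`-mers shared between a
#' seed and the genome are chained by genomic proximity, each chain is
#' aligned back to the seed (anchored global alignment) and reported as
#' a hit when it passes the identity and length filters.  Both strands
#' are searched; minus-strand hits carry forward-genome coordinates.
#' Ordering is deterministic (contig, start, seed id).
#'
#' @param genome named character vector of contig sequences (or a FASTA
#'   path).
#' @param seeds named character vector of seed sequences (or a FASTA
#'   path).
#' @param min_identity minimum percent identity (default 85, the
#'   operative ERV screening threshold).
#' @param min_length minimum hit length in bp.
#' @param word_size exact-match word size (>= 8).
#' @return data frame of `SeedHit` rows: `contig`, `start`, `end`
#'   (0-based half-open), `strand`, `identity`, `length`, `seed_id`.
#' @export
seed_search <- function(genome, seeds, min_identity = 85, min_length = 100L,
                        word_size = 16L) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta(genome)
  if (is.character(seeds) && length(seeds) == 1L && file.exists(seeds))
    seeds <- read_fasta(seeds)
  if (length(genome) == 0L || length(seeds) == 0L)
    stop("empty genome or seed set")
  if (any(grepl("[^ACGTN]", c(genome, seeds))))
    stop("sequences must be DNA over {A,C,G,T,N}")
  if (word_size < 8L) stop("word_size must be >= 8")
  k <- as.integer(word_size)
  out <- list()
  for (ctg in names(genome)) {
    gs <- genome[[ctg]]
    ng <- nchar(gs)
    if (ng < k) next
    gkm <- substring(gs, seq_len(ng - k + 1L), seq_len(ng - k + 1L) + k - 1L)
    gindex <- split(seq_along(gkm), gkm)
    for (sid in names(seeds)) {
      for (strand in c("+", "-")) {
        ss <- if (strand == "+") seeds[[sid]] else revcomp(seeds[[sid]])
        ns <- nchar(ss)
        if (ns < k) next
        skm <- substring(ss, seq_len(ns - k + 1L), seq_len(ns - k + 1L) + k - 1L)
        hit_idx <- gindex[skm]
        has <- !vapply(hit_idx, is.null, logical(1))
        if (!any(has)) next
        spos <- rep(which(has), lengths(hit_idx[has]))
        gpos <- unlist(hit_idx[has], use.names = FALSE)
        hits <- chain_kmer_hits(gs, ss, spos, gpos, k, min_identity, min_length)
        for (h in hits) {
          h$contig <- ctg; h$strand <- strand; h$seed_id <- sid
          out[[length(out) + 1L]] <- h
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      identity = numeric(0), length = integer(0),
                      seed_id = character(0)))
  res <- do.call(rbind, out)
  res <- res[, c("contig", "start", "end", "strand", "identity", "length",
                 "seed_id")]
  res[order(res$contig, res$start, res$seed_id), , drop = FALSE]
}

#' Import BLAST outfmt-6 style tabular hits
#'
#' Reads the standard 12-column tabular format (query, subject,
#' identity, length, mismatches, gap opens, qstart, qend, sstart, send,
#' evalue, bitscore), converting 1-based inclusive subject coordinates
#' to 0-based half-open and inferring strand from `sstart > send`.
#'
#' @param path path to a tab-separated hit file (no header).
#' @return data frame of `SeedHit` rows as in [seed_search].
#' @export
import_tabular_hits <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) != 12L)
      stop("malformed hit row ", i, ": expected 12 columns, found ",
           length(f))
    sstart <- suppressWarnings(as.integer(f[9]))
    send <- suppressWarnings(as.integer(f[10]))
    ident <- suppressWarnings(as.numeric(f[3]))
    len <- suppressWarnings(as.integer(f[4]))
    if (anyNA(c(sstart, send, ident, len)))
      stop("malformed hit row ", i, ": non-numeric coordinate or identity")
    if (ident < 0 || ident > 100)
      stop("malformed hit row ", i, ": identity out of [0,100]")
    strand <- if (sstart > send) "-" else "+"
    lo <- min(sstart, send); hi <- max(sstart, send)
    out[[i]] <- data.frame(contig = f[2], start = lo - 1L, end = hi,
                           strand = strand, identity = ident, length = len,
                           seed_id = f[1])
  }
  res <- do.call(rbind, out)
  res[order(res$contig, res$start, res$seed_id), , drop = FALSE]
}

#' Extract candidate loci around hits with flanking sequence
#'
#' Expands every hit by `flank` bp on both sides, clamps to contig
#' bounds, optionally merges overlapping expanded intervals on the same
#' contig, and slices the locus sequences from the genome.
#' Minus-strand loci (dominant hit strand) are reverse-complemented so
#' that downstream annotation is strand-agnostic; the original strand
#' is retained.
#'
#' @param hits data frame from [seed_search] or [import_tabular_hits].
#' @param genome named character vector of contigs (or FASTA path).
#' @param flank flank size in bp (default 10000).
#' @param merge merge overlapping expanded intervals (default `TRUE`).
#' @return data frame of `CandidateLocus` rows: `locus_id`, `contig`,
#'   `start`, `end`, `strand`, `n_hits`, `seed_ids`, `sequence`
#'   (plus-oriented with respect to the dominant hit strand).
#' @export
extract_loci <- function(hits, genome, flank = 10000L, merge = TRUE) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta(genome)
  if (nrow(hits) == 0L)
    return(data.frame(locus_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), n_hits = integer(0),
                      seed_ids = character(0), sequence = character(0)))
  missing_ctg <- setdiff(unique(hits$contig), names(genome))
  if (length(missing_ctg))
    stop("hit contig absent from genome: ", paste(missing_ctg, collapse = ", "))
  out <- list()
  for (ctg in unique(hits$contig)) {
    h <- hits[hits$contig == ctg, , drop = FALSE]
    clen <- nchar(genome[[ctg]])
    s <- pmax(0L, h$start - as.integer(flank))
    e <- pmin(clen, h$end + as.integer(flank))
    if (merge) {
      ir <- IRanges::reduce(IRanges::IRanges(start = s + 1L, end = e))
      ms <- IRanges::start(ir) - 1L
      me <- IRanges::end(ir)
    } else {
      ms <- s; me <- e
    }
    for (i in seq_along(ms)) {
      inside <- h$start >= ms[i] & h$end <= me[i]
      hh <- h[inside, , drop = FALSE]
      ## dominant strand: strand of the longest contributing hit
      strand <- if (nrow(hh)) hh$strand[which.max(hh$length)] else "+"
      seqs <- substr(genome[[ctg]], ms[i] + 1L, me[i])
      if (strand == "-") seqs <- revcomp(seqs)
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, start = ms[i], end = me[i], strand = strand,
        n_hits = nrow(hh),
        seed_ids = paste(unique(hh$seed_id), collapse = ","),
        sequence = seqs)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$start), , drop = FALSE]
  res <- cbind(locus_id = sprintf("locus%03d", seq_len(nrow(res))), res)
  rownames(res) <- NULL
  res
}

#' Write candidate loci as FASTA and BED6
#' @param loci data frame from [extract_loci].
#' @param out_prefix output path prefix.
#' @return named vector of written paths, invisibly.
#' @export
write_loci <- function(loci, out_prefix) {
  fa <- paste0(out_prefix, "_loci.fasta")
  bed <- paste0(out_prefix, "_loci.bed")
  write_fasta(setNames(loci$sequence, loci$locus_id), fa)
  bedln <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", loci$contig, loci$start,
                   loci$end, loci$locus_id, 0L, loci$strand)
  writeLines(bedln, bed)
  invisible(c(fasta = fa, bed = bed))
}
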