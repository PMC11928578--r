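## Reference-guided structural annotation of candidate loci.

#' Detect the LTR pair (and TSD) of a proviral locus
#'
#' Proviral LTRs are identical direct repeats at integration, so a
#' provirus appears as the highest-scoring pair of similar direct
#' repeats separated by at least `min_internal` bp.  Shared k-mers of
#' the locus against itself vote for the repeat offset; the maximal
#' scoring matched segment along the dominant offset (match +1,
#' mismatch -2) defines the repeat extent; boundaries are then polished
#' within +/- 6 bp to the position flanked by an exact 4-10 bp
#' target-site duplication when one exists.
#'
#' @param locus DNA string.
#' @param min_ltr_length minimum LTR length in bp (default 100).
#' @param min_identity minimum percent identity between the two repeat
#'   copies (default 80).
#' @param min_internal minimum distance between the repeat copies
#'   (default 4000).
#' @return `NULL` when no repeat pair passes the thresholds ("no
#'   provirus"), else a list with `ltr5`, `ltr3` (0-based half-open
#'   intervals in locus coordinates), `tsd` (string or `NA`),
#'   `identity` (percent between copies) and `n_diff` (mismatching
#'   positions between copies).
#' @export
detect_ltr_pair <- function(locus, min_ltr_length = 100L, min_identity = 80,
                            min_internal = 4000L) {
  n <- nchar(locus)
  if (n <= 2L * min_ltr_length) return(NULL)
  k <- 12L
  ch <- seq_chars(locus)
  km <- substring(locus, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  idx <- split(seq_along(km), km)
  idx <- idx[lengths(idx) >= 2L & lengths(idx) <= 12L]
  if (!length(idx)) return(NULL)
  ds <- unlist(lapply(idx, function(p) {
    cmb <- utils::combn(sort(p), 2L)
    d <- cmb[2L, ] - cmb[1L, ]
    d[d >= min_internal + min_ltr_length]
  }), use.names = FALSE)
  if (length(ds) < 5L) return(NULL)
  tab <- table(ds)
  d <- as.integer(names(tab)[which.max(tab)])
  if (max(tab) < 5L) return(NULL)
  ## maximal scoring matched segment along offset d
  m <- ch[seq_len(n - d)] == ch[seq_len(n - d) + d]
  sc <- ifelse(m, 1, -2)
  best <- 0; best_a <- 0L; best_b <- -1L
  cur <- 0; cur_a <- 1L
  for (i in seq_along(sc)) {
    if (cur <= 0) { cur <- 0; cur_a <- i }
    cur <- cur + sc[i]
    if (cur > best) { best <- cur; best_a <- cur_a; best_b <- i }
  }
  if (best_b - best_a + 1L < min_ltr_length) return(NULL)
  a <- best_a; b <- best_b
  ## trim terminal mismatches
  while (a < b && !m[a]) a <- a + 1L
  while (b > a && !m[b]) b <- b - 1L
  ## polish boundaries within +/- 6 bp: score candidates by flanking-TSD
  ## length plus the canonical TG...CA repeat ends, penalized by shift
  tsd <- NA_character_
  best_sc <- -Inf; best_cand <- NULL
  for (da in -6L:6L) for (db in -6L:6L) {
    a2 <- a + da; b2 <- b + db
    if (a2 < 2L || b2 <= a2 || b2 + d > n) next
    kt_found <- 0L; tsd_cand <- NA_character_
    for (kt in 10L:4L) {
      if (a2 - kt < 1L || b2 + d + kt > n) next
      left <- substr(locus, a2 - kt, a2 - 1L)
      if (left == substr(locus, b2 + d + 1L, b2 + d + kt)) {
        kt_found <- kt; tsd_cand <- left; break
      }
    }
    tg <- substr(locus, a2, a2 + 1L) == "TG" &&
      substr(locus, a2 + d, a2 + d + 1L) == "TG"
    ca_end <- substr(locus, b2 - 1L, b2) == "CA" &&
      substr(locus, b2 + d - 1L, b2 + d) == "CA"
    sc <- kt_found + 2L * tg + 2L * ca_end - abs(da) - abs(db)
    if (sc > best_sc ||
        (sc == best_sc && abs(da) + abs(db) <
           abs(best_cand$da) + abs(best_cand$db))) {
      best_sc <- sc
      best_cand <- list(a = a2, b = b2, tsd = tsd_cand, da = da, db = db)
    }
  }
  if (!is.null(best_cand)) {
    a <- best_cand$a; b <- best_cand$b; tsd <- best_cand$tsd
  }
  len <- b - a + 1L
  if (len < min_ltr_length) return(NULL)
  seg5 <- substr(locus, a, b)
  seg3 <- substr(locus, a + d, b + d)
  ndiff <- sum(seq_chars(seg5) != seq_chars(seg3))
  ident <- 100 * (1 - ndiff / len)
  if (ident < min_identity) return(NULL)
  if (d - len < min_internal) return(NULL)
  list(ltr5 = c(a - 1L, b), ltr3 = c(a + d - 1L, b + d),
       tsd = tsd, identity = ident, n_diff = ndiff)
}

## column-level mapping from a pairwise alignment (ref row, query row)
aln_maps <- function(ref_aln, qry_aln) {
  rc <- seq_chars(ref_aln); qc <- seq_chars(qry_aln)
  list(rc = rc, qc = qc, rpos = cumsum(rc != "-"), qpos = cumsum(qc != "-"))
}

## map a 0-based half-open reference interval to query coordinates
map_interval <- function(maps, s0, e0) {
  col_s <- match(s0 + 1L, maps$rpos * (maps$rc != "-"))
  col_e <- match(e0, maps$rpos * (maps$rc != "-"))
  if (is.na(col_s) || is.na(col_e)) return(c(NA_integer_, NA_integer_))
  qs <- maps$qpos[col_s] - as.integer(maps$qc[col_s] != "-")
  qe <- maps$qpos[col_e]
  c(qs, qe)
}

#' Reference-guided gene mapping
#'
#' Globally aligns a provirus to an annotated reference provirus and
#' projects the reference feature boundaries through the alignment.
#' Features that fall entirely inside an alignment gap are reported
#' absent.
#'
#' @param provirus provirus sequence (5'LTR through 3'LTR).
#' @param ref_seq reference provirus sequence.
#' @param ref_features data frame with `feature`, `start`, `end`
#'   (0-based half-open, reference coordinates).
#' @param min_identity identity floor (percent); below it genes are
#'   left unmapped and the provirus flagged.
#' @return list with `features` (data frame: feature, start, end,
#'   present; provirus coordinates), `identity`, `flagged`, and the
#'   alignment rows (`ref_aln`, `prov_aln`).
#' @export
map_genes <- function(provirus, ref_seq, ref_features, min_identity = 50) {
  aln <- align_pair(ref_seq, provirus)
  ident <- pair_identity(aln)
  if (ident < min_identity) {
    f <- ref_features
    f$start <- NA_integer_; f$end <- NA_integer_; f$present <- FALSE
    return(list(features = f, identity = ident, flagged = TRUE,
                ref_aln = aln[1L], prov_aln = aln[2L]))
  }
  maps <- aln_maps(aln[1L], aln[2L])
  f <- ref_features
  f$present <- FALSE
  for (i in seq_len(nrow(f))) {
    iv <- map_interval(maps, ref_features$start[i], ref_features$end[i])
    f$start[i] <- iv[1L]; f$end[i] <- iv[2L]
    ## a feature whose reference span maps into an alignment gap projects
    ## to (nearly) nothing; require a minimal mapped width to call it
    ref_w <- ref_features$end[i] - ref_features$start[i]
    min_w <- max(1L, min(30L, floor(0.5 * ref_w)))
    f$present[i] <- !anyNA(iv) && (iv[2L] - iv[1L]) >= min_w
  }
  list(features = f, identity = ident, flagged = FALSE,
       ref_aln = aln[1L], prov_aln = aln[2L])
}

#' Scan late-domain and CETTG motif states
#'
#' Translates gag and env in the mapped reading frame and searches for
#' the canonical motifs (PRPPIY / PQPPVL; PPPY / TPPY; CETTG) within
#' +/- `window` amino acids of the reference-homologous position.
#'
#' @param features mapped feature data frame from [map_genes] (must
#'   include gag/env and the `motif_*` rows).
#' @param provirus provirus sequence.
#' @param ref_features reference feature data frame (for motif
#'   positions relative to their genes).
#' @param window search window in amino acids (default 15).
#' @return list with states `gag_ld1`, `gag_ld2`, `env_cettg`.
#' @export
scan_motifs <- function(features, provirus, ref_features, window = 15L) {
  get_iv <- function(df, f) {
    r <- df[df$feature == f, , drop = FALSE]
    if (!nrow(r) || !isTRUE(r$present[1L])) return(NULL)
    c(r$start[1L], r$end[1L])
  }
  ref_iv <- function(f) {
    r <- ref_features[ref_features$feature == f, , drop = FALSE]
    if (!nrow(r)) NULL else c(r$start[1L], r$end[1L])
  }
  scan_one <- function(gene, motif_feature, targets, other_state) {
    giv <- get_iv(features, gene)
    if (is.null(giv) || anyNA(giv)) return("absent")
    ## the motif's reference-homologous position must itself map into the
    ## provirus; a position swallowed by a deletion means the motif region
    ## is missing, not altered
    if (is.null(get_iv(features, motif_feature))) return("absent")
    rg <- ref_iv(gene); rm <- ref_iv(motif_feature)
    if (is.null(rg) || is.null(rm)) return("absent")
    aa_pos <- (rm[1L] - rg[1L]) %/% 3L + 1L       # reference-homologous aa
    aa <- translate_dna(substr(provirus, giv[1L] + 1L, giv[2L]))
    if (!nzchar(aa)) return("absent")
    lo <- max(1L, aa_pos - window)
    hi <- min(nchar(aa), aa_pos + window + max(nchar(targets)))
    win <- substr(aa, lo, hi)
    for (t in targets) if (grepl(t, win, fixed = TRUE)) return(t)
    other_state
  }
  list(
    gag_ld1 = scan_one("gag", "motif_gag_ld1", c("PRPPIY", "PQPPVL"), "other"),
    gag_ld2 = scan_one("gag", "motif_gag_ld2", c("PPPY", "TPPY"), "other"),
    env_cettg = scan_one("env", "motif_env_cettg", "CETTG", "altered"))
}

#' Assess ORF intactness of the mapped genes
#'
#' Translates each mapped gene in frame and reports internal stop
#' codons.  `full_length` requires zero internal stops and at least
#' `full_length_frac` of the reference gene length.
#'
#' @param features mapped feature data frame from [map_genes].
#' @param provirus provirus sequence.
#' @param ref_features reference features (for reference gene lengths).
#' @param full_length_frac length fraction required for full-length
#'   status (default 0.9).
#' @return data frame: gene, status (`full_length`, `premature_stop`,
#'   `partial`, `absent`), `stop_positions` (semicolon-joined codon
#'   indices), `longest_orf_codons`.
#' @export
assess_orfs <- function(features, provirus, ref_features,
                        full_length_frac = 0.9) {
  genes <- c("gag", "pro", "pol", "env")
  out <- lapply(genes, function(g) {
    r <- features[features$feature == g, , drop = FALSE]
    ref <- ref_features[ref_features$feature == g, , drop = FALSE]
    ref_len <- ref$end[1L] - ref$start[1L]
    if (!nrow(r) || !isTRUE(r$present[1L]) || anyNA(c(r$start[1L], r$end[1L])))
      return(data.frame(gene = g, status = "absent", stop_positions = "",
                        longest_orf_codons = 0L))
    len <- r$end[1L] - r$start[1L]
    aa <- translate_dna(substr(provirus, r$start[1L] + 1L, r$end[1L]))
    st <- which(seq_chars(aa) == "*")
    st <- st[st < nchar(aa)]                       # terminal stop is fine
    runs <- if (nchar(aa)) {
      bound <- c(0L, st, nchar(aa) + 1L)
      max(diff(bound) - 1L)
    } else 0L
    status <- if (len < full_length_frac * ref_len) "partial"
      else if (length(st)) "premature_stop" else "full_length"
    data.frame(gene = g, status = status,
               stop_positions = paste(st, collapse = ";"),
               longest_orf_codons = runs)
  })
  do.call(rbind, out)
}

#' Detect diagnostic deletions from the reference alignment
#'
#' Measures contiguous reference-relative gaps within each gene and
#' matches them against expected deletion lengths within a tolerance;
#' unmatched gaps of at least 50 nt are reported as `other`.
#'
#' @param ref_aln,prov_aln aligned reference and provirus rows from
#'   [map_genes].
#' @param ref_features reference features (gene intervals).
#' @param expected data frame with columns `gene` and `length`
#'   (defaults to the diagnostic 133/1487/2216 nt set).
#' @param tolerance match tolerance in nt (default 10).
#' @return data frame: gene, expected (`133`/`1487`/`2216`/`other`),
#'   observed, present.
#' @export
detect_deletions <- function(ref_aln, prov_aln, ref_features,
                             expected = NULL, tolerance = 10L) {
  if (is.null(expected))
    expected <- data.frame(gene = c("pol", "env", "pol"),
                           length = c(133L, 1487L, 2216L))
  maps <- aln_maps(ref_aln, prov_aln)
  gapcol <- maps$qc == "-" & maps$rc != "-"
  out <- list()
  if (any(gapcol)) {
    r <- rle(gapcol)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(col_s = starts[r$values], col_e = ends[r$values])
    genes <- c("gag", "pro", "pol", "env")
    for (i in seq_len(nrow(runs))) {
      rs <- maps$rpos[runs$col_s[i]]      # 1-based ref positions of the gap
      re <- maps$rpos[runs$col_e[i]]
      glen <- re - rs + 1L
      mid <- (rs + re) / 2
      gene <- NA_character_
      for (g in genes) {
        gi <- ref_features[ref_features$feature == g, , drop = FALSE]
        if (nrow(gi) && mid > gi$start[1L] && mid <= gi$end[1L]) gene <- g
      }
      if (is.na(gene)) next
      cand <- expected[expected$gene == gene &
                       abs(expected$length - glen) <= tolerance, , drop = FALSE]
      if (nrow(cand)) {
        out[[length(out) + 1L]] <- data.frame(
          gene = gene, expected = as.character(cand$length[1L]),
          observed = glen, present = TRUE)
      } else if (glen >= 50L) {
        out[[length(out) + 1L]] <- data.frame(
          gene = gene, expected = "other", observed = glen, present = TRUE)
      }
    }
  }
  if (!length(out))
    return(data.frame(gene = character(0), expected = character(0),
                      observed = integer(0), present = logical(0)))
  do.call(rbind, out)
}

#' Assign a provirus to a subgroup
#'
#' The nearest reference consensus by whole-provirus percent identity
#' decides the major group; within group B the presence of the
#' env-deletion signature separates B1 (present) from B2 (absent).
#' Identity below the floor yields `unassigned`.
#'
#' @param provirus provirus sequence.
#' @param consensuses named character vector of subgroup consensus (or
#'   ancestral reference) sequences; names among `A`, `B`, `B1`, `B2`,
#'   `C`.
#' @param deletions deletion signature data frame (see
#'   [detect_deletions]); used for the B1/B2 rule.
#' @param floor identity floor in percent (default 70).
#' @param identities optional precomputed named identity vector (one
#'   entry per consensus) to avoid re-aligning.
#' @return list with `subgroup`, `nearest`, `identity`.
#' @export
assign_subgroup <- function(provirus, consensuses, deletions = NULL,
                            floor = 70, identities = NULL) {
  if (!length(consensuses)) stop("at least one consensus required")
  ids <- if (!is.null(identities)) identities else
    vapply(consensuses, function(cs)
      pair_identity(align_pair(provirus, cs)), numeric(1))
  best <- names(ids)[order(-ids, names(ids))][1L]
  if (ids[[best]] < floor)
    return(list(subgroup = "unassigned", nearest = best,
                identity = unname(ids[[best]])))
  major <- if (startsWith(best, "B")) "B" else best
  sub <- major
  if (major == "B") {
    env_del <- !is.null(deletions) && nrow(deletions) &&
      any(deletions$gene == "env" & deletions$expected == "1487" &
            deletions$present)
    sub <- if (env_del) "B1" else "B2"
  }
  list(subgroup = sub, nearest = best, identity = unname(ids[[best]]))
}

#' Annotate one candidate locus end to end
#'
#' Runs LTR pair detection, reference-guided gene mapping, motif and
#' ORF assessment, deletion signature detection and subgroup
#' assignment.
#'
#' @param locus locus sequence (plus-oriented).
#' @param locus_id identifier.
#' @param references named character vector of subgroup reference
#'   sequences (full proviruses).
#' @param ref_features reference feature data frame (shared gene
#'   coordinates; 0-based half-open).
#' @param min_ltr_length,ltr_min_identity passed to [detect_ltr_pair].
#' @param tolerance deletion-length tolerance in nt.
#' @return a `provirus_call`, or `NULL` when no provirus is found.
#' @export
annotate_locus <- function(locus, locus_id, references, ref_features,
                           min_ltr_length = 100L, ltr_min_identity = 80,
                           tolerance = 10L) {
  lp <- detect_ltr_pair(locus, min_ltr_length, ltr_min_identity)
  if (is.null(lp)) return(NULL)
  pv_start <- lp$ltr5[1L]; pv_end <- lp$ltr3[2L]
  provirus <- substr(locus, pv_start + 1L, pv_end)
  ## nearest reference for the reference-guided steps
  ids <- vapply(references, function(cs)
    pair_identity(align_pair(provirus, cs)), numeric(1))
  nearest <- names(ids)[order(-ids, names(ids))][1L]
  mg <- map_genes(provirus, references[[nearest]], ref_features)
  dels <- detect_deletions(mg$ref_aln, mg$prov_aln, ref_features,
                           tolerance = tolerance)
  motifs <- scan_motifs(mg$features, provirus, ref_features)
  orfs <- assess_orfs(mg$features, provirus, ref_features)
  asg <- assign_subgroup(provirus, references, deletions = dels,
                         identities = ids)
  structure(list(
    locus_id = locus_id,
    provirus = c(pv_start, pv_end),
    ltr5 = lp$ltr5, ltr3 = lp$ltr3, tsd = lp$tsd,
    ltr_identity = lp$identity,
    subgroup = asg$subgroup, nearest_reference = asg$nearest,
    ref_identity = asg$identity, flagged = mg$flagged,
    features = mg$features, motifs = motifs, orfs = orfs,
    deletions = dels,
    ltr5_seq = substr(locus, lp$ltr5[1L] + 1L, lp$ltr5[2L]),
    ltr3_seq = substr(locus, lp$ltr3[1L] + 1L, lp$ltr3[2L]),
    provirus_seq = provirus), class = "provirus_call")
}

#' @export
print.provirus_call <- function(x, ...) {
  cat(sprintf("provirus_call %s [%d-%d] subgroup %s (%.1f%% to %s)\n",
              x$locus_id, x$provirus[1L], x$provirus[2L], x$subgroup,
              x$ref_identity, x$nearest_reference))
  cat(sprintf("  LTRs: %d-%d / %d-%d (%.2f%% pair identity), TSD %s\n",
              x$ltr5[1L], x$ltr5[2L], x$ltr3[1L], x$ltr3[2L],
              x$ltr_identity, ifelse(is.na(x$tsd), "none", x$tsd)))
  cat(sprintf("  motifs: %s/%s/%s; ORFs: %s\n", x$motifs$gag_ld1,
              x$motifs$gag_ld2, x$motifs$env_cettg,
              paste(sprintf("%s=%s", x$orfs$gene, x$orfs$status),
                    collapse = " ")))
  invisible(x)
}

#' Annotate a table of candidate loci
#'
#' @param loci data frame from [extract_loci].
#' @param references,ref_features,... passed to [annotate_locus].
#' @return list of `provirus_call` objects (loci with no provirus are
#'   dropped).
#' @export
annotate_loci <- function(loci, references, ref_features, ...) {
  calls <- list()
  for (i in seq_len(nrow(loci))) {
    pc <- annotate_locus(loci$sequence[i], loci$locus_id[i], references,
                         ref_features, ...)
    if (!is.null(pc)) {
      pc$contig <- loci$contig[i]
      pc$locus_start <- loci$start[i]
      pc$locus_end <- loci$end[i]
      pc$strand <- loci$strand[i]
      calls[[length(calls) + 1L]] <- pc
    }
  }
  calls
}

#' Flatten provirus calls to a one-row-per-provirus feature report
#' @param calls list of `provirus_call` objects.
#' @return data frame.
#' @export
calls_table <- function(calls) {
  if (!length(calls)) return(data.frame())
  do.call(rbind, lapply(calls, function(x) {
    data.frame(
      locus_id = x$locus_id, subgroup = x$subgroup,
      provirus_start = x$provirus[1L], provirus_end = x$provirus[2L],
      ltr5_start = x$ltr5[1L], ltr5_end = x$ltr5[2L],
      ltr3_start = x$ltr3[1L], ltr3_end = x$ltr3[2L],
      tsd = ifelse(is.na(x$tsd), "", x$tsd),
      ltr_identity = x$ltr_identity, ref_identity = x$ref_identity,
      motif_gag_ld1 = x$motifs$gag_ld1, motif_gag_ld2 = x$motifs$gag_ld2,
      motif_env_cettg = x$motifs$env_cettg,
      orf_summary = paste(sprintf("%s=%s", x$orfs$gene, x$orfs$status),
                          collapse = ";"),
      deletions = if (nrow(x$deletions))
        paste(sprintf("%s:%s", x$deletions$gene, x$deletions$observed),
              collapse = ";") else "")
  }))
}

#' Write provirus calls as GFF3
#'
#' @param calls list of `provirus_call` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_gff3 <- function(calls, path) {
  lines <- "##gff-version 3"
  for (x in calls) {
    seqid <- x$locus_id
    row <- function(type, iv, attr)
      sprintf("%s\tervkit\t%s\t%d\t%d\t.\t+\t.\t%s", seqid, type,
              iv[1L] + 1L, iv[2L], attr)
    lines <- c(lines,
               row("provirus", x$provirus,
                   sprintf("ID=%s;subgroup=%s", seqid, x$subgroup)),
               row("LTR", x$ltr5, sprintf("ID=%s_LTR5", seqid)),
               row("LTR", x$ltr3, sprintf("ID=%s_LTR3", seqid)))
    for (i in seq_len(nrow(x$features))) {
      f <- x$features[i, ]
      if (!isTRUE(f$present) || anyNA(c(f$start, f$end))) next
      iv <- c(f$start, f$end) + x$provirus[1L]
      lines <- c(lines, row(f$feature, iv,
                            sprintf("ID=%s_%s", seqid, f$feature)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
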