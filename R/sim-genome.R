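## Germline-colonization simulator: plant proviruses of known age,
## subgroup and feature content into a synthetic host genome.

apply_ltr_indels <- function(ltr, combo) {
  if (nrow(combo) == 0L) return(ltr)
  combo <- combo[order(-combo$offset), , drop = FALSE]
  for (i in seq_len(nrow(combo))) {
    o <- combo$offset[i]
    if (combo$type[i] == "deletion") {
      ltr <- paste0(substr(ltr, 1L, o),
                    substr(ltr, o + combo$length[i] + 1L, nchar(ltr)))
    } else {
      ins <- combo$seq[i]
      if (!nzchar(ins))
        ins <- with_seed(derive_seed(o * 131L + combo$length[i], 77L),
                         random_dna(combo$length[i]))
      ltr <- paste0(substr(ltr, 1L, o), ins,
                    substr(ltr, o + 1L, nchar(ltr)))
    }
  }
  ltr
}

combo_label <- function(combo) {
  if (nrow(combo) == 0L) return("")
  paste(sprintf("%s:%d:%d", ifelse(combo$type == "deletion", "del", "ins"),
                combo$offset, combo$length), collapse = "+")
}

classify_ld1 <- function(aa) {
  if (aa == "PRPPIY") "PRPPIY" else if (aa == "PQPPVL") "PQPPVL" else "other"
}
classify_ld2 <- function(aa) {
  if (aa == "PPPY") "PPPY" else if (aa == "TPPY") "TPPY" else "other"
}
classify_cettg <- function(aa) {
  if (aa == "CETTG") "CETTG" else "altered"
}

## write amino acids over an nt interval of a sequence (0-based start)
overwrite_aa <- function(seqstr, start0, aa) {
  codons <- vapply(seq_chars(aa), function(a) AA_CODONS[[a]][1L], character(1))
  nt <- paste(codons, collapse = "")
  paste0(substr(seqstr, 1L, start0), nt,
         substr(seqstr, start0 + nchar(nt) + 1L, nchar(seqstr)))
}

## build one provirus of a subgroup; all randomness from the current RNG
simulate_provirus <- function(config, subgroup, anc, id) {
  age <- draw_age(config$age_distribution)
  menu <- config$ltr_indel_menu[[subgroup]]
  ci <- sample.int(length(menu$combos), 1L, prob = menu$prob)
  combo <- menu$combos[[ci]]
  ltr <- apply_ltr_indels(anc$ltr, combo)
  ltr_anc_len <- nchar(anc$ltr)
  total_len <- nchar(anc$sequence)
  internal <- substr(anc$sequence, ltr_anc_len + 1L, total_len - ltr_anc_len)
  feats <- anc$features
  feats <- feats[!feats$feature %in% c("LTR5", "LTR3"), , drop = FALSE]
  feats$start <- feats$start - ltr_anc_len
  feats$end <- feats$end - ltr_anc_len

  ltr5 <- evolve_sequence(ltr, age, config)
  ltr3 <- evolve_sequence(ltr, age, config)
  internal <- evolve_sequence(internal, age, config)

  gene_iv <- function(g) unlist(feats[feats$feature == g, c("start", "end")])

  ## per-provirus motif variant swaps (overwrite after evolution)
  motif_states <- c(gag_ld1 = NA_character_, gag_ld2 = NA_character_,
                    env_cettg = NA_character_)
  if (runif(1) < config$tppy_swap_prob[[subgroup]]) {
    iv <- gene_iv("motif_gag_ld2")
    internal <- overwrite_aa(internal, iv[["start"]], "TPPY")
  }
  if (runif(1) < config$cettg_alter_prob[[subgroup]]) {
    iv <- gene_iv("motif_env_cettg")
    internal <- overwrite_aa(internal, iv[["start"]], "CETAG")
  }

  ## premature stop codons (planted after evolution, exact by construction)
  genes <- c("gag", "pro", "pol", "env")
  motif_codon_block <- list(
    gag = c(MOTIF_AA_POS$gag_ld1 - 5L, MOTIF_AA_POS$gag_ld2 + 10L),
    env = c(MOTIF_AA_POS$env_cettg - 5L, MOTIF_AA_POS$env_cettg + 10L))
  for (g in genes) {
    p <- config$stop_codon_probability[[g]]
    if (!is.na(p) && runif(1) < p) {
      iv <- gene_iv(g)
      ncod <- (iv[["end"]] - iv[["start"]]) %/% 3L
      cand <- 15L:(ncod - 15L)
      blk <- motif_codon_block[[g]]
      if (!is.null(blk)) cand <- setdiff(cand, blk[1]:blk[2])
      idx <- cand[sample.int(length(cand), 1L)]
      at <- iv[["start"]] + 3L * (idx - 1L)
      internal <- paste0(substr(internal, 1L, at), "TAA",
                         substr(internal, at + 4L, nchar(internal)))
    }
  }

  ## diagnostic deletions (exact lengths, planted after evolution)
  specs <- config$deletion_specs
  specs <- specs[specs$subgroup == subgroup, , drop = FALSE]
  planted <- specs[runif(nrow(specs)) < specs$probability, , drop = FALSE]
  if (nrow(planted)) {
    planted$del_start <- vapply(seq_len(nrow(planted)), function(i)
      gene_iv(planted$gene[i])[["start"]] + planted$offset[i], numeric(1))
    planted <- planted[order(-planted$del_start), , drop = FALSE]
    for (i in seq_len(nrow(planted))) {
      s0 <- planted$del_start[i]; L <- planted$length[i]
      internal <- paste0(substr(internal, 1L, s0),
                         substr(internal, s0 + L + 1L, nchar(internal)))
      ## shift / shrink feature intervals
      drop_row <- logical(nrow(feats))
      for (j in seq_len(nrow(feats))) {
        if (feats$end[j] <= s0) next
        if (feats$start[j] >= s0 + L) {
          feats$start[j] <- feats$start[j] - L
          feats$end[j] <- feats$end[j] - L
        } else if (feats$start[j] <= s0 && feats$end[j] >= s0 + L) {
          feats$end[j] <- feats$end[j] - L      # deletion inside feature
        } else {
          drop_row[j] <- TRUE                    # feature swallowed/truncated
        }
      }
      feats <- feats[!drop_row, , drop = FALSE]
    }
  }
  del_label <- if (nrow(planted))
    paste(sprintf("%s:%d", planted$gene, planted$length), collapse = ";") else ""

  ## truth scans against the emitted internal sequence
  del_genes <- unique(planted$gene)
  for (m in names(motif_states)) {
    f <- paste0("motif_", m)
    if (!f %in% feats$feature) { motif_states[[m]] <- "absent"; next }
    host_gene <- if (startsWith(m, "gag")) "gag" else "env"
    if (host_gene %in% del_genes &&
        gene_iv(f)[["start"]] > gene_iv(host_gene)[["start"]] + 0) {
      ## motif survives only if no frameshifting deletion sits upstream of it
      up_del <- planted[planted$gene == host_gene &
                        planted$del_start < gene_iv(f)[["start"]], , drop = FALSE]
      if (nrow(up_del) && any(up_del$length %% 3L != 0L)) {
        motif_states[[m]] <- "absent"; next
      }
    }
    iv <- gene_iv(f)
    aa <- translate_dna(substr(internal, iv[["start"]] + 1L, iv[["end"]]))
    motif_states[[m]] <- switch(m, gag_ld1 = classify_ld1(aa),
                                gag_ld2 = classify_ld2(aa),
                                env_cettg = classify_cettg(aa))
  }
  stops <- character(0)
  orf_status <- character(0)
  for (g in genes) {
    if (g %in% del_genes) {
      orf_status <- c(orf_status, sprintf("%s=partial", g))
      next
    }
    iv <- gene_iv(g)
    aa <- translate_dna(substr(internal, iv[["start"]] + 1L, iv[["end"]]))
    internal_stops <- which(seq_chars(aa) == "*")
    internal_stops <- internal_stops[internal_stops < nchar(aa)]
    if (length(internal_stops)) {
      stops <- c(stops, sprintf("%s:%d", g, internal_stops))
      orf_status <- c(orf_status, sprintf("%s=premature_stop", g))
    } else {
      orf_status <- c(orf_status, sprintf("%s=full_length", g))
    }
  }

  sequence <- paste0(ltr5, internal, ltr3)
  list(id = id, subgroup = subgroup, age = age, sequence = sequence,
       ltr5_length = nchar(ltr5), ltr3_length = nchar(ltr3),
       ltr5 = ltr5, ltr3 = ltr3,
       ltr_indels = combo_label(combo), ltr_combo = ci,
       deletions = del_label,
       stops = paste(stops, collapse = ";"),
       orf_status = paste(orf_status, collapse = ";"),
       motif_states = motif_states,
       strand = if (runif(1) < 0.5) "+" else "-")
}

#' Simulate a host genome with planted proviruses
#'
#' Draws a uniform-composition host background, builds the subgroup
#' ancestral proviruses, and for each planted copy: draws an insertion
#' age, evolves the two LTRs independently and the internal region once
#' under the CpG-aware substitution process, plants subgroup-diagnostic
#' deletions, LTR indel combinations, motif variants and premature stop
#' codons, and inserts the provirus at a random position flanked by a
#' duplicated target site.  Fully reproducible from `config$rng_seed`.
#'
#' Truth motif states and ORF stop lists describe the emitted genome
#' (scanned after evolution), so downstream recovery can be checked
#' exactly.
#'
#' @param config a [sim_config].
#' @param out_prefix optional path prefix; writes
#'   `<prefix>_genome.fasta`, `<prefix>_truth.tsv`,
#'   `<prefix>_ancestors.fasta`, `<prefix>_reference_features.tsv` and
#'   `<prefix>_config.txt`.
#' @return an `erv_simulation`: list with `genome` (named character),
#'   `truth` (data frame; 0-based half-open coordinates), `ancestors`,
#'   `ancestor_features`, `config`, and `files` when written.
#' @export
simulate_insertions <- function(config, out_prefix = NULL) {
  subgroups <- names(config$n_per_subgroup)[config$n_per_subgroup > 0L]
  n_total <- sum(config$n_per_subgroup)
  res <- with_seed(config$rng_seed, {
    host <- random_dna(config$host_length)
    ancestors <- lapply(setNames(nm = subgroups), build_ancestral_provirus,
                        config = config)
    pvs <- list()
    k <- 0L
    for (sg in subgroups) {
      for (i in seq_len(config$n_per_subgroup[[sg]])) {
        k <- k + 1L
        pvs[[k]] <- simulate_provirus(config, sg, ancestors[[sg]],
                                      sprintf("pv%03d_%s", k, sg))
      }
    }
    ## insertion points: sorted with min_spacing, via the gap construction
    margin <- 2000L
    free <- (config$host_length - 2L * margin) -
      (n_total - 1L) * config$min_spacing
    if (free <= n_total)
      stop("cannot place ", n_total, " insertions with min_spacing ",
           config$min_spacing, " in host_length ", config$host_length,
           "; increase host_length")
    pos <- margin + floor(sort(runif(n_total, 0, free))) +
      (seq_len(n_total) - 1L) * config$min_spacing
    tsd_len <- sample(seq(config$tsd_length_range[1], config$tsd_length_range[2]),
                      n_total, replace = TRUE)
    list(host = host, ancestors = ancestors, pvs = pvs, pos = pos,
         tsd_len = tsd_len)
  })

  ## assemble genome left to right
  pieces <- character(0)
  truth <- vector("list", n_total)
  prev <- 0L                      # host consumed so far (0-based)
  out_len <- 0L
  for (i in seq_len(n_total)) {
    p <- res$pos[i]; k <- res$tsd_len[i]
    pv <- res$pvs[[i]]
    tsd <- substr(res$host, p + 1L, p + k)
    left <- substr(res$host, prev + 1L, p + k)   # host up to and incl. TSD
    ins <- if (pv$strand == "+") pv$sequence else revcomp(pv$sequence)
    pieces <- c(pieces, left, ins)
    start <- out_len + nchar(left)
    out_len <- start + nchar(ins)
    prev <- p                                     # TSD re-emitted after provirus
    truth[[i]] <- data.frame(
      provirus_id = pv$id, subgroup = pv$subgroup, contig = config$contig,
      start = start, end = out_len, strand = pv$strand,
      true_age = pv$age, tsd = tsd,
      ltr5_length = pv$ltr5_length, ltr3_length = pv$ltr3_length,
      planted_deletions = pv$deletions,
      planted_ltr_indels = pv$ltr_indels,
      ltr_combo = pv$ltr_combo,
      planted_stops = pv$stops,
      orf_status = pv$orf_status,
      motif_gag_ld1 = pv$motif_states[["gag_ld1"]],
      motif_gag_ld2 = pv$motif_states[["gag_ld2"]],
      motif_env_cettg = pv$motif_states[["env_cettg"]])
  }
  pieces <- c(pieces, substr(res$host, prev + 1L, config$host_length))
  genome <- setNames(paste(pieces, collapse = ""), config$contig)
  truth <- if (n_total) do.call(rbind, truth) else data.frame()

  out <- structure(list(
    genome = genome, truth = truth,
    ancestors = vapply(res$ancestors, `[[`, character(1), "sequence"),
    ancestor_features = res$ancestors[[1L]]$features,
    ancestor_ltrs = vapply(res$ancestors, `[[`, character(1), "ltr"),
    config = config, files = NULL), class = "erv_simulation")

  if (!is.null(out_prefix)) {
    files <- c(genome = paste0(out_prefix, "_genome.fasta"),
               truth = paste0(out_prefix, "_truth.tsv"),
               ancestors = paste0(out_prefix, "_ancestors.fasta"),
               features = paste0(out_prefix, "_reference_features.tsv"),
               config = paste0(out_prefix, "_config.txt"))
    write_fasta(genome, files[["genome"]])
    con <- file(files[["truth"]], "w")
    writeLines("# coordinates are 0-based half-open", con)
    write.table(truth, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    write_fasta(out$ancestors, files[["ancestors"]])
    write.table(out$ancestor_features, files[["features"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    scalars <- config[vapply(config, function(x)
      is.atomic(x) && length(x) <= 4L, logical(1))]
    writeLines(sprintf("%s = %s", names(scalars),
                       vapply(scalars, function(x)
                         paste(x, collapse = ","), character(1))),
               files[["config"]])
    out$files <- files
  }
  out
}

#' @export
print.erv_simulation <- function(x, ...) {
  cat(sprintf("erv_simulation: %d proviruses in a %s bp genome (%s)\n",
              nrow(x$truth), format(nchar(x$genome), big.mark = ","),
              paste(sprintf("%s=%d", names(table(x$truth$subgroup)),
                            as.integer(table(x$truth$subgroup))),
                    collapse = ", ")))
  invisible(x)
}
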