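## Pipeline orchestration: simulate -> mine -> annotate -> consensus ->
## date -> ltr-clades, with a run manifest and a consolidated report.

## extract the sequence of one mapped feature from a provirus call
call_feature_seq <- function(call, feature) {
  f <- call$features[call$features$feature == feature, , drop = FALSE]
  if (!nrow(f) || !isTRUE(f$present[1L]) || anyNA(c(f$start[1L], f$end[1L])))
    return(NULL)
  substr(call$provirus_seq, f$start[1L] + 1L, f$end[1L])
}

#' Run the full ERV characterization pipeline
#'
#' Executes mine -> annotate -> consensus -> date -> ltr-clades on a
#' genome (optionally produced by the simulator first), each stage
#' feeding the next, and returns all stage outputs plus a run manifest.
#'
#' @param sim a [sim_config] to simulate a genome first, or an
#'   `erv_simulation`, or `NULL` to use `genome`/`seeds` inputs.
#' @param genome named character vector of contigs (or FASTA path);
#'   ignored when `sim` is given.
#' @param seeds named character vector of seed sequences; defaults to
#'   the simulator's subgroup ancestors when `sim` is given.
#' @param references named subgroup reference provirus sequences used
#'   for reference-guided annotation and subgroup assignment.
#' @param ref_features reference feature table (feature/start/end,
#'   0-based half-open).
#' @param flank extraction flank in bp (default 10000).
#' @param min_identity mining identity threshold in percent (default 85).
#' @param M substitution rate per nt per Myr for dating.
#' @param divisor gene-consensus divisor (1 or 2).
#' @param outlier_identity consensus outlier threshold in percent.
#' @param subgroup_cut K2P distance cut for gene dating subgroups
#'   (`NULL` disables splitting).
#' @param min_indel minimum LTR indel length for fingerprinting.
#' @param jaccard Jaccard threshold for clade merging.
#' @param out_dir optional output directory for stage files.
#' @return an `erv_run`: list with `hits`, `loci`, `calls`,
#'   `consensuses`, `ages` (an `erv_ages`), `age_summary`, `clades`,
#'   `fingerprints`, `trees`, `manifest`, and `sim` when simulated.
#' @export
run_pipeline <- function(sim = NULL, genome = NULL, seeds = NULL,
                         references = NULL, ref_features = NULL,
                         flank = 10000L, min_identity = 85,
                         M = DEFAULT_RATE_M, divisor = 1,
                         outlier_identity = 60, subgroup_cut = NULL,
                         min_indel = 3L, jaccard = 0, out_dir = NULL) {
  t0 <- Sys.time()
  manifest <- list(tool = sprintf("ervkit %s",
                                  as.character(utils::packageVersion("ervkit"))),
                   started = format(t0), counts = list(), files = character(0))
  simulation <- NULL
  if (inherits(sim, "sim_config")) simulation <- simulate_insertions(sim)
  else if (inherits(sim, "erv_simulation")) simulation <- sim
  if (!is.null(simulation)) {
    genome <- simulation$genome
    if (is.null(seeds)) seeds <- simulation$ancestors
    if (is.null(references)) references <- simulation$ancestors
    if (is.null(ref_features)) ref_features <- simulation$ancestor_features
    manifest$rng_seed <- simulation$config$rng_seed
    manifest$counts$simulated <- nrow(simulation$truth)
  }
  if (is.null(genome) || is.null(seeds))
    stop("mine: genome and seeds are required")

  ## --- mine ---
  hits <- seed_search(genome, seeds, min_identity = min_identity)
  loci <- extract_loci(hits, genome, flank = flank)
  manifest$counts$hits <- nrow(hits)
  manifest$counts$loci <- nrow(loci)

  ## --- annotate ---
  if (is.null(references) || is.null(ref_features))
    stop("annotate: reference sequences and feature annotation are required")
  calls <- annotate_loci(loci, references, ref_features)
  manifest$counts$proviruses <- length(calls)
  subgroups <- vapply(calls, `[[`, character(1), "subgroup")

  ## --- consensus (per assigned subgroup, whole provirus) ---
  consensuses <- list()
  outliers <- list()
  for (sg in sort(unique(subgroups))) {
    members <- calls[subgroups == sg]
    if (length(members) < 2L) next
    seqs <- setNames(vapply(members, `[[`, character(1), "provirus_seq"),
                     vapply(members, `[[`, character(1), "locus_id"))
    block <- align_sequences(seqs)
    excl <- if (length(seqs) >= 3L) flag_outliers(block, outlier_identity)
            else character(0)
    keep <- block$rows[!names(block$rows) %in% excl]
    consensuses[[sg]] <- majority_consensus(keep)
    outliers[[sg]] <- excl
  }
  manifest$counts$consensus_subgroups <- length(consensuses)

  ## --- date: LTR pairs ---
  estimates <- list()
  for (pc in calls) {
    e <- ltr_pair_age(pc, M = M)
    estimates[[length(estimates) + 1L]] <-
      cbind(ages_table(list(e)), subgroup = pc$subgroup)
  }

  ## --- date: genes vs (sub)group consensus ---
  excluded_ids <- unlist(outliers, use.names = FALSE)
  for (sg in sort(unique(subgroups))) {
    members <- calls[subgroups == sg]
    ids <- vapply(members, `[[`, character(1), "locus_id")
    members <- members[!ids %in% excluded_ids]
    for (g in c("gag", "pro", "pol", "env")) {
      gs <- lapply(members, call_feature_seq, feature = g)
      ok <- !vapply(gs, is.null, logical(1))
      if (sum(ok) < 2L) next
      gseqs <- setNames(unlist(gs[ok]),
                        vapply(members[ok], `[[`, character(1), "locus_id"))
      part <- if (!is.null(subgroup_cut) && length(gseqs) >= 3L)
        split_dating_subgroups(gseqs, cut = subgroup_cut)
      else setNames(rep(1L, length(gseqs)), names(gseqs))
      for (cl in unique(part)) {
        cs <- gseqs[part == cl]
        if (length(cs) < 2L) next   # singleton gene age is undefined
        block <- align_sequences(cs)
        cons <- majority_consensus(block)$consensus
        for (id in names(cs)) {
          e <- gene_consensus_age(cs[[id]], cons, M = M, divisor = divisor,
                                  id = id, gene = g)
          estimates[[length(estimates) + 1L]] <-
            cbind(ages_table(list(e)), subgroup = sg)
        }
      }
    }
  }
  ages <- if (length(estimates)) erv_ages(do.call(rbind, estimates)) else NULL
  age_summary <- if (!is.null(ages)) summarize_ages(ages) else NULL
  manifest$counts$age_estimates <- if (is.null(ages)) 0L else nrow(ages)

  ## --- ltr-clades per major group ---
  fingerprints <- list(); clades <- list(); trees <- list()
  major <- substr(subgroups, 1L, 1L)
  for (mg in sort(unique(major[subgroups != "unassigned"]))) {
    members <- calls[major == mg & subgroups != "unassigned"]
    ltrs <- character(0)
    for (pc in members) {
      ltrs[paste0(pc$locus_id, "_5")] <- pc$ltr5_seq
      ltrs[paste0(pc$locus_id, "_3")] <- pc$ltr3_seq
    }
    if (length(ltrs) < 2L) next
    block <- align_sequences(ltrs, center = "longest")
    fp <- fingerprint_indels(block, min_indel_length = min_indel)
    fingerprints[[mg]] <- fp
    clades[[mg]] <- cluster_fingerprints(fp, threshold = jaccard)
    if (length(ltrs) >= 3L) {
      dm <- block_distance_matrix(block)
      dm[is.na(dm)] <- max(dm, na.rm = TRUE) * 2
      trees[[mg]] <- nj_tree(dm)
    }
  }
  manifest$counts$ltr_clades <- vapply(clades, function(x)
    length(unique(x)), integer(1))

  manifest$finished <- format(Sys.time())
  out <- structure(list(hits = hits, loci = loci, calls = calls,
                        consensuses = consensuses, outliers = outliers,
                        ages = ages, age_summary = age_summary,
                        fingerprints = fingerprints, clades = clades,
                        trees = trees, manifest = manifest,
                        sim = simulation), class = "erv_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(out_dir, ...)
    write_loci(loci, p("mine"))
    write_calls_gff3(calls, p("calls.gff3"))
    tab <- calls_table(calls)
    write.table(tab, p("calls.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (length(consensuses))
      write_fasta(vapply(consensuses, `[[`, character(1), "consensus"),
                  p("consensus.fasta"))
    if (!is.null(ages))
      write.table(as.data.frame(ages), p("ages.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    if (!is.null(age_summary))
      write.table(age_summary, p("age_summary.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    for (mg in names(trees))
      ape::write.tree(trees[[mg]], p(sprintf("ltr_tree_%s.nwk", mg)))
    writeLines(render_report(out), p("report.txt"))
    files <- list.files(out_dir, full.names = TRUE)
    manifest$files <- setNames(vapply(files, file_digest, character(1)),
                               basename(files))
    out$manifest <- manifest
    writeLines(c(sprintf("tool: %s", manifest$tool),
                 sprintf("started: %s", manifest$started),
                 sprintf("finished: %s", manifest$finished),
                 sprintf("count %s: %s", names(manifest$counts),
                         vapply(manifest$counts, function(x)
                           paste(x, collapse = ","), character(1))),
                 sprintf("file %s: %s", names(manifest$files),
                         manifest$files)),
               p("manifest.txt"))
  }
  out
}

#' @export
print.erv_run <- function(x, ...) {
  cat("erv_run\n")
  for (nm in names(x$manifest$counts))
    cat(sprintf("  %s: %s\n", nm,
                paste(x$manifest$counts[[nm]], collapse = ", ")))
  invisible(x)
}

#' Render a consolidated run report
#'
#' Produces a plain-text report: provirus counts per subgroup, motif
#' and ORF tallies, an age grid in the "~ mean (+/- sd)" style, and LTR
#' clade counts.  Sections whose stage did not run are marked.
#'
#' @param run an `erv_run` from [run_pipeline].
#' @return character vector of report lines.
#' @export
render_report <- function(run) {
  lines <- c("ERV characterization report", "===========================")
  calls <- run$calls
  if (length(calls)) {
    sg <- vapply(calls, `[[`, character(1), "subgroup")
    tab <- table(sg)
    lines <- c(lines, "", "Provirus counts per subgroup:",
               sprintf("  %s: %d", names(tab), as.integer(tab)))
    mot <- t(vapply(calls, function(x)
      unlist(x$motifs), character(3)))
    lines <- c(lines, "", "Motif tallies:")
    for (j in colnames(mot)) {
      t2 <- table(mot[, j])
      lines <- c(lines, sprintf("  %s: %s", j,
                                paste(sprintf("%s=%d", names(t2),
                                              as.integer(t2)),
                                      collapse = ", ")))
    }
    orf <- unlist(lapply(calls, function(x)
      paste(x$orfs$gene, x$orfs$status, sep = "=")))
    t3 <- table(orf)
    lines <- c(lines, "", "ORF tallies:",
               sprintf("  %s: %d", names(t3), as.integer(t3)))
  } else {
    lines <- c(lines, "", "Annotation: not run")
  }
  if (!is.null(run$age_summary)) {
    lines <- c(lines, "", "Age estimates (Myr):")
    s <- run$age_summary
    for (i in seq_len(nrow(s)))
      lines <- c(lines, sprintf("  %-4s %-15s %-4s n=%-3d %s", s$subgroup[i],
                                s$method[i], s$gene[i], s$n[i], s$label[i]))
  } else {
    lines <- c(lines, "", "Dating: not run")
  }
  if (length(run$clades)) {
    lines <- c(lines, "", "LTR clades:")
    for (mg in names(run$clades))
      lines <- c(lines, sprintf("  group %s: %d clades over %d LTRs", mg,
                                length(unique(run$clades[[mg]])),
                                length(run$clades[[mg]])))
  } else {
    lines <- c(lines, "", "LTR clades: not run")
  }
  lines
}
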