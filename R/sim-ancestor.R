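## Ancestral provirus construction for the simulator.
##
## One backbone provirus (5'LTR - PBS - leader - gag - pro - pol - env -
## trailer - PPT - 3'LTR) is derived per configuration seed; subgroup
## ancestors diverge from it by synonymous codon replacement inside
## genes (keeping every ORF stop-free regardless of divergence depth)
## and free substitution in non-coding parts, then carry their
## subgroup's canonical late-domain and CETTG motif codons.

PBS_SEQ <- "TGGGGGCCCGAACAGGGA"
PPT_SEQ <- "AAGAAAGGGGGGA"
LEADER_LEN <- 150L
TRAILER_LEN <- 60L

## amino acid positions (1-based) of the planted motifs within their genes
MOTIF_AA_POS <- list(gag_ld1 = 110L, gag_ld2 = 130L, env_cettg = 350L)

MOTIF_BY_SUBGROUP <- list(
  A  = c(gag_ld1 = "PRPPIY", gag_ld2 = "PPPY", env_cettg = "CETTG"),
  B1 = c(gag_ld1 = "PQPPVL", gag_ld2 = "PPPY", env_cettg = "CETTG"),
  B2 = c(gag_ld1 = "PQPPVL", gag_ld2 = "PPPY", env_cettg = "CETTG"),
  C  = c(gag_ld1 = "PQPPVL", gag_ld2 = "TPPY", env_cettg = "CETTG"))

major_group <- function(subgroup) {
  c(A = "A", B1 = "B", B2 = "B", C = "C")[[subgroup]]
}

## random stop-free ORF of n_codons codons (ATG ... stop)
make_orf <- function(n_codons) {
  aas <- setdiff(names(AA_CODONS), c("*", "M"))
  aa <- c("M", sample(aas, n_codons - 2L, replace = TRUE), "*")
  codons <- vapply(aa, function(a) {
    cs <- AA_CODONS[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1), USE.NAMES = FALSE)
  paste(codons, collapse = "")
}

## replace a fraction of codons with synonymous alternatives
synonymize <- function(gene, fraction) {
  n <- nchar(gene) %/% 3L
  codons <- substring(gene, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  pick <- which(runif(n) < fraction)
  for (i in pick) {
    aa <- translate_dna(codons[i])
    alts <- setdiff(AA_CODONS[[aa]], codons[i])
    if (length(alts)) codons[i] <- alts[sample.int(length(alts), 1L)]
  }
  paste(codons, collapse = "")
}

## substitute bases independently at probability p (non-coding divergence)
substitute_bases <- function(x, p) {
  ch <- seq_chars(x)
  hit <- which(runif(length(ch)) < p)
  for (i in hit) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
  chars_seq(ch)
}

## overwrite the codons for amino acids `aa` starting at codon `pos`
write_motif <- function(gene, pos, aa) {
  res <- seq_chars(aa)
  codons <- vapply(res, function(a) AA_CODONS[[a]][1L], character(1))
  nt <- paste(codons, collapse = "")
  paste0(substr(gene, 1L, 3L * (pos - 1L)), nt,
         substr(gene, 3L * (pos - 1L) + nchar(nt) + 1L, nchar(gene)))
}

## deterministic backbone shared by all subgroups of one configuration
sim_backbone <- function(config) {
  with_seed(derive_seed(config$rng_seed, 1L), {
    ltr <- paste0("TG", random_dna(config$ltr_length - 4L), "CA")
    genes <- lapply(config$gene_lengths %/% 3L, make_orf)
    list(ltr = ltr, leader = random_dna(LEADER_LEN),
         trailer = random_dna(TRAILER_LEN), genes = genes)
  })
}

#' Build the ancestral provirus of a subgroup
#'
#' Returns the unaged provirus sequence a subgroup's founder virus
#' integrated with, plus a feature map (0-based half-open intervals in
#' provirus coordinates) covering both LTRs, PBS, leader, the four
#' genes, trailer, PPT and the planted motif positions.  The 5' and 3'
#' LTRs are identical, as they are at the moment of integration.
#'
#' @param config a [sim_config].
#' @param subgroup one of `"A"`, `"B1"`, `"B2"`, `"C"`.
#' @return list with `sequence`, `features` (data frame: feature,
#'   start, end), `ltr`, `genes_aa` (translations).
#' @export
build_ancestral_provirus <- function(config, subgroup) {
  if (!subgroup %in% c("A", "B1", "B2", "C"))
    stop("unknown subgroup label: ", subgroup)
  bb <- sim_backbone(config)
  grp <- major_group(subgroup)
  gidx <- match(grp, c("A", "B", "C"))
  div <- with_seed(derive_seed(config$rng_seed, 10L + gidx), {
    list(ltr = substitute_bases(bb$ltr, config$subgroup_divergence * 0.4),
         leader = substitute_bases(bb$leader, config$subgroup_divergence * 0.4),
         trailer = substitute_bases(bb$trailer, config$subgroup_divergence * 0.4),
         genes = lapply(bb$genes, synonymize,
                        fraction = config$subgroup_divergence))
  })
  ## keep canonical LTR ends
  div$ltr <- paste0("TG", substr(div$ltr, 3L, nchar(div$ltr) - 2L), "CA")
  motifs <- MOTIF_BY_SUBGROUP[[subgroup]]
  div$genes$gag <- write_motif(div$genes$gag, MOTIF_AA_POS$gag_ld1,
                               motifs[["gag_ld1"]])
  div$genes$gag <- write_motif(div$genes$gag, MOTIF_AA_POS$gag_ld2,
                               motifs[["gag_ld2"]])
  div$genes$env <- write_motif(div$genes$env, MOTIF_AA_POS$env_cettg,
                               motifs[["env_cettg"]])
  parts <- c(LTR5 = div$ltr, PBS = PBS_SEQ, leader = div$leader,
             gag = div$genes$gag, pro = div$genes$pro,
             pol = div$genes$pol, env = div$genes$env,
             trailer = div$trailer, PPT = PPT_SEQ, LTR3 = div$ltr)
  lens <- nchar(parts)
  ends <- cumsum(lens)
  starts <- ends - lens
  feats <- data.frame(feature = names(parts), start = unname(starts),
                      end = unname(ends))
  gene_start <- function(g) feats$start[feats$feature == g]
  mot <- data.frame(
    feature = c("motif_gag_ld1", "motif_gag_ld2", "motif_env_cettg"),
    start = c(gene_start("gag") + 3L * (MOTIF_AA_POS$gag_ld1 - 1L),
              gene_start("gag") + 3L * (MOTIF_AA_POS$gag_ld2 - 1L),
              gene_start("env") + 3L * (MOTIF_AA_POS$env_cettg - 1L)),
    end = NA_integer_)
  mot$end <- mot$start + 3L * nchar(c(motifs[["gag_ld1"]], motifs[["gag_ld2"]],
                                      motifs[["env_cettg"]]))
  list(sequence = paste(parts, collapse = ""),
       features = rbind(feats, mot),
       ltr = div$ltr,
       genes_aa = lapply(div$genes, translate_dna))
}
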