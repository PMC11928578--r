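---
title: "Dating endogenous retrovirus insertions from LTR and consensus divergence"
author: "ervkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating endogenous retrovirus insertions from LTR and consensus divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervkit)
```

## The problem

Gammaretroviruses such as the koala retrovirus (KoRV) and the gibbon ape
leukemia virus (GALV) occasionally colonize a host germline.  The
integrated copy — the provirus — is then inherited like any other locus,
and a genome assembly can carry tens to hundreds of such copies in
various states of decay.  Characterizing a family of recently
endogenized proviruses involves a chain of steps that `ervkit`
implements end to end:

1. **mine** a genome for loci similar to known retroviral seed
   sequences and extract them with generous flanks;
2. **annotate** each locus: find the paired long terminal repeats
   (LTRs) and the target-site duplication (TSD), map *gag*, *pro*,
   *pol* and *env* against an annotated reference, classify late-domain
   (PRPPIY/PQPPVL, PPPY/TPPY) and CETTG motif states, call premature
   stop codons, and detect the subgroup-diagnostic deletions of 133 nt
   (*pol*/RNaseH), 1487 nt (*env*) and 2216 nt (*pol*);
3. build per-subgroup **majority-rule consensuses** with outlier
   exclusion;
4. **date** every insertion from CpG-masked Kimura 2-parameter (K2P)
   divergence; and
5. fingerprint **LTR indel combinations** into clades.

Every stage is validated against a **germline-colonization simulator**
that plants proviruses of known age, subgroup and feature content into
a synthetic host genome, so recovery can be checked against truth
without any downloads.

## The dating model

At the moment of integration the 5' and 3' LTRs of a provirus are
identical, because both are copied from the same template during
reverse transcription.  Afterwards each LTR accumulates substitutions
independently at the neutral rate $M$ (substitutions/nt/Myr), so the
expected divergence between the pair after $T$ million years is $2MT$
and

$$T = \frac{D}{2M},$$

where $D$ is the K2P-corrected distance between the two LTRs,

$$D = -\tfrac12\ln(1 - 2P - Q) - \tfrac14\ln(1 - 2Q),$$

with $P$ and $Q$ the transition and transversion proportions over
compared sites.  The default rate is the mammalian
$M = 0.0022$ substitutions/nt/Myr (`DEFAULT_RATE_M`).  Saturation
(either logarithm argument non-positive) is reported as an explicit
outcome, never as a silent `Inf`, so summaries can count exclusions.

The second estimator dates each proviral gene against its subgroup
majority consensus.  For a recently expanded family the consensus
approximates the ancestral sequence, so divergence accrues along **one**
lineage and the default divisor is $c = 1$ ($T = D/M$); the two-lineage
divisor $c = 2$ is selectable (`divisor = 2`) and every output row
records which was used.  This choice matters by an exact factor of two,
is not derivable from first principles for a consensus of finite depth,
and is therefore stamped into the output rather than hidden.

### CpG masking and the mask-substitution coupling

Methylated CpG dinucleotides deaminate spontaneously, mutating an order
of magnitude faster than other sites, which would inflate divergence
ages.  `mask_cpg()` therefore excludes from the comparison every column
that is part of a CpG in **any** row (both members of the dinucleotide,
with adjacency evaluated on each row's degapped sequence), and columns
containing gaps or ambiguity codes are excluded separately.

Masking on the *present-day* pair has a subtle side effect: an ordinary
substitution that happens to create a CpG with its neighbour (for
example T→C in front of a G) is masked along with the genuinely
hypermutable sites, and such self-masking removes observed
substitutions preferentially, deflating $D$.  The probability that a
random substitution self-masks is computable exactly from the base
context of the retained columns — separately for transitions (the
single K2P transition target either completes a CpG or it does not) and
transversions (each of the two targets drawn with equal probability).
The age estimators therefore rescale the observed $P$ and $Q$ by these
factors before applying the K2P correction (`mask_correction = TRUE`,
the default).  The correction is what makes the estimator recover the
simulation's configured rate when CpG sites are *not* hypermutable, and
keeps it nearly unbiased when they are; the uncorrected masked distance
is retained in every result (`D_uncorrected`).  `k2p_distance()` itself
is the plain textbook statistic, so it can be cross-checked against
independent implementations.

## The simulator and what it does (not) emulate

`sim_config()` fixes the study conditions:

| parameter | default | meaning |
|---|---|---|
| `rate_M` | 0.0022 | substitutions/nt/Myr, the mammalian neutral rate |
| `cpg_multiplier` | 10 | fold rate increase while a site is in a CpG |
| `kappa` | 2 | transition:transversion rate ratio |
| `age_distribution` | uniform 0–7 Myr | insertion ages |
| `ltr_length` | 500 bp | LTR length |
| `tsd_length_range` | 4–6 bp | target-site duplication (gammaretroviral convention) |
| `deletion_specs` | 133/1487/2216 nt | subgroup-diagnostic deletions with per-subgroup probabilities |
| `stop_codon_probability` | 0.02–0.05 per gene | planted premature stops |

Sequence evolution is a per-site Markov jump process with the
two-parameter (kappa) substitution structure — matching the K2P
distance used downstream, so parameter recovery is internally
consistent — and the CpG multiplier re-evaluates the dinucleotide
context after every substitution, creating exactly the artifact that
masking is meant to remove.  The two LTRs evolve independently for the
drawn age; the internal region evolves once.  Deletions, LTR indel
combinations, motif-variant swaps and stop codons are planted *after*
evolution so that recovery tests are exact; truth motif states and stop
lists describe the **emitted** genome.  LTR indels are applied to the
ancestral LTR before duplication, as they would be present in the
integrating virus.

Subgroup ancestors (A, B, C share gene coordinates; B1/B2 differ only
by planted deletions) diverge from one backbone by synonymous codon
replacement inside genes — keeping ORFs stop-free at any backbone
separation — plus free substitution in non-coding parts, and then carry
their subgroup's canonical motif codons.  LTRs begin `TG` and end `CA`,
the conserved retroviral terminal inverted repeat.

The simulator does **not** model recombination, gene conversion between
LTRs, solo-LTR formation, segregating insertions, indel mutation inside
genes, or host base composition structure.  Consequently, passing
recovery tests shows the pipeline is correct *under neutral
substitution with planted structural features*; on real data,
LTR–LTR gene conversion is expected to bias LTR-pair ages downward
(a documented limitation of the method, not corrected here), and
alignment of genuinely indel-rich families will be harder than the
simulator makes it.

## Numerical and algorithmic choices

* **Pairwise alignment**: Needleman–Wunsch with affine gaps
  (match 2, mismatch −3, open 5, extend 2) through Biostrings; for
  sequences over 2 kb an anchored variant chains unique exact 16-mers
  (longest increasing subsequence) and runs the DP only between
  anchors, which places the large diagnostic deletions exactly and
  keeps provirus-scale alignments fast.
* **Mining identity** is gap-compressed: indel runs longer than 30 nt
  act as alignment breaks and do not dilute identity, mirroring how a
  gapped local search reports separate high-identity segments around a
  long deletion; the 85% screen therefore retains deletion-bearing
  proviruses while still rejecting 20%-mutated copies.
* **LTR pair detection** votes for the repeat offset with shared
  k-mers, takes the maximal scoring matched segment along that offset
  (+1/−2), and polishes boundaries within ±6 bp by preferring an exact
  4–10 bp flanking TSD and `TG…CA` termini over raw score; failure to
  find a TSD never rejects the provirus (old insertions lose their
  TSDs).
* **Majority consensus**: the gap counts as a symbol; gap-won columns
  are omitted from the consensus but kept in the column map; ties break
  by the fixed order A < C < G < T with any base beating the gap, and
  tied columns are reported.
* **Outlier exclusion** removes the member with the lowest identity to
  the current consensus (recomputing after each removal) while below
  60% — a deterministic surrogate for manual curation of sequences that
  "do not align properly"; the threshold is a package choice, not an
  empirical constant.
* **Deletion signatures** match reference-relative gap runs against the
  expected lengths within ±10 nt; unmatched gaps ≥ 50 nt are reported
  as `other`.  The tolerance keeps the 133/1487/2216 classes distinct
  while absorbing ragged alignment edges.
* **Full-length ORFs** require zero internal stops and ≥ 90% of the
  reference gene length — no standard numeric threshold exists, so the
  fraction is configurable.
* **Dating subgroups** (`split_dating_subgroups`) cut an average-linkage
  dendrogram of pairwise K2P distances at a configurable height
  (0.04 by default); singleton clusters are skipped because a
  consensus of one sequence dates nothing.
* **LTR clades** are fingerprint-based (presence/absence over gap
  blocks ≥ 3 nt in the master LTR alignment), not tree-based; the
  neighbor-joining tree (negative branches clamped, midpoint-rooted)
  is diagnostic output only.  A Jaccard threshold (default 0, i.e.
  clades are exactly the distinct indel vectors) governs clade merging.
  Two robustness rules keep fingerprints stable under alignment
  jitter: gap runs separated by fewer than `min_indel_length` non-gap
  columns are merged into one block, and a row carries a block when it
  has at least `min_indel_length` gapped columns there.  The master
  LTR alignment is built with the **longest** member as the
  center-star center: a deletion-carrying center would force
  deletion-free members to insert columns at member-specific positions,
  gapping unrelated rows and conflating distinct indel combinations.

## Validation scale

The test suite validates the simulator and pipeline at desk scale:
recovery of all planted features (subgroup, deletion lengths, motif
states, stop codons, LTR boundaries within ±5 bp at ages ≤ 2 Myr) on a
fixed-seed 50-provirus genome of ~1.4 Mb; rate recovery from 1,000
simulated LTR pairs at 2 Myr; age-vs-truth regression at ages 0.5–5 Myr
with 200 pairs per age; and clade recovery from a 58-provirus run
planting two A-type and five B-type LTR indel combinations.  These
sizes were chosen so the whole suite runs in minutes while leaving the
Monte-Carlo checks enough replicates to be sharp.

## Known limitations

* LTR pair detection assumes substitution-dominated divergence between
  the two copies of one provirus (a single repeat offset); proviruses
  whose LTR pair differs by internal indels will get approximate
  boundaries.
* The center-star MSA is deterministic and adequate for young,
  high-identity families; deeply diverged families should be aligned
  with an external aligner via the `aligner_cmd` template.
* The gene-consensus clock inherits all caveats of treating a majority
  consensus as an ancestor: shared derived states among members pull
  the consensus toward the majority lineage and compress its ages.
* No statistical uncertainty is attached to individual ages; per-site
  stochasticity at 500 bp LTRs makes single-provirus ages coarse
  (one substitution ≈ 0.45 Myr at the default rate), which is why
  subgroup summaries report mean ± SD.
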