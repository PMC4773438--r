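---
title: "Models and methods behind ampliclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ampliclone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliclone)
```

ampliclone analyses deep paired-end amplicon sequencing of multiplexed
CRISPR/Cas9 editing experiments: indel detection tolerant of very large
deletions, mutant-read-frequency (MRF) quantification, ploidy-aware
zygosity interpretation, indel-signature lineage tracking, off-target
screening and rearrangement-junction detection. This vignette documents the
models, the tunable parameters, and the design decisions taken where the
design was genuinely open.

## Coordinates and the cut-site convention

All coordinates are 0-based and half-open. A target site stores the 20-nt
protospacer, its NGG PAM and a `cut_pos`: the blunt Cas9 double-strand
break falls between `cut_pos - 1` and `cut_pos`, three nucleotides 5' of
the PAM-proximal protospacer end. Guides on the minus strand are handled by
embedding (and validating against) the reverse complement of
protospacer + PAM; `validate_panel()` enforces the convention.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the statistical
conditions under which the analysis side is validated, and it emits full
ground truth (clone allele maps, per-sample expected allele frequencies)
alongside the reads.

**What it emulates.**

* A 15-site panel across mouse chromosomes in which four chromosomes carry
  more than one target site (chr4 × 4, chr6 × 2, chr11 × 2, chr18 × 2),
  yielding nine possible intra-chromosomal fusions. Amplicons are 400 nt by
  default with the cut inside the central 50%, so 300-nt mates always span
  the cut; this mirrors amplifying a few hundred base pairs around each
  target site.
* An NHEJ repair-outcome model: deletions with probability 0.9 versus
  insertions 0.1; deletion lengths 1–363 bp and insertion lengths 1–32 bp;
  the indel anchor jittered within ±2 bp of the cut (1–5 bp upstream of
  the PAM). The study-scale ranges fix only the extrema and the
  deletion:insertion ratio; the length *law* is open, and we chose
  truncated geometric distributions (means 6 bp and 2 bp) once, because a
  monotonically decreasing law reproduces the observed inverse
  size–frequency relationship. Point-mass or custom laws can be supplied
  (`del_len_probs` / `ins_len_probs`).
* Clonal tumours: per site, the sgRNA is delivered and active in the
  founding cell with probability `edit_prob = 0.8` (chosen once so that
  roughly 7–14 of the 15 sites are mutated per tumour, matching the
  observed multiplexing efficiency); at an active site each chromosome
  copy is edited independently with `copy_edit_prob = 0.9`. Identical
  outcomes on different copies collapse to one allele, as in real data.
* Karyotype: `default_clones()` builds five diploid clones and one
  poly-/aneuploid clone (per-chromosome copy numbers 3–7, with the
  two-site chromosome 6 fixed at 7 copies), so sites with up to seven
  distinct alleles occur. With this mix the cohort's expected
  complete-inactivation fraction lands near three quarters as an emergent
  property of `copy_edit_prob`, not as a hard-coded number.
* Samples: mixtures of clones plus a stromal wild-type fraction (tissue),
  pure cell lines and single-cell clones, and metastases that inherit
  their founding clone's signature unchanged — CRISPR exposure was
  transient, so no private target-site indels arise (a drift flag is
  deliberately absent; drift can be emulated by deriving a modified
  clone).
* Sequencing: MiSeq-like 2 × 300 bp pairs, uniform per-base substitution
  errors (default 0.1%, an error floor comparable to deep amplicon runs),
  and a configurable fraction of discordant mates (default 3%) emulating
  unpaired reads.

**What it does not emulate** (and what passing tests therefore do not
show about real data): PCR amplification bias and chimeras, quality-score
profiles and indel sequencing errors, microhomology-driven outcome
preferences, contamination between samples, and subclonal evolution after
editing. In particular, because the error model is substitution-only,
sequencing errors never create spurious indel observations; the
read-support filter is therefore exercised by design (thresholds,
bookkeeping, monotonicity) rather than by realistic indel noise.

**Fast path.** `simulate_site_tables()` draws per-site allele counts
multinomially from the expected frequencies, skipping read synthesis and
alignment. Under the substitution-only error model this is statistically
equivalent at the allele-table level and is used for cohort-scale
experiments (lineage replicates, copy-number recovery); read-level
simulation exercises the full path at smaller scale.

## Alignment with a long-deletion state

Reads are assigned to amplicons by k-mer voting on both strands (12-mers,
every 13th position, at least two votes); a pair is kept only when both
mates vote for the same amplicon in opposite orientations. Discordant or
unassigned pairs are excluded from every downstream count.

`align_read()` is a semi-global Gotoh dynamic program: the read is
consumed end to end, reference overhangs are free, gaps are affine
(open 6, extend 1, match +2, mismatch −4). A fourth transition deletes any
stretch of ≥ 30 reference bases for a single flat cost of 24, implemented
with a per-row prefix maximum so the DP stays O(nm). Consequences:

* a deletion of length L costs min(6 + L, 24 for L ≥ 30), so one long
  deletion always beats fragmented representations — the property that
  standard mappers lack for 100+ bp deletions;
* at L = 18 the affine and flat costs tie; between 18 and 30 the affine
  branch is used. The crossover constants were fixed once; the contract
  ("a single deletion representation wins, and scores equal an exhaustive
  DP oracle") is what the tests pin down, not the constants.

Ties in the traceback prefer diagonal over deletion over insertion over
jump, which pushes indels leftward; `extract_indels()` additionally
left-normalizes every observation (VCF-style shuffling), making allele
identity representation-invariant and idempotent.

**Counting window.** Only alignments spanning `cut_pos ± 20` bp enter a
site's denominator, and only indel operations overlapping that window are
counted. The window bounds what "an indel at the target site" means; 20 bp
is wide enough for jittered anchors and resected junctions and narrow
enough to exclude unrelated polymorphisms. Each *pair* contributes once:
mate observations are deduplicated, and if mates disagree the observation
closest to the cut (then leftmost) is kept.

## MRF bookkeeping and the support filter

`pileup_site()` merges identical normalized indels into alleles;
MRF_i = support_i / total spanning pairs. Count conservation
(wild type + Σ support + unassigned = total) is enforced at every stage:
support removed by `filter_indels()` moves to an *unassigned* tally, never
to wild type, so filtering can never manufacture wild-type evidence and MRF
denominators never change.

The documented filter is strict-greater: an allele is true only when
supported by *more than* 100 mutant reads — appropriate at real MiSeq
depth. Because validation cohorts run at hundreds, not tens of thousands,
of pairs per site, `scaled_filter_params()` scales the threshold as
max(10, 1% of coverage); the 100-read value remains the default of
`filter_params()`. The error floor (default MRF 0.005) operationalizes
"above sequencing error rates", which is otherwise unquantified.

## Zygosity and allele-copy assignment

In cell lines and single-cell clones, a mutated site with wild-type
fraction ≤ `wt_epsilon` is *complete* inactivation; above it, *partial*.
`wt_epsilon` defaults to 0.01 because a literal absence of wild-type reads
is unattainable at a 0.1% sequencing error rate. Tissue samples never
receive zygosity calls — stromal admixture makes wild-type reads
uninterpretable — and report `mutated_zygosity_indeterminate` instead.

`assign_allele_copies()` enumerates all compositions of the copy number
k (1–12, from a karyotype table) over the observed alleles including wild
type, minimizing Σ(freq_i − c_i/k)². Exhaustive enumeration is exact and
cheap (C(k+m−1, m−1) compositions; 1,820 at k = 12, m = 6). Ties at the
minimal residual are flagged ambiguous and broken toward more wild-type
copies — conservative about claiming loss. More alleles than copies, all
above a noise floor, is flagged infeasible (subclonality or a wrong
karyotype) while still returning the best assignment.
`min_copies_at_editing()` gives the complementary lower bound: distinct
alleles + retained wild type ≥ copies present when Cas9 was active.

## Lineage tracking

A clone signature is the set of exact (site, position, type, length,
sequence) identities of surviving alleles. Marker identity is exact by
default; a relaxed mode (position + type + length) exists for noisy
callers. Distance between signatures is Jaccard distance on marker sets;
two empty signatures return 1 with a warning (no evidence of relatedness).

`deconvolve_primaries()` clusters signatures by single linkage and cuts at
`max_intra_distance = 0.3` — samples of the same clone at adequate coverage
have distance near 0, independent clones near 1, so the cut is
uncritical inside a wide band. A sample is *mixed* when, after attributing
it to the cluster sharing most markers, its residual markers still link
(≥ `min_shared = 2`) to another cluster; its singleton cluster is dropped
when other clusters explain ≥ 95% of its markers. Single-cell-clone
signatures, when included, simply form their own cluster and thereby
partition the mixed sample's markers. Metastasis assignment requires
`min_shared = 2` shared markers and a margin of `min_margin = 1` over the
runner-up; these defaults formalize comparisons that were done manually in
study settings and are deliberately exposed.

## Rearrangement screening

Candidates are enumerated combinatorially: all same-chromosome pairs as
head-to-tail deletion joins (inversion-type joins are excluded — unordered
pair counting is what makes a 15-site panel yield exactly nine intra-
chromosomal candidates), and all cross-chromosome pairs in both derivative
orientations. The predicted junction is prefix(A, up to cut) +
suffix(B, from cut).

`detect_junction()` screens sequences with a k-mer prefilter (a supporting
read must share k-mers with *both* seam flanks; wild-type reads carry only
one side), then aligns survivors to the predicted junction with the same
long-deletion-aware DP. A read supports the junction when each side of the
seam has ≥ 25 matched bases at ≥ 90% window identity, where insertions
outside the seam count against identity — this defeats degenerate
alignments that hide non-matching read content in gap operations.
Breakpoint offsets are read off the seam-overlapping deletion (A-side
resection negative, B-side positive); small seam indels are reported as
`junction_indel`. A call is confirmed when both offsets are within
`tol = 10` bp — "breakpoints at the cut sites" up to NHEJ resection.
Reciprocal translocations are recognized by detecting both derivative
junctions; one derivative is non-reciprocal.

## Surveyor estimator

From gel band intensities, f_cleaved = Σcut/(uncut + Σcut) and the indel
fraction is 1 − √(1 − f_cleaved) — the standard duplex-reformation
correction (an external formula, adopted as-is). The estimator is monotone
with fixed points 0 and 1; a saturated assay returns 1 with a warning.

## Numerical and degenerate-input choices

* Alignment scores are integers; the flat jump cost never interacts with
  overflow (scores bounded by ±2 × read length × max |score|).
* `pileup_site()` rejects observation sets exceeding the spanning-read
  count (bookkeeping violation) and demands one observation per pair.
* Zero-coverage sites are `no_data` everywhere — never wild-type-only in
  the off-target screen, never classified for zygosity.
* Degenerate fusion candidates (identical genomic cut coordinates) warn;
  `predicted_deletion_size()` refuses cross-chromosome pairs.
* All generator randomness flows through R's RNG; a fixed
  `sim_config(seed=)` makes cohort output byte-identical.

## Validation scale

The test-suite and `scripts/acceptance.R` run at sizes chosen to exercise
the statistics without waste: read-level cohorts at 250 pairs/site
(six cell lines + one normal, ~26k pairs), allele-copy recovery at 5,000×
multinomial draws for k = 2..7, lineage tracking over 50 seeded cohorts at
1,000×, junction round-trips at tens of pairs per derivative plus 50
junction-free cohorts, and a 200-instance alignment-oracle comparison at
≤ 60 nt. The oracle is an independent full-matrix R implementation with a
naive jump scan, kept deliberately separate from the Rcpp prefix-maximum
implementation it checks.

## Known limitations

* No indel-type sequencing errors are modelled, so the false-positive side
  of the support filter is untested against realistic noise.
* Inversion-type intra-chromosomal joins and junctions whose resection
  exceeds the breakpoint tolerance are not detected.
* Copy assignment assumes a clonal population at the stated karyotype;
  subclonality is only flagged (infeasible), not deconvolved.
* Read pairs are aligned per mate (no overlap-merging consensus), so a
  mate disagreement resolves heuristically toward the cut-proximal
  observation.
* The aligner is amplicon-scale by design: O(read × amplicon) per pair,
  not a genome-scale mapper.
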