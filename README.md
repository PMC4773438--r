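# ampliclone

Analysis of deep paired-end amplicon sequencing from **multiplexed
CRISPR/Cas9 editing experiments in tumours**, together with a fully
ground-truthed synthetic cohort generator for validating every stage.

When many sgRNAs are co-delivered to somatic cells, the resulting tumours
carry a combinatorial pattern of indels at the target sites. Quantifying
those indels from amplicon sequencing raises several linked problems that
this package addresses end to end:

* **Large deletions.** NHEJ deletions at a Cas9 cut can reach hundreds of
  bp; standard short-read mappers fragment or soft-clip such reads, so the
  events are lost. `align_read()` implements a semi-global affine-gap
  aligner (match +2, mismatch −4, gap open −6, gap extend −1) with an extra
  flat-cost long-deletion transition (−24 for deletions ≥ 30 bp), so a
  single 363-bp deletion stays a single alignment operation.
* **Allele quantification.** Indels are left-normalized against the
  amplicon and aggregated per site into allele tables. The mutant read
  frequency of allele *i* is MRF_i = support_i / (reads spanning the cut ±
  20 bp window); alleles are retained only when supported by *more than*
  `min_mutant_reads` reads (default 100; `scaled_filter_params()` scales
  this for desk-scale simulations) and above an MRF error floor.
* **Zygosity and ploidy.** In pure cell populations, a mutated site with no
  wild-type reads (≤ ε) is completely inactivated; retained wild-type reads
  mean at least one intact chromosome. `assign_allele_copies()` searches all
  compositions of the karyotype copy number *k* over the observed alleles,
  minimizing Σ(freq_i − c_i/k)², so e.g. four allele frequencies can be
  placed on seven chromosome copies.
* **Lineage tracking.** The exact indel identities act as clonal barcodes:
  `deconvolve_primaries()` clusters samples by Jaccard distance between
  signatures (single linkage) and flags mixed biopsies;
  `assign_metastases()` assigns nodules to their tumour of origin by shared
  markers.
* **Structural variants.** All same-chromosome target pairs are candidate
  deletions and all cross-chromosome pairs candidate translocations (both
  derivatives); `detect_junction()` verifies that read-supported junction
  breakpoints lie at the predicted cut sites.
* **Surveyor assay.** `surveyor_indel_fraction()` converts gel band
  intensities to an edited fraction via the duplex-reformation correction
  1 − √(1 − f_cleaved).

## Worked example

Simulate a small two-clone experiment, sequence one heterozygous cell line,
and call its alleles:

```r
library(ampliclone)
set.seed(42)

panel  <- simulate_panel(seed = 42)              # 15-site default panel
clones <- list(Tu1 = simulate_clone(panel, clone_id = "Tu1"))
sample <- sample_truth("Tu1_cl", "cell_line", c(Tu1 = 1))

cfg <- sim_config(coverage_per_site = 200, unpaired_fraction = 0.03)
rd  <- simulate_sample_reads(sample, clones, panel, cfg)

res <- call_sample(rd$r1, rd$r2, panel, filter = scaled_filter_params(200))
round(res$unpaired_fraction, 3)
#> [1] 0.03
res$tables[["Trp53"]]
#> site_allele_table: Trp53 - 195 spanning reads, 2 allele(s), cumulative MRF 1.0000
#>   pos type length      seq support       mrf
#> 1 202  del      8 AAAACGCA     105 0.5384615
#> 2 201  del      6   GAAAAC      90 0.4615385
classify_site(res$tables[["Trp53"]], "cell_line")
#> [1] "complete"
```

Both Trp53 copies carry (different) deletions, no wild-type reads remain,
so the gene is completely inactivated; the two MRFs near 0.5 are the two
chromosome copies of a diploid clone. Copy assignment makes that explicit:

```r
assign_allele_copies(site_allele_freqs(res$tables[["Trp53"]]), k = 2)
#> allele_copy_assignment over 2 copies: WT=0, del8@202=1, del6@201=1 (residual 0.002959)
```

## Package layout

| file | contents |
|---|---|
| `R/panel.R` | target-site panels, validation, TSV/FASTA IO |
| `R/indel_model.R` | NHEJ outcome model, left-alignment, indel application |
| `R/simulate.R`, `R/cohort.R` | clones, samples, reads, junctions, truth tables |
| `R/align.R`, `src/align.cpp` | pairing/assignment and the long-deletion-aware DP |
| `R/pileup.R` | allele tables, MRF, support filter, summaries, Surveyor |
| `R/allelic.R` | zygosity calls, ploidy-constrained copy assignment |
| `R/lineage.R` | signatures, Jaccard clustering, metastasis assignment |
| `R/rearrange.R` | fusion candidates, junction detection, classification |

The methods vignette (`vignettes/ampliclone-methods.Rmd`) documents the
model assumptions, parameter defaults and the design decisions behind them.
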