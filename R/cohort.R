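# Default study-scale cohort: six tumour cell lines (one polyploid), one
# electroporated-normal control, metastases for lineage experiments.

#' Default study-like clone set
#'
#' Six clonal tumours on the default 15-site panel: five with stable diploid
#' karyotypes and one poly-/aneuploid clone whose per-chromosome copy
#' numbers range up to 7 (its multi-site chromosome 6 carries 7 copies), so
#' sites on it can carry more than two distinct indel alleles.
#'
#' @param panel a `target_panel`.
#' @param model an [indel_model()].
#' @param edit_prob per-site delivery/activity probability.
#' @param copy_edit_prob per-copy editing probability at active sites.
#' @return Named list of six `clone_truth` objects (`Tu1` .. `Tu6`; `Tu2` is
#'   the polyploid clone).
#' @export
default_clones <- function(panel, model = indel_model(), edit_prob = 0.8,
                           copy_edit_prob = 0.9) {
  chroms <- unique(panel$chrom)
  clones <- list()
  for (i in 1:6) {
    id <- paste0("Tu", i)
    ploidy <- if (i == 2) {
      pl <- setNames(sample(3:7, length(chroms), replace = TRUE), chroms)
      pl["chr6"] <- 7L
      pl
    } else 2L
    clones[[id]] <- simulate_clone(panel, model, ploidy = ploidy,
                                   edit_prob = edit_prob,
                                   copy_edit_prob = copy_edit_prob,
                                   clone_id = id)
  }
  clones
}

#' Default study-like sample set
#'
#' One cell-line sample per clone plus one electroporated-normal tissue
#' control (pure stromal wild type); cell lines carry no stromal admixture.
#'
#' @param clones named list of `clone_truth` (e.g. [default_clones()]).
#' @return List of `sample_truth` objects.
#' @export
default_samples <- function(clones) {
  samples <- lapply(names(clones), function(id) {
    sample_truth(paste0(id, "_cl"), "cell_line", setNames(1, id))
  })
  c(samples, list(sample_truth("PancTi", "normal", stromal_wt_fraction = 1)))
}
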