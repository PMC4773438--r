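# Zygosity classification and ploidy-constrained allele-copy assignment.
#
# Complete inactivation means no wild-type reads remain (up to a small
# epsilon absorbing sequencing error); partial means at least one chromosome
# retained the wild-type sequence. Zygosity is only interpretable in pure
# cancer cell populations (cell lines, single-cell clones) - tissue carries
# stromal wild-type reads, so no call is made there.

#' Classify target-gene inactivation at one site
#'
#' For cell lines and single-cell clones: `complete` when the wild-type read
#' fraction is at most `wt_epsilon` and at least one allele survives;
#' `partial` when alleles coexist with wild-type reads above `wt_epsilon`;
#' `unmutated` with no surviving alleles. Tissue samples get
#' `mutated_zygosity_indeterminate` or `unmutated` (zygosity cannot be
#' deduced under stromal admixture). Zero spanning reads give `no_data`.
#'
#' @param table a filtered `site_allele_table`.
#' @param sample_kind one of `tumour_tissue`, `cell_line`,
#'   `single_cell_clone`, `metastasis`, `normal`.
#' @param wt_epsilon maximum wild-type read fraction still compatible with
#'   complete inactivation (default 0.01; a literal zero is unattainable at
#'   typical sequencing error rates).
#' @return One of `"complete"`, `"partial"`, `"unmutated"`,
#'   `"mutated_zygosity_indeterminate"`, `"no_data"`.
#' @export
classify_site <- function(table, sample_kind, wt_epsilon = 0.01) {
  stopifnot(inherits(table, "site_allele_table"))
  sample_kind <- match.arg(sample_kind,
                           c("tumour_tissue", "cell_line",
                             "single_cell_clone", "metastasis", "normal"))
  if (table$total_spanning_reads == 0) return("no_data")
  n_alleles <- nrow(table$alleles)
  wt_frac <- table$wt_reads / table$total_spanning_reads
  if (sample_kind %in% c("cell_line", "single_cell_clone")) {
    if (n_alleles == 0) return("unmutated")
    if (wt_frac <= wt_epsilon) return("complete")
    return("partial")
  }
  if (n_alleles >= 1) return("mutated_zygosity_indeterminate")
  "unmutated"
}

#' Classify all sites of a sample
#'
#' @param tables named list of filtered `site_allele_table`.
#' @param sample_kind as in [classify_site()].
#' @param wt_epsilon as in [classify_site()].
#' @return data.frame with `site_id`, `status`, `cumulative_mrf`.
#' @export
classify_sample_sites <- function(tables, sample_kind, wt_epsilon = 0.01) {
  data.frame(
    site_id = vapply(tables, `[[`, "", "site_id"),
    status = vapply(tables, classify_site, "", sample_kind = sample_kind,
                    wt_epsilon = wt_epsilon),
    cumulative_mrf = vapply(tables, `[[`, 0, "cumulative_mrf"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Cohort fractions of complete versus partial inactivation
#'
#' Over all mutated sites in cell-line / single-cell-clone samples, the
#' fraction with complete inactivation and the fraction retaining at least
#' one wild-type allele. The two fractions sum to 1.
#'
#' @param statuses character vector of site statuses (or a data.frame with a
#'   `status` column).
#' @return Named numeric vector `c(complete =, partial =)`.
#' @export
cohort_zygosity_fractions <- function(statuses) {
  if (is.data.frame(statuses)) statuses <- statuses$status
  n_complete <- sum(statuses == "complete")
  n_partial <- sum(statuses == "partial")
  if (n_complete + n_partial == 0) {
    stop("no mutated sites with zygosity calls")
  }
  c(complete = n_complete / (n_complete + n_partial),
    partial = n_partial / (n_complete + n_partial))
}

# all compositions of k into m nonnegative parts (rows)
compositions_of <- function(k, m) {
  if (m == 1) return(matrix(k, ncol = 1))
  out <- vector("list", k + 1)
  for (c1 in 0:k) {
    sub <- compositions_of(k - c1, m - 1)
    out[[c1 + 1]] <- cbind(c1, sub, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' Assign allele frequencies to integer chromosome copies
#'
#' Exhaustive search over all compositions of the karyotype copy number `k`
#' into one count per allele (wild type included), minimizing the sum of
#' squared deviations between observed frequencies and `copies / k`. Ties at
#' the minimal residual are broken toward assignments with more wild-type
#' copies (conservative about loss) and flagged ambiguous. When there are
#' more alleles than copies and every frequency is above `noise_floor`, the
#' site is flagged infeasible (subclonality or a wrong karyotype).
#'
#' @param freqs named numeric vector of allele frequencies including the
#'   wild type; must sum to 1 within `tol`.
#' @param k chromosome copy number (1-12).
#' @param wt_name name of the wild-type entry in `freqs`.
#' @param noise_floor frequencies at or below this may be explained by noise.
#' @param tol allowed deviation of `sum(freqs)` from 1.
#' @return An `allele_copy_assignment`: list with `copies` (named integer,
#'   summing to `k`), `residual`, `ambiguous`, `infeasible`.
#' @examples
#' assign_allele_copies(c(WT = 0.42, A = 0.29, B = 0.15, C = 0.14), k = 7)
#' @export
assign_allele_copies <- function(freqs, k, wt_name = "WT",
                                 noise_floor = 0.02, tol = 0.05) {
  stopifnot(is.numeric(freqs), !is.null(names(freqs)), all(freqs >= 0),
            k >= 1, k <= 12)
  if (abs(sum(freqs) - 1) > tol) {
    stop("allele frequencies must sum to 1 (got ", round(sum(freqs), 4), ")")
  }
  m <- length(freqs)
  infeasible <- m > k && all(freqs > noise_floor)

  comps <- compositions_of(as.integer(k), m)
  resid <- colSums((t(comps) / k - freqs)^2)
  best <- min(resid)
  ties <- which(resid <= best + 1e-9)
  ambiguous <- length(ties) > 1
  if (ambiguous && wt_name %in% names(freqs)) {
    wt_col <- match(wt_name, names(freqs))
    ties <- ties[order(-comps[ties, wt_col])]
  }
  pick <- ties[1]
  structure(list(copies = setNames(as.integer(comps[pick, ]), names(freqs)),
                 k = as.integer(k),
                 residual = resid[pick],
                 ambiguous = ambiguous,
                 infeasible = infeasible),
            class = "allele_copy_assignment")
}

#' @export
print.allele_copy_assignment <- function(x, ...) {
  cat("allele_copy_assignment over", x$k, "copies:",
      paste(names(x$copies), x$copies, sep = "=", collapse = ", "),
      sprintf("(residual %.4g%s%s)\n", x$residual,
              if (x$ambiguous) ", ambiguous" else "",
              if (x$infeasible) ", INFEASIBLE" else ""))
  invisible(x)
}

#' Allele frequencies of a site table, wild type included
#'
#' Convenience accessor feeding [assign_allele_copies()]: named frequencies
#' of every surviving allele plus the wild-type fraction.
#'
#' @param table a filtered `site_allele_table`.
#' @return Named numeric vector (`WT` first).
#' @export
site_allele_freqs <- function(table) {
  stopifnot(inherits(table, "site_allele_table"))
  total <- table$total_spanning_reads
  if (total == 0) stop("no spanning reads at ", table$site_id)
  al <- table$alleles
  nm <- if (nrow(al)) paste0(al$type, al$length, "@", al$pos) else character()
  setNames(c(table$wt_reads / total, al$support / total), c("WT", nm))
}

#' Lower bound on chromosome copies at editing time
#'
#' The number of distinct surviving indel alleles, plus one if wild-type
#' reads remain above `wt_epsilon`: every distinct allele (and a retained
#' wild type) marks at least one chromosome copy present when Cas9 was
#' active.
#'
#' @param table a filtered `site_allele_table`.
#' @param wt_epsilon wild-type fraction above which a wild-type copy is
#'   counted.
#' @return Integer lower bound (at least 1).
#' @export
min_copies_at_editing <- function(table, wt_epsilon = 0.01) {
  stopifnot(inherits(table, "site_allele_table"))
  wt_frac <- if (table$total_spanning_reads > 0)
    table$wt_reads / table$total_spanning_reads else 0
  max(1L, nrow(table$alleles) + as.integer(wt_frac > wt_epsilon))
}
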