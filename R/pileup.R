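# Per-site allele tables, mutant-read-frequency (MRF) bookkeeping, the
# read-support filter, cohort spectrum summaries, off-target verdicts and
# the Surveyor gel-band estimator.

#' Construct a site allele table
#'
#' The container for per-site calling results. MRF of an allele is its
#' supporting read (pair) count divided by all spanning reads at the site;
#' the cumulative MRF sums over all mutant alleles. Count conservation
#' (`wt_reads + sum(support) + unassigned_reads == total_spanning_reads`)
#' is enforced.
#'
#' @param site_id site label.
#' @param alleles data.frame with `pos`, `type`, `length`, `seq`, `support`.
#' @param wt_reads spanning reads carrying no windowed indel.
#' @param unassigned_reads support removed by filtering (never reassigned to
#'   wild type).
#' @return A `site_allele_table`.
#' @export
new_site_allele_table <- function(site_id, alleles, wt_reads,
                                  unassigned_reads = 0L) {
  stopifnot(wt_reads >= 0, unassigned_reads >= 0)
  if (nrow(alleles)) {
    alleles <- alleles[order(-alleles$support, alleles$pos, alleles$type), ]
    rownames(alleles) <- NULL
  }
  total <- wt_reads + sum(alleles$support) + unassigned_reads
  alleles$mrf <- if (total > 0) alleles$support / total else numeric(nrow(alleles))
  structure(list(site_id = site_id,
                 total_spanning_reads = as.integer(total),
                 alleles = alleles,
                 wt_reads = as.integer(wt_reads),
                 unassigned_reads = as.integer(unassigned_reads),
                 cumulative_mrf = sum(alleles$mrf)),
            class = "site_allele_table")
}

#' @export
print.site_allele_table <- function(x, ...) {
  cat("site_allele_table:", x$site_id, "-", x$total_spanning_reads,
      "spanning reads,", nrow(x$alleles), "allele(s), cumulative MRF",
      sprintf("%.4f", x$cumulative_mrf), "\n")
  if (nrow(x$alleles)) print(x$alleles, ...)
  invisible(x)
}

#' Aggregate indel observations into a site allele table
#'
#' Identical normalized indels (same pos, type, length, seq) are merged into
#' one allele with summed support; spanning reads carrying no windowed indel
#' are wild type.
#'
#' @param observations data.frame of per-pair observations (`pos`, `type`,
#'   `length`, `seq`, `pair_id`), at most one per pair.
#' @param spanning_read_count number of read pairs spanning the counting
#'   window.
#' @param site site id or panel row.
#' @return A `site_allele_table`.
#' @examples
#' pileup_site(data.frame(pos = 10, type = "del", length = 3, seq = "AAA",
#'                        pair_id = c("p1", "p2")), 100, "S1")
#' @export
pileup_site <- function(observations, spanning_read_count, site) {
  site <- if (is.character(site)) list(site_id = site) else as_site(site)
  stopifnot(spanning_read_count >= 0)
  n_mut <- if (nrow(observations)) length(unique(observations$pair_id)) else 0L
  if (nrow(observations) > 0 && anyDuplicated(observations$pair_id)) {
    stop("more than one observation per pair; deduplicate upstream")
  }
  if (n_mut > spanning_read_count) {
    stop("bookkeeping violation: ", n_mut,
         " mutant pairs exceed spanning read count ", spanning_read_count)
  }
  if (nrow(observations)) {
    key <- paste(observations$pos, observations$type, observations$length,
                 observations$seq, sep = "|")
    agg <- observations[!duplicated(key), c("pos", "type", "length", "seq")]
    agg$support <- as.integer(table(key)[key[!duplicated(key)]])
  } else {
    agg <- data.frame(pos = integer(), type = character(),
                      length = integer(), seq = character(),
                      support = integer(), stringsAsFactors = FALSE)
  }
  new_site_allele_table(site$site_id, agg,
                        wt_reads = spanning_read_count - n_mut)
}

#' Read-support filter parameters
#'
#' `min_mutant_reads` uses strict-greater semantics: an allele is retained
#' only if supported by *more than* this many mutant reads (the documented
#' default of 100 matches deep MiSeq runs). `error_floor` removes alleles at
#' or below a minimum MRF, operationalizing "above sequencing error rates".
#'
#' @param min_mutant_reads strict support threshold (default 100).
#' @param error_floor minimum MRF (default 0.005).
#' @return A `filter_params` list.
#' @export
filter_params <- function(min_mutant_reads = 100L, error_floor = 0.005) {
  stopifnot(min_mutant_reads >= 0, error_floor >= 0, error_floor < 1)
  structure(list(min_mutant_reads = as.integer(min_mutant_reads),
                 error_floor = error_floor),
            class = "filter_params")
}

#' Coverage-scaled filter parameters
#'
#' For desk-scale synthetic runs the support threshold scales with coverage
#' as `max(10, 0.01 * coverage)`; the 100-read default of [filter_params()]
#' remains the documented setting for real MiSeq depth.
#'
#' @param coverage expected spanning reads per site.
#' @param error_floor minimum MRF.
#' @return A `filter_params` list.
#' @export
scaled_filter_params <- function(coverage, error_floor = 0.005) {
  filter_params(max(10L, as.integer(ceiling(0.01 * coverage))), error_floor)
}

#' Apply the read-support filter to an allele table
#'
#' Alleles with support less than or equal to `min_mutant_reads`, or MRF at
#' or below `error_floor`, are removed; their support moves to the
#' `unassigned` tally (never to wild type), so count conservation holds and
#' MRF denominators are unchanged. Raising the threshold never adds alleles.
#'
#' @param table a `site_allele_table`.
#' @param params a [filter_params()].
#' @return The filtered `site_allele_table` (attribute `filtered = TRUE`).
#' @export
filter_indels <- function(table, params = filter_params()) {
  stopifnot(inherits(table, "site_allele_table"))
  al <- table$alleles
  keep <- al$support > params$min_mutant_reads & al$mrf > params$error_floor
  removed <- sum(al$support[!keep])
  out <- new_site_allele_table(
    table$site_id, al[keep, c("pos", "type", "length", "seq", "support")],
    wt_reads = table$wt_reads,
    unassigned_reads = table$unassigned_reads + removed)
  attr(out, "filtered") <- TRUE
  attr(out, "filter_params") <- params
  out
}

#' Cohort-level indel spectrum summary
#'
#' Summarizes filtered allele tables across samples: deletion/insertion
#' event fractions (each surviving allele is one event), size ranges, and
#' the per-sample count of mutated target genes (the two Cdkn2a sites
#' collapse to one gene when a panel with a `gene` column is supplied).
#'
#' @param tables_by_sample named list (sample) of named lists (site) of
#'   `site_allele_table`.
#' @param panel optional `target_panel` supplying the site-to-gene map.
#' @return A `cohort_summary` list with `n_samples`, `n_events`,
#'   `deletion_fraction`, `insertion_fraction`, `deletion_size_range`,
#'   `insertion_size_range`, `genes_mutated_per_sample`, and the flat
#'   `events` table.
#' @export
compute_cohort_summary <- function(tables_by_sample, panel = NULL) {
  stopifnot(length(tables_by_sample) >= 1)
  gene_of <- function(site) {
    if (is.null(panel) || !"gene" %in% names(panel)) return(site)
    g <- panel$gene[match(site, panel$site_id)]
    ifelse(is.na(g), site, g)
  }
  rows <- list()
  for (sm in names(tables_by_sample)) {
    for (tab in tables_by_sample[[sm]]) {
      if (nrow(tab$alleles) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sm, site_id = tab$site_id,
        gene = gene_of(tab$site_id),
        type = tab$alleles$type, length = tab$alleles$length,
        support = tab$alleles$support, mrf = tab$alleles$mrf,
        stringsAsFactors = FALSE)
    }
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample = character(), site_id = character(),
               gene = character(), type = character(), length = integer(),
               support = integer(), mrf = numeric(), stringsAsFactors = FALSE)
  n_events <- nrow(events)
  dfrac <- if (n_events) mean(events$type == "del") else NA_real_
  genes_per_sample <- vapply(names(tables_by_sample), function(sm) {
    length(unique(events$gene[events$sample == sm]))
  }, integer(1))
  structure(list(
    n_samples = length(tables_by_sample),
    n_events = n_events,
    deletion_fraction = dfrac,
    insertion_fraction = if (n_events) 1 - dfrac else NA_real_,
    deletion_size_range = if (any(events$type == "del"))
      range(events$length[events$type == "del"]) else c(NA_integer_, NA_integer_),
    insertion_size_range = if (any(events$type == "ins"))
      range(events$length[events$type == "ins"]) else c(NA_integer_, NA_integer_),
    genes_mutated_per_sample = genes_per_sample,
    events = events
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("cohort_summary:", x$n_samples, "samples,", x$n_events,
      "indel events\n")
  cat(sprintf("  deletions %.1f%% (sizes %s-%s bp), insertions %.1f%% (sizes %s-%s bp)\n",
              100 * x$deletion_fraction,
              x$deletion_size_range[1], x$deletion_size_range[2],
              100 * x$insertion_fraction,
              x$insertion_size_range[1], x$insertion_size_range[2]))
  cat("  mutated genes per sample:",
      paste(names(x$genes_mutated_per_sample),
            x$genes_mutated_per_sample, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Write a cohort summary as JSON
#'
#' @param summary a `cohort_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  x <- unclass(summary)
  x$events <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Off-target screen verdicts
#'
#' For each (sample, site) position: `no_data` when no spanning reads were
#' obtained, `mutated` when any allele survives the read-support filter,
#' else `wild_type_only`. Zero-coverage positions are never reported
#' wild-type.
#'
#' @param tables_by_sample named list (sample) of named lists (site) of
#'   `site_allele_table` over the off-target panel.
#' @param params a [filter_params()].
#' @return An `offtarget_screen` data.frame (`sample`, `site_id`,
#'   `verdict`) with per-verdict counts in attribute `counts`.
#' @export
offtarget_screen <- function(tables_by_sample, params = filter_params()) {
  rows <- list()
  for (sm in names(tables_by_sample)) {
    for (tab in tables_by_sample[[sm]]) {
      verdict <- if (tab$total_spanning_reads == 0) "no_data"
      else if (nrow(filter_indels(tab, params)$alleles) > 0) "mutated"
      else "wild_type_only"
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sm, site_id = tab$site_id, verdict = verdict,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  counts <- c(positions = nrow(out),
              wild_type_only = sum(out$verdict == "wild_type_only"),
              mutated = sum(out$verdict == "mutated"),
              no_data = sum(out$verdict == "no_data"))
  attr(out, "counts") <- counts
  class(out) <- c("offtarget_screen", "data.frame")
  out
}

#' @export
print.offtarget_screen <- function(x, ...) {
  ct <- attr(x, "counts")
  cat("off-target screen:", ct["positions"], "positions;",
      ct["wild_type_only"], "wild-type only,", ct["mutated"], "mutated,",
      ct["no_data"], "no data\n")
  invisible(x)
}

#' Surveyor-assay indel fraction from gel band intensities
#'
#' The cleaved fraction is `sum(cut) / (uncut + sum(cut))`; the indel
#' fraction applies the standard duplex-reformation correction
#' `1 - sqrt(1 - f_cleaved)`. Monotone in the cleaved fraction with fixed
#' points 0 and 1; a saturated assay (all DNA cleaved) returns 1 with a
#' warning.
#'
#' @param uncut_intensity integrated intensity of the uncut band.
#' @param cut_intensities intensities of the cleavage product bands.
#' @return Estimated indel fraction in `[0, 1]`.
#' @examples
#' surveyor_indel_fraction(81, 19) # 0.10
#' @export
surveyor_indel_fraction <- function(uncut_intensity, cut_intensities) {
  stopifnot(uncut_intensity >= 0, all(cut_intensities >= 0))
  total <- uncut_intensity + sum(cut_intensities)
  if (total <= 0) stop("total band intensity must be positive")
  f <- sum(cut_intensities) / total
  if (f >= 1) {
    warning("saturated assay: all DNA cleaved")
    return(1)
  }
  1 - sqrt(1 - f)
}
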