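# Synthetic cohort generator: clonal tumours with per-chromosome ploidy,
# stromal wild-type admixture, metastases inheriting their primary's indel
# signature, paired-end reads with uniform substitution errors, and fusion /
# translocation junction amplicons. Every sample carries full ground truth.

#' Simulation configuration
#'
#' @param seed optional integer seed; a fixed seed makes cohort output
#'   byte-identical across runs.
#' @param coverage_per_site read pairs simulated per target site and sample.
#' @param read_length read length in nt (MiSeq-like 2 x 300 bp default).
#' @param substitution_error_rate uniform per-base substitution probability.
#' @param unpaired_fraction fraction of pairs whose second mate is discordant
#'   (drawn from a different amplicon), emulating unpaired reads.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = NULL, coverage_per_site = 500L,
                       read_length = 300L, substitution_error_rate = 0.001,
                       unpaired_fraction = 0.03) {
  stopifnot(coverage_per_site > 0, read_length >= 30,
            substitution_error_rate >= 0, substitution_error_rate < 1,
            unpaired_fraction >= 0, unpaired_fraction < 1)
  structure(list(seed = seed,
                 coverage_per_site = as.integer(coverage_per_site),
                 read_length = as.integer(read_length),
                 substitution_error_rate = substitution_error_rate,
                 unpaired_fraction = unpaired_fraction),
            class = "sim_config")
}

#' Simulate a clonal tumour genotype
#'
#' Each target site is delivered/active with probability `edit_prob`; at an
#' active site every chromosome copy acquires an independent indel with
#' probability `copy_edit_prob`. Identical outcomes on different copies
#' collapse to the same allele identity.
#'
#' @param panel a `target_panel`.
#' @param model an [indel_model()].
#' @param ploidy single integer (all chromosomes) or named integer vector of
#'   per-chromosome copy numbers covering all panel chromosomes.
#' @param edit_prob per-site probability that the sgRNA was delivered and
#'   active in the founding cell.
#' @param copy_edit_prob per-copy editing probability at an active site.
#' @param clone_id label.
#' @return A `clone_truth` list with `clone_id`, `ploidy`, and `alleles`
#'   (data.frame: site_id, copy, type, pos, length, seq).
#' @export
simulate_clone <- function(panel, model = indel_model(), ploidy = 2L,
                           edit_prob = 0.8, copy_edit_prob = 0.9,
                           clone_id = "clone1") {
  chroms <- unique(panel$chrom)
  if (length(ploidy) == 1 && is.null(names(ploidy))) {
    ploidy <- setNames(rep(as.integer(ploidy), length(chroms)), chroms)
  }
  if (!all(chroms %in% names(ploidy))) {
    stop("ploidy must cover all panel chromosomes")
  }
  stopifnot(all(ploidy >= 1))

  rows <- list()
  for (i in seq_len(nrow(panel))) {
    if (runif(1) >= edit_prob) next
    k <- ploidy[[panel$chrom[i]]]
    site <- panel[i, ]
    for (copy in seq_len(k)) {
      if (runif(1) < copy_edit_prob) {
        ind <- sample_indel(model, site, 1)
        rows[[length(rows) + 1L]] <- data.frame(
          site_id = site$site_id, copy = copy, type = ind$type,
          pos = ind$pos, length = ind$length, seq = ind$seq,
          stringsAsFactors = FALSE)
      }
    }
  }
  alleles <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site_id = character(), copy = integer(), type = character(),
               pos = integer(), length = integer(), seq = character(),
               stringsAsFactors = FALSE)
  structure(list(clone_id = clone_id, ploidy = ploidy, alleles = alleles),
            class = "clone_truth")
}

#' Ground-truth indel signature of a clone
#'
#' @param clone a `clone_truth`.
#' @return data.frame of unique (site_id, pos, type, length, seq) markers.
#' @export
clone_signature <- function(clone) {
  unique(clone$alleles[, c("site_id", "pos", "type", "length", "seq")])
}

#' Describe a sequenced sample
#'
#' @param sample_id label.
#' @param kind one of `tumour_tissue`, `cell_line`, `single_cell_clone`,
#'   `metastasis`, `normal`.
#' @param clone_mixture named numeric vector of clone fractions (may be
#'   empty for `normal` samples).
#' @param stromal_wt_fraction wild-type (stromal) admixture; clone fractions
#'   plus stroma must sum to 1.
#' @param parent_primary clone id of the tumour of origin (required for
#'   metastases).
#' @return A `sample_truth` list.
#' @export
sample_truth <- function(sample_id, kind, clone_mixture = numeric(),
                         stromal_wt_fraction = 0, parent_primary = NULL) {
  kind <- match.arg(kind, c("tumour_tissue", "cell_line",
                            "single_cell_clone", "metastasis", "normal"))
  tot <- sum(clone_mixture) + stromal_wt_fraction
  if (abs(tot - 1) > 1e-8) {
    stop("clone fractions + stromal_wt_fraction must sum to 1 (got ", tot, ")")
  }
  if (kind == "metastasis" && is.null(parent_primary)) {
    stop("metastasis samples need parent_primary")
  }
  structure(list(sample_id = sample_id, kind = kind,
                 clone_mixture = clone_mixture,
                 stromal_wt_fraction = stromal_wt_fraction,
                 parent_primary = parent_primary),
            class = "sample_truth")
}

#' Metastasis sample derived from a primary clone
#'
#' Metastases inherit their primary's full signature (CRISPR expression was
#' transient, so no private target-site indels arise by default).
#'
#' @param clone the founding `clone_truth`.
#' @param sample_id label.
#' @param stromal_wt_fraction wild-type admixture in the nodule.
#' @return A `sample_truth` of kind `metastasis`.
#' @export
metastasis_sample <- function(clone, sample_id, stromal_wt_fraction = 0) {
  sample_truth(sample_id, "metastasis",
               setNames(1 - stromal_wt_fraction, clone$clone_id),
               stromal_wt_fraction, parent_primary = clone$clone_id)
}

allele_key <- function(df) {
  paste(df$site_id, df$pos, df$type, df$length, df$seq, sep = "|")
}

#' Expected per-site allele frequencies of a sample
#'
#' Combines clone mixture fractions, per-chromosome copy numbers and stromal
#' admixture into the expected mutant read frequency of every allele, plus
#' the wild-type fraction, at every site. Frequencies sum to 1 per site.
#'
#' @param sample a `sample_truth`.
#' @param clones named list of `clone_truth` objects.
#' @param panel a `target_panel`.
#' @return data.frame with columns `site_id`, `type` (`"WT"` for the
#'   wild-type row), `pos`, `length`, `seq`, `freq`.
#' @export
expected_allele_freqs <- function(sample, clones, panel) {
  out <- list()
  for (i in seq_len(nrow(panel))) {
    sid <- panel$site_id[i]
    chrom <- panel$chrom[i]
    freqs <- list()
    wt <- sample$stromal_wt_fraction
    for (cid in names(sample$clone_mixture)) {
      cl <- clones[[cid]]
      if (is.null(cl)) stop("unknown clone in mixture: ", cid)
      frac <- sample$clone_mixture[[cid]]
      k <- cl$ploidy[[chrom]]
      al <- cl$alleles[cl$alleles$site_id == sid, , drop = FALSE]
      wt <- wt + frac * (k - nrow(al)) / k
      if (nrow(al)) {
        keys <- allele_key(al)
        for (u in unique(keys)) {
          n_copies <- sum(keys == u)
          row <- al[match(u, keys), ]
          prev <- freqs[[u]]
          if (is.null(prev)) {
            prev <- data.frame(site_id = sid, type = row$type, pos = row$pos,
                               length = row$length, seq = row$seq, freq = 0,
                               stringsAsFactors = FALSE)
          }
          prev$freq <- prev$freq + frac * n_copies / k
          freqs[[u]] <- prev
        }
      }
    }
    al_df <- if (length(freqs)) do.call(rbind, freqs) else NULL
    wt_df <- data.frame(site_id = sid, type = "WT", pos = NA_integer_,
                        length = NA_integer_, seq = NA_character_, freq = wt,
                        stringsAsFactors = FALSE)
    out[[sid]] <- rbind(al_df, wt_df)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

apply_substitution_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  nerr <- rbinom(length(reads), nchar(reads), rate)
  for (i in which(nerr > 0)) {
    ch <- strsplit(reads[i], "")[[1]]
    at <- sample.int(length(ch), nerr[i])
    ch[at] <- vapply(ch[at],
                     function(b) sample(setdiff(BASES, b), 1), "")
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

# paired reads over a template: R1 is the template prefix, R2 the
# reverse-complemented suffix; templates shorter than the read length yield
# full-length template reads (large deletions)
make_read_pairs <- function(template, n, read_length, error_rate) {
  L <- nchar(template)
  rl <- min(read_length, L)
  r1 <- rep(substr(template, 1, rl), n)
  r2 <- rep(revcomp(substr(template, L - rl + 1, L)), n)
  list(r1 = apply_substitution_errors(r1, error_rate),
       r2 = apply_substitution_errors(r2, error_rate))
}

#' Simulate paired amplicon reads for one sample
#'
#' Read pairs per site are multinomially allocated to alleles (and wild
#' type) according to the sample's expected allele frequencies, sequenced
#' with uniform substitution errors, and a configurable fraction of pairs is
#' made discordant (mate 2 drawn from a different amplicon) to emulate
#' unpaired reads.
#'
#' @param sample a `sample_truth`.
#' @param clones named list of `clone_truth`.
#' @param panel a `target_panel`.
#' @param config a [sim_config()].
#' @return list with `sample_id`, named read vectors `r1`, `r2` (names are
#'   pair ids), and `truth` (the [expected_allele_freqs()] table).
#' @export
simulate_sample_reads <- function(sample, clones, panel,
                                  config = sim_config()) {
  truth <- expected_allele_freqs(sample, clones, panel)
  r1 <- r2 <- character(0)
  pair_n <- 0L
  for (i in seq_len(nrow(panel))) {
    sid <- panel$site_id[i]
    amp <- panel$amplicon_seq[i]
    tt <- truth[truth$site_id == sid, , drop = FALSE]
    counts <- as.integer(rmultinom(1, config$coverage_per_site, tt$freq))
    for (j in seq_len(nrow(tt))) {
      if (counts[j] == 0) next
      template <- if (tt$type[j] == "WT") amp else
        apply_indel(amp, tt[j, ])
      pr <- make_read_pairs(template, counts[j], config$read_length,
                            config$substitution_error_rate)
      r1 <- c(r1, pr$r1)
      r2 <- c(r2, pr$r2)
    }
  }
  n <- length(r1)
  ids <- sprintf("%s:p%07d", sample$sample_id, seq_len(n))
  names(r1) <- names(r2) <- ids

  # discordant mates emulating unpaired reads
  n_orphan <- rbinom(1, n, config$unpaired_fraction)
  if (n_orphan > 0) {
    idx <- sample.int(n, n_orphan)
    for (ix in idx) {
      site_of <- ((ix - 1L) %/% config$coverage_per_site) + 1L
      others <- setdiff(seq_len(nrow(panel)), site_of)
      if (length(others) > 0) {
        other <- if (length(others) == 1) others else sample(others, 1)
        oamp <- panel$amplicon_seq[other]
        rl <- min(config$read_length, nchar(oamp))
        r2[ix] <- apply_substitution_errors(
          revcomp(substr(oamp, nchar(oamp) - rl + 1, nchar(oamp))),
          config$substitution_error_rate)
      } else {
        r2[ix] <- random_dna(config$read_length)
      }
    }
    attr(r1, "orphan_ids") <- names(r1)[idx]
  }
  list(sample_id = sample$sample_id, r1 = r1, r2 = r2, truth = truth)
}

#' Simulate a full multi-sample cohort
#'
#' Runs [simulate_sample_reads()] for every sample under one seed and
#' optionally writes FASTQ pairs, truth tables, the panel TSV and the
#' amplicon FASTA to a directory. With a fixed seed the output is
#' byte-identical across runs.
#'
#' @param panel a `target_panel`.
#' @param clones named list of `clone_truth`.
#' @param samples list of `sample_truth`.
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return Invisibly, a list with `reads` (per-sample read sets), `panel`,
#'   `clones`, `samples`, `config`.
#' @export
simulate_cohort <- function(panel, clones, samples, config = sim_config(),
                            out_dir = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  for (s in samples) {
    bad <- setdiff(names(s$clone_mixture), names(clones))
    if (length(bad)) stop("sample ", s$sample_id,
                          " references unknown clones: ",
                          paste(bad, collapse = ", "))
  }
  reads <- lapply(samples, simulate_sample_reads, clones = clones,
                  panel = panel, config = config)
  names(reads) <- vapply(samples, `[[`, "", "sample_id")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_panel(panel, file.path(out_dir, "panel.tsv"),
                file.path(out_dir, "amplicons.fasta"))
    for (nm in names(reads)) {
      write_fastq(reads[[nm]]$r1,
                  file.path(out_dir, paste0(nm, "_R1.fastq.gz")))
      write_fastq(reads[[nm]]$r2,
                  file.path(out_dir, paste0(nm, "_R2.fastq.gz")))
      write.table(reads[[nm]]$truth,
                  file.path(out_dir, paste0(nm, "_truth.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    truth_alleles <- do.call(rbind, lapply(clones, function(cl) {
      if (nrow(cl$alleles) == 0) return(NULL)
      cbind(clone_id = cl$clone_id, cl$alleles)
    }))
    if (!is.null(truth_alleles)) {
      write.table(truth_alleles, file.path(out_dir, "clone_alleles.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(list(reads = reads, panel = panel, clones = clones,
                 samples = samples, config = config))
}

#' Fast generator path: per-site allele tables without read simulation
#'
#' Draws observed allele counts directly from the sample's expected allele
#' frequencies (multinomial at the given coverage), bypassing read synthesis
#' and alignment. Statistically this matches the read-level pipeline under
#' the package's substitution-only error model, in which sequencing errors
#' never create spurious indel observations; it is the scale-friendly path
#' for cohort-level experiments.
#'
#' @param sample a `sample_truth`.
#' @param clones named list of `clone_truth`.
#' @param panel a `target_panel`.
#' @param coverage spanning read pairs per site.
#' @return named list of `site_allele_table` objects.
#' @export
simulate_site_tables <- function(sample, clones, panel, coverage = 1000L) {
  truth <- expected_allele_freqs(sample, clones, panel)
  out <- list()
  for (sid in panel$site_id) {
    tt <- truth[truth$site_id == sid, , drop = FALSE]
    counts <- as.integer(rmultinom(1, coverage, tt$freq))
    wt_reads <- sum(counts[tt$type == "WT"])
    mut <- tt$type != "WT" & counts > 0
    alleles <- data.frame(pos = tt$pos[mut], type = tt$type[mut],
                          length = tt$length[mut], seq = tt$seq[mut],
                          support = counts[mut], stringsAsFactors = FALSE)
    out[[sid]] <- new_site_allele_table(sid, alleles, wt_reads)
  }
  out
}

#' Simulate a rearrangement junction amplicon and its reads
#'
#' The junction sequence is the prefix of site A's amplicon up to its cut
#' concatenated with the suffix of site B's amplicon from its cut
#' ("breakpoints at the exact sgRNA target sites"), optionally with a small
#' indel at the seam. Reciprocal translocations also emit the B->A
#' derivative junction.
#'
#' @param panel a `target_panel`.
#' @param siteA,siteB site ids (must differ).
#' @param class `intra_deletion`, `translocation_reciprocal` or
#'   `translocation_nonreciprocal`.
#' @param junction_indel optional list `list(type = "del"|"ins", length =)`
#'   applied at the seam of each derivative.
#' @param coverage read pairs per derivative junction.
#' @param config a [sim_config()] (read length / error rate reused).
#' @return list with `class`, `references` (named junction sequences),
#'   `seams` (0-based seam offset per derivative), and `reads` (r1/r2).
#' @export
simulate_junction_amplicon <- function(panel, siteA, siteB, class,
                                       junction_indel = NULL,
                                       coverage = 200L,
                                       config = sim_config()) {
  class <- match.arg(class, c("intra_deletion", "translocation_reciprocal",
                              "translocation_nonreciprocal"))
  if (siteA == siteB) stop("siteA and siteB must differ")
  ia <- match(siteA, panel$site_id)
  ib <- match(siteB, panel$site_id)
  if (is.na(ia) || is.na(ib)) stop("unknown site id")
  if (coverage <= 0) stop("coverage must be positive")

  junction_seq <- function(i, j) {
    paste0(substr(panel$amplicon_seq[i], 1, panel$cut_pos[i]),
           substr(panel$amplicon_seq[j], panel$cut_pos[j] + 1,
                  nchar(panel$amplicon_seq[j])))
  }
  refs <- setNames(junction_seq(ia, ib), paste0(siteA, "->", siteB))
  seams <- setNames(panel$cut_pos[ia], names(refs))
  if (class == "translocation_reciprocal") {
    refs <- c(refs, setNames(junction_seq(ib, ia),
                             paste0(siteB, "->", siteA)))
    seams <- c(seams, setNames(panel$cut_pos[ib], names(refs)[2]))
  }

  templates <- refs
  if (!is.null(junction_indel)) {
    for (nm in names(templates)) {
      s <- seams[[nm]]
      tpl <- templates[[nm]]
      if (junction_indel$type == "del") {
        l <- junction_indel$length
        lft <- l %/% 2
        templates[[nm]] <- paste0(substr(tpl, 1, s - lft),
                                  substr(tpl, s + (l - lft) + 1, nchar(tpl)))
      } else {
        templates[[nm]] <- paste0(substr(tpl, 1, s),
                                  random_dna(junction_indel$length),
                                  substr(tpl, s + 1, nchar(tpl)))
      }
    }
  }

  r1 <- r2 <- character(0)
  for (nm in names(templates)) {
    pr <- make_read_pairs(templates[[nm]], coverage, config$read_length,
                          config$substitution_error_rate)
    r1 <- c(r1, pr$r1)
    r2 <- c(r2, pr$r2)
  }
  ids <- sprintf("junc:p%06d", seq_along(r1))
  names(r1) <- names(r2) <- ids
  list(class = class, references = refs, seams = seams,
       reads = list(r1 = r1, r2 = r2))
}
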