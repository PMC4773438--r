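# Target-site panels: one row per sgRNA locus with its amplicon reference,
# chromosome label, protospacer/PAM, strand and blunt-cut position.
#
# Coordinates are 0-based, half-open throughout; `cut_pos` marks the blunt
# double-strand break between amplicon positions cut_pos - 1 and cut_pos,
# 3 nt 5' of the PAM-proximal end of the protospacer.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Default 15-site target panel layout
#'
#' Site, gene and chromosome labels for a multiplexed pancreatic
#' tumour-suppressor panel: four chromosomes carry more than one target site
#' (chr4 x 4, chr6 x 2, chr11 x 2, chr18 x 2), giving nine possible
#' intra-chromosomal fusions. The two Cdkn2a sites collapse to one gene in
#' gene-level summaries; the two Rosa26 intronic sites are neutral controls
#' and stay distinct. `genomic_cut` coordinates are synthetic placeholders
#' (the Cdkn2a pair is placed 18 kb apart).
#'
#' @return A data.frame with columns `site_id`, `gene`, `chrom`,
#'   `genomic_cut`.
#' @export
default_panel_layout <- function() {
  data.frame(
    site_id = c("Cdkn2a-ex1b", "Cdkn2a-ex2", "Cdkn2b", "Arid1a",
                "Rosa26.1", "Rosa26.2", "Trp53", "Brca1", "Apc", "Smad4",
                "Brca2", "Pten", "Arid1b", "Tgfbr2", "Smarca4"),
    gene = c("Cdkn2a", "Cdkn2a", "Cdkn2b", "Arid1a",
             "Rosa26.1", "Rosa26.2", "Trp53", "Brca1", "Apc", "Smad4",
             "Brca2", "Pten", "Arid1b", "Tgfbr2", "Smarca4"),
    chrom = c("chr4", "chr4", "chr4", "chr4",
              "chr6", "chr6", "chr11", "chr11", "chr18", "chr18",
              "chr5", "chr19", "chr17", "chr9", "chr8"),
    genomic_cut = c(89294000L, 89276000L, 89090000L, 133680000L,
                    113070000L, 113076000L, 69580000L, 101490000L,
                    34310000L, 76900000L,
                    150540000L, 32800000L, 5010000L, 116110000L, 84210000L),
    stringsAsFactors = FALSE
  )
}

#' Simulate a target-site amplicon panel
#'
#' Generates one random amplicon per site with an implanted protospacer +
#' NGG PAM on a random strand, and records the blunt Cas9 cut position
#' (3 nt 5' of the PAM-proximal protospacer end). Cut positions are placed
#' within the central 50% of the amplicon so that 300-nt paired reads always
#' span the cut.
#'
#' @param layout data.frame with columns `site_id`, `chrom` and optionally
#'   `gene`, `genomic_cut`; defaults to [default_panel_layout()].
#' @param amplicon_length amplicon length in nt (default 400).
#' @param gc GC content of the random background sequence.
#' @param seed optional integer seed for reproducibility.
#' @return A `target_panel` data.frame with columns `site_id`, `gene`,
#'   `chrom`, `strand`, `protospacer`, `pam`, `cut_pos` (0-based),
#'   `amplicon_seq` and optionally `genomic_cut`.
#' @examples
#' panel <- simulate_panel(seed = 1)
#' nrow(panel)
#' @export
simulate_panel <- function(layout = default_panel_layout(),
                           amplicon_length = 400, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is.data.frame(layout), nrow(layout) >= 1,
            all(c("site_id", "chrom") %in% names(layout)))
  if (anyDuplicated(layout$site_id)) {
    stop("invalid layout: duplicate site_id: ",
         paste(unique(layout$site_id[duplicated(layout$site_id)]),
               collapse = ", "))
  }
  if (amplicon_length < 60) stop("amplicon_length too short")
  if (!"gene" %in% names(layout)) layout$gene <- layout$site_id

  L <- as.integer(amplicon_length)
  lo <- ceiling(0.25 * L)
  hi <- floor(0.75 * L)

  n <- nrow(layout)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  cut_pos <- integer(n)
  protospacer <- pam <- amplicon <- character(n)

  for (i in seq_len(n)) {
    cp <- sample(seq.int(max(lo, 23L), min(hi, L - 23L)), 1)
    proto <- random_dna(20, gc)
    pm <- paste0(sample(BASES, 1), "GG")
    seq <- strsplit(random_dna(L, gc), "")[[1]]
    if (strand[i] == "+") {
      # [protospacer 20][PAM 3]; cut between p+16 and p+17 => cut_pos = p+17
      p <- cp - 17L
      seq[(p + 1):(p + 20)] <- strsplit(proto, "")[[1]]
      seq[(p + 21):(p + 23)] <- strsplit(pm, "")[[1]]
    } else {
      # reverse-complement occupies q..q+22; cut_pos = q + 6
      q <- cp - 6L
      seq[(q + 1):(q + 23)] <- strsplit(revcomp(paste0(proto, pm)), "")[[1]]
    }
    cut_pos[i] <- cp
    protospacer[i] <- proto
    pam[i] <- pm
    amplicon[i] <- paste(seq, collapse = "")
  }

  panel <- data.frame(
    site_id = layout$site_id, gene = layout$gene, chrom = layout$chrom,
    strand = strand, protospacer = protospacer, pam = pam,
    cut_pos = cut_pos, amplicon_seq = amplicon, stringsAsFactors = FALSE
  )
  if ("genomic_cut" %in% names(layout)) panel$genomic_cut <- layout$genomic_cut
  class(panel) <- c("target_panel", "data.frame")
  validate_panel(panel)
  panel
}

#' Validate a target-site panel
#'
#' Checks the structural invariants of a panel: unique site ids, the
#' protospacer + PAM present in the amplicon on the stated strand, and the
#' cut position 3 nt 5' of the PAM-proximal protospacer end, strictly inside
#' the amplicon.
#'
#' @param panel a `target_panel` data.frame.
#' @return `TRUE`, invisibly; stops on violation.
#' @export
validate_panel <- function(panel) {
  req <- c("site_id", "chrom", "strand", "protospacer", "pam",
           "cut_pos", "amplicon_seq")
  if (!all(req %in% names(panel))) {
    stop("panel is missing columns: ",
         paste(setdiff(req, names(panel)), collapse = ", "))
  }
  if (anyDuplicated(panel$site_id)) stop("duplicate site_id in panel")
  for (i in seq_len(nrow(panel))) {
    amp <- panel$amplicon_seq[i]
    L <- nchar(amp)
    cp <- panel$cut_pos[i]
    if (!(cp > 0 && cp < L)) stop("cut_pos out of bounds at ", panel$site_id[i])
    if (panel$strand[i] == "+") {
      expect <- paste0(panel$protospacer[i], panel$pam[i])
      at <- cp - 17L
    } else {
      expect <- revcomp(paste0(panel$protospacer[i], panel$pam[i]))
      at <- cp - 6L
    }
    if (at < 0 || substr(amp, at + 1, at + 23) != expect) {
      stop("protospacer/PAM not at expected cut-site position for ",
           panel$site_id[i])
    }
  }
  invisible(TRUE)
}

#' Write a panel to TSV (and amplicon FASTA)
#'
#' @param panel a `target_panel`.
#' @param tsv_path output TSV path (amplicon sequences are omitted from the
#'   TSV; they go to the FASTA).
#' @param fasta_path optional amplicon FASTA path.
#' @return `tsv_path`, invisibly.
#' @export
write_panel <- function(panel, tsv_path, fasta_path = NULL) {
  cols <- intersect(c("site_id", "gene", "chrom", "strand", "protospacer",
                      "pam", "cut_pos", "genomic_cut"), names(panel))
  write.table(as.data.frame(panel)[, cols], tsv_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(fasta_path)) {
    seqs <- Biostrings::DNAStringSet(setNames(panel$amplicon_seq,
                                              panel$site_id))
    Biostrings::writeXStringSet(seqs, fasta_path)
  }
  invisible(tsv_path)
}

#' Read a panel from TSV + amplicon FASTA
#'
#' @param tsv_path panel TSV as written by [write_panel()].
#' @param fasta_path amplicon FASTA with one record per `site_id`.
#' @return A validated `target_panel`.
#' @export
read_panel <- function(tsv_path, fasta_path) {
  tab <- read.delim(tsv_path, stringsAsFactors = FALSE)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  idx <- match(tab$site_id, names(seqs))
  if (anyNA(idx)) stop("FASTA is missing amplicons for some panel sites")
  tab$amplicon_seq <- as.character(seqs)[idx]
  if (!"gene" %in% names(tab)) tab$gene <- tab$site_id
  class(tab) <- c("target_panel", "data.frame")
  validate_panel(tab)
  tab
}
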