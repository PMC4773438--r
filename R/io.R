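# FASTQ / TSV / VCF interfaces. Sequence IO goes through Biostrings.

#' Write reads as FASTQ
#'
#' @param reads named character vector (names become read ids); qualities
#'   are constant (the simulator models substitution errors, not quality
#'   profiles).
#' @param path output path; `.gz` suffix triggers compression.
#' @param qual quality character used for every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, qual = "I") {
  s <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::BStringSet(strrep(qual, Biostrings::width(s)))
  Biostrings::writeXStringSet(s, path, format = "fastq", qualities = q,
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#'
#' @param path FASTQ path (optionally gzipped).
#' @return Named character vector of read sequences (ids truncated at the
#'   first whitespace).
#' @export
read_fastq <- function(path) {
  s <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}

#' Export per-site indel calls
#'
#' `tsv`: one row per surviving allele with support and MRF. `vcf`: minimal
#' VCF 4.2 against the amplicon references, with indels anchored on the base
#' before the event as usual.
#'
#' @param tables named list of `site_allele_table`.
#' @param path output path.
#' @param format `"tsv"` or `"vcf"`.
#' @param panel required for `vcf` (amplicon sequences provide REF/ALT
#'   context).
#' @param sample_id sample label written into the VCF header.
#' @return `path`, invisibly.
#' @export
write_indel_calls <- function(tables, path, format = c("tsv", "vcf"),
                              panel = NULL, sample_id = "sample") {
  format <- match.arg(format)
  rows <- list()
  for (tab in tables) {
    al <- tab$alleles
    if (nrow(al) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = tab$site_id, pos = al$pos, type = al$type,
      length = al$length, seq = al$seq, support = al$support, mrf = al$mrf,
      wt_reads = tab$wt_reads, total = tab$total_spanning_reads,
      stringsAsFactors = FALSE)
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(site_id = character(), pos = integer(), type = character(),
               length = integer(), seq = character(), support = integer(),
               mrf = numeric(), wt_reads = integer(), total = integer(),
               stringsAsFactors = FALSE)

  if (format == "tsv") {
    write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }

  if (is.null(panel)) stop("VCF export needs the panel for REF context")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ampliclone",
               paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                      "Description=\"Read depth per allele\">"),
               "##INFO=<ID=MRF,Number=1,Type=Float,Description=\"Mutant read frequency\">",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      sample_id)), con)
  for (i in seq_len(nrow(calls))) {
    amp <- panel$amplicon_seq[match(calls$site_id[i], panel$site_id)]
    p0 <- calls$pos[i]
    if (calls$type[i] == "del") {
      if (p0 > 0) {
        anchor <- substr(amp, p0, p0)
        ref <- paste0(anchor, calls$seq[i]); alt <- anchor; vpos <- p0
      } else { # deletion at position 0: anchor on the following base
        nxt <- substr(amp, p0 + calls$length[i] + 1, p0 + calls$length[i] + 1)
        ref <- paste0(calls$seq[i], nxt); alt <- nxt; vpos <- 1
      }
    } else {
      if (p0 > 0) {
        anchor <- substr(amp, p0, p0)
        ref <- anchor; alt <- paste0(anchor, calls$seq[i]); vpos <- p0
      } else {
        nxt <- substr(amp, 1, 1)
        ref <- nxt; alt <- paste0(calls$seq[i], nxt); vpos <- 1
      }
    }
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tMRF=%.6g\tAD\t%d,%d",
                       calls$site_id[i], vpos, ref, alt, calls$mrf[i],
                       calls$wt_reads[i], calls$support[i]), con)
  }
  invisible(path)
}

#' Read a karyotype table
#'
#' Tabular per-sample, per-chromosome copy numbers (e.g. derived from
#' M-FISH), used to constrain [assign_allele_copies()].
#'
#' @param path TSV with columns `sample`, `chrom`, `copy_number`.
#' @return data.frame.
#' @export
read_karyotype <- function(path) {
  k <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample", "chrom", "copy_number")
  if (!all(req %in% names(k))) {
    stop("karyotype table needs columns: ", paste(req, collapse = ", "))
  }
  if (any(k$copy_number < 1)) stop("copy numbers must be >= 1")
  k
}

#' Write a sample-by-site status matrix
#'
#' Mirrors a cohort overview heatmap: one row per sample, one column per
#' site, entries `status:cumulative_mrf`.
#'
#' @param statuses named list (sample) of data.frames from
#'   [classify_sample_sites()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_status_matrix <- function(statuses, path) {
  sites <- unique(unlist(lapply(statuses, `[[`, "site_id")))
  cols <- lapply(statuses, function(df) {
    v <- sprintf("%s:%.3f", df$status, df$cumulative_mrf)
    v[match(sites, df$site_id)]
  })
  out <- data.frame(site_id = sites, cols, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
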