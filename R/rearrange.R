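# Structural-variant screening: enumerate candidate fusions from the target
# panel (all same-chromosome pairs for intra-chromosomal deletions; all
# cross-chromosome pairs in both derivative orientations for
# translocations), then detect junction-supporting reads against the
# predicted junction reference and verify that breakpoints sit at the cut
# sites.

predicted_junction_seq <- function(panel, ia, ib) {
  paste0(substr(panel$amplicon_seq[ia], 1, panel$cut_pos[ia]),
         substr(panel$amplicon_seq[ib], panel$cut_pos[ib] + 1,
                nchar(panel$amplicon_seq[ib])))
}

empty_candidates <- function() {
  data.frame(siteA = character(), siteB = character(), chromA = character(),
             chromB = character(), same_chrom = logical(), seam = integer(),
             predicted_deletion_span = integer(), junction_seq = character(),
             stringsAsFactors = FALSE)
}

fusion_candidate_row <- function(panel, ia, ib) {
  data.frame(
    siteA = panel$site_id[ia], siteB = panel$site_id[ib],
    chromA = panel$chrom[ia], chromB = panel$chrom[ib],
    same_chrom = panel$chrom[ia] == panel$chrom[ib],
    seam = panel$cut_pos[ia],
    predicted_deletion_span = if ("genomic_cut" %in% names(panel) &&
                                  panel$chrom[ia] == panel$chrom[ib])
      abs(panel$genomic_cut[ib] - panel$genomic_cut[ia]) else NA_integer_,
    junction_seq = predicted_junction_seq(panel, ia, ib),
    stringsAsFactors = FALSE)
}

#' Enumerate candidate intra-chromosomal deletions
#'
#' All unordered same-chromosome site pairs, modelled as head-to-tail
#' deletion joins (the upstream cut's prefix fused to the downstream cut's
#' suffix; sites are ordered by genomic coordinate when available). The
#' candidate count equals `sum over chromosomes of choose(n_sites, 2)`.
#'
#' @param panel a `target_panel`.
#' @return A `fusion_candidates` data.frame (possibly empty) with the
#'   predicted junction sequence and deletion span per candidate.
#' @examples
#' nrow(enumerate_intrachrom_fusions(simulate_panel(seed = 1))) # 9
#' @export
enumerate_intrachrom_fusions <- function(panel) {
  rows <- list()
  for (ch in unique(panel$chrom)) {
    idx <- which(panel$chrom == ch)
    if ("genomic_cut" %in% names(panel)) {
      idx <- idx[order(panel$genomic_cut[idx])]
    }
    if (length(idx) < 2) next
    prs <- combn(idx, 2)
    for (p in seq_len(ncol(prs))) {
      rows[[length(rows) + 1L]] <-
        fusion_candidate_row(panel, prs[1, p], prs[2, p])
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_candidates()
  class(out) <- c("fusion_candidates", "data.frame")
  out
}

#' Enumerate candidate inter-chromosomal translocations
#'
#' All cross-chromosome site pairs, each in both derivative orientations
#' (A-prefix + B-suffix and B-prefix + A-suffix), so reciprocal events can
#' be recognized by detecting both derivatives.
#'
#' @param panel a `target_panel`.
#' @return A `fusion_candidates` data.frame, two rows per unordered pair.
#' @export
enumerate_transloc_candidates <- function(panel) {
  n <- nrow(panel)
  rows <- list()
  if (n >= 2) {
    prs <- combn(seq_len(n), 2)
    for (p in seq_len(ncol(prs))) {
      ia <- prs[1, p]; ib <- prs[2, p]
      if (panel$chrom[ia] == panel$chrom[ib]) next
      rows[[length(rows) + 1L]] <- fusion_candidate_row(panel, ia, ib)
      rows[[length(rows) + 1L]] <- fusion_candidate_row(panel, ib, ia)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_candidates()
  class(out) <- c("fusion_candidates", "data.frame")
  out
}

# cheap screen before dynamic programming: a junction-supporting sequence
# must share k-mers with both flanks of the predicted seam (wild-type reads
# carry only one side), tolerant of sequencing errors and seam resection
junction_prefilter <- function(seqs, jref, seam, k = 13L, flank = 60L,
                               min_hits = 2L) {
  L <- nchar(jref)
  lk <- substr(jref, max(1L, seam - flank + 1L), seam)
  rk <- substr(jref, seam + 1L, min(L, seam + flank))
  kmers <- function(s, step = 1L) {
    n <- nchar(s) - k + 1L
    if (n < 1) return(character())
    pos <- seq(1L, n, by = step)
    substring(s, pos, pos + k - 1L)
  }
  lkm <- kmers(lk)
  rkm <- kmers(rk)
  rc <- revcomp(seqs)
  vapply(seq_along(seqs), function(i) {
    for (s in c(seqs[i], rc[i])) {
      skm <- kmers(s, step = 2L)
      if (sum(lkm %in% skm) >= min_hits && sum(rkm %in% skm) >= min_hits) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1))
}

# per-read junction evidence: anchors on both sides of the seam plus the
# seam-overlapping indel (breakpoint resection / non-templated insertion)
read_junction_evidence <- function(read, jref, seam, tol, anchor,
                                   min_identity, params) {
  pseudo <- list(site_id = "junction", amplicon_seq = jref, cut_pos = seam)
  a_f <- align_read(read, pseudo, params)
  a_r <- align_read(revcomp(read), pseudo, params)
  aln <- if (is.null(a_f) && is.null(a_r)) return(NULL)
  else if (is.null(a_r) || (!is.null(a_f) && a_f$score >= a_r$score)) a_f
  else a_r

  # anchor windows either side of the seam, padded by tol so that junction
  # resection within tolerance does not starve them
  left_win <- c(seam - anchor - tol, seam)   # [lo, hi)
  right_win <- c(seam, seam + anchor + tol)
  overlap <- function(rpos, len, win) {
    max(0L, min(rpos + len, win[2]) - max(rpos, win[1]))
  }
  # per window: matched bases, mismatched bases, and inserted bases not
  # attributable to the seam indel (insertions hide non-matching read
  # content, so they count against window identity)
  m_l <- x_l <- i_l <- 0L
  m_r <- x_r <- i_r <- 0L
  rpos <- aln$ref_start
  offA <- 0L; offB <- 0L
  jindel <- NULL
  for (i in seq_len(nrow(aln$ops))) {
    op <- aln$ops$op[i]
    len <- aln$ops$len[i]
    if (op == "=") {
      m_l <- m_l + overlap(rpos, len, left_win)
      m_r <- m_r + overlap(rpos, len, right_win)
    } else if (op == "X") {
      x_l <- x_l + overlap(rpos, len, left_win)
      x_r <- x_r + overlap(rpos, len, right_win)
    }
    if (op %in% c("=", "X", "D")) {
      if (op == "D" && rpos + len >= seam - tol && rpos <= seam + tol) {
        offA <- offA - max(0L, min(rpos + len, seam) - min(rpos, seam))
        offB <- offB + max(0L, rpos + len - max(rpos, seam))
        jindel <- paste0("del", len)
      }
      rpos <- rpos + len
    } else if (op == "I") {
      if (rpos >= seam - tol && rpos <= seam + tol) {
        jindel <- paste0("ins", len)
      } else {
        if (rpos > left_win[1] && rpos < left_win[2]) i_l <- i_l + len
        if (rpos > right_win[1] && rpos < right_win[2]) i_r <- i_r + len
      }
    }
  }
  need <- ceiling(min_identity * anchor)
  idty <- function(m, x, i) if (m + x + i == 0) 0 else m / (m + x + i)
  if (m_l < need || m_r < need ||
      idty(m_l, x_l, i_l) < min_identity ||
      idty(m_r, x_r, i_r) < min_identity) return(NULL)
  list(offA = offA, offB = offB, jindel = if (is.null(jindel)) "none" else jindel)
}

#' Detect a rearrangement junction from reads
#'
#' Aligns candidate sequences (reads or an assembled product, either
#' orientation) against the predicted junction reference
#' (prefix of A up to its cut + suffix of B from its cut). A sequence
#' supports the junction when it aligns with matching anchors on both sides
#' of the seam; breakpoint offsets are read off the seam-overlapping
#' deletion (A-side resection negative, B-side positive) and small seam
#' indels are reported as `junction_indel`. The call is confirmed when both
#' offsets are within `tol`.
#'
#' @param seqs character vector of reads / assembled sequences.
#' @param candidate one row of a `fusion_candidates` table.
#' @param tol breakpoint tolerance in bp (default 10), allowing NHEJ
#'   junction resection while still requiring cuts "at" the target sites.
#' @param anchor matched bases required on each side of the seam.
#' @param min_identity fraction of the anchor that must match.
#' @param min_support minimum supporting sequences for a call.
#' @param params an [align_params()].
#' @return A `rearrangement_call` (list) or `NULL` when unsupported.
#' @export
detect_junction <- function(seqs, candidate, tol = 10L, anchor = 25L,
                            min_identity = 0.9, min_support = 1L,
                            params = align_params()) {
  stopifnot(tol >= 0)
  if (is.data.frame(candidate)) candidate <- as.list(candidate[1, ])
  keep <- junction_prefilter(seqs, candidate$junction_seq, candidate$seam)
  ev <- list()
  for (s in seqs[keep]) {
    e <- read_junction_evidence(s, candidate$junction_seq, candidate$seam,
                                tol, anchor, min_identity, params)
    if (!is.null(e)) ev[[length(ev) + 1L]] <- e
  }
  if (length(ev) < min_support) return(NULL)
  key <- vapply(ev, function(e) paste(e$offA, e$offB, e$jindel, sep = "|"), "")
  modal <- names(sort(table(key), decreasing = TRUE))[1]
  e <- ev[[match(modal, key)]]
  structure(list(siteA = candidate$siteA, siteB = candidate$siteB,
                 chromA = candidate$chromA, chromB = candidate$chromB,
                 same_chrom = candidate$same_chrom,
                 support = length(ev),
                 breakpoint_offset_A = e$offA,
                 breakpoint_offset_B = e$offB,
                 junction_indel = e$jindel,
                 confirmed = abs(e$offA) <= tol && abs(e$offB) <= tol,
                 class = NA_character_),
            class = "rearrangement_call")
}

#' @export
print.rearrangement_call <- function(x, ...) {
  cat(sprintf("rearrangement_call %s->%s (%s) support=%d offsets=(%d,%d) %s%s\n",
              x$siteA, x$siteB,
              if (is.na(x$class)) "unclassified" else x$class,
              x$support, x$breakpoint_offset_A, x$breakpoint_offset_B,
              if (x$junction_indel == "none") "" else
                paste0("junction_indel=", x$junction_indel, " "),
              if (x$confirmed) "[confirmed]" else "[unconfirmed]"))
  invisible(x)
}

#' Classify confirmed rearrangement calls for one sample
#'
#' Same-chromosome junctions are intra-chromosomal deletions; a
#' cross-chromosome pair with both derivative junctions detected is a
#' reciprocal translocation, with one derivative a non-reciprocal
#' translocation.
#'
#' @param calls list of `rearrangement_call`s from one sample.
#' @return The same list with `class` filled in on confirmed calls.
#' @export
classify_rearrangements <- function(calls) {
  calls <- Filter(Negate(is.null), calls)
  pair_key <- vapply(calls, function(cl) {
    paste(sort(c(cl$siteA, cl$siteB)), collapse = "~")
  }, "")
  confirmed <- vapply(calls, `[[`, TRUE, "confirmed")
  for (i in seq_along(calls)) {
    if (!confirmed[i]) next
    if (calls[[i]]$same_chrom) {
      calls[[i]]$class <- "intra_deletion"
    } else {
      both <- sum(pair_key == pair_key[i] & confirmed) >= 2
      calls[[i]]$class <- if (both) "translocation_reciprocal"
      else "translocation_nonreciprocal"
    }
  }
  calls
}

#' Predicted genomic deletion size between two same-chromosome cuts
#'
#' @param panel a `target_panel` with a `genomic_cut` column.
#' @param siteA,siteB site ids on the same chromosome.
#' @return Distance in bp between the genomic cut coordinates (0 is flagged
#'   degenerate with a warning).
#' @export
predicted_deletion_size <- function(panel, siteA, siteB) {
  ia <- match(siteA, panel$site_id)
  ib <- match(siteB, panel$site_id)
  if (is.na(ia) || is.na(ib)) stop("unknown site id")
  if (panel$chrom[ia] != panel$chrom[ib]) {
    stop("sites are on different chromosomes; no deletion size defined")
  }
  if (!"genomic_cut" %in% names(panel)) {
    stop("panel has no genomic_cut coordinates")
  }
  d <- abs(panel$genomic_cut[ib] - panel$genomic_cut[ia])
  if (d == 0) warning("degenerate candidate: identical cut coordinates")
  d
}

#' Export rearrangement calls as a BEDPE-like table
#'
#' @param calls list of `rearrangement_call`s (classified).
#' @param panel a `target_panel` (for chromosome labels / coordinates).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_rearrangements_bedpe <- function(calls, panel, path) {
  calls <- Filter(Negate(is.null), calls)
  rows <- lapply(calls, function(cl) {
    ia <- match(cl$siteA, panel$site_id)
    ib <- match(cl$siteB, panel$site_id)
    gc <- if ("genomic_cut" %in% names(panel)) panel$genomic_cut else
      rep(NA_integer_, nrow(panel))
    data.frame(chromA = cl$chromA, posA = gc[ia] + cl$breakpoint_offset_A,
               chromB = cl$chromB, posB = gc[ib] + cl$breakpoint_offset_B,
               siteA = cl$siteA, siteB = cl$siteB,
               class = cl$class, support = cl$support,
               confirmed = cl$confirmed, stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
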