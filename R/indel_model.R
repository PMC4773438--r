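# NHEJ repair-outcome model for Cas9 blunt cuts: deletion-biased indel
# spectrum with truncated-geometric size distributions and positional jitter
# of the indel anchor around the cut (1-5 bp upstream of the PAM).

#' Construct an indel outcome model
#'
#' Describes the repair-outcome distribution at a Cas9 cut: deletion versus
#' insertion bias, truncated-geometric size distributions (size and frequency
#' correlate inversely), and jitter of the indel anchor around the cut
#' position. Defaults emulate a strongly deletion-biased spectrum (90:10)
#' with deletions of 1-363 bp (mean 6) and insertions of 1-32 bp (mean 2).
#'
#' @param p_deletion probability that an indel is a deletion.
#' @param del_len_max,ins_len_max maximum deletion/insertion length (bp).
#' @param del_len_mean,ins_len_mean mean of the geometric length law before
#'   truncation.
#' @param del_len_probs,ins_len_probs optional explicit probability vectors
#'   over lengths `1:del_len_max` / `1:ins_len_max`, overriding the
#'   geometric defaults.
#' @param pos_offsets integer offsets of the indel anchor relative to
#'   `cut_pos` (the default -2..2 spans 1-5 bp upstream of the PAM).
#' @param pos_probs probabilities for `pos_offsets`.
#' @return An `indel_model` list.
#' @examples
#' m <- indel_model()
#' sum(m$del_len_probs)
#' @export
indel_model <- function(p_deletion = 0.9,
                        del_len_max = 363, ins_len_max = 32,
                        del_len_mean = 6, ins_len_mean = 2,
                        del_len_probs = NULL, ins_len_probs = NULL,
                        pos_offsets = -2:2,
                        pos_probs = c(0.1, 0.2, 0.4, 0.2, 0.1)) {
  stopifnot(p_deletion >= 0, p_deletion <= 1,
            del_len_max >= 1, ins_len_max >= 1,
            length(pos_offsets) == length(pos_probs),
            all(pos_probs >= 0))
  if (is.null(del_len_probs)) {
    del_len_probs <- dgeom(seq_len(del_len_max) - 1, prob = 1 / del_len_mean)
  }
  if (is.null(ins_len_probs)) {
    ins_len_probs <- dgeom(seq_len(ins_len_max) - 1, prob = 1 / ins_len_mean)
  }
  stopifnot(length(del_len_probs) == del_len_max,
            length(ins_len_probs) == ins_len_max,
            all(del_len_probs >= 0), all(ins_len_probs >= 0))
  structure(list(
    p_deletion = p_deletion,
    del_len_probs = del_len_probs / sum(del_len_probs),
    ins_len_probs = ins_len_probs / sum(ins_len_probs),
    pos_offsets = as.integer(pos_offsets),
    pos_probs = pos_probs / sum(pos_probs)
  ), class = "indel_model")
}

#' Left-align (normalize) an indel against a reference
#'
#' Shifts an indel to its leftmost equivalent placement, the canonical
#' representation used throughout for allele identity. Idempotent.
#'
#' @param ref reference sequence (character scalar).
#' @param pos 0-based reference offset of the indel (deletion: first deleted
#'   base; insertion: the inserted bases sit immediately before `pos`).
#' @param type `"del"` or `"ins"`.
#' @param seq deleted or inserted bases.
#' @return list with normalized `pos` and `seq`.
#' @export
left_align_indel <- function(ref, pos, type, seq) {
  len <- nchar(seq)
  stopifnot(len >= 1, pos >= 0)
  if (type == "del") {
    stopifnot(substr(ref, pos + 1, pos + len) == seq)
    while (pos > 0 &&
           substr(ref, pos, pos) == substr(ref, pos + len, pos + len)) {
      pos <- pos - 1
    }
    seq <- substr(ref, pos + 1, pos + len)
  } else if (type == "ins") {
    while (pos > 0 && substr(ref, pos, pos) == substr(seq, len, len)) {
      seq <- paste0(substr(ref, pos, pos), substr(seq, 1, len - 1))
      pos <- pos - 1
    }
  } else {
    stop("type must be 'del' or 'ins'")
  }
  list(pos = pos, seq = seq)
}

#' Apply an indel to an amplicon sequence
#'
#' @param amplicon reference sequence.
#' @param indel list or one-row data.frame with `type`, `pos` (0-based),
#'   `length`, `seq`.
#' @return The mutated allele sequence.
#' @export
apply_indel <- function(amplicon, indel) {
  pos <- indel$pos
  len <- indel$length
  if (indel$type == "del") {
    paste0(substr(amplicon, 1, pos), substr(amplicon, pos + len + 1,
                                            nchar(amplicon)))
  } else {
    paste0(substr(amplicon, 1, pos), indel$seq,
           substr(amplicon, pos + 1, nchar(amplicon)))
  }
}

#' Draw indel alleles from an outcome model
#'
#' Samples `n` independent repair outcomes at a target site. Deletions are
#' centred on the jittered anchor; insertions are inserted at it. Lengths
#' that would extend past the amplicon bounds are resampled (the number of
#' resampled draws is returned as attribute `n_resampled`). Returned indels
#' are left-aligned against the amplicon, so identical outcomes have
#' identical (pos, type, length, seq) identity.
#'
#' @param model an [indel_model()].
#' @param site one panel row (or list) with `amplicon_seq` and `cut_pos`.
#' @param n number of draws.
#' @return data.frame with columns `type`, `pos`, `length`, `seq`.
#' @export
sample_indel <- function(model, site, n = 1) {
  stopifnot(inherits(model, "indel_model"), n >= 1)
  amp <- site$amplicon_seq
  L <- nchar(amp)
  cut <- site$cut_pos

  is_del <- runif(n) < model$p_deletion
  anchors <- cut + sample(model$pos_offsets, n, replace = TRUE,
                          prob = model$pos_probs)
  out <- data.frame(type = ifelse(is_del, "del", "ins"),
                    pos = NA_integer_, length = NA_integer_,
                    seq = NA_character_, stringsAsFactors = FALSE)
  n_resampled <- 0L
  for (i in seq_len(n)) {
    a <- anchors[i]
    if (is_del[i]) {
      for (try in 1:100) {
        len <- sample.int(length(model$del_len_probs), 1,
                          prob = model$del_len_probs)
        start <- a - len %/% 2L
        if (start >= 1 && start + len <= L - 1) break
        len <- NA_integer_
        n_resampled <- n_resampled + 1L
      }
      if (is.na(len)) { # pathological bounds; a 1-bp deletion always fits
        len <- 1L
        start <- max(1L, min(a, L - 2L))
      }
      seq <- substr(amp, start + 1, start + len)
      la <- left_align_indel(amp, start, "del", seq)
    } else {
      len <- sample.int(length(model$ins_len_probs), 1,
                        prob = model$ins_len_probs)
      pos <- max(1L, min(a, L - 1L))
      seq <- random_dna(len)
      la <- left_align_indel(amp, pos, "ins", seq)
    }
    out$pos[i] <- la$pos
    out$length[i] <- len
    out$seq[i] <- la$seq
  }
  attr(out, "n_resampled") <- n_resampled
  out
}
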