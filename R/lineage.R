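# Clonal lineage tracking: CRISPR indel identities act as heritable
# barcodes. Signatures are sets of exact (site, pos, type, length, seq)
# markers; Jaccard distance between signatures drives single-linkage
# clustering of samples into independent primaries, and metastases are
# assigned to the primary sharing most markers.

#' Build a clone signature from filtered allele tables
#'
#' One marker per surviving allele; marker identity is exact on site,
#' normalized position, type, length and sequence.
#'
#' @param tables named list of filtered `site_allele_table`.
#' @param sample_id label for the signature.
#' @return A `clone_signature` (list with `sample_id` and `markers`
#'   data.frame).
#' @export
build_signature <- function(tables, sample_id) {
  rows <- list()
  for (tab in tables) {
    if (nrow(tab$alleles) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = tab$site_id, pos = tab$alleles$pos, type = tab$alleles$type,
      length = tab$alleles$length, seq = tab$alleles$seq,
      stringsAsFactors = FALSE)
  }
  markers <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(site_id = character(), pos = integer(), type = character(),
               length = integer(), seq = character(), stringsAsFactors = FALSE)
  rownames(markers) <- NULL
  structure(list(sample_id = sample_id, markers = markers),
            class = "clone_signature")
}

#' Marker keys of a signature
#'
#' @param sig a `clone_signature` (or a marker data.frame, or an already
#'   flattened character vector of keys).
#' @param relaxed drop the inserted/deleted sequence from the identity
#'   (position + type + length only), for noisy callers.
#' @return Character vector of marker keys.
#' @export
marker_keys <- function(sig, relaxed = FALSE) {
  if (is.character(sig)) return(sig)
  m <- if (inherits(sig, "clone_signature")) sig$markers else sig
  if (nrow(m) == 0) return(character())
  if (relaxed) paste(m$site_id, m$pos, m$type, m$length, sep = "|")
  else paste(m$site_id, m$pos, m$type, m$length, m$seq, sep = "|")
}

#' Jaccard distance between clone signatures
#'
#' `1 - |a and b| / |a or b|` over marker keys. Two empty signatures have no
#' evidence of relatedness and return 1 with a warning.
#'
#' @param a,b `clone_signature`s (or marker key vectors).
#' @param relaxed see [marker_keys()].
#' @return Distance in `[0, 1]`.
#' @export
signature_distance <- function(a, b, relaxed = FALSE) {
  ka <- marker_keys(a, relaxed)
  kb <- marker_keys(b, relaxed)
  un <- union(ka, kb)
  if (length(un) == 0) {
    warning("both signatures empty; distance undefined, returning 1")
    return(1)
  }
  1 - length(intersect(ka, kb)) / length(un)
}

#' Deconvolve independent primary tumours from sample signatures
#'
#' Single-linkage clustering of signatures at Jaccard distance
#' `max_intra_distance`. A sample sharing at least `min_shared` markers with
#' two or more other clusters is reported mixed; a singleton cluster formed
#' by a mixed sample whose markers are covered by the clusters it shares
#' with is dropped from the clone list (its constituents are reported in the
#' mixed-sample partition instead). Output is invariant to sample order.
#'
#' @param signatures list of `clone_signature`s (single-cell-clone
#'   signatures may be included; they partition mixed samples).
#' @param min_shared markers required to link a sample to a cluster.
#' @param max_intra_distance single-linkage cut height.
#' @param relaxed see [marker_keys()].
#' @return A `clone_deconvolution`: list with `clusters` (list of sample-id
#'   vectors), `profiles` (marker-key set per cluster), `mixed` (per mixed
#'   sample: the clusters it shares markers with and the marker partition),
#'   `membership`, and the `hclust` tree.
#' @export
deconvolve_primaries <- function(signatures, min_shared = 2L,
                                 max_intra_distance = 0.3, relaxed = FALSE) {
  stopifnot(length(signatures) >= 1)
  ids <- vapply(signatures, `[[`, "", "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids in signatures")
  names(signatures) <- ids
  keys <- lapply(signatures, marker_keys, relaxed = relaxed)
  # stable order so clustering output cannot depend on input order
  ord <- order(ids)
  ids <- ids[ord]
  keys <- keys[ord]

  n <- length(ids)
  if (n == 1) {
    memb <- setNames(1L, ids)
    tree <- NULL
  } else {
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        un <- union(keys[[i]], keys[[j]])
        d <- if (length(un) == 0) 1 else
          1 - length(intersect(keys[[i]], keys[[j]])) / length(un)
        D[i, j] <- D[j, i] <- d
      }
    }
    tree <- hclust(stats::as.dist(D), method = "single")
    memb <- cutree(tree, h = max_intra_distance)
  }

  cluster_ids <- sort(unique(memb))
  profile_of <- function(c, exclude = NULL) {
    members <- setdiff(ids[memb == c], exclude)
    unique(unlist(keys[members], use.names = FALSE))
  }

  # a sample is mixed when its markers are not explainable by one cluster:
  # after attributing it to the cluster sharing most markers, the residual
  # markers still link (>= min_shared) to at least one other cluster
  mixed <- list()
  for (s in ids) {
    shares <- vapply(cluster_ids, function(c) {
      length(intersect(keys[[s]], profile_of(c, exclude = s)))
    }, integer(1))
    if (max(shares) < min_shared) next
    c1 <- cluster_ids[which.max(shares)]
    residual <- setdiff(keys[[s]], profile_of(c1, exclude = s))
    extra <- vapply(setdiff(cluster_ids, c1), function(c) {
      length(intersect(residual, profile_of(c, exclude = s)))
    }, integer(1))
    linked <- c(c1, setdiff(cluster_ids, c1)[extra >= min_shared])
    if (length(linked) >= 2) {
      partition <- lapply(linked, function(c) {
        intersect(keys[[s]], profile_of(c, exclude = s))
      })
      names(partition) <- paste0("cluster", linked)
      covered <- unique(unlist(partition, use.names = FALSE))
      mixed[[s]] <- list(components = linked, partition = partition,
                         private = setdiff(keys[[s]], covered))
    }
  }

  # drop singleton clusters that are just a mixed sample explained by others
  drop <- integer()
  for (s in names(mixed)) {
    c_own <- memb[[s]]
    if (sum(memb == c_own, na.rm = TRUE) == 1) {
      others <- setdiff(mixed[[s]]$components, c_own)
      covered <- unique(unlist(lapply(others, profile_of, exclude = s),
                               use.names = FALSE))
      if (length(keys[[s]]) > 0 &&
          mean(keys[[s]] %in% covered) >= 0.95) {
        drop <- c(drop, c_own)
        memb[[s]] <- NA_integer_
      }
    }
  }
  keep_ids <- setdiff(cluster_ids, drop)
  clusters <- lapply(keep_ids, function(c) ids[!is.na(memb) & memb == c])
  profiles <- lapply(keep_ids, function(c) {
    unique(unlist(keys[ids[!is.na(memb) & memb == c]], use.names = FALSE))
  })
  names(clusters) <- names(profiles) <- paste0("cluster", keep_ids)

  structure(list(clusters = clusters, profiles = profiles, mixed = mixed,
                 membership = memb, tree = tree),
            class = "clone_deconvolution")
}

#' @export
print.clone_deconvolution <- function(x, ...) {
  cat("clone_deconvolution:", length(x$clusters), "clone cluster(s)\n")
  for (nm in names(x$clusters)) {
    cat(" ", nm, "(", length(x$profiles[[nm]]), "markers ):",
        paste(x$clusters[[nm]], collapse = ", "), "\n")
  }
  if (length(x$mixed)) {
    cat("  mixed samples:", paste(names(x$mixed), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export the sample dendrogram as Newick
#'
#' @param x a `clone_deconvolution` (or an `hclust`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_dendrogram_newick <- function(x, path) {
  tree <- if (inherits(x, "clone_deconvolution")) x$tree else x
  if (is.null(tree)) stop("no dendrogram available (fewer than 2 samples)")
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Assign metastases to their tumour of origin
#'
#' Each metastasis is assigned to the primary sharing the most markers,
#' provided the shared count reaches `min_shared` and the margin over the
#' second-best primary reaches `min_margin`; otherwise it is `ambiguous`.
#'
#' @param met_signatures list of `clone_signature`s for metastases.
#' @param primaries named list of primary signatures (or marker-key vectors,
#'   e.g. `profiles` from [deconvolve_primaries()]).
#' @param min_shared minimum shared markers.
#' @param min_margin minimum lead over the runner-up.
#' @param relaxed see [marker_keys()].
#' @return An `origin_assignment` data.frame (`met_id`, `assigned_primary`,
#'   `shared_markers`, `margin`) with per-primary assignment fractions in
#'   attribute `fractions`.
#' @export
assign_metastases <- function(met_signatures, primaries, min_shared = 2L,
                              min_margin = 1L, relaxed = FALSE) {
  stopifnot(length(primaries) >= 1, !is.null(names(primaries)))
  pkeys <- lapply(primaries, marker_keys, relaxed = relaxed)
  rows <- lapply(met_signatures, function(sig) {
    mk <- marker_keys(sig, relaxed)
    shared <- vapply(pkeys, function(p) length(intersect(mk, p)), integer(1))
    ord <- order(-shared)
    best <- shared[ord[1]]
    second <- if (length(shared) > 1) shared[ord[2]] else 0L
    margin <- best - second
    ok <- best >= min_shared && margin >= min_margin
    data.frame(met_id = sig$sample_id,
               assigned_primary = if (ok) names(pkeys)[ord[1]] else "ambiguous",
               shared_markers = best, margin = margin,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  assigned <- out$assigned_primary[out$assigned_primary != "ambiguous"]
  fr <- if (length(assigned))
    table(factor(assigned, levels = names(pkeys))) / length(assigned)
  else setNames(rep(NA_real_, length(pkeys)), names(pkeys))
  attr(out, "fractions") <- fr
  class(out) <- c("origin_assignment", "data.frame")
  out
}
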