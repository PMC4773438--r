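# Small programmatic fixtures shared across tests.

tiny_layout <- function(n_sites, n_chroms = n_sites) {
  data.frame(site_id = paste0("S", seq_len(n_sites)),
             chrom = paste0("chr", rep_len(seq_len(n_chroms), n_sites)),
             stringsAsFactors = FALSE)
}

tiny_panel <- function(n_sites = 2, n_chroms = n_sites, amplicon_length = 300,
                       seed = NULL) {
  simulate_panel(tiny_layout(n_sites, n_chroms),
                 amplicon_length = amplicon_length, seed = seed)
}

# allele table built directly from counts
table_from_counts <- function(site_id, wt, alleles = NULL) {
  if (is.null(alleles)) {
    alleles <- data.frame(pos = integer(), type = character(),
                          length = integer(), seq = character(),
                          support = integer(), stringsAsFactors = FALSE)
  }
  new_site_allele_table(site_id, alleles, wt)
}

allele_row <- function(pos, type, length, seq, support) {
  data.frame(pos = pos, type = type, length = length, seq = seq,
             support = support, stringsAsFactors = FALSE)
}

# a signature object straight from marker keys (site|pos|type|len|seq)
signature_from_keys <- function(sample_id, keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  markers <- data.frame(
    site_id = vapply(parts, `[[`, "", 1),
    pos = as.integer(vapply(parts, `[[`, "", 2)),
    type = vapply(parts, `[[`, "", 3),
    length = as.integer(vapply(parts, `[[`, "", 4)),
    seq = vapply(parts, `[[`, "", 5),
    stringsAsFactors = FALSE)
  structure(list(sample_id = sample_id, markers = markers),
            class = "clone_signature")
}

mk <- function(i) sprintf("S%d|%d|del|3|AAA", i, 100 + i)

# two clones with guaranteed disjoint signatures and >= min_markers each
disjoint_clone_pair <- function(panel, model = indel_model(),
                                min_markers = 3, max_tries = 20) {
  for (t in seq_len(max_tries)) {
    a <- simulate_clone(panel, model, clone_id = "TuA")
    b <- simulate_clone(panel, model, clone_id = "TuB")
    ka <- with(clone_signature(a), paste(site_id, pos, type, length, seq))
    kb <- with(clone_signature(b), paste(site_id, pos, type, length, seq))
    if (length(ka) >= min_markers && length(kb) >= min_markers &&
        length(intersect(ka, kb)) == 0) {
      return(list(TuA = a, TuB = b))
    }
  }
  stop("could not build disjoint clone pair")
}
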