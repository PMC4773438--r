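test_that("signatures are built deterministically from filtered tables", {
  tabs <- list(
    S1 = new_site_allele_table("S1", allele_row(10, "del", 2, "AT", 900),
                               100),
    S2 = table_from_counts("S2", 1000))
  s1 <- build_signature(tabs, "a")
  s2 <- build_signature(tabs, "a")
  expect_identical(s1, s2)
  expect_equal(nrow(s1$markers), 1)
  empty <- build_signature(list(S2 = table_from_counts("S2", 100)), "e")
  expect_equal(nrow(empty$markers), 0)
})

test_that("two samples of the same clone yield identical signatures", {
  set.seed(71)
  panel <- tiny_panel(5, seed = 71)
  cl <- simulate_clone(panel, clone_id = "c1")
  s <- sample_truth("x", "cell_line", c(c1 = 1))
  fp <- scaled_filter_params(2000)
  sig <- function() {
    tabs <- lapply(simulate_site_tables(s, list(c1 = cl), panel, 2000),
                   filter_indels, params = fp)
    marker_keys(build_signature(tabs, "x"))
  }
  expect_setequal(sig(), sig())
})

test_that("Jaccard distance behaves as a metric on marker sets", {
  a <- signature_from_keys("a", mk(1:4))
  b <- signature_from_keys("b", mk(3:6))
  expect_equal(signature_distance(a, a), 0)
  expect_equal(signature_distance(a, b), signature_distance(b, a))
  disjoint <- signature_from_keys("c", mk(10:12))
  expect_equal(signature_distance(a, disjoint), 1)
  # |intersection| = 5, |union| = 10 -> 0.5
  x <- signature_from_keys("x", mk(1:8))
  y <- signature_from_keys("y", mk(4:10))
  expect_equal(signature_distance(x, y), 0.5)
  expect_warning(
    d <- signature_distance(signature_from_keys("e1", character()),
                            signature_from_keys("e2", character())),
    "empty")
  expect_equal(d, 1)

  # triangle inequality over random small sets
  set.seed(72)
  universe <- mk(1:8)
  for (i in 1:50) {
    s3 <- lapply(1:3, function(j) {
      signature_from_keys(paste0("t", j),
                          sample(universe, sample(1:8, 1)))
    })
    d12 <- signature_distance(s3[[1]], s3[[2]])
    d13 <- signature_distance(s3[[1]], s3[[3]])
    d23 <- signature_distance(s3[[2]], s3[[3]])
    expect_lte(d12, d13 + d23 + 1e-12)
  }
})

test_that("relaxed marker identity ignores the indel sequence", {
  a <- signature_from_keys("a", "S1|100|del|3|AAA")
  b <- signature_from_keys("b", "S1|100|del|3|TTT")
  expect_equal(signature_distance(a, b), 1)
  expect_equal(signature_distance(a, b, relaxed = TRUE), 0)
})

test_that("biopsy deconvolution finds two primaries and flags the mixed biopsy", {
  keysA <- mk(1:6)
  keysB <- mk(101:106)
  sigs <- c(
    lapply(1:7, function(i) {
      signature_from_keys(paste0("biopsy", i + 1), keysA)
    }),
    list(signature_from_keys("biopsy1", c(keysA, keysB))),
    # single-cell clones defining the second tumour
    lapply(1:3, function(i) signature_from_keys(paste0("scc", i), keysB))
  )
  dec <- deconvolve_primaries(sigs)
  expect_length(dec$clusters, 2)
  expect_equal(names(dec$mixed), "biopsy1")
  profs <- lapply(dec$profiles, sort)
  expect_true(any(vapply(profs, identical, TRUE, sort(keysA))))
  expect_true(any(vapply(profs, identical, TRUE, sort(keysB))))
  # the mixed biopsy is partitioned into both constituent signatures
  part <- dec$mixed$biopsy1$partition
  expect_setequal(unlist(part, use.names = FALSE), c(keysA, keysB))
})

test_that("identical signatures form a single cluster; disjoint clones separate", {
  same <- lapply(1:4, function(i) signature_from_keys(paste0("s", i), mk(1:5)))
  expect_length(deconvolve_primaries(same)$clusters, 1)

  set.seed(73)
  three <- lapply(1:3, function(i) {
    signature_from_keys(paste0("c", i), mk(1:4 + 10 * i))
  })
  dec <- deconvolve_primaries(three)
  expect_length(dec$clusters, 3)
})

test_that("deconvolution output is invariant to sample input order", {
  set.seed(74)
  sigs <- c(
    lapply(1:3, function(i) signature_from_keys(paste0("a", i), mk(1:5))),
    lapply(1:3, function(i) signature_from_keys(paste0("b", i), mk(21:25))))
  d1 <- deconvolve_primaries(sigs)
  d2 <- deconvolve_primaries(rev(sigs))
  norm <- function(d) {
    cl <- lapply(d$clusters, sort)
    cl[order(vapply(cl, `[[`, "", 1))]
  }
  expect_equal(unname(norm(d1)), unname(norm(d2)))
})

test_that("dendrogram exports as Newick", {
  sigs <- c(
    lapply(1:2, function(i) signature_from_keys(paste0("a", i), mk(1:5))),
    list(signature_from_keys("b", mk(11:15))))
  dec <- deconvolve_primaries(sigs)
  nwk <- tempfile(fileext = ".nwk")
  export_dendrogram_newick(dec, nwk)
  txt <- readLines(nwk)
  expect_match(txt, "a1")
  expect_match(txt, ";$")
})

test_that("metastases are assigned to the primary sharing most markers", {
  pA <- signature_from_keys("Tu1", mk(1:6))
  pB <- signature_from_keys("Tu2", mk(101:106))
  mets <- c(
    lapply(1:5, function(i) signature_from_keys(paste0("m", i), mk(1:6))),
    lapply(6:9, function(i) signature_from_keys(paste0("m", i), mk(101:106))))
  out <- assign_metastases(mets, list(Tu1 = pA, Tu2 = pB))
  expect_equal(out$assigned_primary,
               c(rep("Tu1", 5), rep("Tu2", 4)))
  fr <- attr(out, "fractions")
  expect_equal(unname(fr[["Tu1"]]), 5 / 9)
  expect_equal(unname(fr[["Tu2"]]), 4 / 9)

  # empty signature and perfect tie are ambiguous
  amb <- assign_metastases(
    list(signature_from_keys("m0", character()),
         signature_from_keys("mt", c(mk(1:2), mk(101:102)))),
    list(Tu1 = pA, Tu2 = pB))
  expect_equal(amb$assigned_primary, c("ambiguous", "ambiguous"))
  expect_equal(amb$margin[2], 0)
})

test_that("lineage recovery is perfect across seeded replicate cohorts", {
  # clones with >= 3 private markers, coverage 1000x: all 9 metastases per
  # cohort must be assigned correctly and no unmixed biopsy flagged mixed
  set.seed(75)
  panel <- tiny_panel(8, n_chroms = 4, seed = 75)
  n_cohorts <- 10
  correct <- 0L
  total <- 0L
  false_mixed <- 0L
  for (co in seq_len(n_cohorts)) {
    pair <- disjoint_clone_pair(panel)
    clones <- list(TuA = pair$TuA, TuB = pair$TuB)
    fp <- scaled_filter_params(1000)
    sig_of <- function(id, clone_id, kind = "cell_line") {
      s <- sample_truth(id, kind, setNames(1, clone_id),
                        parent_primary = if (kind == "metastasis") clone_id)
      tabs <- lapply(simulate_site_tables(s, clones, panel, 1000),
                     filter_indels, params = fp)
      build_signature(tabs, id)
    }
    biopsies <- lapply(1:4, function(i) sig_of(paste0("b", i), "TuA"))
    dec <- deconvolve_primaries(biopsies)
    false_mixed <- false_mixed + length(dec$mixed)

    origin <- rep(c("TuA", "TuB"), c(5, 4))
    mets <- lapply(seq_along(origin), function(i) {
      sig_of(paste0("met", i), origin[i], kind = "metastasis")
    })
    primaries <- list(TuA = sig_of("pA", "TuA"), TuB = sig_of("pB", "TuB"))
    out <- assign_metastases(mets, primaries)
    correct <- correct + sum(out$assigned_primary == origin)
    total <- total + length(origin)
  }
  expect_equal(correct, total)
  expect_equal(false_mixed, 0L)
})
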