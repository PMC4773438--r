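test_that("the default panel yields nine intra-chromosomal fusion candidates", {
  panel <- simulate_panel(seed = 81)
  cand <- enumerate_intrachrom_fusions(panel)
  expect_equal(nrow(cand), 9)   # C(4,2) + C(2,2) * 3 = 6 + 3
  expect_true(all(cand$same_chrom))
  # head-to-tail join ordered by genomic coordinate
  expect_true(all(!is.na(cand$predicted_deletion_span)))
})

test_that("enumeration counts match the closed forms on random panels", {
  set.seed(82)
  for (i in 1:5) {
    n <- sample(3:8, 1)
    nchr <- sample(1:4, 1)
    panel <- tiny_panel(n, n_chroms = nchr, seed = 82 + i)
    tab <- table(panel$chrom)
    expect_equal(nrow(enumerate_intrachrom_fusions(panel)),
                 sum(choose(tab, 2)))
    inter_pairs <- (n^2 - sum(tab^2)) / 2
    expect_equal(nrow(enumerate_transloc_candidates(panel)), 2 * inter_pairs)
  }
  # one site per chromosome: no intra candidates
  p1 <- tiny_panel(3, n_chroms = 3, seed = 99)
  expect_equal(nrow(enumerate_intrachrom_fusions(p1)), 0)
  # three sites on one chromosome: C(3,2) = 3
  p3 <- tiny_panel(3, n_chroms = 1, seed = 98)
  expect_equal(nrow(enumerate_intrachrom_fusions(p3)), 3)
  expect_equal(nrow(enumerate_transloc_candidates(p3)), 0)
})

test_that("cross-chromosome pairs produce both derivative junctions", {
  panel <- tiny_panel(2, n_chroms = 2, seed = 83)
  cand <- enumerate_transloc_candidates(panel)
  expect_equal(nrow(cand), 2)
  expect_setequal(paste(cand$siteA, cand$siteB), c("S1 S2", "S2 S1"))
})

test_that("exact junctions are detected with breakpoint offsets (0,0)", {
  set.seed(84)
  panel <- tiny_panel(3, n_chroms = 1, seed = 84)
  cand <- enumerate_intrachrom_fusions(panel)
  cand <- cand[cand$siteA == "S1" & cand$siteB == "S2" |
               cand$siteA == "S2" & cand$siteB == "S1", ][1, ]
  sim <- simulate_junction_amplicon(panel, cand$siteA, cand$siteB,
                                    "intra_deletion", coverage = 50,
                                    config = sim_config(seed = 84))
  seqs <- c(sim$reads$r1, sim$reads$r2)
  call <- detect_junction(seqs, cand, min_support = 5)
  expect_false(is.null(call))
  expect_true(call$confirmed)
  expect_equal(call$breakpoint_offset_A, 0)
  expect_equal(call$breakpoint_offset_B, 0)
  expect_equal(call$junction_indel, "none")
  expect_gte(call$support, 50)
})

test_that("a small deletion at the seam is reported as a junction indel", {
  set.seed(85)
  panel <- tiny_panel(2, n_chroms = 1, seed = 85)
  cand <- enumerate_intrachrom_fusions(panel)[1, ]
  sim <- simulate_junction_amplicon(panel, cand$siteA, cand$siteB,
                                    "intra_deletion",
                                    junction_indel = list(type = "del",
                                                          length = 2),
                                    coverage = 40,
                                    config = sim_config(seed = 85))
  call <- detect_junction(c(sim$reads$r1, sim$reads$r2), cand,
                          min_support = 5)
  expect_false(is.null(call))
  expect_true(call$confirmed)
  expect_equal(call$junction_indel, "del2")
  expect_lte(abs(call$breakpoint_offset_A), 2)
  expect_lte(abs(call$breakpoint_offset_B), 2)
})

test_that("reads from unrelated amplicons never support a junction", {
  set.seed(86)
  panel <- tiny_panel(3, n_chroms = 1, seed = 86)
  cand <- enumerate_intrachrom_fusions(panel)[1, ]
  # wild-type reads from both parent amplicons plus an unrelated site
  wt_reads <- unlist(lapply(panel$amplicon_seq, function(a) {
    c(substr(a, 1, 300), ampliclone:::revcomp(substr(a, 101, 400)))
  }))
  expect_null(detect_junction(wt_reads, cand))
})

test_that("junction-free simulations produce zero calls across replicates", {
  set.seed(87)
  panel <- tiny_panel(4, n_chroms = 2, seed = 87)
  cands <- enumerate_intrachrom_fusions(panel)
  cl <- list(c1 = simulate_clone(panel, clone_id = "c1"))
  smp <- list(sample_truth("s", "cell_line", c(c1 = 1)))
  n_calls <- 0L
  for (i in 1:10) {
    cfg <- sim_config(seed = 870 + i, coverage_per_site = 30)
    sim <- simulate_cohort(panel, cl, smp, cfg)
    seqs <- c(sim$reads$s$r1, sim$reads$s$r2)
    for (ci in seq_len(nrow(cands))) {
      if (!is.null(detect_junction(seqs, cands[ci, ], min_support = 3))) {
        n_calls <- n_calls + 1L
      }
    }
  }
  expect_equal(n_calls, 0L)
})

test_that("rearrangement classes are assigned from derivative evidence", {
  mk_call <- function(siteA, siteB, same_chrom, confirmed = TRUE) {
    structure(list(siteA = siteA, siteB = siteB, chromA = "x", chromB = "y",
                   same_chrom = same_chrom, support = 100L,
                   breakpoint_offset_A = 0L, breakpoint_offset_B = 0L,
                   junction_indel = "none", confirmed = confirmed,
                   class = NA_character_),
              class = "rearrangement_call")
  }
  calls <- classify_rearrangements(list(
    mk_call("Cdkn2b", "Apc", FALSE),     # der + reciprocal partner
    mk_call("Apc", "Cdkn2b", FALSE),
    mk_call("Pten", "Arid1b", FALSE),    # single derivative
    mk_call("Cdkn2a-ex1b", "Cdkn2a-ex2", TRUE)))
  classes <- vapply(calls, `[[`, "", "class")
  expect_equal(classes, c("translocation_reciprocal",
                          "translocation_reciprocal",
                          "translocation_nonreciprocal",
                          "intra_deletion"))
})

test_that("all three junction classes are recovered end to end", {
  set.seed(88)
  panel <- tiny_panel(4, n_chroms = 2, seed = 88)  # S1/S3 chr1, S2/S4 chr2
  cfg <- sim_config(seed = 88, coverage_per_site = 40)
  intra <- enumerate_intrachrom_fusions(panel)
  inter <- enumerate_transloc_candidates(panel)

  run <- function(siteA, siteB, class) {
    sim <- simulate_junction_amplicon(panel, siteA, siteB, class,
                                      coverage = 40, config = cfg)
    seqs <- c(sim$reads$r1, sim$reads$r2)
    cands <- rbind(intra, inter)
    calls <- list()
    for (i in seq_len(nrow(cands))) {
      calls[[length(calls) + 1L]] <-
        detect_junction(seqs, cands[i, ], min_support = 5)
    }
    classify_rearrangements(calls)
  }

  got <- run("S1", "S3", "intra_deletion")
  expect_length(got, 1)
  expect_equal(got[[1]]$class, "intra_deletion")
  expect_equal(c(got[[1]]$breakpoint_offset_A, got[[1]]$breakpoint_offset_B),
               c(0L, 0L))

  got <- run("S1", "S2", "translocation_reciprocal")
  expect_length(got, 2)
  expect_setequal(vapply(got, `[[`, "", "class"),
                  "translocation_reciprocal")

  got <- run("S1", "S2", "translocation_nonreciprocal")
  expect_length(got, 1)
  expect_equal(got[[1]]$class, "translocation_nonreciprocal")
})

test_that("predicted deletion sizes come from genomic cut coordinates", {
  panel <- simulate_panel(seed = 89)
  expect_equal(predicted_deletion_size(panel, "Cdkn2a-ex1b", "Cdkn2a-ex2"),
               18000)
  expect_error(predicted_deletion_size(panel, "Cdkn2a-ex2", "Apc"),
               "different chromosomes")
  layout <- tiny_layout(2, 1)
  layout$genomic_cut <- c(1000L, 19000L)
  p2 <- simulate_panel(layout, seed = 89)
  expect_equal(predicted_deletion_size(p2, "S1", "S2"), 18000)
  layout$genomic_cut <- c(5000L, 5000L)
  p3 <- simulate_panel(layout, seed = 89)
  expect_warning(d <- predicted_deletion_size(p3, "S1", "S2"), "degenerate")
  expect_equal(d, 0)
})
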