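test_that("pileup with no observations is all wild type", {
  obs <- data.frame(site_id = character(), pos = integer(),
                    type = character(), length = integer(), seq = character(),
                    pair_id = character(), stringsAsFactors = FALSE)
  tab <- pileup_site(obs, 1000, "S1")
  expect_equal(tab$wt_reads, 1000)
  expect_equal(tab$total_spanning_reads, 1000)
  expect_equal(tab$cumulative_mrf, 0)
  expect_equal(nrow(tab$alleles), 0)
})

test_that("identical normalized indels from different pairs merge into one allele", {
  obs <- data.frame(site_id = "S1", pos = 100L, type = "del", length = 3L,
                    seq = "AAA", pair_id = c("p1", "p2"),
                    stringsAsFactors = FALSE)
  tab <- pileup_site(obs, 10, "S1")
  expect_equal(nrow(tab$alleles), 1)
  expect_equal(tab$alleles$support, 2)
  expect_equal(tab$alleles$mrf, 0.2)
  expect_equal(tab$wt_reads, 8)
})

test_that("observations exceeding spanning reads are a bookkeeping error", {
  obs <- data.frame(site_id = "S1", pos = 1L, type = "del", length = 1L,
                    seq = "A", pair_id = c("p1", "p2", "p3"),
                    stringsAsFactors = FALSE)
  expect_error(pileup_site(obs, 2, "S1"), "bookkeeping")
})

test_that("support filter uses strict-greater semantics at the boundary", {
  mk_tab <- function(support, total = 20000) {
    new_site_allele_table("S1", allele_row(10, "del", 2, "AT", support),
                          wt_reads = total - support)
  }
  p <- filter_params(min_mutant_reads = 100, error_floor = 0.001)
  expect_equal(nrow(filter_indels(mk_tab(100), p)$alleles), 0)   # removed
  expect_equal(nrow(filter_indels(mk_tab(101), p)$alleles), 1)   # retained
  # identity at zero thresholds
  t0 <- mk_tab(5)
  f0 <- filter_indels(t0, filter_params(0, 0))
  expect_equal(f0$alleles$support, t0$alleles$support)
})

test_that("filtered support moves to unassigned, never to wild type", {
  tab <- new_site_allele_table(
    "S1", rbind(allele_row(10, "del", 2, "AT", 500),
                allele_row(30, "ins", 1, "G", 40)), wt_reads = 460)
  f <- filter_indels(tab, filter_params(100, 0.005))
  expect_equal(f$wt_reads, 460)
  expect_equal(f$unassigned_reads, 40)
  expect_equal(nrow(f$alleles), 1)
  # count conservation at every stage
  expect_equal(f$wt_reads + sum(f$alleles$support) + f$unassigned_reads,
               f$total_spanning_reads)
  expect_equal(f$total_spanning_reads, tab$total_spanning_reads)
  # MRF denominator unchanged by filtering
  expect_equal(f$alleles$mrf, 500 / 1000)
})

test_that("raising the support threshold never adds alleles (monotonicity)", {
  set.seed(51)
  sup <- sample(1:500, 20)
  tab <- new_site_allele_table(
    "S1", allele_row(1:20 * 3, "del", 2, "AT", sup), wt_reads = 5000)
  prev <- Inf
  for (thr in c(0, 10, 50, 100, 400)) {
    n <- nrow(filter_indels(tab, filter_params(thr, 0))$alleles)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("MRF estimates tighten with coverage (consistency)", {
  set.seed(52)
  panel <- tiny_panel(1, seed = 52)
  cl <- simulate_clone(panel, clone_id = "het", edit_prob = 0)
  cl$alleles <- data.frame(site_id = "S1", copy = 1L, type = "del",
                           pos = 70L, length = 4L, seq = "ACGT",
                           stringsAsFactors = FALSE)
  s <- sample_truth("CL", "cell_line", c(het = 1))
  err <- function(cov) {
    reps <- vapply(1:20, function(i) {
      tab <- simulate_site_tables(s, list(het = cl), panel, cov)[["S1"]]
      abs(tab$alleles$mrf[1] - 0.5)
    }, 0)
    mean(reps)
  }
  expect_lt(err(5000), err(500))
})

test_that("cohort summary computes fractions, sizes and gene collapse", {
  tabs <- list(
    Tu1 = list(
      A = new_site_allele_table("Cdkn2a-ex1b",
                                allele_row(10, "del", 5, "AAAAA", 300), 700),
      B = new_site_allele_table("Cdkn2a-ex2",
                                allele_row(20, "del", 2, "GT", 400), 600),
      C = new_site_allele_table("Trp53",
                                allele_row(30, "ins", 7, "ACGTACG", 200), 800)),
    Tu2 = list(
      C = new_site_allele_table("Trp53",
                                allele_row(31, "del", 363, strrep("A", 363),
                                           500), 500)))
  panel_map <- data.frame(site_id = c("Cdkn2a-ex1b", "Cdkn2a-ex2", "Trp53"),
                          gene = c("Cdkn2a", "Cdkn2a", "Trp53"))
  sm <- compute_cohort_summary(tabs, panel_map)
  expect_equal(sm$n_events, 4)
  expect_equal(sm$deletion_fraction, 0.75)
  expect_equal(sm$insertion_fraction, 0.25)
  expect_equal(sm$deletion_size_range, c(2, 363))
  expect_equal(sm$insertion_size_range, c(7, 7))
  # the two Cdkn2a sites collapse to one mutated gene
  expect_equal(unname(sm$genes_mutated_per_sample["Tu1"]), 2L)
  expect_equal(unname(sm$genes_mutated_per_sample["Tu2"]), 1L)
})

test_that("a single insertion-only sample has insertion fraction 1", {
  tabs <- list(s = list(S1 = new_site_allele_table(
    "S1", allele_row(5, "ins", 1, "T", 900), 100)))
  sm <- compute_cohort_summary(tabs)
  expect_equal(sm$insertion_fraction, 1)
  expect_equal(sm$deletion_fraction, 0)
})

test_that("off-target verdicts distinguish wild-type, mutated and no-data", {
  tabs <- list(s1 = list(
    ot1 = table_from_counts("ot1", 1000),
    ot2 = new_site_allele_table("ot2", allele_row(10, "del", 2, "AT", 300),
                                700),
    ot3 = table_from_counts("ot3", 0)))
  sc <- offtarget_screen(tabs, filter_params(100, 0.005))
  v <- setNames(sc$verdict, sc$site_id)
  expect_equal(unname(v["ot1"]), "wild_type_only")
  expect_equal(unname(v["ot2"]), "mutated")
  expect_equal(unname(v["ot3"]), "no_data")
})

test_that("a 108-site x 6-sample wild-type screen reports 648 wild-type-only positions", {
  set.seed(53)
  tabs <- lapply(1:6, function(s) {
    tt <- lapply(1:108, function(i) {
      # a few sporadic error-level observations, all below the filter
      noise <- rbinom(1, 200, 0.001)
      al <- if (noise > 0) allele_row(50, "del", 1, "A", noise) else NULL
      if (is.null(al)) table_from_counts(paste0("ot", i), 200)
      else new_site_allele_table(paste0("ot", i), al, 200 - noise)
    })
    names(tt) <- paste0("ot", 1:108)
    tt
  })
  names(tabs) <- paste0("Tu", 1:6)
  sc <- offtarget_screen(tabs, scaled_filter_params(200))
  ct <- attr(sc, "counts")
  expect_equal(unname(ct["positions"]), 648)
  expect_equal(unname(ct["wild_type_only"]), 648)
})

test_that("surveyor estimator matches the analytic correction and is monotone", {
  expect_equal(surveyor_indel_fraction(100, 0), 0)
  expect_equal(surveyor_indel_fraction(81, 19), 1 - sqrt(0.81))
  expect_equal(surveyor_indel_fraction(81, 19), 0.1)
  expect_equal(surveyor_indel_fraction(25, c(50, 25)), 0.5)
  # monotone increasing in the cleaved fraction
  fr <- vapply(seq(0, 0.95, by = 0.05),
               function(f) surveyor_indel_fraction(1 - f, f), 0)
  expect_true(all(diff(fr) > 0))
  expect_warning(expect_equal(surveyor_indel_fraction(0, 10), 1), "saturated")
  expect_error(surveyor_indel_fraction(0, 0), "positive")
})

test_that("indel calls export to TSV and minimal VCF", {
  panel <- tiny_panel(1, seed = 54)
  amp <- panel$amplicon_seq[1]
  tab <- new_site_allele_table(
    "S1", allele_row(100, "del", 3, substr(amp, 101, 103), 400), 600)
  tsv <- tempfile(fileext = ".tsv")
  write_indel_calls(list(tab), tsv, "tsv")
  got <- read.delim(tsv)
  expect_equal(got$support, 400)
  vcf <- tempfile(fileext = ".vcf")
  write_indel_calls(list(tab), vcf, "vcf", panel = panel)
  lines <- readLines(vcf)
  expect_true(any(grepl("^##fileformat=VCFv4.2", lines)))
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 1)
  f <- strsplit(body, "\t")[[1]]
  expect_equal(f[2], "100")                       # 1-based anchor
  expect_equal(nchar(f[4]) - nchar(f[5]), 3)      # deletion of 3 bp
})
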