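test_that("binomial p-value closed forms hold exactly", {
  expect_equal(binomial_pvalue(10, 10, 0.01), 1)
  expect_equal(binomial_pvalue(0, 7, 0.01), 0.01^7)
  expect_equal(binomial_pvalue(0, 1, 0.001), 0.001)
  expect_error(binomial_pvalue(5, 10, 0), "p_err")
  expect_error(binomial_pvalue(5, 10, 1), "p_err")
})

test_that("binomial p-value matches term-by-term summation", {
  for (p_err in c(1e-3, 0.01)) {
    for (n_tot in c(1, 5, 10, 50, 120)) {
      for (n_ref in unique(round(seq(0, n_tot, length.out = 8)))) {
        want <- binom_cdf_sum(n_ref, n_tot, 1 - p_err)
        got <- binomial_pvalue(n_ref, n_tot, p_err)
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
})

test_that("p-value decreases as mismatches increase at fixed coverage", {
  n_tot <- 60
  p <- binomial_pvalue(n_tot - (0:20), n_tot, 0.001)
  expect_true(all(diff(p) <= 0))
})

test_that("fractional weights round half-up before testing", {
  # n_ref 4.5 -> 5, n_tot 9.5 -> 10
  expect_equal(binomial_pvalue(4.5, 9.5, 0.01),
               stats::pbinom(5, 10, 0.99))
})

test_that("multi-mapper weights: uniform splitting vs raw counts", {
  set.seed(50)
  ref <- reference_set("rRNA", c("r1", "r2", "r3"),
                       replicate(3, random_dna(40)),
                       subtype = c("18S", "18S", "28S"))
  mm <- function(pos, rb, qb) {
    data.frame(ref_pos = pos, ref_base = rb, read_base = qb,
               stringsAsFactors = FALSE)
  }
  # one sequence, count 6, 3 hits, mismatch at ref pos 12 of each
  hits <- fake_hits(c("r1", "r2", "r3"), c(10L, 10L, 10L),
                    c(20L, 20L, 20L),
                    mismatches = list(
                      mm(12L, substr(ref$entries$sequence[1], 12, 12), "A"),
                      mm(12L, substr(ref$entries$sequence[2], 12, 12), "A"),
                      mm(12L, substr(ref$entries$sequence[3], 12, 12), "A")))
  rec <- fake_record("S", 6L, hits)
  adj <- pile_mismatches(rec, ref, "uniform_adjusted")
  expect_equal(nrow(adj), 3L)
  expect_equal(adj$n_mut, rep(2, 3))
  raw <- pile_mismatches(rec, ref, "raw")
  expect_equal(raw$n_mut, rep(6, 3))
  # raw >= adjusted everywhere; split weights conserve the count
  expect_true(all(raw$n_mut >= adj$n_mut))
  expect_equal(sum(adj$n_mut), 6)
  # n_ref: positions covered with the reference base get the weight
  expect_equal(adj$n_ref, rep(0, 3))
  expect_equal(adj$n_tot, adj$n_ref + adj$n_mut)
})

test_that("pileup equals an independent per-position tally", {
  set.seed(51)
  refseq <- random_dna(60)
  ref <- reference_set("rRNA", "r1", refseq, subtype = "18S")
  idx <- build_index(ref, 6L)
  # 100 reads over a planted modified base at pos 30, fraction 0.3
  n <- 100
  starts <- sample(15:25, n, replace = TRUE)
  modded <- stats::runif(n) < 0.3
  alt <- setdiff(c("A", "C", "G", "T"), substr(refseq, 30, 30))[1]
  reads <- vapply(seq_len(n), function(i) {
    s <- substr(refseq, starts[i], starts[i] + 19L)
    if (modded[i]) substr(s, 30 - starts[i] + 1, 30 - starts[i] + 1) <- alt
    s
  }, character(1))
  uq <- collapse_reads(reads)
  recs <- do.call(rbind, lapply(seq_len(nrow(uq)), function(i) {
    fake_record(uq$sequence[i], uq$count[i],
                align_all(uq$sequence[i], idx,
                          alignment_policy(1, both_strands = FALSE)))
  }))
  piled <- pile_mismatches(recs, ref, "raw")
  site <- piled[piled$position == 30 & piled$alt_base == alt, ]
  expect_equal(site$n_mut, sum(modded))
  expect_equal(site$n_tot, n)
  expect_equal(site$n_ref, n - sum(modded))
})

test_that("site calling filters on coverage and corrects p-values", {
  sites <- data.frame(
    ref_id = c("r1", "r1", "r2"), position = c(5L, 9L, 3L),
    ref_base = "A", alt_base = "G",
    n_ref = c(35, 4, 50), n_mut = c(15, 2, 0),
    n_tot = c(50, 6, 50), stringsAsFactors = FALSE)
  called <- call_sites(sites, mismatch_config(min_coverage = 10))
  expect_equal(nrow(called), 2L)          # low-coverage site excluded
  expect_false(9L %in% called$position)
  planted <- called[called$position == 5L, ]
  expect_true(planted$significant)        # 30% mismatch at cov 50
  expect_true(planted$p_value < 1e-20)
  expect_false(called$significant[called$position == 3L])
  expect_equal(called$q_value,
               stats::p.adjust(called$p_value, "BH"))
})

test_that("null sites at the base-calling error rate are calibrated", {
  set.seed(52)
  n_sites <- 500
  cov <- 50
  p_err <- 0.001
  n_mut <- stats::rbinom(n_sites, cov, p_err)
  p <- binomial_pvalue(cov - n_mut, cov, p_err)
  rate <- mean(p <= 0.05)
  true_rate <- stats::pbinom(cov - 1, cov, 1 - p_err)  # P(>=1 mismatch)
  se <- sqrt(true_rate * (1 - true_rate) / n_sites)
  expect_lt(abs(rate - true_rate), 3 * se + 1e-12)
})

test_that("EMS/TUS statistics count sequences with significant sites", {
  mm <- function(pos, qb) {
    data.frame(ref_pos = pos, ref_base = "A", read_base = qb,
               stringsAsFactors = FALSE)
  }
  recs <- rbind(
    fake_record("S1", 3L, fake_hits("r1", 1L, 20L,
                                    mismatches = list(mm(10L, "G")))),
    fake_record("S2", 2L, fake_hits("r1", 5L, 24L,
                                    mismatches = list(mm(12L, "T")))),
    fake_record("S3", 1L, fake_hits("r1", 1L, 20L)))
  recs$category <- c("tsRNA", "tsRNA", "miRNA")
  sites <- data.frame(ref_id = "r1", position = 10L, ref_base = "A",
                      alt_base = "G", n_ref = 10, n_mut = 5,
                      n_tot = 15, p_value = 1e-9, q_value = 1e-9,
                      significant = TRUE, stringsAsFactors = FALSE)
  tab <- category_mismatch_stats(recs, sites)
  expect_equal(tab$EMS[tab$category == "tsRNA"], 1)
  expect_equal(tab$TUS[tab$category == "tsRNA"], 2)
  expect_equal(tab$percentage[tab$category == "tsRNA"], 50)
  expect_equal(tab$percentage[tab$category == "miRNA"], 0)
  # no significant sites -> all zero
  sites$significant <- FALSE
  expect_true(all(category_mismatch_stats(recs, sites)$percentage == 0))
})
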