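test_that("RPM normalization follows reads per million clean reads", {
  recs <- rbind(fake_record("AAAA", 3L, fake_hits("m1", 1L, 4L)),
                fake_record("CCCC", 7L, fake_hits("r1", 1L, 4L)))
  recs$category <- c("miRNA", "rsRNA")
  st <- preprocess_stats(n_input_reads = 10L, n_clean_reads = 10L,
                         n_unique_sequences = 2L)
  sm <- summarize_sample(recs, st)
  tab <- sm$category_table
  expect_equal(tab$rpm[tab$category == "miRNA"], 3e5)
  expect_equal(tab$rpm[tab$category == "rsRNA"], 7e5)
  expect_equal(sum(tab$rpm), 1e6)
  expect_equal(sum(tab$reads), st$n_clean_reads)
})

test_that("count mismatch between annotation and stats is a hard error", {
  recs <- fake_record("AAAA", 3L, fake_hits("m1", 1L, 4L))
  st <- preprocess_stats(n_input_reads = 5L, n_clean_reads = 5L)
  expect_error(summarize_sample(recs, st), "pipeline bug")
})

test_that("an all-unannotated sample still sums RPM to one million", {
  recs <- rbind(fake_record("AAAA", 4L, fake_hits(character(0),
                                                  integer(0),
                                                  integer(0))),
                fake_record("CCCC", 6L, fake_hits(character(0),
                                                  integer(0),
                                                  integer(0))))
  recs$category <- "unannotated"
  recs$genome_match <- NA_character_
  st <- preprocess_stats(n_input_reads = 10L, n_clean_reads = 10L)
  sm <- summarize_sample(recs, st)
  expect_equal(unique(sm$category_table$category), "unannotated")
  expect_equal(sum(sm$category_table$rpm), 1e6)
  expect_equal(unique(sm$category_table$genome_match), "NA")
})

test_that("length table marginals equal a direct recount", {
  tmp <- withr::local_tempdir()
  fxdir <- file.path(tmp, "fx")
  fx <- generate_fixture(small_fixture_spec(seed = 61), dir = fxdir)
  res <- run_pipeline(run_config(
    input = file.path(fxdir, "reads.fastq"),
    bundle = file.path(fxdir, "bundle.yaml"),
    adapter = fx$spec$adapter))
  lt <- res$summary$length_table
  raw_len <- nchar(fx$reads$sequence) - nchar(fx$spec$adapter)
  want <- table(raw_len)
  got <- tapply(lt$reads, lt$length, sum)
  expect_equal(as.integer(got[names(want)]), as.integer(want))
  expect_equal(sum(lt$reads), res$stats$n_clean_reads)
})

test_that("pipeline writes the fixed output layout deterministically", {
  tmp <- withr::local_tempdir()
  fxdir <- file.path(tmp, "fx")
  fx <- generate_fixture(small_fixture_spec(seed = 62), dir = fxdir)
  cfg <- function(out) {
    run_config(input = file.path(fxdir, "reads.fastq"),
               bundle = file.path(fxdir, "bundle.yaml"),
               adapter = fx$spec$adapter, out = out)
  }
  run_pipeline(cfg(file.path(tmp, "out1")))
  run_pipeline(cfg(file.path(tmp, "out2")))
  expected <- c("summary.tsv", "annotation.tsv", "length_dist.tsv",
                file.path("tsrna_profiles", "coverage.tsv"),
                file.path("tsrna_profiles", "classes.tsv"),
                file.path("rsrna_profiles", "coverage.tsv"),
                file.path("rsrna_profiles", "subtype_expression.tsv"),
                file.path("mismatch", "sites.tsv"),
                file.path("mismatch", "category_stats.tsv"))
  for (f in expected) {
    expect_true(file.exists(file.path(tmp, "out1", f)), info = f)
    expect_identical(readLines(file.path(tmp, "out1", f)),
                     readLines(file.path(tmp, "out2", f)),
                     info = f)
  }
  expect_true(file.exists(file.path(tmp, "out1", "run_log.txt")))
})

test_that("skip-mismatch leaves other outputs unchanged", {
  tmp <- withr::local_tempdir()
  fxdir <- file.path(tmp, "fx")
  fx <- generate_fixture(small_fixture_spec(seed = 63), dir = fxdir)
  base <- run_config(input = file.path(fxdir, "reads.fastq"),
                     bundle = file.path(fxdir, "bundle.yaml"),
                     adapter = fx$spec$adapter,
                     out = file.path(tmp, "full"))
  run_pipeline(base)
  skip <- base
  skip$out <- file.path(tmp, "skipped")
  skip$skip_mismatch <- TRUE
  run_pipeline(skip)
  expect_false(dir.exists(file.path(tmp, "skipped", "mismatch")))
  expect_identical(
    readLines(file.path(tmp, "full", "annotation.tsv")),
    readLines(file.path(tmp, "skipped", "annotation.tsv")))
  expect_identical(
    readLines(file.path(tmp, "full", "summary.tsv")),
    readLines(file.path(tmp, "skipped", "summary.tsv")))
})

test_that("empty input after filtering yields a zero summary, no error", {
  tmp <- withr::local_tempdir()
  fxdir <- file.path(tmp, "fx")
  generate_fixture(small_fixture_spec(seed = 64), dir = fxdir)
  path <- file.path(tmp, "tiny.fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII",
               "@r2", "ACGTNACGTACGTACGTACGT", "+",
               strrep("I", 21)), path)
  expect_warning(
    res <- run_pipeline(run_config(input = path,
                                   bundle = file.path(fxdir,
                                                      "bundle.yaml"),
                                   out = file.path(tmp, "empty_out"))),
    "no reads survived")
  expect_equal(res$stats$n_clean_reads, 0L)
  expect_equal(res$stats$n_discarded_length, 1L)
  expect_equal(res$stats$n_discarded_alphabet, 1L)
  expect_true(file.exists(file.path(tmp, "empty_out", "summary.tsv")))
})

test_that("missing inputs fail fast with the offending path", {
  expect_error(run_pipeline(run_config(input = "does_not_exist.fq",
                                       bundle = "also_missing.yaml")),
               "does_not_exist.fq")
})
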