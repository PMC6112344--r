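test_that("a planted substring is found at its exact coordinates", {
  set.seed(10)
  ref <- reference_set("genome", "chr1", random_dna(200))
  idx <- build_index(ref)
  q <- substr(ref$entries$sequence, 11, 30)
  hits <- align_all(q, idx, alignment_policy(0))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 11L)
  expect_equal(hits$end, 30L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$n_mismatch, 0L)
  # reverse complement maps to the same coordinates on the minus strand
  rc_hits <- align_all(revcomp(q), idx, alignment_policy(0))
  expect_equal(rc_hits$start, 11L)
  expect_equal(rc_hits$end, 30L)
  expect_equal(rc_hits$strand, "-")
})

test_that("matcher equals the brute-force oracle at m in 0..2", {
  set.seed(11)
  ref <- reference_set("genome", c("chrA", "chrB"),
                       c(random_dna(1500), random_dna(700)))
  cache <- new.env()
  for (k in c(6L, 12L)) {         # k=6 seeds all strata; k=12 forces
    idx <- build_index(ref, k)    # the full-scan fallback at m >= 1
    for (i in 1:40) {
      q <- if (i %% 2 == 0) {
        random_dna(20)
      } else {                    # planted with 0-2 substitutions
        src <- if (i %% 4 == 1) "chrA" else "chrB"
        s <- sample(nchar(ref$entries$sequence[
          match(src, ref$entries$ref_id)]) - 19, 1)
        raw <- substr(ref$entries$sequence[
          match(src, ref$entries$ref_id)], s, s + 19)
        mutate_dna(if (i %% 3 == 0) revcomp(raw) else raw,
                   sample(0:2, 1))
      }
      for (m in 0:2) {
        got <- align_all(q, idx, alignment_policy(m, strata = FALSE))
        want <- naive_align(q, ref, m, cache = cache)
        expect_equal(hit_key(got), hit_key(want),
                     info = sprintf("k=%d i=%d m=%d", k, i, m))
      }
    }
  }
})

test_that("hit sets grow monotonically with the mismatch allowance", {
  set.seed(12)
  ref <- reference_set("genome", "chr", random_dna(2000))
  idx <- build_index(ref, 6L)
  for (i in 1:20) {
    s <- sample(1980, 1)
    q <- mutate_dna(substr(ref$entries$sequence, s, s + 19),
                    sample(0:2, 1))
    keys <- lapply(0:2, function(m) {
      hit_key(align_all(q, idx, alignment_policy(m, strata = FALSE)))
    })
    # a placement found at m is found at m+1 (keys embed n_mismatch,
    # compare on coordinates only)
    coords <- lapply(0:2, function(m) {
      h <- align_all(q, idx, alignment_policy(m, strata = FALSE))
      paste(h$ref_id, h$start, h$strand)
    })
    expect_true(all(coords[[1]] %in% coords[[2]]))
    expect_true(all(coords[[2]] %in% coords[[3]]))
  }
})

test_that("aligning the reverse complement swaps strands only", {
  set.seed(13)
  ref <- reference_set("genome", "chr", random_dna(800))
  idx <- build_index(ref, 6L)
  for (i in 1:10) {
    q <- mutate_dna(substr(ref$entries$sequence, i * 50, i * 50 + 21),
                    1)
    a <- align_all(q, idx, alignment_policy(1, strata = FALSE))
    b <- align_all(revcomp(q), idx, alignment_policy(1, strata = FALSE))
    flip <- c(`+` = "-", `-` = "+")
    expect_equal(sort(paste(a$ref_id, a$start, flip[a$strand],
                            a$n_mismatch)),
                 sort(paste(b$ref_id, b$start, b$strand,
                            b$n_mismatch)))
  }
})

test_that("strata keeps only minimum-mismatch placements", {
  # reference carries an exact copy and a 1-substitution copy
  set.seed(14)
  core <- random_dna(20)
  ref <- reference_set("genome", "chr",
                       paste0(random_dna(50), core, random_dna(50),
                              mutate_dna(core, 1), random_dna(50)))
  idx <- build_index(ref, 6L)
  all_hits <- align_all(core, idx, alignment_policy(1, strata = FALSE,
                                                    both_strands = FALSE))
  expect_equal(sort(all_hits$n_mismatch), c(0L, 1L))
  best <- align_all(core, idx, alignment_policy(1, strata = TRUE,
                                                both_strands = FALSE))
  expect_equal(best$n_mismatch, 0L)
  expect_equal(best$start, 51L)
})

test_that("mismatch detail reports reference positions and bases", {
  ref <- reference_set("genome", "chr",
                       "AAAAAAAAAACCCCCCCCCCGGGGGGGGGG")
  idx <- build_index(ref, 6L)
  q <- "AAAAAAAAAACCCCCACCCC"            # C->A at reference pos 16
  h <- align_all(q, idx, alignment_policy(1, both_strands = FALSE))
  expect_equal(nrow(h), 1L)
  mm <- h$mismatches[[1]]
  expect_equal(mm$ref_pos, 16L)
  expect_equal(mm$ref_base, "C")
  expect_equal(mm$read_base, "A")
})

test_that("reference N never matches and short queries warn", {
  ref <- reference_set("genome", "chr",
                       "ACGTACGTNCGTACGTACGTACGT")
  idx <- build_index(ref, 6L)
  q <- substr("ACGTACGTACGTACGTACGTACGT", 1, 20)  # N replaced by A
  h0 <- align_all(q, idx, alignment_policy(0, both_strands = FALSE))
  expect_equal(nrow(h0), 0L)
  h1 <- align_all(q, idx, alignment_policy(1, both_strands = FALSE))
  # the ACGT-periodic reference admits placements at offsets 1 and 5,
  # each with the N as the single mismatch
  expect_true(nrow(h1) > 0L)
  expect_true(all(h1$n_mismatch == 1L))
  expect_true(all(vapply(h1$mismatches,
                         function(m) m$ref_base == "N", logical(1))))
  expect_warning(res <- align_all("ACGT", idx, alignment_policy(0)),
                 "shorter than seed")
  expect_equal(nrow(res), 0L)
})

test_that("SAM export writes mandatory columns and NM tags", {
  set.seed(15)
  ref <- reference_set("rRNA", "18S_rRNA_1", random_dna(100),
                       subtype = "18S")
  idx <- build_index(ref, 6L)
  q <- substr(ref$entries$sequence, 21, 40)
  h <- align_many(c(q, revcomp(q)), idx, alignment_policy(0))
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(h, ref, path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  expect_equal(length(body), 2L)
  f <- strsplit(body, "\t")
  expect_equal(as.integer(vapply(f, `[`, "", 4)), c(21L, 21L))
  expect_setequal(vapply(f, `[`, "", 2), c("0", "16"))
  expect_true(all(vapply(f, `[`, "", 12) == "NM:i:0"))
  # both records carry the reference-orientation sequence
  expect_true(all(vapply(f, `[`, "", 10) == q))
})
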