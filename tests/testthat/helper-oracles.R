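# Independent oracles and small builders shared across tests.

# Brute-force aligner: raw-byte comparison of the query against every
# window of every reference entry, both strands.  Deliberately shares
# no code with the package's seed-and-extend matcher.
naive_align <- function(query, refset, m, both_strands = TRUE,
                        cache = NULL) {
  q <- toupper(query)
  L <- nchar(q)
  parts <- list()
  for (r in seq_len(nrow(refset$entries))) {
    ref <- refset$entries$sequence[r]
    n <- nchar(ref)
    if (n < L) next
    key <- paste(r, L)
    mat <- if (!is.null(cache) && !is.null(cache[[key]])) {
      cache[[key]]
    } else {
      wins <- substring(ref, 1:(n - L + 1L), L:n)
      mm <- vapply(wins, charToRaw, raw(L), USE.NAMES = FALSE)
      if (!is.null(cache)) cache[[key]] <- mm
      mm
    }
    if (L == 1L) mat <- matrix(mat, nrow = 1L)
    for (strand in c("+", "-")[c(TRUE, both_strands)]) {
      oq <- if (strand == "+") q else revcomp(q)
      cnt <- colSums(mat != charToRaw(oq))
      hit <- which(cnt <= m)
      if (length(hit)) {
        parts[[length(parts) + 1L]] <- data.frame(
          ref_id = refset$entries$ref_id[r], start = hit,
          end = hit + L - 1L, strand = strand,
          n_mismatch = as.integer(cnt[hit]), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(parts, list(data.frame(
    ref_id = character(), start = integer(), end = integer(),
    strand = character(), n_mismatch = integer(),
    stringsAsFactors = FALSE))))
  out <- out[order(out$ref_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

hit_key <- function(df) {
  sort(paste(df$ref_id, df$start, df$end, df$strand, df$n_mismatch))
}

# Term-by-term binomial CDF: P(X <= k), X ~ Binomial(n, p), summed in
# log space, independent of pbinom.
binom_cdf_sum <- function(k, n, p) {
  i <- 0:k
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
        collapse = "")
}

# substitute n_sub random positions of a DNA string
mutate_dna <- function(s, n_sub) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  for (i in sample(seq_along(ch), n_sub)) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

# a one-row annotation-record-like data.frame with given hits
fake_record <- function(sequence, count, hits) {
  out <- data.frame(sequence = sequence, count = count,
                    genome_match = "MG", category = "rsRNA",
                    detail = "other", n_hits = nrow(hits),
                    stringsAsFactors = FALSE)
  out$hits <- list(hits)
  out
}

# alignment-shaped hits data.frame builder
fake_hits <- function(ref_id, start, end, strand = "+",
                      mismatches = NULL) {
  n <- length(ref_id)
  out <- data.frame(query = rep("", n), ref_id = ref_id, start = start,
                    end = end, strand = rep_len(strand, n),
                    n_mismatch = vapply(seq_len(n), function(i) {
                      if (is.null(mismatches)) 0L
                      else nrow(mismatches[[i]])
                    }, integer(1)), stringsAsFactors = FALSE)
  out$mismatches <- if (is.null(mismatches)) {
    replicate(n, data.frame(ref_pos = integer(),
                            ref_base = character(),
                            read_base = character(),
                            stringsAsFactors = FALSE),
              simplify = FALSE)
  } else mismatches
  out
}

# small, fast fixture for module-level pipeline tests
small_fixture_spec <- function(seed = 11L, ...) {
  fixture_spec(seed = seed, genome_length = 3000L, n_mirna = 3L,
               n_trna = 2L, n_rrna = 4L, n_pirna = 3L,
               reads_per_source = 80L, n_random_reads = 5L, ...)
}
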