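# Ungapped short-sequence matcher with Bowtie-v-mode-like semantics:
# all placements of a query on a reference set with at most m
# substitutions (m in 0..2), both strands, optional best-stratum
# filtering.  Seed-and-extend with pigeonhole seeding (m+1 disjoint
# blocks; any placement with <= m mismatches leaves one block exact, so
# its k-prefix is an exact seed) guarantees full sensitivity whenever
# floor(L/(m+1)) >= k; shorter queries fall back to a full scan.

#' Alignment policy
#'
#' @param max_mismatch maximum substitutions m (0, 1 or 2; ungapped).
#' @param strata keep only placements with the minimum observed
#'   mismatch count for each query.
#' @param both_strands search the reverse complement as well.
#' @return an \code{alignment_policy} object.
#' @export
alignment_policy <- function(max_mismatch = 0L, strata = TRUE,
                             both_strands = TRUE) {
  max_mismatch <- as.integer(max_mismatch)
  stopifnot(max_mismatch %in% 0:2)
  structure(list(max_mismatch = max_mismatch,
                 strata = isTRUE(strata),
                 both_strands = isTRUE(both_strands)),
            class = "alignment_policy")
}

#' Reverse-complement DNA strings
#'
#' @param x character vector over A/C/G/T/N.
#' @return reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           intToUtf8(rev(utf8ToInt(s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Build an exact k-mer seed index over a reference set
#'
#' @param refset a \code{reference_set}.
#' @param k seed length (default 12; must be >= 4).
#' @return a \code{seed_index}: k-mer hash plus integer-encoded
#'   reference sequences, deterministic for a given input.
#' @export
build_index <- function(refset, k = 12L) {
  k <- as.integer(k)
  if (k < 4L) stop("seed length k must be >= 4")
  stopifnot(inherits(refset, "reference_set"))
  seqs <- refset$entries$sequence
  kmap <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_along(seqs)) {
    n <- nchar(seqs[r])
    if (n < k) next
    km <- substring(seqs[r], 1:(n - k + 1L), k:n)
    sp <- split(seq_along(km), km)
    # N-containing seeds are unusable (N never matches a read base)
    sp <- sp[!grepl("N", names(sp), fixed = TRUE)]
    for (key in names(sp)) {
      kmap[[key]] <- rbind(kmap[[key]],
                           cbind(rep.int(r, length(sp[[key]])),
                                 sp[[key]]))
    }
  }
  structure(list(
    set_name = refset$name,
    ref_ids = refset$entries$ref_id,
    subtypes = refset$entries$subtype,
    seqs = seqs,
    ints = lapply(seqs, utf8ToInt),
    lens = nchar(seqs),
    k = k,
    kmap = kmap
  ), class = "seed_index")
}

empty_alignments <- function() {
  out <- data.frame(query = character(), ref_id = character(),
                    start = integer(), end = integer(),
                    strand = character(), n_mismatch = integer(),
                    stringsAsFactors = FALSE)
  out$mismatches <- list()
  out
}

#' Find all placements of a query on an indexed reference set
#'
#' Returns every placement with at most \code{policy$max_mismatch}
#' substitutions (no indels), on both strands if enabled.  Coordinates
#' are 1-based inclusive on the forward reference; for minus-strand
#' placements the mismatch detail reports the read base after
#' reverse-complementing the query into reference orientation.
#' Reference N bases never match.  With \code{strata}, only placements
#' carrying the minimum observed mismatch count are kept.  Queries
#' shorter than the seed length yield an empty result with a warning.
#'
#' @param query DNA string over A/C/G/T.
#' @param index a \code{seed_index} from [build_index()].
#' @param policy an [alignment_policy()].
#' @return data.frame of alignments sorted by (ref_id, start, strand):
#'   columns query, ref_id, start, end, strand, n_mismatch and a list
#'   column \code{mismatches} of data.frames (ref_pos, ref_base,
#'   read_base).
#' @export
align_all <- function(query, index, policy = alignment_policy()) {
  stopifnot(inherits(index, "seed_index"))
  q <- toupper(query)
  L <- nchar(q)
  if (L < index$k) {
    warning("query shorter than seed length (", L, " < ", index$k,
            "); no alignment attempted")
    return(empty_alignments())
  }
  m <- policy$max_mismatch
  rows <- align_one_strand(q, index, m, "+")
  if (policy$both_strands) {
    rows <- c(rows, align_one_strand(revcomp(q), index, m, "-"))
  }
  if (length(rows) == 0L) return(empty_alignments())
  out <- do.call(rbind, lapply(rows, function(h) {
    data.frame(query = q, ref_id = h$ref_id, start = h$start,
               end = h$end, strand = h$strand,
               n_mismatch = h$n_mismatch, stringsAsFactors = FALSE)
  }))
  out$mismatches <- lapply(rows, `[[`, "mismatches")
  if (policy$strata && nrow(out) > 0L) {
    out <- out[out$n_mismatch == min(out$n_mismatch), , drop = FALSE]
  }
  ord <- order(out$ref_id, out$start, out$strand)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# All hits of one oriented query sequence (already in reference
# orientation); strand is a label only.
align_one_strand <- function(oq, index, m, strand) {
  qints <- utf8ToInt(oq)
  L <- length(qints)
  b <- L %/% (m + 1L)
  cand <- if (b >= index$k) {
    pigeonhole_candidates(oq, index, m, b)
  } else {
    full_scan_candidates(index, L)
  }
  if (is.null(cand) || nrow(cand) == 0L) return(list())
  hits <- list()
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1L]
    s <- cand[i, 2L]
    refints <- index$ints[[r]]
    if (s < 1L || s + L - 1L > index$lens[r]) next
    window <- refints[s:(s + L - 1L)]
    diff <- which(window != qints)
    if (length(diff) > m) next
    mm <- if (length(diff)) {
      data.frame(ref_pos = s + diff - 1L,
                 ref_base = strsplit(intToUtf8(window[diff]), "")[[1]],
                 read_base = strsplit(intToUtf8(qints[diff]), "")[[1]],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(ref_pos = integer(), ref_base = character(),
                 read_base = character(), stringsAsFactors = FALSE)
    }
    hits[[length(hits) + 1L]] <- list(
      ref_id = index$ref_ids[r], start = s, end = s + L - 1L,
      strand = strand, n_mismatch = length(diff), mismatches = mm)
  }
  hits
}

pigeonhole_candidates <- function(oq, index, m, b) {
  k <- index$k
  refs <- integer(0)
  starts <- integer(0)
  for (i in 0:m) {
    off <- i * b
    key <- substr(oq, off + 1L, off + k)
    mat <- index$kmap[[key]]
    if (!is.null(mat)) {
      refs <- c(refs, mat[, 1L])
      starts <- c(starts, mat[, 2L] - off)
    }
  }
  if (length(refs) == 0L) return(NULL)
  unique(cbind(refs, starts))
}

full_scan_candidates <- function(index, L) {
  parts <- lapply(seq_along(index$lens), function(r) {
    noff <- index$lens[r] - L + 1L
    if (noff < 1L) return(NULL)
    cbind(rep.int(r, noff), seq_len(noff))
  })
  do.call(rbind, parts)
}

#' Align many queries against an indexed reference set
#'
#' @param queries character vector of DNA strings.
#' @param index a \code{seed_index}.
#' @param policy an [alignment_policy()].
#' @return one alignment data.frame (see [align_all()]) with rows from
#'   all queries, in query order.
#' @export
align_many <- function(queries, index, policy = alignment_policy()) {
  parts <- lapply(queries, align_all, index = index, policy = policy)
  out <- do.call(rbind, c(parts, list(empty_alignments())))
  rownames(out) <- NULL
  out
}

#' Export alignments as minimal SAM
#'
#' Writes the mandatory columns plus the NM tag; minus-strand records
#' carry the reverse-complemented (reference-orientation) sequence and
#' flag 16, matching SAM convention.
#'
#' @param alignments alignment data.frame from [align_all()].
#' @param refset the \code{reference_set} aligned against (for
#'   \code{@SQ} headers).
#' @param path output path.
#' @export
write_sam <- function(alignments, refset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  e <- refset$entries
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", e$ref_id, nchar(e$sequence)),
             con)
  if (nrow(alignments) == 0L) return(invisible(path))
  seqs <- ifelse(alignments$strand == "-", revcomp(alignments$query),
                 alignments$query)
  lines <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                   alignments$query,
                   ifelse(alignments$strand == "-", 16L, 0L),
                   alignments$ref_id, alignments$start,
                   nchar(alignments$query), seqs,
                   alignments$n_mismatch)
  writeLines(lines, con)
  invisible(path)
}
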