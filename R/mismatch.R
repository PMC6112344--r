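# Candidate RNA-modification site calling from mismatch pileups.
# A reference position where the mismatched-nucleotide fraction exceeds
# what base-calling error explains (binomial model) is a proxy for a
# modification that perturbed reverse transcription.

#' Mismatch-calling configuration
#'
#' @param p_err base-calling error rate in (0,1); default 0.001
#'   (Phred 30).
#' @param method \code{"uniform_adjusted"} (default; a multi-mapping
#'   sequence's count is split uniformly over its hits, assuming the
#'   multiple loci express equally) or \code{"raw"} (full count at
#'   every hit, which inflates false positives for multi-mappers).
#' @param alpha significance threshold on the corrected p-value.
#' @param min_coverage minimum (weighted) n_tot for a site to be
#'   tested.
#' @param correction multiple-testing correction: \code{"bh"},
#'   \code{"bonferroni"} or \code{"none"}.
#' @return a \code{mismatch_config} object.
#' @export
mismatch_config <- function(p_err = 0.001,
                            method = c("uniform_adjusted", "raw"),
                            alpha = 0.05, min_coverage = 10,
                            correction = c("bh", "bonferroni", "none")) {
  stopifnot(p_err > 0, p_err < 1, min_coverage >= 1, alpha > 0,
            alpha <= 1)
  structure(list(p_err = p_err, method = match.arg(method),
                 alpha = alpha, min_coverage = min_coverage,
                 correction = match.arg(correction)),
            class = "mismatch_config")
}

# round half up: the binomial is defined on integers and uniform
# splitting yields fractional weights; base round() is half-to-even.
round_half_up <- function(x) floor(x + 0.5)

#' Binomial mismatch-enrichment p-value
#'
#' Probability of observing at most \code{n_ref} perfectly matched
#' nucleotides out of \code{n_tot} when each base matches independently
#' with probability \code{1 - p_err}: the lower tail of
#' Binomial(n_tot, 1 - p_err) evaluated at the observed n_ref.  Small
#' values indicate mismatch enrichment beyond base-calling error.
#' Weighted counts are rounded half-up to integers first.
#'
#' @param n_ref weighted count of reference-matching nucleotides at the
#'   site.
#' @param n_tot weighted total coverage (n_ref + n_mut), >= 1.
#' @param p_err base-calling error rate in (0,1).
#' @return p-values in \[0,1\] (vectorized); p = 1 when n_ref = n_tot
#'   and p = p_err^n_tot when n_ref = 0.
#' @export
binomial_pvalue <- function(n_ref, n_tot, p_err) {
  if (any(p_err <= 0) || any(p_err >= 1)) {
    stop("p_err must lie strictly between 0 and 1")
  }
  nr <- round_half_up(n_ref)
  nt <- round_half_up(n_tot)
  stopifnot(all(nr >= 0), all(nr <= nt), all(nt >= 1))
  stats::pbinom(nr, nt, 1 - p_err)
}

#' Pile up mismatch and reference-support counts
#'
#' Walks every hit of every annotated sequence (alignments produced
#' with at least one allowed mismatch) and accumulates, per reference
#' position: \code{n_mut}, the weighted count of sequences mismatching
#' there (per alternative base), and \code{n_ref}, the weighted count
#' of sequences covering the position with the reference base.  Raw
#' weighting uses the full sequence count at every hit;
#' uniform_adjusted divides the count by the sequence's number of hits.
#'
#' @param records annotation data.frame rows (sequence, count, hits).
#' @param refset the \code{reference_set} the hits refer to.
#' @param method \code{"uniform_adjusted"} or \code{"raw"}.
#' @return data.frame of sites: ref_id, position, ref_base, alt_base,
#'   n_ref, n_mut, n_tot -- one row per observed (ref_id, position,
#'   alt_base), sorted by (ref_id, position, alt_base).
#' @export
pile_mismatches <- function(records, refset,
                            method = c("uniform_adjusted", "raw")) {
  method <- match.arg(method)
  e <- refset$entries
  len_of <- stats::setNames(nchar(e$sequence), e$ref_id)
  seq_of <- stats::setNames(e$sequence, e$ref_id)
  ref_env <- new.env(hash = TRUE, parent = emptyenv())   # pos -> n_ref
  mut_env <- new.env(hash = TRUE, parent = emptyenv())   # site -> n_mut
  bump <- function(env, key, w) {
    cur <- env[[key]]
    env[[key]] <- if (is.null(cur)) w else cur + w
  }
  for (i in seq_len(nrow(records))) {
    hits <- records$hits[[i]]
    if (nrow(hits) == 0L) next
    w <- if (method == "uniform_adjusted") {
      records$count[i] / nrow(hits)
    } else {
      records$count[i]
    }
    for (j in seq_len(nrow(hits))) {
      rid <- hits$ref_id[j]
      if (is.na(len_of[rid]) || hits$end[j] > len_of[rid] ||
          hits$start[j] < 1L) {
        stop("alignment coordinates outside reference: ", rid)
      }
      mm <- hits$mismatches[[j]]
      covered <- hits$start[j]:hits$end[j]
      matched <- setdiff(covered, mm$ref_pos)
      for (p in matched) bump(ref_env, paste(rid, p), w)
      if (nrow(mm) > 0L) {
        for (q in seq_len(nrow(mm))) {
          bump(mut_env, paste(rid, mm$ref_pos[q], mm$read_base[q]), w)
        }
      }
    }
  }
  keys <- ls(mut_env)
  if (length(keys) == 0L) {
    return(data.frame(ref_id = character(), position = integer(),
                      ref_base = character(), alt_base = character(),
                      n_ref = numeric(), n_mut = numeric(),
                      n_tot = numeric(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, " ", fixed = TRUE)
  rid <- vapply(parts, `[`, character(1), 1L)
  pos <- as.integer(vapply(parts, `[`, character(1), 2L))
  alt <- vapply(parts, `[`, character(1), 3L)
  n_mut <- vapply(keys, function(k) mut_env[[k]], numeric(1),
                  USE.NAMES = FALSE)
  n_ref <- vapply(paste(rid, pos), function(k) {
    v <- ref_env[[k]]
    if (is.null(v)) 0 else v
  }, numeric(1), USE.NAMES = FALSE)
  out <- data.frame(ref_id = rid, position = pos,
                    ref_base = substr(seq_of[rid], pos, pos),
                    alt_base = alt, n_ref = n_ref, n_mut = n_mut,
                    n_tot = n_ref + n_mut, stringsAsFactors = FALSE)
  out <- out[order(out$ref_id, out$position, out$alt_base), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Test piled sites for mismatch enrichment
#'
#' Sites with \code{n_tot >= min_coverage} are tested with
#' [binomial_pvalue()]; p-values are corrected per the configuration
#' and the significance flag set where the corrected value is at most
#' \code{alpha}.
#'
#' @param sites data.frame from [pile_mismatches()].
#' @param config a [mismatch_config()].
#' @return the tested sites with columns p_value, q_value and
#'   significant added, sorted by (ref_id, position); sites below the
#'   coverage floor are excluded.
#' @export
call_sites <- function(sites, config = mismatch_config()) {
  tested <- sites[sites$n_tot >= config$min_coverage, , drop = FALSE]
  if (nrow(tested) == 0L) {
    tested$p_value <- numeric(0)
    tested$q_value <- numeric(0)
    tested$significant <- logical(0)
    return(tested)
  }
  tested$p_value <- binomial_pvalue(tested$n_ref, tested$n_tot,
                                    config$p_err)
  adj <- switch(config$correction, bh = "BH",
                bonferroni = "bonferroni", none = "none")
  tested$q_value <- stats::p.adjust(tested$p_value, method = adj)
  tested$significant <- tested$q_value <= config$alpha
  tested <- tested[order(tested$ref_id, tested$position,
                         tested$alt_base), , drop = FALSE]
  rownames(tested) <- NULL
  tested
}

#' Per-category mismatch-rate statistics
#'
#' For each annotation category: TUS, the total number of unique
#' sequences, and EMS, the number of unique sequences carrying at least
#' one mismatch at a significant site; percentage = EMS / TUS * 100.
#'
#' @param records annotation data.frame (all categories).
#' @param sites called sites (from [call_sites()], typically pooled
#'   over categories); only rows with \code{significant} are used.
#' @return data.frame of (category, EMS, TUS, percentage), sorted by
#'   category.
#' @export
category_mismatch_stats <- function(records, sites) {
  sig <- sites[sites$significant, , drop = FALSE]
  sig_keys <- paste(sig$ref_id, sig$position, sig$alt_base)
  has_sig <- vapply(records$hits, function(hits) {
    if (nrow(hits) == 0L) return(FALSE)
    for (j in seq_len(nrow(hits))) {
      mm <- hits$mismatches[[j]]
      if (nrow(mm) > 0L &&
          any(paste(hits$ref_id[j], mm$ref_pos, mm$read_base) %in%
              sig_keys)) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  cats <- sort(unique(records$category))
  out <- data.frame(
    category = cats,
    EMS = vapply(cats, function(cc) {
      sum(has_sig[records$category == cc])
    }, numeric(1)),
    TUS = vapply(cats, function(cc) {
      sum(records$category == cc)
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$percentage <- ifelse(out$TUS > 0, out$EMS / out$TUS * 100, 0)
  out
}
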