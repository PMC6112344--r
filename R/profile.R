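# tsRNA derivation-locus classification and positional coverage
# profiles of tsRNAs/rsRNAs along their precursors.

TSRNA_CLASSES <- c("five_prime", "three_prime_CCA", "three_prime",
                   "internal")

#' Classify a tsRNA alignment by derivation locus
#'
#' A fragment on a mature tRNA of (intronless) length \code{L} (CCA
#' reference length L+3) is \code{five_prime} when it starts at
#' position 1, \code{three_prime_CCA} when it lies on the CCA-appended
#' reference and reaches its 3' end (position L+3), \code{three_prime}
#' when it ends exactly at L without reaching into the CCA, and
#' \code{internal} otherwise.  Precedence for fragments satisfying
#' several conditions (e.g. spanning a whole tiny precursor) is
#' five_prime > three_prime_CCA > three_prime.  Real fragment ends are
#' ragged; \code{tolerance} widens each boundary test by that many
#' bases (default 0: exact boundary equality).
#'
#' @param start,end 1-based alignment coordinates on the reference.
#' @param mature_len mature tRNA length L.
#' @param on_cca_ref whether the alignment is on the CCA-appended
#'   reference (length L+3) rather than the genomic entry (length L).
#' @param tolerance boundary wobble in nt.
#' @return character vector of classes.
#' @export
classify_tsrna <- function(start, end, mature_len, on_cca_ref = TRUE,
                           tolerance = 0L) {
  ref_len <- ifelse(on_cca_ref, mature_len + 3L, mature_len)
  if (any(end > ref_len)) {
    stop("alignment end beyond reference length (corrupt alignment)")
  }
  if (any(start < 1L | end < start)) stop("invalid alignment interval")
  out <- rep("internal", length(start))
  is3 <- end >= mature_len - tolerance & end <= mature_len
  out[is3] <- "three_prime"
  cca <- on_cca_ref & end >= mature_len + 3L - tolerance
  out[cca] <- "three_prime_CCA"
  out[start <= 1L + tolerance] <- "five_prime"
  out
}

# Best class of one sequence across its (canonicalized) tsRNA hits,
# by the classification precedence.
classify_tsrna_record <- function(hits, mature_len_of, tolerance = 0L) {
  L <- mature_len_of[hits$ref_id]
  cls <- classify_tsrna(hits$start, hits$end, L, on_cca_ref = TRUE,
                        tolerance = tolerance)
  TSRNA_CLASSES[min(match(cls, TSRNA_CLASSES))]
}

#' Classify annotated tsRNA sequences
#'
#' @param records annotation data.frame (rows with category
#'   \code{tsRNA} are classified; hits are on the mature/CCA
#'   reference).
#' @param trna_cca_set the \code{tRNA_CCA} reference set.
#' @param tolerance boundary wobble passed to [classify_tsrna()].
#' @return character vector, one class per tsRNA record (named by
#'   sequence); non-tsRNA rows are dropped.
#' @export
classify_tsrna_sample <- function(records, trna_cca_set,
                                  tolerance = 0L) {
  e <- trna_cca_set$entries
  mature_len_of <- stats::setNames(nchar(e$sequence) - 3L, e$ref_id)
  ts <- records[records$category == "tsRNA", , drop = FALSE]
  if (nrow(ts) == 0L) return(stats::setNames(character(0), character(0)))
  cls <- vapply(ts$hits, classify_tsrna_record, character(1),
                mature_len_of = mature_len_of, tolerance = tolerance)
  stats::setNames(cls, ts$sequence)
}

#' Build per-precursor coverage profiles
#'
#' Each sequence's RPM (count / total_clean_reads * 1e6) is distributed
#' over its hits -- \code{uniform_split} divides the weight by the
#' sequence's number of hits, \code{count_each} adds full weight at
#' every hit -- and added to the coverage of positions start..end of
#' each hit precursor.  Under uniform_split the summed profile RPM
#' conserves the category RPM computed directly from counts.
#'
#' @param records annotation data.frame rows of one category.
#' @param refset the \code{reference_set} the hits refer to (for
#'   lengths/subtypes).
#' @param total_clean_reads RPM denominator (> 0).
#' @param multimap_policy \code{"uniform_split"} (default) or
#'   \code{"count_each"}.
#' @return list of \code{precursor_profile} objects (ref_id, subtype,
#'   length, coverage vector in RPM, total_rpm), one per precursor with
#'   at least one assigned read; coverage is invariant to record order.
#' @export
build_profile <- function(records, refset, total_clean_reads,
                          multimap_policy = c("uniform_split",
                                              "count_each")) {
  multimap_policy <- match.arg(multimap_policy)
  stopifnot(total_clean_reads > 0)
  e <- refset$entries
  len_of <- stats::setNames(nchar(e$sequence), e$ref_id)
  subtype_of <- stats::setNames(e$subtype, e$ref_id)
  cov <- lapply(len_of, numeric)
  total <- stats::setNames(numeric(length(len_of)), names(len_of))
  for (i in seq_len(nrow(records))) {
    hits <- records$hits[[i]]
    if (nrow(hits) == 0L) next
    seq_rpm <- rpm(records$count[i], total_clean_reads)
    w <- if (multimap_policy == "uniform_split") seq_rpm / nrow(hits)
         else seq_rpm
    for (j in seq_len(nrow(hits))) {
      rid <- hits$ref_id[j]
      if (is.na(len_of[rid])) {
        stop("hit refers to unknown precursor: ", rid)
      }
      cov[[rid]][hits$start[j]:hits$end[j]] <-
        cov[[rid]][hits$start[j]:hits$end[j]] + w
      total[rid] <- total[rid] + w
    }
  }
  used <- names(total)[total > 0]
  lapply(used, function(rid) {
    structure(list(ref_id = rid, subtype = subtype_of[[rid]],
                   length = len_of[[rid]], coverage = cov[[rid]],
                   total_rpm = total[[rid]]),
              class = "precursor_profile")
  })
}

#' Aggregate tsRNA profiles by isoacceptor
#'
#' tsRNA profiles are reported per isoacceptor (e.g. Gly-GCC): gene
#' copies of one isoacceptor are summed position-wise from position 1,
#' padding shorter copies to the longest.
#'
#' @param profiles list of \code{precursor_profile}.
#' @return list of \code{precursor_profile}, one per subtype, with
#'   ref_id set to the subtype.
#' @export
aggregate_by_subtype <- function(profiles) {
  if (length(profiles) == 0L) return(list())
  subs <- vapply(profiles, `[[`, character(1), "subtype")
  lapply(sort(unique(subs)), function(st) {
    grp <- profiles[subs == st]
    len <- max(vapply(grp, `[[`, integer(1), "length"))
    cv <- numeric(len)
    for (p in grp) cv[seq_len(p$length)] <- cv[seq_len(p$length)] + p$coverage
    structure(list(ref_id = st, subtype = st, length = len,
                   coverage = cv,
                   total_rpm = sum(vapply(grp, `[[`, numeric(1),
                                          "total_rpm"))),
              class = "precursor_profile")
  })
}

#' Total expression per precursor subtype
#'
#' @param profiles list of \code{precursor_profile}.
#' @return data.frame of (subtype, rpm), sorted by subtype; group sums
#'   conserve the ungrouped total.
#' @export
subtype_expression <- function(profiles) {
  if (length(profiles) == 0L) {
    return(data.frame(subtype = character(), rpm = numeric(),
                      stringsAsFactors = FALSE))
  }
  subs <- vapply(profiles, `[[`, character(1), "subtype")
  tot <- vapply(profiles, `[[`, numeric(1), "total_rpm")
  agg <- tapply(tot, subs, sum)
  data.frame(subtype = names(agg), rpm = as.numeric(agg),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write coverage profiles as long-format TSV
#'
#' Columns ref_id, subtype, position (1-based), rpm.
#'
#' @param profiles list of \code{precursor_profile}.
#' @param path output path.
#' @export
write_profile_tsv <- function(profiles, path) {
  parts <- lapply(profiles, function(p) {
    data.frame(ref_id = p$ref_id, subtype = p$subtype,
               position = seq_len(p$length), rpm = p$coverage,
               stringsAsFactors = FALSE)
  })
  tab <- if (length(parts)) do.call(rbind, parts) else
    data.frame(ref_id = character(), subtype = character(),
               position = integer(), rpm = numeric())
  utils::write.table(format_num_df(tab), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write one profile as bedGraph
#'
#' Coordinates are converted from the internal 1-based inclusive
#' positions to bedGraph's 0-based half-open intervals (position p
#' becomes \code{[p-1, p)}); runs of equal coverage are merged.
#'
#' @param profile a \code{precursor_profile}.
#' @param path output path.
#' @export
write_bedgraph <- function(profile, path) {
  cv <- profile$coverage
  r <- rle(cv)
  ends <- cumsum(r$lengths)
  starts0 <- c(0L, ends[-length(ends)])
  keep <- r$values != 0
  tab <- data.frame(chrom = profile$ref_id, start = starts0[keep],
                    end = ends[keep],
                    value = format(r$values[keep], digits = 10,
                                   trim = TRUE, scientific = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
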