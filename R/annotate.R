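# Hierarchical sequential annotation: each unique sequence gets a
# genome-match flag (MG/UMG), computed independently, and is assigned
# to the first reference set in the hierarchy with at least one hit.
# The genome flag never blocks RNA-set annotation, which is what lets
# rRNA-derived fragments from rDNA absent from the genome assembly
# (and CCA-spanning tRNA fragments) be recovered as UMG rsRNAs/tsRNAs.

CATEGORY_OF_SET <- c(miRNA = "miRNA", rRNA = "rsRNA", tRNA = "tsRNA",
                     tRNA_CCA = "tsRNA", piRNA = "piRNA",
                     ncRNA_other = "other_ncRNA")

# Stages of the hierarchy: tRNA and tRNA_CCA are searched together as
# one tsRNA stage.
hierarchy_stages <- function(bundle) {
  lapply(bundle$hierarchy, function(nm) {
    if (nm == "tRNA" && "tRNA_CCA" %in% names(bundle$sets)) {
      c("tRNA", "tRNA_CCA")
    } else nm
  })
}

# Build (or reuse) seed indexes for the genome and all bundle sets.
bundle_indexes <- function(bundle, k = 12L) {
  idx <- list()
  if (!is.null(bundle$genome)) idx$genome <- build_index(bundle$genome, k)
  for (nm in names(bundle$sets)) {
    idx[[nm]] <- build_index(bundle$sets[[nm]], k)
  }
  idx
}

#' Flag a sequence as match-genome or unmatch-genome
#'
#' @param sequence DNA string (or vector of them).
#' @param genome_index \code{seed_index} over the genome set.
#' @param policy an [alignment_policy()].
#' @return character vector of "MG"/"UMG".
#' @export
flag_genome <- function(sequence, genome_index, policy = alignment_policy()) {
  vapply(sequence, function(s) {
    if (nrow(align_all(s, genome_index, policy)) > 0L) "MG" else "UMG"
  }, character(1), USE.NAMES = FALSE)
}

# Canonicalize tsRNA-stage hits onto the CCA-appended mature reference:
# a placement at [s, e] on the genomic tRNA entry is the same placement
# on its mature (tRNA + CCA) entry, so hits found in both sets are one
# biological placement and are deduplicated (otherwise n_hits and
# uniform-split weights would double-count).
canonicalize_tsrna_hits <- function(hits, suffix = "_mature") {
  if (nrow(hits) == 0L) return(hits)
  on_genomic <- !grepl(paste0(suffix, "$"), hits$ref_id)
  hits$ref_id[on_genomic] <- paste0(hits$ref_id[on_genomic], suffix)
  key <- paste(hits$ref_id, hits$start, hits$end, hits$strand)
  hits <- hits[!duplicated(key), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Annotate one unique sequence against a bundle
#'
#' Reference sets are queried in hierarchy order; the first set with at
#' least one hit determines the category (miRNA set to miRNA, rRNA set
#' to rsRNA, tRNA/tRNA_CCA sets to tsRNA, piRNA to piRNA, ncRNA_other
#' to other_ncRNA); lower sets are not queried after a win.  The detail
#' field collects the subtypes of the winning hits.  A sequence hitting
#' nothing is \code{unannotated} with empty hits.
#'
#' @param sequence DNA string.
#' @param count read count of the unique sequence.
#' @param bundle a \code{database_bundle}.
#' @param policy an [alignment_policy()].
#' @param indexes optional precomputed [bundle_indexes()] (built on the
#'   fly otherwise).
#' @return one-row annotation data.frame: sequence, count,
#'   genome_match, category, detail, n_hits, plus list column
#'   \code{hits}.
#' @export
annotate_sequence <- function(sequence, count, bundle,
                              policy = alignment_policy(),
                              indexes = NULL) {
  if (is.null(indexes)) indexes <- bundle_indexes(bundle)
  gm <- if (is.null(bundle$genome)) NA_character_ else
    flag_genome(sequence, indexes$genome, policy)
  category <- "unannotated"
  detail <- ""
  hits <- empty_alignments()
  for (stage in hierarchy_stages(bundle)) {
    stage_hits <- do.call(rbind, lapply(stage, function(nm) {
      align_all(sequence, indexes[[nm]], policy)
    }))
    if (!is.null(stage_hits) && nrow(stage_hits) > 0L) {
      if (identical(CATEGORY_OF_SET[[stage[1L]]], "tsRNA")) {
        stage_hits <- canonicalize_tsrna_hits(stage_hits)
      }
      category <- CATEGORY_OF_SET[[stage[1L]]]
      detail <- hit_detail(stage_hits, bundle, stage)
      hits <- stage_hits
      break
    }
  }
  out <- data.frame(sequence = sequence, count = as.integer(count),
                    genome_match = gm, category = category,
                    detail = detail, n_hits = nrow(hits),
                    stringsAsFactors = FALSE)
  out$hits <- list(hits)
  out
}

# Subtypes of the entries hit within the winning stage, unique and
# sorted for determinism, comma-joined.
hit_detail <- function(hits, bundle, stage) {
  subtype_of <- character(0)
  for (nm in stage) {
    e <- bundle$sets[[nm]]$entries
    subtype_of[e$ref_id] <- e$subtype
  }
  st <- subtype_of[hits$ref_id]
  st <- st[!is.na(st)]
  if (length(st) == 0L) return("other")
  paste(sort(unique(st)), collapse = ",")
}

#' Annotate a sample of unique sequences
#'
#' Element-wise [annotate_sequence()]; input order is preserved.
#'
#' @param unique_seqs data.frame of \code{sequence}, \code{count}.
#' @param bundle a \code{database_bundle}.
#' @param policy an [alignment_policy()].
#' @param k seed length for the indexes.
#' @return annotation data.frame, one row per unique sequence.
#' @export
annotate_sample <- function(unique_seqs, bundle,
                            policy = alignment_policy(), k = 12L) {
  indexes <- bundle_indexes(bundle, k)
  if (nrow(unique_seqs) == 0L) {
    out <- data.frame(sequence = character(), count = integer(),
                      genome_match = character(), category = character(),
                      detail = character(), n_hits = integer(),
                      stringsAsFactors = FALSE)
    out$hits <- list()
    return(out)
  }
  parts <- lapply(seq_len(nrow(unique_seqs)), function(i) {
    annotate_sequence(unique_seqs$sequence[i], unique_seqs$count[i],
                      bundle, policy, indexes)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Write the per-sequence annotation table
#'
#' TSV with one row per unique sequence; comment header records the
#' bundle hierarchy and alignment policy.
#'
#' @param records annotation data.frame from [annotate_sample()].
#' @param n_clean_reads RPM denominator.
#' @param bundle the bundle used (for the header).
#' @param policy the policy used (for the header).
#' @param path output path.
#' @export
write_annotation_tsv <- function(records, n_clean_reads, bundle,
                                 policy, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# hierarchy: ", paste(bundle$hierarchy, collapse = " > ")),
    sprintf("# policy: max_mismatch=%d strata=%s both_strands=%s",
            policy$max_mismatch, policy$strata, policy$both_strands)
  ), con)
  tab <- records[, c("sequence", "count")]
  tab$RPM <- rpm(records$count, n_clean_reads)
  tab$genome_match <- records$genome_match
  tab$category <- records$category
  tab$detail <- records$detail
  tab$n_hits <- records$n_hits
  utils::write.table(format_num_df(tab), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Reads-per-million normalization
#'
#' @param count read counts.
#' @param n_clean_reads total clean reads (the denominator; not mapped
#'   reads).
#' @return counts per million clean reads.
#' @export
rpm <- function(count, n_clean_reads) {
  stopifnot(n_clean_reads > 0)
  count / n_clean_reads * 1e6
}
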