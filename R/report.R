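# Annotation summary: sample-level tables, length distributions, RPM
# normalization, and the pipeline orchestrator.

# Deterministic numeric formatting so identical runs write identical
# bytes regardless of options(digits)/scipen.
format_num_df <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      df[[nm]] <- format(df[[nm]], digits = 12, trim = TRUE,
                         scientific = FALSE)
    }
  }
  df
}

#' Summarize an annotated sample
#'
#' Builds the category-by-genome-match table (unique sequences, reads,
#' RPM) and the per-length distribution table; verifies that category
#' read totals reconcile with the pre-processing statistics (a failure
#' is a pipeline bug, not a data property) and that RPM sums to 1e6.
#'
#' @param records annotation data.frame covering all unique sequences.
#' @param stats the sample's \code{preprocess_stats}.
#' @return a \code{sample_summary}: list of \code{stats},
#'   \code{category_table} (category, genome_match, unique_sequences,
#'   reads, rpm) and \code{length_table} (category, genome_match,
#'   length, reads, rpm).
#' @export
summarize_sample <- function(records, stats) {
  stopifnot(inherits(stats, "preprocess_stats"))
  if (sum(records$count) != stats$n_clean_reads) {
    stop("annotation read total (", sum(records$count),
         ") != n_clean_reads (", stats$n_clean_reads,
         "); pipeline bug")
  }
  gm <- ifelse(is.na(records$genome_match), "NA", records$genome_match)
  nclean <- stats$n_clean_reads
  if (nrow(records) > 0L) {
    key <- paste(records$category, gm, sep = "\r")
    agg_reads <- tapply(records$count, key, sum)
    agg_uniq <- tapply(records$count, key, length)
    parts <- strsplit(names(agg_reads), "\r", fixed = TRUE)
    category_table <- data.frame(
      category = vapply(parts, `[`, character(1), 1L),
      genome_match = vapply(parts, `[`, character(1), 2L),
      unique_sequences = as.integer(agg_uniq),
      reads = as.integer(agg_reads),
      rpm = rpm(as.numeric(agg_reads), nclean),
      stringsAsFactors = FALSE, row.names = NULL
    )
    category_table <- category_table[
      order(category_table$category, category_table$genome_match), ,
      drop = FALSE]
    rownames(category_table) <- NULL
    len <- nchar(records$sequence)
    lkey <- paste(records$category, gm, len, sep = "\r")
    lreads <- tapply(records$count, lkey, sum)
    lparts <- strsplit(names(lreads), "\r", fixed = TRUE)
    length_table <- data.frame(
      category = vapply(lparts, `[`, character(1), 1L),
      genome_match = vapply(lparts, `[`, character(1), 2L),
      length = as.integer(vapply(lparts, `[`, character(1), 3L)),
      reads = as.integer(lreads),
      rpm = rpm(as.numeric(lreads), nclean),
      stringsAsFactors = FALSE, row.names = NULL
    )
    length_table <- length_table[
      order(length_table$category, length_table$genome_match,
            length_table$length), , drop = FALSE]
    rownames(length_table) <- NULL
    stopifnot(abs(sum(category_table$rpm) - 1e6) < 1e6 * 1e-6,
              sum(length_table$reads) == nclean)
  } else {
    category_table <- data.frame(category = character(),
                                 genome_match = character(),
                                 unique_sequences = integer(),
                                 reads = integer(), rpm = numeric(),
                                 stringsAsFactors = FALSE)
    length_table <- data.frame(category = character(),
                               genome_match = character(),
                               length = integer(), reads = integer(),
                               rpm = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(stats = stats, category_table = category_table,
                 length_table = length_table),
            class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("sample_summary: %d clean reads, %d unique sequences\n",
              x$stats$n_clean_reads, x$stats$n_unique_sequences))
  print(x$category_table)
  invisible(x)
}

#' Pipeline run configuration
#'
#' @param input path to the reads file.
#' @param bundle a \code{database_bundle} or the path to a YAML bundle
#'   manifest.
#' @param format input format: fastq, fasta or collapsed.
#' @param adapter optional 3' adapter sequence; NULL disables trimming.
#' @param min_length,max_length clean-read length window.
#' @param mismatch maximum substitutions for alignment (0-2); at least
#'   1 is required for mismatch-site analysis.
#' @param strata keep only minimum-mismatch placements per sequence.
#' @param multimap multi-mapper weighting for profiles
#'   (\code{uniform_split} or \code{count_each}).
#' @param p_err,mm_method,alpha,min_coverage,correction mismatch-site
#'   calling parameters (see [mismatch_config()]).
#' @param terminal_tolerance boundary wobble for tsRNA locus classes.
#' @param skip_mismatch disable the mismatch-site stage.
#' @param seed_k seed length of the alignment index.
#' @param out optional output directory; NULL keeps results in memory.
#' @return a \code{run_config} list.
#' @export
run_config <- function(input, bundle,
                       format = c("fastq", "fasta", "collapsed"),
                       adapter = NULL, min_length = 15L,
                       max_length = 45L, mismatch = 1L, strata = TRUE,
                       multimap = c("uniform_split", "count_each"),
                       p_err = 0.001,
                       mm_method = c("uniform_adjusted", "raw"),
                       alpha = 0.05, min_coverage = 10,
                       correction = c("bh", "bonferroni", "none"),
                       terminal_tolerance = 0L, skip_mismatch = FALSE,
                       seed_k = 12L, out = NULL) {
  structure(list(
    input = input, bundle = bundle, format = match.arg(format),
    adapter = adapter, min_length = min_length,
    max_length = max_length, mismatch = as.integer(mismatch),
    strata = strata, multimap = match.arg(multimap), p_err = p_err,
    mm_method = match.arg(mm_method), alpha = alpha,
    min_coverage = min_coverage, correction = match.arg(correction),
    terminal_tolerance = as.integer(terminal_tolerance),
    skip_mismatch = isTRUE(skip_mismatch), seed_k = as.integer(seed_k),
    out = out
  ), class = "run_config")
}

#' Run the full annotation pipeline
#'
#' Pre-processing (trim, filter, collapse), hierarchical annotation
#' with genome flagging, annotation summary and length distribution,
#' tsRNA locus classification and isoacceptor profiles, rsRNA
#' precursor profiles and subtype expression, and (unless skipped)
#' mismatch-site calling with per-category EMS/TUS statistics.  When
#' \code{config$out} is set, canonical TSV outputs and a run log are
#' written there; re-running with identical inputs produces
#' byte-identical tables (the pipeline is deterministic).
#'
#' @param config a [run_config()].
#' @return (invisibly when writing) list with elements \code{unique},
#'   \code{stats}, \code{records}, \code{summary},
#'   \code{tsrna_classes}, \code{tsrna_class_table},
#'   \code{tsrna_profiles}, \code{rsrna_profiles},
#'   \code{rsrna_subtypes}, \code{mismatch} (NULL when skipped) and
#'   \code{out}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(config$input)) {
    stop("missing input file: ", config$input)
  }
  bundle <- config$bundle
  if (is.character(bundle)) {
    if (!file.exists(bundle)) stop("missing bundle manifest: ", bundle)
    bundle <- load_bundle(bundle)
  }
  pp <- preprocess(config$input, config$format, config$adapter,
                   config$min_length, config$max_length)
  policy <- alignment_policy(config$mismatch, strata = config$strata,
                             both_strands = TRUE)
  records <- annotate_sample(pp$unique, bundle, policy, k = config$seed_k)
  nclean <- pp$stats$n_clean_reads
  if (nclean == 0L) {
    warning("no reads survived pre-processing; writing empty summary")
  }
  summary <- summarize_sample(records, pp$stats)

  # tsRNA: locus classes and per-isoacceptor profiles on the mature
  # (CCA-appended) reference
  tsrna_classes <- character(0)
  tsrna_class_table <- data.frame(class = character(), reads = integer(),
                                  rpm = numeric(), stringsAsFactors = FALSE)
  tsrna_profiles <- list()
  ts_rec <- records[records$category == "tsRNA", , drop = FALSE]
  if (!is.null(bundle$sets$tRNA_CCA) && nrow(ts_rec) > 0L) {
    tsrna_classes <- classify_tsrna_sample(records, bundle$sets$tRNA_CCA,
                                           config$terminal_tolerance)
    creads <- tapply(ts_rec$count, tsrna_classes[ts_rec$sequence], sum)
    tsrna_class_table <- data.frame(
      class = names(creads), reads = as.integer(creads),
      rpm = rpm(as.numeric(creads), nclean),
      stringsAsFactors = FALSE, row.names = NULL)
    tsrna_profiles <- aggregate_by_subtype(
      build_profile(ts_rec, bundle$sets$tRNA_CCA, nclean,
                    config$multimap))
  }

  # rsRNA: per-precursor profiles and subtype expression
  rsrna_profiles <- list()
  rs_rec <- records[records$category == "rsRNA", , drop = FALSE]
  if (!is.null(bundle$sets$rRNA) && nrow(rs_rec) > 0L) {
    rsrna_profiles <- build_profile(rs_rec, bundle$sets$rRNA, nclean,
                                    config$multimap)
  }
  rsrna_subtypes <- subtype_expression(rsrna_profiles)

  mismatch <- NULL
  if (!config$skip_mismatch && config$mismatch >= 1L) {
    mismatch <- run_mismatch_stage(records, bundle, config)
  }

  result <- list(unique = pp$unique, stats = pp$stats,
                 records = records, summary = summary,
                 tsrna_classes = tsrna_classes,
                 tsrna_class_table = tsrna_class_table,
                 tsrna_profiles = tsrna_profiles,
                 rsrna_profiles = rsrna_profiles,
                 rsrna_subtypes = rsrna_subtypes,
                 mismatch = mismatch, out = config$out)
  if (!is.null(config$out)) {
    write_outputs(result, bundle, policy, config)
    return(invisible(result))
  }
  result
}

# Mismatch stage: pile each category's sequences against the reference
# set that won its annotation, call sites per set, pool the EMS/TUS
# statistics across categories.
run_mismatch_stage <- function(records, bundle, config) {
  cfg <- mismatch_config(p_err = config$p_err,
                         method = config$mm_method,
                         alpha = config$alpha,
                         min_coverage = config$min_coverage,
                         correction = config$correction)
  set_of_cat <- list(miRNA = "miRNA", rsRNA = "rRNA",
                     tsRNA = "tRNA_CCA", piRNA = "piRNA",
                     other_ncRNA = "ncRNA_other")
  sites_by_cat <- list()
  for (cat in names(set_of_cat)) {
    set <- bundle$sets[[set_of_cat[[cat]]]]
    rec <- records[records$category == cat, , drop = FALSE]
    if (is.null(set) || nrow(rec) == 0L) next
    piled <- pile_mismatches(rec, set, cfg$method)
    sites_by_cat[[cat]] <- call_sites(piled, cfg)
  }
  empty <- data.frame(ref_id = character(), position = integer(),
                      ref_base = character(), alt_base = character(),
                      n_ref = numeric(), n_mut = numeric(),
                      n_tot = numeric(), p_value = numeric(),
                      q_value = numeric(), significant = logical(),
                      stringsAsFactors = FALSE)
  all_sites <- do.call(rbind, c(unname(sites_by_cat), list(empty)))
  rownames(all_sites) <- NULL
  list(config = cfg, sites_by_category = sites_by_cat,
       sites = all_sites,
       category_stats = category_mismatch_stats(records, all_sites))
}

write_outputs <- function(result, bundle, policy, config) {
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  nclean <- result$stats$n_clean_reads

  # summary.tsv: stats as comment header, then the category table
  con <- file(file.path(out, "summary.tsv"), "w")
  st <- result$stats
  writeLines(sprintf("# %s\t%d", names(unclass(st)),
                     unlist(unclass(st))), con)
  utils::write.table(format_num_df(result$summary$category_table), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)

  if (nclean > 0L) {
    write_annotation_tsv(result$records, nclean, bundle, policy,
                         file.path(out, "annotation.tsv"))
  } else {
    writeLines(paste("sequence", "count", "RPM", "genome_match",
                     "category", "detail", "n_hits", sep = "\t"),
               file.path(out, "annotation.tsv"))
  }
  utils::write.table(format_num_df(result$summary$length_table),
                     file.path(out, "length_dist.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  dir.create(file.path(out, "tsrna_profiles"), showWarnings = FALSE)
  write_profile_tsv(result$tsrna_profiles,
                    file.path(out, "tsrna_profiles", "coverage.tsv"))
  utils::write.table(format_num_df(result$tsrna_class_table),
                     file.path(out, "tsrna_profiles", "classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  dir.create(file.path(out, "rsrna_profiles"), showWarnings = FALSE)
  write_profile_tsv(result$rsrna_profiles,
                    file.path(out, "rsrna_profiles", "coverage.tsv"))
  utils::write.table(format_num_df(result$rsrna_subtypes),
                     file.path(out, "rsrna_profiles",
                               "subtype_expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(result$mismatch)) {
    dir.create(file.path(out, "mismatch"), showWarnings = FALSE)
    utils::write.table(format_num_df(result$mismatch$sites),
                       file.path(out, "mismatch", "sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(format_num_df(result$mismatch$category_stats),
                       file.path(out, "mismatch", "category_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  log_lines <- c(
    sprintf("srnaprofiler %s",
            as.character(utils::packageVersion("srnaprofiler"))),
    sprintf("input: %s", config$input),
    sprintf("input_md5: %s",
            unname(tools::md5sum(config$input))),
    sprintf("format: %s", config$format),
    sprintf("adapter: %s",
            if (is.null(config$adapter)) "none" else config$adapter),
    sprintf("length_window: %d-%d", config$min_length,
            config$max_length),
    sprintf("policy: max_mismatch=%d strata=%s", config$mismatch,
            config$strata),
    sprintf("multimap: %s", config$multimap),
    sprintf("hierarchy: %s", paste(bundle$hierarchy, collapse = " > ")),
    sprintf("mismatch_stage: %s",
            if (config$skip_mismatch) "skipped" else sprintf(
              "p_err=%g method=%s alpha=%g min_coverage=%g correction=%s",
              config$p_err, config$mm_method, config$alpha,
              config$min_coverage, config$correction))
  )
  writeLines(log_lines, file.path(out, "run_log.txt"))
  invisible(out)
}
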