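# Reference collections: loading, validation, subtype extraction, and
# construction of CCA-appended mature tRNA sequences.

#' Construct a reference set
#'
#' @param name set name, one of \code{genome}, \code{miRNA},
#'   \code{rRNA}, \code{tRNA}, \code{tRNA_CCA}, \code{piRNA},
#'   \code{ncRNA_other}.
#' @param ref_id character vector of unique entry identifiers.
#' @param sequence character vector of uppercase DNA sequences
#'   (alphabet A/C/G/T/N; N in a reference never matches a read base).
#' @param subtype optional per-entry subtype tag (rRNA subtype such as
#'   "28S", tRNA isoacceptor such as "Gly-GCC"); defaults to "other".
#' @return an object of class \code{reference_set}.
#' @export
reference_set <- function(name, ref_id, sequence, subtype = NULL) {
  name <- match.arg(name, c("genome", "miRNA", "rRNA", "tRNA",
                            "tRNA_CCA", "piRNA", "ncRNA_other"))
  ref_id <- as.character(ref_id)
  sequence <- toupper(as.character(sequence))
  stopifnot(length(ref_id) == length(sequence))
  if (anyDuplicated(ref_id)) {
    stop("duplicate ref_id in set '", name, "': ",
         ref_id[duplicated(ref_id)][1L])
  }
  if (length(sequence) && any(!nzchar(sequence))) {
    stop("empty sequence in set '", name, "'")
  }
  if (length(sequence) && any(grepl("[^ACGTN]", sequence))) {
    stop("reference sequences must be over {A,C,G,T,N} in set '",
         name, "'")
  }
  if (is.null(subtype)) subtype <- rep("other", length(ref_id))
  structure(list(
    name = name,
    entries = data.frame(ref_id = ref_id, sequence = sequence,
                         subtype = as.character(subtype),
                         stringsAsFactors = FALSE)
  ), class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("reference_set '%s': %d entries\n", x$name,
              nrow(x$entries)))
  invisible(x)
}

#' Default subtype-extraction patterns per set
#'
#' rRNA headers carry the precursor subtype token (5S, 5.8S, 12S, 16S,
#' 18S, 28S, 45S); tRNA headers carry the isoacceptor token
#' (e.g. Gly-GCC).  For miRNA and piRNA sets the entry id itself is the
#' subtype (the annotation detail users want).  Unmatched headers fall
#' back to subtype "other".
#'
#' @param name set name.
#' @return a regex with one capture group, or NA (id-as-subtype), or
#'   NULL (no extraction).
#' @export
default_subtype_pattern <- function(name) {
  switch(name,
    rRNA = "(5\\.8S|5S|12S|16S|18S|28S|45S)",
    tRNA = ,
    tRNA_CCA = "([A-Za-z]{3}-[ACGTN]{3})",
    miRNA = ,
    piRNA = NA_character_,
    NULL
  )
}

#' Load a reference set from FASTA
#'
#' @param path FASTA file of reference sequences.
#' @param name set name (see [reference_set()]).
#' @param subtype_pattern regex with one capture group applied to the
#'   full FASTA header to extract the per-entry subtype; entries with
#'   no match get subtype "other".  \code{NA} uses the entry id as the
#'   subtype; missing uses [default_subtype_pattern()].
#' @return a \code{reference_set}.
#' @export
load_fasta_set <- function(path, name,
                           subtype_pattern = default_subtype_pattern(name)) {
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  subtype <- extract_subtype(headers, ids, subtype_pattern)
  reference_set(name, ids, as.character(ss), subtype)
}

extract_subtype <- function(headers, ids, pattern) {
  if (is.null(pattern)) return(rep("other", length(ids)))
  if (length(pattern) == 1L && is.na(pattern)) return(ids)
  m <- regexpr(pattern, headers, perl = TRUE)
  out <- rep("other", length(headers))
  hit <- m > 0L
  out[hit] <- sub(paste0(".*?", pattern, ".*"), "\\1", headers[hit],
                  perl = TRUE)
  out
}

#' Build mature (CCA-appended) tRNA references
#'
#' Mature tRNAs carry an enzymatically appended 3' CCA that is absent
#' from genomic tRNA sequence; fragments spanning it therefore fail
#' genome matching.  This returns a parallel set in which every
#' sequence has "CCA" appended; entry ids keep the original id plus a
#' recorded suffix so the genomic entry is recoverable with
#' [base_ref_id()].
#'
#' @param trna_set a \code{reference_set} with name \code{tRNA}.
#' @param suffix id suffix marking mature entries (default "_mature").
#' @return a \code{reference_set} named \code{tRNA_CCA}.
#' @export
build_mature_trna <- function(trna_set, suffix = "_mature") {
  stopifnot(inherits(trna_set, "reference_set"),
            trna_set$name == "tRNA")
  e <- trna_set$entries
  out <- reference_set("tRNA_CCA",
                       ref_id = if (nrow(e)) paste0(e$ref_id, suffix)
                                else character(0),
                       sequence = if (nrow(e)) paste0(e$sequence, "CCA")
                                  else character(0),
                       subtype = e$subtype)
  attr(out, "id_suffix") <- suffix
  out
}

#' Strip the mature-tRNA id suffix
#'
#' @param ref_id character vector of ids.
#' @param suffix the suffix recorded by [build_mature_trna()].
#' @return genomic tRNA ids.
#' @export
base_ref_id <- function(ref_id, suffix = "_mature") {
  sub(paste0(suffix, "$"), "", ref_id)
}

#' Assemble a database bundle
#'
#' A bundle is the ordered collection of reference sets that defines
#' the annotation hierarchy, plus the (optional) genome used for the
#' match-genome / unmatch-genome flag.  The mature (CCA-appended) tRNA
#' set is derived automatically from the genomic tRNA set, so 3'CCA
#' fragments, which cannot match the genome, are still recovered.
#'
#' @param genome optional genome \code{reference_set}; when absent the
#'   genome-match flag is reported as NA.
#' @param miRNA,rRNA,tRNA,piRNA,ncRNA_other optional
#'   \code{reference_set}s.
#' @param hierarchy annotation order over set names; default
#'   miRNA > rRNA > tRNA > piRNA > ncRNA_other (tRNA and tRNA_CCA form
#'   one stage).
#' @param provenance free-text version label recorded in output
#'   headers.
#' @return object of class \code{database_bundle}.
#' @export
database_bundle <- function(genome = NULL, miRNA = NULL, rRNA = NULL,
                            tRNA = NULL, piRNA = NULL,
                            ncRNA_other = NULL,
                            hierarchy = c("miRNA", "rRNA", "tRNA",
                                          "piRNA", "ncRNA_other"),
                            provenance = "") {
  sets <- list(miRNA = miRNA, rRNA = rRNA, tRNA = tRNA, piRNA = piRNA,
               ncRNA_other = ncRNA_other)
  sets <- sets[!vapply(sets, is.null, logical(1))]
  stopifnot(all(hierarchy %in% c("miRNA", "rRNA", "tRNA", "piRNA",
                                 "ncRNA_other")))
  hierarchy <- hierarchy[hierarchy %in% names(sets)]
  if (length(hierarchy) == 0L) stop("bundle hierarchy is empty")
  for (nm in names(sets)) {
    stopifnot(inherits(sets[[nm]], "reference_set"))
  }
  if (!is.null(tRNA)) sets$tRNA_CCA <- build_mature_trna(tRNA)
  structure(list(
    genome = genome,
    sets = sets,
    hierarchy = hierarchy,
    provenance = provenance
  ), class = "database_bundle")
}

#' @export
print.database_bundle <- function(x, ...) {
  cat("database_bundle\n")
  cat("  genome:", if (is.null(x$genome)) "absent" else
    sprintf("%d entries", nrow(x$genome$entries)), "\n")
  cat("  hierarchy:", paste(x$hierarchy, collapse = " > "), "\n")
  invisible(x)
}

#' Load a bundle from a YAML manifest
#'
#' The manifest maps set names to FASTA paths and optional subtype
#' patterns, e.g.
#' \preformatted{
#' genome: {path: genome.fa}
#' rRNA:   {path: rrna.fa, subtype_pattern: "(5\\.8S|18S|28S)"}
#' }
#' Relative paths are resolved against the manifest's directory.
#'
#' @param manifest_path path to the YAML manifest.
#' @return a \code{database_bundle}.
#' @export
load_bundle <- function(manifest_path) {
  man <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  get_set <- function(nm) {
    ent <- man[[nm]]
    if (is.null(ent)) return(NULL)
    path <- ent$path
    if (!file.exists(path)) path <- file.path(base, ent$path)
    if (!file.exists(path)) {
      stop("missing reference file for set '", nm, "': ", ent$path)
    }
    pat <- if (!is.null(ent$subtype_pattern)) ent$subtype_pattern
           else default_subtype_pattern(nm)
    load_fasta_set(path, nm, pat)
  }
  hier <- if (!is.null(man$hierarchy)) unlist(man$hierarchy)
          else c("miRNA", "rRNA", "tRNA", "piRNA", "ncRNA_other")
  database_bundle(
    genome = get_set("genome"),
    miRNA = get_set("miRNA"),
    rRNA = get_set("rRNA"),
    tRNA = get_set("tRNA"),
    piRNA = get_set("piRNA"),
    ncRNA_other = get_set("ncRNA_other"),
    hierarchy = hier,
    provenance = if (!is.null(man$provenance)) man$provenance else ""
  )
}

#' Write a reference set to FASTA
#'
#' Headers are \code{ref_id} alone; writing then reloading with
#' [load_fasta_set()] reproduces the entries (subtypes re-extracted
#' from ids).
#'
#' @param set a \code{reference_set}.
#' @param path output FASTA path.
#' @export
write_reference_fasta <- function(set, path) {
  ss <- Biostrings::BStringSet(
    stats::setNames(set$entries$sequence, set$entries$ref_id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
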