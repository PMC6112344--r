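# Deterministic synthetic-data generator: a toy genome, a reference
# bundle and reads with known category / locus / modification ground
# truth, so every pipeline stage is testable without downloads.
#
# References are rejection-sampled so that no 15-mer (on either strand)
# is shared between any two reference entries, or repeated within one
# entry; with clean reads >= 15 nt this makes annotation ground truth
# unambiguous.  A chosen fraction of rRNA entries is left out of the
# toy genome, emulating rDNA absent from a genome assembly, which
# plants unmatch-genome rsRNAs.

#' Specification for a synthetic fixture
#'
#' @param seed integer seed; fully determines the output.
#' @param genome_length approximate toy genome length in bp.
#' @param n_mirna,n_trna,n_rrna,n_pirna number of reference entries per
#'   set.
#' @param reads_per_source reads generated from each source category
#'   (miRNA, tsRNA, rsRNA, piRNA).
#' @param n_random_reads reads from random sequences matching nothing
#'   (ground truth: unannotated).
#' @param tsrna_class_mix fractions over the four tsRNA locus classes;
#'   must sum to 1.
#' @param modification_sites data.frame with columns \code{ref_id}
#'   (source entry id), \code{position} (1-based on that entry),
#'   \code{alt_base} (NA picks a deterministic non-reference base) and
#'   \code{mismatch_fraction}; the default plants one site at position
#'   10 of the first tRNA with fraction 0.3, inside the 5' fragment
#'   region so coverage is high.
#' @param umg_rrna_fraction fraction of rRNA entries excluded from the
#'   toy genome (round(fraction * n_rrna) entries).
#' @param error_rate per-base uniform sequencing error rate.
#' @param adapter 3' adapter appended to every read (NULL for none).
#' @param read_len_range length range for rsRNA fragments and the
#'   fragment classes.
#' @return a \code{fixture_spec} object.
#' @export
fixture_spec <- function(seed = 1L, genome_length = 5000L,
                         n_mirna = 5L, n_trna = 4L, n_rrna = 4L,
                         n_pirna = 4L, reads_per_source = 600L,
                         n_random_reads = 10L,
                         tsrna_class_mix = c(five_prime = 0.4,
                                             three_prime = 0.2,
                                             three_prime_CCA = 0.2,
                                             internal = 0.2),
                         modification_sites = NULL,
                         umg_rrna_fraction = 0.5, error_rate = 0,
                         adapter = "TGGAATTCTCGGGTGCCAAGG",
                         read_len_range = c(15L, 35L)) {
  stopifnot(all(tsrna_class_mix >= 0),
            abs(sum(tsrna_class_mix) - 1) < 1e-9,
            all(names(tsrna_class_mix) %in% TSRNA_CLASSES),
            umg_rrna_fraction >= 0, umg_rrna_fraction <= 1,
            error_rate >= 0, error_rate < 1)
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 n_mirna = n_mirna, n_trna = n_trna, n_rrna = n_rrna,
                 n_pirna = n_pirna,
                 reads_per_source = as.integer(reads_per_source),
                 n_random_reads = as.integer(n_random_reads),
                 tsrna_class_mix = tsrna_class_mix,
                 modification_sites = modification_sites,
                 umg_rrna_fraction = umg_rrna_fraction,
                 error_rate = error_rate, adapter = adapter,
                 read_len_range = as.integer(read_len_range)),
            class = "fixture_spec")
}

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

kmers_of <- function(seq, k = 15L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1L), k:n)
}

both_strand_kmers <- function(seq, k = 15L) {
  c(kmers_of(seq, k), kmers_of(revcomp(seq), k))
}

new_registry <- function() new.env(hash = TRUE, parent = emptyenv())

registry_has <- function(reg, kmers) {
  for (km in kmers) if (!is.null(reg[[km]])) return(TRUE)
  FALSE
}

registry_add <- function(reg, kmers) {
  for (km in kmers) reg[[km]] <- TRUE
  invisible(reg)
}

# Sample a sequence whose 15-mers (both strands) neither collide with
# the registry nor repeat internally; `extra` is sequence context that
# must be collision-free too but is not part of the returned string
# (e.g. the CCA tail of a tRNA).
sample_unique_seq <- function(len, reg, tail = "", forbid = NULL,
                              max_tries = 1000L) {
  for (try in seq_len(max_tries)) {
    s <- rand_seq(len)
    if (!is.null(forbid) && forbid(s)) next
    full <- paste0(s, tail)
    km <- both_strand_kmers(full)
    if (anyDuplicated(km)) next
    if (registry_has(reg, km)) next
    registry_add(reg, km)
    return(s)
  }
  stop("could not sample a collision-free sequence of length ", len,
       " (spec infeasible?)")
}

# Largest-remainder apportionment of n into integer counts ~ fracs.
apportion <- function(n, fracs) {
  raw <- n * fracs
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fracs))
}

inject_errors <- function(seq, error_rate, protect = integer(0)) {
  if (error_rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < error_rate)
  hit <- setdiff(hit, protect)
  for (i in hit) ch[i] <- sample(setdiff(BASES, ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Generate a synthetic fixture
#'
#' Builds the reference sets and toy genome, draws reads per source
#' with the requested tsRNA locus-class mix, injects planted
#' modification mismatches and uniform sequencing errors, appends the
#' adapter, and records per-read ground truth.  The appended adapter is
#' verified (under the generation seed) to trim back to the exact read;
#' reads whose own 3' end would trigger a premature adapter match are
#' resampled, keeping ground truth exact.  With \code{error_rate = 0}
#' the full pipeline at one allowed mismatch recovers category, tsRNA
#' class, genome flag and planted modification sites exactly.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional directory: writes \code{reads.fastq}, one FASTA
#'   per reference set, \code{bundle.yaml} and
#'   \code{ground_truth.tsv}.
#' @return list with \code{reads} (read_id, sequence, quality),
#'   \code{bundle} (a \code{database_bundle}), \code{sets} (named
#'   reference sets incl. genome), \code{ground_truth},
#'   \code{excluded_rrna} (ids left out of the genome) and
#'   \code{modification_sites} (with resolved alt bases and
#'   pipeline-visible ref ids).
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  reg <- new_registry()
  rl_min <- spec$read_len_range[1]
  rl_max <- spec$read_len_range[2]
  stopifnot(rl_min >= 15L, rl_max >= rl_min)

  # --- reference sets ---------------------------------------------
  mirna_len <- sample(21:22, spec$n_mirna, replace = TRUE)
  mirna <- reference_set("miRNA",
    ref_id = sprintf("toy-miR-%d", seq_len(spec$n_mirna)),
    sequence = vapply(mirna_len, sample_unique_seq, character(1),
                      reg = reg),
    subtype = sprintf("toy-miR-%d", seq_len(spec$n_mirna)))

  iso_pool <- c("Gly-GCC", "Glu-CTC", "Lys-CTT", "His-GTG", "Val-CAC",
                "Asp-GTC")
  iso <- rep_len(iso_pool, spec$n_trna)
  trna_len <- sample(70:90, spec$n_trna, replace = TRUE)
  # bodies must not end in CCA: a genomic 3' fragment would otherwise
  # be indistinguishable from a CCA-end fragment
  no_cca_tail <- function(s) endsWith(s, "CCA")
  trna <- reference_set("tRNA",
    ref_id = sprintf("tRNA-%s-%d", iso, seq_len(spec$n_trna)),
    sequence = vapply(trna_len, sample_unique_seq, character(1),
                      reg = reg, tail = "CCA", forbid = no_cca_tail),
    subtype = iso)

  rr_sub <- rep_len(c("5.8S", "18S", "28S"), spec$n_rrna)
  rr_len <- c(`5.8S` = 120L, `18S` = 150L, `28S` = 180L)[rr_sub]
  rrna <- reference_set("rRNA",
    ref_id = sprintf("%s_rRNA_%d", rr_sub, seq_len(spec$n_rrna)),
    sequence = vapply(rr_len, sample_unique_seq, character(1),
                      reg = reg),
    subtype = rr_sub)

  pirna_len <- sample(26:31, spec$n_pirna, replace = TRUE)
  pirna <- reference_set("piRNA",
    ref_id = sprintf("toy-piR-%d", seq_len(spec$n_pirna)),
    sequence = vapply(pirna_len, sample_unique_seq, character(1),
                      reg = reg),
    subtype = sprintf("toy-piR-%d", seq_len(spec$n_pirna)))

  n_excl <- round(spec$umg_rrna_fraction * spec$n_rrna)
  excluded <- if (n_excl > 0) {
    sort(sample(seq_len(spec$n_rrna), n_excl))
  } else integer(0)
  excluded_ids <- rrna$entries$ref_id[excluded]

  # --- toy genome --------------------------------------------------
  planted <- c(mirna$entries$sequence,
               trna$entries$sequence,
               rrna$entries$sequence[setdiff(seq_len(spec$n_rrna),
                                             excluded)],
               pirna$entries$sequence)
  after_trna <- c(rep(FALSE, spec$n_mirna), rep(TRUE, spec$n_trna),
                  rep(FALSE, length(planted) - spec$n_mirna -
                        spec$n_trna))
  sp_len <- max(30L, (spec$genome_length - sum(nchar(planted))) %/%
                  (length(planted) + 1L))
  sample_spacer <- function(no_cca_start) {
    repeat {
      s <- rand_seq(sp_len)
      if (no_cca_start &&
          sum(strsplit(substr(s, 1, 3), "")[[1]] ==
                c("C", "C", "A")) >= 2) next
      if (!registry_has(reg, both_strand_kmers(s))) return(s)
    }
  }
  pieces <- character(2L * length(planted) + 1L)
  pieces[1L] <- sample_spacer(FALSE)
  for (i in seq_along(planted)) {
    pieces[2L * i] <- planted[i]
    pieces[2L * i + 1L] <- sample_spacer(after_trna[i])
  }
  genome <- reference_set("genome", "chr_toy",
                          paste(pieces, collapse = ""))
  genome_seq <- genome$entries$sequence
  genome_rc <- revcomp(genome_seq)
  in_genome <- function(s) {
    grepl(s, genome_seq, fixed = TRUE) || grepl(s, genome_rc,
                                                fixed = TRUE)
  }

  # --- modification sites ------------------------------------------
  mods <- spec$modification_sites
  if (is.null(mods)) {
    mods <- data.frame(ref_id = trna$entries$ref_id[1L],
                       position = 10L, alt_base = NA_character_,
                       mismatch_fraction = 0.3,
                       stringsAsFactors = FALSE)
  }
  all_entries <- rbind(mirna$entries, trna$entries, rrna$entries,
                       pirna$entries)
  seq_of <- stats::setNames(all_entries$sequence, all_entries$ref_id)
  for (i in seq_len(nrow(mods))) {
    rid <- mods$ref_id[i]
    if (is.na(seq_of[rid])) stop("modification ref_id unknown: ", rid)
    rb <- substr(seq_of[rid], mods$position[i], mods$position[i])
    if (is.na(mods$alt_base[i])) {
      mods$alt_base[i] <- setdiff(BASES, rb)[1L]
    }
    if (mods$alt_base[i] == rb) {
      stop("alt_base equals the reference base at ", rid, ":",
           mods$position[i])
    }
  }
  # id as the pipeline reports it (tsRNA hits live on the mature set)
  mods$pipeline_ref_id <- ifelse(
    mods$ref_id %in% trna$entries$ref_id,
    paste0(mods$ref_id, "_mature"), mods$ref_id)

  # --- reads -------------------------------------------------------
  trna_seq <- trna$entries$sequence
  mature_seq <- paste0(trna_seq, "CCA")
  adapter <- spec$adapter
  gt <- list()
  reads <- list()
  terminal_protect <- function(cls, rl) {
    # keep planted terminal boundaries intact under sequencing error
    if (cls %in% c("five_prime", "three_prime", "three_prime_CCA")) {
      c(1L, rl)
    } else integer(0)
  }
  add_read <- function(category, ref_id, src_seq, start, end,
                       tsrna_class = NA_character_,
                       genome_match = "MG") {
    raw <- substr(src_seq, start, end)
    rl <- nchar(raw)
    modified <- FALSE
    for (i in seq_len(nrow(mods))) {
      if (!is.na(ref_id) && mods$pipeline_ref_id[i] == ref_id &&
          mods$position[i] >= start && mods$position[i] <= end &&
          stats::runif(1) < mods$mismatch_fraction[i]) {
        off <- mods$position[i] - start + 1L
        substr(raw, off, off) <- mods$alt_base[i]
        modified <- TRUE
      }
    }
    raw <- inject_errors(raw, spec$error_rate,
                         protect = terminal_protect(tsrna_class, rl))
    n <- length(reads) + 1L
    reads[[n]] <<- raw
    gt[[n]] <<- data.frame(
      read_id = sprintf("read%06d", n), category = category,
      ref_id = ref_id, start = start, end = end,
      tsrna_class = tsrna_class, modified = modified,
      genome_match = genome_match, stringsAsFactors = FALSE)
  }

  rps <- spec$reads_per_source
  for (i in seq_len(rps)) {           # miRNA: full mature sequences
    j <- sample.int(spec$n_mirna, 1L)
    add_read("miRNA", mirna$entries$ref_id[j],
             mirna$entries$sequence[j], 1L,
             nchar(mirna$entries$sequence[j]))
  }

  cls_counts <- apportion(rps, spec$tsrna_class_mix)
  for (cls in names(cls_counts)) {
    for (i in seq_len(cls_counts[[cls]])) {
      j <- sample.int(spec$n_trna, 1L)
      L <- trna_len[j]
      mid <- paste0(trna$entries$ref_id[j], "_mature")
      frag_max <- min(rl_max, L - 1L)
      if (cls == "five_prime") {
        rl <- sample(rl_min:frag_max, 1L)
        add_read("tsRNA", mid, mature_seq[j], 1L, rl, cls, "MG")
      } else if (cls == "three_prime") {
        rl <- sample(rl_min:frag_max, 1L)
        add_read("tsRNA", mid, mature_seq[j], L - rl + 1L, L, cls,
                 "MG")
      } else if (cls == "three_prime_CCA") {
        rl <- sample(max(rl_min, 4L):min(rl_max, L + 2L), 1L)
        add_read("tsRNA", mid, mature_seq[j], L + 3L - rl + 1L,
                 L + 3L, cls, "UMG")
      } else {                         # internal
        start <- sample(2:(L - rl_min - 1L), 1L)
        rl <- sample(rl_min:min(rl_max, L - start), 1L)
        add_read("tsRNA", mid, mature_seq[j], start,
                 start + rl - 1L, cls, "MG")
      }
    }
  }

  for (i in seq_len(rps)) {           # rsRNA: random fragments
    j <- sample.int(spec$n_rrna, 1L)
    len <- rr_len[j]
    rl <- sample(rl_min:min(rl_max, len), 1L)
    start <- sample.int(len - rl + 1L, 1L)
    add_read("rsRNA", rrna$entries$ref_id[j],
             rrna$entries$sequence[j], start, start + rl - 1L,
             NA_character_,
             if (j %in% excluded) "UMG" else "MG")
  }

  for (i in seq_len(rps)) {           # piRNA: full sequences
    j <- sample.int(spec$n_pirna, 1L)
    add_read("piRNA", pirna$entries$ref_id[j],
             pirna$entries$sequence[j], 1L,
             nchar(pirna$entries$sequence[j]))
  }

  for (i in seq_len(spec$n_random_reads)) {
    repeat {
      s <- sample_unique_seq(sample(20:30, 1L), reg)
      if (!in_genome(s)) break
    }
    add_read("unannotated", NA_character_, s, 1L, nchar(s),
             NA_character_, "UMG")
  }

  reads <- unlist(reads)
  gt <- do.call(rbind, gt)

  # append adapter; resample nothing -- verify trimming restores the
  # read exactly, and regenerate the random tail of adapter handling
  # by trimming check (reads whose suffix fakes an adapter start are
  # vanishingly rare but would break ground truth)
  if (!is.null(adapter)) {
    araw <- charToRaw(toupper(adapter))
    ok <- vapply(reads, function(r) {
      isTRUE(find_adapter_start(paste0(r, adapter), araw, 6L, 0.1) ==
               nchar(r) + 1L)
    }, logical(1), USE.NAMES = FALSE)
    if (any(!ok)) {
      # drop offending reads (deterministic under the seed)
      reads <- reads[ok]
      gt <- gt[ok, , drop = FALSE]
      gt$read_id <- sprintf("read%06d", seq_along(reads))
    }
    full <- paste0(reads, adapter)
  } else {
    full <- reads
  }
  read_tab <- data.frame(read_id = gt$read_id, sequence = full,
                         quality = strrep("I", nchar(full)),
                         stringsAsFactors = FALSE)
  rownames(gt) <- NULL

  bundle <- database_bundle(genome = genome, miRNA = mirna,
                            rRNA = rrna, tRNA = trna, piRNA = pirna,
                            provenance = sprintf("toy fixture seed=%d",
                                                 spec$seed))
  out <- list(reads = read_tab, bundle = bundle,
              sets = list(genome = genome, miRNA = mirna, rRNA = rrna,
                          tRNA = trna, piRNA = pirna),
              ground_truth = gt, excluded_rrna = excluded_ids,
              modification_sites = mods, spec = spec)
  if (!is.null(dir)) write_fixture(out, dir)
  out
}

write_fixture <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "reads.fastq"), "w")
  writeLines(rbind(paste0("@", fx$reads$read_id), fx$reads$sequence,
                   "+", fx$reads$quality), con)
  close(con)
  files <- c(genome = "genome.fa", miRNA = "mirna.fa", rRNA = "rrna.fa",
             tRNA = "trna.fa", piRNA = "pirna.fa")
  for (nm in names(files)) {
    write_reference_fasta(fx$sets[[nm]], file.path(dir, files[[nm]]))
  }
  man <- list(genome = list(path = "genome.fa"),
              miRNA = list(path = "mirna.fa"),
              rRNA = list(path = "rrna.fa"),
              tRNA = list(path = "trna.fa"),
              piRNA = list(path = "pirna.fa"),
              provenance = fx$bundle$provenance)
  yaml::write_yaml(man, file.path(dir, "bundle.yaml"))
  utils::write.table(fx$ground_truth,
                     file.path(dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
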