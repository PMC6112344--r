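---
title: "Annotating small RNA fragments with srnaprofiler: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating small RNA fragments with srnaprofiler: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnaprofiler)
```

## The problem

Small-RNA sequencing libraries contain far more than microRNAs. tRNA-derived
small RNAs (tsRNAs, also called tRFs) and rRNA-derived small RNAs (rsRNAs)
are abundant in many tissues, yet general-purpose annotation pipelines either
drop them or, worse, discard them before annotation because they fail genome
matching. Two biological quirks cause that loss:

* mature tRNAs carry a 3′ **CCA** trinucleotide that is added
  enzymatically and is absent from genomic tRNA sequence, so any fragment
  spanning the CCA end cannot align to the genome;
* large parts of the rDNA repeat are absent from common genome assemblies,
  so fragments of those rRNA precursors are "unmatch genome" even though
  their precursor sequence is perfectly well known.

`srnaprofiler` addresses this by decoupling the genome-match flag from
annotation: every unique sequence gets an **MG/UMG** flag (match /
unmatch genome), computed independently, and is then annotated against the
full set of RNA references regardless of that flag.

## The procedure

The pipeline has four stages.

**1. Pre-processing.** The 3′ sequencing adapter is trimmed (leftmost
placement with at least `min_overlap = 6` bases of adapter prefix and a
mismatch fraction at most `max_error_rate = 0.1`); sequences are uppercased
and U is converted to T before any test (references are DNA); reads with
bases outside A/C/G/T are discarded, as are reads outside the length window
(default 15–45 nt, covering the miRNA through tsRNA/rsRNA size classes).
Surviving ("clean") reads are collapsed into unique sequences with counts;
`n_clean_reads` is the denominator of every RPM (reads per million clean
reads) in the output. No quality-based filtering is applied; qualities are
carried through trimming untouched otherwise.

**2. Hierarchical annotation.** Each unique sequence is aligned against the
genome (for the MG/UMG flag) and then against the reference sets in
hierarchy order — by default miRNA > rRNA > tRNA > piRNA > other ncRNA,
configurable in the bundle manifest. The first set with at least one hit
decides the category; later sets are not queried. The tRNA stage searches
both the genomic tRNA set and a derived set with CCA appended
(`build_mature_trna()`); hits are canonicalized onto the CCA-appended
("mature") entry and deduplicated so that one biological placement is never
counted twice in multi-mapper weights.

Alignment is ungapped with at most *m* substitutions (*m* ∈ {0, 1, 2}),
both strands, implemented as seed-and-extend with pigeonhole seeding: the
query is cut into *m*+1 disjoint blocks, so any placement with at most *m*
mismatches leaves one block exact and its *k*-prefix is an exact seed.
When `floor(L/(m+1)) < k` the matcher falls back to a full scan of every
offset, preserving full sensitivity for short queries. The test suite holds
the matcher to exact agreement with a brute-force enumeration oracle.
Multi-mapping placements are always all kept; `strata = TRUE` (the default)
keeps only the placements with the minimum observed mismatch count per
sequence, so an exactly-matching sequence is not also assigned spurious
1-mismatch placements. An N base in a reference never matches any read base.

The pipeline default is `mismatch = 1` with strata on, used for both
annotation and the mismatch analysis below: one alignment pass serves both,
and sequences carrying a genuine modification-induced mismatch are still
categorized (they would be lost at *m* = 0). Annotation-only runs at
*m* = 0 are available through the policy argument.

**3. Profiles.** tsRNA hits are classified by derivation locus on the
mature tRNA of length *L* (CCA reference length *L*+3): `five_prime` when
the fragment starts at position 1, `three_prime_CCA` when it reaches
position *L*+3, `three_prime` when it ends exactly at *L*, otherwise
`internal`, with precedence 5′ > 3′CCA > 3′ for fragments satisfying
several. The boundaries are exact by default; real fragment ends are
ragged, so a `terminal_tolerance` (nt) widens each boundary test when asked
for. Coverage profiles add each sequence's RPM across its hit interval;
under the default `uniform_split` policy a multi-mapper's weight is divided
by its number of hits, which makes every conservation law exact: subtype
RPM sums equal category RPM, and total RPM is 10^6. `count_each` (full
weight at every hit) is available for comparison. tsRNA profiles are
reported per isoacceptor (gene copies summed from position 1, padded to the
longest copy); rsRNA profiles are reported per precursor together with a
subtype expression table (5.8S/18S/28S, etc.).

**4. Mismatch-enrichment sites.** RNA modifications perturb reverse
transcription and leave mismatch pileups. At each reference position with
an observed mismatch we accumulate `n_mut` (weighted count of sequences
mismatching there, per alternative base) and `n_ref` (weighted count
covering the position with the reference base); `n_tot = n_ref + n_mut`.
The p-value is the lower binomial tail

p = P(X ≤ n_ref), X ~ Binomial(n_tot, 1 − p_err),

i.e. the probability of seeing this few matching bases if mismatches arose
only from base-calling error at rate `p_err`. Two weighting methods exist:
`raw` (full sequence count at every hit — inflates false positives for
multi-mappers) and the default `uniform_adjusted` (count divided by the
number of hits, assuming the loci express equally). Weighted counts are
rounded half-up before the binomial evaluation, since the distribution is
defined on integers and base `round()` is half-to-even. Sites with
`n_tot < min_coverage` (default 10) are not tested; tested p-values are
Benjamini–Hochberg corrected by default (`bonferroni` and `none`
available) and flagged significant at `alpha = 0.05`. Per category the
output reports TUS (total unique sequences) and EMS (unique sequences
containing at least one significant mismatch site).

### Parameter defaults at a glance

| parameter | default | meaning |
|---|---|---|
| `min_length`/`max_length` | 15/45 nt | clean-read window |
| `min_overlap`/`max_error_rate` | 6 / 0.1 | adapter placement tolerance |
| `mismatch` | 1 | substitutions allowed in alignment |
| `strata` | TRUE | keep only best-stratum placements |
| `multimap` | uniform_split | profile weighting |
| `p_err` | 0.001 | base-calling error rate (Phred 30) |
| `min_coverage` | 10 | weighted n_tot floor for testing |
| `alpha` / `correction` | 0.05 / BH | significance call |
| `terminal_tolerance` | 0 | tsRNA boundary wobble |
| `seed_k` | 12 | exact k-mer seed length |

`p_err`, `alpha`, `min_coverage` and the correction are deliberately plain
flags: the binomial model is standard, but the thresholds that make a site
"a modification" are a judgement call that should stay visible to the user.

## What the synthetic fixtures emulate

`generate_fixture()` builds a toy genome and reference bundle in which
every ground truth is known: reference entries are rejection-sampled so no
15-mer (either strand) is shared between any two entries or repeated within
one, which makes category assignment of any clean read (≥ 15 nt)
unambiguous; a chosen fraction of rRNA entries (default 0.5) is left out of
the genome to plant UMG rsRNAs; tsRNA reads are drawn with a fixed locus
class mix (default 0.4/0.2/0.2/0.2 over 5′/3′/3′CCA/internal); one
modification site is planted by default at position 10 of the first tRNA
(inside the 5′-fragment region, so its coverage is high) with mismatch
fraction 0.3; the 3′ adapter is appended to every read. Defaults
(600 reads per source over 5/4/4/3-entry reference sets, toy genome ≈ 5 kb)
keep a full pipeline run under a minute while leaving the planted
modification site with coverage above 50.

What the fixtures do **not** emulate: sequence composition bias, ragged
fragment ends, tRNA introns and secondary structure, quality-score
structure, true multi-mapping families (reference entries are deliberately
dissimilar), and realistic modification chemistry. Passing the fixture
tests therefore demonstrates the bookkeeping — hierarchy, flags,
conservation, calibration — not performance on real libraries, where
parameter choices (especially `terminal_tolerance` and the mismatch
thresholds) matter.

## Numerical and design choices

* **Determinism.** Collapsed sequences are sorted by descending count then
  sequence; alignments by (ref_id, start, strand); all table writers format
  numerics explicitly. Two identical runs produce byte-identical outputs.
* **Tie-breaks.** A sequence hitting several entries of the winning set
  keeps all hits; its `detail` is the sorted, comma-joined set of their
  subtypes.
* **Degenerate inputs.** Empty input after filtering writes a zero summary
  with a warning rather than failing; a count mismatch between annotation
  and pre-processing statistics is a hard error (it can only be a bug).
* **Fractional counts.** Uniform splitting produces fractional weights;
  they are kept exact through piling and rounded half-up only at the
  binomial evaluation.
* **tRNA introns** are not removed; intronless (mature-sequence) tRNA
  references are expected, as distributed by the common tRNA databases.
* **External aligners.** The internal matcher is the only engine; it is
  exact at these reference scales and keeps the package self-contained.
  For genome-scale references a user would map externally and import, which
  is out of scope here.
* **Problem sizes in the tests.** Oracle-equivalence runs 500 queries × 3
  mismatch levels against a 5 kb reference; the binomial grid covers
  n_tot ≤ 200 at three error rates; null calibration uses 2,000 simulated
  sites; the end-to-end fixture uses the generator defaults above. These
  sizes make every property checkable in seconds while still exercising the
  seeded, the fallback and the multi-block code paths.

## Known limitations

Ungapped alignment only (no indels); no quality-aware error model (a
single global `p_err`); no probabilistic reassignment of multi-mappers
across categories (the hierarchy is strict first-hit); no anticodon-loop
aware tRNA-half classification; significant sites are candidate
modification positions, not chemical assignments.

## A minimal run

```{r example, eval = FALSE}
fx <- generate_fixture(fixture_spec(seed = 1), dir = "fixture")
res <- run_pipeline(run_config(
  input = "fixture/reads.fastq", bundle = "fixture/bundle.yaml",
  adapter = fx$spec$adapter, out = "results"))
res$summary$category_table
res$tsrna_class_table
res$mismatch$sites[res$mismatch$sites$significant, ]
```
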