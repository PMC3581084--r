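---
title: "Evaluating ITS2 minibarcodes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating ITS2 minibarcodes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A DNA barcode is useful in practice only if it can be amplified from the
material people actually have — herbarium sheets, dried market samples,
degraded tissue — and still separates species. For plants, the nuclear
ribosomal internal transcribed spacer region (ITS1 + 5.8S + ITS2, about
634 nt) discriminates species well but amplifies poorly from degraded
DNA, whereas its second spacer alone (ITS2, about 233 nt) amplifies
easily. `minibarcode` implements the desk half of that comparison: given
a corpus of labelled sequences (or a simulated stand-in), it excises
ITS2 from full-length ITS, quantifies the barcode gap of each locus,
compares the two loci pair-by-pair, and measures how often three
standard identification criteria return the right species.

## The pipeline

1. **Curation** (`curate`): records shorter than `min_length_bp`
   (default 100 nt) or lacking a genus/species label are removed. The
   report partitions the input exactly
   (`n_input = n_removed_short + n_removed_unlabelled + n_kept`).
2. **Region annotation** (`build_profile`, `annotate`,
   `annotate_corpus`): ITS2 is delimited by locating two conserved
   motifs — the 5.8S gene and the 5' end of the 28S gene — with small
   profile HMMs decoded by Viterbi dynamic programming.
3. **Distances** (`align_global`, `distance_matrix`): every unordered
   pair is globally aligned once (Needleman–Wunsch with affine gaps);
   from the aligned transition/transversion counts both the uncorrected
   p-distance and the Kimura 2-parameter (K2P) distance are derived.
4. **Divergence summaries** (`divergence_summary`): the six standard
   inter/intraspecific parameters, each mean ± SD.
5. **Locus comparison** (`compare_loci`): a paired Wilcoxon signed-rank
   test of the same pairs' distances under full ITS vs excised ITS2.
6. **Identification** (`identify_corpus`): leave-one-out best hit, best
   match, and best close match, at species and genus rank.

`run_pipeline` orchestrates these stages, writes every intermediate as
TSV/FASTA plus a JSON manifest with a hash of the analysis
configuration, and is byte-deterministic given the seed.

## Annotation model

The annotation uses one small profile HMM per conserved motif rather
than one joint model of the whole ITS: boundary accuracy at the two ends
of ITS2 is all that downstream stages need, and two independent
placements are far easier to reason about and test.

* Each profile has match states with per-position emission log-odds
  (bits, against a uniform 0.25 background), built from two or more
  equal-length (optionally gapped) reference sequences:
  `p = (count + pseudocount) / (total + 4·pseudocount)`, columns with
  more than 50% gaps dropped. Default Laplace pseudocount 1.
* Decoding is *glocal*: global over the profile (every match state is
  visited or deleted), local over the sequence (free start and end).
  Insert states emit at background (0 bits); transition penalties
  default to −4 bits to open and −1 bit to extend an insertion or
  deletion. A placement counts as found when its Viterbi score reaches
  the profile's threshold, default 10 bits — a score the best placement
  in random sequence essentially never reaches for motifs of 60+
  positions, while even a 160-position profile at several percent
  per-site divergence scores in the hundreds of bits.
* ITS2 is the interval between the 5.8S placement's end and the 28S
  flank placement's start. If the flank is missing but 5.8S is found,
  ITS2 runs to the sequence end and the record is flagged `TRUNCATED`
  (kept, like `OK`, for downstream analysis); if the two placements
  overlap or are out of order, the lower-scoring one is rejected. Both
  profiles are also scored on the reverse complement, and the record is
  flipped when the reverse orientation wins for both.
* An optional third profile for the leading (18S 3') flank refines the
  ITS1 start; without it ITS1 is taken to start at the sequence start.
  No further 18S/ITS1 boundary refinement is attempted.
* Coordinates are 0-based half-open everywhere, including truth files
  and reports.

The shipped profiles are built from fixed *synthetic* reference motifs
(see below); for biological data you must build profiles from real,
correctly annotated reference alignments with `build_profile`.

## Alignment and distances

The aligner is exact dynamic programming, not a heuristic search:
corpora at desk scale (hundreds to a few thousand records) make
all-pairs optimal alignment affordable, and exactness makes tie handling
reproducible.

* Global alignment: match +1, mismatch −1, gap open −5, gap extend −2.
  A gap of length L costs `open + L·ext`, i.e. the first gap character
  costs −7. Ties break deterministically: diagonal, then up, then left.
* Local (search-style) alignment for best hit: match +1, mismatch −3,
  same gap costs.
* Pairwise deletion: aligned columns containing a gap or any ambiguity
  code in either sequence are excluded from the compared-site count.
* p-distance = (transitions + transversions) / compared sites. K2P
  `d = −½·ln(1−2P−Q) − ¼·ln(1−2Q)` with P and Q the transition and
  transversion proportions; when either logarithm's argument is
  non-positive (saturation) the distance is `NaN`, counted, excluded
  from every summary, and reported.
* Each unordered pair is aligned once and the value mirrored, so the
  matrix is symmetric by construction. Distances are computed on the
  region as given: the two-locus contrast runs the identical machinery
  on the full-ITS corpus and on the excised-ITS2 corpus.

K2P is the default model for the divergence summaries (the convention
of the barcode-gap literature); the uncorrected p-distance is the
default for the nearest-neighbour identification criteria (matching the
convention of nearest-neighbour barcoding software, whose similarity
threshold is defined on uncorrected distance). Both are selectable.
Whether a multiple alignment would be preferable is deliberately left
to the user: the package accepts pre-aligned input like any other
corpus, but performs no MSA itself.

## The six divergence parameters

For species with at least two samples (conspecific pairs) and genera
with at least two species (congeneric heterospecific pairs):

| parameter | unit averaged over |
|---|---|
| `avg_intra_avg` | per-species mean conspecific distance |
| `avg_intra_max` | per-species maximum conspecific distance ("coalescent depth") |
| `avg_intra_between_intra_species` | all conspecific pairs pooled (theta analogue) |
| `avg_interbyG_avg` | per-genus mean congeneric heterospecific distance (theta-prime analogue) |
| `avg_interbyG_min` | per-species nearest heterospecific congener distance |
| `avg_between_interbyGenus` | all congeneric heterospecific pairs pooled |

SDs are taken over the same averaging units. Cross-genus pairs never
enter any summary. By default every unit (species, genus) counts
equally; `weighted = TRUE` weights unit means by their pair counts, in
which case the unit-averaged and pooled parameters coincide — the
algebraic identity is property-tested. Whether sample-size weighting is
"right" is a genuinely open choice; unweighted is the default because it
matches how the parameters are usually quoted.

## Wilcoxon locus comparison

The pairing unit is the individual sequence pair — congeneric
heterospecific pairs for the interspecific test, conspecific pairs for
the intraspecific one — each contributing its distance under locus 1
versus locus 2. Pair-level pairing is used because the tests are meant
to have one observation per distance, not per species or genus. Zero
differences are dropped; absolute differences are ranked with mid-rank
ties; `w_plus` is the rank sum where the first locus exceeds the second.
The two-sided p-value is exact for n ≤ 25 (the distribution of the rank
sum over all 2^n sign assignments, computed by convolution over doubled
mid-ranks, which equals full enumeration), and otherwise a normal
approximation with tie correction and a 0.5 continuity correction. The
rank-sum identity `w⁺ + w⁻ = n(n+1)/2` holds by construction and is
property-tested, as is exact agreement with enumeration at small n.

## Identification criteria

All criteria are leave-one-out: each record is queried against every
other record, and only the query itself is excluded (records that might
be duplicates of the same individual are *not* excluded; a flag can drop
singleton-species queries from the denominator, which are structurally
unable to be CORRECT under the nearest-neighbour criteria and depress
the correct rate when kept — the default keeps them).

* **Best hit**: exhaustive optimal local alignment against every
  reference (no seeding heuristics, no E-values — at desk scale the
  exact search is affordable and reproducible). The top score wins;
  integer score ties across taxa give AMBIGUOUS.
* **Best match**: the minimum-distance reference set decides; ties
  (relative tolerance 1e-9, so that floating-point ties are explicit
  and reproducible) across several species give AMBIGUOUS, with no
  limit on how distant the best match may be.
* **Best close match**: as best match, but when the nearest neighbour
  is farther than the threshold (default 0.03, the 97% similarity
  rule) the query is NO_MATCH. The boundary is inclusive — a neighbour
  at exactly 0.03 is within — a convention choice that is documented,
  configurable, and covered by a boundary test. The threshold only
  gates whether identification is attempted; the assignment still uses
  the minimum-distance set.

Percentages (CORRECT / AMBIGUOUS / INCORRECT / NO_MATCH) partition the
queries. The per-genus report lists, for every genus with at least
`min_species` species (default 20), the share of queries that were not
CORRECT at species rank.

## The synthetic corpus generator

`simulate_corpus` emulates the statistical structure the analysis
assumes, so the whole stack is testable offline:

* a genus/species/sample hierarchy with unequal species and sample
  counts;
* composite sequences: leading 18S-3' flank + ITS1 + 5.8S + ITS2 +
  trailing 28S-5' flank, with near-invariant 5.8S/flanks and
  fast-evolving spacers;
* one random root per genus; species ancestors derived with per-spacer-
  site substitution probability `d_inter`; samples derived with
  `d_intra`; conserved segments mutate at `conserved_rate_5_8s` at both
  steps; substitutions carry a transition:transversion ratio (default
  2:1); single-base indels (default 0.002/site) occur in spacers only.

Defaults: 20 genera, 2–8 species per genus, 1–4 samples per species;
ITS1 230–252 nt, ITS2 220–246 nt, 5.8S fixed at 160 nt, flanks 60 nt —
centring full ITS near 634 nt and ITS2 near 233 nt, the typical plant
averages. `d_intra = 0.010` and `d_inter = 0.040` per site per lineage
give realized pairwise full-ITS divergences around 0.015 within species
and 0.07–0.08 between congeners, a realistic regime for large plant ITS
corpora; because two lineages mutate independently from their common
ancestor, the expected pairwise spacer divergence at rate d is
`2d(1−d) + d²/2` (the d²/2 term is the chance that both copies mutate
to the same base under the 2:1 transition bias), and the Monte-Carlo
tests check the realized divergence against exactly this expression.

The conserved segments are *fixed synthetic motifs* — arbitrary 160/60/
60-nt strings hard-coded in the package — not biological 5.8S or rRNA
sequences. That choice keeps every test free of downloads and makes the
planted ground truth exact; it also means the shipped profiles are only
valid for synthetic data.

What the generator does **not** model: rate heterogeneity across sites,
realistic indel length spectra, coalescent genealogies, paralogous ITS
copies, chimeras, mislabelled taxonomy, or laboratory failure modes
(PCR success rates cannot be simulated from sequences at all). Passing
tests on synthetic corpora therefore demonstrate the correctness of the
computations and the qualitative locus contrast, not the field accuracy
of any particular barcode.

## Numerical and degenerate-input choices

* Sequences are uppercased with U→T on every ingest path; the alphabet
  is IUPAC codes plus `-`. Taxonomy travels in a sidecar TSV
  (`record_id`, `genus`, `species`) because FASTA description formats
  are inconsistent; a "first two words of the description" fallback
  parser exists but is off by default. Species identity is exact string
  match on the normalized (genus, species) pair — no synonym
  resolution.
* Empty corpora after curation, corpora with no multi-sample species,
  genera with no second species, and all-zero paired differences all
  raise (or return) explicit, named conditions rather than NA results.
* `NaN` distances are excluded and counted everywhere; a pair with no
  comparable sites is `NaN` under both models.
* All randomness flows through the configuration seed; the pipeline
  writes no timestamps, so identical configs give byte-identical
  output trees. Stage outputs are plain TSV/FASTA, so a run can be
  resumed or partially re-done by feeding any stage's output files to
  the next stage's function.

## Problem sizes

The shipped tests and the acceptance script use corpora of roughly
30–300 records (e.g. 20 genera × 5 species × 3 samples for the
barcode-gap check; about 165 records for the end-to-end locus
comparison). These sizes give stable percentages and Monte-Carlo
margins while keeping an all-pairs exact-alignment analysis quick on a
single CPU; the same code paths scale to corpora in the low thousands.

## Known limitations

* The annotation model is a minimal profile HMM: no secondary-structure
  or covariance information, one motif per boundary, and no attempt to
  resolve multiple tandem ITS copies within a record.
* "Partial sequence" screening is represented only by the explicit
  length filter; no database-driven screening of misannotated or
  contaminant records is performed, and taxonomy labels are trusted.
* K2P saturation on very divergent pairs (common for cross-genus
  comparisons of spacers) yields `NaN`; those pairs are excluded from
  summaries, which is the standard but not the only possible treatment.
* The Wilcoxon pairing unit (sequence pairs) treats pairs as
  exchangeable observations; pairs sharing a sequence are not
  independent, as in the usual application of this test to distance
  matrices.
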