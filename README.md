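# minibarcode

Barcode-gap analysis and species identification for ITS/ITS2
minibarcodes.

## What this is for

DNA barcoding identifies species from short standard sequences. For
plants, the full nuclear ribosomal ITS region (ITS1 + 5.8S + ITS2,
~634 nt) discriminates species well but is hard to amplify from
degraded material (herbarium sheets, dried medicinal products), whereas
the ITS2 spacer alone (~233 nt) amplifies easily — a candidate
*minibarcode*. `minibarcode` is for researchers who want to quantify
what is lost (and gained) by trading the full-length region for the
short one on a labelled sequence corpus:

- **Region excision** — profile-HMM placement of the conserved 5.8S and
  28S-flank motifs delimits ITS2 inside full-length sequences (Viterbi
  decoding, glocal: global over the profile, local over the sequence).
- **Barcode gap** — the six standard divergence parameters, three
  intraspecific and three interspecific, on K2P or p-distances:
  - intraspecific: mean over species of the mean conspecific distance
    (`avg_intra_avg`), mean of the per-species maxima — the coalescent
    depth (`avg_intra_max`), and all conspecific pairs pooled (the
    theta analogue);
  - interspecific (congeners only): mean over genera of the per-genus
    mean (`avg_interbyG_avg`, the theta-prime analogue), mean over
    species of the nearest-congener distance (`avg_interbyG_min`), and
    all congeneric heterospecific pairs pooled.
- **Paired locus comparison** — Wilcoxon signed-rank test over the same
  sequence pairs' distances under the two loci (exact for n ≤ 25, tie-
  and continuity-corrected normal approximation beyond).
- **Identification** — three leave-one-out criteria:
  *best hit* (exhaustive Smith–Waterman search, top score wins),
  *best match* (nearest neighbour by p-distance, ties → ambiguous), and
  *best close match* (best match gated by a 3% distance threshold,
  i.e. 97% similarity; no neighbour within it → unidentified).

Distances: p = (transitions + transversions) / compared sites, and
K2P `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` with P, Q the transition
and transversion proportions (pairwise deletion of gap/ambiguous
columns).

A seeded synthetic-corpus generator (`simulate_corpus`) produces
hierarchical genus/species/sample corpora with composite
flank–ITS1–5.8S–ITS2–flank architecture and a planted ground truth, so
every stage is testable without downloading anything. Its conserved
motifs are fixed synthetic strings, not biological rRNA sequences.

## Worked example

```r
library(minibarcode)

cfg <- simulation_config(n_genera = 6, species_per_genus = c(2, 4),
                         samples_per_species = c(2, 3), seed = 42)
sim <- simulate_corpus(cfg)
corpus_summary(sim$corpus)
#>   samples genera species mean_length
#> 1      50      6      19       756.7

ann <- annotate_corpus(sim$corpus, reference_profiles())
# 50/50 records annotated, all status OK; ann$corpus holds excised ITS2

dm <- distance_matrix(ann$corpus, model = "K2P")
divergence_summary(dm, ann$corpus)
#> Divergence summary (substitutions/site, mean +/- SD)
#>   avg_intra_avg                     0.0222 +/- 0.0087  (n = 19)
#>   avg_intra_max                     0.0257 +/- 0.0106  (n = 19)
#>   avg_intra_between_intra_species   0.0236 +/- 0.0095  (n = 43)
#>   avg_interbyG_avg                  0.1035 +/- 0.0136  (n = 6)
#>   avg_interbyG_min                  0.0915 +/- 0.0122  (n = 50)
#>   avg_between_interbyGenus          0.1072 +/- 0.0201  (n = 150)
#>   species (intra) 19, genera 6, NaN excluded 0

res <- identify_corpus(ann$corpus, "BEST_CLOSE_MATCH", "species",
                       dm = distance_matrix(ann$corpus, model = "p"))
res$report
#> BEST_CLOSE_MATCH at species rank (50 queries)
#>   correct 78.00%  ambiguous 0.00%  incorrect 0.00%  no match 22.00%
```

Reading the numbers: the intraspecific means (~0.02 substitutions/site)
sit far below the congeneric interspecific means (~0.10) — a clear
barcode gap — so nearest-neighbour identification almost never picks a
wrong species. The 22% "no match" queries are records whose species has
no other sample within the 3% threshold (many of them singletons, which
are kept in the denominator by default and can never be identified
correctly under a nearest-neighbour criterion).

The whole flow (curation → annotation/excision → distances →
divergence + Wilcoxon locus comparison → identification reports, for
full ITS and ITS2 side by side) is orchestrated by `run_pipeline()`:

```r
res <- run_pipeline(pipeline_config(sim = cfg, region_mode = "BOTH",
                                    out_dir = "run1"))
res$comparison     # six parameters, Wilcoxon directions, % correct per locus
```

Outputs are TSV/FASTA plus a JSON manifest; the same config and seed
reproduce the output tree byte-identically. A thin command-line wrapper
with `simulate` / `curate` / `annotate` / `distances` / `divergence` /
`identify` / `compare` / `run-all` subcommands is installed at
`inst/scripts/minibarcode-pipeline.R`.

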