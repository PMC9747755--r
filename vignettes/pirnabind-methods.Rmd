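---
title: "piRNAbind: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{piRNAbind: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piRNAbind)
```

# The hybridization model

piRNAbind scores the duplex formed by a piRNA and an equally long mRNA
window as a strictly additive sum of per-pair free-energy increments.
Four pair types contribute: the canonical G-C (6.37 kJ/mol, 3 hydrogen
bonds) and A-U (4.25 kJ/mol, 2 bonds), the G-U wobble and the
noncanonical A-C pair (2.12 kJ/mol, 1 bond each). Every other base
combination is a mismatch and contributes nothing. Energies are stored as
positive magnitudes and reported with a minus sign; every comparison
("stronger binding", thresholds) is on magnitudes.

The model's assumptions, stated plainly:

* **Ungapped, full-length, antiparallel.** Window position *i* (5′→3′)
  pairs with piRNA position *L − i + 1*. No bulges, internal loops or
  partial alignments: RNA–RNA duplexes are antiparallel and the scoring
  unit is the whole piRNA.
* **No stacking or terminal corrections.** The increments are per pair
  only; this is deliberately simpler than nearest-neighbour
  thermodynamics and makes ΔG linear in the pair composition.
* **Mismatches are free but idle.** A mismatch costs no energy; the
  selection ratio (below) is what bounds mismatch content, since every
  mismatch forfeits its position's canonical energy.

For each piRNA, ΔGm is the energy against its perfect canonical
complement (G/C positions contribute 6.37, A/U positions 4.25). The
selection statistic is the percentage 100·ΔG/ΔGm, which is invariant
under uniform rescaling of the energy table and equals 100 exactly when
every pair is canonical.

```{r}
sc <- scoreDuplex("CCCCC", "GGGGG")
c(dG = dG(sc), dGm = dGm(sc), ratio = ratioPct(sc))
```

The energy constants can be overridden through `PairEnergyModel()`, but
the ordering G-C > A-U > wobble/noncanonical > 0 is enforced: it is what
guarantees that the fully canonical complement attains the maximum, so
0 ≤ ΔG ≤ ΔGm and the ratio is a true percentage.

# Scanning

`scanTargets()` evaluates *every* start position 1 … L − l + 1 of every
transcript for every piRNA — an exhaustive enumeration, not a seed-based
heuristic — and keeps placements with ratio ≥ `minRatioPct`.

* **`minRatioPct` (percent, default 90).** The working definition of a
  binding site. 95 and 97 are natural stricter settings; the default is
  deliberately permissive because cellular piRNA concentrations vary by
  orders of magnitude, so a weaker but abundant piRNA can still silence.
* **Same-piRNA thinning (`suppressOverlaps`, default `TRUE`).** In
  repetitive or low-complexity context a strong site also clears the
  threshold at ±1–2 nt shifts of itself. Overlapping placements of one
  piRNA are therefore thinned to local maxima by ΔG (ties keep the
  smaller start), which reports one start coordinate per genuine site.
  Set `FALSE` to obtain the raw enumeration (the test suite compares that
  mode against an independent brute-force rescorer).
* **Regions.** A site is labelled 5′UTR/CDS/3′UTR by the region holding
  its *start* position (sites are reported by start coordinate, so a
  boundary-straddling site takes its start's region). Only the sense
  strand is scanned: the question is regulation of this transcript.

Reported energies, pair counts and pairing strings for passing sites are
recomputed through `scoreDuplex()`, so the scanner's fast path can never
drift from the reference scoring path — the truth tables of the
synthetic generator rely on this.

# Competition between overlapping sites

Overlapping sites cannot be bound simultaneously. `resolveCompetition()`
flags, in every connected component of the overlap graph, the site with
the greatest |ΔG| as `preferred`; ties fall back to the higher ratio,
then the lexicographically smallest piRNA id (a deterministic, if
arbitrary, last resort). Competitor sites are retained in the output —
competition is a finding, not a filter — and the operation is idempotent.

# Cluster statistics

`buildClusters()` merges sites into clusters: connected components under
"overlap by ≥ `minOverlapNt` nt" (default 1, i.e. any overlap joins;
adjacency does not). Clusters are computed within one gene *and* one
region label, so a cluster never crosses a 5′UTR/CDS/3′UTR boundary.
Statistics per cluster:

* **length** — the inclusive span, end − start + 1. All 1-based
  inclusive coordinate arithmetic in the package follows this
  convention; it is the one that reproduces hand-computed spans such as
  108–172 → 65 nt or 4,940–5,125 → 186 nt.
* **compaction ratio** — summed member piRNA lengths / cluster length:
  how strongly overlap compresses the sequence hosting the sites. If all
  members sit at one position it equals the member count.
* **region-to-cluster ratio** — region length / cluster length.

Both ratios are reported to one decimal with halves rounded *away from
zero* (`roundHalfAway()`), not banker's rounding; that is the convention
that matches conventional hand rounding of such ratios (e.g. 891/118 =
7.55… → 7.6). `findStartGroups()` reports groups of ≥ `minGroup`
(default 5) distinct piRNAs whose sites begin at the identical position.

# Marker selection

`selectMarkers()` proposes (piRNA, gene) associations whose *best* site
(max |ΔG|; ties by ratio, then smaller start) passes either criterion:
|ΔG| ≥ `minAbsDg` (default 170 kJ/mol) or ratio ≥ `minRatioPct`
(default 97 %). "−170 kJ/mol or more" is read on magnitudes — stronger
binding — and both cutoffs are inclusive (≥). The unit of selection is
the association, not the site, because a marker is a piRNA–gene
relationship; the `criterion` column records which threshold(s) passed.
Raising either cutoff can only shrink the selection (tested property).
Cluster membership is *not* required of a marker: the two criteria are
applied at site level only. `crossGenePirnas()` complements this by
listing piRNAs with passing sites in several genes — marker candidates
that are *not* gene-selective.

# The synthetic-data generator

`generateDataset()` realizes a `simulationConfig()`: a stated synthetic
world, not a tuning dial. Defaults, chosen once:

* 60 background piRNAs, lengths uniform on 24–34 nt (the span of the
  piRNA class; no length distribution is standard, so uniform), i.i.d.
  bases at G+C 0.5;
* three transcripts of 2/4/6 kb with nonempty 5′UTR, CDS and 3′UTR
  (transcripts of real candidate genes span roughly 1–8 kb);
* eight single plants of graded pair composition (0–4 degraded
  positions), including one designed to fall *below* the 90 % cutoff so
  recovery tests exercise both sides of the threshold;
* one staggered cluster plan (5 sites, 3-nt stagger), one identical-start
  group (6 piRNAs), and one 54-nt region shared by all three genes
  targeted by 4 staggered piRNAs.

**Planting mechanics.** A single plant writes the piRNA's reverse
complement into the transcript and then degrades the stated numbers of
pairs by substituting the *mRNA* side at distinct random positions:
under a piRNA G, C→U makes a wobble; under a piRNA A, U→C makes an A-C
pair; setting the window base equal to the piRNA base makes a mismatch
(identical bases never pair in this model). Wobble/noncanonical
substitutions are only possible where the facing piRNA base permits
them, so eligibility is computed from the pair table.

**Clusters, start groups and shared regions are derived, not
inserted.** Physically writing k mutually overlapping reverse
complements into one window would destroy each other; instead the member
piRNAs are *derived from* the transcript window (staggered perfect
complements; start-group members additionally carry one piRNA-side
wobble substitution each so they are distinct sequences). The truth
table is recomputed from the final transcript with `scoreDuplex()`
after all modifications, so expected energies are exact whichever way a
site was created.

**Determinism.** Each transcript and each shared-region plan consumes
its own RNG stream seeded from the master seed, so outputs are
byte-identical across runs and adding a transcript does not reshuffle
the others.

**What a green test does and does not establish.** The generator
emulates the *structures* the pipeline detects — planted complements,
overlap clusters, shared starts, cross-gene homology — on an i.i.d.
background. It does not emulate real transcriptome composition bias,
piRNA abundance, RNA secondary structure or target-site accessibility;
recovery on synthetic data validates the algorithmic chain
(generator → scanner → statistics), not the biological discovery power
of the energy model.

# Numerical choices and degenerate inputs

* ΔG values are sums of two-decimal constants; tests compare them at
  tolerance 1e-12 (exact up to floating-point summation), and TSV output
  prints one decimal.
* Threshold comparisons are plain `>=` on doubles; a placement landing
  within one ulp of the cutoff is decided by floating point, which is
  irrelevant for the discrete ratios real compositions produce.
* Transcripts shorter than a piRNA yield no sites (not an error); an
  empty piRNA set yields an empty, fully typed result.
* Transcripts without CDS annotation are rejected by default; with
  `allowMissing = TRUE` they are treated as all-3′UTR.
* FASTA input is normalized (T→U, case-folded); ambiguity codes are
  rejected outright rather than skipped, because silently dropping
  positions would distort scores.

# Limitations

* The additive model has no stacking, temperature or accessibility
  terms; ΔG values are comparable within this model only.
* Strictly ungapped: piRNAs binding with short bulges would be missed or
  under-scored.
* Cluster "non-randomness" is not statistically tested; the package
  reports descriptive ratios only.
* Marker thresholds are conventions inherited from the analysis style
  this package implements, not calibrated error rates.
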