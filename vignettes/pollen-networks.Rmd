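---
title: "From pollen amplicon reads to network and individual specialisation"
author: "pollenNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From pollen amplicon reads to network and individual specialisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenNet)
```

## The problem

Hoverflies and other flower visitors carry mixed pollen loads that record
which plants they have recently visited. Sequencing the plant barcode
marker *rbcL* from the pollen washed off an individual insect, and matching
the reads against a labelled reference library, turns each insect into a
quantitative pollen profile. From a collection of profiles gathered across
sites and seasonal periods one can ask three nested questions:

1. **Community level** — how specialised is the bipartite insect x plant
   pollen-transport network (the index H2')?
2. **Species level** — how exclusive are a given insect species'
   interactions compared with what the other species use (the index d')?
3. **Individual level** — is a single insect effectively a *single-plant
   visitor* (one dominant pollen taxon) or a *multi-plant visitor*, and
   does that depend on season and sex?

pollenNet implements the full computation, plus a synthetic-data module so
that every stage is testable end to end without any external download.

## Pipeline stages and their parameters

### Read preparation

Paired 2x300 bp reads are quality-trimmed, merged by overlap, and
length-filtered.

* **Quality trimming** (`quality_trim`) uses a trailing sliding window
  (window 4, threshold Q20 by default): scanning from the 5' end the read
  is cut before the first window whose mean quality drops below the
  threshold, and any remaining trailing bases below the threshold are then
  removed. The window rule alone can leave up to `window - 1` trailing
  low-quality bases, which is why the per-base pass follows it. Neither
  step can lengthen a read.
* **Merging** (`merge_pairs`) reverse-complements the reverse mate and
  scans all overlaps of at least `min_overlap = 20` bases, accepting the
  overlap with the smallest mismatch fraction (ties to the longest) if that
  fraction is at most `max_mismatch_fraction = 0.1`. Disagreements inside
  the overlap resolve to the higher-quality base, ties to the forward base.
  These two defaults are conventions of common read mergers; neither is
  dictated by the analysis itself, so both sit in the configuration.
* **Length filter** (`length_filter`) keeps merged reads *strictly longer*
  than 450 bp. The boundary is exclusive and pinned by a test: a 450-base
  merged read is dropped, a 451-base read kept.

### Consensus taxonomic assignment

Reads are compared against a reference library whose FASTA headers carry
three ranks (`species|genus|family`). Candidate references are prefiltered
by shared 8-mer count and scored by banded local alignment (match +1,
mismatch −2, gap open −5, gap extend −2, band half-width 16 around the
dominant shared-k-mer diagonal — the usual seed-and-extend shortcut for
high-identity amplicon hits). Raw scores are reported as bit scores
`(1.28·S − ln 0.46)/ln 2`; because the transform is strictly monotone it
affects reporting only, never a call.

The consensus rule examines the top-scoring hits for each read:

1. if they are all one **species**, the read is assigned to that species;
2. else if at least **60%** of the hits share one **genus** (inclusive
   threshold), the read is assigned to that genus;
3. else the read is "various", resolved to a **family or tribe** when at
   least 90% of hits agree at that rank, and otherwise **unknown**.

Two genuinely open design points are worth stating. First, the "top
20 maximum bit scores" consensus basis: with a reference library holding
one sequence per species, a rule applied to the 20 best hits *of any
score* would almost never see a single species, because close relatives
always align. The package therefore applies the consensus to the hits tied
at the maximum bit score (capped at `top_n = 20`), which is how a
top-bit-score rule behaves when each species is represented by many
accessions; `consensus = "all_retained"` switches to the literal top-20
basis. Second, the 60% rule counts *hit records*, not distinct reference
species; this too is configurable in spirit by how the reference library
is built. A mechanical family-consensus rule (threshold 0.90) plus an
optional allow-list of permitted taxa stands in for case-by-case expert
curation, trading judgement for reproducibility.

Per-insect counts of identified reads are converted to percentages
(`profile_insects`) to control for amplification differences between
samples; insects with no identified reads are excluded and reported
separately.

### Network metrics

Interaction matrices are built per site x period on a
presence/absence-per-individual basis: cell (i, j) counts the individuals
of insect species i carrying plant taxon j at any positive percentage
(`presence_min_percent = 0`; raising it discards trace presences). Using
individuals rather than read counts avoids the amplification and
pollen-production biases that make read abundance only semi-quantitative.

* `H2` is the two-dimensional Shannon entropy of the cell distribution
  (natural logarithms, `0·ln 0 = 0`).
* `h2_bounds` computes the extremes attainable under the observed
  marginals. The maximum starts from an even integer fill near
  `A_i·C_j/m` and hill-climbs with single-unit 2x2 cycle moves (the integer
  edges of the transportation polytope). The minimum uses an exact
  argument: minimising entropy is equivalent to maximising `Σ a·ln a`,
  a convex separable objective whose optimum over the transportation
  polytope is at a vertex, and every vertex arises by repeatedly saturating
  some cell with `min(remaining A_i, remaining C_j)`; a memoised recursion
  over those placements therefore returns the exact integer minimum. The
  recursion is used up to 12 cells; for larger matrices greedy
  concentration plus extreme-step cycle descent stands in. An exhaustive
  enumeration oracle (`enumerate_entropy_extremes`, capped at m = 12)
  verifies both bounds across every small marginal combination in the test
  suite.
* `H2' = (H2max − H2)/(H2max − H2min)`, clipped to [0, 1]; degenerate
  networks with `H2max = H2min` (e.g. a single cell) report 0.
* `d` for a species row is the Kullback–Leibler divergence of its
  interaction proportions from overall partner availability `q_j = C_j/m`;
  `dmax = ln(m/A_i)`, and `dmin` is the minimum over integer allocations of
  the row total (largest-remainder start, single-unit exchange descent,
  verified against enumeration for small rows).
  `d' = (d − dmin)/(dmax − dmin)`, clipped to [0, 1]. Species absent from
  a period are omitted rather than reported as zero.

H2' was computed on species-aggregated rows (not individual-insect rows),
matching the convention of reporting species-level d' alongside the
network statistic.

### Individual specialisation

An insect is a *single-plant visitor* when its dominant taxon reaches at
least 90% of identified reads — inclusive at exactly 90.0, a threshold
chosen because heterospecific carry-over (pollen acquired from stigmas or
the wider environment) makes perfect purity unrealistic. Ties for the
dominant taxon are broken lexicographically and flagged.

`fit_binomial_glmm` models single versus multi status with period and sex
as fixed effects and crossed Gaussian random intercepts for site and
insect species, maximising the Laplace-approximated marginal likelihood
(lme4, one adaptive quadrature node — the standard and only available
choice for crossed designs). Coding is explicit so signs are
interpretable: response single = 1; period early = 0 / late = 1; sex
female = 0 / male = 1. A positive period coefficient therefore means
single-plant visiting is *more* common late. With both variances
constrained to zero the model reduces exactly to ordinary logistic
regression, which the test suite checks against a hand-rolled IRLS fit.
Constant responses raise a separation error rather than a misleading fit.

## The synthetic community

The generator emulates the statistical structure the analysis assumes:

* **Reference library** (`generate_reference_db`): species sequences are
  evolved from one random root along a family/genus/species hierarchy by
  independent substitutions, with expected within-genus divergence smaller
  than between-genus divergence (defaults 5% and 15%; the ordering is
  enforced).
* **Pollen mixtures** (`generate_insects`): with a period-dependent
  probability (0.40 early, 0.24 late — the seasonal decline of flower
  constancy) an insect is a near-pure specialist whose dominant proportion
  is drawn from Beta(20, 1) truncated to at least 0.9, i.e. dominant but
  not perfectly pure; otherwise proportions come from a symmetric Dirichlet
  over 2–6 taxa sampled proportional to plant availability. Insect species
  are drawn from a six-species pool with uneven capture weights
  (5:57:2:41:53:17), and the default design simulates 14 insects per site
  early and 31 late.
* **Reads** (`generate_reads`): per-read source taxa follow the true
  proportions; the forward read is the first 300 bases of the 500-base
  amplicon, the reverse read the reverse complement of the last 300;
  substitution errors are i.i.d. per base (default 0.5%). The error model
  is substitution-only — no indels — so merged lengths are deterministic
  and the >450 bp filter behaves predictably; a configurable
  short-amplicon fraction exists purely to exercise that filter. Per-insect
  read depth is lognormal (meanlog log 200, sdlog 0.6) — no per-insect
  depth distribution is dictated by the analysis, so this is a modelling
  choice: a few hundred reads per insect keeps multinomial sampling error
  on a 90% dominance call around a percentage point while staying cheap to
  simulate.

What the generator deliberately does **not** model: PCR amplification
bias, chimeras, index hopping, indel sequencing errors, or any real plant
taxonomy. Passing tests therefore demonstrate that the *computation* is
correct under its stated assumptions, not that real pollen data are free
of these artefacts; on real libraries the percentage data remain
semi-quantitative, which is exactly why networks are built on
presence/absence.

## Numerical conventions and degenerate inputs

* Entropies and divergences use natural logarithms; `0·ln 0 = 0`
  throughout.
* All consensus and classification thresholds are inclusive
  ("60% or more", "90% or above"); boundary behaviour is pinned by tests.
* Hit tables sort by bit score descending with reference id as the
  deterministic tie-break; dominant-taxon ties break lexicographically and
  carry a flag.
* Empty cases have defined answers: an empty FASTQ parses to zero records,
  `m = 0` matrices refuse entropy, species with zero captures are omitted
  from d', periods with no insects are absent from summaries, and depth 0
  simulates empty files.
* Determinism: every random stage is seeded from the single pipeline seed,
  and a fixed seed reproduces every output file byte for byte.

## Problem sizes used by the checks

The package's own verification runs at deliberate scales: the
entropy-bounds oracle sweeps every marginal pair with at most 10
interactions on matrices up to 3x3; assignment recovery uses a 16-species
library (4 families x 2 genera x 2 species, 3% within-genus divergence),
50 insects at depth 200 and 0.5% error; mixed-model recovery uses 50
replicates of 400 insects at a true period log-odds of 1; and the
end-to-end determinism fixture uses 12 insects at depth 30. The
study-scale demonstration in `scripts/acceptance.R` simulates 4 sites with
14/31 insects per period (180 insects, tens of thousands of read pairs)
and completes in a couple of minutes on one core.

## Known limitations

* The aligner is a banded heuristic anchored on the dominant shared-k-mer
  diagonal; reads with no k-mer in common with a reference (possible only
  at extreme divergence or error) receive no hit and fall to "unknown".
* `dmin` and the large-matrix `H2min` are heuristics refined by local
  search; they are exact in every enumerable case the suite checks, but
  carry no global guarantee at arbitrary scale.
* The GLMM assumes crossed, independent Gaussian intercepts; nested or
  correlated designs are out of scope.
* Reference-library completeness is assumed: a pollen taxon absent from
  the library can at best be called at a higher rank, never discovered.
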