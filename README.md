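# pollenNet

**pollenNet** turns raw pollen-metabarcoding reads into ecological
conclusions about pollen transport. It is written for ecologists studying
flower visitors (the motivating system is *Eristalis* hoverflies on
species-rich grasslands) who sequence the plant DNA barcode *rbcL* from
the pollen carried by individual insects and want, from those reads:

1. **per-insect pollen profiles** — consensus taxonomic assignment of each
   merged read against a labelled reference library, aggregated to
   percentages per insect;
2. **pollen-transport networks** — site x period bipartite matrices on a
   presence/absence-per-individual basis, with the network specialisation
   index *H2′* and the species-level exclusivity index *d′*;
3. **individual specialisation** — classification of each insect as a
   single-plant visitor (dominant taxon ≥ 90 % of identified reads) or a
   multi-plant visitor, modelled against season and sex with a
   binomial mixed model (crossed random intercepts for site and species).

A first-class synthetic-community module simulates reference libraries,
ground-truth pollen mixtures and error-bearing 2x300 bp paired reads, so
the whole pipeline is testable without any sequencing data.

## The statistics at the core

For an interaction matrix with cells `a_ij` (individuals of insect
species *i* carrying plant taxon *j*), totals `A_i`, `C_j`, `m` and
proportions `p_ij = a_ij/m`, `q_j = C_j/m`:

* **Two-dimensional Shannon entropy** `H2 = −Σ_ij p_ij ln p_ij`.
* **Network specialisation** `H2′ = (H2max − H2) / (H2max − H2min)`,
  standardised against the entropy extremes attainable under the observed
  marginals; 0 = complete generalisation, 1 = complete specialisation.
  The minimum is computed exactly for small matrices via a vertex search
  of the transportation polytope, and both bounds are verified against an
  exhaustive enumeration oracle in the test suite.
* **Species exclusivity** `d_i = Σ_j (a_ij/A_i) ln((a_ij/A_i)/q_j)`
  (Kullback–Leibler divergence from overall partner availability),
  standardised to `d′ ∈ [0, 1]` with `dmax = ln(m/A_i)` and an integer
  minimising allocation for `dmin`.
* **Consensus assignment**: top-bit-score hits per read; one species →
  species call; ≥ 60 % of hits one genus → genus call; else family/tribe
  at ≥ 90 % agreement or unknown. Bit scores are
  `(1.28·S − ln 0.46)/ln 2` with megablast-style `+1/−2` scoring.
* **Individual model**: logistic mixed model
  `single ~ period + sex + (1|site) + (1|species)` (Laplace
  approximation; single = 1, late = 1, male = 1).

## Worked example

Simulate a small community, assign its reads, and compute every level of
specialisation:

```r
library(pollenNet)
db <- generate_reference_db(2, 2, 2,
        divergence = list(within_genus = 0.03, between_genus = 0.12),
        seed = 11)
idx <- build_reference_index(db, k = 8)
avail <- setNames(rep(1, 8), db$taxa$species_id)
mix <- generate_insects(8, "MEAD", "early", availability = avail, seed = 12)
reads <- generate_reads(mix, db, read_sim_config(depth = 120), seed = 13)
merged <- merge_pairs(reads$fwd, reads$rev)
kept <- length_filter(merged$merged, 450)        # strict >450 bp filter
asg <- assign_reads(kept, idx)
asg$insect_id <- sub("_read\\d+$", "", asg$read_id)
profiles <- profile_insects(asg, mix$insects)

mat <- build_interaction_matrix(profiles, "MEAD", "early")
h <- h2_prime(mat)
cat(sprintf("H2 = %.3f  in [H2min %.3f, H2max %.3f]  ->  H2' = %.3f\n",
            h$H2, h$H2min, h$H2max, h$H2prime))
#> H2 = 2.831  in [H2min 1.980, H2max 3.063]  ->  H2' = 0.213
print(d_prime(mat), digits = 2)
#>       species row_total    d  dmin dmax dprime
#> 1 E_horticola         9 0.32 0.053 0.98   0.28
#> 2   E_nemorum         6 0.40 0.185 1.39   0.18
#> 3  E_pertinax         7 0.33 0.103 1.23   0.20
#> 4     E_tenax         2 1.39 0.875 2.48   0.32
table(classify_individuals(profiles)$visitor_class)
#>  multi single
#>      5      3
```

Reading the numbers: `H2' = 0.213` says this little network sits much
closer to complete generalisation (0) than specialisation (1) — its
entropy is near the maximum its margins allow. Each `d'` is likewise low:
no insect species monopolises plant taxa the others ignore. Three of the
eight individuals are single-plant visitors, i.e. at least 90 % of their
identified reads came from one plant taxon — individual-level constancy
coexisting with community-level generalisation.

The same flow, end to end with reports written as TSVs, is one call:

```r
cfg <- pipeline_config(out_dir = "pollen_out", seed = 1)
run_pipeline(cfg)
```

or from a shell, `Rscript inst/scripts/pollen_pipeline.R all --out-dir
pollen_out --seed 1` (subcommands `simulate`, `assign`, `networks`,
`classify`, `report`, `all`).

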