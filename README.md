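# microdeg

Hydrocarbon-degradation potential and degradation kinetics for bacterial
amplicon communities.

Urban-tree microbiomes (leaf surfaces, tree-cavity organic soil) host
bacteria that can degrade airborne hydrocarbon pollutants — alkanes and
polycyclic aromatic hydrocarbons (PAHs) such as naphthalene. 16S rRNA
amplicon surveys show which genera are present; `microdeg` estimates what
they might do with it, and provides the degradation-experiment accounting
such studies pair with community profiling. It is aimed at microbial
ecologists analysing genus-level abundance tables together with
biodegradation assays.

## What it computes

**Degradation potential.** For genus *g* and functional marker set *m*
(e.g. *alkB*, *ladA*-alpha, naphthalene dioxygenase), the coefficient

&nbsp;&nbsp;&nbsp;&nbsp;*c(g, m)* = (genomes of *g* carrying *m*) / (genomes of *g*) ∈ [0, 1]

is the fraction of the genus's genomes harboring the marker genes,
derived from profile-HMM annotation of a genome database
(`read_hmm_hits()`, `build_coefficients()`). A sample's potential is the
coefficient-weighted relative abundance, in percent of the community:

&nbsp;&nbsp;&nbsp;&nbsp;*P(s, m)* = 100 · Σ_g *r(s, g)* · *c(g, m)*

(`estimate_potential()`). Unscorable (unclassified or
database-absent) taxa contribute zero and are reported per sample as an
`unscored_fraction`, never renormalized away.

**Kinetics.** Percent removal against heat-killed controls
(`removal_percent()`); first-order decay fitted on log residual
concentrations with the intercept fixed at 100% at the starting time,
slope *b* = Σ *t*(ln *y* − ln 100) / Σ *t*², half-life ln 2 / (−*b*)
(`fit_first_order()`); condition contrasts with pooled-variance *t* tests
(`compare_decay()`); abiotic-loss series (`abiotic_loss()`).

**Community tables.** Domain/organelle ASV filtering (`filter_asvs()`),
rank collapse with `unclassified_<family>` bins (`collapse_to_rank()`),
minor-taxon aggregation into "Other genera" (`aggregate_minor()`),
Hellinger transform and sign-stable PCA (`hellinger()`,
`pca_ordination()`).

**Statistics and simulation.** Kruskal–Wallis with Dunn post-hoc
comparisons and Holm adjustment (`kruskal_wallis()`, `dunn_posthoc()`),
isolate-screening summaries with set-arithmetic cross-checks
(`screening_summary()`), and seeded generators with ground truth for
communities, genome traits, decay series and flask assays
(`gen_community()`, `gen_genome_traits()`, `gen_decay()`, `gen_flask()`).

## Worked example

```r
library(microdeg)

# genome traits: 4 Sphingomonas genomes (1 alkB+, none nahAc+),
# 2 Massilia genomes (both alkB+, 1 nahAc+)
pres <- rbind(
  g1 = c(alkB = 1, nahAc = 0), g2 = c(alkB = 0, nahAc = 0),
  g3 = c(alkB = 0, nahAc = 0), g4 = c(alkB = 0, nahAc = 0),
  g5 = c(alkB = 1, nahAc = 1), g6 = c(alkB = 1, nahAc = 0))
genus <- c(g1 = "Sphingomonas", g2 = "Sphingomonas", g3 = "Sphingomonas",
           g4 = "Sphingomonas", g5 = "Massilia", g6 = "Massilia")
coeffs <- build_coefficients(genome_trait_table(pres, genus),
  list(marker_set("alkB", "alkB"),
       marker_set("naphthalene_dioxygenase", "nahAc")))
coeffs$coeff
#>              alkB naphthalene_dioxygenase
#> Massilia     1.00                     0.5
#> Sphingomonas 0.25                     0.0

rel <- matrix(c(0.7, 0.2, 0.1), 1, 3,
              dimnames = list("leaf1", c("Sphingomonas", "Massilia",
                                         "unclassified_Bacillaceae")))
pot <- estimate_potential(abundance_table(rel, mode = "relative"), coeffs)
pot$potential
#>       alkB naphthalene_dioxygenase
#> leaf1 37.5                      10
pot$unscored_fraction
#> leaf1
#>    10
```

37.5% of this community is estimated to carry alkane-monooxygenase genes
(70% *Sphingomonas* at coefficient 0.25 plus 20% *Massilia* at 1.0), 10%
to carry naphthalene dioxygenases — note *Sphingomonas* contributes
nothing there because none of its database genomes carries the gene —
and 10% of the community (the unclassified family bin) cannot be scored
at all.

```r
sim <- gen_decay(seed = 1)  # 6 d vs 24 d half-life regime, noisy
fit <- fit_first_order(sim$experiment, "inoculated", window = c(0, 4))
c(slope = fit$slope_b, half_life = fit$half_life)
#>      slope  half_life
#> -0.1261673  5.4938742
```

A first-4-days fixed-intercept fit on one simulated noisy series recovers
a 5.5-day half-life for the 6-day truth; `compare_decay()` on the same
simulation separates the 6-day and 24-day conditions at t = −8.08
(df = 10, p = 1.1e−05).

## Analysis workflow

Numbered drivers under `analysis/` run the full synthetic study and write
tables under `results/`:

```sh
Rscript analysis/01_simulate_community.R    # community + genome traits
Rscript analysis/02_degradation_potential.R # coefficients, potentials, PCA
Rscript analysis/03_kinetics_greenhouse.R   # decay fits and contrasts
Rscript analysis/04_flask_screening.R       # flask removals, KW/Dunn, screening
```

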