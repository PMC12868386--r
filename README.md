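# fecaldiet

Replicate-aware diet analysis from faecal DNA metabarcoding, for studies of
social wildlife that pair eDNA with behavioural observation.

Faecal metabarcoding identifies what an animal ate by sequencing short
universal marker regions (e.g. the plant *trnL* P6 loop and vertebrate 16S)
from DNA in droppings. The raw output — read counts per sample, PCR
replicate and taxon — is noisy: low-abundance artefacts, single-replicate
contaminants, failed amplifications. `fecaldiet` turns those counts into
per-sample diet profiles and the downstream statistics a field study needs:

- **Replicate QC and RRA** — library-wide minimum-read filtering (default:
  taxa with fewer than 10 reads per marker library are dropped), a
  replicate-consensus rule (taxa present in only one of three PCR
  replicates are treated as artefacts), event-based taxon exclusions, and
  relative read abundance `rra(t) = reads(t) / total reads`, averaged across
  replicates onto the unit simplex.
- **Provenance scoring** — each taxon carries an expert score: 0 natural,
  0.5 uncertain, 1 anthropogenic. A sample's anthropogenic percentage is
  `100 · Σ s_t · rra_t / Σ rra_t`; partitions, allocation bounds for the
  uncertain mass, and per-group density summaries are built on top.
- **Method comparison** — focal-follow feeding seconds as observational
  abundance, genus-level harmonization, Venn partitions, 33/32-day period
  breakdowns, and logit-scale OLS agreement between the two methods.
- **Similarity modelling** — Bray-Curtis dissimilarity
  `d(x,y) = Σ|x−y| / Σ(x+y)`, NMDS ordination, PERMANOVA, and Gaussian
  mixed models on z-standardized pairwise similarity
  (`similarity_z ~ Group*Sex*Age + (1|individual pair) + (1|date pair) +
  (1|relationship)` and `similarity_z ~ Group*Relationship + …`), with
  relationship categories *Same individual* / *Mother-Infant* / *Other*
  and Type-II likelihood-ratio term tests.
- **Synthetic data with ground truth** — a Dirichlet-multinomial generator
  (group, individual and matriline levels, single-replicate contaminants,
  biased observational readout) so every stage is testable end to end.

Distance, ordination and permutation numerics delegate to `vegan`; mixed
models to `lme4`. The QC chain, provenance arithmetic, dyadic design and
term tests are implemented here and verified against brute-force oracles
in the test suite.

## Worked example

```r
library(fecaldiet)
library(dplyr)

sim <- simulate_dataset(sim_config(seed = 2024))   # 2 groups x 12 monkeys
b   <- sim$bundle                                  # reads, taxa, samples, focal

qc     <- qc_pipeline(b$reads, b$taxa, b$samples)  # filters + RRA + merge
scores <- provenance_scores(b$taxa)

partition_by_provenance(qc$rra, scores, b$samples, by = "group")
#>     unit natural_pct uncertain_pct anthropogenic_pct
#> 1 groupA        84.4         10.56              5.08
#> 2 groupB        75.8          9.98             14.24
```

The two simulated groups were built with anthropogenic (score-1) diet
shares of 5% and 15%; the pipeline recovers 5.08% and 14.24% from the raw
replicate counts. Composition differs between groups:

```r
d  <- bray_curtis(rra_matrix(qc$rra))
pm <- permanova(d, b$samples$group[match(rownames(d), b$samples$sample_id)],
                n_permutations = 999, seed = 1)
#> PERMANOVA R2 = 0.1576, p = 0.001

fit <- fit_similarity_model(build_pairwise_table(d, b$samples), 2)
#>   term                chisq    df  p_value
#> 1 group               13.6      1 2.21e- 4
#> 2 relationship       272.       2 1.08e-59
#> 3 group:relationship   2.88     2 2.37e- 1
```

Repeated samples from the same individual are far more similar than other
pairs (the `relationship` term), and within-group similarity differs
between the groups. Finally, the eDNA profiles agree with the simulated
focal-follow observations on the logit scale:

```r
mp  <- match_proportions(qc$rra, b$observations, b$taxa)
reg <- regress_methods(mp$matched)        # logit OLS, eDNA on observation
#> slope 1.00, R2 0.999, p 6.92e-46, n = 29
```

A thin command-line wrapper for the file-droppable stages (simulate,
validate, qc, score) ships in `inst/cli/fecaldiet.R`; tables are plain TSV
in a fixed dialect (`reads.tsv`, `taxa.tsv`, `samples.tsv`, `focal.tsv`).

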