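---
title: "Methods: replicate-aware diet analysis from faecal metabarcoding data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replicate-aware diet analysis from faecal metabarcoding data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`fecaldiet` implements a complete analysis chain for diet studies that
sequence faecal DNA with universal metabarcoding primers and, in parallel,
record feeding behaviour by focal-follow observation. The pipeline starts at
the assigned read-count table — one row per (sample, PCR replicate, marker
library, taxon) — and ends at group-level composition tests and dyadic
mixed models of dietary similarity. Sequence processing (read assembly,
clustering, taxonomic assignment) is out of scope: those steps belong to the
dedicated bioinformatics tools that produce the read-count table this
package consumes.

# Quality control and relative read abundance

Read counts from PCR-replicated metabarcoding are contaminated by two
well-known artefact classes: low-abundance noise (tag jumps, sequencing
error residue) and sporadic cross-contamination that typically appears in a
single PCR replicate. The QC chain addresses them in a fixed order:

1. **Library-wide minimum reads** (`filter_min_reads`): a taxon with fewer
   than 10 total reads in a marker library (plant or vertebrate) is
   removed. "Fewer than" is strict — 10 reads survive. The threshold is a
   tunable count with default 10.
2. **Replicate consensus** (`filter_replicate_support`): within each
   sample, a taxon detected in fewer than 2 of the (nominally 3) successful
   replicates is treated as an artefact and removed. Samples with fewer
   than 2 successful replicates are excluded outright, because the
   consensus rule is undefined for them; every exclusion is logged with a
   reason.
3. **Event-based exclusion** (`exclude_taxon_by_date`): when a known food
   was experimentally provisioned on given dates (e.g. peanut rewards),
   that taxon's reads are stripped from samples collected exactly one day
   later.
4. **RRA** (`compute_rra`): within each (sample, replicate), a taxon's
   relative read abundance is its reads divided by the replicate total, so
   each replicate is a point on the unit simplex. Replicates with zero
   total reads are dropped, never divided.
5. **Merge** (`merge_replicates`): a sample's profile is the arithmetic
   mean RRA across its contributing replicates, counting a taxon absent
   from a replicate as 0 there.

Two choices here were genuinely open and are exposed as options:

* **Renormalisation after merging** (`renormalize`, default `TRUE`).
  Zero-imputed means no longer sum to one whenever replicates disagree
  about presence; we restore the simplex by renormalising, since every
  downstream statistic (Bray-Curtis, provenance percentages) assumes
  compositional rows. The raw mean is available with
  `renormalize = FALSE`.
* **Marker pooling** (`pool_markers`, default `TRUE`). Plant and
  vertebrate counts are pooled within a replicate before normalising, so a
  sample's profile spans its whole detected diet and per-sample provenance
  percentages add to 100 across both libraries. Per-marker normalisation
  is available for analyses of one library at a time. Pooling does make
  the two libraries' read scales directly comparable, which is an
  approximation: amplification efficiency differs between primer sets.

# Provenance scoring

Each taxon carries an expert-assigned provenance score: 0 (natural), 0.5
(uncertain origin), 1 (anthropogenic). The score file is an input — the
package validates it but never guesses scores. A sample's anthropogenic
percentage is

$$100 \times \frac{\sum_t s_t \, \mathrm{rra}_t}{\sum_t \mathrm{rra}_t},$$

which is linear in the scores and invariant to rescaling the profile.
`partition_by_provenance` reports the mass in the three score classes
(summing to 100); group-level partitions average samples with equal
weights, because RRA already normalises sequencing depth.

Because the score-1 mass is only a lower bound on human-derived food,
`allocate_uncertain` turns a partition into a (min, max) interval under
three allocation rules for the uncertain mass: `none` (keep the minimum),
`half` (split evenly), and `proportional` (split by the observed
natural:anthropogenic ratio). No rule is privileged; published analyses
rarely state which arithmetic produced their upper bounds, so all three are
provided.

Density summaries of per-sample percentages use a Gaussian kernel with
Silverman's rule-of-thumb bandwidth, evaluated on a grid clipped to
[0, 100] and renormalised to integrate to one there — without the
renormalisation, mass leaking past the boundaries would make densities of
low-percentage groups visually incomparable.

# Comparing eDNA with focal-follow observations

Observational records are only reliable to genus, so both datasets are
harmonized to genus level or higher (`harmonize_to_rank`): species collapse
to their genus label; genus and coarser ranks map to themselves. Feeding
seconds act as the observational abundance measure; each method's
proportions are computed over its full taxon set and never renormalised
after matching, so both axes remain shares of the whole diet. Agreement is
summarised by:

* a Venn partition of detected taxa by method and food class;
* per-period composition using consecutive 33/32-day months, half-open on
  the right so boundary dates are assigned exactly once;
* OLS regression of eDNA share on observational share over the matched
  taxon set, by default after a logit transform
  $\operatorname{logit}(p) = \log(p/(1-p))$ that keeps a few dominant taxa
  from dominating the fit. Proportions of exactly 0 or 1 are clamped to
  $[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-6}$, before the
  logit. Observation is the predictor; the regression direction is a
  presentation choice, not a causal claim.

# Dissimilarity, ordination and group tests

Sample profiles are compared with Bray-Curtis dissimilarity
($\sum_t |x_t - y_t| / \sum_t (x_t + y_t)$), ordinated by multi-start NMDS,
and tested for group/period structure by PERMANOVA with the add-one
permutation estimator $p = (1 + \#\{F^* \ge F\})/(1 + B)$. All three
delegate their numerics to **vegan** (`vegdist`, `metaMDS`, `adonis2`),
the standard implementations in this field; the package's tests verify the
wrappers against brute-force reimplementations of the distance and the
PERMANOVA sums of squares. Seeds are mandatory arguments, so ordination
and permutation results are reproducible by construction.

# Dyadic similarity models

Pairwise similarity is $1 - d_{\mathrm{BC}}$, z-standardized over all
retained pairs ("standardised similarity"). Each unordered sample pair
carries its relationship category — *Same individual*, *Mother-Infant*
(one individual is the recorded mother of the other), *Other* — plus
unordered covariate combinations (sex combo FF/FM/MM, age combo over
adult/juvenile). Two model specifications are provided:

* Model 1: `similarity_z ~ group * sex_combo * age_combo +
  (1 | individual_pair) + (1 | date_pair) + (1 | relationship)`
* Model 2: `similarity_z ~ group * relationship +
  (1 | individual_pair) + (1 | date_pair)`

Three design decisions deserve comment, because dyadic rows make the usual
mixed-model formulation ambiguous:

* **Random-effect encoding.** A pairwise row has no single individual or
  date, so "individual" and "date" intercepts are encoded as single
  factors over the unordered pair of individual ids and the unordered pair
  of dates. This is explicit and simple, but it does not give each
  individual its own variance component (a multiple-membership structure
  would; that is out of scope).
* **Pair scope.** The default keeps within-group pairs only, which is the
  natural scope when group is a fixed effect; `scope = "all"` retains
  cross-group pairs (labelled `cross-group`) for descriptive comparisons
  such as mother-infant similarity across groups. Standardisation is
  always over the retained pairs.
* **Term tests.** Numerical fitting is delegated to **lme4**; the package
  owns design construction and inference. Each fixed term gets a Type-II
  likelihood-ratio test on maximum-likelihood fits: the model containing
  the term plus every term not containing it, against the same model
  without it. This reports main effects ignoring their own interactions,
  matching the way such model summaries are conventionally presented;
  Wald chi-squares would be the main alternative and generally agree at
  these sample sizes. AIC, BIC, RMSE and an $R^2$ of fitted versus
  observed values are reported for model comparison. Convergence and
  singularity messages are collected on the fit object rather than
  silently discarded — with only three relationship levels, the
  `(1 | relationship)` variance in Model 1 is frequently estimated at the
  boundary.

A caveat the models inherit from their field: rows sharing a sample are
dependent beyond what the pair-level intercepts capture. The package keeps
the stated model rather than switching to dyadic-dependence-aware
inference (MRQAP and relatives), which is explicitly out of scope; p-values
for between-group contrasts should be read with that in mind.

# The synthetic-data generator

`simulate_dataset` produces a complete study — metadata, true diet
profiles, replicate read counts, focal observations — with known ground
truth, so that every pipeline property is testable without real data. The
generative model is the simplest hierarchy exhibiting the structure the
analysis targets:

* **Population.** Two social groups of 12 individuals (adult females and
  males, juveniles), 3 mother-infant pairs per group, 3 samples per
  individual over a 130-day window, no same-day re-collection.
* **Diets.** Group mean compositions place 5% vs 15% of diet mass on
  anthropogenic (score-1) taxa and 10% on uncertain (score-0.5) taxa in
  both groups, so expected score-weighted anthropogenic percentages are
  10% vs 20% — a 10-point shift. Within each class, mass follows a
  geometric abundance series (a few dominant taxa, a long rare tail). The
  group base is drawn from a Dirichlet with concentration
  `alpha_group = 10000` — the group diet is treated as a near-fixed
  condition of the study, the draw adding only mild run-to-run variation.
  Individuals draw from `Dirichlet(tau * base)` with `tau = 150`
  (per-individual anthropogenic shares spread over roughly ±5 points);
  infants draw from `Dirichlet(kappa * mother)` with `kappa = 200`. The
  ordering of pairwise similarities (Same individual > Mother-Infant >
  Other) is structural whenever between-individual variability `2/tau`
  clearly exceeds the matriline scale `1/kappa`, which these defaults
  satisfy.
* **Reads.** Multinomial counts at 20,000 reads per replicate, triplicate
  PCR, 2% replicate failure. With probability 0.05 per replicate, one
  taxon from a dedicated five-taxon contaminant pool (zero dietary mass,
  score 0) is injected into exactly that replicate with a log-normal read
  count floored at 10 reads. Confining contaminants to zero-diet taxa
  makes the consensus filter's removal rate an exact, assertable quantity:
  an injected taxon can never legitimately appear in a second replicate.
* **Observations.** Feeding seconds are a multinomial readout of the true
  profile with optional per-taxon handling-time multipliers and
  detectabilities, emulating the known biases of focal data (long-handling
  foods overestimated; inconspicuous foods missed). With both set to 1 the
  readout is unbiased; with handling bias $h$ on one taxon its expected
  observed share is $h p / (1 + (h - 1) p)$.

What the generator deliberately does **not** emulate: digestion-driven
distortion of read counts relative to ingested biomass, marker-specific
amplification bias, seasonal phenology, spatial structure, and
database-incompleteness effects. Passing the recovery tests therefore
shows the pipeline is internally coherent — unbiased under its own
assumptions and robust to the artefact classes it filters — not that RRA
equals dietary proportion in real faecal samples.

# Calibration and problem sizes

The test suite checks, at sizes chosen to keep the whole suite desk-scale:

* exact equivalence of the QC chain, RRA, provenance percentage and
  Bray-Curtis against brute-force loop reimplementations (100 random
  fixtures, tolerance 1e-12);
* PERMANOVA type-I error on structureless 20-sample communities
  (500 simulations, 999 permutations), expected within [0.03, 0.07] at
  nominal 0.05;
* full-pipeline recovery of the 10-point anthropogenic shift within
  3 points, and the similarity ordering, in at least 90% of 100 default
  simulations, with 100% removal of injected contaminants;
* mixed-model calibration on tables simulated from the dyadic Gaussian
  model itself: group-term null rejection within [0.02, 0.08] over 200
  simulations and relationship-term power of at least 0.9 at the
  documented effect sizes (+0.6 residual-sd for Same individual, +0.3 for
  Mother-Infant). Simulating from the model, rather than through the
  compositional pipeline, is deliberate: pipeline-generated pairwise
  tables carry shared-sample dependence that the fitted model (like its
  field-standard counterparts) does not represent, so only the
  model-consistent simulation yields a meaningful size calibration of the
  term tests.

`scripts/acceptance.R` re-runs these computations end to end and writes
the resulting quantities to JSON.

# Known limitations

* RRA is a compositional proxy, not a biomass estimate; cross-marker
  pooling compounds primer-efficiency differences.
* The replicate-consensus rule removes genuinely rare taxa that amplify
  stochastically, biasing profiles slightly toward dominant taxa.
* Dyadic model p-values do not account for shared-sample dependence
  (see above).
* The uncertain-mass allocation rules bound, but cannot identify, the true
  anthropogenic share; resolving score-0.5 taxa requires better reference
  databases or finer markers, not different arithmetic.
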