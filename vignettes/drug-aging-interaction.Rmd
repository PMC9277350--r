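---
title: "Scoring drug-induced effects on tissue aging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring drug-induced effects on tissue aging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugaging)
```

## The model

`drugaging` asks whether a drug pushes a tissue's transcriptome in the
direction that tissue normally drifts with age, or against it. Both sides
of the comparison are reduced to ternary per-gene signatures on a shared
gene universe (the intersection of gene identifiers between the expression
dataset and the treatment-profile dataset, sorted lexicographically):

**Aging side.** Within one tissue, each gene's expression is correlated
with donor age by Spearman's rank correlation (average ranks for ties;
two-sided p from the t approximation `t = rho * sqrt((n-2)/(1-rho^2))`).
Genes with `rho > 0.2` and `p < 0.05` become +1, genes with `rho < -0.2`
and `p < 0.05` become −1, all others 0. Donor ages may arrive as numeric
years or as decade brackets; brackets are converted to ordinal ranks,
which leaves a rank-based correlation unchanged. When the primary rule
yields few genes — typical for small tissues, where the p-threshold is
hard to reach — the signature instead takes the 500 strongest positive and
500 strongest negative correlations (ranked by rho, ties broken by gene
id; if heavy ties make the two directions collide, the positive side wins
and the negative side fills from the remaining genes). The fallback
trigger `min_total` defaults to 1000 on genome-scale universes.

**Drug side.** Treatment experiments arrive as per-gene differential
z-score profiles grouped into replicate sets. Replicate groups whose
median pairwise Spearman correlation falls below 0.2 are discarded —
irreproducible experiments would otherwise vote in the recurrence count.
Across all retained experiments of one drug in one cell line (pooled over
dose and time), a gene is +1 if its z exceeds 1 (strictly) in at least
20 % of experiments and more often up than down; −1 symmetrically; a gene
passing both directions with an exact tie stays 0.

**Interaction.** For an aging signature `r` and a drug signature `z`:
specificity `S = sum(r != 0 & z != 0) / sum(r != 0)`; concordant and
discordant counts are the genes with `r*z > 0` and `r*z < 0`; the adjusted
concordance ratio `adjCR = (n_conc + 1)/(n_disc + 1)` carries a
pseudocount so that pairs with no discordant genes remain scorable. The
shared genes split into four quadrants (drug-up/age-up, drug-down/age-down,
drug-up/age-down, drug-down/age-up) that feed the enrichment step.

**Significance.** The null distribution of adjCR is obtained by
re-assigning both signatures' +1/−1 labels uniformly at random over the
universe, preserving each signature's positive and negative counts, and
recomputing adjCR; a normal distribution is fitted to the permuted values
by sample mean and standard deviation and a two-sided p-value is taken,
with direction read from adjCR vs 1. Internally the permutation is drawn
by sequential hypergeometric sampling of the 2×2 sign-overlap table, which
has exactly the distribution of shuffling both label vectors (only the
relative placement of labels matters — this is also why re-randomizing one
signature or both yields the same null) at O(1) cost per permutation; the
test suite verifies the equivalence against explicit label shuffling.
Given a seed, results are bit-reproducible, and each (drug, cell, tissue)
pair scores on its own derived substream so scoring order is irrelevant.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `rho_cut`, `p_cut` | 0.2, 0.05 | aging primary selection rule |
| `fallback_k`, `min_total` | 500, 1000 | fallback size and trigger |
| `z_cut` | 1 | per-experiment significance on the z scale (strict) |
| `frac_cut` | 0.2 | recurrence fraction ("20 % or more", non-strict) |
| `min_rep_corr` | 0.2 | median pairwise replicate Spearman to keep a group |
| `n_perm` | 10000 | permutations per pair |
| `s_min` | 0.45 | specificity threshold for calling |
| `cr_lo`, `cr_hi` | 0.9, 1.1 | adjCR dead zone (no call inside) |
| `p_max` | 0.01 | permutation p threshold (raw; a BH column is reported) |

All are exposed through `default_config()` and the YAML config of
`run_pipeline()`.

## Numerical choices and degenerate inputs

- Zero-variance genes get `rho = 0, p = 1` instead of `NA`, keeping the
  correlation table total and the gene out of the signature.
- `|rho| = 1` maps to `p = 0` (the t statistic diverges).
- `CR` is flagged infinite when no discordant gene exists; all inference
  uses the always-finite adjCR.
- A degenerate permutation null (`sd = 0`, e.g. signatures covering the
  whole universe) warns and returns `p = 1`.
- Duplicate gene identifiers are collapsed by the arithmetic mean of their
  rows (deterministic and order-independent); gene matching is exact and
  case-sensitive, with no alias resolution.
- Samples without a parseable age and profiles with incomplete metadata
  are dropped with a logged count; a missing age *column* is a hard error.
- The normal null can optionally be fitted on `log(adjCR)`
  (`null = "log"`): a ratio statistic is right-skewed, and the log scale
  calibrates visibly better at small overlap counts (see below). The raw
  scale stays the default.

## The synthetic generator

`simulate_expression()` plants positively and negatively age-correlated
genes as `baseline + effect * standardized(age) + N(0, noise_sd)` with
ages uniform on 20–71 years; `effect_for_rho()` converts a target Spearman
rho into the planting coefficient through the bivariate-normal relation
`rho_S = (6/pi) * asin(r/2)` (verified empirically in the tests, not
assumed). `simulate_profiles()` plants recurrently responding genes:
within a replicate group each planted gene is active with probability
`recur_frac`, active genes draw `N(±z_effect, 1)`, everything else
`N(0, 1)`. With `group_sd > 0` a dense latent response vector is shared by
all profiles of a group — real replicate profiles correlate through their
genome-wide treatment response, not only through the eventual signature
genes, and at 10,000 genes a sparse planted signature alone cannot carry a
median replicate correlation of 0.2. The default is `group_sd = 0`, which
keeps null genes exactly `N(0, 1)` for the closed-form false-call-rate
checks.

The `small_preset()` study (2,000 genes, 200 donors, 250+250 planted aging
genes at rho ≈ 0.5; per drug 200+200 planted genes, 10 replicate groups of
3 at 60 % recurrence and z-effect 3; 1,000 permutations) runs the full
recovery loop in well under a second. Its fallback trigger is 100 rather
than 1000: a 500+500 fallback is half of this universe and should only
fire if the primary rule nearly fails. The `full_scale_preset()` mirrors
a realistic study shape — 10,000 shared genes, 17 tissues (13 brain
regions, skeletal muscle, kidney cortex, two adipose depots) matched to 4
normal cell lines (NPC, SKL, HA1E, ASC), 28 drugs at 30 donors per tissue
— and is used to exercise the pipeline at scale; per-tissue sample counts
and permutation counts in the tests are kept small so the whole suite runs
in minutes.

What the generator does **not** emulate: gene–gene correlation structure
in expression (GTEx co-expression), dose–response and time trends in the
profiles, moderated-z estimation noise, and identifier mismatch between
datasets. Passing recovery tests therefore demonstrate correctness of the
scoring machinery under the planted model, not robustness to those
real-data features.

## Design choices where the design was open

- **Reproducibility criterion**: median pairwise Spearman within replicate
  group, threshold 0.2, computed over all genes; singleton groups carry no
  internal evidence and are dropped unless `keep_singletons = TRUE`.
  Recurrence is computed after this filter.
- **Both-direction conflicts** in the drug rule resolve by majority;
  exact ties stay 0.
- **Strictness**: `z > 1` strict (a z of exactly 1 does not count);
  recurrence `>= 20 %` non-strict.
- **Two-sided p** with direction read from adjCR vs 1: the framework
  tests acceleration and protection symmetrically.
- **Fallback** applies to the signature as a whole (triggered on the total
  selected count), not per direction.
- **Enrichment background** is the shared gene universe, not the genome:
  the whole analysis lives on the intersection space. The test is
  one-sided (enrichment only), with a Haldane 0.5 correction on the odds
  ratio when a table cell is zero, and both raw p and BH q reported.
  Quadrant lists are enriched separately by default (signed presentation:
  down-quadrants get negative odds ratios), with a pooled mode available.

## Known limitations

- The normal approximation to the permutation null is coarse when the
  expected number of shared genes is small (tens): adjCR is then a ratio
  of small discrete counts, its null is right-skewed, and two-sided
  normal p-values deviate measurably from uniformity even though the
  decision-relevant tail rate stays near nominal (about 0.017 below a
  nominal 0.01 in the package's own calibration runs at 200-gene
  signatures in a 2,000-gene universe). On genome-scale universes with
  500–1000-gene signatures the counts are an order of magnitude larger
  and the approximation is much better behaved; `null = "log"` is the
  conservative alternative at small scale.
- Raw p-values drive event calling (a BH column is informational), so the
  expected number of false events grows with the number of pairs tested.
- Signature construction treats experiments as exchangeable after the
  reproducibility filter; systematic dose or time structure is pooled
  away by design.
- Age brackets are handled as ordinals, which is exact for rank
  correlation but discards within-bracket resolution.
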