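---
title: "Scoring small-molecule / miRNA association from perturbation signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring small-molecule / miRNA association from perturbation signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigmir)
```

## The problem

A miRNA transfection and a drug treatment each leave a transcriptome-wide
fingerprint. When a molecule's fingerprint consistently *reverses* a
miRNA's, the molecule is a candidate inhibitor of that miRNA's programme;
when it mimics it, a candidate activator. `sigmir` scores this similarity
between probe-level expression profiles of the two perturbation classes and
attaches an empirical significance to every molecule–miRNA pair. All
quantities are computed at the probe level on a shared array platform;
cross-platform probe mismatches are handled by intersection at scoring
time, never at read time.

## From profile to signature and pattern

Every profile is reduced to two objects: a **response signature** (the
up- and down-regulated probe sets) and a **ranked response pattern** (all
probes, ordered most-up to most-down by the ranking statistic). Three
statistics cover the three experimental designs:

* **Fold change** (unreplicated miRNA transfections, one sample per
  class): ratio `t/c` on the linear scale, calling `t/c >= 2` up and
  `t/c <= 1/2` down, ranked by `log2(t/c)`. The reciprocal down-rule makes
  the two directions symmetric, which the two-sided enrichment step
  requires.
* **SAM** (designs with >= 2 replicates per class): the regularised
  statistic `d = (mean(T) - mean(C)) / (s + s0)` where `s` is the pooled
  standard error of the mean difference. Our `s0` is the median of the
  per-probe `s` — a deliberate simplification of the original quantile
  optimisation that is reproducible, parameter-free and preserves the
  ranking behaviour. The null is built from class-label permutations
  (all distinct assignments when fewer than 10 exist, with a warning;
  otherwise 100 sampled assignments). Probes are called at the *least
  stringent* symmetric threshold on `|d|` whose estimated median FDR stays
  at or below the target (default 0.05): among all thresholds meeting the
  FDR target we take the one calling the most probes, since a more
  stringent cutoff never helps recall and the FDR estimate is what limits
  precision.
* **Amplitude** (small-molecule instances, one treatment and one control
  vector): `a = (t - c)/((t + c)/2)`, bounded in (−2, 2), with
  `a > 2/3` exactly when `t > 2c` and `a < -2/3` exactly when `t < c/2`.
  The default call threshold `|a| > 2/3` therefore corresponds to the same
  twofold change as the fold-change rule.

`build_signature()` dispatches automatically: replicated designs go to
SAM; unreplicated small-molecule instances to amplitude; unreplicated
miRNA transfections to fold change. Probes with missing values are dropped
listwise per profile. Ties in any ranking statistic are broken by probe ID,
lexicographically — determinism across platforms matters more than any
particular tie order, and ties have measure zero for continuous data.

## Enrichment and the total enrichment score

A signature direction `S` is scored against the opposite perturbagen's
pattern `L` (length `N`, `N_H` hits) by the weighted KS running sum:
walking `L` from the top,

    P_hit(i)  = sum of |r_j|^p over hits j <= i / sum over all hits,
    P_miss(i) = (# misses <= i) / (N - N_H),

and `ES` is the signed value of `P_hit - P_miss` at its maximum absolute
deviation. The weights `r_j` are the ranking statistics of the pattern
being scanned, with exponent `p = 1` by default; `p = 0` recovers the
classic unweighted statistic, and if every hit lands on a zero-weight probe
the unweighted form is used with a warning. Signature members absent from
`L` are dropped (cross-platform intersection is the caller's
responsibility); a direction that ends up empty propagates as a null
marker. When the maximum positive and maximum negative deviations tie in
absolute value the positive one is taken, and the comparison carries a
1e-12 tolerance so that floating-point rounding cannot flip a
mathematically exact tie; among equal deviations the earliest position
wins.

The four directional scores of an (instance, miRNA) pair are combined per
direction of comparison by the sign-opposition rule

    TES = (ES_up - ES_down)/2   if the two scores have opposite signs,
    TES = 0                     otherwise,

and the pair's `TES` is the mean of `TES_sm2mir` and `TES_mir2sm`. The
rule rewards exactly the configuration that indicates a real relationship
— the up-set at one end of the pattern and the down-set at the other — and
returns 0 when both sets drift to the same end, which is what unrelated or
artefactual signatures do. When one direction is null the surviving score
is halved (`ES_up/2` or `-ES_down/2`), keeping the `[-1, 1]` range and not
rewarding one-sided evidence twice. This combination (and its placement at
the TES stage rather than the AS stage) is a design choice of this
package: it is the convention of connectivity-map style scoring, and every
printed property of the score — range, sign semantics, "farther from 0
means stronger" — holds under it.

## The association score and its null

A molecule has `t` instances among the `n` instances scored against one
miRNA profile. All `n` are ranked by signed TES, descending (ranking by
|TES| is available via `rank_by = "absolute"`; signed is the default
because mimicry and reversal are distinct biology and the composite should
keep the sign). With `V(1..t)` the focal molecule's positions,

    a = max_j ( j/t - V(j)/n ),   b = max_j ( V(j)/n - (j-1)/t ),
    AS = a  if a >= b  else  -b.

The `a = b` tie resolves to the positive branch, again a measure-zero
determinism choice. Rank ties are broken by `(molecule_id, instance_id)`.
`n` is always the realised number of scored instances in the run, not any
fixed corpus size.

Significance is a signature-resampling permutation test: each round draws
size-matched random up/down sets — uniformly, without replacement — from
the miRNA's pattern and from each focal instance's pattern, recomputes the
focal instances' TES and the focal AS, and the p-value is the fraction of
random |AS| above the observed |AS| (strict inequality; add-one smoothing
is available behind a flag for users who need a positive minimum p). Two
scope decisions matter here. First, non-focal instances keep their
*observed* TES in the per-round ranking: re-deriving every instance's TES
each round would multiply the cost by the cohort size while testing the
same null — "this molecule's signatures have no specific relationship to
this miRNA" — so the focal-only recomputation is the default and only
implementation. Second, the miRNA and molecule signatures are resampled
jointly in each round rather than alternately. Each pair's RNG stream is
seeded from a hash of `(seed, molecule_id, mirna_profile_id)`, making
every p-value reproducible in isolation and independent of processing
order. No multiple-testing correction is applied by default (the output
reports raw p at the chosen alpha); a Benjamini–Hochberg column is
available via `bh = TRUE`.

## The synthetic cohort generator

`simulation_design()` + `generate_cohort()` emulate the two data classes
the method consumes: one miRNA-transfection experiment and a cohort of
small-molecule instances. Log2-scale baselines are Normal(7, 1) per probe,
planted signature probes shift by ±`effect` in the treatment class, every
sample adds Normal(0, `noise_sd`) noise, and values are exponentiated to
the linear scale. The defaults — 1000 probes, 50+50 planted probes,
`effect = 3` (an eightfold change), `noise_sd = 0.3`, 20 molecules × 3
instances, unreplicated designs — describe a clearly separated planted
signal at a cohort size a desk run can iterate on; the planted molecule's
relation to the miRNA (`mimic` / `reversal` / `null`) and its signature
`overlap` are the experimental dials. Probe IDs are synthetic
(`P000001`…); the generator makes no pretence of real array identifiers.

What the generator does *not* emulate: probe-affinity effects, batch and
chip artefacts, correlated probe blocks, heavy-tailed noise, or
normalisation pipelines. Passing tests therefore demonstrate that the
statistics, the enrichment walk, the KS composite and the permutation
machinery behave correctly under a controlled generative model — not that
the method is robust to real microarray pathology, which is the
responsibility of upstream preprocessing.

## Verification at a glance

The test suite checks each stage against an independent oracle or a known
closed form: the enrichment walk against a brute-force position-by-position
implementation (exhaustively, for every subset of patterns up to length
12), the KS composite against explicit evaluation of both maxima
(exhaustively for all position sets up to `n = 8`), the amplitude against
its printed twofold boundary equivalences, SAM against planted and null
simulations, p-value uniformity on no-association cohorts (10 cohorts of
20 molecules × 3 instances at 200 permutations), and planted-reversal
recovery across 10 seeds at 1000 permutations. These problem sizes are the
package's own verification scale: large enough for the distributional
checks to have power, small enough to iterate on.

## Known limitations

* Unreplicated fold-change and amplitude calls have no variance model; a
  noisy probe with a large ratio is called as readily as a clean one.
  This is inherent to the 1-vs-1 instance design.
* The SAM implementation is two-class unpaired only; no paired or
  multi-class designs, and no moderated-t alternative.
* The permutation null resamples signature *membership* but keeps the
  ranked patterns fixed; structure in the pattern itself (e.g. correlated
  probe blocks) is not represented in the null.
* With `n_perm` permutations the smallest achievable p-value is 0 (or
  `1/(n_perm + 1)` with add-one smoothing); ranking among very strong
  associations is carried by AS, not p.
* Input matrices are assumed preprocessed and on a common platform; the
  package performs no normalisation and no probe-to-gene mapping.
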