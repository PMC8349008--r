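---
title: "Methods: patient-sharing provider networks from claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patient-sharing provider networks from claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis in one paragraph

`psnet` starts from paid claims (inpatient, outpatient, pharmacy) for a
population with behavioral-health diagnoses, builds the cohort of adults
whose care involves the specialty groups of interest, projects
patient-provider claims onto an undirected provider graph thresholded at
three shared patients, keeps the largest connected component, finds
modularity-maximizing communities and nested sub-communities, computes
per-patient Bice–Boxerman continuity of care (CoC) and per-provider
structural metrics, and fits community random-intercept linear models
relating a provider's local transitivity to their mean patient continuity.

# Cohort rules and their encoding

**Age.** The schema carries birth *year* only, as claims extracts usually
do. "At least 18 at the start of the year and under 65 at its end" is
encoded as `year - birth_year >= 18` and `year - birth_year < 65`. Because
`year - birth_year` is the age everyone reaches by December 31, the upper
bound is exact and the lower bound is conservative in the sense that a
person turning 18 during the year qualifies — consistent with cohort tables
that footnote the youngest band as including people who turn 18 mid-year.

**Diagnosis.** All diagnosis positions on all claim types count, including
facility claims with no individual provider. Codes map to six mutually
exclusive categories by a rank hierarchy (schizophrenia/psychotic >
bipolar > depression/mood > anxiety/stress > other mental > substance use):
a patient-year is assigned the highest-ranked category matched by any code.
Nicotine dependence (F17), neonatal abstinence (P96.1) and fetal alcohol
(Q86.0) codes never qualify on their own. The shipped prefix table is a
compact stand-in for the full CCSR crosswalk and is user-replaceable; the
hierarchy logic does not change with the mapping.

**Provider types.** Taxonomy codes map to `pcp`, `psychiatrist`,
`psychologist`, `bh_specialist`; anything unmapped is `other` and is
excluded from the analytic network (and from cohort qualification). The
shipped ~20-code table stands in for the full NUCC set.

**Insurance.** A patient's category over the window derives from the set of
payers on their claims: both public payers → `dual`; commercial plus any
public payer → `commercial_plus_public`; otherwise the single observed
class. This covers simultaneous and sequential coverage with one rule.

# Network construction

Two providers share a patient when each has at least one claim naming them
for that patient anywhere in the window. By default **all claim types**
naming an individual provider contribute (`edge_source = "all_claims"`);
the alternative `"outpatient_visits"` restricts sharing to deduplicated
outpatient visits. The source description of patient sharing does not
restrict the claim type, and the claims universe is explicitly
inpatient + outpatient + pharmacy, so all-claims is the default; the switch
exists because the narrower reading is defensible.

Edges require ≥ 3 distinct shared patients (the standard spurious-tie
threshold in this literature) and are **unweighted** afterwards: community
inference is described in terms of presence/absence of connections, so
shared-patient counts are kept only as edge metadata. One network is built
for the full two-year window. Component-size ties during largest-component
extraction are broken toward the component containing the lexicographically
smallest provider id — irrelevant in practice, necessary for deterministic
tests.

# Community detection

Modularity of a partition with communities $c$ is
$Q = \sum_c [\, e_c/m - (d_c/2m)^2 \,]$ with $m$ edges, $e_c$
within-community edges and $d_c$ total degree. The package implements the
Clauset–Newman–Moore agglomeration itself rather than calling a library:

* only *connected* community pairs are merge candidates (merging
  disconnected communities cannot raise $Q$);
* the pair with maximal $\Delta Q = 2(w_{ij} - a_i a_j)$ is merged; ties
  (within $10^{-12}$) break toward the lexicographically smallest
  (id$_a$, id$_b$) pair, a community's id being the smallest member
  provider id. This makes results invariant to vertex ordering, which the
  reference implementations do not guarantee;
* the returned partition is the one at the peak of the $Q$ trajectory, and
  its stored modularity is *recomputed from the definition* (not taken from
  the accumulated trajectory), so it matches definitional oracles to
  $10^{-12}$;
* the full merge history (pair, $\Delta Q$, running $Q$) is retained for
  auditing and testing.

Sub-communities re-run the same algorithm on each community's induced
subgraph using that subgraph's own edge count. Communities and
sub-communities under 10 providers are excluded from further analysis.
Hierarchical labels read `C2.S3`; at each level labels are ordered by
decreasing size with id-based tie-breaks.

# Continuity of care

For a patient-year with $n$ deduplicated outpatient visits ($n_i$ with
provider $i$), $CoC = (\sum_i n_i^2 - n)\,/\,(n(n-1))$, equal to the
fraction of ordered visit pairs made to the same provider — the
pair-counting identity the test suite exploits as an independent oracle. A
visit is an outpatient-type claim with an E&M procedure code (99201–99499
by default) naming an individual provider, at most one per
patient-provider-day. Patient-years with fewer than 4 visits are
ineligible: low utilizers make the index extremely variable.

Provider mean CoC averages, unweighted, the CoC of all *eligible
patient-years* in which the provider appears, pooled across both study
years (CoC itself is always computed within year). Pooling patient-years is
the simplest reading consistent with a single per-provider average over a
two-year window. Alter CoC is the unweighted mean of the neighbors' mean
CoC, skipping neighbors with missing values; providers with no usable
neighbor get a missing value, not zero.

Local transitivity is edges-among-neighbors over $k(k-1)/2$; it is
*missing* (not zero) below degree 2, and such providers drop out of
transitivity averages and of the models by listwise deletion — silent zeros
would bias every downstream mean.

In the sub-community table, "% PCP connections within sub-community" is a
per-provider proportion (PCP neighbors inside the provider's sub-community
over all PCP neighbors) averaged over providers that have at least one PCP
connection; providers with none contribute nothing. That is the only
denominator under which the statistic can reach 100%.

# Association models

The provider-level model is
$CoC = I + \beta_1 T + \beta_3 P + \beta_4 S + \beta_5 A_{CoC} + u + e$,
with $T$ the provider's transitivity, $P$ the distinct patient count over
the window, $S$ specialty contrasts against the PCP reference, $A_{CoC}$
the alter mean CoC (included in Model 2 only), and $u$ a Gaussian random
intercept at the **community** level — the level named in the model
description; a switch allows sub-community grouping. (The coefficient
numbering skips $\beta_2$; that gap is treated as typographical, not as a
missing predictor.) Estimation is REML via `lme4`; p-values are 1-df Wald
tests on the normal approximation, with no small-sample degrees-of-freedom
correction, matching the stated testing approach. Predictors enter on their
raw scales; the standardized transitivity effect is reported as
`raw slope × SD(T)/SD(CoC)`, a derived quantity rather than a refit. With
fewer than two communities the random intercept is unidentifiable and the
fitter falls back to ordinary least squares with a warning; a boundary
(singular) fit is reported, not treated as an error.

# The synthetic world

`sim_config()` defaults *are* the stated world:

| parameter | default | why |
|---|---|---|
| communities × subs × providers/sub | 5 × 5 × 80 (2,000 providers) | five communities and ~24 sub-communities at desk scale |
| specialty mix | 3833/823/498/3102 of 8256 | the published network composition |
| patients | 20,000 | desk-scale analogue of ~477k |
| diagnosis, insurance, sex margins | published cohort proportions | |
| age range at first year | 17–66 uniform | includes out-of-range ages so the filters have work to do |
| visits/patient-year | negative binomial, mean 6, size 1.2 | overdispersed utilization; a realistic share clears the 4-visit floor |
| personal provider set `m` | 4, Zipf weights tempered by `concentration` (1.5) | yields CoC spanning roughly the observed 0.16–0.39 sub-community range |
| locality | `p_within_sub` 0.75, then `p_within_com` 0.8 | plants the two-level structure |
| `popularity` | 1 (Zipf over provider rank within sub) | claims networks have heavy-tailed provider volumes (median degree far below the mean); without volume concentration almost no pair reaches 3 shared patients at this scale and the planted structure cannot appear in the thresholded graph |

Patients pick a home sub-community; each slot of their personal provider
set draws a pool (own sub-community, else own community, else anywhere) and
then a provider by volume weight inside it; each visit draws from the
personal set with concentration-sharpened weights. Outpatient claims carry
E&M codes and category-consistent F-codes (plus comorbidity codes and
occasional F17.200 secondaries to exercise the exclusion rule); background
pharmacy and facility claims (empty provider id) exercise
diagnosis-classification and visit-identification paths. Identical
configurations produce byte-identical output; the generator seeds a local
RNG and restores the caller's stream.

What the generator does **not** emulate: ICD-10 comorbidity co-occurrence,
geography, payment amounts, referral direction, seasonal utilization. A
green end-to-end test therefore establishes that the machinery recovers
planted structure and planted effects under realistic marginals — not that
any substantive finding about real provider networks is reproduced.

For model validation the provider-level generator
(`simulate_provider_profiles()` + `plant_coc_outcome()`) plants the linear
model directly at the provider level, deliberately decoupling
model-recovery tests from the realism of the visit-level generator. Planted
outcomes are clipped to [0, 1] and the clipped fraction is reported;
recovery experiments use parameter regimes with zero clipping
(σ_u = 0.02, σ_e = 0.05 around published-scale coefficients).

# Numerical choices and degenerate inputs

* Modularity is undefined on an edgeless graph and signalled as an error;
  graphs with < 2 vertices yield a single trivial community.
* ΔQ tie tolerance 10⁻¹²; Q-peak snapshots require improvement > 10⁻¹².
* Unknown taxonomy codes are `other` by contract; malformed ICD-10 codes
  are skipped with a warning; patients with missing birth year are excluded
  and counted separately.
* Zero-variance variables make correlations undefined (`NA` plus a
  warning), never 0.
* An over-aggressive edge threshold that empties the graph degrades
  gracefully: cohort artifacts are still produced and a warning names the
  condition.
* Written CSV artifacts round floats to 6 decimals; in-memory results are
  full precision.

# Known limitations

* The fast-greedy implementation is pure R; it handles the desk-scale
  world (thousands of vertices) in seconds but is not tuned for
  hundred-thousand-vertex graphs.
* CoC eligibility, being per patient-year, interacts with the two-year
  pooling of provider means; providers seen only by low-utilization
  patients have missing CoC and leave the models by listwise deletion
  (counts are logged).
* The shipped taxonomy and diagnosis mappings are deliberately small;
  substantive use requires the licensed full code sets, supplied as
  replacement files.
* Wald normal-approximation p-values are anti-conservative in very small
  community counts; with few groups the random-intercept variance is often
  estimated at the boundary.
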