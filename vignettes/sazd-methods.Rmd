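---
title: "Methods: models, estimators and design choices in sazd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in sazd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sazd)
```

## The problem

A line that produces female-biased broods may do so for many reasons:
X-linked segregation distortion (SD) that kills or incapacitates Y-bearing
sperm; maternally transmitted endosymbionts that kill sons (SK);
constitutive genetic variation for male viability; feminization of XY
individuals by cytoplasmic, X-linked or Y-linked factors; endosymbiont-
induced asexuality; or sexually antagonistic zygotic drive (SA-ZD), a
paternal effect by which the father's X harms the sons that did not inherit
it. SA-ZD is the one etiology with no diagnostic phenotype — it looks
exactly like sex-specific viability — so it can only be established by a
process of elimination across a designed panel of crosses. `sazd`
implements the panel's arithmetic, an automated decision key over it, and a
forward simulator of all competing etiologies so that the key's operating
characteristics can be measured.

## The mechanism model

All mechanisms are expressed as relative survivals or probabilities in
`[0, 1]` (`mechanism_params()`), and all are *activated by genotype*, not by
the parameters alone: the paternal chain (`s_Y`, `s_son_embryo`,
`s_son_post`) fires only for sires whose X carries the driver flag;
son-killing, cytoplasmic feminization and asexuality fire only through
infected dams; the constitutive viability locus is keyed to the offspring's
autosomal dose from the line named by `v_male_origin`, with a configurable
dominance. Key modelling commitments:

* **Multiplicative composition.** Co-occurring male-mortality mechanisms
  multiply on male survival. Independence is the minimal assumption and
  reproduces the sequential SD-then-SA-ZD arithmetic: the subadult
  expectation under `s_Y = a, s_son_post = b` equals the embryo expectation
  under a single `s_Y = a·b` (a tested identity).
* **Sperm killing precedes syngamy.** `s_Y` reweights zygote sex without
  consuming eggs: incapacitated Y-sperm simply lose the fertilization race.
  This is what allows total egg-to-subadult mortality to stay modest while
  the embryo sex ratio is already strongly biased — the observation the
  `mortality_sufficiency()` check formalizes.
* **Stage timing.** Only the paternal `s_son_embryo` can act before the
  embryo census; SK and constitutive viability act entirely after it. The
  screen's first step assumes embryos are sexed before most male-specific
  mortality; if an SK agent killed before the census the key would exit left
  at step 1 (a known false-negative mode, not modelled as the default).
* **Penetrance per sire.** A driver sire either expresses fully or is inert,
  drawn once per sire (per vial in the simulator). Closed forms return the
  pooled-count expectation, i.e. the count mixture over expressing and
  non-expressing sires, which is what a multi-sire experiment estimates.
* **Feminization.** A feminized XY zygote develops, survives and is counted
  as a female from syngamy on; it is exempt from male-specific mortality.
  Whether *embryo* sexing sees it as female is the `sexing` argument
  (`"phenotype"` for sex-specific protein staining, `"karyotype"` for
  chromosomal markers), because the key folds feminization etiologies into
  different exits depending on that choice.
* **Suppressors.** A suppressor declaration names the parameters it restores
  to neutral and where it acts (`"sire"` germline or `"offspring"`).
  Carriage travels on the Y or as an autosomal dominant with the carrier's
  transmission probability; expectations enumerate offspring carriage
  classes exactly, and the simulator draws them per son.

## The synthetic-data generator

`simulate_cross()` realizes the model per vial: one sire per vial, a fixed
(default 150, a typical cull level that avoids larval crowding) or Poisson
egg count, zygote sexes drawn binomially at the sperm-survival-weighted male
probability, then per-individual binomial thinning at the embryo and
post-embryo stages. Vial-level heterogeneity enters by beta-perturbing the
zygote-sex and survival probabilities with intra-class correlation `rho`;
`rho = 0` is pure binomial sampling and leaves the pooled expectation on the
closed forms, larger `rho` widens per-vial variation without moving it. A
sex-independent `base_survival` thins all offspring after the embryo census
so that total-mortality checks have something realistic to measure.

`screen_design()` fixes the study conditions the screen is simulated under:
40 subadult vials of 150 eggs per cross plus 12 embryo-census vials of 120
eggs for the parental crosses, giving roughly 1,400 sexed embryos and
5,000–7,000 subadults per cross — the scale at which the original screen
operated. Defaults `rho = 0.02` (mild vial heterogeneity, typical of
benign-condition vial counts) and `base_survival = 0.92` (sex-independent
egg-to-adult loss consistent with an ~84% total survival once male-specific
death is added) were fixed once as realistic values; neither is derivable
from the counts themselves. F1 and backcross parents are derived by
Mendelian transmission (a son's X from the dam, Y from the sire; compound-X
dams invert this), so backcross genotypes need not be specified by hand.

What the generator does **not** emulate: density-dependent larval survival,
development-time differences between sexes, sperm competition among sires,
within-line genetic segregation beyond the suppressor and viability loci,
and drift in line composition across generations. Passing tests therefore
show that the key discriminates the *modelled* etiologies at realistic
counts — not that real vials are beta-binomial or that real suppressors are
single dominant loci.

## Estimators

* `survival_Y_rel_X(E) = (100·50/E − 50)/50` and
  `survival_m_rel_f(E, F) = (100·E/F − E)/(100 − E)` are exact inversions of
  the percent-female construction; round-trip identities are tested to
  machine precision. `F < E` is clamped to 1 and flagged rather than
  returned as a >1 "survival".
* `sex_ratio_ci()` fits an intercept-only beta-binomial by maximum
  likelihood across vials (the vial is the unit of replication) and profiles
  the likelihood for the interval. With a single vial, an all-female/all-male
  pool, or a fitted intra-class correlation below 1e-5 it returns the pooled
  exact Clopper–Pearson interval instead — exact and conservative where the
  mixture model is unidentifiable. Vials with zero counted offspring are
  dropped; single-sex vials are kept (excluding them would bias the
  estimate downward under strong distortion).
* `recombination_upper_bound()` uses the one-sided exact binomial upper
  limit on the no-driver-class proportion, divided by the detectable
  recombinant fraction (1/2: double-driver recombinants are
  indistinguishable from parentals). From 0/354 this gives 1.69 cM; the
  figure of 2.0 cM sometimes quoted for this design corresponds to 298
  informative sires under the same arithmetic, and this package reports the
  exact value rather than matching the rounder figure. Point estimates at or
  beyond free recombination are capped at 50 cM and flagged `unlinked`.

## The decision key

`run_screen()` evaluates the six steps in order and stops at the first
leftward exit. Two operationalizations were genuinely open:

* **"Significantly greater" at step 1** is confidence-interval exclusion
  (`F` lower bound above `E` upper bound) rather than a two-proportion test;
  CI exclusion uses the same beta-binomial machinery as the estimates
  themselves and is conservative.
* **"Much greater / much less" (`>>`, `<<`)** require both significance and
  magnitude: the realized deviation must exceed a fraction `tau`
  (default 0.5) of the maximum possible deviation — `predicted − 50` at step
  2a, `F − 50` elsewhere. "Most of the deviation" has no canonical number;
  half is the weakest reading of "most". `"≈"` is simply the negation of the
  corresponding `<<` test, mirroring the key's binary structure. No
  multiplicity correction is applied across steps because the key is
  sequential with early stopping.

The false-positive property — under SD-only, SK, constitutive-viability and
Y-linked ground truths at the default design, the SA-ZD verdict rate stays
within the nominal error rate — is asserted over 200 seeded simulations in
the test suite. Two sensitivity limits are worth knowing. First, suppressors
of the zygotic component present in the control line make the screen exit
left under a true SA-ZD line (a false *negative*, asserted as expected
behaviour in the tests). Second, `tau = 0.5` trades power for robustness:
when a strong SD component inflates `F − 50`, a *combined* secondary
mechanism (e.g. SD plus a recessive viability locus) can deviate by less
than half the maximum at every step and slip through to an SA-ZD verdict;
the key is designed to discriminate etiologies one at a time, as its
dichotomous structure implies.

## The linkage assay

Primary families are tested for female bias with a one-sided exact binomial
test; non-significant sires are followed up through grandsons, each of whom
carries a possible driver with probability 1/2 (their mother is at most
heterozygous), so `k` grandsons detect a carrier mother with probability
`1 − (1/2)^k`. Because the follow-up asks a single question per sire across
`k` families, the per-family rescue level is Bonferroni-adjusted to
`alpha/k`; without this, ten tests at `alpha = 0.05` would spuriously
"rescue" about a third of genuinely driver-free sires and bias the map
distance downward. The grandson family-size filter (`min_grandson_family`)
is applied before testing and is configurable, as the original design only
reports that small grandson families were avoided.

## Problem sizes and determinism

The test suite simulates at the default design scale (about 42,000
offspring per simulated screen) and uses 200 screens for the false-positive
property, 100,050 zygotes for simulator-versus-oracle checks and 5×10^4
offspring for parameter recovery — sizes chosen so Monte-Carlo error is an
order of magnitude below every asserted tolerance. All simulation entry
points take an explicit seed; identical seeds reproduce byte-identical
outputs, and pipeline artifacts embed the seed and full configuration.

## Known limitations

* Suppressor genetics is single-locus, fully dominant, with no linkage to
  the viability locus or the driver.
* The key propagates point estimates of the survivals (interval endpoints
  enter only through the significance checks), matching how the screen's
  quantities are used in practice.
* `E < 50` (drive against the X) is out of scope and rejected.
* The beta-binomial profile interval assumes a common vial-level correlation
  across vials of a cross; strongly bimodal vial sets (e.g. mixed expressing
  and non-expressing sires under low penetrance) are summarized, not
  modelled, by the overdispersion parameter.
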