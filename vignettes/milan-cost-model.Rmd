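---
title: "Modeling the cost of FNAC-based triage of salivary gland lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the cost of FNAC-based triage of salivary gland lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milancost)
```

## The clinical question

A patient presents with an ultrasound-confirmed nodule of the parotid or
submandibular gland. Most such lesions are benign, but 20--30% of salivary
gland tumors are malignant, and the two groups need very different operations:
a gland-conserving excision (partial parotidectomy or submandibulectomy) for
benign disease versus an oncologic procedure with neck dissection for
malignancy. Two diagnostic strategies compete:

* **Upfront surgery** — excise the lesion without prior tissue diagnosis and
  let intraoperative frozen section / final histology decide. A malignant
  result after a gland-conserving excision forces a *revision* operation.
* **FNAC first** — an ultrasound-guided fine-needle aspiration, reported under
  the Milan System (MSRSGC), triages the lesion into one of seven categories,
  each with a known risk of malignancy (ROM) and a management recommendation.
  Surgery happens only where the category indicates it.

`milancost` models the *direct cost per case* of the two strategies as a
decision tree, evaluates the tree exactly and by Monte Carlo cohort
simulation, and compares strategies across management scenarios.

## The decision tree

Both arms start with a chance split on anatomic site (`site_mix`, probability
of parotid). In the FNAC arm the cytologic category then dictates the pathway:

| Category | Meaning | Pathway |
|---|---|---|
| I | non-diagnostic | one repeat FNAC |
| II | non-neoplastic | clinical/radiological follow-up, no surgery |
| III | AUS | one repeat FNAC |
| IVa | benign neoplasm | surgery with probability `iva_surgery_rate`, else follow-up |
| IVb | SUMP | gland-conserving surgery |
| V | suspicious | surgery with intraoperative frozen section |
| VI | malignant | surgery with intraoperative frozen section |

Rules shared by all built-in models:

* **One repeat FNAC, never two.** A category I/III lesion gets exactly one
  repeat; if the repeat again reads I/III the patient goes straight to a
  gland-conserving excision. Otherwise the second category's own pathway is
  followed.
* **Revision arm.** Malignant histology after a gland-conserving excision adds
  a completion neck dissection — the gland is already out, so only the neck
  dissection tariff is added (never a second gland excision).
* **Frozen section for V/VI.** A malignant frozen section upgrades the case to
  the primary oncologic procedure (total parotidectomy + neck dissection, or
  submandibulectomy + neck dissection at its bundled tariff); a benign frozen
  section leaves it at the gland-conserving excision.
* **Upfront arm.** Every patient gets the site-appropriate gland-conserving
  excision with frozen section; with probability `upfront_malignancy_rate` the
  histology is malignant and the completion oncologic procedure is *appended*
  (billed on top). A `completion = "replace"` mode, which bills only the
  difference between the oncologic bundle and the excision already performed,
  is available for sensitivity analysis; append is the default because
  revision surgery in practice is a second full procedure.

Costs attach to nodes as increments summed along a path, which is the natural
encoding for revision surgery. Decision nodes carry a fixed chosen branch:
the package compares two given strategies, it never optimizes a policy. No
QALYs, utilities, discounting, currency conversion, or multi-year horizons are
modeled — a single diagnostic episode, cost only. Complication rates are
shipped as a descriptive table (`complication_table()`) and deliberately kept
out of the simulation: they vary widely across patient collectives, and
omitting them is conservative for the FNAC arm since the complication burden
falls mainly on surgery.

## Parameters and defaults

Tariffs (`builtin_cost_table()`): 2025 US fees (CPT; e.g. partial
parotidectomy $13,316, neck dissection $15,396, FNAC $141) and German
DRG/OPS + EBM fees (partial parotidectomy 5047.34 EUR, neck dissection
9864.74 EUR, FNAC 15.37 EUR). Frozen section and follow-up carry no published
tariff and default to 0 (configurable); a repeat FNAC is priced like the
first. Monetary values are carried at full precision and rounded only in
report output.

Three probability sets (`builtin_parameters()`):

* `1a`/`1b` — MSRSGC 2nd-edition estimates (US / German tariffs). The
  published category frequencies are ranges, so the built-ins use range
  midpoints, with an open bound `< x` read as `x/2` and `> x` as the midpoint
  of `(x, 100)`, renormalized to sum to 1. ROMs are the published point
  values (category IVa `< 3%` becomes 1.5%, VI `> 98%` becomes 99%).
* `1c` — a real-world single-center series of 1289 FNACs with final
  histology; category counts (314/182/113/501/72/54/53) are used directly and
  ROMs are the observed per-category malignancy fractions.

Three quantities are not published anywhere and had to be fixed as package
design choices; all are plain fields of `model_parameters()` and overridable
from config files:

* `site_mix = 0.8` parotid. Parotid lesions dominate major salivary gland
  series at roughly this share; the exact split of the modeled cohorts is not
  published.
* `second_fnac_dist = category_dist`: the repeat FNAC redistributes over the
  first-pass marginal distribution — the minimal assumption when nothing is
  published about how repeats resolve.
* `upfront_malignancy_rate = 0.25`: the malignancy prevalence in the upfront
  arm, where no cytology shapes the case mix. We use the midpoint of the
  20--30% malignant share reported for salivary gland tumors, for two
  reasons. First, the upfront arm operates on the presenting population, so
  its prevalence is an epidemiological quantity, not a function of the FNAC
  tables. Second, the cytology-implied alternative (`weighted_rom()`,
  \(\sum_c P(c)\,\mathrm{ROM}(c)\)) differs markedly between probability sets
  (0.239 for the MSRSGC estimates, 0.178 for the real-world table) while the
  published upfront-arm means of the two German models are statistically
  identical — the upfront arm evidently did not inherit the FNAC-arm
  prevalence. A caveat follows from the first reason: FNAC series
  over-represent non-diagnostic and non-neoplastic material, so the two arms
  model slightly different populations; users who want strict internal
  consistency can set `upfront_malignancy_rate = weighted_rom(params)`.

The IVa scenario dial reflects real heterogeneity in managing benign
neoplasms: the base case resects all of them, the 70% scenario resects only
the share of histotypes with documented malignant-transformation potential
(pleomorphic adenoma, basal cell adenoma), and the 0% scenario follows all of
them conservatively. Missed malignancies under conservative management
(categories II and unoperated IVa) incur no modeled downstream cost — the
model covers one diagnostic episode, so the FNAC arm's savings in the 0%
scenario are an upper bound with respect to long-term costs.

## Evaluators and numerical choices

Two exact evaluators are implemented independently and used as each other's
oracle: recursive roll-back (`expected_cost()`) and exhaustive path
enumeration (`enumerate_paths()`, whose probability-weighted cost sum must
match roll-back within 1e-6 relative — pure floating point, no measurement
noise). Structural validation (`validate_tree()`) uses a probability
tolerance of 1e-9 and rejects trees before any evaluation. Zero-probability
branches are dropped at build time, so path tables contain only reachable
paths.

The Monte Carlo simulator (`simulate_tree()`) resolves each chance node with
one uniform draw against the cumulative branch probabilities in declared
branch order — the simplest bit-reproducible scheme. A master seed drives
each run; grid runs derive per-run sub-seeds as
`(seed * 10007 + 7919 k) mod 2147483562 + 1`, so every (model, arm, scenario)
cell is independently reproducible. Arms use independent streams rather than
common random numbers; `compare_arms()` therefore compares independent
cohorts, which is what the reported standard errors assume. The default
cohort is n = 10,000, matching the published analysis; the convergence
diagnostic (`convergence_check()`) flags a run whose mean deviates from the
analytic expectation by more than 3.5 standard errors (false-alarm rate below
1/2000 per check).

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure of the real-world
series: category from `category_dist`, malignancy as a Bernoulli draw with
the category's ROM, site from `site_mix` *independently of category* (no
category-by-site cross-tabulation is published; independence is the minimal
assumption and is a stated limitation, not a claim about the real data).
`estimate_parameters()` recovers frequencies and ROMs with exact
Clopper--Pearson intervals — exact rather than normal-approximation because
categories V and VI have expected counts of only ~50 at the real cohort size
of 1289. What passing recovery tests show is that the generator and estimator
are consistent with each other at the stated confidence level; they cannot
show that real FNAC series are multinomial-Bernoulli, free of site-category
dependence, reader drift, or repeat-FNAC selection effects.

Test problem sizes were chosen to make the binomial bands tight relative to
the effects asserted: single-cohort recovery at n = 1e5, coverage simulation
at 500 replicates of n = 2000, Monte Carlo convergence at n up to 1e5.

## Calibration against the published means

The published analysis reports its node probabilities only in a figure, not
numerically, so the built-in sets rest on the documented fallback assumptions
above. `calibration_report()` compares a simulated grid against the published
per-case means (`published_costs()`); nothing in the simulation reads those
published values. Under the fallback parameterization the simulated means
track the published ones closely for the upfront arm and for the FNAC arm at
IVa rates 1.0 and 0.7, while the IVa-rate-0 FNAC means come out higher than
published — the published drop between the 70% and 0% scenarios is larger
than any linear function of the IVa surgery rate allows under the stated
pathway rules, so the original IVa sub-tree must differ structurally in a way
the text does not determine. The analytic orderings and savings directions
(FNAC arm cheaper in every model and scenario; base-case savings of at least
30%) hold regardless of these assumptions and are asserted exactly in the
test suite.

## Known limitations

* Single-episode direct costs only; no long-term follow-up costs for missed
  malignancies, no indirect costs, no complications.
* Tariff point estimates; US fees in particular vary widely across payers.
* The three unpublished quantities above are assumptions, and the IVa-rate-0
  scenario is calibration-sensitive to them.
* Homogeneous patients: no comorbidity, frailty, or histologic subtype
  structure below the category level.
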