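---
title: "Mechanistic cholestasis prediction: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic cholestasis prediction: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cholmech)
```

## The problem and the modelling idea

Cholestasis — impaired bile flow — is a common form of drug-induced liver
injury, and a large share of cholestatic drugs act by inhibiting the hepatic
transporters that move bile salts and organic anions across the hepatocyte
membrane (BSEP, the MRPs, the OATPs, BCRP, P-gp). A purely structural QSAR
model can predict *whether* a compound inhibits a transporter in vitro, but
inhibition at some concentration only matters if therapy actually produces
that concentration in plasma.

`cholmech` therefore couples three models:

1. **Transporter QSAR panel** — eight per-transporter regressors predict the
   half-maximal inhibitory concentration (IC50, µM) of a compound from its
   structure.
2. **PBTK model** — a six-compartment, flow-limited physiologically based
   toxicokinetic model maps an oral dosing regimen to the steady-state
   plasma concentration (Css).
3. **QIVIVE reverse dosimetry + decision rule** — by linearity of Css in
   dose, each predicted IC50 converts into the oral dose rate that would
   sustain that concentration in plasma (the "in vivo dose"). A compound is
   flagged cholestatic when its therapeutic dose T~D~ exceeds the in vivo
   dose for enough of the selected transporters, under an OR / AND /
   Majority rule and a user correction factor K.

## The PBTK model

Compartments: gut, liver, lungs, arteries, veins, kidneys, plus a gut-lumen
depot. Absorption is first order (rate `ka`, absorbed fraction `f_abs`) from
the depot into gut tissue. All tissues are flow-limited: blood leaves tissue
*i* at concentration $C_i / Kp_i$. Two clearance pathways:

* **hepatic**: rate $f_{ub} \cdot CL_{int,s} \cdot C_{liv}/Kp_{liv}$, the
  well-stirred liver model, with whole-liver intrinsic clearance scaled from
  the hepatocyte assay value:
  $CL_{int,s} = CL_{int} \cdot \text{hepatocellularity} \cdot
  \text{liver mass} \cdot 60 / 10^9$ (µL/min/10^6 cells → L/h);
* **renal**: glomerular filtration of unbound drug,
  $GFR \cdot f_{ub} \cdot C_{art}$.

The circulation closes exactly: cardiac output passes through the lungs;
arterial blood splits into portal, hepatic-arterial, renal and a direct
arteriovenous remainder; the venous pool collects liver and kidney outflow
plus the remainder. Mass balance (administered = in system + metabolized +
excreted + unabsorbed) is tracked at every output time and closes to
solver precision; the test suite requires closure within 0.1% and observes
~10^-13^.

### Closed-form steady state

For a continuous oral intake $R$ (mg/h) the exact steady state of this ODE
system is

$$
C_{ss} \;=\; \frac{R \cdot f_{abs} \cdot F_h}{GFR \cdot f_{ub} + CL_h},
\qquad
CL_h = \frac{Q_l \, f_{ub} \, CL_{int,s}}{Q_l + f_{ub}\, CL_{int,s}},
\qquad
F_h = \frac{Q_l}{Q_l + f_{ub}\, CL_{int,s}},
$$

with $Q_l$ the total hepatic blood flow (portal + arterial). The
first-pass availability $F_h$ is not optional: orally absorbed drug enters
the liver before the systemic circulation, so for high-clearance compounds
($f_{ub} CL_{int,s} \gg Q_l$) omitting it overstates Css more than
ten-fold. We verified by hand (solving the linear system) and numerically
that this expression is the exact steady state of the simulated ODEs; the
suite checks ODE-vs-closed-form agreement within 5% at terminal steady
state over randomized parameters, and observes <1%.

### Css definition and numerics

"Css" here is the **time-average of the plasma concentration over the final
dosing interval** — the quantity the closed form returns, invariant to
dosing frequency at a fixed daily dose (peak and trough are not). The
average is computed from a running-AUC state integrated alongside the
system, so it is accurate to solver tolerance rather than output-grid
density (a 24-point trapezoid on a peaky once-daily profile can be several
percent off; the AUC state removes that artifact). The solver is `lsoda`
(stiff-capable) with rtol 10^-8^, atol 10^-10^, ≥24 output points per
dosing interval, and repeated doses applied as events on the depot.

### Physiological defaults

A 70 kg adult: cardiac output 350 L/h; portal flow 70, hepatic-arterial 20,
renal 70 L/h (remainder shunted artery→vein); GFR 6.7 L/h; liver 1800 g at
110·10^6 hepatocytes/g; standard tissue volumes; `ka` 2.16 h^-1;
`f_abs` 1. Tissue:blood partition coefficients default to 1 and the
blood:plasma ratio to 1: the pipeline's inputs (FUB, CLint) do not
determine tissue partitioning, and the steady-state average that QIVIVE
uses is clearance-dominated — partitioning moves the shape of the profile,
not its average. Every value is overridable per run (`build_parameters()`
or a `key = value` physiology file).

### Units

Two conventions the input schema leaves open are fixed here and should be
kept in mind when preparing tables: **Doses max is mg/day** (divided by
body weight for the comparison), and **CLint is µL/min/10^6 hepatocytes**.
Regimen daily doses are mg/kg/day (the QIVIVE-standard unit); conversion
from mg/day uses the body weight.

## QIVIVE and the decision rule

Because the model is linear, $C_{ss}(d) = d \cdot C_{ss}(1)$, and the oral
dose equivalent of an in vitro concentration is a single division:

$$
d_{t} = \frac{IC50_t \cdot MW / 1000}{C_{ss}(1\ \text{mg/kg/day})}
\quad\text{[mg/kg/day]},
$$

computed per transporter $t$. The suite closes the loop by simulating the
regimen at $d_t$ and recovering the IC50 (as mg/L) within 5%.

**Correction factor K.** K acts on the in vivo doses before the comparison.
The package *divides* by K: K > 1 lowers the flagging threshold and marks
more compounds, i.e. K is a conservative uncertainty factor. The opposite
convention is one flag away (`k_multiplies = TRUE`). Either way the flagged
set grows monotonically with the conservative direction, which the suite
verifies on synthetic batches.

**Rules.** A transporter votes cholestatic when T~D~ (converted to
mg/kg/day) is *strictly greater* than its K-corrected in vivo dose; ties
vote negative. OR requires ≥1 vote, AND all votes, MAJORITY strictly more
than half. These semantics imply AND ⇒ MAJORITY ⇒ OR, verified exhaustively
for every vote pattern over 1–8 selected transporters. The continuous score
used for ranking (and AUC) is the fraction of positive votes — the rule
output is a threshold on it, and it is the natural graded analogue of the
vote count.

## The QSAR panel

The eight transporters carry a fixed algorithm assignment: random forest
for BCRP, MRP2, MRP4, OATP1B1 and P-gp; RBF support vector machine for
MRP3 and OATP1B3; gradient boosting (XGBoost) for BSEP. Models are
regressors on **pIC50** (−log10 molar), the standard QSAR target scale —
training on log-scale stabilizes variance across the orders of magnitude
that IC50s span; predictions are transformed back via
$IC50_{\mu M} = 10^{6 - pIC50}$.

**Featurization** is a 1024-bit OpenBabel FP2 linear-fragment fingerprint
concatenated with a physicochemical block (MW, logP, TPSA, H-bond donors,
two acceptor counts, molar refractivity). Inputs are canonicalized first
and salts reduced to the largest organic fragment, so equivalent SMILES
spellings map to one vector. The recipe is identified by a
`feature_spec_id` stamped into every trained model and checked at
prediction time; it is deliberately pluggable, since no descriptor set is
canonical for this endpoint.

**Hyperparameters** are fixed, documented defaults rather than per-dataset
searches, with one exception:

* random forest — 500 trees, default mtry;
* SVM — a univariate screen keeps the top-k features by absolute
  correlation with the target, then an RBF machine is fit on standardized
  screened features; k ∈ {32, 64, 128}, cost ∈ {1, 10} and γ ∈
  {0.2, 1, 5}/k are chosen by 5-fold cross-validation on shared folds.
  The screen matters: an RBF distance dominated by ~1000 uninformative
  fingerprint bits buries the signal, and screening is routine QSAR
  practice for kernel methods;
* XGBoost — 300 rounds, η 0.05, depth 4, `colsample_bytree` 0.3,
  `subsample` 0.8, λ 5, `min_child_weight` 5, single-threaded. The
  shallow, column-subsampled, regularized configuration consistently
  generalized better on wide fingerprint blocks than deeper unregularized
  trees.

Training is seeded and reproducible (bitwise for the forest and XGBoost;
SVM fitting is deterministic). Panels persist as one serialized estimator
per transporter plus a JSON manifest recording recipe, seeds and
hyperparameters. No applicability-domain filter is applied; that is a
possible extension.

## The synthetic-data generator

Everything is testable offline because the package generates its own data
from an embedded library of 217 real drug structures:

* **Compound tables** — FUB, CLint and maximum dose are drawn log-uniformly
  (defaults: FUB 0.02–1, CLint 0.5–100 µL/min/10^6 cells, dose 5–2000
  mg/day — each spans the range seen across marketed oral drugs). The
  Activity label is **assigned by the generative rule itself**: noise-free
  planted IC50s for all eight transporters, reverse dosimetry under default
  physiology, OR rule at K = 1. Ground truth is therefore recoverable: an
  oracle panel that reproduces the planted functions drives the pipeline to
  accuracy 1 by construction, and the suite checks exactly that.
* **IC50 training tables** — per transporter, pIC50 is a planted linear
  function of a small set of descriptor columns (8 informative fingerprint
  bits plus the physicochemical block, standardized over the library) plus
  Gaussian noise. The variance decomposition is explicit: signal variance
  = `signal_strength` · 1.44, default noise sd = √((1 −
  `signal_strength`) · 1.44), so the planted, recoverable R² equals
  `signal_strength` (total spread ≈1.2 pIC50 units, a realistic assay
  range). Planted pIC50 centres at 3.5 (~300 µM) — transporter inhibition
  is typically weak, and this centring also balances the generated labels.

What the generator does **not** emulate: the chemical space and class
balance of any real reference set; correlated inhibition across
transporters (planted functions are drawn independently); heteroscedastic
or non-Gaussian assay noise; measurement censoring ("IC50 > 100 µM"); and
structures outside the 217-compound library. Passing tests therefore
demonstrate internal correctness and recoverability of a known
ground truth — not prospective accuracy on real chemistry.

## Problem sizes and checks

The property suite runs: 20 randomized parameter sets for conservation and
ODE/closed-form agreement (simulated to ≥7 terminal half-lives); 10
compounds for the QIVIVE round trip; all 510 vote patterns for the rules;
a 200-compound batch for K-monotonicity; 1000 random labelled score sets
plus the exhaustive 2×2 confusion sweep (entries 0–50) for the metrics;
and, for signal recovery, 400-row training tables at `signal_strength` 0.8
evaluated by a pooled two-fold cross split (each half predicted by a model
trained on the other), requiring held-out R² ≥ 0.5 per transporter. The
pooled split is used because a single 20% holdout of 80 rows estimates R²
with a standard error near 0.1, large enough to fail an adequate model by
luck. Because tables of several hundred rows are drawn with replacement
from a 217-structure library, train and test folds can share structures
(with independent noise); held-out R² on these fixtures is accordingly an
internal-consistency measure, not an external-validation estimate.

## Known limitations

* Human physiology only; no population variability, no nonlinear
  (saturable) clearance, no transporter-mediated disposition of the
  compound itself.
* Renal clearance is filtration-only (no secretion/reabsorption).
* The decision layer compares average Css to IC50; peak-driven or
  accumulation-driven toxicity is out of scope.
* AUC of the rule output is computed from the vote-fraction score, which is
  coarse for small transporter selections (many ties; midranks are used).
* Comma-decimal CSV files are not supported (period decimal separator
  only).
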