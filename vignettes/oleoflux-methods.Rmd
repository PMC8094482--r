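---
title: "Stoichiometric lipid-yield analysis: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stoichiometric lipid-yield analysis: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oleoflux)
```

## The question the package answers

Oleaginous yeasts store triacylglycerols (TAGs) made from two cytosolic
currencies: acetyl-CoA (the carbon donor) and NADPH (the reductant). In the
native route, glucose runs down glycolysis to pyruvate, enters the
mitochondrion via pyruvate dehydrogenase, and returns to the cytosol as
acetyl-CoA through citrate and ATP:citrate lyase, while NADPH comes from the
oxidative pentose phosphate pathway (PPP). A classic rewiring replaces part
of this with phosphoketolase (Xpk), which cleaves xylulose 5-phosphate into
acetyl phosphate plus glyceraldehyde 3-phosphate, and phosphotransacetylase
(Pta), which converts acetyl phosphate to acetyl-CoA. Because the Xpk
substrate is itself a PPP product, the rewired route co-produces NADPH and
acetyl-CoA and loses less carbon as CO2.

`oleoflux` quantifies this comparison exactly: how many moles of glucose
must be consumed, at best, per mole of TAG under each network, and what mass
yield (g/g) that implies. It also formalizes the redox argument for why a
phosphofructokinase (Pfk) deletion alone is lethal on glucose: all carbon is
then forced through the oxidative PPP, which overproduces NADPH that this
yeast - lacking a cytosolic NADPH oxidase - cannot reoxidize.

## Precursor and cofactor demand

For a TAG with three acyl chains of lengths $L_i$ (carbons) and $d_i$ double
bonds:

* acetyl-CoA demand $= \sum_i L_i / 2$ (chains grow by two-carbon units);
* all but each chain's primer acetyl unit enters as malonyl-CoA
  ($\sum_i (L_i/2 - 1)$ units, one ATP each via acetyl-CoA carboxylase);
* NADPH demand $= \sum_i 2\,(16/2 - 1)$ for condensations up to C16 plus
  $2\,(L_i-16)/2$ per elongation step beyond C16;
* desaturation consumes reduced cofactor too, but whether the desaturase
  prefers NADH or NADPH is unsettled, so it is a separate line item excluded
  from the NADPH total by default;
* the glycerol backbone contributes three carbons via glycerol 3-phosphate.

For triolein (3 x C18:1, C57H104O6) this gives 27 acetyl-CoA and 48 NADPH
per mole:

```{r demand}
precursor_demand(triolein())
```

## The network model

Networks are small, curated reaction sets with exact rational
coefficients. Conventions:

* **Single pseudo-compartment.** The mitochondrial detour (PDH, citrate
  synthase, ATP:citrate lyase) is lumped into one cytosolic-effective
  reaction: pyruvate + ATP -> acetyl-CoA + CO2 + NADH.
* **Cofactor pairs** (NADPH/NADP+, NADH/NAD+, ATP/ADP) are represented by
  the reduced/charged member only; water, protons, phosphate and free CoA
  are omitted.
* **Lumps**: lower glycolysis (Ga3P -> pyruvate, +2 ATP +1 NADH), the
  oxidative PPP (G6P -> pentose-P + CO2 + 2 NADPH), the non-oxidative PPP
  (3 pentose-P <-> 2 F6P + Ga3P), fatty acid synthesis (the TAG sink built
  automatically from `precursor_demand()`, so changing the target TAG
  propagates), respiration, and a maintenance ATPase.
* **Formulas** attached to metabolites describe the carbon skeleton;
  elemental balance checks therefore skip H and O (water/redox bookkeeping
  is implicit) and skip cofactor members, which reduces to exact carbon
  accounting. Reactions tagged `lumped` can be exempted.

The four packaged networks are the native pathway, the Pfk deletion, and
the Xpk/Pta addition in both backgrounds. The phosphoketolase reaction uses
the X5P mode by default; an F6P mode with configurable product is exposed
via `xpk_reaction("f6p")` because the in-vivo product spectrum of
F6P-phosphoketolase is less settled, and we prefer not to guess which the
field's accounting intends.

## The optimization

`min_substrate()` solves

$$\min \; v_{\mathrm{uptake}} \quad \text{s.t.} \quad S v = 0 \text{ (internal metabolites)},\; v_{\mathrm{irrev}} \ge 0,\; v_{\mathrm{product}} = 1,$$

with strict cofactor balance: a strict cofactor has *no* free sink, so its
row must close exactly. NADH closes through the lumped respiration
reaction; surplus ATP is drained by the maintenance ATPase; NADPH by
default has no outlet other than fatty acid synthesis. `overflow` mode adds
a free sink for a cofactor - the modelling analogue of an organism that can
dispose of excess NADPH.

### The one calibrated parameter: effective P/O

Everything in the networks is textbook stoichiometry except one number: the
ATP yield per NADH respired. The native optimum is insensitive to it (any
value above ~0.5 gives 18 glucose/triolein: 13.5 to acetyl-CoA, 4 fully
oxidized in the cyclic oxidative PPP for 48 NADPH, 0.5 to the backbone).
The rewired optimum *is* sensitive, because the Xpk route sacrifices
glycolytic ATP and NADH, making ATP the binding constraint. The default,
P/O = 16/15 ~ 1.07, is calibrated so that the rewired-network optimum
equals the standard whole-pathway accounting of the Xpk/Pta advantage - a
saving of 2.3 moles of glucose per mole of triolein (47/3 ~ 15.7 versus
18), equivalently 0.31 versus 0.27 g/g. An effective P/O near 1 is
biologically reasonable for cytosolic NADH oxidized through the external
dehydrogenase, bypassing proton-pumping complex I. At the optimum the ATP
balance closes with zero slack: all 25 NADH are respired and exactly cover
the 25-ATP deficit of uptake, carboxylation and the citrate-lyase route.
Users modelling a different respiratory assumption set `atp_per_nadh`
explicitly; `atp_policy = "ignored"` removes the ATP row altogether, which
lets reverse transketolase feed phosphoketolase and drops the optimum to
163/12.

### Exact arithmetic

All coefficients, the simplex tableau and the reported optima are exact
rationals (integer numerator/denominator pairs with gcd reduction and an
overflow guard far below 2^53). This is deliberate: the headline results
are exact integers and small fractions (18, 47/3, 120 excess NADPH), and a
floating LP would reduce "equals 18" to "equals 18 up to tolerance". Two
independent solvers are implemented: a two-phase primal simplex with
Bland's smallest-index rule (anti-cycling, and - with columns ordered
lexicographically by reaction id - a deterministic optimal vertex among
degenerate alternatives), and a brute-force enumerator of basic feasible
solutions used as a verification oracle on networks small enough (a size
guard refuses more than 14 reactions; fixtures are first reduced to their
active routes). The test suite checks solver/oracle agreement on every
fixture and on 100 seeded random networks.

### Infeasibility diagnosis

For an infeasible problem, `feasibility_report()` adds slack sinks to every
strict cofactor and minimizes each sink in turn: the minimum unavoidable
overproduction per unit product. A strictly positive minimum names a
blocking cofactor. For the Pfk-deletion network the diagnosis is exact and
parameter-free: producing one triolein forces 168 NADPH against a demand of
48, an irreducible excess of 120 - NADPH is the blocking cofactor, and
either an overflow valve or the Xpk/Pta reactions restore feasibility.

```{r dpfk}
feasibility_report(yield_problem(dpfk_network()))
```

## Measurement arithmetic

The assay module implements the calculations, not the chemistry:

* **Pta (DTNB) specific activity**: least-squares slope of A412 vs time,
  over readings below a 2.0 AU saturation cutoff; slope / (13.5 mM^-1cm^-1
  x path) x reaction volume / mg extract protein. Non-positive slopes
  return activity 0 with a flag (extracts without the enzyme read at
  background). The fitting window is all points by default; truncation is
  recorded.
* **Xpk (ferric hydroxamate)**: endpoint A540 per mg protein, optionally
  per minute.
* **Fold change**: sample / mean(parent), no background subtraction.
* **Bodipy**: fluorescence / OD600.
* **Fermentation metrics**: LFDCW = DCW - lipid; whole-batch lipid yield
  with the baseline at inoculation; content = final lipid / final DCW;
  cell-specific productivity over a stated window (default days 2-5) as
  lipid formed / (mean LFDCW x window length). The field convention for
  the LFDCW average is not standardized, so both trapezoidal (default) and
  endpoint-mean modes are implemented and labelled; neither is claimed to
  be anyone's exact convention.

## The synthetic-data generators

The generators exist to give every estimator inputs with known truth; they
are not mechanistic bioreactor models. The fermentation law is two-phase:
consumption ramps exponentially through a lag/growth phase until the
lipogenesis onset day, then declines linearly to a residual; lipid titer is
strictly proportional to cumulative consumption (so the whole-batch yield
estimator recovers the true yield *exactly* at zero noise); lipid-free
biomass grows on the pre-onset consumption and is constant afterwards,
matching the "growth has slowed" premise of the productivity window.
Defaults: 150 g/L glucose, daily sampling over 5 days, onset day 2, yield
0.20 g/g, biomass yield 0.25 g/g on the growth-phase half of consumption,
10 g/L residual - implying ~61 % final lipid content. Noise is
multiplicative log-normal (mean 1) per sample; DCW is clipped up to the
lipid titer if noise inverts them, with a flag. Assay traces are linear
with the slope obtained by inverting the estimator, plus additive Gaussian
read noise.

What the generators do *not* emulate - and therefore what passing
recovery tests cannot certify on real data: by-product dynamics (citrate,
polyols), evaporation and sampling-volume effects, non-constant yields
across the batch, correlated measurement errors, detector nonlinearity
beyond the saturation cutoff, and any kinetics (the LP yields are
stoichiometric ceilings, not rate predictions).

## Codon redesign rule

`replace_rare_codons()` substitutes every codon whose *relative synonymous
usage* is at or below the threshold (inclusive; default 2 %) with its
family's maximum-frequency codon. Frequencies are per-amino-acid fractions
summing to 1 within each family - on a genome-wide per-codon scale a 2 %
cut would be meaningless for one- and two-codon families. Ties for the
family maximum break toward the lexicographically smallest codon, making
the rewrite deterministic; stop codons are never rewritten; internal stops
are an error. The profile reports exactly the codons the rewrite would
change, so profile count and change report always agree, and the operation
is idempotent and protein-preserving (property-tested against an
independent translation oracle). The usage table is a user input: which
reference gene set to compute it from is a substantive choice the package
does not make for you. `synthetic_usage_table()` generates valid but
artificial tables for tests and demos.

## Numerical choices and degenerate inputs

* Rational overflow guards abort rather than silently losing exactness.
* `product_amount = 0` short-circuits to the zero flux vector.
* Degenerate alternative LP optima are resolved deterministically (Bland +
  lexicographic column order); reported fluxes are one optimal vertex.
* Zero glucose consumed makes the batch yield undefined (error, not NaN);
  DCW below lipid titer violates a physical invariant and errors.
* Glucose non-monotonicity is tolerated up to a stated relative tolerance
  (measurement noise), larger excursions error.
* Atomic weights are conventional two-decimal values; mass yields are
  reported at full precision and rounded only for display.

## Problem sizes

The shipped analyses and tests run at desk scale by design: networks of
14-16 reactions, oracle enumerations up to a few thousand bases, 20-100
seeded Monte-Carlo replicates, and 1000-sequence codon property sweeps.
These sizes were chosen as the smallest that exercise every code path and
pin every reported number; all are reproducible from fixed seeds.

## Known limitations

* Yields are theoretical maxima under steady state; no growth objective,
  no flux-variability analysis, no kinetics, no regulation.
* The single-compartment lump ignores transport costs and mitochondrial
  redox shuttles; the effective P/O absorbs all of that into one number.
* Elemental checking is carbon-centric by construction of the skeleton
  formulas.
* The codon rule optimizes frequency only - no GC, secondary-structure or
  motif constraints.
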