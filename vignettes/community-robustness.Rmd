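---
title: "Methods: knockout robustness of a cross-feeding community"
author: "cofba"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knockout robustness of a cross-feeding community}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofba)
```

## The model

`cofba` simulates a well-mixed co-culture of up to two species, each
described by a stoichiometric metabolic network, and asks how strongly
single-reaction knockouts perturb the community under two ecological
contexts that differ only in the starting medium.

At each time step of length `dt` every species solves a flux balance
program over its flux vector $v$ (mmol/gDW/h):

$$\max_v \; \mu \quad \text{s.t.} \quad S v = 0,\;
  l \le v \le u,\; v_{\mathrm{sec},m} = r_m \mu$$

where $\mu$ is the flux through the biomass reaction (1/h) and the last
constraint couples the secretion of selected metabolites (here
methionine in the S-like species) to growth at $r_m$ mmol per gDW of
new biomass. Internally the coupling is imposed by adding $r_m$ at the
(metabolite, biomass) entry of the balance matrix, which — because the
coupled metabolite's extracellular pool is touched by exactly one
exchange reaction — is algebraically identical to the stated equality
and keeps the stored stoichiometry untouched.

Because the optimal flux vector of an FBA program is generally not
unique, and because the identity of secreted byproducts is precisely
what couples the two species, a second stage fixes $\mu$ at its optimum
and minimizes $\sum_j |v_j|$ (linearized by flux splitting). This makes
the byproduct spectrum a deterministic function of the inputs. The
tie-break can be disabled (`tie_break = "none"`), but every exported
default uses it, and the test suite asserts that stage two never moves
$\mu$ by more than $10^{-9}$.

An infeasible program is interpreted as "this network cannot satisfy
its constraints, so the cell does not grow": the solver reports
$\mu = 0$ with no fluxes, and the biomass then simply decays at the
death rate. This is deliberate — a knockout that disconnects biomass
production or maintenance is a biological outcome, not a numerical
error.

### Environment dynamics

The environment is a single well-mixed box (default edge 0.5 mm, volume
$1.25\times10^{-7}$ L) holding metabolite pools in mmol. Per step:

1. every species receives uptake bounds
   $V_{\max} c/(K_m + c)$ from the same pool snapshot
   ($c$ = amount/volume; defaults $K_m = 10\,\mu M$,
   $V_{\max} = 10$ mmol/gDW/h);
2. all FBA programs are solved independently;
3. if the species jointly request more of a finite pool than it holds,
   each species' uptake bound for that pool is capped at its *realized*
   request scaled by amount/requested, and the programs are re-solved
   (at most `rescale_iterations` rounds, default 10). Capping the
   realized request rather than the kinetic bound matters: a species
   whose uptake is limited internally (e.g. by downstream oxygen
   demand) would otherwise ignore a bound rescaling entirely and the
   allocation would never converge;
4. biomass follows the forward-Euler update
   $B \leftarrow B(1 + (\mu - d)\,dt)$ with unconditional death rate
   $d$ (default 0.01/h), and pools receive
   $\sum_s v_{\mathrm{ex},s} B_s\, dt$.

All species see the same snapshot and pools are updated once per step,
so the trajectory is invariant to the order of the species list; a
seeded random sequential mode (`update_order = "random"`) is available
for comparison with platforms that randomize calculation order, but is
never the default. "Unlimited" metabolites (the supplemented acetate
and methionine of the competitive medium) saturate uptake at
$V_{\max}$ and are never decremented; this reproduces an inexhaustible
reservoir without infinite pool values. Pools with magnitude below
`tolerance` ($10^{-15}$ mmol) are clamped to zero to stop residual
round-off from masquerading as substrate.

The defaults of `sim_config()` and `make_environment()` are the study
conditions of the screen: 10 h horizon at `dt` 0.1 h, inocula of
$3\times10^{-7}$ g per species, cooperative medium with
$1.2\times10^{-5}$ mmol lactose as limiting resource, oxygen at
$6.2\times10^{-5}$ mmol in every medium, and competition created by
adding unlimited acetate and methionine to the same base.

## The synthetic cross-feeding pair

`make_toy_pair()` generates a hand-solvable stand-in for the published
genome-scale pair, reproducing the three mechanisms that matter:

* **methionine auxotrophy** — the E-like model has no methionine
  synthesis (the *metB*-lesion analogue) and its biomass reaction
  consumes 0.15 mmol methionine per gDW, the value of the published
  *E. coli* reconstruction's biomass composition. An earlier draft used
  0.5, equal to the partner's secretion coupling, but that locks the
  two species' biomass gains 1:1 whenever methionine limits growth and
  erases the carbon consumer's dominance; 0.15 restores the observed
  community structure (E-like majority in cooperation);
* **acetate cross-feeding** — both catabolic routes of the E-like model
  (aerobic, `lcts + 2 O₂ → 6 ATP + 2 ac`, and fermentative,
  `lcts → 2 ATP + 2 ac`) excrete acetate, the only substrate of the
  S-like respirer (`ac + 2 O₂ → 3 ATP`), whose methionine secretion is
  growth-coupled at 0.5 mmol/gDW;
* **oxygen-efficiency asymmetry** — per mmol O₂ the E-like model makes
  0.3 gDW aerobically (and can grow without O₂ at all by fermenting),
  the S-like model 0.15 gDW; `toy_params()` rejects any parameter set
  that loses this asymmetry, since it is what structures competition
  for the shared finite oxygen pool.

Both models also carry a forced ATP maintenance flux (`ATPM`, lower
bound 2 mmol ATP/gDW/h in the E-like and 1 in the S-like model). The
maintenance demand is not decoration: without it, a methionine-free
cooperative medium is a mathematical deadlock. With zero methionine the
E-like optimum is $\mu = 0$, the flux-minimization stage then chooses
the all-zero flux vector, no acetate is ever secreted, and neither
species can start. Maintenance forces resting cells to catabolize
carbon, so a lactose-fed cell secretes acetate while it waits for
methionine — the "jumpstart" that nucleates the mutualism. The E-like
demand must exceed the S-like demand because at equal inocula the
partner's own maintenance burns acetate at exactly the rate a
same-maintenance consumer would supply it; the chosen 2:1 asymmetry
(within the range of published non-growth-associated maintenance
values, e.g. 3.15 mmol/gDW/h for *E. coli*) leaves a surplus that
compounds into growth. A satisfying consequence is that the maintenance
reaction itself reproduces the screen's most interesting essentiality
class: knocking out `ATPM` is harmless — in fact beneficial — in the
supplemented medium but lethal to the cooperative community, the
behavior reported for maintenance-energy reactions in the genome-scale
screen.

With these choices the hand-derived optima used as frozen test oracles
are: E-like $\mu = (30 + 10 - 2)/10 = 3.8$/h at saturated uptake
(aerobic flux 5 capped by oxygen, fermentation 5), 2.8 with
fermentation knocked out, 1.8 with oxygen lost (fermentation only), 0
without methionine; S-like $\mu = (15 - 1)/10 = 1.4$/h with methionine
secretion 0.7 mmol/gDW/h.

## The screen and its statistics

`run_screen()` simulates the unperturbed pair once per condition, then
every single-reaction knockout of the focal species against an
unperturbed partner. Monoculture essentiality is judged in the
competition medium (lactose plus unlimited acetate and methionine),
which supplies everything a partner would. Each mutant × condition
record carries the final biomasses and three metrics relative to the
same condition's unperturbed outcome: Euclidean community distance
(percent), normalized composition and normalized biomass. All three are
invariant to a common rescaling of the biomasses, and the unperturbed
record maps to (0, 1, 1) exactly.

Essentiality is a threshold on the *biomass gain* ratio
(final − initial), not on final biomass: over a 10 h horizon the
initial inoculum is a visible fraction of a non-growing mutant's final
biomass, and a ratio of finals would grade dead mutants by their decay
rather than by growth. When the unperturbed reference itself fails to
gain, a mutant is essential iff it also fails to gain. The default
threshold is 2% of the unperturbed gain; effects on composition or
biomass of at least 1% (inclusive) are counted as substantive.

`summarize_screen()` (also available as `summary()` on the screen
object) compares the two contexts: standard deviations of every metric
per condition — sample standard deviations with the $n-1$ denominator —
computed both over mutants non-essential in *every* context and over
all mutants; a mean-centered Levene test per metric (one-way ANOVA on
$|x - \bar x_{\text{group}}|$, p from the upper tail of
$F(k-1, N-k)$ via `pf()`); substantive-effect counts; and the squared
Pearson correlation of per-mutant effects across conditions, computed
by default over mutants non-essential in both co-culture conditions
(`r2_include_essential` flips this, since large-effect mutants dominate
the correlation when included). Mutants whose community goes extinct
have undefined composition and are recorded as missing, which excludes
them from the composition analyses; they are necessarily essential, so
the non-essential analyses are unaffected. Reported Levene p-values are
floored at $2.2\times10^{-16}$. Degenerate Levene inputs — zero
within-group spread of the absolute deviations — are reported in the
table with the error message rather than aborting the whole summary,
with one distinction: groups with identical *nonzero* absolute
deviations compare as exactly equal variances ($W = 0$, $p = 1$), while
constant groups carry no variance information at all and are flagged
degenerate.

## Numerical choices

The linear programs are solved by a dense bounded-variable two-phase
primal simplex written for this package, recomputing the basic solution
from the factorized basis at every iteration (no update drift) and
switching from Dantzig to Bland pricing on stalls. The FBA programs
here are small (tens of variables), where a dense method is fast and
transparent; the kernel is validated in the test suite against
brute-force vertex enumeration on random programs and against an
independent interior-point/simplex implementation (SciPy HiGHS) on
FBA-shaped programs, including infeasibility classification.
Feasibility and optimality tolerances are $10^{-9}$; fluxes below
$10^{-9}$ are reported as 0. Variable bounds must be finite — models
use ±1000 mmol/gDW/h as "unbounded", the field's convention.

The biomass update is the discrete Euler form $B(1+(\mu-d)dt)$, not the
exponential $Be^{(\mu-d)dt}$: at $dt = 0.1$ h the difference is below
other model error, the Euler form matches the convention of the
platforms this engine mirrors, and it makes the closed-form
single-species trajectory $B_0(1+(\mu-d)dt)^n$ exact, which the tests
exploit at $10^{-9}$ relative tolerance. Exchange bookkeeping is exact
by construction (pool increments are the realized fluxes times biomass
times `dt`), asserted at $10^{-12}$ relative tolerance plus the
near-zero clamp.

## Problem sizes and what the tests show

The package's own experiments run on the synthetic pair: 12 + 8
reactions, 100 dFBA steps per simulation, and a full screen of
24 co-culture plus 13 monoculture simulations, which completes in well
under a minute on one core. These sizes were chosen so every optimum is
hand-checkable and the whole suite is exact; they demonstrate the
machinery and the qualitative ecology (obligate mutualism with E-like
dominance, independence under supplementation, fermentation fallback
shifting composition toward the partner, the cooperation-only
essentiality class, and identical monoculture/competition essentiality
sets). What they do not show is genome-scale behavior: flux magnitudes,
the published variance values and substantive counts, and the 287/+10
essentiality split belong to the iJO1366/iRR1083 reconstructions, which
must be supplied as SBML files (the reader maps SBML-FBC bounds onto
the internal JSON dialect; model checksums are recorded in all outputs
so file-version discrepancies are traceable). The toy's competitive
medium also favors the respirer in *absolute* biomass — unlimited
acetate is a far richer resource relative to the toy's small network
than it is at genome scale — so only composition *shifts*, not
absolute dominance, transfer from toy to full scale in competition.

## Known limitations

* Single well-mixed box: no spatial structure, diffusion or lattice.
* At most two species per community.
* Reaction-level knockouts only; no gene–protein–reaction mapping.
* No lag phases, regulation, or kinetic rate laws beyond
  Michaelis–Menten uptake caps.
* SBML import reads Level 3 with FBC bounds (plus reversibility
  defaults); SBML writing is not supported — the JSON dialect is the
  canonical interchange format.
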