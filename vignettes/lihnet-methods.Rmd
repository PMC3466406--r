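---
title: "Logical hypergraph analysis of signaling networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logical hypergraph analysis of signaling networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lihnet)
```

## The model class and its assumptions

`lihnet` represents a signaling network as a logical interaction
hypergraph: species carry discrete activity levels (`0..max_level`, with 1
the Boolean case), and each hyperarc is an AND conjunction of literals that
drives its target to a stated level. Several hyperarcs into one target
combine by OR, so any logical function can be written in sum-of-products
form; dummy species can factor large expressions, and reservoir species
model shared protein pools (they have no incoming arcs, and their literal
appears in every complex that contains the pool — setting the reservoir to
0 then disables all of them by plain AND semantics, with no special engine
support).

Two modeling conventions deserve emphasis because the field's tools differ
on them:

* **Threshold literals.** A positive literal with threshold $t$ is true iff
  the species value is $\ge t$; a negated literal iff it is $< t$. We chose
  threshold (rather than equality) semantics because it makes activation
  monotone in the level — raising an activator's level never deactivates a
  target — which is the biologically sensible reading of stepwise activity
  levels. The bundled fixtures only use levels where the two readings
  coincide.
* **OR across levels.** When several arcs into one multivalued target are
  satisfied, the target adopts the **maximum** satisfied level; if an
  undetermined arc could still exceed that level, the target stays
  undetermined, because its final value is not unique.

Incomplete-truth-table (ITT) gates encode multi-input activation where only
the unanimous corners are known: all inputs active gives the target level,
all inactive gives 0, anything mixed is unknown. This deliberately limits
determinacy instead of inventing an AND or OR that the evidence does not
support. A species regulated by an ITT gate may have no other regulators —
mixing an ITT gate with OR arcs has no defined semantics, and the validator
rejects it.

## Logical steady states

`compute_lss()` propagates clamps by three-valued (Kleene) iteration to the
least fixed point of the information order: every unclamped species starts
undetermined; an arc is false as soon as one literal is determined false,
true when all are determined true; a species with arcs becomes 0 when all
are false, or the maximum satisfied level when no open arc could exceed it.
Species with no active arcs take their clamp, else their declared default
level, else remain undetermined. The update is monotone — determined values
never change — so the fixed point is unique, independent of evaluation
order, and reached within `n_species * (max_level + 1)` sweeps (the
iteration cap guards implementation bugs, not the mathematics). Every
determined value agrees with every synchronous fixed point consistent with
the clamps; the test suite checks this against exhaustive $2^n$ state
enumeration on random Boolean models.

**Clamps versus propagation.** A clamp models constitutive override
(ligand presence, knockout, small-molecule inhibition), so when propagation
would assign a different value the clamp wins and the disagreement is
recorded in the state's `conflicts` table. Precedence is perturbation >
input > frozen; `scenario_perturb()` overlays intervention candidates on a
context by removing the affected species from the other maps first.

**Time scales.** Feedback loops can prevent a unique steady state (negative
loops oscillate, positive loops are multistationary). Cycle-closing arcs
are therefore tagged with time scale 2 and removed in
`time_scale_mode = "initial"`, opening the loops so the initial response is
computable; species left without arcs then fall back to clamp/default. The
`mapk_toy` fixture shows both regimes: at full scales the negative ERK
feedback leaves Raf/MEK/ERK and the feedback dummy undetermined, while the
initial response is fully determined. The dummy carries default level 0 so
that the opened loop starts from the unstimulated reference, mirroring how
the loop would be inactive before signal arrival. The cross-talk fixtures
likewise put the mutual MAPK↔PI3K activation at scale 2 — without this the
unstimulated network would be undetermined — and all observation scoring
runs at the initial response, while module-clamp truth-table analyses
(where clamps break the loop) run at full scales so cross-talk can fill in
unclamped modules.

`explain_indeterminacy()` attributes undetermined species to undefined
inputs, ITT gates, or membership in a cycle of the undetermined subnetwork,
and propagates causes downstream, so a large undetermined region can be
traced to its sources.

## Minimal intervention sets

An intervention set is a set of constitutive clamps whose application on
top of a context yields a steady state satisfying a goal; it is *minimal*
when no proper subset of its support (under any clamp values) suffices.
`compute_mis()` enumerates size-ascending with superset pruning, which
yields exactly the support-minimal sets — no approximations. Three policy
choices matter:

* Goals require **determined** satisfaction: an undetermined goal species
  is a failure, because an incalculable response is not an enforced one.
* Candidates may be clamped to 0 or their maximum level by default
  (`candidate_levels = "extremes"`), reflecting complete activation or
  inhibition of a target; `"all"` admits intermediate levels, in which case
  one support can contribute several distinct sets.
* The goal species itself is excluded from candidates by default
  (clamping the goal trivially enforces it and is uninformative); context
  perturbations are excluded, while context inputs and frozen species
  remain candidates because an intervention overrides them.

`mis_direct_mediators()` implements the constrained variant used to find
the species of a module that *directly* mediate a response: every module
species is frozen at its value in the unstimulated reference state and
interventions are restricted to the module, so candidates that act only by
activating their downstream neighbors drop out (in a chain A→B→C with goal
C, freezing A and B at 0 leaves only B=1).

`annotate_mis_overlap()` cross-tabulates intervention-target membership
with a mutation list over a species universe, optionally after removing
species whose basal activity the model does not represent, and
`fisher_one_tailed()` tests enrichment of mutated species among targets as
the exact upper-tail hypergeometric probability at fixed margins (the
direction tested is enrichment; it reproduces both bundled contingency
p-values, 0.2596 and 0.0513).

## Interaction graphs and feedback loops

`to_interaction_graph()` splits every AND (and ITT) gate into one signed
edge per literal and removes duplicated identical edges; a pair of opposite
signs between the same species is retained, and each sign choice yields a
distinct signed cycle. Feedback loops are elementary cycles (no repeated
node except closure), enumerated with Johnson's blocked backtracking over
the simple digraph; a cycle's sign is the parity of its inhibiting edges,
self-loops count with length 1, and cycles are reported in a canonical
rotation starting at their lexicographically smallest node.
`loop_participation()` ranks species by cycle membership, the quantity used
to nominate regulators of bistable switches such as the restriction point.

## Scoring predictions and structural sensitivity

`compare_observations()` counts single (scenario, species) observations —
a per-scenario aggregate is available — as match, mismatch or
indeterminate; indeterminate is deliberately not a mismatch, since
indeterminacy is information about the model's structure rather than a
wrong claim. Expected calls of 1 are matched by any positive level, because
activity calls from literature or discretized assays carry no level
information.

`sensitivity_scan()` perturbs structure, not parameters: remove a
time-scale-1 reaction, or weaken an AND conjunction into parallel OR arcs
or an ITT gate, for all combinations of 1–3 eligible arcs (or a seeded
sample). Edit kinds are not mixed within a pool by default, so each pool
isolates one error mode. Each variant's correct-prediction count is
reported relative to the unedited model (= 100%); the summary gives mean,
minimum and the fraction of the pool at or above 90%. ITT conversion is
refused when the target has other incoming arcs (see above), so its pool
ranges only over exclusively-regulated targets.

`enumerate_variants()` searches a finite space of optional edits for
variants that reproduce every observation, grouped into *versions*. Two
groupings are offered: by the prediction vector over the dataset's
scenarios (default), and by the full input–output truth table
(`group_by = "full_io"`). The default follows the convention that a version
collects wiring variations indistinguishable on the probed conditions — a
keep-or-remove choice among redundant arcs then lands in one version even
though the full truth tables differ — while `full_io` distinguishes them.

## Canalizing-input hierarchies

`io_truth_table()` evaluates the steady state for all $2^n$ assignments of
Boolean source inputs (refusing more than 20 inputs). `minimal_dnf()`
computes all prime implicants by Quine–McCluskey merging and then an exact
minimum set cover (essential primes first, exhaustive search over the
rest; ties broken by fewest literals, then lexicographically) — exact
because the input counts of interest are small. A first-order (strong)
canalizing input is an input with a value that forces the output
constant over all other assignments; the analysis then fixes all tier-1
inputs at their non-canalizing values and reads the second tier off the
residual function's minimal DNF, so second-order (weak) canalizing inputs
and canalizing *combinations* (multi-literal implicants such as
insulin·TNFα) emerge from the same construction. Undetermined table rows
abort the extraction rather than being coerced. Functions without any
canalizing input (XOR) return an empty hierarchy with the residual flagged.

On the refined cross-talk fixture this yields tier 1 = {TGFβ → 0} — the
growth inhibitor vetoes DNA synthesis against any mitogen — and tier 2 =
{HGF, EGF, IL6, insulin·TNFα}, and the reconstruction
$\neg\text{TGFb} \wedge (\text{HGF} + \text{EGF} + \text{IL6} +
\text{Insulin}\cdot\text{TNFa})$ reproduces all 64 rows.

## The assay discretizer

DNA-content assays are modeled as
$\log_2$ intensity $= \mu + \beta_{\text{treatment}} + b_{\text{experiment}}
+ \varepsilon$, with a random intercept per experiment (biological
variability between animals) and residual technical error. Intensities are
first scaled to the average intensity of their experiment and
log2-transformed; treatment-vs-control contrasts come from the REML fit
(`lme4`), and a treatment is called 1 when its log2 fold change is positive
and significant at $\alpha = 0.05$.

Numerical and inferential choices:

* **P-values** are one-sided (upper tail: induction) per comparison with
  containment degrees of freedom ($N - n_{\text{exp}} - n_{\text{treat}} +
  1$), so the binary call — which already requires a positive estimate —
  has rate $\alpha$ under a null effect. Single-step Dunnett adjustment
  over the contrast family (`multcomp`) is available via
  `adjust = "dunnett"`; the family size is always reported in the metadata.
  Confidence intervals are two-sided 95% for plotting.
* **Scaling removes the experiment offsets almost exactly**, so the
  random-intercept variance typically sits at the zero boundary; the
  discretizer then falls back to a fixed-effects model with experiment as a
  blocking factor and flags it. In balanced designs the contrasts and their
  standard errors are unchanged by this fallback. `scale = FALSE` fits the
  mixed model on raw log2 intensities, which is how the variance components
  themselves are estimated and tested for recovery.

`simulate_assay()` generates data from exactly this model
(`intensity = baseline · 2^(effect + b + e)`), which is also its limitation:
it emulates multiplicative plate effects, log-normal noise and a shared
experiment intercept, but not dose–response saturation, edge effects,
heteroscedastic well failures or cell death (a negative fold change is the
closest it comes). Passing calibration and power checks on these
simulations therefore validates the inferential machinery, not the
biological assay.

## Problem sizes and determinism

The test suite validates the engines against independent oracles at sizes
where exhaustive computation is itself trustworthy and fast: steady states
against $2^n$ fixed-point enumeration on 200 random Boolean models of up to
12 species; intervention sets against brute-force clamp enumeration with
superset filtering on 100 models of up to 10 species at sizes ≤ 2; cycle
enumeration against naive DFS on 100 digraphs of up to 9 nodes; prime
implicant covers against an exhaustive implicant oracle on 100 random
4-input functions; discretizer calibration on 1000 null and 500
effect-size-1 simulated assays with 4 experiments × 3 technical replicates,
experiment sd 0.2 and technical sd 0.1 on the log2 scale — the design and
noise levels of a typical primary-hepatocyte assay campaign. All generators
take explicit seeds, restore the caller's RNG state, and are
bit-reproducible per seed.

## Known limitations

* Only input–output logic: no attractor or trajectory analysis, no
  asynchronous dynamics, no ODE conversion.
* Two time scales; the initial-response mode removes all scale-2 arcs at
  once rather than ordering them.
* SBML-qual export covers Boolean models without ITT gates; multivalued
  export is refused because threshold literals do not map one-to-one onto
  default-term semantics.
* `minimal_dnf`'s exact cover is exponential in the number of
  non-essential primes; it is intended for the ≤ 20-input tables the
  truth-table guard admits, and in practice for far fewer.
* The bundled cross-talk fixtures are reduced module-level surrogates
  constrained to reproduce printed behavioral statements; they are not a
  species-level reconstruction of hepatocyte signaling.
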