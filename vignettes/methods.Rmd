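---
title: "Methods: enzyme-promiscuity extension of gut-microbiota metabolic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enzyme-promiscuity extension of gut-microbiota metabolic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`phenoflux`, the assumptions behind them, the parameters that matter, and
the choices we made where the design was genuinely open. It states no
empirical result beyond what the test suite and `scripts/acceptance.R`
compute.

## The problem

Phenolic compounds reach the colon largely intact and are transformed
there by the gut microbiota into smaller, often more bioactive
metabolites. Public reconstructions describe only a fraction of this
chemistry: most dietary phenolics appear in no universal reaction
database, so their degradation routes cannot be recovered by ordinary
gap-filling. Enzyme promiscuity offers a way in: enzymes accept substrates
beyond their annotated ones, so a reaction generalized into a structural
rule can be applied to a novel compound to propose an "underground"
reaction. The pipeline predicts such reactions for phenolic sources,
connects them to the known network, and asks what a given diet and
community can produce.

## Network model

A `metabolic_network` is three aligned tables — metabolites, reactions,
and a triplet stoichiometry (negative coefficients are substrates) — from
which the sparse stoichiometric matrix $S$ (metabolites × reactions) is
derived on demand. Reversibility is tied to the bounds
(`reversible` $\iff lb < 0$); irreversible reactions default to
$[0, 1000]$ and reversible to $[-1000, 1000]$ in arbitrary
mmol gDW$^{-1}$ h$^{-1}$ units. The caps are the conventional
large finite bounds that keep every LP bounded. Exchange reactions are
single-metabolite boundary reactions on extracellular compounds;
compartments are tagged `c` / `e` / `lumen` with the suffix convention
`met[c]`.

Metabolite identity across databases is the standard InChI string (with
stereo layers) when available, the raw id otherwise; this is how compound
matching is done when merging AGORA/SEED-style content
(`merge_networks`). Duplicate
reactions are detected by canonical stoichiometry signature — the sorted
(identity-key, coefficient) multiset, orientation-normalized so an
irreversible reaction and its mirror image are distinct but a reversible
one matches either way — with taxa and EC sets unioned on collapse.
Published universal databases do not document their duplicate criterion;
signature equality is this package's choice and the only criterion used.

`filter_universal` implements the universal-database criterion: keep
exactly the reactions with at least one taxon in the allowed set *and*
with an InChI for every participating metabolite. The operation is
idempotent and may produce an empty network.

## Reaction rules and scoring

A rule is a mono-substrate SMARTS transformation with an atom-environment
diameter (even, 6–16 admitted; larger is more specific), a biological
score in $[0,1]$ taken from the rule table as given, and a reference to
the annotated template reaction it was derived from. Rule application,
InChI canonicalization and fingerprints are delegated to RDKit through a
bundled Python helper (`inst/python/chemtools.py`, batched JSON over a
subprocess, memoised per session); no R toolkit applies SMARTS reaction
transforms. Stereochemistry is retained in InChI identity but SMARTS
matching is stereo-agnostic, matching how rule tables are usually written.

The chemical score of applying a rule to substrate $s$ is the Tanimoto
similarity of 2048-bit radius-2 Morgan fingerprints between $s$ and the
rule's template substrate. Only the cutoff (0.6) is fixed by the
procedure this mirrors; radius-2 circular fingerprints follow the
convention of RetroPath RL, the retrosynthesis tool whose input/output
contract this package adopts. Acceptance requires biological score ≥ 0.1 *and* chemical
score ≥ 0.6, both inclusive — a transformation exactly at a cutoff is
kept. When several diameters of the same template rule yield the same
product set, the highest (most specific) diameter wins; diameters are
searched jointly and no published precedence exists, so this is the
package's tie-break.

### Completion and atomic balancing

Rules are mono-substrate, so a prediction like
"daidzein 4′-O-glucuronide → daidzein + D-glucuronate" is incomplete as a
reaction. Completion copies candidate co-substrates from the template
(e.g. water for hydrolyses) and candidate small co-products (≤ 30 atoms,
to exclude the template's structural product), then solves the elemental
balance as a bounded integer search: coefficients of the query substrate
in $\{1,2\}$, predicted products in $1..4$, optional species in $0..4$,
scanned in order of increasing total coefficient sum (then smallest
maximum) so the minimal solution is found first and deterministically.
Hydrogen and charge are balanced jointly, with protons allowed as an
implicit balancer species on either side. If no assignment zeroes every
element residual and the charge residual, the prediction is discarded with
a `balance_error` and counted — never silently dropped. Every emitted
reaction therefore has exactly zero residuals, which the tests verify with
an independent formula-summation oracle.

## Biosensor search

RetroPath RL explores the extended metabolic space with Monte Carlo Tree
Search. This pipeline consumes only that tool's inputs and outputs
(sources, sinks, rules, cutoffs, a scope of transformations), so the
stochastic search is replaced by a deterministic best-first policy:
the frontier is ordered by the combined chemical × biological score of the
transformation that produced each compound, ties broken by insertion
order; a compound in the sink set is never expanded; a compound is
expanded at most once (which also prevents cycles); expansion stops at
`itermax` (default 1000), the wall-clock `time_budget` (default 28 800 s),
or frontier exhaustion. Determinism makes the search testable — identical
inputs give byte-identical scopes — and a seeded stochastic rollout mode
could be added behind the same contract. `max_depth` (default 6
transformations) bounds chain length — a hard cap that iteration and time
limits alone do not give, and that synthetic stress tests rely on.

Pathway extraction walks the scope from the source, branching over
alternative transformations and product sets; a pathway is *connected*
when every terminal metabolite is a sink, and chains that die at a
non-sink compound with no outgoing transformation are counted as
disconnected but not returned. All connected pathways are returned;
ranking them for manual curation is left to the caller.

## Constraint-based core

All LP machinery works on the steady-state polytope
$\{v : S v = 0,\ lb \le v \le ub\}$ with flux tolerance
$\varepsilon = 10^{-6}$ ("nonzero flux"; the community convention,
configurable via `flux_problem(tol=)`). FVA solves min/max per
reaction; blocked reactions are those with $|v| \le \varepsilon$
throughout, and removing them leaves a flux-consistent network (verified
as a fixpoint).

The solver backend is `pracma::linprog` behind a thin adapter
(`lp_solve`), so backends are swappable: bounded problems are
shifted to the nonnegative standard form, upper bounds become inequality
rows, and the result is mapped back. Two quirks of that backend required
care. First, it breaks simplex pivot ties by sampling; the adapter pins a
local RNG seed (restoring the caller's state) so every LP — and hence
FASTCORE and FVA — is deterministic. Second, its big-M phase occasionally
lands on a singular basis; the adapter retries over a ladder of big-M
values crossed with deterministic column permutations before declaring
failure, and reports infeasibility as a distinct status. The FVA tests
compare against a vertex-enumeration oracle on all small fixtures.

Weighted FASTCORE follows the published LP-7/LP-10 scheme: LP-7 maximizes
the number of core reactions reaching flux $\ge \epsilon^*$, LP-10
minimizes the weighted sum of absolute fluxes over the penalty set while
forcing the supported core, and the outer loop alternates with direction
flips for reversible core reactions and a singleton fallback. We use
$\epsilon^* = \max(100\,\varepsilon, 10^{-4})$ for "supported" and collect
the support at $\max(10\,\varepsilon, 0.05\,\epsilon^*)$ — well below the
forcing level, because a reaction carrying the forced flux through
non-unit stoichiometry sits near the forcing value and must not fall off
the threshold (the published implementation avoids the same edge by
rescaling). A core reaction blocked in the universal network raises a
`core_infeasible_error` naming the reaction. Penalty weights default to 1
for annotated and 100 for unannotated reactions; no published weight
values exist, and both are arguments.

## Integration pipeline

`sequential_gapfill` processes compounds one at a time in sorted-id order
(sorted order makes runs reproducible, and
FASTCORE is order-sensitive in principle, so order-insensitivity is
checked on fixtures but not asserted). For each compound the core is the
base network plus that compound's predicted reactions; infeasible
compounds are skipped and reported. The base network always survives —
it is in every core. `prune_and_consistency` then removes non-boundary
reactions without taxa and iterates blocked-reaction removal to a
fixpoint.

The single-species analysis treats a dead-end metabolite as one that is
only produced or only consumed within a species' induced sub-network under
the bounds (the standard definition). Where the
(species, metabolite) pair appears in the transport-evidence table a
transport + exchange pair is added; otherwise the species' annotation is
removed from the stranded reactions. What counts as sufficient transport
evidence is an editorial judgement, so the evidence table is an explicit
input rather than a built-in heuristic.

## Community models and output prediction

`build_community` gives each species its own compartment; extracellular
metabolites of the single-species models pool into a shared lumen, so the
species' transport reactions become the species–lumen links, and each
lumen metabolite gets one exchange. Contextualization opens uptake
($lb = -1000$) only for the food's compounds, leaves secretion open
everywhere, and closes all reactions of absent species to $[0,0]$.
Species presence is binary (abundance > 0 after filtering; the threshold
is configurable), and food composition is qualitative, so uptake bounds
are opened uniformly and no biomass objective is imposed — the predictive rule is pure FVA: an output
microbial metabolite is one whose lumen exchange reaches maximum secretion
flux $> \varepsilon$. Monotonicity (adding reactions never shrinks any
context's output set; closing a species never adds outputs) is tested on
random synthetic contexts.

## Validation statistics

Predictions and metabolomics calls are pooled into one global 2×2 table
over all (metabolite, sample) cells of a fixed universe, giving a single
headline p-value per model version; the universe (all measured cells, or
only the version-discordant metabolites) is an explicit argument, so both
poolings can be reported. The two-sided Fisher
test is implemented by exact hypergeometric enumeration with the
probability-mass rule (all tables with the observed margins whose
probability does not exceed the observed one, with a $10^{-7}$ relative
tie tolerance), clamped to $[0,1]$; a zero margin returns $p = 1$ with a
warning. Tests compare against an independent `lchoose`-based enumeration
oracle and against `stats::fisher.test`.

## Synthetic data: what it emulates and what it does not

`generate_universe` draws metabolites from a curated library of 18
phenolic scaffolds (phenol and benzoate derivatives, hydroxycinnamic
acids, isoflavones, flavones, a flavanone and a flavonol) plus currency
species (water, methanol, glucose, glucuronate), decorated with the
modifications gut microbes reverse most often — O-methyl ethers,
O-glucosides, O-glucuronides — so hydrolysis and demethylation rules have
realistic match semantics. Annotated reactions are the corresponding
deconjugations (with water and the released sugar/alcohol), each with
species drawn over the requested taxa; per-species transports and
reversible exchanges make the universe flux-consistent by construction,
and a posterior `blocked_reactions` check is part of the tests.
`plant_pathways` decorates universe scaffolds further to create novel
sources whose depth-$d$ hidden chains are withheld from the universe; the
rule table contains degradation rules at several diameters per annotated
template, so the search can rediscover the chains, and the full ground
truth is returned. `simulate_metabolomics` draws presence calls at the
chosen sensitivity and specificity. A single global seed fans out to
per-component streams through a documented splitting hash.

What the generator does **not** emulate: mass-spectral artefacts
(adducts, in-source fragmentation, intensity-dependent dropout), 16S read
noise and taxonomic mis-assignment, quantitative diet composition, and
the curation biases of real rule tables (biological scores are drawn
uniformly in $[0.5, 1]$). Passing tests therefore demonstrate the
*pipeline logic* — recovery of plantable chemistry, flux-consistent
integration, monotone community predictions, calibrated validation — not
performance on real metabolomics.

## Problem sizes and runtime choices

The default study conditions in the tests and the acceptance script are a
3-species universe with 14 compounds and 2 planted 2-step sources; the
recovery property uses 20 replicate plantings at depths 1–3 on the same
universe with the permissive chemical cutoff 0.2 (template and query
conjugates of different scaffolds sit near Tanimoto 0.3–0.5, so the
default 0.6 is intentionally stricter than the synthetic analogy);
monotonicity uses a 2-species, 10-compound universe over 50 random
contexts, and the Fisher oracle sweep is exhaustive to $n \le 16$ plus a
400-table random battery with margins ≤ 30. These sizes keep the LP load
of the pure-R simplex modest while exercising every code path; all of
them are arguments, and nothing in the implementation is specific to
these scales.

## Known limitations

* The best-first search returns a subset of the stochastic tool's scope
  when score ties are resolved differently; the contract (connected
  pathways into the sink set) is unchanged.
* FASTCORE is a heuristic: it guarantees a flux-consistent superset of the
  core but not the global weight optimum; the tests pin it to an
  exhaustive-subset oracle only on designed small fixtures.
* The dense-simplex LP backend limits practical problem size to a few
  hundred reactions; real reconstructions (thousands of reactions) would
  need a sparse solver behind the same adapter contract.
* Elemental balancing searches bounded integer coefficients (≤ 4); exotic
  stoichiometries outside that box are rejected rather than solved.
* The SBML layer covers Level-3 core with fbc-style bounds as produced by
  this package; it is an interchange subset, not a general SBML parser.
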