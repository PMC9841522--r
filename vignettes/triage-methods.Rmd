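---
title: "Methods: virtual-screening triage, diversity selection and compound metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual-screening triage, diversity selection and compound metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, conventions and design choices behind
`screentriage`: what each stage computes, which parameters matter and why
their defaults are what they are, what the synthetic generator does and does
not emulate, and the numerical conventions used throughout.

## The triage model

The package implements the standard funnel of a structure-based virtual
screen against a kinase-like ATP site. Its stages are deliberately
decoupled — each consumes and produces plain tables or SDF files — because
the expensive steps in a real campaign (docking, rescoring) happen in
external engines between the stages.

### Stage-1 library filter

A compound is removed when it matches any substructure alert or strictly
exceeds any property bound. The default bounds — more than 4 aromatic
rings, more than 10 rotatable bonds, more than 3 hydrogen-bond donors,
clogP above 5, TPSA above 125 Å² — encode a conventional lead-like profile
for kinase decks; a compound sitting exactly at a bound passes. All fired
rules are reported per compound, not just the first, so filter output can
be audited.

Descriptor conventions, chosen where several definitions circulate:

* *Aromatic rings*: SSSR (smallest set of smallest rings) of the sanitized
  structure; a fused bicycle counts as two rings, not one envelope.
* *Rotatable bonds*: non-ring single bonds between two non-terminal heavy
  atoms, excluding triple-bond-adjacent bonds. Amide C–N rotors are
  excluded by default (the common vendor convention) and can be included
  via `include_amide_rotors = TRUE`, since the exact vendor definition in
  any given campaign is rarely documented.
* *clogP, TPSA, H-bond donors*: OpenBabel's implementations, via
  ChemmineOB. These are well-tested standard estimators, but any two logP
  engines disagree at the fraction-of-a-log-unit level; thresholds should
  be read as conventions, not physical constants.

The built-in alert list is a small curated set of PAINS-like and
reactive-group SMARTS (quinones, catechols, Michael acceptors, acyl/sulfonyl
halides, aldehydes, strained heterocycles, azo/nitroso, anhydrides,
α-halo ketones). It is a pragmatic default, *not* a reproduction of any
published list; full external lists load from two-column CSV via
`read_alert_set()`.

### Stage-2 pool filter

Applied after consensus pooling, when it is worth paying for better
descriptors on the small pool: remove compounds with logD > 5 **and**
PSA > 100 Å². The conjunction is a genuine modelling choice — the
prose convention "logD > 5 and PSA > 100 were removed" admits both
readings — and the package defaults to AND (the literal reading; only
compounds bad on *both* axes are removed), with `combine = "or"` exposed.

logD at pH 7.4 in real campaigns comes from vendor calculators. The
built-in surrogate (`estimate_logd()`) is deliberately simple — logP minus
fixed penalties per basic amine (−2.0) and carboxylic acid (−1.5) — and is
labelled non-reproducing; callers are expected to supply vendor-computed
`logd`/`psa` columns, which is how the pipeline and the synthetic scenario
use the stage.

### Pharmacophore pose filter

A model is a set of typed projection spheres plus exclusion spheres, with
an m-of-n match requirement (default radius 1.4 Å, 2-of-4 in the shipped
example). The semantics adopted:

* A *projection sphere* marks where the complementary **ligand** polar
  heavy atom should sit: an acceptor sphere (projected from a protein
  donor) must contain a ligand acceptor atom, and vice versa. Protein
  coordinates are never needed; model centers are free parameters of the
  model file.
* Only heavy atoms are tested, both for features and exclusions; polar
  hydrogens are folded into the donor typing of their heavy atom, because
  docked SDF poses frequently lack explicit hydrogens.
* Distance exactly equal to the radius counts as inside (≤). Matching is
  evaluated on docked coordinates as given — no re-fitting — so results are
  exactly invariant under joint rigid motions of pose and model (a tested
  invariant).
* Atom typing is rule-based from connectivity: acceptors are N/O atoms
  that are not positively charged and not amide/sulfonamide nitrogens;
  donors are N/O bearing at least one (explicit or implied) hydrogen.
  These rules are the package's own convention; pharmacophore engines
  differ in detail (e.g. whether a projected point computed from ligand
  geometry, rather than the atom position, is tested), and the chosen
  atom-in-sphere rule is documented rather than claimed to replicate any
  particular engine.

Per compound, any passing pose passes the compound; the reported best pose
maximizes matched features, ties broken by the smallest summed
atom-to-center distance, then by first pose index.

### Consensus pooling

Each scoring function contributes its top-N compounds (ties at the cut
broken by id, so prefixes are deterministic); the pool is the union with
per-engine provenance. Raw scores from heterogeneous engines are not
comparable, so the global order is positional: sort by (best rank across
engines, mean rank over engines where present, id). This scale-free rule
is the package's documented choice — workflows of this kind rarely state
their cross-engine ordering — and it is isolated behind `global_rank()` so
an alternative fusion rule can be substituted. For L full lists the pool
size is provably in [N, L·N], a tested invariant.

### Diversity selection

Fingerprints are hashed circular (Morgan-type) fingerprints computed by
OpenBabel's ECFP implementation; `radius` counts bond shells, with the
radius-4 default matching workflows that quote "Morgan, radius 4" — note
that some toolkits quote the same parameter as a *diameter* (ECFP4 =
radius 2), which is why the parameter is exposed. Hashing is 4096-bit,
folded by OR to `nbits` (default 2048); collisions are accepted, as in
standard practice. Tanimoto similarity of two empty fingerprints is
defined as 1 (identical objects).

Clustering is PAM (Kaufman–Rousseeuw BUILD + SWAP) on the full distance
matrix, implemented in C++ with a FastPAM1-style O(n·(n−k)) swap sweep per
iteration. PAM was chosen over Voronoi-style k-medoids for determinism and
solution quality: given the seed (which only permutes tie-breaking order in
BUILD and SWAP) and the input order, the output is fully reproducible, and
the returned cost trace is non-increasing by construction — both tested
contracts. PAM is a local search: on small *unstructured* random distance
matrices it reaches the exhaustive optimum in most but not all instances
(identically to `cluster::pam`, which serves as an independent reference in
the tests); on instances with actual cluster structure — the population a
diversity picker faces — agreement with the exhaustive optimum was
observed universally, and the test suite pins 50 such seeded instances.

The purchase set takes each cluster's best-ranked member, force-adds the
global top-m (default 50) not already selected, and trims the worst-ranked
compounds back to the target size, reporting the trimmed ids worst-first.
Every selected compound carries a reason code (`cluster_best` /
`topM_added`), and trimmed compounds are reported rather than silently
dropped.

### Compound metrics

* LE = c·pIC50/HAC with c = 2.303·R·T at 298.15 K = 1.364 kcal/mol. The
  constant is configurable because 1.37 is also in circulation; at the
  2-decimal reporting precision typical anchor values are insensitive to
  the choice.
* LLE = pIC50 − logP (1 decimal).
* Hit rate = 100·hits/screened (1 decimal).
* Kp,uu = (total brain × fu,brain)/(total plasma × fu,plasma) (2
  decimals); invariant under common unit rescaling of the totals.

Reported values use half-up rounding at the printed precision
(`round_half_up()`), matching how fixed-precision values are printed in
experimental sections; IEEE round-half-even would differ on exact halves.

### Formula masses

`parse_formula()` reads Hill-notation ion formulas as printed in mass
spectrometry sections. Trailing digits before a charge sign are element
subscripts ("…O2S2+" is two sulfurs, charge +1); multiple charges are
written sign-first ("Fe+2") or repeated ("Ca++"). Monoisotopic masses sum
the most-abundant-isotope masses (NIST/AME values, carbon exactly 12);
average masses sum IUPAC standard atomic weights. By default **no**
electron-mass correction is applied for charged species: calculated [M+H]+
values in the literature are most often plain atom sums, and the package's
pinned anchors follow that convention; `electron_correct = TRUE` subtracts
charge × 0.00054858 u for the strict ion mass. Both conventions circulate,
sometimes within one experimental section, which is why the flag exists and
why regression anchors are pinned only to entries that are self-consistent
under the default.

## The synthetic generator

`gen_molecules()`, `gen_poses()`, `gen_ranked_lists()`, `gen_labels()` and
the orchestrating `gen_funnel_scenario()` produce every input the pipeline
consumes, with planted ground truth. All are pure functions of their
parameters and one integer seed (sub-generators draw from named streams, so
adding a generator does not shift another's stream).

* **Molecules** come from a fragment grammar — 8 heteroaryl amine cores ×
  2 linkers × 4 ring decorations × 15 caps (sulfones, sulfonamides,
  amides, ethers, nitriles) = 960 distinct, chemically valid structures
  echoing kinase-inhibitor chemotypes. Grammar compounds pass the default
  stage-1 filter by construction; property violators are separate planted
  molecules, each firing exactly one rule (e.g. a penta-azaaryl chain for
  the ring-count rule, tridecane for clogP, trinitrobenzene for TPSA).
  A grammar guarantees validity and lets quotas be planted by construction
  instead of rejection sampling.
* **Poses** place the planned number of polar atoms inside feature spheres
  at radius·u, u ~ U(0, 0.9), all other atoms on a remote lattice at least
  two radii from every sphere; exclusion violations plant one atom inside
  an exclusion sphere. Sphere overlap in the model is rejected up front so
  plants cannot be ambiguous.
* **Rank lists** solve the union arithmetic exactly: with prefix size N
  and target pool P, a members are shared 3-ways and b 2-ways with
  3a + 2b + c = 3N, a + b + c = P, balanced so each engine holds exactly N
  pool members ahead of filler entries; one engine is lower-better to
  exercise direction handling.
* **Labels** are Bernoulli(hit_rate), default 0.5% — the hit-rate scale of
  a typical structure-based campaign.

The shipped funnel scenario plants the full arithmetic 3×1000 → 2057 →
1743 → 960 clusters → 960 selected with 21 trimmed. Its one non-obvious
construction: the 1743 stage-2 survivors form 960 structure *families*
(pairs share one SMILES; 21 pairs sit entirely inside the consensus
top-50, 762 pairs have their worse member below the top-50, 177 are
singletons). Within-family fingerprint distance is exactly 0 and
between-family distance is positive (verified for the whole grammar), so
the k = 960 PAM partition is the provable cost-0 optimum and recovers the
families exactly, which in turn makes the 50 − 29 = 21 trim arithmetic
exact rather than statistical.

What the generator does **not** emulate: realistic docking-score
distributions and their correlation structure, conformer strain, tautomer
and protonation-state enumeration, vendor-library chemotype imbalance, or
fingerprint near-duplicates that straddle cluster boundaries. Passing the
planted tests therefore demonstrates that the *logic* of every stage is
correct and deterministic, not that any particular real campaign's
intermediate counts would be reproduced; those depend on commercial decks
and external engines.

## Problem sizes and numerical choices

The shipped scenario runs the funnel at the full scale its defaults encode
(deck ≈ 2250, pool 2057, clustering 1743 → 960) in a few minutes on one
core; unit tests
use decks of 1–200 compounds and clustering instances of n ≤ 8 (where the
exhaustive oracle is feasible) plus seeded 200-pose screens. Distance
matrices are kept dense (an n = 1743 matrix is ~24 MB); the implementation
is not intended beyond ~10⁴ compounds.

Tolerances: geometric comparisons use exact ≤ at machine precision
(boundary-inclusive by design); PAM improvement uses an absolute 1e-12
epsilon so zero-gain swap cycles terminate; mass tables are pinned
constants compared at printed precision (4 decimals), insulating tests
against fifth-decimal isotope-table revisions.

## Known limitations

* Descriptors inherit OpenBabel's conventions; campaigns built on vendor
  calculators (clogP, logD, TPSA variants) will classify borderline
  compounds differently. Callers can supply precomputed descriptor columns
  wherever thresholds are applied.
* The pharmacophore atom-typing rules are intentionally minimal
  (kekulized-structure heuristics; pyrrole-type NH lone-pair availability
  is not modelled).
* PAM results, while deterministic, are local optima on pathological
  (non-metric, unstructured) distance matrices.
* The consensus global-rank rule is one defensible choice among several;
  rank-fusion schemes based on score normalization are out of scope.
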