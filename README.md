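# screentriage

Virtual-screening triage for structure-based hit finding, built around the
funnel used in kinase inhibitor campaigns: a large vendor deck is cut down by
substructure alerts and physicochemical property rules, docked poses are
filtered against a 3D pharmacophore with exclusion volumes, the top-N ranks
of several docking scoring functions are pooled, a second property cut is
applied to the pool, and a diverse purchase set is assembled by K-medoids
clustering on fingerprint distances. The package also computes the standard
compound-quality metrics used when the resulting hits are profiled, and the
calculated m/z values used to confirm compound identity.

It is aimed at computational chemists who run such campaigns with external
docking engines (GOLD, Glide, MOE and the like) and want the *triage* around
those engines to be reproducible, scriptable and testable. The docking
engines themselves are out of scope: poses and scores are consumed as SDF
and CSV inputs.

## The pipeline

For a deck D, alert set A, thresholds T, pharmacophore P, engine rank lists
R1..RL and sizes (N, k, target, m):

1. **Stage-1 filter** — remove compounds matching any alert in A or
   exceeding any property bound (defaults: aromatic rings > 4, rotatable
   bonds > 10, H-bond donors > 3, clogP > 5, TPSA > 125 Å²; strict
   inequalities).
2. **Pharmacophore filter** — a docked pose passes P if at least
   `min_required` of its typed projection spheres (radius 1.4 Å by default)
   contain a complementary ligand heavy atom, and no heavy atom enters an
   exclusion sphere. A compound passes if any pose passes.
3. **Consensus pool** — union of the top-N entries of each rank list;
   member order by the key (best positional rank across engines, mean
   positional rank over engines present, id).
4. **Stage-2 filter** — remove pool members with logD > 5 AND PSA > 100 Å²
   (OR semantics available).
5. **Diversity selection** — Morgan-type circular fingerprints (radius 4,
   2048 bits), Tanimoto distance d = 1 − |a∩b|/|a∪b|, PAM K-medoids into k
   clusters; take each cluster's best-ranked member, force-add the global
   top-m, trim the worst-ranked back to `target`.
6. **Metrics** — LE = 1.364·pIC50/HAC (kcal/mol per heavy atom),
   LLE = pIC50 − logP, hit rate = 100·hits/screened, and
   Kp,uu = (C_brain·fu_brain)/(C_plasma·fu_plasma).

A molecular-formula mass calculator (`monoisotopic_mass()`,
`average_mass()`) reproduces calculated HRMS/LRMS m/z values at printed
precision.

## Worked example

Every input can be synthesized with planted ground truth, so the whole
funnel runs without any external data:

```r
library(screentriage)

sc <- gen_funnel_scenario(seed = 17)   # planted deck, rank lists, truth
res <- run_funnel(sc)                  # pool -> stage-2 -> cluster -> select
res$counts
#>      pool survivors  clusters    chosen   trimmed
#>      2057      1743       960       960        21

monoisotopic_mass("C16H15N4OS+")   # [M+H]+ of a thienopyrimidine hit
#> [1] 311.0967
ligand_efficiency(6.70, 20)        # pIC50 6.70, 20 heavy atoms
#> [1] 0.46
hit_rate(5, 960)                   # 5 actives from a 960-compound plate set
#> [1] 0.5
```

The counts read as: three top-1000 rank lists pool to 2057 unique
compounds; the stage-2 property cut leaves 1743; these cluster into 960
groups; the purchase set of 960 results after force-adding the consensus
top-50 and trimming the 21 worst-ranked over-quota compounds.

File-based runs are driven by a config (`run_config()` / `run_pipeline()`),
and `inst/cli/triage.R` exposes the same operations as shell subcommands
(`run`, `filter`, `pharm-filter`, `pool`, `cluster-select`, `metrics`,
`masscalc`, `simulate`).

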