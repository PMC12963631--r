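# scfvforge

Charge-based design, prediction and ranking of scFv intrabodies.

## The problem

Antibody variable fragments (Fv) are extracellular proteins: most are
electropositive with isoelectric points above physiological pH. Joined
into single-chain variable fragments (scFv) and expressed in the
cytoplasm as *intrabodies*, they usually aggregate. Intracellular
solubility turns out to track a single, easily engineered sequence
feature — the counting net charge

```
c = (#K + #R) − (#D + #E)
```

— and percent partitioning into the soluble mammalian cell fraction is
well approximated over the working range (+3 to −20) by the line

```
percent soluble = −4.6237 · c + 8.2469
```

with *high solubility* defined as strictly > 70%. `scfvforge` is for
protein engineers who want to reformat an existing antibody as a
working intrabody: it profiles variable domains (net charge, charge at
pH 5.5, pI, GRAVY, aliphatic mole percent), predicts solubility,
assembles constructs from charged linker/tag libraries with the VLVH
orientation rule, budgets charge toward a target solubility, builds
fixed-position masks for inverse-folding tools, and validates, ranks
and summarises their output ensembles. A deterministic synthetic-data
module makes every analysis testable offline.

## Worked example

Reformat a (synthetic) antibody whose Fv carries the repertoire-typical
charge of +2 — VH framework +3, VH CDR −2 — into a high-solubility
intrabody construct, then rescore an inverse-folding ensemble:

```r
library(scfvforge)

fv <- generate_fv(seed = 42)          # a stand-in for a sequenced antibody
region_charges(fv$vl, fv$vh)
#> VL: framework +1, CDR +0, domain +1
#> VH: framework +3, CDR -2, domain +1

predict_for_sequence(paste0(fv$vl$sequence, fv$vh$sequence))
#> net charge +2 -> 0.00% soluble (not high solubility)
```

The bare Fv would be essentially insoluble in the cytoplasm. Invert
the predictor to find the required construct charge and a minimal part
set:

```r
budget <- charge_budget(fv_charge = 2, target_percent = 70)
budget
#> required construct charge: -14
#> recommendation: linker composed(-9) + tags 3xFLAG -> charge -14 (72.98% predicted)

cons <- assemble_scfv(fv$vl, fv$vh, linker = budget$recommendation$linker,
                      tags = budget$recommendation$tags)
cons
#> scFv construct (VLVH): N[3xFLAG] VL-kappa | composed(-9) | VH C[-]
#>   266 aa, net charge -14, predicted solubility 72.98%
```

A charge of −14 is the largest integer meeting 70%; the recommendation
is a −9 composed linker plus the 3xFLAG tag (−7) against the Fv's +2.
Now build the production mask (CDRs, interface β-strands and linker
fixed), validate and rank a design ensemble, and summarise it:

```r
mask <- build_fixed_mask(cons, "production")
mask
#> <fixed_mask production: 114 fixed positions incl. linker>

cands <- generate_ensemble(cons, mask, n = 100, substitution_rate = 0.3,
                           charge_bias = -0.6, seed = 42)
vc <- mapply(function(c, i) validate_candidate(cons, c, mask, model_rank = i),
             cands, seq_along(cands), SIMPLIFY = FALSE)
ranked <- rank_candidates(vc)
ranked[[1]]$predicted_percent
#> [1] 100

ensemble_summary(cons, vc, mask)
#> ensemble of 100 valid candidates
#>   mean conservation: 0.861
#>   non-fixed positions substituted in consensus: VL 24%, VH 31%
#>   VL framework charge: parent +1 -> consensus -12
#>   VH framework charge: parent +3 -> consensus -13
```

Fixed positions (CDRs, cysteines, the VL 61–82 and VH 66–86 salt
bridges, the linker) are untouched in every valid candidate; roughly
30% of non-fixed positions are substituted in the consensus; and the
charge-biased redesign flips the electropositive VH framework negative
— the signature of a successful intrabody redesign. Ranking is
solubility-first (predicted percent descending, generator rank on
ties), so the top candidate is the most negatively charged valid
design.

The same steps run from the shell:

```sh
forge simulate fv --seed 42 --out fv.fasta
forge assemble fv.fasta scfv.fasta --linker "(G4D)4" --tags 3xFLAG,HA --report design.json
forge predict scfv.fasta pred.tsv --mode asis
```

## Layout

* `R/` — modules: `seqio` (FASTA/report I/O, scFv decomposition),
  `numbering` (Chothia template transfer, regions, mutations, salt
  bridges), `physchem` (charge/pI/GRAVY/aliphatic), `solubility`
  (predictor + linear fit), `construct` (libraries, assembly,
  budgeting), `redesign` (masks, validation, ranking, ensembles),
  `cohort` (filtering, dedup, surveys), `fixtures` (seeded
  generators), `cli`.
* `vignettes/intrabody-design.Rmd` — the model, its assumptions,
  numerical choices and limitations.
* `tests/testthat/` — unit, property and acceptance suites; all
  fixtures are generated in code.
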