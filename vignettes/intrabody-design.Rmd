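---
title: "Charge-based design of scFv intrabodies: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge-based design of scFv intrabodies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scfvforge)
```

## The problem

Antibodies are secreted proteins. Their variable fragments (Fv) evolved
for the oxidising, proteoglycan-rich extracellular space and are
typically electropositive, with isoelectric points above physiological
pH. Expressed in the cytoplasm as single-chain variable fragments
(scFv "intrabodies"), most of them aggregate. The single sequence
feature that best separates soluble from insoluble intrabodies is the
whole-molecule *counting net charge*

$$ c \;=\; (\#K + \#R) - (\#D + \#E), $$

and over the practically relevant range (roughly $+3$ to $-20$) the
percent of protein partitioning into the soluble fraction of mammalian
cells is well described by a line

$$ \widehat{S}(c) \;=\; -4.6237\,c + 8.2469 \quad (\%), $$

with "high solubility" defined as strictly more than 70% soluble
partitioning. `scfvforge` packages this predictor together with
everything needed to *act* on it: Chothia numbering and CDR/framework
segmentation, charged linker/tag libraries and construct assembly,
charge budgeting, fixed-position masks plus validation/ranking of
inverse-folding outputs, and repertoire-scale filtering utilities —
all exercisable on synthetic sequences with no downloads.

## The predictor and its assumptions

`predict_percent()` evaluates the line above and clamps into
$[0, 100]$; the raw line is unbounded and percentages outside that
interval are physically meaningless. Clamping is applied after, never
during, fitting (`fit_linear()` is plain OLS on unclamped values).
Three assumptions matter:

* **Counting charge, not titration charge.** The predictor was
  calibrated on $(K+R)-(D+E)$; histidines and termini are ignored at
  physiological pH. `charge_ph55()` (which adds histidines) and the
  Henderson–Hasselbalch machinery behind `isoelectric_point()` exist
  as separate observables and are deliberately *not* substituted into
  the predictor.
* **Charge is a proxy for surface charge.** Variable domains are small
  and their charged residues are essentially always at least partly
  solvent exposed, which is why a sequence-level count works at all.
  The package does not attempt structure-based surface-charge
  corrections.
* **Strict threshold.** `classify_high_solubility()` uses a strict
  `> 70` boundary; a prediction of exactly 70% is not-high.

## Numbering by template transfer

`number_domain()` aligns a query against three embedded
Chothia-labelled templates (a human VH3-23/JH4 heavy template, an
IGKV1-39/JK kappa template and an IGLV1-40-style lambda template) with
`Biostrings::pairwiseAlignment` (local, BLOSUM62, gap open 10, extend
1 — fixed for determinism). The best template's labels transfer across
matched columns; query insertions receive insertion codes (a, b, c…);
deletions drop labels. A query is accepted as a variable domain only
if its alignment score exceeds **0.30 of the template's self-alignment
score**. This threshold was calibrated against the score distribution
of shuffled templates (which retain composition but not the fold
signal and score ≈ 0.05–0.08 of self) and genuinely divergent
germlines (≈ 0.5 and above); anything near the threshold is not an
antibody domain. The engine is deliberately desk-scale — it is not a
replacement for a profile-HMM numbering suite, but it is exact on the
framework/CDR charge arithmetic this package needs, and it is fully
deterministic.

Region boundaries are data, not code: `default_region_map()` ships
CDR ranges VL 24–34 / 50–56 / 89–97 and VH 25–32 / 52–56 / 95–102.
Note that VH CDR1 starting at 25 is one residue wider than the
canonical Chothia H1 (26–32); the package follows the boundary set
used to build its masks rather than resolving the discrepancy, and the
map can be swapped wholesale. Insertion-coded residues inherit the
region of their base number. Coordinates: `source_span` and mask
indices are 0-based half-open; Chothia labels are 1-based.

## Construct assembly rules

* **Orientation.** Auto orientation is always VLVH. Positively charged
  VH domains translated first (VHVL) lose the chaperoning effect of
  the VL and show reduced solubility, so an explicit VHVL request with
  a positive-charge VH is honoured but warned about. We chose the
  unconditional VLVH default (rather than conditioning on VH charge)
  because VLVH is the more reliable orientation overall and charge
  swap mutations are the stated remedy when VHVL is required.
* **Linkers.** The library holds (G4S)4 and six electronegative
  derivatives with charges 0/−4/−4/−7/−7/−10/−10.
  `linker_for_charge()` returns a library member at 0/−4/−7/−10 and
  otherwise composes a 20-mer over {G,S,D} with the exact requested
  charge; 20 residues keeps the flexibility envelope of the (G4X)4
  family.
* **Tags.** 3xFLAG (−7, N-terminal by default) and HA (−2,
  C-terminal) jointly contribute −9. The myc sequence used
  experimentally is not published; the canonical EQKLISEEDL is assumed
  and its counting charge is −3 (computed, like all part charges,
  from sequence — never hardcoded).
* **Charge budgeting.** `charge_budget()` inverts the predictor: the
  required construct charge is the largest integer $c$ with
  $\widehat S(c) \ge$ the target. The part search prefers the fewest
  modifications; if even linker −10 + 3xFLAG + HA (−19 total) falls
  short it reports the residual gap and states that framework
  charge-swap mutations are additionally needed.

## Inverse-folding support

`build_fixed_mask()` resolves three published mask modes to concrete
indices: `cdr_only` (the six CDRs), `extended` (CDR1–FR2–CDR2 and CDR3
grown by flanking residues: VL 24–36/47–56/86–97, VH 26–59/91–105) and
`production` (VL 24–56/86–100, VH 26–56/92–105 plus the linker — the
mode that in practice preserves antigen binding, because two thirds of
the β-strands flanking each CDR sit in the domain interface).
`validate_candidate()` enforces what redesign must never change: fixed
positions, cysteines, and the conserved salt bridges VL Arg/Lys61–Asp82
and VH Arg/Lys66–Asp86 at the N-termini of β-strands D and F, whose
disruption destabilises the domain. Ranking is solubility-first:
predicted percent descending, generator rank ascending on ties, then
sequence — a total order, so shuffled input cannot change the result.
Whether the original sort was strictly lexicographic or blended is not
specified anywhere; both are available (`weights =` selects a weighted
sum) with lexicographic as the default. Invalid candidates are
excluded rather than penalised, since fixed positions are constrained
at generation time and a violation indicates a pipeline fault, not a
bad design.

## What the synthetic generators emulate — and what they do not

`generate_fv()` starts from the embedded templates and substitutes at
eligible positions (never cysteines, salt bridges, glycines/prolines
or the three terminal residues of either end) until requested
per-region charges are met. Defaults state the repertoire world the
analyses assume: **VH framework +3, VH CDR −2, VL framework +1, VL CDR
0**, i.e. a paired-Fv charge of +2 — the modal charge and the
framework/CDR di-polarity of heavy domains seen in large repertoires.
A few neutral-for-neutral CDR substitutions decorrelate CDR keys
across seeds without touching charge.

`generate_ensemble()` draws a set of design positions and one
replacement per position *once per ensemble*, and candidates adopt the
replacement with probability 0.8. This mirrors the behaviour of real
inverse-folding models, which substitute particular (surface)
positions consistently across their outputs; independent per-candidate
substitution would never move the consensus and could not reproduce
the observed consensus-level framework charge shifts. The default
substitution rate of 0.3 matches the ≈30% of non-fixed positions
changed in practice.

`generate_solubility_dataset()` draws integer charges uniformly over
+3…−20 and adds Gaussian noise (σ = 10%) around the true line,
truncating into $[0, 100]$. Truncation (not resampling) is used,
which slightly biases extreme-charge bins toward the interior — at
zero noise, charges +2/+3 predict negative percent and are truncated,
so exact-recovery tests use a truncation-free range (−19…+1). A
closed-form check, $R^2 = 1/(1 + \sigma^2/(\beta^2\,\mathrm{Var}\,x))
\approx 0.91$ at the default settings, anchors the Monte-Carlo bands
used in the tests.

None of the generators emulate germline diversity, somatic
hypermutation statistics, or real linker-sequence variety. A green
test therefore establishes that the *algorithms* are correct on inputs
with the assumed statistical structure — not that any particular
repertoire-scale percentage is reproduced. Headline database fractions
(e.g. how many repertoire scFvs clear 70% with a given tag/linker
combination) require external repertoire snapshots and are explicitly
outside the test surface; the cohort module's correctness is
established on synthetic cohorts by brute-force checks instead.

## Numerical choices

* **pI.** Bisection on the Henderson–Hasselbalch total charge over pH
  0–14 to |charge| < 10⁻⁴, independently under two pinned pKa tables
  (a Bjellqvist-style table and an IPC-protein-style table); the
  reported pI is the mean across tables, mirroring calculators that
  average across scales. Free termini are included by default. A
  dense-grid oracle (0.001 pH steps) agrees to 0.01 pH.
* **Aliphatic index.** The unweighted mole percent of A/V/I/L, exactly
  as defined in the source method — this is *not* Ikai's weighted
  index; the classical form is available via `weighted = TRUE`.
* **Linker detection.** A linker is the maximal run of {G,S,D,E}
  longer than six residues lying between two numbering-positive
  domain segments. The alphabet is fixed to the charged-linker family
  to avoid absorbing framework residues; gap residues outside the run
  are returned to the flanking domains so that parsing always
  concatenates back to the input exactly. Two qualifying runs raise an
  ambiguity error rather than a guess. Tags are recognised only by
  exact match against a declared library — unknown tags must be
  declared, not inferred.
* **Ties.** Consensus ties keep the parent residue; dedup charge ties
  keep the lexicographically smallest id; ranking ties fall back to
  generator rank, then sequence.

## Known limitations

* Numbering is template-transfer against three templates; exotic
  germlines, heavy CDR-H3 insertions beyond a handful of residues, or
  camelid/VHH domains may number poorly. The acceptance threshold
  fails closed (not-a-domain error).
* The predictor is linear and charge-only by design; residual spread
  around the line (stability, hydrophobic patches) is real and is the
  reason inverse-folding rescoring exists in the workflow.
* `extract_fv()` truncates at the template FR4 end; unusual J regions
  may lose a terminal residue to the constant-region side.
* Cohort metadata is a flat per-record contract; mapping a real
  database's annotations onto it is the caller's responsibility.
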