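---
title: "Modelling anaerobic energy metabolism in Vickermania"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling anaerobic energy metabolism in Vickermania}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vickerflux)
```

## The biological problem

*Vickermania ingenoplastis* is a two-flagellar trypanosomatid that thrives
under anaerobic conditions and is insensitive to cyanide. Its genome lacks
the subunits of respiratory complexes III and IV and cytochrome *c*, while
complexes I, II and V and an alternative oxidase (AOX) are retained. Energy
metabolism therefore rests on fermentative glycolysis: glucose is degraded
to acetate, ethanol, succinate and propionate, and all ATP in the default
model comes from substrate-level phosphorylation.

`vickerflux` turns that qualitative picture into a small, fully curated
compartmentalized stoichiometric model and recomputes the per-glucose
accounting by constraint-based optimization instead of by hand:

* **glycosome** — hexokinase through phosphoglycerate kinase, plus the
  succinate branch: PEP carboxykinase, malate dehydrogenase, fumarate
  hydratase and the NADH-dependent fumarate reductase;
* **cytosol** — phosphoglycerate mutase, enolase, pyruvate kinase, pyruvate
  decarboxylase and the Zn-type alcohol dehydrogenase;
* **mitochondrion** — pyruvate dehydrogenase, the acetate:succinate
  CoA-transferase/succinyl-CoA ligase cycle, the methylmalonyl-CoA
  "propionate cycle", the residual (non-cyclic) Krebs reactions, and the
  respiratory chain.

The flux balance problem is the standard one: maximize the pooled
per-compartment ATP-drain flux subject to steady state $S v = 0$ and flux
bounds, everything expressed in mol per mol glucose.

## Modelling conventions

**Carbon-skeleton balance only.** Every non-exchange reaction must balance
carbon exactly; hydrogen, oxygen, protons, water, inorganic phosphate and
charge are not tracked, because the accounting this model reproduces is kept
in moles of carbon compounds and moles of ATP. CoA, adenine nucleotides,
NAD(H), ubiquinone, cytochrome *c* and the proton-motive coupling unit are
zero-carbon carriers, so acyl transfers balance on the skeletons they carry.
The ATP drains are written `atp -> adp` accordingly. Coefficients are stored
as exact rationals from the moment an equation is parsed.

**Boundary convention.** Every species that occurs in a reaction is a row of
$S$, including extracellular ones; the system is opened only by the
one-sided, export-positive exchange reactions (`glc_e ->`). This is the
usual convention of constraint-based toolchains, and it guarantees a
transporter can never bypass a closed exchange — the anaerobic constraint is
exactly "zero flux through the oxygen exchange".

**Compartmented redox.** The glycosomal NAD(H) pool is autonomous: the two
NADH formed by glycosomal glyceraldehyde-3-phosphate dehydrogenase per
glucose must be reoxidized inside the organelle, which is precisely what
forces one PEP equivalent into the succinate branch (malate dehydrogenase
and fumarate reductase each regenerate one NAD⁺). The cytosolic and
mitochondrial NAD(H) pools are connected by one explicit reversible shuttle
pseudo-reaction, because the ethanol branch must reoxidize NADH formed by
the mitochondrial pyruvate dehydrogenase and no named carrier system is
available for the organism; the shuttle moves redox equivalents without
moving carbon.

**Glucose uptake as capacity.** A scenario's `glucose_uptake` bounds the
uptake (`ex_glc` in `[-u, 0]`) rather than forcing it. At any optimum in
which glucose has value the full capacity is consumed, so yields are
unchanged, while structural cuts such as a hexokinase knockout give the
honest answer 0 rather than an infeasible program.

**Capacity bound 100.** Unconstrained reactions get `|v| <= 100` mol per mol
glucose. With uptake fixed at 1, no feasible flux in the curated networks
approaches 15, so the bound is slack; keeping magnitudes small also keeps
the exact rational arithmetic far from its overflow guard.

## The propionate cycle as curated

The three methylmalonyl-CoA enzymes (epimerase, mutase, and propionyl-CoA
carboxylase run in the decarboxylating direction) plus a CoA transferase
form a cycle that converts succinate to propionate + CO₂ with a net gain of
one ATP:

* CoA transferase: propionyl-CoA + succinate → propionate + succinyl-CoA
* mutase/epimerase: succinyl-CoA ↔ (R)- ↔ (S)-methylmalonyl-CoA
* carboxylase (decarboxylating): (S)-methylmalonyl-CoA + ADP → propionyl-CoA + CO₂ + ATP

Because the CoA transferase regenerates succinyl-CoA directly, the
succinyl-CoA ligase carries no net flux in the unit cycle and the net ATP is
exactly the carboxylase's +1 — `propionate_cycle_atp()` solves the unit
cycle in exact arithmetic and returns `1`. This is the only curation
consistent with the enzyme list and a net yield of one ATP per propionate.

## Respiratory chain and the P/O parameter

Complexes I and II reduce ubiquinone; in *Vickermania* the only route from
ubiquinol to oxygen is AOX, which pumps no protons. Proton-motive coupling
is represented by an explicit pseudo-metabolite: complexes I, III and IV
each export one coupling unit per two electrons, and the ATP synthase
converts one unit into `po_ratio` ATP. The default `po_ratio = 0` makes the
synthase a pure sink (the chain can still turn over) and reproduces
substrate-level-only accounting; the parameter exists because the coupling
stoichiometry is genuinely organism- and condition-dependent and no value is
fixed by the data the model rests on. Setting it above zero adds oxidative
ATP only aerobically, as the tests assert.

The inhibitor set follows the organism's pharmacology: SHAM zeroes AOX,
cyanide zeroes complex IV (a no-op in presets that lack it, reproducing the
observed cyanide insensitivity), malonate zeroes succinate dehydrogenase.
Complex II is irreversible toward fumarate + ubiquinol: rhodoquinone, which
anaerobic eukaryotes use to run this enzyme backwards, has never been
reported in trypanosomatids, so quinone-linked fumarate reduction is
excluded and succinate formation is purely glycosomal.

## What the optimizer finds

```{r anaerobic}
sol <- load_preset("vickermania") |>
  apply_scenario(scenario(aerobic = FALSE, block_succinate_export = TRUE)) |>
  maximize_atp()
sol
```

The anaerobic optimum is 3.5 mol ATP per mol glucose — 2 from glycolysis
plus the succinate branch, 1/2 from the acetate branch, 1 from the
propionate cycle — with 0.5 ethanol, 0.5 acetate and 1.0
succinate+propionate, a 2:1 reduced-to-oxidized product ratio. The packaged
`accounting_vector()` pins the same assignment by hand and
`verify_accounting()` confirms it satisfies steady state with an exactly
zero residual. `flux_ranges()` shows the optimum is a corner: with the ATP
objective fixed, succinate export is forced to zero and the propionate cycle
to one, because excreting succinate would forfeit the cycle's ATP. The
`block_succinate_export` switch in the accounting scenario pins that corner
explicitly rather than leaving it to optimality alone.

The bloodstream *T. brucei* preset reproduces the classical comparison:
2 ATP aerobically (G3P/DHAP shuttle plus AOX), 1 ATP anaerobically with
equimolar pyruvate and glycerol via glycerol kinase reversal.

## Numerical design

Two independent solvers answer every optimization:

* a floating-point two-phase primal simplex (R, dense tableau; Dantzig
  pivoting with a Bland fallback, feasibility/optimality tolerance 1e-9),
  followed by a parsimonious second stage that minimizes total absolute flux
  at the fixed optimum so the reported vertex is deterministic even when the
  optimum is degenerate;
* an exact rational simplex (C++, int64 fractions with 128-bit
  intermediates and a hard overflow guard, Bland-safeguarded and therefore
  finite) that re-derives the optimum with no floating point at all.

A third, genuinely brute-force routine (`enumerate_yield_brute()`)
enumerates every vertex of the flux polytope in exact arithmetic for small
systems, with a combinatorial guard that refuses anything large; it
certifies the exact simplex on toy networks, and the exact simplex then
certifies the float route on every preset, oxygen state and knockout the
test suite sweeps. Yields of the curated networks are exact halves, and
they are reported as such (`"7/2"`).

Degenerate inputs behave predictably: zero glucose capacity gives the zero
flux vector; an infeasible bound combination returns status `"infeasible"`
naming the constraint class; dead-end metabolites (citrate,
2-oxoglutarate, glycosomal AMP) force their reactions to zero flux at
steady state, which is how the non-cyclic Krebs claim is *observed* rather
than asserted.

## The synthetic-data generator

`random_gene_table()` emulates the structure of the organism's gene
inventory — most enzymes in one or a few copies, a configurable absent
fraction (default 0.2), geometric copy numbers (mean 2, truncated at 200,
matching the scale of the amplified families), log-normal read counts — so
the genotype-to-activity mapping and knockout monotonicity can be exercised
without any sequence data. It does not simulate sequences, reads,
orthology inference or linkage between enzymes; passing tests therefore
show that the *mapping and optimization machinery* behaves correctly on
tables with realistic shape, not that any particular genome would produce
those tables. The packaged `genes_vickermania_synthetic.tsv` encodes the
published copy-number and absence calls for the named key enzymes
(hexokinase 19, glycosomal/cytosolic GAPDH 39/38, AOX 6, complexes III/IV
and cytochrome *c* absent); its gene identifiers, expression columns and
remaining copy numbers are synthetic placeholders, as the filename states.

## Problem sizes and reproducibility

The curated networks span 42–66 reactions over ~60 species, so every LP
solves in well under a second and the full dual-route sweep (four presets ×
two oxygen states × every single-enzyme knockout, plus 100 seeded random
knockouts) runs in a couple of minutes on one core. All generators and the
acceptance script take explicit seeds; identical seeds give byte-identical
tables and identical reported numbers.

## Known limitations

* No thermodynamics, kinetics, growth objective or biomass equation: the
  model answers stoichiometric yield questions only.
* Elemental balancing is carbon-only by design; the model cannot detect a
  hydrogen- or phosphate-unbalanced transcription error.
* The `leishmania_like` preset is a respiratory-chain comparator (the
  curated set plus complexes III/IV and cytochrome *c*), not a
  reconstruction of *Leishmania major* metabolism.
* Amino-acid catabolism, β-oxidation, the pentose-phosphate shunt and
  heme/catalase reactions are carried as presence flags in the preset
  manifest and given no stoichiometry; they do not contribute to glucose
  yields. NADP-linked enzymes (malic enzyme, the anabolic isocitrate
  dehydrogenase) are excluded because the model carries no NADP(H) pool.
* Copy number feeds reaction activity only as presence/absence; the model
  does not scale flux bounds with gene dosage or expression.
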