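---
title: "Inferring molybdenum utilization traits from homology evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring molybdenum utilization traits from homology evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molytrait)
library(dplyr)
```

## The problem

Molybdenum (Mo) — and its heavier twin tungsten (W) — is catalytically
active only when chelated by a pterin scaffold, forming the molybdenum
cofactor (Moco). Whether an organism can use Mo is therefore not a single
gene's affair: it requires (i) a molybdate/tungstate uptake system, (ii) the
multi-step Moco biosynthetic pathway, and (iii) at least one
cofactor-dependent enzyme. `molytrait` turns per-organism homology evidence
(tabular protein-vs-genome search hits against curated seed sequences) into
trait verdicts at each of these levels, and aggregates them into the summary
surfaces a comparative survey needs: occurrence tables, transporter overlap
decompositions, molybdoproteome size distributions, domain-fusion
inventories, phylogenetic screens for horizontally transferred trait
cassettes, and trait-by-environment proportion tables.

Because genome-scale input cannot ship with a package, `molytrait` includes
a first-class synthetic-community generator whose ground-truth labels are
consistent with the emitted evidence *by construction*. Every downstream
stage is validated against that truth.

## Trait-calling model

**Hit filtering.** A hit is retained iff its e-value is at most
`evalue_max` (default 0.01) and the aligned fraction of the query is at
least `coverage_min` (default 0.20). Coverage is computed on the query
(seed) side: the seeds are full-length curated proteins, whereas target
genomes may be fragmentary, so subject-side coverage would penalise draft
assemblies. Both thresholds are inclusive (`<=`, `>=`).

**Ortholog assignment.** Each protein is assigned to the family of its top
surviving seed (highest bit score; ties broken by lower e-value, then
lexicographically smaller seed id). Two safeguards apply:

* *Exclusion seeds.* Mo-independent look-alikes — NuoG (resembles DMSOR
  members) and NifE (resembles nitrogenase) — sit in the registry as
  exclusion seeds. A protein whose top hit is an exclusion seed is
  discarded, not reassigned to its second-best family.
* *Ambiguity.* A protein whose top bit score is shared by seeds of two
  different families is left unassigned and logged. Such cases are resolved
  in practice by gene-neighbourhood or phylogenetic evidence, which a
  homology-only pipeline should not guess at. A single bifunctional seed
  spanning two activities (plant Cnx1 = moeA + mogA) is *not* ambiguous; it
  satisfies both labels.

Reciprocal (bidirectional) best hits are available via
`bidirectional_best_hits()` for symmetric orthology between two proteomes;
the pair set is always a partial matching.

**Pathway rule.** The seven key genes are grouped into the three
biosynthetic steps: step 1 (GTP → cPMP): *moaA*, *moaC*; step 2 (cPMP →
molybdopterin): *moaD*, *moaE*, *moeB*; step 3 (metal insertion): *moeA*,
*mogA*. The pathway is called present iff every step has at least one gene
*and* at least `pathway_majority` of the seven are present. "Most of the
key genes" is quantified here as a strict majority, 4 of 7; the parameter
is exposed because the verbal criterion admits other readings.

**Utilization categories.** The Moco utilization trait = complete pathway
AND at least one molybdoenzyme (SO, XO, DMSOR, AOR, or MOSC — MOSC counts
as enzyme-positive, and AOR is included because Moco here covers both
metals). An organism is Mo-utilizing if it has that trait or nitrogenase.
This yields the four-way partition `both` / `moco_only` / `nif_only` /
`none`. Partial traits (pathway without enzyme, enzymes without pathway)
are cross-tabulated against nitrogenase as *orphan* classes.

**Transporters.** An ABC system (ModABC, WtpABC, TupABC) is called present
iff its substrate-binding A subunit is present together with at least one
of B/C. The A subunit confers substrate specificity, so it anchors the
call; requiring all three subunits would punish split or mis-called
permease genes. MOT1/MOT2 are single-gene calls. Kingdom gates ensure
prokaryotic profiles never yield MOT calls and vice versa.

**Molybdoproteome size and richness.** The proteome size counts assigned
molybdoenzyme genes; nitrogenase is excluded by default (a flag includes
it). `rich` is a *strict* threshold: size > 20.

**Tungstoproteins.** Three rules: all AOR members; FDH/ACH orthologs in
strictly anaerobic (`oxygen_req == "anaerobic"`) bacteria; FWD orthologs in
methanogenic archaea. Methanogens are recognised by a taxon-path rank
matching `^Methano`, which covers the methanogen classes
(Methanobacteria, Methanococci, Methanomicrobia) without a separate flag.

**Rounding.** All printed percentages use round-half-up at the configured
decimals (1 for occurrence tables, 2 for environment tables). Base R's
round-half-even would print 97.25 as 97.2; occurrence tables in this field
print 97.3, so the package implements `round_half_up()` explicitly.

## Fusion detection

Domain hits (protein, accession, interval, score, e-value) are tiled
greedily: strongest first, a hit accepted iff it overlaps every accepted
hit by at most `overlap_tolerance` residues (default 10 — the boundary
jitter of real annotations). Tie-breaks (lower e-value, then smaller
start) make tiling deterministic and invariant to input row order. A
fusion event is a tiled architecture containing catalytic domains of
exactly one molybdoenzyme family plus a non-catalytic partner;
architectures spanning two catalytic families are logged and skipped
rather than guessed. `cross_family_partners()` then marks partners fused
to two or more families — the pattern expected of domains serving Moco
utilization generally.

## Phylogenetic screen for transferred trait cassettes

Gene trees are built by neighbor joining on p-distance matrices (pairwise
deletion of gap sites). NJ is implemented in the package so that
tie-breaking is fully specified (Q-criterion ties resolved by the
lexicographically smallest pair of taxon ids; negative branch estimates
clamped at 0) and therefore byte-reproducible; `ape::nj` serves as an
independent cross-check in the test suite, and on additive matrices both
recover the generating topology and branch lengths exactly. Trees are
midpoint-rooted for orientation — the displayed trees this mirrors are
rooted without a stated outgroup, and midpoint rooting needs no extra
input. A gene tree supports transfer when the focal leaf's sister group is
dominated by a foreign taxonomic class (majority vote; ties are
"ambiguous" and never count). An organism is flagged when at least
`hgt_min_trees` (default 3) gene trees concur. No published quantification
exists for "how many concordant trees make a transfer call"; 3 is this
package's explicit choice — one tree is routine phylogenetic noise, two
can share a single ancient signal, three independent loci agreeing on the
same foreign clade is hard to explain otherwise. Optional column-resampling
bootstrap support is available (`bootstrap_support()`, default 100
replicates) but does not gate the flag by default, keeping the screen fast.

## Environment association

`trait_by_factor()` reports, per habitat or oxygen-requirement category,
the fraction of organisms carrying a feature, with exact binomial
(Clopper–Pearson) confidence intervals. Organisms with unknown factor
values are excluded from denominators (the alternative — counting them as
negatives — would conflate missing metadata with trait absence). The
analysis is restricted to bacteria by default: archaea are dominated by
aquatic, anaerobic Mo users, which would bias pooled proportions. No
hypothesis test is applied by default; `compare_categories()` offers a
two-proportion chi-square as a clearly-labelled extension.

## What the generator emulates — and what it does not

`generate_community()` draws, per organism: a kingdom, taxonomy, habitat
and oxygen class; a utilization category (per-kingdom weights matching the
published occurrence structure, or habitat/oxygen-conditional Bernoulli
draws); a molybdoproteome size (negative binomial, mu = 8, size = 4 —
most organisms under 20 genes, a thin tail into the 70s, matching the
shape of surveyed proteome-size distributions); transporter systems
(per-kingdom inclusion probabilities from the published transporter
frequencies); planted orphans, fusions, and an optional two-clade
transfer scenario. Factor categories are allocated by exact
stratification, so per-category sample sizes are deterministic.

Evidence is emitted with margins: hits for present genes have e-value at
most a tenth of the cutoff and coverage at least twice the minimum, while
decoy rows (20% of the table) always fail at least one criterion. Truth
labels are therefore recovered with zero error in the noise-free default
— which is precisely what the end-to-end tests assert. An optional
`dropout` probability (default 0) deletes evidence for truly present
genes, emulating incompletely assembled genomes.

The generator does **not** emulate: realistic protein sequences or genome
coordinates; correlated gene loss along a phylogeny; pseudogenes;
annotation noise in domain boundaries beyond simple weak decoy hits; or
indels (transfer-scenario sequences evolve by substitution only, so
alignments are trivially exact and p-distances analytic). Passing tests
on synthetic data demonstrate that the *inference rules* are implemented
correctly and recover planted structure — not that the rules are robust
to the full noise spectrum of real draft genomes.

Transfer-scenario divergences default to 0.05 within clades and 0.45
between them: far enough that sister-clade votes are unanimous, far below
the 0.75 saturation zone (which triggers a warning, not an error).

## Problem sizes and numerical choices

The validation suite runs communities of a few hundred organisms
(256-element kingdoms for category-structure checks; 2,000 per factor
category for proportion-recovery checks, matching the exact binomial 99%
acceptance intervals used), 5–8-taxon trees for NJ round-trips, and
20-replicate tree batches in the acceptance script. These sizes make every
check exact or tightly bounded while keeping a full run in well under five
minutes on one CPU.

Degenerate inputs are handled explicitly: empty hit files yield empty
typed tables; empty factor categories are flagged (`NA` percent), never
divided; an all-gap sequence pair yields p-distance 0 with a warning; a
zero-organism scenario is an error; inclusion–exclusion identities of
overlap tables are verified before returning and violations raised as
internal errors.

## A worked run

```{r example, eval = FALSE}
library(molytrait)

comm <- generate_community(scenario_config(
  n_organisms = c(archaea = 60, bacteria = 150, eukaryota = 40),
  hgt_scenario = TRUE, rng_seed = 1))

bundle <- run_pipeline(comm)
glance(bundle)          # one-row community summary
tidy(bundle)            # per-organism trait calls
bundle$occurrence       # per-kingdom Mo-utilization percentages
bundle$orphans          # partial-trait cross-tabulation
bundle$hgt$report       # transfer screen on the attached scenario

autoplot(bundle$proteomes)
autoplot(bundle$env$habitat)
```

## Known limitations

* Trait calls are purely presence-based; no attempt is made to rescue
  calls from unassembled genomes or detect pseudogenes.
* The homology layer consumes precomputed hit tables; it does not execute
  searches, HMM scans, or alignments.
* p-distances are uncorrected; model-based distances (JC, Kimura) are not
  implemented.
* The transfer screen uses sister-clade taxonomy only; operon-adjacency
  evidence is out of scope.
* Each metadata row is treated as one organism; no strain/species
  deduplication is attempted.
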