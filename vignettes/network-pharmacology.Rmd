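---
title: "Network pharmacology with planted synthetic data: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network pharmacology with planted synthetic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The workflow

Network pharmacology asks which metabolites of a complex natural extract
act on which disease-relevant proteins, and through which pathways. The
classical workflow chains publicly available web services; `netpharm`
re-implements the computational chain as local, seeded, testable code:

1. **Drug-likeness screening.** Each metabolite is screened by four
   rule-of-five assertions — molecular weight ≤ 500 Da, H-bond acceptors
   ≤ 10, H-bond donors ≤ 5, Moriguchi logP (MLOGP) ≤ 4.15 — allowing at
   most one violation, plus an Abbott oral-bioavailability gate
   (score > 0.50). All rule boundaries are inclusive: a descriptor
   exactly at its threshold passes. Source descriptions of the
   bioavailability cutoff are not always consistent; because the Abbott
   score is discrete with 0.55 as its standard pass level, the strict
   "> 0.50" reading is the defensible gate, and every screening report
   records the gate it applied.
2. **Target-set algebra.** Compound targets are the *intersection* of two
   prediction sources (a gene must be supported by both); disease genes
   are the *union* of three curated sources (any curated evidence
   counts). Their intersection — the *common targets* — drives every
   downstream stage. Gene identity is the normalized symbol string
   (uppercased, trimmed, deduplicated); no alias or ortholog resolution
   is attempted, since the emulated services already emit symbols.
3. **PPI hub ranking.** The common targets form a protein–protein
   interaction network (combined confidence scores, medium-confidence
   cutoff 0.400, inclusive, with 0–1000 integer scores auto-scaled to
   0–1). Three centralities rank hub genes:
   * **Degree** — the neighbor count $|N(v)|$;
   * **MNC** — the size of the largest connected component of the
     subgraph induced by $N(v)$ (with $v$ excluded);
   * **MCC** — $\sum_{C \in S(v)} (|C|-1)!$ over the maximal cliques
     $C$ containing $v$.
   Genes in the top-3 of all three rankings are the consensus key
   targets.
4. **Mushroom–compound–target (M-C-T) network.** A tripartite network
   links the mushroom to its screened compounds and each compound to its
   common targets. Compounds are prioritized by their count of distinct
   target neighbors.
5. **Enrichment.** Each annotation term is tested by the one-sided
   hypergeometric upper tail
   $P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$, with
   Benjamini–Hochberg Q values, the rich factor $k/K$ and the gene
   percentage $100k/n$.
6. **Reactivity.** Frontier-orbital descriptors: gap
   $|E_\mathrm{HOMO} - E_\mathrm{LUMO}|$, chemical hardness
   $\eta = \mathrm{gap}/2$, softness $S = 1/\eta$; a candidate strictly
   softer than every standard drug is flagged as the most reactive.
7. **Docking comparison.** Candidate scores (kcal/mol, more negative =
   stronger) are classified against reference ligands docked on the same
   receptor.

## Interpretation choices in the ranking formulas

**"Maximal" cliques in MCC.** The MCC formula is stated over "maximum
cliques"; read literally (only the globally largest cliques) it would
zero out most nodes and contradict the behavior of the plugin ecosystem
that popularized the score. `netpharm` enumerates *maximal* cliques —
cliques not extendable by any node — with a pivoting Bron–Kerbosch
recursion, which is the established reading. An isolated node lies in
its own singleton maximal clique and scores $0! = 1$.

Under this reading, for every node
$\mathrm{MCC}(v) \ge \mathrm{Degree}(v) \ge \mathrm{MNC}(v)$: each
neighbor of $v$ lies in at least one maximal clique containing $v$, a
clique of size $c$ contributes $(c-1)! \ge c-1$, and the neighborhood
component counted by MNC can never exceed the neighborhood itself. The
test suite asserts this ordering across a thousand generated nodes, and
checks all three scores against brute-force oracles (exhaustive bitmask
subset scan for cliques, hand-rolled BFS for components) on random
graphs of up to 15 nodes.

**Hardness sign.** $(E_\mathrm{HOMO} - E_\mathrm{LUMO})/2$ is negative
under the usual sign convention while hardness is conventionally
reported positive; the absolute value is taken. Orbital-energy units
are carried through from the input verbatim — bundled example tables
label them kcal/mol although the magnitudes resemble Hartree — because
every downstream comparison is scale-free. A LUMO below the HOMO warns
rather than errors, since supplied tables can have sign ambiguities.
The worked example used throughout the package anchors the key
compound at HOMO $-0.224$; its LUMO is set to $-0.0589$ so the gap
$0.1651$ reproduces the hardness $0.08255$, the value the comparison
stage is expected to flag as softer than both standard drugs.

**Docking "comparable" band.** Prose descriptions of near-equal binding
need a numeric rule: a candidate within ±0.5 kcal/mol of the best
reference score on the same target is *comparable*; below every
reference and outside that band it is *stronger than all references*;
otherwise *weaker*. Independently, scores strictly below −8 kcal/mol
flag a *strong binder* (−8.0 exactly does not). Both constants are
configuration keys.

**Tie-breaking.** All rankings break score ties by ascending symbol, so
every ranking, consensus and report is fully deterministic.

**Degenerate inputs.** Diameter and radius are computed on the largest
connected component (the study-shaped network is connected, so this
only matters for degenerate graphs); empty networks error; an empty
common-target set aborts the M-C-T stage; a query gene outside the
enrichment universe errors rather than being silently dropped.

## What the synthetic generators emulate

The pipeline's original inputs are web-service exports that cannot be
redistributed or re-queried reproducibly. Every input is therefore
emulated by a seeded generator with *planted, recoverable structure*,
and the generator defaults are the study-shaped conditions:

* **27 metabolites, none violating the screen** (`frac_violators = 0`);
  violator fractions are available for testing the gate itself.
  Bioavailability is drawn from the discrete Abbott levels
  {0.11, 0.17, 0.55, 0.56, 0.85} because the gate is threshold-based.
* **A 2000-gene universe.** The real analysis pooled 7283 disease genes
  from databases of >20k genes; 2000 genes with three disease lists of
  600/450/350 keeps every set relationship intact at a size the whole
  suite can re-run in seconds. Symbols are synthetic (`G000001`, ...);
  the planted hub is cosmetically named `TLR4` for readability.
* **Two association sources with Jaccard-controlled pooled overlap**
  (default 0.5), six compounds planted with single-source-only targets
  (so exactly 21 of 27 connect to the common set), and one compound
  planted with maximal target coverage (the "key compound").
* **42 planted common targets**, chosen as a hitting set over the shared
  target pool so that every connected compound retains at least one
  link — mirroring how the real funnel yielded 42 common targets
  connected to 21 bioactives.
* **A PPI generator** wiring the planted hub to ≥ 85% of all nodes and
  into every planted clique (sizes 5, 4, 3), over a background
  edge probability of 0.2 (chosen to match an average degree near 8 on
  42 nodes). Planted edges carry combined scores ≥ 700 so the
  0.400 confidence cutoff can never delete planted structure;
  background scores span 150–1000.
* **An annotation generator** planting one term whose query overlap is
  `ceiling(fold × expectation)` (default fold 5) among uniformly
  sampled background terms.

What the generators do **not** emulate: real score distributions of the
prediction services, STRING evidence channels beyond the combined
score, GO graph structure (terms are flat sets), gene-length or
annotation biases, and correlated term membership. Passing tests
therefore demonstrate that the *algorithms* recover planted structure
under controlled conditions — not that any particular biological claim
holds on real data.

## Statistical calibration and problem sizes

The hypergeometric test is discrete: the largest attainable p-value
below 0.05 depends on the term size, so the fraction of null tests
below 0.05 is systematically *at or below* the nominal level. The null
calibration check uses background terms of 200–600 genes on the
2000-gene universe — sizes chosen (by direct computation of the
achieved significance level, before any simulation) to make the
discrete null near-continuous; the expected fraction is ≈ 0.035, within
three binomial standard errors of 0.05 at 1000 simulated queries, and
conservatively below it. Smaller terms would push the achieved level
further from nominal without changing the test's validity.

Simulation sizes used by the tests and the acceptance script — 100
random graphs (≤ 15 nodes) against the brute-force oracles, 1000 nodes
for the score-ordering invariant, 20 seeds for hub recovery, 50 seeds
for planted-term recovery, 1000 null queries — were chosen so the full
suite re-runs in a few minutes while keeping Monte-Carlo error well
inside every asserted margin.

## A worked run

```{r}
res <- run_pipeline(default_config(), seed = 1)
str(res$summary)
```

The funnel (27 screened → 21 connected → 42 common targets), the
consensus hub, the key compound, the planted pathway at rank 1, and the
two docking classifications are all recomputed live here; the README's
example shows the same output.

## Known limitations

* MCC uses exact factorials; cliques beyond ~170 members would overflow
  to `Inf`. Biological interaction networks are far below this, and
  such a clique would dominate any ranking anyway.
* Clique enumeration is exponential in the worst case; it is intended
  for the tens-of-nodes networks this workflow produces, not for
  proteome-scale graphs.
* The enrichment background is the annotation collection's own gene
  union unless a universe is supplied; with the emulated collections
  the universe is always explicit.
* Database-scale counts (hundreds of compound targets, thousands of
  disease genes) are reproduced in *shape*, not magnitude; rerunning
  against real exports only requires swapping the generator outputs for
  files under `config$inputs`.
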