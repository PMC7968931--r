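---
title: "Methods: ensemble diversity, NED, and condensate morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble diversity, NED, and condensate morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nedfold)
```

## The scientific problem

RNA-binding proteins with multivalent domains phase-separate into
condensates whose shape depends on the RNA they recruit: predominantly
structured 3'UTRs give sphere-like droplets, while RNAs with large
unstructured stretches form intermolecular RNA-RNA contacts that act as a
semi-rigid skeleton and force irregular, mesh-like morphologies. The
computable handle on "unstructured-ness" is the *conformational
heterogeneity* of the thermodynamic ensemble of secondary structures: an RNA
locked into one strong fold has low heterogeneity; an RNA whose ensemble is
spread over many mutually incompatible pairings has high heterogeneity, and
its unpaired stretches are available for intermolecular pairing.

`nedfold` implements that pipeline end to end: a partition-function folding
engine; **ensemble diversity**, defined as the expected base-pair distance
between two independent draws from the Boltzmann ensemble,
$d = 2\sum_{i<j} p_{ij}(1 - p_{ij})$; its length-normalised form **NED**
$= d / n$; a dual-threshold classifier for sphere- vs network-forming RNAs;
sequence features (AUUUA AU-rich elements, GC content); CLIP/3'UTR interval
counting; a site-matching simulator for dimerization-element multivalency;
and the rank statistics used to compare RNA cohorts. Everything runs on
synthetic data generated inside the package.

Note that prose definitions of ensemble diversity sometimes say "the number
of potential structures". A count of structures grows exponentially and
cannot sit in the 0.2-0.4-per-nucleotide range that NED values occupy; the
expected base-pair distance (the quantity folding software actually
reports) does. We implement the distance definition, and the brute-force
enumeration oracle in the test suite pins down its factor-2 convention.

## The folding engine

The engine computes, by dynamic programming over nested (pseudoknot-free)
structures with the six canonical/wobble pair types and a minimum hairpin
loop of 3 nt:

* the partition sum $Z = \sum_S e^{-E(S)/RT}$ (open chain contributes 1);
* exact base-pair probabilities $p_{ij}$ by an inside-outside algorithm;
* the MFE structure by min-plus recursion with a deterministic traceback
  (at equal energy the leftmost position is left unpaired first);
* the centroid (pairs with $p_{ij} > 1/2$; conflicting pairs cannot both
  exceed 1/2, so no repair step is ever needed);
* the per-position unpaired profile $q_i = 1 - \sum_j p_{ij}$ and "large
  disordered region" (LDR) calls: maximal runs with $q_i > \tau$
  (default 0.5) of at least 30 nt. The literature never quantifies
  "large", so both knobs are explicit parameters.

### Energy models

Two small, fully documented models ship with the package. They are authored
here and are deliberately *not* the Turner 2004 parameter set; reproducing
another program's absolute ensemble values is out of scope, and every
analysis in the package either works on the engine's own scale or takes NED
values from a supplied table.

* **pairsum** — the energy of a structure is the sum of per-pair energies
  (GC $-3.0$, AU $-2.0$, GU $-1.0$ kcal/mol); loops are free. Exact
  expected values are hand-computable, which makes this the model used in
  worked examples and unit tests.
* **stacking** (default) — helically adjacent pairs score a stack energy
  built from per-pair strengths $w$(GC, AU, GU) $= 3, 2, 1$ as
  $-((w_o + w_i)/2 + 0.5)$ kcal/mol; hairpins pay
  $5.0 + 1.08\,\log(L/3)$; internal/bulge loops pay
  $2.0 + 1.08\,\log(a+b) + 0.4\,|a-b|$, and loops with $a+b > 30$ unpaired
  nt are disallowed (a standard loop-span cap, part of the model
  definition); multibranch and exterior loops are free.

Temperature enters through $RT = 0.0019872 \cdot T$ kcal/mol with
$T = 310.15$ K by default.

### Numerics

All partition arrays are per-position scaled (each position contributes one
factor $1/s$, with $s$ chosen from the MFE as
$s = e^{-1.07\,\mathrm{MFE}/(RT\,n)}$), so the engine stays in double
range for sequences far beyond the lengths used here; $\log Z$ is reported
exactly. The inside-outside recursions run in $O(n^3)$ time (the interior
loop cap bounds those sums by a constant). Sequences longer than
`max_length` (default 7500 nt) are refused with an explicit error rather
than approximated. The exhaustive-enumeration oracle
(`enumerate_structures()`, guarded at 25 nt) is an independent code path:
the test suite checks $Z$, every $p_{ij}$, the MFE and the ensemble
diversity against it to $10^{-9}$ relative tolerance on both models.

## The morphology classifier

Observed screens separate at NED $\approx 0.28$: most network formers sit
above 0.280 and most sphere formers below 0.265. `classify_ned()` applies
those two cut-offs; values inside the open gap $[0.265, 0.280]$ are
assigned to the nearer threshold by default (midpoint 0.2725 going to
network, so the rule is total), or reported as a third label under
`gap_rule = "indeterminate"`. Raising an RNA's NED can never move its call
from network toward sphere, and with `lo == hi` the rule degenerates to a
single cut. `evaluate_predictions()` scores calls against observed
morphology; `quartile_check()` reports the fraction of a group strictly
beyond a cut-off.

These published cut-offs live on the scale of the folding software used to
derive them. The shipped engine has its own scale (an AU-rich random
200-mer sits near NED 0.23 under the stacking model), so the end-to-end
demo separates its synthetic sets at a fixed engine-scale cut of 0.12 —
half the expected unstructured value — rather than at 0.28/0.265. Tables
of NED values produced elsewhere are analysed with the published
thresholds unchanged.

## Sequence features and concentrations

AU-rich elements are counted as the canonical pentamer AUUUA,
case-insensitive and T/U-agnostic. Whether overlapping matches should
count is unstated in the literature; both modes are available and
overlapping is the default (an `AUUUAUUUA` run then counts 2). Copy
numbers convert to molarity via a fixed cell volume (2000 µm³ by default:
10 copies $\approx$ 8 pM, 10,000 $\approx$ 8 nM) and to mass via a flat
330 Da/nt (3500 nt $\leftrightarrow$ 1155 kDa). Published mass figures
derived from slightly different nucleotide-mass conventions differ by up
to ~5 %; `per_nt_mass` is a parameter.

## CLIP/3'UTR interval counting

BED3/BED6 intervals are parsed with per-line validation (malformed lines
are reported with line numbers) into `GRanges`; overlap counting is
delegated to `GenomicRanges`. A peak "falls into" a UTR at $\ge 1$ bp
overlap (configurable), strand-aware by default since PAR-CLIP is
stranded. The union count across datasets is the per-UTR *maximum* — a tag
counted if detected in at least one dataset; a merge-then-count
alternative sits behind `union_mode = "merge"`. UTRs are binned by union
count (default 0 / 1-4 / $\ge 5$).

## The multivalency simulator

Dimerization elements are declared with symmetric partnerships (e.g.
D1a$\leftrightarrow$D1b heterotypic, D2$\leftrightarrow$D2 homotypic);
constructs carry ordered site lists; `match_sites()` draws free compatible
site pairs (on distinct molecules) uniformly at random and matches them
irreversibly until none remain. Because a site's matches are confined to
its partner class, the process factorises over partnership classes and is
simulated per class. This is the simplest model that distinguishes valency
1 from valency 2: single-site pools can only dimerise (largest component
$\le 2$ always), while two-site complementary circuits percolate into a
giant component covering most of the pool. No equilibrium, kinetics or
geometry is modelled, and the simulator is used only for such
property-level contrasts, never to fit quantitative observations.
`duplex_scan()` finds the minimum-energy contiguous antiparallel run
between two sequences (no interior loops — a documented limitation that
keeps its oracle trivial).

## Synthetic data: what it emulates, what it does not

* `gen_hairpin()` — stem + loop + reverse-complement stem: one
  locked-in local structure (NED $\sim 10^{-4}$).
* `gen_unstructured()` — i.i.d. residues at a given AU fraction (default
  0.8): weak, promiscuous pairing and high NED.
* `insert_antisense()` — the structure-stabilising mutant: antisense
  copies of donor windows inserted downstream. Each oligo goes a short gap
  (default 4 nt) downstream of its *own* donor so the stems are
  sequential; inserting both oligos at one point would make the two
  duplexes mutually crossing, split the ensemble between them and raise
  rather than lower NED. Insertions must not split an AUUUA element nor
  change the total ARE count (antisense material can introduce new
  matches); `plan_antisense_insertion()` finds compliant coordinates
  deterministically.
* `gen_cohort()` — a two-group screen table: truncated-normal NED
  (defaults 0.24/0.31, sd 0.03), log-normal lengths (medians 1.2/1.8 kb,
  log-sd 0.45), Poisson ARE counts (5/kb), 19 + 28 RNAs — chosen so
  summary ranges bracket observed screens (NED 0.18-0.38, lengths
  0.5-3 kb) and so that a 14 + 14 comparison at this effect size has
  $\ge 80\%$ power.
* `gen_clip_tracks()` — Poisson peaks over synthetic UTRs in two
  datasets; enriched UTRs at 10$\times$ the background rate of 0.5
  peaks/kb (nonspecific CLIP background below one peak per kb; higher
  backgrounds let the Poisson tail of long UTRs flood the top count bin
  with false positives).

Every generator is a pure function of its arguments including the seed.
What passing on synthetic data shows: the engine orders structured below
unstructured RNAs, the mutant direction is negative, percolation requires
valency $\ge 2$, the statistics are calibrated. What it does not show:
agreement with any specific genomic RNA's absolute NED (real 3'UTRs have
local composition structure, repeats and long-range pairings no i.i.d.
model reproduces), nor image-derived quantities, which are outside the
package's scope.

## Statistics

`mann_whitney()` reports $U_1$ from midranks and the tie-corrected
$z = (U_1 - n_1 n_2/2)/\sigma$, two-sided normal $p$, and — for
$n_1 + n_2 \le 12$ — an exact permutation $p$ over all
$\binom{n}{n_1}$ assignments. No continuity correction is applied by
default (signed $z$ values are then directly comparable across software
that reports plain $z$); the `continuity` flag restores it, and with it
the normal $p$ tracks the exact $p$ within 0.05 for every tie-free
configuration at the smallest sizes, which is not achievable without the
correction ($n_1{=}n_2{=}3$, $U{=}3$: exact 0.70 vs plain-normal 0.51).
Group orientation is fixed — sphere first — so reported signs are
reproducible. Kruskal-Wallis wraps `stats::kruskal.test`; for two tie-free
groups its $H$ equals $z^2$, which the tests verify numerically. Pearson's
$r$ is `stats::cor` with validation. No multiple-testing correction is
applied anywhere.

## Problem sizes and determinism

The shipped analyses run at desk scale: oracle checks at $n \le 20$ (100
sequences), NED contrasts on 20 seeds of 200-nt sequences, the mutant
contrast on 150-nt sequences, percolation with 1000 molecules, 2000 null
simulations for the type-I check and 200 cohorts for power. The full test
suite completes in about a minute on one CPU; `scripts/acceptance.R`
recomputes every headline quantity in well under a minute per stage. All
randomness flows from explicit seeds; outputs carry a header with package
version, config hash and seed, and reruns are byte-identical.

## Known limitations

* The energy models are compact teaching-grade parameterisations: NED
  values are comparable *within* the engine, not across folding software.
* No pseudoknots, no co-transcriptional folding, no suboptimal-structure
  sampling, no dangles/coaxial terms.
* `duplex_scan` is contiguous-only.
* The matching simulator has no detailed balance; percolation statements
  are qualitative contrasts, not fitted quantities.
* Published screen tables are consumed, never re-derived: recomputing a
  specific 3'UTR's NED from genomic sequence requires the original
  external energy model and annotation and is explicitly not attempted.
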