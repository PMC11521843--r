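---
title: "Eplet-based allele disparity: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eplet-based allele disparity: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epletatlas)
```

## The model

HLA alleles provoke humoral immune responses through epitopes on the
molecular surface, and *eplets* — patches of 2–5 polymorphic amino-acid
residues catalogued in eplet registries — serve as proxies for those
epitopes. An eplet name encodes its own definition: `44KM` places lysine at
position 44 and methionine at 45 of the mature protein; `163LS/G` places
leucine at 163 and either serine or glycine at 164 (the `/` alternative
attaches to the last enumerated position; this reading is isolated in
`parse_eplet_name()` so it can be revisited if registry conventions turn
out to differ).

Collecting all antibody-confirmed eplets assigned to an allele and marking
their residues at the corresponding positions yields the allele's
*polymorphic amino-acid profile*: a sparse map from mature-protein position
to a residue set. Everything downstream works in this "differential
amino-acid space":

* **Distance.** The disparity of two alleles is the Hamming distance
  between their profiles — the number of positions at which their residue
  sets are disjoint. Residue sets with alternatives agree whenever they
  overlap.
* **Disparity graphs.** Within one allele group (alleles sharing the first
  name field, e.g. A\*01), every allele is linked to its nearest
  neighbour(s), giving a 1-nearest-neighbour graph whose 0-distance
  components are *monomorphic clusters* — alleles indistinguishable at
  every confirmed-eplet position.
* **Cross-reactivity.** An allele strictly closer to some foreign-group
  allele than to any member of its own group is *cross-reactive* in the
  computational sense; such foreign neighbours are added to the group's
  graph as external nodes.
* **Mismatch counting.** For a donor–recipient pair, donor alleles absent
  from the recipient genotype at a locus are antigen/allele mismatches;
  the eplets they carry that the recipient repertoire lacks are the eplet
  mismatches.

## Coordinate namespaces

Distances are only meaningful where mature-protein numbering is
comparable. The default partition of the 11 classical loci
(`default_namespaces()`) puts the class I heavy chains A, B and C in one
space — B↔C nearest neighbours are genuine findings, not artefacts — and
the DRB chains DRB1/3/4/5 in another, while DQA1, DQB1, DPA1 and DPB1 each
stand alone. The partition is a plain two-column table and can be replaced
wherever a `namespaces` argument appears. A consequence worth knowing:
whether an HLA-A allele may pick its nearest neighbour from B or C is a
property of this table, not of the code; the default allows it, a
user-supplied `{A}`-only namespace forbids it.

## Parameters that matter

* **`policy`** (`"difference"`, default, or `"shared_only"`): alleles cover
  different position sets, and the registries do not say how to compare a
  position covered by only one profile. The default counts it as a
  difference, on the view that the absence of a confirmed eplet from a
  repertoire is itself a mismatch signal; `shared_only` restricts the count
  to jointly covered positions. With singleton residue sets and the default
  policy the distance is a metric (the triangle inequality is
  property-tested); with `/`-alternatives overlap is not transitive, so the
  metric property is *not* guaranteed and not claimed.
* **`confirmed_only`** (default `TRUE`): analyses are restricted to
  antibody-confirmed eplets. Unconfirmed eplets can be kept end-to-end via
  the flag, but none of the bundled validation exercises that path against
  real data.
* **Cross-reactivity tie rule:** strict inequality, ties resolve to the own
  group. The alternative (ties count as cross-reactive) would inflate
  cross-reactivity counts; strictness makes the singleton-group rule the
  only source of "trivial" 100% values (the DPB1 pattern, where nearly
  every allele is its own group).
* **Nearest-neighbour ties:** *all* minimal-distance neighbours are kept.
  A single arbitrary neighbour would make graphs depend on input order;
  keeping the argmin set makes every structure a deterministic function of
  the registry.
* **Frequent-eplet threshold** (`threshold = 0.8`): an eplet is "frequent"
  in a group when strictly more than 80% of the group's alleles carry it;
  exactly 4 of 5 does not qualify. The boundary is unit-tested.
* **Mismatch scope and direction:** per-locus repertoire and
  host-versus-graft direction by default, matching how such cohorts are
  usually tabulated; `scope = "class"` pools the recipient's whole HLA
  class, `direction = "gvh"` swaps the roles.

## Merging overlapping eplets

Two eplets assigned to one allele may cover the same position. The profile
builder intersects the residue sets and treats an empty intersection as a
hard data error (`epletatlas_conflict`), naming the allele, position and
clashing eplets, because it indicates an internally inconsistent registry
rather than something the software should silently patch. Lenient mode
skips such alleles with a warning. The bundled example registry
deliberately contains published group signatures that conflict under this
rule (e.g. `62GE` with `62GK` at position 63); they document real
inconsistencies in published listings — possibly a sign that some registry
names skip non-polymorphic positions rather than enumerating consecutive
ones — and exercise the error path. Mismatch counting is unaffected: it
operates on eplet sets, never on merged profiles.

## Motif prevalence

For a set of profiles, the prevalence of residue *r* at position *p* is
the profile count carrying *r* there, divided by the number of profiles;
a profile whose residue set at *p* has *k* alternatives contributes *1/k*
to each, so each covered profile contributes total weight 1 and
`prevalence + gap_fraction` sums to exactly 1 at every position — an
invariant the tests check on random registries. Positions nobody covers in
the plotted span render as empty bars.

## The synthetic-data generator

`simulate_registry()` emulates the structure reported for real allele
groups — one monomorphic core cluster per group surrounded by a "halo" of
similar alleles, plus occasional alleles closer to a foreign group — with
every feature planted by *eplet sharing*, never by editing distances:

* each group's signature is a set of eplets tiling `n_positions` positions
  with a group-specific residue letter (defaults: 4 groups per locus,
  8 alleles per group, 12 positions in 4 eplets — small enough to inspect
  by hand, large enough that cores, halos and planted cross-reactive
  alleles are all distinct);
* core alleles (default 3) carry the signature verbatim, so their pairwise
  distance is 0;
* halo alleles swap the first signature eplet for a variant differing at
  exactly `halo_mutation_distance` positions (default 2), each halo with
  its own variant letter, so halo→core distance is exactly the mutation
  distance;
* a planted cross-reactive allele carries a foreign signature mutated at a
  single position, making its nearest neighbour the foreign core at
  distance 1 while every own-group allele is `n_positions` away.

Parameter combinations that would break the planted guarantees are
rejected before emission: at most one cross-reactive allele per group (two
in one group targeting the same foreign group would tie at distance 1 and
void the strict inequality), cores of at least 2 whenever cross-reactive
alleles are planted (a singleton core targeted at distance 1 would itself
become cross-reactive), and `2·halo_mutation_distance + 2 ≤ n_positions`
(so halos stay closer to home than to anything foreign). The construction
is deterministic given `seed` — the only randomness is the assignment of
residue letters through R's seeded sampler.

What the generator does **not** emulate: realistic allele frequencies,
registry-scale allele counts (hundreds per group are supported but not the
default), multi-residue `/`-eplets, overlapping eplets within one allele,
or alleles whose position coverage differs within a group. Passing the
recovery tests therefore shows the pipeline is correct on registries with
clean planted structure; it does not certify statistical behaviour on any
real registry snapshot, whose counts also shift with every registry
release.

## The bundled example registry

`example_registry()` ships a small fixture transcribed from published
listings: the complete 10-eplet repertoire of A\*01:01 (with A\*01:02 as
its monomorphic companion and the unconfirmed 9S/17S pair that separates
the two only when `confirmed_only = FALSE`), the most-frequent-eplet
signatures of common A, B and C groups attached to one representative
allele per group, and a handful of per-allele additions inferred from a
published donor–recipient mismatch table (tagged `pair_inference` in the
raw TSV). It is *not* a registry snapshot: one allele of the bundled
cohort (B\*56:01) has no published eplet information at all, which is why
the cohort examples run with `strict = FALSE`, under which unknown alleles
contribute an empty repertoire with a warning instead of an error.

## Numerical and degenerate-input choices

* Residue sets are encoded as 20-bit integer masks, one bit per amino
  acid; disjointness is a bitwise AND, and distances are exact integer
  counts — there are no floating-point tolerances anywhere in the distance
  path.
* A singleton group has no own-group distance (`d_own = NA`); it is
  classified cross-reactive whenever any foreign allele exists in its
  namespace, and `nearest_neighbours(scope = "own_group")` returns an
  empty set rather than an error.
* An empty registry reads and writes as headers-only tables; an empty
  profile renders as a string of placeholders; `motif_prevalence()` of an
  empty collection is an error, not a table of NaNs.
* Null-expression alleles (`N` suffix) are parsed and stored but excluded
  from analysis by default.
* Graph layout is a rendering concern only; the exported GraphML/DOT/JSON
  structures are byte-identical across repeated runs.

## Problem sizes used in the checks

The bundled validation runs on registries of 15–100 alleles: 50 simulated
registries for the brute-force oracle comparison, 20 seeds for exact
planted-structure recovery, and a handful of registries for the
conservation and metric properties. These sizes were chosen so each
guarantee is exercised across many random constructions while any single
failure remains small enough to debug by hand.

## Known limitations

* The eplet grammar covers names of the forms seen in published listings
  (`<position><RESIDUES>[/<residue>]` with consecutive positions); real
  registries may contain decorated or non-consecutive names that would be
  rejected (or skipped in lenient mode).
* No structural (3D) mapping, no population-frequency weighting, no
  statistical testing of cross-reactivity enrichment, and no clinical
  interpretation of mismatch counts.
* Registry-version-dependent statistics (allele counts per locus, exact
  published cross-reactivity percentages) are not reproducible from the
  fixture; `inst/scripts/validate_snapshot.R` recomputes them from any
  user-supplied registry snapshot for manual comparison.
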