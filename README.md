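# epletatlas

Eplet-based HLA amino-acid atlases, disparity graphs and donor–recipient
mismatch analysis, for transplantation immunologists and HLA
bioinformaticians who work with eplet registries.

## The idea

The immune response after transplantation is driven by mismatched HLA
epitopes, for which *eplets* — small configurations of 2–5 polymorphic
amino-acid residues catalogued in eplet registries — are the standard
proxy. An eplet name encodes its residues: `44KM` is lysine 44 +
methionine 45 of the mature protein; `163LS/G` is leucine 163 with serine
*or* glycine at 164. Collecting the antibody-confirmed eplets of an allele
gives its **polymorphic amino-acid profile** — a sparse map
position → residue set.

With every allele embedded in this differential amino-acid space the
package computes, for alleles *a*, *b* with profiles *P_a*, *P_b*:

* the **Hamming distance**
  d(a, b) = #\{ p : P_a(p) ∩ P_b(p) = ∅ \},
  counting a position covered by only one profile as a difference
  (configurable);
* per allele group, the **1-nearest-neighbour disparity graph**: each
  allele linked to all of its minimal-distance neighbours, 0-distance
  components forming *monomorphic clusters*;
* **cross-reactive alleles**: alleles strictly closer to another group
  than to their own (min_{g(b)≠g(a)} d(a,b) < min_{g(b)=g(a)} d(a,b)),
  added to the foreign group's graph as external nodes;
* group/locus **summary tables** (cross-reactivity counts, eplets carried
  by >80% of a group) and **donor–recipient mismatch reports**: donor
  alleles absent from the recipient genotype, and the eplets they carry
  that the recipient repertoire lacks.

A synthetic-registry generator plants monomorphic cores, fixed-distance
halo alleles and cross-reactive alleles by eplet sharing, so the whole
pipeline is validated by exact recovery of known structure.

## Worked example

```r
library(epletatlas)

reg <- example_registry()           # bundled registry of published listings
prof <- build_profile(reg, "A*01:01")
prof
#> profile of A*01:01 (21 positions from 10 eplets)
#>   44:K 45:M 62:Q 63:E 65:R 66:N 67:A 76:A 77:N 78:T 79:G 80:T 90:D
#>   138:M 139:I 144:K 145:R 163:R 164:G 166:D 167:G
```

The 10 confirmed eplets of A\*01:01 expand to 21 polymorphic positions;
rendered over positions 44–80 the profile reads `KM...QE.RNA...ANTGT`-style
aligned text (`profile_to_sequence_string()`). Group structure and
cross-reactivity:

```r
dm <- distance_matrix(build_atlas(reg, groups = c("A*01", "A*03", "A*30")))
group_summary_table(dm, registry = reg)[, 1:5]
#>   group n_alleles n_cross_reactive pct_cross_reactive cross_reactivity
#> 1  A*01         2                0                  0                -
#> 2  A*03         1                1                100         1 (100%)
#> 3  A*30         1                1                100         1 (100%)
```

A\*01:01 and A\*01:02 share every confirmed eplet (distance 0, one
monomorphic cluster, no cross-reactivity — rendered "-"); the two
singleton groups are trivially cross-reactive. Donor–recipient pairs:

```r
rep <- mismatch_report(reg, read_pairs(example_pairs_path()), strict = FALSE)
rep[1:3, c("pair_id", "n_allele_mismatches", "n_eplet_mismatches", "mismatched_eplets")]
#>   pair_id n_allele_mismatches n_eplet_mismatches                  mismatched_eplets
#> 1       1                   1                  1                                56R
#> 2       2                   1                  8 44KM, 62QE, 76ANT, 90D, 138MI, ...
#> 3       3                   2                  5     62EE, 65GK, 144KR, 161D, 166DG
```

Pair 1's single allele mismatch (A\*30:01) costs one eplet mismatch
(`56R`); pair 2's single mismatch (A\*01:01) costs eight; pair 3 mismatches
both alleles yet only five eplets — the disparity-driven variability that
motivates eplet-level matching.

The same operations are scriptable via the CLI
(`exec/epletatlas <atlas|motif|graph|summarize|mismatch|simulate>`), which
serializes atlases as TSV/aligned text, motif tables as TSV with
stacked-bar PNG/SVG plots, and disparity graphs as GraphML/DOT/JSON.

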