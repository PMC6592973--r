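# apohybrids

Parentage inference for fern species complexes that mix diploid sexual
and polyploid **apogamous** (apomictic) taxa.

Apogamous ferns make 32 unreduced spores per sporangium instead of the
sexual 64, yet they keep hybridizing with their sexual relatives —
triploid apomicts can produce reduced diploid (2x) spores through
irregular meiosis, so a 2x gamete from a 3x apomict can fuse with a 1x
gamete from a 2x sexual and found a *new* 3x apomict without any
ploidy increase (the hybridization cycle).  The result is a reticulate
species complex whose members can be untangled from three marker
systems per voucher: a maternally inherited plastid haplotype, a
dosage-blind nuclear allele set scored by PCR-SSCP, and cytology
(spore counts → reproductive mode, chromosome counts → ploidy as a
multiple of the base number x, here 2n = 82/123/164 → 2x/3x/4x with
x = 41).

`apohybrids` turns that reasoning into a tested pipeline.  For every
putative hybrid it enumerates ordered (maternal, paternal) parent
pairs and keeps those satisfying

1. **maternal plastid inheritance** — the maternal parent carries the
   hybrid's plastid base type;
2. **allele coverage** — the two gamete payloads union to exactly the
   observed allele set, with each loss from a segregating gamete
   penalized;
3. **gamete-ploidy arithmetic** — gamete ploidies sum to the hybrid's
   ploidy and the offspring mode matches (apogamous whenever an
   apomictic gamete is involved).

Alleles never observed as any taxon's sole constitution spawn
hypothesized unsampled parental lineages.  Hypotheses are ranked by an
explicit preference order (fewest unknown parents, fewest allele
losses, hybridization-cycle crosses first, progenitors before
hybrid-derived parents), and the top hypotheses are assembled into a
directed **reticulogram** with solid maternal, dashed paternal and
thin-solid autopolyploidization edges (DOT / GraphML / JSON export).
A synthetic-data generator produces specimen tables, gene trees and
sequences with the same structure for end-to-end testing and
parameter-recovery experiments.

## Worked example

The package ships the voucher table of the *Diplazium hachijoense*
complex (42 specimens, 10 named species + 4 unnamed taxa):

```r
library(apohybrids)

spc <- diplazium_complex()
inf <- infer_parentage(spc)
top_hypotheses(inf)[, 1:5]
#>           species specimen_group        maternal        paternal       pattern
#> 1  D. conterminum           <NA>        D. takii        D. sp. F            P3
#> 2  D. hachijoense           <NA>    D. amamianum        D. takii            P3
#> 3   D. nipponicum           <NA>    D. amamianum        D. sp. J allopolyploid
#> 4  D. okinawaense           <NA>  D. hachijoense    D. dilatatum            P3
#> 5        D. sp. 1           <NA>    D. dilatatum        D. sp. G            P2
#> 6        D. sp. 2           <NA> D. doederleinii        D. sp. K            P3
#> 7        D. sp. 3           <NA>    D. amamianum D. doederleinii            P3
#> 8        D. sp. 4           <NA>    D. amamianum        D. sp. H            P3
#> 9   D. taiwanense              α    D. dilatatum        D. takii            P3
#> 10  D. taiwanense              β        D. takii    D. dilatatum            P3
#> 11   D. virescens           <NA>        D. takii        D. sp. E            P3
```

Reading the output: the triploid apomict *D. hachijoense* (alleles
{B, D}, plastid δ) arises as a hybridization-cycle (P3) cross with the
diploid sexual *D. amamianum* as maternal parent (it supplies the δ
plastid and allele D through a reduced 1x gamete) and the triploid
apomict *D. takii* as paternal parent (allele B through a reduced 2x
irregular-meiosis gamete).  *D. taiwanense* is inferred per specimen
group because its vouchers carry two plastid types — evidence of
recurrent, reciprocal origins from the same parents.  Six alleles
(E, F, G, H, J, K) occur only inside hybrids, so six unsampled
parental lineages are postulated (`inf$registry`); lineage H is
promoted to a triploid apomict because no diploid sexual H can yield
the triploid apogamous *D.* sp. 4.  The backcross case:

```r
print(inf$results[[which(sapply(inf$results, `[[`, "species") == "D. okinawaense")]], n = 1)
#> Parentage of D. okinawaense ({A,B}, plastid δ)
#>   1. D. hachijoense (maternal) x D. dilatatum  [P3, 3x, losses=1, unknowns=0]
```

*D. okinawaense* carries the δ plastid of the *D. amamianum* lineage
but neither of its alleles — the only consistent reading is a
backcross with *D. hachijoense* as maternal parent whose irregular
2x gamete lost allele D through segregation (one loss penalty).

The reticulogram (20 nodes: 14 sampled taxa + 6 hypothesized
lineages; 22 parent edges):

```r
g <- build_reticulogram(inf)
igraph::gorder(g); igraph::gsize(g)
#> [1] 20
#> [1] 22
export_dot(g, "reticulogram.dot")
```

A shell-friendly wrapper with the same verbs lives at
`inst/cli/apohybrids.R` (`summarize`, `infer`, `export`, `type`,
`simulate`).

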