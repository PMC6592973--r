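---
title: "Inferring reticulate origins in sexual-apogamous fern complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring reticulate origins in sexual-apogamous fern complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apohybrids)
```

## The inference problem

Apogamous (apomictic) ferns reproduce from unreduced spores, yet they
hybridize with sexual relatives and form species complexes with
continuous morphological variation.  `apohybrids` reconstructs the
parentage of such complexes from three kinds of evidence per voucher
specimen:

* a maternally inherited **plastid haplotype** label (Greek base types
  with subtype indices, e.g. `δ3`),
* a biparentally inherited **nuclear allele constitution** scored from
  PCR-SSCP band patterns (Latin base types, e.g. `B2D1`).  SSCP cannot
  measure allele dosage, so a constitution is a *set* of alleles:
  `A1A1B1`, `A1B1B1` and `A1B1` are the same observation.  The set is
  therefore the unit of inference throughout the package,
* **cytology**: reproductive mode from spore counts per sporangium (64
  = sexual meiosis, 32 = unreduced diplospores, anything else
  undetermined) and ploidy from sporophytic chromosome counts as
  multiples of the base number x (default x = 41, so 2n = 82/123/164
  give 2x/3x/4x).

## Gamete model

Hybrid formation is constrained by which gametes each parent can make
(ploidies in units of x):

| parent              | gamete                      | ploidy | payload |
|---------------------|-----------------------------|--------|---------|
| sexual, even p      | reduced meiotic             | p/2    | subset of its alleles (all of them for a single-type diploid) |
| sexual, any p       | unreduced (optional)        | p      | all alleles |
| apogamous, p        | unreduced diplospore        | p      | all alleles |
| apogamous, 3x       | irregular-meiosis reduced   | 2      | subset of its alleles |

The four canonical hybridization patterns follow from this table: P1
(3x apomict unreduced × 1x from a 2x sexual → 4x), P2 (2x apomict
unreduced × 1x → 3x), P3 (2x irregular-meiosis gamete from a 3x
apomict × 1x → 3x, the *hybridization cycle*: recurrent triploid
apomict formation without ploidy increase) and P4 (2x irregular × 2x
from a 4x sexual → 4x).  Same-taxon doubling is labeled
`autopolyploid`, an all-sexual combination with an unreduced gamete
`allopolyploid`, anything else `other`.  Offspring involving any
apomictic gamete are apogamous; offspring of two sexual gametes are
sexual.  Whether a 3x apomict can also make 1x gametes is not
supported by observation and is excluded.

Segregation payloads (`subset_allowed`) must carry at least one
allele: a 2x gamete contains two genome copies, so an empty payload is
not a physical option — unobserved alleles in such a gamete are
*losses*, counted and penalized, not free choices.

## Parentage constraints and ranking

For a putative hybrid, every ordered (maternal, paternal) pair from
the pool of sampled taxa and hypothesized lineages is screened against
three constraints:

1. **maternal plastid**: the maternal candidate must carry the focal
   plastid base type.  If *no* pool member carries it (a private
   haplotype, as for the tetraploid sexual *D. nipponicum* and its ε
   haplotype), the constraint carries no information; it is waived and
   the result flagged `plastid_unmatched` rather than discarded.
2. **allele coverage**: the two gamete payloads must union to exactly
   the observed constitution; every dropped allele from a segregating
   gamete costs one allele-loss penalty.
3. **cross arithmetic**: gamete ploidies must sum to the focal ploidy
   and the offspring mode must match, where determined; undetermined
   values constrain nothing.

Alleles observed only inside hybrids (never as any taxon's sole
constitution) are *orphans*; each spawns one hypothesized unsampled
lineage carrying exactly that allele.  Hypothesized lineages default
to diploid sexual — the least assuming parent for a P3 cross — and are
tried alternatively as triploid apomicts; a lineage is promoted to
triploid apogamous in the registry when the top-ranked hypothesis that
uses it requires the alternative (as for lineage H: a diploid sexual H
cannot give a triploid apomict with an unreduced maternal 1x gamete
from a diploid sexual).

Surviving hypotheses are ranked by an explicit qualitative preference,
not a statistical score: fewer hypothesized parents; fewer allele
losses; fewer hypothesized parents used under the non-default
apomictic assumption; pattern order P3 < P1 < P2 < P4 < allopolyploid
< autopolyploid < other (the hybridization cycle is the default
mechanism in these complexes; allele loss and rarer mechanisms are
invoked only when forced); fewer *composite* parents (taxa that are
themselves multi-allele hybrids — a hybrid is proposed as a parent
only when no progenitor explains the data equally well, which is what
forces the backcross reading of *D. okinawaense*); a sampled maternal
parent before a hypothesized one; and finally lexicographic
tie-breaks, making the output order fully deterministic.

Only the top-ranked hypothesis per taxon becomes an edge pair of the
exported reticulogram; all alternatives stay in the JSON report.
Taxa whose vouchers carry more than one plastid base type (e.g.
*D. taiwanense*, with α and β specimens) are inferred per plastid
group, which is how recurrent reciprocal origins are read from
individual specimens.

## Handling of undetermined and conflicting cells

Blank mode/ploidy cells stay unknown and propagate as *unconstrained*:
an unknown-mode parent is tried under both modes, an unknown ploidy
under the plausible range 2x–4x (the range observed in complexes of
this kind; configurable).  A taxon whose vouchers conflict (e.g.
*D. dilatatum* with both sexual-diploid and apogamous vouchers) is
reported as a conflict, not silently merged, and likewise contributes
both repertoires — which is load-bearing: the apogamous origin of
*D.* sp. 1 from *D. dilatatum* is only explicable through the
apogamous cytotype.

## Allele typing from gene trees

When per-locus gene trees are supplied, base types are assigned by
clade support rather than trusted from the labels: a leaf takes the
type of the reference taxa (taxa whose own constitution is a single
type) in the *smallest* supported clade containing it and at least one
reference leaf.  "Smallest" is a deliberate choice — it is the most
local, most conservative statement of shared ancestry, and it is
well-defined because any two clades containing the same leaf are
nested.  A clade is supported when its posterior probability exceeds
0.95 or its bootstrap percentage exceeds 70 (strictly greater; both
must pass in `strict_support` mode when both are present; an absent
support value is absent, not zero).  Mixed reference types in the
decisive clade leave the leaf `unassigned`.  Typing is a verification
stage: without trees, the pipeline trusts the type letters embedded in
the specimen labels.  Type delimitation by raw sequence similarity is
deliberately not implemented — no quantitative criterion is
established for it in this system.

## What the simulator emulates — and what it does not

`simulate_complex()` realizes a truth network (progenitors plus
hybridization events) into exactly the artifacts the pipeline
consumes: a specimen TSV with dosage-masked allele sets, per-locus
gene trees whose clades are the true type genealogy with injected
supports, and per-locus FASTA sequences.  Design choices:

* Sequences evolve under an equal-rates (Jukes–Cantor-style)
  substitution model — the simulator tests typing and inference logic,
  not substitution-model fit.  Defaults: 600 bp (the scale of a short
  nuclear intron matrix), 25 substitutions between base types, 2
  between subtypes.
* Supports are injected (1.0/100 minus configurable noise), not
  estimated; tree inference is out of scope end to end.
* Allele dropout models segregation loss: each allele of a
  segregating payload is lost with the configured probability, at
  least one allele always transmits.
* Identifiability conditions are built into generated topologies: no
  ordered parent pair repeats, and the two parents of an event never
  share a plastid base type.  The real complex satisfies both (its
  recurrent origins are reciprocal, differing in the maternal parent);
  networks violating them are genuinely ambiguous and no method could
  recover a unique answer from constitution data.
* `hachijoense_network()` is the complex-shaped benchmark: 5 sampled
  progenitors, 6 unsampled orphan lineages and 11 events, including
  the backcross with intrinsic allele loss and the allopolyploid
  origin.  Reciprocal origins appear as two offspring taxa so that
  each has its own voucher series.

What passing simulation tests does *not* show about real data: the
generator produces clean labels (no scoring errors), complete cytology
for every simulated voucher, no within-species coalescent variation,
no recombination within loci, and plastid haplotypes that always match
a sampled progenitor (a private haplotype like ε never arises because
offspring inherit an existing maternal plastid).  Conclusions about
robustness to those features cannot be drawn from the suite.

## Problem sizes and runtime choices

The shipped experiments are sized so the whole suite runs in about a
minute on one core: oracle cross-checks use 100 random ≤8-taxon
datasets and 100 random 12-leaf support trees; recovery experiments
use the 11-event benchmark network and 20 replicate seeds per dropout
level (0, 0.15, 0.3, 0.5).  Enumeration is exact, not sampled, at
these sizes; the hypothesis space for the packaged 14-taxon complex
(a few hundred surviving hypotheses per focal taxon) is enumerated in
under a second.

## Known limitations

* Ranking is a made-explicit qualitative preference; it attaches no
  probabilities and no uncertainty to the chosen origin.  Co-ranked
  alternatives are visible in the report, not resolved.
* Aneuploid counts are rejected rather than modeled.
* Subtype indices (allele variants within a base type) are carried
  through but not used as evidence; inference operates on base types.
* Direction of time beyond maternal/paternal roles (which taxon came
  first) is not inferred; the DAG check only rejects outright cyclic
  parenthoods.
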