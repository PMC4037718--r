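# flspace — fragrance chemical space analysis with Molecular Quantum Numbers

Fragrance molecules are small, volatile organic compounds — mostly C/H/O(/S)
skeletons with very few polar groups. `flspace` is an R toolkit for exploring
that corner of chemical space the way it is done in descriptor-based virtual
screening:

* **MQN descriptors.** Every molecule is summarised by the 42 Molecular
  Quantum Numbers — integer counts of atoms (`c`, `s`, acyclic/cyclic N and O,
  heavy atom count …), bonds (acyclic/cyclic × single/double/triple,
  rotatable bonds), polarity features (H-bond acceptor/donor atoms and sites,
  charges at pH 7.4) and topology (node degrees, ring sizes over the smallest
  set of smallest rings, fused-ring atoms/bonds). Molecules are ionized at
  pH 7.4 by a rule table (carboxylic/sulfonic/sulfinic/phosphonic O–H
  deprotonated; aliphatic amines, amidines and guanidines protonated) before
  counting.
* **Fragrance-likeness (FL) filter.** A molecule is fragrance-like when
  HAC ≤ 21, its heavy elements are within {C, O, S}, O + S ≤ 3 and it has at
  most one H-bond donor.
* **Similarity searching.** The city-block distance
  CBD(a, b) = Σᵢ |aᵢ − bᵢ| is the similarity measure in every descriptor
  space. An `mqn_index` buckets a library by the MQN sum; because
  |Σa − Σb| ≤ CBD(a, b), a range query only inspects buckets within `d_max`
  of the query sum yet returns exactly the brute-force hit set. Searches can
  be restricted by database bit mask, to isomers (same molecular formula),
  and to molecules with the query's H-bond donor/acceptor counts.
* **Chemical-space maps.** A covariance PCA of a reference MQN set defines a
  (PC1, PC2) plane; any collection is projected onto it, rasterized to a
  pixel grid, and coloured in HSL space (hue blue→cyan→green→yellow→red→
  magenta with the per-pixel property mean, saturation fading to grey with
  the per-pixel SD). Each pixel reports its "average molecule", the member
  closest (by CBD) to the pixel's mean MQN vector.
* **Ligand-based virtual screening.** Fragrance families are curated
  (promiscuous members removed, FL rules enforced, minimum size 10), the
  family medoid is the reference, the family is diluted into a background
  library and ranked by CBD in one of four spaces — MQN, a 1024-bit path
  fingerprint (Sfp), a 1024-bit extended-connectivity fingerprint of bond
  diameter 4 (ECfp4), or molecular weight. Enrichment is measured by the
  rank-averaged Mann–Whitney AUC and the recovery of actives in the top
  0.1/1/10% of the ranked library.

Parsing, canonicalization (stereo-aware), Hill formulas, clogP and the two
fingerprints are delegated to Open Babel (via `ChemmineOB` and the `obabel`
binary). The descriptors, filter, index, maps and screening protocol are
implemented in the package, and built-in generators (a C/H/O/S fragment
grammar for decoy libraries; an edit-move engine for structural-analog
families) make everything runnable without external databases.

## Worked example

Search a synthetic fragrance-like library for neighbours of menthone, the
peppermint ketone, keeping its H-bond profile (0 donors, 1 acceptor) fixed:

```r
library(flspace)

menthone <- "CC1CCC(C(C)C)C(=O)C1"
compute_mqn(menthone)            # nonzero entries shown
#>   c   ao  hac  asb  adb  csb  rbc  hba hbam  asv  atv  cdv  ctv   r6
#>  10    1   11    4    1    6    1    1    2    4    1    3    3    1

decoys <- generate_decoys(2000, seed = 42)
idx <- build_index(decoys)
range_search(idx, menthone, d_max = 12, lock_hbd = TRUE, lock_hba = TRUE)
#>        id cbd
#> 1 D001483   5
#> 2 D000378   8
#> 3 D001477  11
#> 4 D001170  12
```

The top hit at CBD 5, `CCC1CC(C)CCC1C(=O)C`, is — like menthone — a
monocyclic C10/C11 ketone with three acyclic substituents: nearest
neighbours in MQN space are constitutional analogs. Screening a planted
family of 15 generated menthone analogs diluted in the same 2000 decoys:

```r
fam <- generate_analog_family(menthone, 15, seed = 7)
res <- run_enrichment(fam, decoys, space = "MQN")   # medoid reference, CBD ranking
res
#> <enrichment 'family' in MQN space: AUC 99.6%, 14 actives in 2014 candidates>
#>   recovery: 0.1% -> 7.1%, 1% -> 71.4%, 10% -> 100.0%
#>   reference: A001
```

An AUC of 99.6% and 71% of the actives inside the top 1% of the ranked
library is the early-recovery behaviour that makes MQN similarity usable
for screening. The FL filter behaves as the curation rules require —
nitrogen heterocycles are excluded by the element rule:

```r
is_fragrance_like(c(menthone = menthone, pyrazine = "c1cnccn1"))
#>         id passed failed_rules hac os hbd
#> 1 menthone   TRUE               11  1   0
#> 2 pyrazine  FALSE     ELEMENTS   6  0   0
```

A command-line wrapper covers the same workflows
(`flspace mqn|filter|profile|index|search|map|lbvs|fixtures`), e.g.

```sh
flspace filter --in db.smi --out db.fl.smi --report report.json
flspace search --index lib --query "CC1CCC(C(C)C)C(=O)C1" --dmax 12 --lock-hbd --lock-hba --out hits.tsv
```

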