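---
title: "Methods: MQN descriptors, fragrance-likeness and similarity screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MQN descriptors, fragrance-likeness and similarity screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flspace)
```

This vignette documents the models and conventions behind `flspace`: what is
counted, which rules fire, where the numerical choices sit, and what the
built-in generators do and do not emulate.

## The molecular graph and its provenance

All computation happens on a heavy-atom graph with explicit per-atom
hydrogen counts, parsed from Open Babel's kekulized V2000 output. Two
consequences are deliberate:

* **Kekulized bond orders.** The MQN bond classes distinguish only
  single/double/triple, so aromatic systems must be kekulized before
  counting; benzene then contributes three cyclic single and three cyclic
  double bonds, deterministically. Inputs whose aromatic systems cannot be
  kekulized are rejected with an error.
* **Largest organic fragment.** Salts and multi-fragment records keep only
  the largest carbon-containing fragment before any downstream computation;
  fragrance-like molecules are single neutral organics, and every module
  assumes one connected component.

Duplicate removal compares stereo-aware canonical SMILES, so enantiomer
pairs — such as the two carvones, which smell of spearmint and caraway
respectively — are distinct molecules by default; `dedup(ignore_stereo =
TRUE)` collapses them when a constitution-level view is wanted.

## Ionization at pH 7.4

Descriptors are computed on the physiologically ionized form. The rule
table is deliberately coarse — a pKa-free classification, not a prediction:

* deprotonated: O–H on carboxylic, sulfonic, sulfinic and
  phosphonic/phosphate groups (every matching acidic O–H, one negative
  charge each);
* protonated: aliphatic primary/secondary/tertiary amines (excluding
  amides, sulfonamides, anilines and unsaturated-ring nitrogens), and the
  imine nitrogen of amidines and guanidines;
* untouched: alcohols, phenols, thiols, amides.

The table is idempotent and never changes heavy-atom composition, so
formulas and topology descriptors are unaffected; only `pos`, `neg`, the
donor/site counts and the molecular weight can shift. The `pos`/`neg`
descriptors count charged *atoms*; for the functional groups above this
equals the count of charged groups.

## The 42 counts and their conventions

Most MQN entries are unambiguous graph counts. Four groups need a stated
convention, which the package pins as follows:

* **Cyclic/acyclic membership** of atoms and bonds uses ring-bond
  (non-bridge) membership; ring-size counts `r3`…`rg10` and the fused-ring
  counts `afr`/`bfr` use the smallest set of smallest rings. The SSSR is
  built from the shortest cycle through every ring bond, selected greedily
  by size under GF(2) independence until the circuit rank
  (bonds − atoms + components) is reached; candidate order is deterministic
  (size, then lexicographic edge set), which fixes the basis in tied fused
  systems. Note that this is the *minimal* SSSR: symmetric cages report
  exactly circuit-rank rings (α-pinene: two), where symmetry-perceiving
  toolkits may report more.
* **Rotatable bonds** (`rbc`): acyclic single bonds between two heavy atoms
  of heavy-degree ≥ 2, excluding bonds with a triple-bonded end. This is
  the common convention; the descriptor's original definition lives in
  prior literature and is not restated anywhere normative, so it is pinned
  here and documented.
* **Donors/acceptors**: acceptors are all O plus N except amide and
  pyrrole-type ring N ("pyrrole-type" = all-single-bonded ring N inside an
  unsaturated ring — an aromaticity-free approximation); donors are N/O
  bearing ≥ 1 H; sulfur is neither (thiol S–H does not count as a donor, a
  switchable convention shared between the filter and the descriptors so
  they can never disagree). Site counts: `hbdm` = hydrogens on donors;
  `hbam` = 2 per neutral acceptor O, 3 per anionic O, 1 per acceptor N.
* **Node degrees** use heavy-atom degree only; isolated heavy atoms are in
  no degree class.

Five conservation identities tie the vector together (N and O splits, bond
class totals, ring count = circuit rank, node count = non-isolated heavy
atoms); the test suite enforces them on every curated molecule and on
10,000 generated ones, and cross-checks formulas, heavy-atom counts and
SSSR sizes against an independent toolkit.

## The fragrance-likeness filter

The four rules (HAC ≤ 21; heavy elements ⊆ {C, O, S}; O + S ≤ 3; HBD ≤ 1)
are evaluated on the ionized graph, all four always (no short-circuit), so
the failed-rule set is complete — a 25-atom tri-ol amine reports HAC,
ELEMENTS and HBD together. clogP appears only in the property profiles
(Open Babel's atom-contribution estimator), never in filtering. No
nitrogen-permissive variant is provided: admitting nitrogen floods any
fragrance-like subset with amine-rich chemistry that represents only a
minor fraction of fragrance molecules.

## Exact similarity search

The index hashes each library entry by its MQN sum. For a query `q` with
boundary `d_max`, only buckets with sum in `[Σq − d_max, Σq + d_max]` are
inspected — sound because the L1 distance can never be smaller than the
difference of coordinate sums. Within the inspected buckets the full CBD is
computed, then the database mask (bitwise match against the wanted mask),
isomer lock (formula equality) and H-bond locks (donor/acceptor equality
with the query) are applied; locks compound with `d_max` rather than
replacing it. Results are ordered by (distance, id), the id tiebreak making
every search reproducible; an indexed query molecule returns itself at
distance 0 as hit number one. The default boundary `d_max = 12` is the
radius that past MQN screening practice found to contain useful analogs.
k-NN is an expanding-ring wrapper (boundary doubled from 4 until k
constrained hits exist), provably equal to the head of the fully sorted
scan. Masks support up to 53 databases so that entry masks remain exactly
representable in doubles in the TSV serialization.

## PCA maps

The map model is a covariance PCA of the centered, *unscaled* reference MQN
matrix: the 42 counts share one scale, and unscaled PCA yields the
size-dominated first component with non-negative loadings that makes the
maps readable (small molecules left, large right; acyclic bottom,
polycyclic top). Each component is sign-flipped if its loading sum is
negative; `standardize = TRUE` gives correlation PCA as the alternative.
"Rank < 2" means fewer than two distinct reference rows; a cloud varying
along a single axis is legitimate (PC1 fraction 1.0). Projection always
uses the reference means and loadings — mapped subsets are never refit, so
different collections land in comparable coordinates.

Rasterization derives the axis ranges from the reference scores expanded by
1% in total (0.5% per side); the expanded bounds map to pixels 0 and
`grid − 1` and out-of-range projections clamp to the border. Pixel colour
is HSL: hue runs 240° → −60° (blue through yellow and red to magenta,
passing orange on the way) linearly over the occupied-pixel mean range;
saturation is `max(0, 1 − sd/sd95)` with `sd95` the 95th percentile of
positive pixel SDs (so a single-member pixel is fully saturated and the
noisiest 5% of pixels are fully grey); lightness is fixed at 0.5. The
mean→hue and sd→saturation formulas are package choices pinned for
determinism — the qualitative scheme (hue follows the mean, grey follows
the spread) is the specification. The per-pixel average molecule is the
member with minimal CBD to the pixel's mean MQN vector, computed in exact
integer arithmetic (n·CBD against column sums) so ties break on ids, never
on floating-point noise.

## Virtual screening protocol

Family curation removes molecules listed in more than five raw families
(promiscuous odorants), removes non-FL members, optionally caps HAC (13
when the background is an enumerated 13-atom universe), and drops families
below 10 members. The reference is the per-space medoid — arg-min of summed
CBD to the other members, ties to the lowest id. The reference is excluded
from the actives and from the ranked list: including it would inflate every
metric identically, so exclusion is the conservative reading (a flag on the
recovery denominator exposes the alternative). Background molecules whose
canonical structure duplicates a family member are removed before dilution.

AUC is the rank-averaged Mann–Whitney statistic in percent — ties, which
are frequent for integer MQN distances, count one half — so
AUC(reversed) = 100 − AUC exactly. Recovery at fraction *f* counts actives
in the top `max(1, floor(f·N))` of the ranking with (distance, id) order at
the cutoff. Both are verified against brute-force pairwise oracles on
randomized tied instances.

## The generators: what they emulate, and what they do not

`generate_decoys()` assembles molecules from a C/H/O/S fragment grammar —
branched alkyl chains, small carbocycles and O-heterocycles, and
carbonyl/ester/ether/thioether/alcohol/aldehyde/acid caps — with heteroatom
and donor budgets inside the FL rules (a `fl_bias = FALSE` mode adds
nitrogen chemistry for filter testing). Heavy-atom counts default to 5–21,
the fragrance size range. The grammar was chosen over exhaustive
enumeration to keep desk-scale runtime; it emulates the *composition* of a
fragrance-like background (sizes, heteroatom density, functional-group
vocabulary) but not the exhaustive regiochemical coverage or ring-system
diversity of an enumerated chemical universe, nor the popularity biases of
catalog databases. Passing tests therefore demonstrate correctness of the
machinery and the qualitative enrichment behaviour, not performance numbers
transferable to any real database.

`generate_analog_family()` applies random edit moves to a seed — chain
homologation/shortening, methyl transposition, ring size ±1,
carbonyl↔alcohol swaps — validating each candidate for valence sanity and
the FL rules. This emulates a family of close constitutional analogs (the
structure of curated odorant families); it does not claim odour activity.
Families generated this way are measurably tighter in MQN space than
random decoy samples, which is exactly the planted signal the screening
tests rely on: with 15-member families diluted into 10,000 decoys, MQN
screening recovers them with mean AUC well above 80% and recovery at 1%
far above the 1% random expectation. Both generators draw all randomness
from an explicit seed through an isolated RNG state, so every library is
reproducible byte for byte.

## Problem sizes and numerical choices

The shipped verification uses 10,000-molecule generated libraries for the
invariant, metric and index-oracle suites (50–100 queries × d_max ∈
{0, 6, 12} × all isomer/H-bond-lock combinations), 10 planted families of
15 for screening, and a 1,000-molecule map on a 50×50 grid for the
pixel-level checks — a grid coarse enough to make crowded pixels common,
which is what the average-molecule and saturation rules need exercising.
Determinism choices worth knowing: SSSR candidate ordering (above), the
(distance, id) tiebreak in every ranking, exact integer arithmetic for
pixel medoids, and molecular weights from standard atomic weights on the
ionized form (menthone − limonene = 18.015 Da, the weight of water).

## Known limitations

* The ionization table is rule-based; unusual acids/bases outside the
  listed groups pass through neutral. No tautomer handling, no continuous
  pKa.
* Donor/acceptor, site-count and rotatable-bond conventions are pinned
  stand-ins for definitions that live in prior literature; descriptor
  values for N-rich molecules may differ from other MQN implementations
  (irrelevant inside the C/H/O/S fragrance-like space).
* Fingerprint bits are reproducible only per Open Babel version; tests pin
  structural properties, not bit patterns.
* The CLI's YAML config layer is not implemented; flags and defaults only.
* Published database-scale figures (retention percentages and recovery
  tables against public repositories) require those databases and are out
  of scope; the package verifies the machinery and its qualitative
  behaviour on generated libraries instead.
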