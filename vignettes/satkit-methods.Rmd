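---
title: "Assembly-free satellitome analysis with satkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly-free satellitome analysis with satkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Satellite DNA (satDNA) — tandemly repeated, largely heterochromatic sequence —
is systematically collapsed by genome assemblers, so assembly-based repeat
annotation can understate the most abundant components of a genome by an
order of magnitude. The established alternative works directly on a
low-coverage (0.1–0.5x) sample of unassembled short reads: reads are clustered
by sequence similarity, clusters whose k-mer graphs are ring-shaped are
recognised as tandem repeats, one consensus monomer is derived per family,
and abundance and divergence are measured by masking reads against the
consensus. `satkit` implements that entire workflow as a reproducible R
package, together with a simulator that plants satellite families of known
abundance and divergence so every stage can be verified against ground truth
without downloading anything.

# Pipeline model, stage by stage

## Read preparation

Pairs are dropped whole (never orphaned) when either mate is shorter than
`min_length` (default: half the read length) or carries more than `max_n`
ambiguous bases (default 0). Subsampling is uniform without replacement and
seed-stable. Coverage is analysed bases over genome size; the display value is
*truncated* to two decimals — the convention under which 271 Mb over a
1187 Mb genome reads "0.22x" — while the full-precision value is kept. The
recommended working range [0.1, 0.5]x is a closed interval.

A note on `min_length`: the workflow this package systematises documents a
length filter of 150 for 101 bp reads, which cannot act as written. Rather
than propagate the inconsistency, `min_length` is an explicit parameter
defaulting to half the read length.

## Read clustering

Reads (mates interleaved) become nodes of a graph; an edge joins two reads
sharing at least `min_shared = 10` distinct *canonical* k-mers (k = 21;
canonical = lexicographic minimum of k-mer and reverse complement, making the
graph strand-symmetric). Two unrelated 101-mers share an expected
81 × 81 / 4^21 ≈ 1.5e-9 canonical 21-mers, and an edge needs ten, so chance
edges are essentially impossible; conversely identical reads share 81.
One adjustment is needed at the low-complexity extreme: a read from a
tandem array of a 9-bp monomer contains only 9 distinct canonical 21-mers in
total, fewer than `min_shared`. The effective per-pair threshold is therefore
`min(min_shared, ceiling(0.8 x smaller repertoire))`, which leaves ordinary
reads untouched and keeps microsatellite-like families connected.

Clusters are connected components (a deliberate simplification relative to
the Louvain-style partitioning of the tool that inspired this stage: simpler,
deterministic, and sufficient at desk scale), ordered by decreasing
abundance; singletons form no cluster. The abundance filter is strict:
clusters must *exceed* `min_abundance = 0.001%` of analysed reads. A
percolation property of the defaults worth knowing: families whose copies are
~10% diverged form one giant component holding the large majority of the
family's reads plus a fringe of 2–5-read fragments; the fragments re-merge
with the family at the catalog stage through consensus identity.

## Tandem detection (ring-shaped k-mer graphs)

Per cluster, a de Bruijn graph over canonical 15-mers is built; a tandem
repeat of unit length L appears as a dominant ring of exactly L nodes, while
single-copy or interspersed (TE-like) sequence yields paths. The monomer is
read off a greedy heaviest-successor walk started from the heaviest nodes;
because the walk follows weight, the traversal letters are the
multiplicity-weighted consensus of the ring.

*Circularity* decides the satellite call: the fraction of the cluster's k-mer
mass attributable to the ring, with threshold 0.5. Attribution is
bubble-inclusive — a k-mer counts when it lies within `floor(k/4)`
substitutions of some cyclic k-mer of the monomer (either strand). The naive
"exact membership" reading would make the threshold unusable: at 5% copy
divergence only 0.95^15 ≈ 46% of k-mers are exactly consensus, yet those
k-mers are unmistakably ring mass (they are SNV bubbles hanging off the
ring). With the Hamming-ball attribution, planted families at up to 10%
divergence score ≥ 0.95 while TE decoys and single-copy clusters score 0 (no
ring at all), leaving the 0.5 threshold a wide margin on both sides.

The main k is 15, with a fallback sweep over k = 13, 11, 9 when no ring is
found. The fallback exists for monomers shorter than k that an unlucky k
cannot resolve, so a fallback candidate is accepted only when its unit is at
most that k long: at small k the graph of even random sequence becomes dense
enough that long spurious cycles appear, and this gate is what keeps them
out. Monomers are reported in canonical rotation (lexicographic minimum over
all rotations of both strands, by Booth's algorithm on each strand), so the
same family detected in different samples, phases or strands compares equal.

## Catalog: dedupe, rank, name

Candidates merge when their canonical monomers align at ≥ 80% identity.
The comparison tiles the shorter unit to the longer unit's length (so GATA
merges with its 9-bp expansion GATAGATTA — variants of one biological
family), doubles the longer (so every rotation is a substring), and aligns
pattern-globally on both strands. Pattern-global anchoring matters: a purely
local alignment trims to any short exact stretch and reports 100% identity
for unrelated monomers. The 80% default sits just above the weakest
cross-species consensus similarity this comparison is expected to respect
(78.5%), so intraspecific variants always merge while cross-family merges
stay out of reach.

Families are ranked by abundance in the reference sample — the male, since
the male read set is the discovery sample and names must be shared across
samples — and named `<SpeciesCode>Sat<NNN>-<RUL>` with a zero-padded rank
(ties: smaller unit, then lexicographic consensus). "ND" marks families not
detected in a sample in the TSV outputs.

## Quantification and K2P landscapes

Each family's reference is its consensus concatenated per the unit-length
rule: units over 100 bp become dimers, units of at most 100 bp become
~200 bp concatemers (`round(200/rul)` copies, round-half-to-even, minimum 2).
The rul = 100 boundary is assigned to the ≤ branch; both rules coincide there
(200 bp either way). Concatemers guarantee that reads spanning a monomer
junction align contiguously.

Reads are screened by shared 13-mers per strand (≥ 2 to be aligned at all)
and aligned ungapped: the best-scoring diagonal run (match +1, mismatch −1)
over all diagonals, references and strands. Ungapped alignment is the correct
counterpart of the simulator's substitution-only mutation model (indels are a
config flag that defaults to 0) and is two orders of magnitude faster than a
gapped aligner here; with no indel columns, transition (P) and transversion
(Q) proportions are counted directly over the aligned window. Each read goes
to at most one family — best score, ties to the forward strand, then to the
lower catalog rank. Hits under 30 aligned bases or over 35% divergence
(chosen beyond the highest satellite divergence plausibly still alignable,
and above the ~32% maximum reported in real satellitomes) are discarded.

Divergence is Kimura 2-parameter, d = −(1/2) ln((1 − 2P − Q)√(1 − 2Q)),
reported in percent, with saturation flagged outside the model's domain.
Abundance is aligned bases over analysed bases; landscapes bin that abundance
by integer-percent K2P intervals [0,1), [1,2), … Per-family bins sum to the
family's genome proportion, the "ALL" landscape is the element-wise sum, and
family proportions plus the unmasked remainder always close to 100%.

## Library comparison and Y-linkage

Catalogs are compared with the same rotation/strand/period-aware identity
(defaults: identity ≥ 78.5%, ≥ 80% of the shorter unit covered; a
database-scale e-value threshold makes no sense for a catalog-vs-catalog
comparison, so a deterministic identity floor replaces it). Matching is a
greedy best-identity assignment, so each family has at most one partner and
the result is symmetric. Family groups are connected components of the match
graph across catalogs; each group lands in the exact subset of catalogs it
occurs in, giving Venn-style shared/exclusive counts whose total equals the
number of groups.

Sex-biased abundance: a family is a Y-linkage candidate when male/female
abundance ratio ≥ 10 (zero denominators replaced by the 0.001% discovery
floor; male-present/female-absent always flags). A moderate excess
(ratio ≥ 2 but below the Y threshold) is labelled a copy-number polymorphism
candidate instead — the signature of population differences in autosomal
heterochromatin rather than of a Y-restricted repeat.

# The synthetic world

`default_family_specs()` is a fixed stated world, not a tuning knob: eight
families at genome proportions 10, 5, 2, 1, 0.5, 0.2, 0.1 and 0.05%, with
copy divergences 2, 1, 10, 5, 3, 4, 2 and 0%. The assignment is the
biologically expected one — the most abundant families carry low divergence
(recent amplification and homogenisation in heterochromatin produce the sharp
low-K2P peaks), the most diverged family (10%, an old euchromatic resident)
sits at 2% so it is still densely sampled at 0.2x — plus one 9-bp Y-linked
GATAGATTA microsatellite mirroring the canonical Y-restricted GATA repeats of
kissing bugs, one GC-rich family (satellites are typically AT-rich; the
exception must also be handled), and a dispersed 1.5-kb TE-like decoy at 1%
with 3% copy divergence that must *not* be called a satellite. Monomer
sequences are derived deterministically from the master seed and regenerated
until primitive with distinct cyclic 15-mers (a monomer that is internally
periodic *should* be reported at its true shorter period, so such draws are
rejected rather than mislabelled).

Genomes place heterochromatic families as large arrays at the
pseudo-chromosome ends (separated by short background spacers so that no
fragment spans two families' arrays), dispersed families as many smaller
arrays, and decoy copies individually — placement mirrors the three FISH
distribution patterns seen in real karyotypes but is cosmetic: downstream
statistics depend only on base composition. Copies mutate independently,
substitutions only, transition:transversion 2:1 by default. Reads are 101 bp
pairs from constant-length 300 bp fragments, mates on opposite strands, with
0.5% uniform base error; every mate records its template start and
majority-overlap origin so recovery can be scored exactly.

What the simulator does *not* model — realistic Illumina error profiles, GC
bias, duplicates, indels, higher-order repeat structure — bounds what a green
test establishes: parameter recovery under a clean substitution model, not
robustness to platform artefacts.

# Numerical choices and degenerate inputs

* Exact accounting everywhere bookkeeping is possible: segment lengths sum to
  the genome length; realised proportions are within ±2% relative of targets
  by construction; male and female genomes built from one seed have
  identical non-Y family content.
* The recovery tolerance for masked abundance (±15% relative) is checked
  against the *exact family base content of the read set* (per-mate overlap
  with family segments), not against the genome proportion: at 0.2x coverage
  of 10 Mb the 0.05% family is drawn as roughly ten read pairs, so
  genome-to-reads Poisson noise alone has ~30% relative spread and would
  dominate a comparison the masking stage has no influence over.
* Seeds: every stochastic operation takes one; pipeline stages derive theirs
  from the master seed by a fixed affine map kept inside 32-bit range.
  Identical config and master seed give byte-identical TSV outputs.
* Memory guardrails are explicit errors (read-count cap, k-mer co-occurrence
  volume cap), never silent truncation.
* Degenerate inputs: empty read sets propagate as empty results (zero
  coverage is legal); an empty read budget aborts the pipeline with a
  machine-readable stage/code; saturated K2P values are flagged and excluded
  from masking rather than clamped; empty clusters yield empty graphs and no
  candidate.

# Known limitations

* Connected components can, in principle, chain two families through a read
  bridging their boundary; the simulator's spacers remove the main source of
  such bridges, and dedupe provides a second line of defence, but adversarial
  array structures (interleaved families at high homology) would defeat both.
* The greedy heaviest-successor walk recovers the highest-weight cycle of
  satellite-like graphs but is not an exact maximum-weight-cycle algorithm;
  pathological weight configurations could mislead it.
* Monomers longer than the walk cap (2500 steps) or clusters thinner than
  ~5x monomer coverage may fail ring detection — at 0.2x coverage this binds
  the smallest detectable family size for long-unit satellites.
* Quantification inherits the ungapped alignment: genuinely indel-rich
  satellite families would be under-masked. The cited real-data workflow uses
  a gapped masker; equivalence with it is not claimed, only recovery of
  planted truth.
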