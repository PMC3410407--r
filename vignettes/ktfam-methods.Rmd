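---
title: "Methods: screening, curation, and reconciliation in ktfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, curation, and reconciliation in ktfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `ktfam`, in the spirit of a methods supplement. The
pipeline inventories plant K⁺ transporter families (HAK/KT/KUP, HKT,
tandem-pore channels, *Shaker*-like channels) by degenerate-motif
screening of proteomes, semi-automatic curation, distance
phylogenetics, and duplication–loss reconciliation against a fixed
five-species land-plant tree.

## Motif screening

Motifs are positional patterns in the dash-separated dialect
(`[S,T]-x-x-T-x-G-[Y,F,L]-G-[D,E]`): each position is a wildcard, a
single residue, or an allowed-residue set. Matching is exact and
position-wise; overlapping hits are reported. Two conventions matter:

* the unknown residue `X` never satisfies a restricted position but is
  accepted by wildcards — a conservative reading that avoids calling
  families on ambiguous sequence;
* channel pore counting selects non-overlapping selectivity-filter hits
  leftmost-greedily, which is deterministic and matches the biological
  picture of discrete pore domains (one for *Shaker*-like subunits, two
  for tandem-pore subunits).

The original protocol does not state how many motifs of a class must
co-occur. The defaults here are a documented reconstruction: HAK
requires at least 3 of the five HAK motifs, HKT requires both HKT
motifs, CHANNEL requires the selectivity-filter motif (motif 1). The
voltage-sensor-like and inner-helix motifs (2, 3) are recorded as
evidence but not required for the channel call, because tandem-pore
channels lack voltage sensors. All thresholds are exposed in
`defaultClassifyRules()`.

Downstream, channel calls are routed to curation pools in a fixed
priority: two or more non-overlapping pore motifs → tandem-pore pool;
otherwise a single pore plus voltage-sensor evidence → *Shaker* pool;
remaining channel calls go to a human-review list (`OTHER_VG`), which
mirrors how BK-like channels were identified by similarity rather than
by motif. The priority order makes the routing robust: a drifted
tandem-pore sequence cannot lose a planted pore motif, and a chance
extra filter hit in a *Shaker*-like sequence only strengthens the
channel call.

## Curation

Curation reconstructs the original semi-automatic procedure:

1. **Length filter.** The threshold is `0.70 ×` the mean span between
   the outermost motif hits of the reference proteins. Discarding is
   strict (`< 70%`), so a candidate exactly at the boundary is kept.
2. **Pairwise scores.** The protocol's "pairwise score" is not formally
   defined; it is re-specified here as percent identity of the optimal
   global alignment (BLOSUM62, gap open 10, extend 0.5 — classic
   ClustalW-like defaults) with the identity count divided by the
   shorter sequence length, rounded to two decimals. This is
   `Biostrings::pid(type = "PID3")` on `pairwiseAlignment()` output.
3. **Pruning.** Pairs scoring exactly 100 are identical sequences; the
   lexicographically larger id of each such pair is dropped and
   recorded (de-duplication, not exclusion of both — excluding both
   would discard genuine identical paralogs). Edges below 20 are
   deleted; connected components of the remainder are the groups.
4. **Selection.** The component with the highest mean member-reference
   score is selected; ties break by larger component, then smallest
   member id, so runs are reproducible.

An empirical caveat documented here deliberately: under this score
definition, *unrelated* random proteins of a few hundred residues
typically score near 20 (median around 21 in simulation), so the edge
threshold cannot by itself separate families that share a curation
pool. Specificity comes from the classification rules, the length
filter, and reference-similarity selection — which is also why the
pipeline curates single-pore and tandem-pore channels separately, as
the original analysis did per family.

## Alignment and block filtering

The progressive aligner is intentionally simple: UPGMA guide tree on
pairwise-identity distances, profile-profile merging by global dynamic
programming with average-of-pairs BLOSUM62 column scores and a linear
gap penalty (8 per gap column). It is adequate for the simulated data,
which evolve without indels; for real data a pre-aligned FASTA can be
wrapped with `Msa()` instead (external-aligner hook).

The block filter uses the stated parameter set: conserved- and
flank-position thresholds of half the number of sequences (read as
`ceiling(n/2)` — a majority-or-tie reading well defined for odd n),
maximum non-conserved run 20, minimum block length 2, gaps counted as
ordinary symbols. Because both thresholds equal half, the distinction
between "conserved" and "highly conserved" positions collapses and a
single CONSERVED status suffices. A consequence of the stated gap rule
is that gap-majority columns can count as conserved; the filter does
not special-case them. Filtering is idempotent: block boundaries end on
flank-qualifying columns, so refiltering changes nothing.

## Trees and support

UPGMA is implemented directly so that tie-breaking is fully specified
(lexicographically smallest pair of cluster ids; cluster id = smallest
member label); heights are half the merge distance, so ultrametric
inputs are reproduced exactly. Neighbor joining delegates to `ape::nj`
with negative branch lengths clamped to zero under a warning. Maximum
likelihood is intentionally out of scope; NJ on identity distances is
the built-in stand-in, and externally inferred trees can be imported as
newick. Bootstrap support resamples alignment columns with replacement
under a caller-supplied seed and counts reference bipartitions in the
replicate trees; identical seeds give bit-identical supports.

## Duplication–loss reconciliation

Rooted gene trees are mapped onto the rooted species tree by LCA
reconciliation in one postorder pass. An internal node is a duplication
iff it shares its species image with one of its children. For a gene
edge (u,v) whose images span k species-tree edges, the minimal
consistent loss count is k−1 when u is a speciation and k when u is a
duplication; each loss is placed on the species edge whose lineage was
bypassed (the off-path child at each charged node). No losses are
charged above the gene root unless a species root constraint is
supplied (`rootConstraint`, off by default).

Unrooted trees are rooted by evaluating D+L for every branch rooting
(`rootByDL`); ties break by the lexicographically smallest canonical
topology string and all tied rootings are reported.

Ancestral dosage uses the **copies exiting a species node** convention:
the number of gene lineages present in that ancestral genome *after*
the duplications mapped to it. This convention reproduces the
internally consistent figure-caption dosages of the packaged fixtures
(HKT = 1 and TPK = 2 at the embryophyte root; *Shaker* = 1 there and 2
at the tracheophyte ancestor, with the K_in copy lost on the
*S. moellendorffii* edge). The reported HAK narrative (two copies at
the embryophyte root alongside at least three pre-tracheophyte
duplications) is not reproducible as a single number under any
parsimony-consistent reading of the stated group memberships — the
packaged HAK fixture reconciles to six exiting copies at the root
because Groups I and IV contain *P. patens* anchors — so the HAK dosage
is surfaced in reports but not asserted as a fixed value.

Fixture gene trees encode only what the reported group structures
state: group memberships where named (SmORK, SKOR and GORK in the K_out
group; the Group I/II/IV HAK anchors; Groups V/VI as *P. patens*-only;
KCO3 sister to TPK2), species-tree-shaped resolution within groups,
same-species loci as species-internal ladders, and the stated group
joins. Memberships not stated anywhere (the TPK two-group split, the
remaining HAK allocations) are deterministic reconstructions and are
marked as such here.

## The synthetic-data generator

The generator stands in for the five proteome releases, which are not
redistributable. Defaults (`simulationConfig()`):

| parameter | default | meaning |
|---|---|---|
| `speciesTree` | packaged 5-species tree, unit branch lengths | lineage scaffold |
| `dupRate` | 0.1 /copy/unit | birth rate of the gene birth–death process |
| `lossRate` | 0.05 /copy/unit | death rate (extinct families are redrawn) |
| `substRate` | 0.05 /site/unit | per-site substitution probability scale |
| `decoysPerSpecies` | 8 | uniform-random decoys, lengths matched to templates |
| `nearMissFraction` | 0.25 | decoys built as broken template copies |

At `substRate = 0.05` and unit branches, within-family identity ranges
from roughly 90% between sisters to about 75–80% across the deepest
splits — far above the 20% curation threshold, while different families
remain at random-background similarity. Family templates are fixed,
deterministically generated proteins with the class motifs planted at
fixed offsets; during evolution, restricted motif positions mutate only
within their allowed sets, so the motif signature is enforced rather
than emergent — this guarantees a well-defined truth set for the
screening stage. Template backgrounds are scrubbed so no window outside
a planted pore span is within two restricted-position substitutions of
the selectivity filter, keeping pore counts stable under drift.
Near-miss decoys are template copies broken at one restricted position
per motif instance of a minimal rule-defeating set (for HAK, where no
single break defeats the ≥3-of-5 rule, three instances are broken).

All randomness derives from one master seed through named substreams
(a 131-polynomial string hash modulo a 31-bit prime), so each stage is
independently reproducible and substream seeds stay within R's integer
range.

What the simulator does **not** emulate: indels (alignments of
simulated families are gap-free by construction), rate heterogeneity
and realistic substitution matrices (replacement is uniform over the 19
alternatives), genome-scale decoy counts, split or partial gene models,
and contamination. Passing the recovery tests therefore demonstrates
the pipeline's logic and bookkeeping, not its performance on real
proteome releases.

## Verification strategy and problem sizes

The test suite checks each stage against an independent oracle: the
motif scanner against a window-by-window check (1000 random 200-residue
proteins), the block filter against a separate step-by-step
implementation (200 random toy alignments), pairwise scores against
exhaustive alignment enumeration at tiny lengths, NJ/UPGMA against 200
random additive/ultrametric instances each, and DL reconciliation
against the minimum over all consistent mappings for every gene-tree
shape with up to 5 leaves over a 3-species tree. End-to-end recovery
runs 50 simulated proteome sets (four families plus decoys, ~60
proteins each) for membership precision/recall, and 50 replicates of
species-specific-duplication simulation for event recovery; the
duplication-recovery check reconciles the simulator's own (unrooted)
gene tree, since a duplication drawn arbitrarily close to a speciation
leaves too little sequence signal for any tree inference to place —
sequence-level power is what the membership run measures. Simulator
calibration compares the mean leaf copy number under duplication-only
growth with the birth-process expectation e^{λt} over 2000 replicates.
These sizes keep a full run in a few minutes on a single core while
exercising every code path.

## Known limitations

* The curation score is a reconstruction of an undocumented quantity;
  absolute threshold semantics (the "<20" cut) therefore differ from
  whatever the original tooling computed internally.
* The progressive aligner is not a general-purpose MSA tool; gapped
  real-world families should be aligned externally.
* Reconciliation assumes binary rooted species trees and pure
  duplication–loss histories (no transfers, no bootstrap-weighted
  rearrangement).
* Fixture gene trees are topological reconstructions of the reported
  group structures, not the original trees themselves; quantities that
  depend on unstated within-group resolution should be read
  accordingly.
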