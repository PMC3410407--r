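# ktfam

Genome-wide inventories of plant potassium (K⁺) transporter and channel
families, as a tested, reusable R pipeline.

Land plants rely on a small set of gene families for K⁺ uptake and
redistribution: HAK/KT/KUP transporters (~12 transmembrane segments),
HKT Na⁺/K⁺ transporters (fourfold TM-P-TM architecture), tandem-pore
(TPK) channels (two pore loops per subunit), voltage-gated *Shaker*-like
channels (5TM-P-TM, one pore), and BK-like channels outside the flowering
plants. `ktfam` reconstructs the comparative-genomics workflow used to
inventory these families across *Arabidopsis thaliana*, *Oryza sativa*,
*Populus trichocarpa*, *Physcomitrella patens* and *Selaginella
moellendorffii*:

1. **Degenerate motif screening** — ten class-specific consensus motifs
   (e.g. the K⁺ channel selectivity-filter region
   `[S,T]-x-x-T-x-G-[Y,F,L]-G-[D,E]`) are compiled from their printed
   dialect and matched position-by-position against whole proteomes;
   family calls follow configurable co-occurrence rules, with channel
   subtypes derived from the count of non-overlapping pore motifs.
2. **Semi-automatic curation** — candidates shorter than 70% of the mean
   outermost-motif span of reference transporters are discarded; the
   remaining *n* sequences are scored all-vs-all (percent identity over
   the shorter sequence from an optimal BLOSUM62 global alignment, gap
   open 10 / extend 0.5); pairs scoring <20 or exactly 100 (identical
   sequences) are removed; the surviving edges fragment the candidates
   into groups and the group most similar to the references is selected.
3. **Six-frame G-Y-G scan** — an exhaustiveness probe that translates
   genomic DNA in all six frames and reports every selectivity-filter
   tripeptide inside stop-to-stop ORFs, with coordinates and a context
   window for human review.
4. **Alignment and block filtering** — a progressive aligner (UPGMA guide
   tree, profile merging) followed by a conserved-block filter: a column
   is conserved when its majority symbol reaches half the sequences, runs
   of >20 non-conserved columns are removed, blocks shorter than 2 are
   dropped, and gaps are not treated differently.
5. **Distance phylogenetics** — UPGMA and neighbor-joining on identity
   distances, with seeded bootstrap support; externally inferred trees
   can be supplied as newick.
6. **Duplication–loss reconciliation** — gene trees are rooted by
   duplication+loss parsimony and mapped onto the five-species tree
   `(Ppatens,(Smoellendorffii,(Osativa,(Athaliana,Ptrichocarpa))))` by
   LCA reconciliation; the package reports duplications, losses placed on
   species edges, and ancestral copy numbers under the "copies exiting a
   species node" convention.

Because the original proteome releases are not redistributable, the
package ships (a) the reported inventory tables as plain-text fixtures
and (b) a birth–death **simulator** that evolves motif-bearing families
along the species tree and emits per-species proteomes with decoys and
full ground truth, so every stage is testable offline.

## Worked example

```r
library(ktfam)

lib <- motifLibrary()
renderMotif(lib[[1]])
#> [1] "[S,T]-x-x-T-x-G-[Y,F,L]-G-[D,E]"
scanMotif("TMTTVGYGD", lib[[1]], proteinId = "demo")
#>   protein_id motif_id start end   matched
#> 1       demo        1     0   9 TMTTVGYGD
```

A synthetic screen end to end — simulate proteomes (four families plus
decoys), then scan, classify, curate and reconcile:

```r
cfg <- simulationConfig(seed = 42)
em  <- emitProteomes(cfg)
scr <- runScreen(em$proteomes, speciesTree = speciesTreeFixture())
head(scr$inventory, 5)
#>           species family                  locus                   name      via
#> 1       Athaliana    HAK       Athaliana|HAK|g4       Athaliana|HAK|g4 selected
#> 2         Osativa    HAK         Osativa|HAK|g3         Osativa|HAK|g3 selected
#> 3         Ppatens    HAK         Ppatens|HAK|g1         Ppatens|HAK|g1 selected
#> 4    Ptrichocarpa    HAK    Ptrichocarpa|HAK|g5    Ptrichocarpa|HAK|g5 selected
#> 5 Smoellendorffii    HAK Smoellendorffii|HAK|g2 Smoellendorffii|HAK|g2 selected
table(scr$inventory$family)
#>    HAK    HKT SHAKER    TPK
#>      5      2      5      3
```

Every locus above is a true simulated family member (`em$truth` carries
the ground truth for checking). Reconciling the packaged TPK ortholog
structure against the species tree recovers the ancestral dosage of the
family:

```r
fx  <- buildFixtureGeneTree("TPK")
rec <- reconcileTrees(fx$tree, speciesTreeFixture(), fx$leafMap)
rec
#> ReconciliationResult: 26 gene leaves on 5 species; D = 17, L = 0
ancestralCopies(rec, "Embryophyta")
#> [1] 2
```

i.e. the last common ancestor of land plants already carried two genes
for TPK channel subunits; the seventeen duplications are the
lineage-specific amplifications of the two ortholog groups.

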