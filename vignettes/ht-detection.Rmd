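---
title: "Detecting horizontal transfer of LINE retrotransposons: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting horizontal transfer of LINE retrotransposons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`htscan` detects horizontal transfer (HT) of LINE retrotransposons between
divergent lineages. This vignette is the package's own account of the
science: the models behind each stage, the parameters that matter and their
defaults, what the simulator does and does not emulate, the numerical
choices, and the places where the design was genuinely open.

## 1. The simulator: what the ground truth is

The generator (`generate_species_tree()`, `sim_config()`, `evolve()`,
`fragment()`) evolves a single TE family along an ultrametric Yule species
tree whose branch lengths are expected substitutions per site.

* **Master element.** `canonical_te()` is a deterministic, synthetic
  3 200-bp LINE-like element: a 150-bp 5'UTR, one 901-codon ORF whose
  translation embeds a fixed 220-aa reverse-transcriptase-like region, and a
  3'UTR. It is built from a fixed internal seed, not from any curated
  consensus; the matching PSSM seed alignment (`rt_seed_alignment()`) is
  likewise synthetic.
* **Substitutions.** Copies accumulate K2P substitutions continuously:
  Poisson-many events per unit branch length, each a transition with
  probability $\kappa/(\kappa+2)$ (default $\kappa = 2$), sites drawn with
  replacement. This is exactly the K80 jump process, so the downstream K2P
  estimator is consistent for the simulated branch lengths.
* **Amplification.** Active copies replicate at `amplification_rate`
  (default 2 per active copy per unit branch length) in a Gillespie birth
  process; a daughter is dead on arrival with `inactivation_prob`
  (default 0.2), and inactivation is permanent — only active copies
  replicate, mirroring families that go extinct in a lineage.
* **Transfers.** HT events are explicit, user-specified plantings (the
  literature offers no quantitative HT rate to simulate from): at a chosen
  time on the recipient branch, a random active copy of the donor lineage is
  snapshotted and seeded into the recipient (`n_copies` founders, default 2).
  Donor and recipient species sets are kept disjoint, because a species
  acting as both within one run would interleave transfer histories within a
  branch, which the edge-atomic simulation rejects.
* **Decay.** `fragment()` applies segmental deletions, Poisson per copy in
  its age, sizes uniform on 31 bp–10 kb (the reported range for
  TE-removing deletions), clipped to the copy; a copy below
  `min_intact_length` (2 kb, the intactness cut-off used for centroid
  selection) is marked non-intact.
* **Placement.** Copies land on random strands at random non-adjacent
  positions (spacing > 1 200 bp so 1-kb flanks never include a neighbouring
  copy) in an i.i.d.-uniform background genome (default 200 kb). A uniform
  background is deliberately the simplest non-homologous context for the
  flank-contrast test.

The default study conditions are 12 species at tree height 0.4
substitutions/site, split into two "classes" at the root bipartition, with
two planted cross-class transfers at 0.9 of the recipient branches. Height
0.4 makes the deepest copies roughly 35–45 % diverged from the master —
far enough that cross-class vertical identity (~0.57) sits near the
clustering floor, close enough that a single nucleotide searcher still
recovers every copy. Genome size, copy numbers (~4–15 per species) and the
event times were chosen once as a realistic, desk-scale caricature of a
deeply diverged family with recent transfers, and are not revisited.

**What the simulator does not emulate:** real repeat landscapes (nested,
overlapping, truncated insertions; tandem repeats; GC/CpG structure),
micro-indels within copies, selection on active copies, recombination, and
assembly error. Passing tests therefore demonstrate correctness of the
*method* under its stated model, not performance on real genomes — in
particular, the flank test is easier here than in real data, where
low-complexity flanks can align spuriously.

## 2. The identity kernel

All thresholds in the pipeline refer to one definition: **identity =
matches / alignment columns, counting internal gaps, excluding terminal
gaps**, over an affine-gap, end-gap-free *fit* alignment (match +2,
mismatch −3, gap open −5, gap extend −2) in which the shorter sequence is
consumed in full and only the longer sequence's overhangs are free. Ties in
length are broken by string order, making the kernel exactly symmetric.

Fit semantics matter: a fully free overlap (dovetail) alignment lets two
unrelated 3-kb sequences align over a 3-column corner at "identity 1.0",
which would make any greedy threshold meaningless. Under the fit kernel the
mapping from divergence to identity is monotone (0.95 at 5 % divergence,
0.83 at 20 %, 0.71 at 40 %, 0.57 at 80 %), with a measured background of
about 0.52 for unrelated 1-kb sequences. Note that 0.52 is far above the
0.25 per-base match probability: optimised gap placement always inflates
the background, which is why the flank threshold (below) sits at 0.6 rather
than near 0.25.

**Distances are a different regime.** The same gap-friendliness that makes
a good identity kernel biases distance estimation: optimised gaps absorb
mismatch columns, which the K2P estimator then excludes, so a pair at true
distance 0.8 can measure 0.43. Distance-critical quantities therefore use
`distance_scoring()` (gap open −20, extend −0.5): gaps model rare segmental
deletions — the only indels the family actually suffers — and the same pair
measures 0.76. `pair_k2p()` packages this. MSA-projected distances are kept
where only relative structure matters (NJ topology, the support-score
denominator), since both sides of those comparisons carry the same bias.

## 3. Mining

`seed_extend_search()` uses exact 11-mer seeds on both strands with x-drop
(50) ungapped extension and per-diagonal coverage masking;
`merge_hits()` chains same-strand hits within 500 bp, giving loci whose
identity is the alignment-length-weighted mean. With copies diverged ≤ 40 %
from the query, multiple surviving seeds per copy make recovery robust:
recall is 1.0 on the study conditions and the ungapped identity estimate
stays within 0.02 of a full-DP oracle (there are no micro-indels to miss).
Minimum hit length 100 bp suppresses random-background seeds.
`rbh_classify()` labels each locus by its best library alignment
(`min_identity` 0.6, above the ~0.52 unrelated background and below the
~0.7 identity of the deepest genuine copies) and flags disagreements with
the mining query's family. Chimeric loci — one element inserted into
another, splitting the host into two same-family loci sandwiching the
insert — are reported by `detect_chimeras()` with the nesting order.

## 4. Representatives, ORFs, RT domains

`select_centroid()` takes the longest intact copy within 2–4 kb;
`build_consensus()` clusters at 70–90 % identity and takes a majority-rule
column consensus (gap-majority columns dropped, ties to the first-seen
member), flagging consensus sequences 1.2× longer than the median member —
the stitched-fragment artefact that makes consensus approaches unreliable
for degraded families. "Intact" is operationalised as *length within the
family bounds and at least one ORF of ≥ 200 aa* (the criterion is not fully
standardised in the field; it is recorded in the configuration). ORF
finding runs on all six frames and, by default, allows non-standard starts
(any stop-free stretch counts, as with `-orfstyle 7`-style scanning). RT
domains are maximal-scoring ungapped envelopes of a log2-odds PSSM
(pseudocount 1, uniform background), threshold 120 bits and minimum length
200 aa — shuffled-sequence nulls top out around 20–40 bits while a true
domain scores several hundred, so the threshold is not delicate.

## 5. Clustering

The greedy centroid engine (`greedy_centroid_cluster()`) processes
sequences in length-descending order (ties by id) and assigns each to the
first centroid at ≥ threshold, else it founds a new cluster — deterministic,
and every member provably ≥ threshold to its centroid. The single-linkage
engine (`single_linkage_cluster()`) joins any pair with a local alignment at
≥ threshold identity covering ≥ 0.5 of the shorter sequence (union–find
components; the overlap floor stops fragment chaining). Single linkage
chains everything a path connects — good for recent transfers, but it
collapses degraded families; the centroid engine keeps them apart, which is
why the analysis default is greedy at 0.55 (cluster ids are prefixed `c_`,
`o_`, `r_` for nucleotide, ORF and RT-domain inputs respectively). An
optional shared-k-mer prefilter is off by default: at 50 % identity,
related sequences can share no 8-mer, so the shortcut is only safe above
~0.7.

## 6. HT validation

Clusters whose members span two classes produce candidate pairs, and four
verdicts gate confirmation:

* **Candidate pairs** are copy-level mutual-best cross-class partners, one
  per species pair. An echo-merging step then treats two pairs sharing a
  species as one event when the shared species' copies form one cohort
  (mutual K2P ≤ 2× the pair transfer distances): a single transfer whose
  founders split their nearest-neighbour votes between the true donor and
  its sister species otherwise yields a duplicate pair, while two genuine
  transfers into one recipient keep cohorts ~0.8 apart and survive.
* **Flank contrast** (`flank_contrast_test()`): both 1-kb flank-to-flank
  identities must stay ≤ 0.6 (`flank_max`; background ≈ 0.52, contamination
  ≈ 1.0). Flank identity that is both above 0.6 *and* within 0.1 (`margin`)
  of the TE identity demotes the pair to `likely_contamination` — the
  whole-region-copied signature. Truncated flanks (scaffold edge) demote to
  `likely_artefact`: short-scaffold candidates cannot be validated.
* **Reciprocal best hit** (`rbh_confirm()`): each copy's best alignment in
  the partner species' full copy set must fall inside the candidate cluster.
* **Discordance** (`score_ht_support()`): (i) in the NJ tree of the cluster
  the pair must group together to the exclusion of every copy from *other*
  same-class species that are species-tree closer than the partner (the
  donor's own conspecific copies legitimately surround a transferred
  lineage and do not count); and (ii) the pair's direct K2P distance must
  be < 0.75 × the species-tree divergence (`discordance_margin`).
  Condition (ii) carries most of the weight: vertically inherited copies in
  two species are *at least* as divergent as the species (deep TE lineage
  sorting only adds distance), so only a transferred copy can sit well
  below that bound; the 25 % margin covers K2P estimation noise at 3-kb
  copies. Condition (i) alone is unreliable precisely because of that
  lineage sorting — the TE gene tree disagrees with the species tree even
  under pure vertical descent.
* **Support score**: pair K2P over the median within-class K2P of the older
  clade (the class with the larger internal median; if neither class has
  two members, the species divergence substitutes). Confirmation requires
  support < 1 — recent transfers score ~0.03–0.06, vertical pairs ~0.7–1.5.
  The score is deliberately reported even when it cannot confirm (< 4
  cluster members leave the tree test undefined and the candidate
  unconfirmable).

Status mapping: contamination signature → `likely_contamination`; truncated
scaffold → `likely_artefact`; all verdicts plus support < 1 → `confirmed`;
anything else → `rejected`.

## 7. Trees, blocks, landscapes

K2P distances exclude gap/N columns and raise an error at the model's
domain edge (`1−2P−Q ≤ 0` or `1−2Q ≤ 0`) rather than returning infinity;
the bootstrap, which resamples columns and can saturate a replicate even
when the original alignment does not, caps saturated distances at 3
instead. The progressive MSA aligns frequency profiles along an
8-mer-distance UPGMA guide tree (soft scores: match +2, mismatch −1, gap
−2.5; determinism given input order). Conserved-block extraction keeps
maximal runs of ≥ 5 columns whose majority character reaches 0.5, with gaps
allowed — only the two block parameters with stated values are honoured;
the full original block-filtering tool has many more. Neighbour joining is
delegated to the standard implementation with negative branch lengths
clamped to zero (deficit moved to the sibling); bootstrap support is the
fraction of replicate NJ trees containing each bipartition (1000 replicates
in analyses, fewer in tests). Maximum-likelihood trees are out of scope; NJ
with bootstrap is the implemented arm. Landscapes bin each copy's length by
its K2P distance to the family reference in 1 % steps, excluding copies
with < 50 % of their length aligned; plain K2P is used (no CpG adjustment,
which some repeat-annotation tools apply).

## 8. Problem sizes and determinism

Analyses and tests run at: 12 species × 200-kb genomes (~50–90 copies of a
3.2-kb element), clusters of ≤ ~90 members, 100-tree NJ exactness checks,
50-instance clustering oracles, 20-seed property checks, and 10 clean
(no-transfer) end-to-end replicates. One end-to-end run takes ~30 s on one
CPU. Every stochastic step draws from a seed recorded in the configuration;
reruns are bit-identical, and the pipeline writes each stage's outputs
before the next stage reads them.

## 9. Known limitations

* The searcher is nucleotide-only; truly ancient homology that only
  protein-space search would find (the role a conserved-domain search plays
  at larger scale) is represented by the RT-domain PSSM stage instead.
* The discordance bound `K2P < 0.75 × d_species` assumes a roughly
  clock-like species tree in substitution units; strong rate variation
  across lineages would erode the vertical lower bound it relies on.
* Landscapes date amplification relative to the family consensus and are
  blind to transfer per se (a transferred lineage is as old as its family);
  they complement, not replace, the cross-species tests.
* The contamination verdict models verbatim region copying; subtler
  cross-contamination (chimeric reads, index hopping) has no analogue here.
* With fewer than four cluster members the tree test is undefined and a
  true transfer cannot be confirmed — a deliberate conservative choice.
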