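---
title: "Annotating and comparing protease repertoires with degradomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating and comparing protease repertoires with degradomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degradomics)
```

## The problem

The degradome — the complete repertoire of protease and protease-like genes
of a genome — is small enough (hundreds of genes) to curate by hand, yet
diverse enough in sequence and genomic organization to defeat any single
automated gene finder. The classic way to characterize the degradome of a
newly sequenced genome is homology transfer from a curated seed set: every
curated protease protein is compared against the genome with a translated
search, hits are assembled into gene models, novel predictions re-enter the
query set, and the resulting per-species gene inventories are compared
across species as a presence/absence/duplication matrix, with phylogenetic
trees resolving families where pairwise orthology is ambiguous.

`degradomics` implements this whole loop as tested, deterministic code, and
pairs it with a synthetic-genome forge so that every stage can be validated
against an exact truth table — something impossible with a real genome,
where the true gene complement is exactly what is unknown.

## Pipeline stages and their models

### Translated search

The search is a classical seeded, gapped translated alignment:

* **Six-frame translation.** Frames `+0,+1,+2` read the forward strand at
  offsets 0–2; `-0,-1,-2` read the reverse complement. Stop codons are kept
  as `*`; codons containing `N` become `X` (scoring 0 against everything,
  so unsequenced stretches neither attract nor repel alignments). Each
  frame carries an exact linear map from protein index back to its
  forward-strand nucleotide span.
* **Seeding.** All length-`k` word pairs (default `k = 4`) with BLOSUM62
  word score at least 13 are seeds. Seeds are found by enumerating the
  neighborhood of every query word once (branch-and-bound over the residue
  alphabet) and looking words up in a hash index of the frame — the same
  design BLAST uses, without the two-hit refinement, which desk-scale
  genomes do not need.
* **Two-stage extension.** A seed must first survive an ungapped X-drop
  extension to a trigger score (default 30) before the gapped extension
  runs — otherwise chance word hits near a real gene nucleate junk HSPs
  whose spans confuse downstream exon chaining. Gapped extension is an
  affine X-drop dynamic program (BLOSUM62, gap open 11, extend 1, X-drop
  20) run in both directions from the seed; a stop codon in the frame is a
  hard barrier. The returned HSP is then trimmed to its maximal-scoring
  run of alignment columns, which removes low-scoring heads and tails that
  X-drop alone tolerates (an extension may wander a short distance past a
  splice site before losing 20 points).
* **Significance.** E-values follow the Karlin–Altschul form
  `E = K·m·n·exp(-λS)` with the standard gapped BLOSUM62/11/1 parameters
  `λ = 0.267`, `K = 0.041`, `m` the query length and `n` the total
  translated length searched. This model is a *conservative ranking
  device, not a calibrated null*: because stop codons bound every
  extension, the attainable alignments live inside stop-free frame
  segments (mean ≈ 21 residues in uniform random DNA), and the short,
  nearly ungapped alignments that remain follow ungapped-like score
  statistics (effective λ ≈ 0.3–0.4 measured on shuffled queries). Both
  effects push observed chance-hit counts roughly an order of magnitude
  *below* the `K·m·n·e^(−λS)` prediction with the textbook gapped
  parameters — reported E-values overstate the false-positive risk, never
  understate it. The shuffled-query calibration test in the suite
  measures exactly this and is expected to flag the discrepancy; the bias
  is documented rather than reparameterized away, since the stated
  defaults are part of the search's contract.

All thresholds are config keys (`search_config()`). They are BLAST-like
defaults chosen a priori, not fitted values.

### Annotate, tune, iterate

* **Clustering.** HSPs sharing a contig and strand whose genomic gaps are
  at most `max_intron` (default 5 kb, matched to the forge's intron plan;
  real vertebrate work would raise it) are single-linkage clustered into
  loci.
* **Chaining.** Within a locus, the maximum-score chain of HSPs colinear
  in both query and genome is found by dynamic programming. Query and/or
  genome overlaps between consecutive HSPs — the footprint of extension
  overshoot at splice junctions — are resolved by trimming residues from
  whichever side of the junction aligns worse, at a penalty of 4 per
  trimmed residue, up to 25 residues; larger conflicts make the pair
  incompatible. An implied intron longer than `max_intron` also blocks a
  transition, which is what prevents chimeric chains stitched across two
  tandem gene copies. The 25-residue allowance is deliberately wider than
  the few residues a clean junction needs: measured overshoot on forged
  genomes regularly reaches 15–20 residues, and a tighter limit silently
  drops whole exons from chains.
* **Multiple genes per locus.** After the best chain is extracted, the
  remaining HSPs (those not overlapping the chained exons) are chained
  again; secondary chains are kept while they reach at least half the
  primary chain score. This is how two tandem copies closer than
  `max_intron` both surface.
* **Tuning.** Each internal exon junction is shifted by up to 15 nt to the
  nearest boundary pair giving a GT…AG intron on the coding strand while
  preserving reading frame (the two shifts congruent mod 3, intron at
  least 20 nt); junctions with no qualifying shift stay put. Candidate
  shifts are ordered by total displacement, so an already-canonical
  junction is a fixed point.
* **Iteration.** All intact predicted proteins (family label inherited
  from the best-scoring query) re-enter the query set and the whole round
  repeats, until no new locus appears or `max_iterations` (default 10;
  convergence on forged data is 2–3 rounds). Overlapping models are
  deduplicated at 50% reciprocal overlap, keeping the higher chain score
  and the earliest discovery round.
* **Linked-HSP rescue.** A short internal exon rarely reaches genome-wide
  significance on its own, so the annotation layer searches at a looser
  E-value (default 0.5) and keeps weak HSPs only when the same query
  already has a strictly significant hit (default `1e-4`) within
  `max_intron` on the same contig and strand — the sum-statistics idea
  behind translated-search exon linking. Pure background therefore stays
  clean: with no significant anchor, nothing is rescued.

### Orthology and the family-status matrix

Cross-species orthology is by reciprocal best hit (RBH) under global
affine-gap alignment (BLOSUM62, 11/1, end gaps charged). A pair is called
only when each member is the other's *unique* best scorer by more than
`margin` (default 0 — strictly greater); exact ties fall into the
conservative `no_clear_orthologue` bucket, which is where large complex
families land. Same-family models on one contig within 1 Mb form tandem
groups; copies further apart or on other contigs are dispersed. Family
status is a pure function of copy counts: 0 → `absent` (or `not_found`
when the expected region's assembly-gap fraction exceeds 20%, the
mechanical form of "the contig where this gene should sit is rich in
unsequenced stretches"), 1 → `present`, 2 → `duplicated`, 3 →
`triplicated`, ≥4 → `expanded`, and any copies but none intact →
`pseudogene_only`. A non-peptidase homolog counts as a gene copy — a
catalytically dead gene is still a gene.

### Catalytic-residue classification

Each model's protein is globally aligned to its family seed; the residues
aligned to the seed's catalytic positions (His/Asp/Ser triad for serine
proteases, His/Cys dyad for cysteine, two Asp for aspartyl, three
zinc-binding residues for metallo) are read off. One substituted or
deleted catalytic residue already abolishes the canonical mechanism, so
the non-peptidase-homolog threshold is ≥ 1 — requiring all residues to be
lost would miss genes that died by a single active-site substitution.
Conservative substitutions (e.g. Ser→Thr) are *not* excused by default;
a `tolerated` argument exists for users who disagree.

### Phylogenetics

For families that are multi-copy anywhere or contain no-clear-orthologue
genes, the pipeline builds a bootstrap consensus tree:

* **Progressive alignment** — neighbor-joining guide tree on normalized
  pairwise alignment-score distances, midpoint-rooted, profiles merged by
  global affine profile–profile alignment. Deterministic: taxa are
  processed in lexicographic order, so input order is irrelevant.
* **Bootstrap** — 100 column resamples (seeded).
* **Parsimony** — plain Fitch on amino-acid states, gaps and ambiguity
  codes as missing data (wildcard). Genetic-code-aware transition
  constraints are intentionally not modeled; uniform-cost Fitch is the
  standard, oracle-checkable baseline. Scoring is exact for binary trees
  including the usual basal trifurcation of unrooted trees (sequential
  folding there equals rooting on the third child's edge).
* **Search** — exhaustive over all unrooted topologies up to 8 taxa
  (10 395 trees), returning *all* minimum-score trees; beyond that,
  deterministic stepwise addition from three fixed taxon orders followed
  by NNI hill-climbing, keeping the best. On forged 7-taxon families the
  heuristic matches the exhaustive optimum in ≥ 95% of replicates.
* **Consensus** — a bipartition is displayed only when present in
  *strictly more than* `threshold` replicates (the pipeline default is 50
  of 100). A replicate that produced several equally parsimonious trees
  contributes each of its bipartitions at weight 1/(number of trees), so
  no replicate counts twice. Thresholds below half the replicates can
  select mutually incompatible splits; that case errors rather than
  silently resolving.
* **Rooting** — on the edge separating a designated outgroup (checked for
  monophyly; the failure message names a violating bipartition). Edge
  supports survive rerooting. In the pipeline the family seed itself is
  the outgroup taxon: it is ancestral to every implanted copy, and a
  single-taxon outgroup is always monophyletic.

## The forge: what the synthetic data does and does not emulate

`forge_genome()` implants back-translated, diverged copies of seed
proteins into i.i.d. uniform random intergenic background.

* **Coordinates** are 0-based half-open everywhere in memory; minus-strand
  exon spans are forward-strand coordinates and splicing happens on the
  reverse complement. Only GFF3 and the BLAST-style tabular file use
  1-based inclusive coordinates, as those formats require.
* **Divergence is hierarchical.** Each species first draws a
  species-level variant of the seed (two thirds of the configured
  divergence), and each copy diverges further from that variant (one
  third), so the expected per-copy divergence from the seed matches the
  configured value while within-species duplicates remain each other's
  closest relatives. A flat per-copy divergence would make copies
  conditionally independent given the seed and erase the duplication
  history a gene tree is supposed to recover. Substitutions only — no
  indels — so catalytic-position bookkeeping stays exact; consequently
  forged families align without gaps, and gap handling is exercised by
  dedicated unit tests rather than by the forge.
* **Gene structure.** Codon-aligned exon boundaries (keeping each exon's
  translation in one reading frame, the geometry a chained HSP model
  reconstructs), introns of 120–240 nt with GT…AG termini, minimum exon
  75 nt. The lower intron bound matters: an in-frame intron much shorter
  than ~40 codons has a realistic chance of translating stop-free and
  surviving the X-drop, letting one HSP bridge two exons. Intergenic
  spacers are 5.5–9 kb — strictly more than `max_intron` — so tandem
  neighbors can never be stitched into one chimeric chain.
* **Events.** Tandem copies share a contig; dispersed copies get one
  contig each; knockouts either substitute every catalytic residue
  (→ non-peptidase homolog) or write a TAA mid-exon at back-translation
  (→ pseudogene fragment).
* **Not emulated:** realistic codon usage, GC structure, repeats, indel
  divergence, split codons at exon boundaries, alternative splicing,
  pseudogene decay beyond a single lesion. Passing tests on forged
  genomes therefore demonstrate the pipeline's bookkeeping and its
  behavior under substitution divergence — not performance on repeat-rich
  or indel-divergent real assemblies.

The divergence level used in the bundled demonstration (0.15) and the
sizes (three species, twelve families, 160–210-residue proteins) were
chosen once as a regime where homology transfer plainly ought to work —
roughly the protein identity of diverged vertebrate orthologs — while
keeping a full three-species run on one CPU in minutes. Divergence levels
among real species-specific expansions are unknown; the forge default
favors recoverability over realism, and the recovery sweep in the
evaluation functions shows recall degrading monotonically as divergence
rises.

## Numerical and degenerate-input choices

* Ties everywhere break deterministically (lexicographic ids, first
  index): two runs of one config are byte-identical, which the test suite
  asserts on the emitted GFF3/TSV/Newick files.
* An empty genome yields six empty frames; an empty HSP set yields an
  empty, correctly-typed table; a single-HSP locus is a one-exon model
  with chain score equal to the HSP score.
* `sample()`-style scalar pitfalls are fenced behind a range helper so a
  degenerate (min = max) length range stays fixed instead of exploding
  into `1:n`.
* Fitch masks are 20-bit integers; anything outside the 20 standard
  residues is the full wildcard mask.
* The E-value model is used as a ranking and calibration device, not an
  exact reproduction of BLAST statistics (no composition-based
  adjustment, no length correction); the package documents this as a
  known bias rather than hiding it.

## Known limitations

* Start codons, UTRs and frameshift-tolerant alignment are out of scope;
  models begin and end where homology does.
* Tandem copies closer than `max_intron` with *small* intergenic gaps can
  in principle still yield one chimeric chain when the implied intron is
  shorter than `max_intron`; the forge's spacing avoids the regime, and
  real-data users should tighten `max_intron` or inspect the composite
  (bgmix) report, whose unmodelled-HSP flag is the review surface for
  exactly this.
* The consensus builder rejects threshold settings below half the
  replicates when retained splits conflict, rather than implementing a
  greedy majority-rule-extended resolution.
* Heuristic tree search is a local optimizer; on 10+-taxon families
  bootstrap supports can be mildly conservative when replicates stop in
  different local optima.

## A worked micro-example

```{r example, eval = FALSE}
cfg <- demo_config(seed = 1)          # 3 species x 12 families, divergence 0.15
run <- run_pipeline(cfg, outdir = "demo_out")
glance(run)                            # one-row run summary
tidy(run)                              # long family x species status table
autoplot(run)                          # status-matrix tile plot
compare_to_truth(run)$status_exact_rate
```

The demonstration plan encodes the comparative patterns the status
vocabulary exists for: a family tandem-duplicated in one species only, a
seven-copy dispersed expansion containing one catalytic knockout, a
family triplicated in two species but single elsewhere, and two families
absent from two species. `compare_to_truth()` scores the run against the
forge's truth table; the acceptance script under `scripts/` reruns this
end-to-end and writes the headline numbers as JSON.
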