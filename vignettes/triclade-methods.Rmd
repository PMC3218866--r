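---
title: "Comparative genomics of a three-species clade: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative genomics of a three-species clade: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`triclade` re-implements, as a tested and reusable pipeline, the
comparative-genomics inference chain used to characterize small fungal
clades: orthology and paralog-family detection, synteny-block construction
with enrichment tests on non-syntenic regions, repeat-induced point
mutation (RIP) dinucleotide indices on repeat families, Nei–Gojobori
Ka/Ks, and codon-usage/CAI checks. Because the interesting claims in such
an analysis (ortholog counts, non-syntenic islands, RIP verdicts, rate
asymmetries) are statements about unobservable evolutionary history, the
package ships a first-class simulator that generates a three-species clade
with complete ground truth, so that every stage can be validated against a
known answer rather than against another tool's output.

## The data model

A genome is a `genome_annotation`: named scaffold sequences plus ordered,
stranded, non-overlapping gene models carrying their CDS and protein.
Internally all coordinates are 0-based half-open; GFF3 input/output
converts to the 1-based inclusive convention at the boundary. One
CDS/protein per gene (no isoforms): pipelines of this kind run on a single
representative model per locus. Gene order within a scaffold is defined by
start coordinate regardless of strand, giving synteny one canonical order
to anchor on.

## The simulator and its assumptions

`simulate_clade()` evolves an ancestral genome down the topology
((B,C),A): A splits first and branch C is the fast, loss-heavy lineage.
Per branch, in a fixed order (substitutions, losses, duplications,
inversions, TE insertions, RIP), the genome is modified at the segment
level so coordinates and intergenic sequence stay consistent. Everything
is driven by one seeded RNG stream: identical configs give identical
clades.

Defaults are the conditions the package is validated under, chosen once:

* **300 genes on 3 scaffolds**, genes 80–200 codons — large enough for
  stable medians and Fisher tests, small enough that the full pipeline
  runs in minutes on one CPU.
* **Substitutions.** Each gene receives Poisson numbers of synonymous and
  nonsynonymous single-base events with expectations `ks·S` and `ka·N`,
  where S and N are the gene's Nei–Gojobori site counts; events pick a
  codon weighted by its current number of eligible variants, then a
  variant uniformly, so repeated hits at a site occur naturally
  (Jukes–Cantor-style). A full codon rate matrix is deliberately not used:
  the only downstream consumer is the NG86 estimator, and this
  construction makes "the estimator recovers the configured rates" a
  meaningful check rather than a shared-model tautology. Branch rates:
  ka/ks = 0.03/0.10 on A, I and B; 0.09/0.30 on C, so that both pairwise
  comparisons against C are elevated (expected pairwise Ks: A–B 0.30,
  B–C 0.40, A–C 0.50) — the fast-derived-lineage pattern.
* **Rearrangement** is small inversions (2–6 genes; 4–10 per branch) with
  breakpoints uniform on gene order, the random-breakage null under which
  small synteny blocks outnumber large ones.
* **Duplications** (10 per branch on A and B, fewer elsewhere) are 30%
  tandem and 70% dispersed into two designated islands per branch. Island
  insertions are anchored on a gene id so members stay contiguous; with
  ~3–4 copies per island they exceed the three-gene break rule and become
  genuine non-syntenic paralog clusters, the structure the enrichment
  analysis is meant to detect. Copies diverge from their source with the
  branch's (ka, ks) at creation — exact clones would produce alignment
  score ties that the RBH tie rule (correctly) discards, which is not how
  real paralogs behave. Duplicates get suffixed ids and are excluded from
  the true-ortholog map.
* **Losses** (2–12 per branch, heaviest on C) make C the gene-poor lineage;
  a consequence worth knowing is that C's own genome ends up almost fully
  syntenic, because the paralog islands that would break its synteny are
  exactly what it lost — the same logic by which a loss-heavy real genome
  shows a low non-syntenic fraction.
* **Transposable elements and RIP.** Two ancestral families of 800 bp, four
  copies each, plus 2–3 fresh insertions per branch, all padded with
  intergenic spacer. On every branch each TE copy independently receives 2
  rounds of RIP at p = 0.2 per CpA (and TpG) site, i.e. ~0.36 expected
  hits per site — enough to push family indices decisively across the
  classification thresholds while leaving copies ~93% identical, so they
  remain (barely) detectable by the repeat finder: the same tension the
  real analysis faces with degenerate repeats.
* **Background sequence.** Intergenic spacers and TE consensus sequences
  come from a first-order Markov chain tuned to genome-like dinucleotide
  structure (TA/AT ≈ 0.67, (CA+TG)/(AC+GT) ≈ 1.23). This matters: under
  uniformly random background the composite RIP index sits at 1.0, below
  the 1.03 threshold, and half of all unmutated families would be called
  RIP-positive. A realistic null is what makes the negative control
  meaningful.

What the simulator does **not** emulate: introns and UTRs, isoforms,
whole-chromosome translocations, satellite DNA, GC-content gradients,
assembly gaps, and annotation error. Passing tests therefore demonstrate
the correctness of the inference chain under its stated model, not
robustness of any particular biological conclusion to annotation noise.

## Homology

All-vs-all protein comparison uses Smith–Waterman local alignment with
BLOSUM62 and affine gaps (open 11, extend 1) — BLASTP's scoring defaults —
behind a shared-k-mer prefilter (k = 5 amino acids): pairs with no exact
5-mer in common are never aligned. The prefilter is an approximation; at
the divergences simulated here (protein identity well above 50%) shared
5-mers are effectively guaranteed, and the truth-recovery tests confirm no
pair is lost. Matches below raw score 50 are discarded (configurable; no
E-value model is implemented).

Reciprocal best hits drop a gene entirely when its top score is tied —
an arbitrary tie-break would inject wrong anchors into synteny, and a
missing anchor is cheaper than a wrong one. Three-way orthologs are closed
RBH triangles; this is a deliberate simplification of orthoMCL-style
clustering, and on duplication-free simulations it equals the true
ortholog map exactly. Paralog families come from Markov clustering (MCL)
of the similarity graph: column-normalized adjacency with self-loops at
the maximum incident weight, alternating expansion and inflation
(default 2.0) to convergence (max change < 1e-6 or 100 iterations),
clusters read from attractor rows. Both the MCL and the alignment scorer
are cross-checked in the test suite against independently coded dense
references.

## Synteny

Blocks are greedy chains of ortholog anchors scanned along genome A:
a chain extends while the next anchor (i) stays on the same scaffold
pair, (ii) is the adjacent anchor in genome-B rank order, continuing the
chain's orientation, and (iii) leaves at most `max_gap = 2` unanchored
genes on either genome. Requiring rank adjacency (not just positional
proximity) is what makes a 3-gene inversion split a chain into
same/inverted/same blocks rather than being jumped over. Chains need at
least 3 anchors and anchor density ≥ 0.5 over the spanned genes — the
density definition the literature leaves numeric-free is made explicit
and configurable here.

A gene is syntenic if it is an anchor or lies inside a block span; outside
spans, a maximal run of ≥ 3 consecutive uncovered genes is a break in
synteny and its genes are non-syntenic, while shorter interruptions are
tolerated. In the pipeline each genome is classified against both partner
genomes and a gene is syntenic if covered in at least one comparison, with
the run rule re-applied to the union.

Enrichment uses Fisher's exact test (two-sided headline, one-sided
alternative reported alongside, since the natural null is directional) with
a chi-square companion, Haldane-corrected odds ratios, and a log10
hypergeometric tail so extreme significance is not floored at double
precision. Per-category tests are Benjamini–Hochberg adjusted. The
permutation null (`shuffle_null`) re-runs block construction on uniformly
shuffled gene orders and reports an empirical p of the form
(1 + #{null ≥ obs}) / (n + 1).

## RIP analysis

Dinucleotide counts are overlapping, forward-strand windows (windows
containing non-ACGT letters are skipped and tallied); multi-sequence input
is summed, which is how short degenerate repeat copies are indexed jointly
per family. The two indices are TA/AT and (CA+TG)/(AC+GT), with a
RIP-positive call iff TA/AT > 0.89 and the composite < 1.03; a zero
denominator leaves the verdict indeterminate. Forward-strand counting is
the convention under which those thresholds were derived; the composite is
already strand-symmetrized, and a both-strands mode exists for the
invariance-minded (the TA/AT index is then reverse-complement invariant,
which the tests exercise).

The repeat finder is a deliberately minimal seed-and-extend stand-in for a
production repeat annotator, validated only on synthetic genomes: k-mers
(k = 12) occurring at least twice on either strand are merged (slack 2k)
into candidate intervals ≥ 400 bp, candidates are single-linkage clustered
at ≥ 92% identity using free-end-gap alignment in the better orientation
(with a minimum aligned span), and clusters with ≥ 3 copies are reported.
Two numeric choices deserve note. Seeding on *pairs* rather than on
`min_copies` occurrences: each RIP-divergent site spoils every k-mer
window covering it in all but one copy, so demanding an exact k-mer shared
by three degraded copies empirically collapses recall; the copy-number
criterion is instead enforced at the clustering stage. And k = 12 rather
than a BLAST-like 16: short enough for dense exact seeds across ~93%
identical copies, long enough that chance triple 12-mers (a few dozen per
genome at this scale) remain isolated and can never chain to 400 bp.

Curated-alignment analysis (`curate_family_copies`) keeps the top fraction
of copies by mean pairwise identity — a stand-in for manually selecting
the most recent insertions — and `alignment_ti_tv` reports the
transition/transversion ratio over ungapped column pairs, with an explicit
infinite flag for the all-transition signature RIP leaves.

## Molecular evolution

Ka/Ks is Nei–Gojobori (1986): mutational-fraction site counting (stop
changes count as nonsynonymous opportunity), difference counts averaged
over all shortest pathways with stop-codon pathways excluded (all-pathway
fallback in the no-valid-path corner), Jukes–Cantor correction, and an
explicit saturation flag at p ≥ 3/4 instead of extrapolation. Codon pairs
come from back-translating a global protein alignment and dropping gapped
columns; stop-containing pairs are rejected, not skipped — a stop codon
reaching the estimator means an upstream bug, and silence would hide it.
The per-codon-pair difference counts are precomputed for all 61×61 sense
pairs and memoized; the test suite checks them against a fresh recursive
enumeration.

Rate sets are compared by medians plus the two-tailed Wilcoxon rank-sum
test — exact when the combined sample is ≤ 20 without ties, tie-corrected
normal approximation otherwise. Both per-gene rates and a
concatenated-marker mode (one NG86 over pooled codon alignments of a
marker panel) are available, since genome papers are often ambiguous about
which of the two their medians mean.

CAI follows the classic construction: relative adaptiveness w = codon
frequency over its most frequent synonym (never-observed codons get
0.5/max-count so the log never diverges), gene CAI the log-space geometric
mean excluding ATG, TGG and stops. The region comparison builds w from
syntenic genes and asks whether non-syntenic genes deviate — the test that
distinguishes "recent duplicates of the core genome" from "foreign
acquisitions".

Marker selection mirrors standard phylogenomic practice: a seeded random
sample of ortholog triples that are syntenic in all genomes and have no
non-orthologous match above 50% identity.

## Pipeline, determinism and scale

`run_full_comparison()` sequences the stages and returns one summary
object; `render_report()` formats it as markdown. Everything downstream of
a config seed is deterministic, and the acceptance script re-derives all
headline numbers from scratch at run time. Stage caching keyed by content
hashes was considered and dropped: at desk scale every stage is a pure
function over in-memory objects and re-running is cheaper than a cache's
complexity.

Problem sizes used in the shipped validation: truth recovery on 20 seeded
40-gene clades; block construction against a brute-force enumerator on
1,000 random ≤ 15-gene instances; RIP power on 100 seeded families;
repeat-finder recall on 20 seeded clades; NG86 recovery on 300 genes of
300 codons plus exact agreement with the enumeration oracle on 500 random
codon pairs; Fisher agreement exhaustively for small tables and on a
random sweep of larger ones; the full default pipeline once end-to-end.

## Known limitations

The homology stage has no E-value statistics; thresholds are raw scores.
The three-way ortholog rule cannot represent many-to-many orthology
(co-orthologs land in paralog families instead). The repeat finder is not
a Piler/RepeatMasker replacement and its defaults are tuned to the
simulator's TE model. The NG86 estimator shares its site-counting
convention with the simulator's event process by design of the method, so
rate recovery validates the estimator's bookkeeping and correction, not
model robustness. Genome-scale published values (Venn counts in the
thousands, 70–78% syntenic identity, index values of specific TE
families) require the real genomes and are out of reach of desk-scale
simulation; the package's claims are therefore property-based, anchored to
simulator truth and to the printed worked examples its statistics can
reproduce exactly.
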