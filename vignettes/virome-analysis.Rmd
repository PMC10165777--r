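---
title: "Mosquito virome profiling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mosquito virome profiling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viromeflow)
```

## Scope

`viromeflow` implements the downstream half of a bulk RNA-virome survey of
field-collected mosquitoes. Its inputs are the artifacts that sequence
search and read mapping leave behind — tabular alignment hits, contig
sequences, per-library metadata and per-OTU read-mapping summaries — not
raw reads. Upstream steps (trimming, assembly, the DIAMOND/RPS-BLAST
searches themselves, phylogenetics) are out of scope; their outputs are
this package's inputs.

The pipeline has five analysis stages plus a generator:

1. **Virus discovery** — candidate selection, false-positive removal,
   greedy clustering, novelty/completeness calls, segment co-assignment.
2. **Quantification and diversity** — expressed-virus calls, RPM,
   Shannon index, binomial downsampling, ordination, K-means profiles.
3. **Food-source assignment** — filtered best-hit LCA against a taxonomy,
   lifted to family/genus, aggregated per kingdom.
4. **Co-occurrence** — hypergeometric over-representation tests between
   viruses and food families across libraries.
5. **Sharing and transmission** — exclusivity/sharing summaries across
   species, regions and years; vertical-versus-environmental labels.
6. **Synthetic data** — a seeded generator with planted ground truth that
   makes every stage testable without access to raw sequencing data.

## Virus discovery

A contig becomes a **candidate** if at least one of three database
searches supports it: a general viral-protein search at e-value
$\le 10^{-5}$, a curated RNA-virus reference search at $\le 10^{-5}$, or
an RdRp domain-profile search at the more permissive $\le 10^{-2}$
(domain models detect remote homology at weaker e-values). Candidates
whose best overall hit — maximum bitscore across viral and competitor
tables (mosquito genome, general protein/nucleotide databases) — is
non-viral are discarded, as are retroviral best hits; survivors therefore
have their best evidence among RNA viruses (Riboviria). Contigs of 300 nt
or less are dropped.

All published thresholds in this chain ("greater than 300", ">80%",
"<80%", "<90%", "higher than 90%", ">50%") are implemented as **strict
inequalities**, exactly as worded; boundary values fall on the
conservative side. The acceptance suite pins this behaviour on dense
boundary grids.

**Clustering.** Redundant contigs are collapsed by CD-HIT-style greedy
incremental clustering: sequences are processed longest-first (ties by
id), each joins the first cluster whose representative it matches at
identity strictly above the threshold (0.90 nucleotide identity for
deduplication; 0.90 protein identity when forming quantification OTUs),
else it seeds a new cluster. Because the word-based heuristic of the
original tool is an implementation detail, the identity engine here is a
deterministic **global (Needleman–Wunsch) alignment** with unit match
score, mismatch −1, gap opening 2, gap extension 1; identity is matches
divided by alignment columns, gap columns included. This definition is
symmetric, equals 1 on self-comparison, and is cheap to verify by
exhaustive all-pairs computation, which the test suite does. The engine
is pluggable (`identity_fn`), so a CD-HIT-compatible provider can be
substituted without touching the clustering logic.

Three identity thresholds coexist deliberately: 90% nucleotide identity
for contig deduplication, 90% protein identity for OTU formation, and the
80% amino-acid species threshold inside the novelty rule. Each is a
separate named argument; they are never merged.

**Novelty and completeness.** A virus is *novel* iff its closest known
homolog matches at <80% amino-acid identity **and** <90% nucleotide
identity; a missing nucleotide-level homolog satisfies the second
condition (nothing to exceed 90%). The RdRp is *complete or nearly
complete* iff the alignment covers >80% of the known protein. Both calls
are monotone in their inputs, which the suite checks property-style.

**Segments.** Multi-segment viruses leave one OTU per segment. Two OTUs
are co-assigned when their presence profiles agree (Jaccard ≥ 0.8) and
their codon-usage bias agrees (cosine distance of 59-codon RSCU vectors
≤ 0.1); groups are connected components of that graph. The source
describes this rule only qualitatively ("co-occurrence frequency and
codon usage"), so both cutoffs are explicit configuration, defaulted
here, flagged as heuristic in the output attributes, and not used by any
downstream stage.

## Quantification and diversity

An OTU is **expressed** in a library only when mapped reads cover
strictly more than half of its reference; abundance is
$\mathrm{RPM} = \text{mapped reads} / \text{non-rRNA reads} \times 10^6$.
RPM is zeroed wherever the expressed call fails, so the matrix invariant
`rpm == 0` wherever `present == FALSE` always holds. Diversity per
library is richness (expressed OTU count), summed RPM, and the Shannon
index $H = -\sum_i p_i \ln p_i$ with natural log, where the $p_i$ are
proportions **of expressed OTUs only** — the proportional-abundance
wording applies after the expression filter, and a library with one
expressed virus has $H = 0$ by definition.

**Downsampling.** Cross-region comparisons must not be confounded by
unequal sequencing effort. The default mode thins every mapped-read count
binomially at rate 0.25/0.50/1.00 and scales the library denominators by
the same rate, recomputing expressed calls and RPM per replicate; rate
1.0 is the exact identity. Because the stated design ("randomly sampled
to achieve equivalent data" over depth *and* individuals) admits a second
reading, whole-library subsampling is also provided
(`subsample_libraries()`); both modes are seeded and bit-reproducible.

**Comparisons.** Group contrasts use the two-sided Wilcoxon rank-sum test
(exact enumeration when both sides have ≤10 tie-free values, else the
normal approximation with tie correction; the method used is recorded)
and the Kruskal–Wallis H test with tie correction against a
$\chi^2_{k-1}$ reference. Ordination is classical metric MDS on Euclidean
distances of `log1p(RPM)`; the transform is configurable because the
source states the distance but not the transform, and log1p keeps
high-abundance libraries from dominating. Axis signs are fixed (first
nonzero loading positive) so runs are comparable. Virus-profile
clustering is Lloyd's K-means on row-normalised profiles, best of 25
seeded restarts; `k = 5` is the default because five communities is the
headline structure this workflow targets, but no model-selection claim is
attached to it.

**Sharing and transmission.** `virus_sharing()` reduces named OTU sets to
integer counts — total distinct, exclusive-to-one-group, pairwise and
k-way intersections — and recomputes every percentage from its integer
numerator and denominator, reported to two decimals with half-up rounding
(so 46/54 prints as 85.19). A virus within one species is a
*vertical-transmission candidate* iff present in every required sampling
year (default: all three); anything mosaic is *environment-derived*.
These labels are hypotheses carried into the sharing contrasts, not
biological proof.

## Food-source assignment

Nucleotide hits of non-viral contigs are filtered in two steps: hits to
arthropod taxa are removed first (presumptive mosquito host material),
then three criteria apply jointly — e-value ≤ 1e−5, aligned fragment
strictly >200 bp, and alignment covering strictly >80% of the contig.
Query coverage is always recomputed as aligned length over contig length
(clamped to 1 for gapped alignments); input coverage columns are ignored
because the two coverage orientations (of the contig, of the subject)
serve different rules and silent misuse is the main failure mode.

For each contig the *equal-best* set holds every hit with bitscore within
`bitscore_tolerance` of the maximum; the default tolerance is 0 (exact
equality), the conservative reading of "equivalent bitscores", and the
knob is exposed. One best hit assigns its own taxon; several assign their
**last common ancestor** (deepest node ancestral to all). The assignment
is then lifted to family (and genus where resolvable); an LCA above
family rank is reported unresolved, and fungal assignments are discarded.
Counting is per contig, not per read. Family × library profiles split by
kingdom (Metazoa = bloodmeal, Viridiplantae = plant diet), and a
saturation curve (mean distinct families over random library orderings)
shows whether sampling depth has plateaued.

## Co-occurrence

For each (virus, food family) pair observed together at least once, the
package tests over-representation of joint presence with the
hypergeometric upper tail $P(X \ge k)$ given margins $K$ (libraries with
the family), $n$ (libraries with the virus) and $N$ (libraries tested),
computed in log space. Presence of a virus is the expressed call;
presence of a family is ≥1 resolved assignment — the minimal,
detection-based reading. Pairs with zero overlap are not tested (their
p-value is 1); the count of excluded pairs is recorded. Significance
follows the raw `p < 0.01` convention of the workflow this package
reproduces, but Benjamini–Hochberg adjusted values are always reported
alongside, and `use_adjusted = TRUE` switches the criterion; whether the
original threshold was multiplicity-adjusted is not stated, so both
numbers are surfaced rather than guessed.

## The synthetic generator

`simulate_dataset()` produces, from one integer seed, a complete
dataset with planted ground truth: reference coding sequences; viral
contigs mutated to controlled amino-acid/nucleotide identities (every
amino-acid change is one non-synonymous substitution, extra nucleotide
divergence comes from synonymous third-position swaps — no indels, so
Hamming identity equals alignment identity, which is verified
internally); hit tables written directly from the planted mutations;
decoy host contigs and short fragments; negative-binomial mapped-read
counts (dispersion 0.5 by default — overdispersion is the realistic
stress case); species-specific virus sets with vertical viruses present
in every library of their species and environment-derived viruses
restricted to at most two years; food-source contigs drawn from the
shipped ~60-node fixture taxonomy (a synthetic stand-in, not real NCBI
data) with planted equal-bitscore ties; and planted virus–family
co-occurrences realised by raising the family's presence probability to
`strength` in libraries containing the virus.

Defaults encode the emulated design: 15 species (first three dominant),
13 locations, years 2018–2020, 200 libraries, identity targets at least
two percentage points away from every threshold so planted labels are
unambiguous. Guaranteeing planted presence (clamping mapped reads to a
positive floor in truth-present cells, capping environment-derived
viruses at two years) is generator design, fixed before any test runs.

What the generator does **not** emulate: real sequence composition and
alignment artefacts (hits are synthesised, not realigned), chimeric
assembly, index hopping, within-family taxonomic ambiguity beyond planted
ties, and read-level noise (the pipeline starts at contigs and
summaries). Passing recovery tests therefore demonstrates that the
*logic* of the pipeline is correct under its stated assumptions, not that
a real survey would achieve these recovery rates.

## Numerical choices and degenerate inputs

* Strict inequalities everywhere a threshold is worded strictly;
  boundary grids in the test suite pin each one.
* Coverages clamped to 1 when gapped alignments exceed sequence length.
* Greedy clustering order: descending length, ties lexicographic —
  deterministic output.
* Hypergeometric tail in log space; exact agreement (<1e−12) with direct
  pmf summation for all parameter tuples with N ≤ 12.
* Shannon on an all-zero vector is an error, not 0 — an empty library has
  no defined diversity; `diversity_table()` reports 0 only for richness
  ≤ 1, where the limit is exact.
* Kruskal–Wallis with all pooled values equal returns H = 0, p = 1 (the
  tie-correction denominator vanishes there).
* Degenerate ordination (all libraries identical) returns all-zero
  coordinates with a warning instead of failing the eigendecomposition.
* All randomness (downsampling, K-means restarts, orderings, the
  generator) flows from explicit integer seeds.

## Problem sizes

The shipped tests and the acceptance script run the generator at 30–60
libraries with 15 planted viruses, and the replicate co-occurrence check
at 100 datasets of 40 libraries. These sizes were chosen so the full
suite completes in about a minute on one CPU while every planted signal
remains unambiguous; all of them are ordinary `sim_config()` parameters,
and nothing in the package logic depends on them.

## Known limitations

* The segment co-assignment rule is a documented heuristic; its two
  cutoffs have no published values behind them.
* The identity engine is a plain global aligner: adequate for the
  clustering contract and for verification, but not a drop-in for
  short-word screened tools on very large inputs.
* Whether nucleotide deduplication originally ran on all contigs or only
  RdRp-bearing ones is ambiguous in the source; this package applies it
  to candidate viral contigs and documents that choice.
* Food assignment gives each contig exactly one family (best-hit set
  only); secondary hits never contribute.
* The fixture taxonomy is intentionally tiny; real analyses should
  supply a full taxonomy table via `read_taxonomy()`.
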