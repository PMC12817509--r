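---
title: "Methods: clustering and annotating full-length 16S long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clustering and annotating full-length 16S long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`ampliclust`, the parameters that matter, the numerical choices made
where the design was genuinely open, and what the synthetic-data tests
do and do not demonstrate about real data.

## Problem setting and assumptions

The input is a directory of per-sample FASTQ files of full-length 16S
rRNA gene amplicons from a long-read platform. The method assumes:

* one file per sample (demultiplexing happened upstream);
* reads span the full amplicon between the 27F/1492R primer pair, in
  random orientation;
* errors are substitution/indel noise at a few percent, high enough
  that near-identical reads from one template rarely collide exactly,
  low enough that k-mer profiles of reads from one species remain more
  similar to each other than to reads from a species ≥ ~5% divergent.

The unit of analysis is the *shared cluster* (pseudo-OTU): a group of
reads, possibly spanning samples, assumed to derive from one 16S
sequence variant.

## Quality control and primer extraction

Reads pass QC when their mean Phred score is at least `min_quality`
(default 10) and their length lies in `[min_len, max_len]` (defaults
1200–1800 bases, bracketing full-length 16S amplicons). The mean is
the arithmetic mean of the Phred values, not the Phred of the mean
error probability; the former is simpler, monotone in per-base
quality, and the thresholds are user-adjustable anyway.

Primer placement is semi-global alignment: the primer must align end
to end, the read contributes free ends. Indels are allowed (long-read
errors are indel-rich, so Hamming matching would under-detect), IUPAC
degeneracy codes match their full sets, and identity is defined as
matched primer positions divided by primer length, so a 20-mer primer
with one error scores 0.95 — the default `primer_min_identity`.
Coordinates are 0-based half-open throughout. The amplicon is the
region *between* the primers, primers excluded, so that shared primer
sequence does not inflate k-mer similarity between unrelated reads.
The read is re-oriented to the forward strand; extraction is invariant
to the input orientation.

Two published variants of the 1492R primer circulate
(`CGGTTACCTTGTTACGACTT` and `CTACGGTTACCTTGTTACGACT`); the package
defaults to the former and accepts any user-supplied pair.

## K-mer profiles, embedding, density clustering

Each read becomes a vector of 4^k k-mer frequencies (k = 5 by default:
1024 dimensions is the established operating point for long 16S reads —
large enough to separate species, small enough that a 1.4-kb read
still populates it). K-mers containing ambiguous bases are skipped; no
canonical (strand) collapsing is applied because reads are already
oriented.

**Embedding.** Profiles are embedded by classical multidimensional
scaling (principal coordinates) of their cosine distances into
`embed_dim` = 2 dimensions. The coordinates are rescaled so the
root-mean-square point norm is 1. The rescaling is what makes the
cluster-selection distance meaningful across datasets: raw cosine
distances between 16S k-mer profiles live on a data-dependent scale
(a few hundredths to a few tenths), whereas after normalization the
separation between distinct species clusters is of order 1 and the
within-cluster spread a fraction of that, so a single default
`select_epsilon` behaves consistently. The `embed_neighbors` field is
retained in `cluster_params()` for configuration compatibility but the
spectral embedding has no neighbourhood-size knob.

**Density clustering.** `density_cluster()` implements the HDBSCAN
family of algorithms directly: core distances at
`min_samples = min_cluster_size` neighbours, mutual-reachability
distances, a single-linkage hierarchy, condensation of the hierarchy
at `min_cluster_size`, excess-of-mass (stability) cluster selection,
and a *selection epsilon*: any selected cluster that split off below
`select_epsilon` is merged into its first ancestor born at or above
that distance. Consequences worth knowing:

* increasing `select_epsilon` can only merge or grow clusters, never
  split them (tested over an epsilon grid);
* the root may be selected, so unimodal data yields one cluster rather
  than all-noise;
* points are members of a selected cluster if they fall out of it or
  any of its condensed descendants; everything else is noise;
* fewer than `min_cluster_size` points short-circuit to all-noise;
* duplicated points produce zero merge heights; λ = 1/h is capped at
  10^12 so stabilities stay finite. Ties in stability favour the
  parent.

`min_cluster_size` defaults to 10 reads — the balance point between
sensitivity to rare community members and false clusters from noise.

## Two-stage clustering and inheritance

Within-sample clustering runs independently per sample; unique cluster
ids are namespaced by sample. For the between-samples stage, up to 100
representatives per unique cluster (all reads if the cluster is
smaller) are pooled and clustered again with the same parameters (a
`between_epsilon` override exists; nothing suggests the two stages
need different strictness). For each unique cluster, let f_S be the
fraction of its representatives assigned to shared cluster S, with
noise-labelled representatives counted in the denominator (the
conservative reading: an uncommitted representative is evidence
against inheritance). If max_S f_S ≥ 0.5 the unique cluster's *full*
read set is inherited by that shared cluster; otherwise the unique
cluster becomes a new shared cluster. A 0.5/0.5 tie (possible only
with an even representative count, no noise, and exactly two shared
labels) breaks toward the lower shared label id. Shared clusters are
renumbered `Cluster_0..` by descending total read count, ties by
group name, so output naming is stable and deterministic.

## Consensus and polishing

Shared clusters larger than `subsample_cap` (default 200) are
uniformly subsampled to that size — the consensus gains little beyond
a couple hundred reads while alignment cost grows linearly.

The consensus engine is a *pileup-majority* scheme: choose as backbone
the read whose length is closest to the cluster's median read length
(a typical read, least likely to carry a large indel bias; ties to the
earliest read for determinism); align every read to the backbone with
a banded overlap alignment (band half-width 80 bases plus a
length-difference allowance; match +2, mismatch −3, gap −4); tally,
per backbone position, the aligned base / substitution / deletion
operations, and per junction the inserted strings; rewrite the draft
by weighted majority. Ties break toward the draft base, which makes
the operation a fixpoint on error-free data. Insertions require a
strict majority of the reads covering the junction, with the modal
inserted string chosen. The rewrite iterates up to 3 times or until
stable; polishing then applies `polish_rounds` (default 2 — the
conventional plateau for majority-style polishers) more rounds against
the same reads. Alignments whose matches cover less than half the
shorter sequence are discarded as unrelated; if no read aligns at all
the draft is returned unchanged with a warning.

An external aligner+polisher pair can replace the built-in scheme via
the `backend` argument of `polish()` (same contract: reads onto
draft, polished draft out).

With ~200 reads at a few percent iid error, per-column majority is
overwhelming, which is why the synthetic tests can demand polished
representatives within 0.5% edit distance of their source reference
(and typically observe exact recovery).

## Taxonomy assignment

Hits per representative come either from an external BLAST outfmt-6
file (authoritative when supplied; 50 hits per query retained) or from
the built-in pairwise search, which computes percent identity over the
overlap alignment and a score-proportional bit-score surrogate — it
exists so the pipeline and its tests run self-contained, not as a
BLAST replacement.

The decision rule, in order:

1. **Gap retention.** Sort hits by (bit score, percent identity)
   descending; discard hits with bit score ≤ best − `gap`
   (default 1). Hits *tied* with the best bit score are always
   retained: at `gap = 0` the literal rule would discard the best hit
   itself, and the rule's evident intent is a tolerance band below the
   top.
2. **Identity masking.** Each retained hit's lineage is masked per
   rank: a label survives only if the hit's percent identity reaches
   the rank floor — species 97, genus 94.5, family 86.5, order 82,
   class 78.5, phylum 75, domain 65. Because the floors decrease
   toward domain, masking monotonicity (nothing classified below an
   unclassified rank) holds by construction. `masking = FALSE`
   disables only this step.
3. **Fraction selection.** Walk ranks species → domain. At rank r,
   tabulate the distinct lineage *prefixes* (domain..r) among retained
   hits — prefixes, so hits masked at species still vote at genus and
   above. If the modal prefix reaches `min_fraction` (default 0.6) of
   the retained hits — the retained subset, not the raw 50 — and its
   label at r is not `unclassified`, return it, back-filled with
   `unclassified` below r. Ties between equally frequent prefixes
   break by higher mean percent identity, then lexicographically.
   If no rank qualifies, the lineage is all-`unclassified`.

Cluster counts can then be collapsed to any rank; collapse is additive
and conserves the table total, with masked ranks accumulating in
`...;s__unclassified`-style bins.

## Evaluation metrics

For a set of observed taxa O and expected taxa E: OET = |O|/|E|,
TAR = |O∩E|/|O|, TDR = |O∩E|/|E| (so OET = TDR/TAR whenever TAR > 0).
An empty observed set reports TAR 0 with a flag rather than NaN.
Bray-Curtis distance is Σ|p−q|/Σ(p+q) over the taxon union. The
regression is ordinary least squares of observed on expected over the
zero-filled union, reporting the slope-test p-value and r².
Filtering before metrics mirrors mock-community practice: drop taxa
below a per-sample relative-abundance floor, then taxa seen in fewer
than a minimum number of samples; abundances are *not* renormalized
afterwards, preserving absolute comparison semantics. Label
harmonization (nomenclature renames) is caller-supplied, never
hard-coded.

## Synthetic data: what it shows and what it does not

The generator derives n species from one random ancestor at a chosen
divergence, assigns 7-rank lineages (optionally with shared genera),
attaches the primer pair, randomizes strand, and applies iid
substitution/insertion/deletion noise with a constant Phred quality
consistent with the total error rate. All randomness flows from one
seed.

The standard test conditions are: 3 species of 1.4 kb at 10% pairwise
divergence, abundances 0.5/0.3/0.2, 300 reads × 2 samples, 3% total
error (1% each substitution/insertion/deletion) — small enough for a
desk-scale run, large enough that every stage is exercised with
non-trivial statistics. Under these conditions the pipeline recovers
all species, reaches TDR = 1 and Bray-Curtis ≤ 0.15 against the
design, and its representatives sit within 0.5% edit distance of
truth.

What this does **not** show: performance under homopolymer-biased or
quality-correlated error (the model is iid), under species below the
primer's amplification bias, at divergences well under ~5% where 16S
simply cannot separate taxa, or against a real reference database with
thousands of near-neighbours, where the identity-masking floors do the
heavy lifting. Real-data accuracy therefore cannot be inferred from
the synthetic suite; the suite validates the algorithmic contracts,
not field performance.

## Known limitations

* The built-in consensus is majority-based, not a true partial-order
  alignment; for clusters mixing templates of very different lengths
  the backbone choice matters more than it would for POA.
* Quality scores are ignored during consensus (no Phred weighting).
* 16S copy-number variation is not corrected; abundances are read
  fractions.
* Chimera detection and per-window quality trimming are out of scope.
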