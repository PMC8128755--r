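---
title: "Methods: detection filtering and expression-restricted networks for the synaptic RNAome"
author: "synaptoNet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection filtering and expression-restricted networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptoNet)
```

## The analysis problem

RNA sequencing of synaptosomes or of the perfusion channel of microfluidic
culture chambers yields read counts for a mixture of mRNAs, lncRNAs,
microRNAs and snoRNAs present at or near synapses. Two questions follow:
which of those species are *reliably* present (as opposed to trace
contamination or noise), and how is the detected mRNA pool wired to the
detected microRNA pool through experimentally validated interactions?
`synaptoNet` answers both with a fixed, reproducible procedure; this
vignette documents the model, its assumptions, and every numerical choice
that was genuinely open.

## Abundance model and detection

**Normalization.** Counts are scaled per sample to transcripts per
million, defined here as pure library-size scaling:
$\mathrm{TPM}(f,s) = c_{fs} / \sum_{f'} c_{f's} \times 10^6$. No
transcript-length term enters, although the acronym often implies one —
for short-read small-RNA libraries and for threshold-style detection a
length correction would change the meaning of the cutoffs. We flag this
prominently because comparisons against length-normalized TPM from other
pipelines are not meaningful. The library size is the column sum of the
count matrix, i.e. the total over all annotated features of the assay;
total mapped reads are not available once a count matrix is the input.

**Thresholds.** A symbol is detected when its replicate-aggregated TPM is
greater than or equal to the biotype cutoff: 1000 TPM for miRNA and snoRNA
from the small-RNA assay, and 50 TPM for mRNA and lncRNA from
synaptosome-depth total RNA (around six million reads per library); deeper
chamber libraries (around twenty million reads) use 100 TPM so that the
cutoffs correspond to comparable raw-count evidence. At 1000 TPM, a
small-RNA feature in a 10,000-read library needs an average raw count of
10 reads — the scale of evidence the cutoff is designed to demand:

```{r}
m <- matrix(c(10L, 9990L), 2, dimnames = list(c("mir-x", "bg"), "s1"))
SummarizedExperiment::assay(tpmNormalize(RnaCounts(m, "small_rna")), "tpm")["mir-x", ]
```

Three choices here were open and are fixed as follows:

* **Replicate aggregation** defaults to the mean across samples (an
  "average raw count" reading); `all` and `any` are selectable. Note that
  `all` ⊆ `any` and `mean` ⊆ `any` hold, but `all` ⊆ `mean` does *not*
  relate to `mean`'s set in general and is deliberately not asserted in
  the tests.
* **Boundary rule**: comparison is inclusive (≥), so a feature exactly at
  the cutoff is detected. Some tie-break must be fixed for
  reproducibility; reading "a cutoff of 1000" inclusively is the
  conventional choice.
* **Symbol collapsing**: detection operates on symbols because network
  nodes are symbols; multiple feature ids sharing a symbol are summed.
  Since TPM is linear in counts at fixed library size, summing TPM rows
  equals collapsing counts before normalization.

Features with biotype `other` (rRNA/tRNA-like background mass) never enter
detection sets; detectable biotypes that do not belong to a matrix's assay
(e.g. miRNA rows in a total-RNA matrix) are excluded with a warning rather
than an error, since mixed annotation tables are common. Predicted gene
models can be excluded from the lncRNA calls; removed symbols are kept in
a side report rather than discarded, so provisional annotations remain
available for follow-up.

## Interaction evidence and the network

Evidence arrives as one canonical TSV per source database
(`source_db, node_a, a_type, node_b, b_type, directed, confidence[, score]`).
The real sources (NPInter, RegNetwork, RISE, STRING, TarBase, TransmiR,
and kin) publish heterogeneous native formats that change between
releases; this package deliberately defines one canonical schema and
leaves per-source field mapping to the user, because the computation — not
the scraping — is the reproducible part. Symbols are normalized at load
(whitespace trimmed, case-folded, species prefixes stripped from mature
microRNA names under a flag that defaults to on), and self-pairs are
dropped.

**Weak filtering.** Records classified as weak are excluded *where a
classification is available*: unlabeled sources pass through untouched.
Sources with numeric scores on a 0–1000 scale are mapped to weak/strong by
a per-source threshold defaulting to 400, the conventional
medium-confidence line for such scores; a score exactly at the threshold
is strong.

**Construction.** The network is built in two steps: (1) an mRNA backbone
from mRNA–mRNA evidence where both endpoints are detected; (2) microRNA →
target edges where the microRNA is detected and the target is a detected
mRNA *on the backbone*. The second condition implements the
intersect-with-the-mRNA-network reading rather than "any detected mRNA":
the regulatory claim is about the connected synaptic mRNA pool. lncRNA
associations and TF → miRNA edges are off by default and can be enabled
per analysis, keeping the core construction minimal. Duplicate pairs
across sources merge into one edge carrying the union of sources; the
result is invariant to record and file order.

**Pruning.** Nodes connected by only one edge are removed. Whether this
was historically a single pass or an iteration to a fixed point is
ambiguous in the field's informal descriptions, so both are implemented:
`one_shot` (default — a single filtering action on input degrees, then
dropping newly isolated nodes) and `iterative`, which equals the 2-core
and is verified against an independent peeling oracle in the tests. Degree
counts distinct neighbors regardless of edge direction or type; self-loops
are rejected at load so they cannot inflate degree.

**Coverage and hubs.** Coverage statistics (fraction of detected mRNAs
targeted; fraction of detected microRNAs with a target) are computed on
the *unpruned* expression-restricted network by default: they describe
targeting of the detected mRNAome, not of the display network. Passing the
pruned graph computes the pruned variant. Hub rankings sort regulators by
distinct detected mRNA targets, descending, with an alphabetical tie-break
so rankings are stable. Percentages are stored exactly to one decimal and
displayed as half-up integers (so 83.3% prints as 83, and a half rounds
away from zero rather than to even); zero denominators yield explicit `NA`
markers, never propagated `NaN`.

## Set comparisons and enrichment

Venn and multi-list overlap reports always carry memberships alongside
counts, because downstream steps (e.g. restricting the network to the
microRNAs shared with an exosome panel) need the members, not just the
sizes. All comparisons run on normalized symbols so that name variants are
an explicit normalization event rather than a silent mismatch.

Over-representation uses the one-sided upper-tail hypergeometric test —
enrichment panels, not depletion, are the target use — with
Benjamini–Hochberg correction per collection. The background defaults to
the detected symbols of the relevant biotype in the dataset under
analysis, not the whole annotation: detection-conditioned ORA is the
defensible default when the query itself was derived from the detected
pool. Query and gene sets are intersected with the background before
testing. The differential-expression call feeding a stimulation analysis
(e.g. a DESeq2 up-regulated list) is an *input*; re-fitting count models
is out of scope, and the pathway-fraction report simply counts what share
of a pathway's background members appear in the supplied increased list.

## What the synthetic data emulate — and what they do not

The generators create: negative-binomial count matrices (dispersion 0.1 by
default, variance $\mu + \mu^2\phi$) over three replicate samples, with
planted detected features at twice their threshold (jittered log-uniformly
up to ~6×) and planted undetected features at half of it or lower;
library sizes drawn uniformly from 5–7 million (total RNA) and 1–3
million (small RNA); six-source interaction tables in which detected
mRNAs form a shuffled ring plus random chords (so every detected mRNA has
a backbone degree of at least two by construction), one planted
50-target hub microRNA over background regulators with at most 10
targets, about 20% weak evidence expressed in each source's dialect,
deliberate cross-source duplicates, and decoy edges touching undetected
features; exact-overlap set pairs (65/54/17 by default); and a 400-gene
stimulation background with one 40-gene pathway of which half is
increased. Feature-universe sizes default to a few hundred per biotype —
large enough for stable statistics, small enough that the full suite and
the acceptance script run in seconds to a couple of minutes.

Ground truth is derived *constructionally* (which features were placed
above threshold; which edges are strong with both endpoints detected and
the target on the backbone), never by running the pipeline on its own
output, so planted-truth tests remain genuine oracles.

These simulations do **not** emulate: read-level artifacts (adapter
content, mapping ambiguity, the upstream read-length mapping filter),
compositional coupling between biotypes, correlated replicate noise,
batch effects, annotation errors, or the heavy-tailed abundance
distributions of real libraries (a small set of `other`-biotype filler
features absorbs the TPM budget instead). Passing tests therefore
demonstrate the correctness of the *procedure* under controlled
separation, not the field performance of the thresholds on real
sequencing data.

## Degenerate inputs and numerical notes

* Zero-library-size samples normalize to all-zero columns with a warning
  and are flagged in the TPM object's metadata.
* An empty detected mRNA set yields an empty network with a warning, not
  an error; empty snoRNA sets yield empty class reports.
* Hypergeometric p-values use the stable upper-tail routine
  (`phyper(k − 1, ..., lower.tail = FALSE)`, exactly 1 at k = 0) and are
  verified against exhaustive enumeration of all draws for universes up
  to N = 12.
* All JSON reports are written with fixed key order and full precision;
  pipeline reruns with an identical config are byte-identical (the
  manifest's timestamp is the only run-specific output).
* Generator seeds are mandatory; every generator is a pure function of
  its config, and derived seeds stay within 32-bit integer range.

## Known limitations

Per-source confidence semantics are reduced to weak/strong/unlabeled plus
one numeric threshold; richer evidence models (per-method weights,
experiment counts) are not represented. The canonical schema ships no
scrapers for live database releases. Coverage percentages depend on the
pruning convention chosen; both conventions are available but only the
unpruned default is extensively characterized. Symbol normalization
handles case and species prefixes, not gene-synonym resolution — an
external synonym table must be applied upstream if sources disagree at
that level.
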