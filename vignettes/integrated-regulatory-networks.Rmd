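---
title: "Models and methods behind intregnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind intregnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intregnet)
```

`intregnet` integrates three layers of gene regulation — transcription
factors binding promoter-proximal DNA, miRNAs repressing mRNAs through
3′UTR seed sites, and protein–protein interactions — into one typed, signed
network, and analyses its hierarchy and motif spectrum. This vignette
explains the models, the tunable parameters and their defaults, the
numerical choices, what the synthetic-data generator does and does not
emulate, and the known limitations.

## Coordinates and annotation

All internal coordinates are 0-based half-open, the BED convention; GFF3's
1-based inclusive coordinates are converted on read and back on write, so a
read→write→read round trip is the identity. The TSS of a feature is its
strand-aware 5′ end: `start` on the `+` strand, `end − 1` on the `−`
strand. Pre-miRNA hairpins are accepted as a dedicated `pre_miRNA` feature
type (annotation dialects differ here; we document ours rather than guess),
and their "start position" is likewise the strand-aware 5′ end.

## TF target calling

A gene is a target of a factor when the **center** of at least one binding
peak falls inside the promoter window of at least one of its transcripts.
The window is `upstream = 1000`, `downstream = 500` bp around the TSS by
default — most promoter-proximal binding signal concentrates in that
1.5 kb — with `strict` (500/300) and `relaxed` (2000/500) presets for
sensitivity analyses. The window is half-open and strand-aware: for a `+`
strand TSS `t` it is `[t − up, t + down)`, for `−` strand the mirror image
`[t − down + 1, t + up + 1)`. The boundary convention (inclusive at the
upstream edge) is a choice the data cannot distinguish; it is fixed and
documented here. Peak centers come from the narrowPeak summit offset when
present, else the interval midpoint.

**HOT regions.** Loci bound by very many factors at once behave
non-specifically: the binding motifs of the individual factors are not
enriched there, so peaks in such regions are poor evidence of direct
regulation. A position is HOT-covered when peaks of at least `threshold`
(default 15) *distinct* factors overlap the 400-bp window centered on it;
maximal runs merge into intervals. Multiple assay conditions of one factor
count once. Because the canonical threshold (15) reflects a panel of ~22
factors, `hot_auto_threshold(n)` scales the occupancy fraction
(`ceiling(0.68 n)`) for smaller panels. Exclusion modes: drop peaks whose
*interval overlaps* a HOT region (the default analysis choice, matching how
such loci are reported), or only those whose *center* falls inside one, or
keep everything.

Whether target sets of one factor assayed at several developmental stages
should be merged is not decidable from first principles; the package
defaults to the union across conditions (each `peak_set` carries its
condition label, so per-stage analyses remain possible).

## Activator/repressor classification

For each transcript the region −2 kb..+2 kb around the TSS is divided into
40 bins of 100 bp, ordered 5′→3′ so bin 1 is always the far-upstream bin.
A read contributes `overlap/read length` to each bin it touches. For every
bin *b*, `r_b` is the Pearson correlation, across transcripts, between the
bin signal and transcript expression in the condition matched to the ChIP
experiment (by default the experiment's own stage label). Expression is
`log2(x+1)`-transformed by default — RNA-seq levels span orders of
magnitude and the log stabilises the correlation — with the raw scale
available via `log_transform = FALSE`.

"Consistent" correlation is operationalised as: at least 70%
(`consistency_cutoff`) of the bins with defined correlation share one
sign; the class is then the sign of the mean correlation, otherwise
`ambiguous`. Bins with zero signal variance are dropped from the
denominator. The 0.7 default reproduces the visual criterion of
consistently one-signed correlation profiles while remaining testable: on
a null with per-bin-independent signal and ≥500 transcripts, fewer than 5%
of factors escape `ambiguous` at this cutoff (verified by simulation in
the test suite). A caveat worth knowing: if transcripts carry a shared
binding-propensity factor across all bins, the 40 bin correlations become
mutually correlated and consistency alone can reach 1 with a vanishing
mean correlation; inspecting `mean_r` alongside the class guards against
this.

Signs propagate per factor: every out-edge of a `positive` factor is `+1`,
of a `negative` factor `−1`; `ambiguous` factors contribute sign-0 edges
that the signed motif census excludes (with a logged count). All
miRNA→gene and miRNA→TF edges are `−1` — miRNA regulation is repressive by
mechanism.

## Network assembly and degree statistics

The eligible gene universe contains the genes for which *both* inputs
exist: an annotated TSS (TF-callable) and at least one annotated 3′UTR
(miRNA-predictable). Edges touching genes outside the universe are dropped
with counts logged. miRNA targeting requires at least one seed site
conserved in all species of the required set — three nematode species by
default, five in strict mode — on at least one transcript of the gene.

Degree histograms (regulatory TFs per gene/miRNA, regulatory miRNAs per
gene, targets per miRNA) are fitted with `count ∝ exp(−λ·degree)` by least
squares of `ln(count)` on degree over occupied bins; zero-count bins are
excluded rather than pseudocounted. The fit is **count-weighted** by
default: tail bins holding one or two nodes contribute `ln` values
dominated by sampling noise, and an unweighted fit lets them drag the
slope — with weighting, the decay rate of simulated geometric degrees at
n = 2000 is recovered within 10% essentially always, which is the
recovery the package's tests assert. `weighted = FALSE` restores the plain
fit. R² is computed on the same (weighted) log scale. Fits are skipped,
flagged, when fewer than three occupied degrees exist. Raw histograms, not
cumulative distributions, are fitted; with binned raw counts the estimate
is transparent and the choice is stated here.

Combinatorial regulation is quantified per regulator pair as the upper-tail
hypergeometric probability of the observed target overlap in the network's
universe, with Benjamini–Hochberg q-values added across the pair matrix as
a modern-reporting extra (raw p preserved as the primary statistic).

## Hierarchy

TF→TF edges, self-loops ignored, bucket the factors: **top** = in-degree 0
(not regulated by any *other* factor — a purely self-regulating factor is
top), **bottom** = out-degree 0 among the rest, **middle** = regulates and
is regulated. The three published bucket rules leave factors regulated
only from the middle unplaced; the regulates-and-is-regulated rule covers
them, making the assignment total for any digraph (cycles included —
mutually regulating factors are middle). miRNAs then join in four layers
by sequential set-difference: those regulating a top factor (highest
priority), then a middle, then a bottom factor, then the rest, which have
only incoming edges. The TF universe defaults to the assayed factors with
outgoing edges, configurable to all annotated TFs.

## Motif census and null models

The census enumerates **exactly** every connected 2- or 3-node subgraph
(via per-node neighbor pairs, de-duplicated), assigning each unordered
node set a canonical label: over all ≤6 node orderings, the digit sequence
(node types, then the six directed edge slots; signs as separate codes in
signed mode) is minimised. Isomorphic subgraphs get identical labels,
non-isomorphic ones distinct labels. Auto-regulation self-loops are a
1-node motif counted separately (`count_autoregulation`), not part of the
3-node census. Exact enumeration is feasible at the scales this package
addresses and removes a sampling approximation; the test suite proves the
census equal to a brute-force all-triples enumerator on random graphs.

Null networks are Maslov–Sneppen double-edge swaps applied *within strata*
— edge type, and additionally sign in signed mode — so each node keeps its
per-type (per-sign) in- and out-degrees exactly. `q = 100` swap attempts
per edge (exposed, since rewiring intensity is a convention); swaps
creating duplicate edges of a type or new self-loops are rejected. Strata
with fewer than two edges cannot be rewired and are flagged. PPI edges are
a fixed scaffold, never rewired. Enrichment reports both
`z = (N_real − μ)/σ` (z flagged undefined when σ = 0) and the add-one
empirical p `(1 + #{null ≥ N_real})/(N + 1)`, which cannot be 0; labels
seen only in nulls appear with `N_real = 0`, exposing depletion. Composite
analyses: miRNAs repressing both endpoints of a PPI edge (null rewires the
miRNA strata only), TF⇄miRNA feedback loops (both strata rewired), and
auto-regulation split into PAR/NAR by sign (null permutes the target slots
of TF→TF edges).

A note on determinism: stratum processing order is derived with a
locale-independent sort, so a given seed yields the same null ensemble on
any system.

## Intronic miRNAs and the host network

A miRNA is intronic in a gene when its hairpin lies wholly inside the gene
span and intersects **no exon of any transcript** of that gene — the
strictest isoform handling; one overlapping isoform exon disqualifies the
pair. Sense-embedded miRNAs (strands match) are presumed co-transcribed
with the host; the host network links `m_a → host(m_b)` whenever the host
of `m_b` is a predicted target of `m_a`, with `a = b` flagged
auto-regulation, all edges repressive. Strand bias is the one-sided exact
binomial tail `P[X ≥ n_sense]` at `p₀ = 0.5`, computed in log space. For
the worm-scale counts 39 of 60, this exact test gives 0.0137, not the
0.007 sometimes quoted for those counts; the package reports the exact
tail and flags the discrepancy rather than reverse-engineering an
unstated test. (The human-scale counts 482 of 588 give 1.6×10⁻⁵⁸, i.e.
2×10⁻⁵⁸ at one significant figure.)

## Specificity scores

The tissue-specificity score of an expression row is the relative entropy
`Σ pᵢ log₂(pᵢ/qᵢ)` of the fractional expression `pᵢ = xᵢ/Σx` against the
uniform null `qᵢ = 1/K`: 0 for uniform expression, `log₂ K` for a point
mass, 2 bits for `(½, ½, 0…)` over 8 tissues. The log base only rescales
(base 2 by default, exposed); `0·log 0 := 0`; all-zero rows are flagged
undefined rather than scored 0. Stage specificity is the same functional
over stages.

## The synthetic-data generator

`simulate_study()` is first-class, tested code that generates every input
the pipeline consumes plus the ground truth. Defaults describe a
desk-scale study chosen once: 1,000 genes on three 4-Mb chromosomes, 20
assayed TFs (alternating planted signs), 60 miRNAs (40% intronic, sense
probability 0.8), 8 tissues, a 7-stage time course, negative-binomial
target counts (mean 40 genes and 5 miRNAs per TF, 25 genes per miRNA, TFs
upweighted as targets so TF→TF and miRNA→TF edges exist), peak-center
jitter SD 200 bp truncated to the default window, 30 background peaks per
TF, 5 HOT loci stacked by 16 factors, binding→expression effect β = 3
with log-normal noise σ = 0.25, 70% of true seed sites conserved in all
five species (the rest in three), decoy sites conserved in two, PPI mean
degree 4, 15% essential genes. These mirror the order of magnitude of a
~20-TF/~160-miRNA compendium while staying fast.

Structural guarantees, by construction: entities are placed ≥2.5 kb apart
so default promoter windows never collide; every true edge's peak center
lies inside the target's default window (jitter is window-truncated);
intronic miRNAs sit ≥1.6 kb from both host ends so their windows stay
clear of the host's. Planted binding profiles are a TSS-centred Gaussian
over a broad plateau, so bound promoters are co-elevated across the whole
±2 kb — the regime in which a consistent correlation profile is the right
read-out. Planted motif counts (`planted_ffl`, `planted_feedback`,
`planted_co_ppi`) inject recorded instances for recovery tests.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: no nucleotide sequences (seed sites are
positional records, not sequence matches); no read-level noise, mapping
artefacts or peak-caller idiosyncrasies; expression noise is i.i.d.
log-normal without stage autocorrelation or batch structure; the PPI
scaffold is Erdős–Rényi, not scale-free; and true edges are planted
independently rather than through an evolved regulatory logic. Tests on
this generator validate the *implementations* under the stated model, not
the biological accuracy of the model itself.

## Orchestration

`run_pipeline(config, outdir)` validates its configuration up front
(fail-fast before any stage runs), executes simulate/load → HOT → target
calling → conservation filtering → assembly → sign classification →
hierarchy → motifs → host network → specificity, writes every artifact as
TSV/BED/JSON and a manifest with md5 checksums; a fixed seed makes reruns
byte-identical. `run_sweep()` covers the 2×2×2 grid {window
default/strict} × {HOT keep/exclude} × {conservation 3/5}; because each
stricter setting filters a superset's output, edge counts are monotone
non-increasing along the grid order, which the acceptance tests verify
pairwise. `robustness_check()` removes 1–30% of edges and reports which
originally significant motifs stay significant, with per-replicate derived
seeds so the 0%-removal replicate reproduces the baseline exactly. These
functions (rather than a shell executable) are the pipeline interface: the
package's users drive analyses from R, and a wrapper script would add a
surface without adding capability.

Problem sizes used in the shipped tests and acceptance script — chosen as
comfortable desk-scale settings — are: unit fixtures of 60–200 genes,
motif-oracle graphs up to 60 nodes, null calibration at 500 transcripts ×
100 replicates, enrichment at 100 nulls, and one default-scale (1,000
gene) study for the sweep.

## Known limitations

* Per-factor (not per-edge) signs: a factor acting as activator on some
  targets and repressor on others is collapsed to its dominant mode or
  `ambiguous`.
* The consistency criterion can be inflated by transcript-level binding
  propensity shared across bins (see above).
* The exponential fit is a descriptive summary; no model comparison
  against power laws or other families is attempted.
* Hierarchy buckets are a coarse three-layer scheme; cycles land in the
  middle layer by definition rather than by an optimisation.
* Exact motif enumeration scales as the number of connected triples;
  beyond ~10⁵ edges the provided uniform-sampling census with
  Horvitz–Thompson scale-up (`census` on sampled triples) or FANMOD-class
  tooling is the right tool.
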