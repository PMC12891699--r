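---
title: "Methods: producer classification, 16S reference curation and network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: producer classification, 16S reference curation and network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobakit)
options(cobakit.verbose = FALSE)
```

## Scope and model

`cobakit` answers three linked questions about a set of prokaryotic
genomes or MAGs and the amplicon data of the community they came from:
which genomes can synthesize cobamides de novo (and by which oxygen
route), which amplicon OTUs correspond to those producers, and whether
producer taxa occupy hub positions in the community's co-occurrence
network.

Cobamide biosynthesis is a long, modular pathway: tetrapyrrole precursor
synthesis, corrin-ring construction (an oxygen-dependent route using the
`cob` gene set or an oxygen-independent route using `cbi` genes), cobalt
chelation (multi-subunit aerobic chelatase vs single-subunit anaerobic
forms), adenosylation, and nucleotide loop assembly shared by both routes;
salvage transporters import exogenous corrinoids instead. Presence of the
pathway is therefore naturally summarized as a *weighted completeness per
branch*: for branch $b$,

$$C_b \;=\; \frac{\sum_{m \in D,\; \mathrm{br}(m)\in\{b,\text{shared}\}} w_m}
                 {\sum_{\mathrm{br}(m)\in\{b,\text{shared}\},\; m\ \mathrm{required}} w_m}$$

with $D$ the set of detected required markers. Module-restricted versions
of the same ratio are reported for diagnosis, and branch-*exclusive*
detections are counted separately to call the oxygen route — shared
early-pathway genes never vote on oxygen requirement.

## Marker evidence and its gates

Evidence arrives as profile-HMM search results in HMMER3 `--domtblout`
format, either produced externally or through the thin `search_markers()`
delegation to a local `hmmsearch`. Two rules turn raw hits into a
presence map:

* **E-value gate.** Full-sequence E-value at most `1e-6`; the boundary
  value itself passes. The full-sequence statistic (not the per-domain
  conditional E-value) matches default hmmsearch reporting.
* **One protein, one marker.** Each protein is assigned to its single
  best-scoring marker — highest bit score, ties by lower E-value, then
  lexicographic marker id — and that assignment is kept only if it passes
  the gate. Assigning *before* gating has two consequences we consider
  features: the detected set grows monotonically as the gate is relaxed,
  and a protein whose best explanation is unconvincing contributes
  nothing rather than falling back to a weaker marker. Both behaviours
  are pinned by property tests against a brute-force assignment oracle.

## Contig-level screening

MAGs are bins, and bins contain mistakes. Three independent guards remove
marker support that is more plausibly contamination or fragmentation than
biology, each logged as a flag:

1. support on contigs shorter than 2 kb that carry no second marker is
   dropped (an isolated gene on a scrap of sequence);
2. when per-contig taxonomy is available, support on contigs whose phylum
   conflicts with the genome's majority phylum is dropped;
3. if every surviving marker sits on a single contig comprising under 5%
   of the genome, the genome is flagged `single_contig_suspect` — the
   pathway may belong to one foreign fragment — and the final call is
   downgraded by exactly one class.

The guards only ever shrink the detected set. The length threshold, the
5% fraction, and phylum-rank comparison are package choices (the
screening intent is standard; its parameters are not), all exposed as
arguments. Majority phylum is the mode over annotated contigs, ties
broken by the genome's own lineage, then alphabetically.

## The four-class rubric

Raw completeness `C_raw = max_b C_b` is adjusted by the genome's own
CheckM-style completeness estimate $q$ (percent):
`C = min(1, C_raw / max(q/100, 0.5))`, so a 60%-complete MAG carrying
45% of the pathway scores 0.75 rather than being under-called. The floor
of 0.5 stops very incomplete bins from being inflated to certainty.
Classes are then

| class | condition |
|---|---|
| `very_likely` | `C >= 0.75` and a chelation-module marker detected |
| `likely` | `0.50 <= C < 0.75`, or `C >= 0.75` without chelatase |
| `possible` | `0.25 <= C < 0.50` |
| `nonproducer` | `C < 0.25` |

All lower bounds are inclusive. The threshold values, the chelation
requirement and the adjustment are defaults of this package — the
four-class contract is fixed, but an alternative rubric (e.g. one tuned
on curated producer genomes) can be passed to `classify()` without code
change. The chelatase requirement exists because cobalt insertion is the
step most specific to corrinoid (rather than generic tetrapyrrole)
synthesis; a genome with high completeness but no chelatase more likely
carries the shared tetrapyrrole trunk. Whether the `possible` class
represents a partial pathway or salvage-only capability is not
distinguished at the class level; both land in `possible`, and the
module-restricted completeness in the report separates them.

The route call is by strict majority of branch-exclusive detections;
equal nonzero counts give `ambiguous`, no diagnostics at all give
`ambiguous` if any shared marker was seen and `none` otherwise.

The shipped catalog (`inst/extdata/scp_markers.tsv`) is a curated
structural stand-in: real cobamide-pathway gene symbols with KO-style
accessions, one accession per marker, 15 required markers per branch. An
authoritative profile list with per-profile accessions drops in verbatim
via `read_marker_catalog()`.

## 16S reference curation and exact annotation

16S genes are sliced from genomes using GFF3 rRNA coordinates (minus
strand reverse-complemented, U normalized to T). Dereplication drops
sequences under 1000 nt — "high quality" is not quantified upstream, so
the package sets a conservative, config-exposed default length — and
collapses exact duplicates and exact substrings into the longest
representative (ties to the lexicographically smallest id, making the
operation deterministic and idempotent).

Producer and nonproducer (control) sets are dereplicated independently;
an identical sequence string appearing in both is quarantined to a
`conflicted` list and excluded from both, because one 16S cannot separate
a producer genome from a nonproducer genome.

OTU annotation is deliberately strict: a query matches a reference only
if it is identical to it, or an exact gap-free substring of it, on either
strand — 100% identity over 100% of the query. Partial-coverage matching
at 100% identity would make calls depend on query length; full coverage
keeps the semantics of "this V4 fragment is consistent with that
reference" uniform. A single substitution therefore voids a match, and an
OTU matching both sets is `ambiguous` rather than forced. An external
aligner can replace the substring scan behind the same contract;
equivalence with an exhaustive (query, reference, strand, offset) scan is
property-tested.

## Co-occurrence networks

OTUs with fewer than 100 total reads are excluded (exactly 100 is kept).
Counts are converted to per-sample relative abundances by default because
sample depths are unequal; `on_counts = TRUE` restores raw-count
behaviour, and both scales keep the type-I error of the pairwise test
near nominal on simulated independent tables. For each OTU pair, Pearson
r with a two-sided p from the t transform ($t = r\sqrt{n-2}/\sqrt{1-r^2}$,
$n-2$ df); an edge requires `p < 0.05` and `|r| > 0`. Uncorrected
all-pairs testing is anticonservative, so Benjamini-Hochberg correction
is available as an option; the uncorrected default mirrors common
practice in microbial network studies. Zero-variance OTUs are excluded
from testing (their r is undefined) but remain nodes.

Topology metrics: degree; closeness as *harmonic* centrality normalized
by $n-1$, which is finite on disconnected graphs (classic closeness is
not, and co-occurrence networks are routinely disconnected); betweenness
on unweighted shortest paths, normalized. Producer-vs-nonproducer
comparisons use two-sided Mann-Whitney tests per metric; when both groups
are fully tied the p-value is reported as 1.

## What the synthetic fixtures emulate — and what they do not

The generators produce: catalogs with the branch structure above;
genomes with marker complements planted at least 0.05 inside a target
class band, passing hits at E in [1e-30, 1e-7] plus decoys just beyond
the gate in (1e-6, 1e-3]; contamination scenarios that trip each
screening guard; 16S communities whose OTUs are exact substrings or
single-substitution mutants of the references (truth verified exhaustively
at generation time); and count tables from a latent Gaussian block model
(within-block correlation `block_rho`, log-normal rates, Poisson
sampling) in which the first block is the producer hub group and half the
OTUs are independent background. Nonproducer genomes carry decoy evidence
only, so their expected route is `none`.

Defaults encode the study conditions the tests run at: 200 genomes (25
per class-by-branch combination) for classifier recovery; 40 OTUs by 50
samples for the network properties (780 pairs for the null false-edge
rate); 60 OTUs with 20% mutants for annotation. These sizes make the
suite complete in well under a minute per property while keeping the
statistical checks (binomial band on the false-edge rate, Mann-Whitney on
planted hubs) meaningful.

Passing on these fixtures shows the machinery is correct, not that real
data are easy: real MAGs have correlated marker loss, HMM scores near the
gate, chimeric bins subtler than one foreign contig; real 16S references
contain near-identical paralogs across phenotypes; real abundance data
are compositional and zero-inflated beyond a log-normal-Poisson. The
strict-identity annotation in particular transfers only to amplicons from
the same primer region as the references.

## Numerical and degeneracy choices

* All randomness flows from explicit seeds (`withr::with_seed`); no
  function touches global RNG state. Identical seeds give byte-identical
  fixture files and pipeline outputs.
* Quality gate boundaries follow the conventional medium-quality MAG
  definition literally: completeness >= 50 inclusive, contamination < 10
  exclusive.
* `r = 1` pairs get `p = 0` exactly (the t transform overflows);
  correlations are clamped to [-1, 1] before the transform.
* Empty inputs are defined rather than fatal wherever they can arise
  legitimately: empty hit tables give empty presence maps, an empty
  nonproducer set builds a valid reference with a warning, zero-read
  samples report fraction 0 with an `empty_sample` flag. Empty *files*
  (genome or query FASTA) are errors, since they indicate a broken path.
* Prodigal-style protein headers are auto-detected per record; plain
  headers lose contig screening for that protein only, with a warning.

## Known limitations

Phenotype calls rest on the catalog: with the stand-in catalog the
four-class outputs are structurally correct but not authoritative for
real genomes. The classifier does not model salvage-and-remodel
phenotypes beyond the `possible` bucket, does not predict lower-ligand
variants, and trusts upstream completeness/contamination estimates.
Network inference is correlation-based; compositionality-aware methods
(SparCC-style) are out of scope, and the BH option changes edge sets
substantially on large tables.
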