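---
title: "Methods: partitioning host and symbiont transcripts"
author: "metapart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioning host and symbiont transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metapart)
```

# The problem and the model

A de novo assembly of RNA-Seq from unsterilised plant tissue interleaves
two transcript populations: the host's, and that of the fungal community
living on and in the tissue. Neither population comes labelled. metapart
partitions them using four weakly correlated signals — GC content,
transcript length, breadth of expression across samples, and homology —
and then condenses the symbiont fraction into gene families.

The method makes three assumptions worth stating explicitly:

1. **Compositional contrast.** Host and symbiont coding sequence differ
   in mean GC by several percentage points (conifer hosts ≈44–45%,
   ascomycete-dominated communities ≈53%). Where the contrast is weaker
   the GC-based read filter loses power but the remaining signals still
   apply.
2. **Occupancy contrast.** The host is present in every sample; any one
   symbiont taxon is present in few. Breadth of expression — quantified
   by tau — therefore separates the populations even where homology is
   silent.
3. **Annotation asymmetry.** Host relatives and a host genome are far
   better represented in protein databases than phyllosphere fungi, so a
   *missing* protein hit is itself weak evidence for symbiont origin,
   formalised in the genome-alignment rescue rule (unassigned + valid
   genome alignment → host).

# Quantification chain and tau

Counts are normalised to FPKM using each sample's column total as the
"million mapped fragments" denominator (read alignment is outside the
package's scope; users holding RSEM FPKM can construct the container in
state `"fpkm"` directly and skip the step). FPKM below 1 is floored to
`log2(FPKM) = 0`, values ≥1 become `log2(FPKM)`, and transcripts silent
everywhere are removed. The chain is enforced by a small state machine
(`counts → fpkm → log2fpkm`) so tau is always computed on the intended
scale. The flooring text of the source protocol immediately precedes its
tau definition, so the chain counts → fpkm → floored log2 → tau is the
reading adopted here; tau's scale invariance makes the difference between
raw and floored inputs small for well-expressed transcripts, but the
floor suppresses spurious specificity from sub-1-FPKM noise.

Tau itself is

$$\tau_i = \frac{1}{n-1} \sum_{j=1}^{n}\left(1 - \frac{a_{ij}}{\max_j a_{ij}}\right)$$

with \(n\) the number of samples (22 in the motivating design). It is 1
for single-sample expression, 0 for uniform expression, scale-invariant,
and monotone under moving expression mass toward the maximal sample. An
all-zero profile is an error by design, not NaN: the removal step owns
that case.

Class distributions of tau are compared with Welch's unequal-variance
t-test (Welch–Satterthwaite degrees of freedom), delegated to
`stats::t.test` and cross-checked in the test suite against the textbook
formulas to ten significant digits. PCA is delegated to `stats::prcomp`
(samples as observations, centering on, scaling off by default).

# Taxonomic assignment

Hits are ranked per transcript by ascending e-value; the strict cutoff
(default `e < 10^-3`) is a required parameter because published analyses
of this kind quote thresholds anywhere between `10^-3` and `10^-8`. Ties
are broken by descending bitscore, then lexicographic subject id — the
ranking needs a total order or assignment would depend on input order.
Taxon labels map to classification labels through a user-replaceable
two-column lookup (`defaultTaxonMap()`), avoiding any live taxonomy
database; unmapped labels become `other`.

The genome-alignment validity rule takes three thresholds: reliable
fraction of the alignment (`minSupport`, inclusive, default 0.99),
transcript coverage (`minCov`, strict, default 0.80) and identity
(`minIdent`, strict, default 0.90). Support is modelled as its own
fraction because the phrasing "99% of the alignment covered 80% of the
transcript" admits two readings; with three independent parameters either
emphasis is configurable and the default encodes both bounds.

# Enrichment filters

**GC read filter.** A pair is kept when the GC of the concatenated mates
is ≥ the threshold (default 46%). Concatenation weights mates by length;
the threshold is inclusive per "46% or higher". GC is computed on the
rounded two-decimal scale used everywhere else (round half to even, so
results do not drift across platforms); ambiguity codes count toward
length but never toward GC.

**Cross-sample identity filter.** Transcripts 100% identical over ≥ k
(default 100) nucleotides in ≥ `minSamples` (default 5) samples are
removed as host background. The implementation indexes canonical
(strand-symmetric) k-mers: a shared identical stretch of ≥ k nt exists
iff a k-mer is shared, so the index is exact for this rule, not a
heuristic. "100% identical" is taken literally — `N` matches nothing,
including another `N`. The transcript's own sample counts toward the
five by default (`includeSelf`), the plain reading of presence "in five
samples"; both monotonicity (in k and in `minSamples`) and idempotence
are asserted as properties in the test suite.

# Homolog clustering

All-vs-all local alignment uses match +1, mismatch −1, affine gaps with
opening 2 and extension 1 (a gap of length L costs 2 + L). Identity is
measured over aligned columns including gap columns — the overlap-local
reading implied by pairing an overlap-length requirement (≥200 nt) with
a similarity requirement (>52%). Both relative strands are tried and the
better score wins; assembled transcript orientation is arbitrary.
Argument order is canonicalised before aligning so the operation is
exactly symmetric even when co-optimal alignments differ in span.

Clustering is agglomerative single linkage on distance 1 − identity, cut
at the edge-emission threshold (distance < 0.48). At that cut single
linkage is exactly the connected components of the match graph — the one
linkage choice that introduces no second free parameter, appropriate
since no cut height beyond the edge threshold is part of the method's
definition. Components are computed with igraph and verified against an
independent union-find oracle on random graphs in the tests. Cluster ids
are assigned by smallest member id and the representative is the longest
member (ties to the smallest id), making output independent of input
order. Clusters below 4 members are dropped as unsupported families;
clusters whose representative is plant-labelled (`host` or
`viridiplantae_other`) are removed; `none` representatives are retained —
absence of a hit is not evidence of plant origin. Pooled cluster
expression is the column-wise sum of member rows.

# What the synthetic generator does and does not emulate

`GeneratorConfig()` defaults encode the study conditions the package
targets: 2,000 + 2,000 transcripts over 22 samples; host GC
Normal(44.5, 3) vs symbiont Normal(53.1, 3) (per-transcript target,
sequence drawn i.i.d. per base with P(G)=P(C)=gc/200 — the simplest
model matching a stated mean); log-normal lengths (meanlog log 1300,
sdlog 0.6 vs meanlog log 420, sdlog 0.5) chosen to echo the roughly
four-fold N50 contrast between plant and fungal assemblies; host breadth
0.9 (Bernoulli per sample); symbiont breadth 0.05, realised as the
stochastic rounding of breadth × nSamples with a minimum of one, so a
symbiont transcript occupies one or two samples and never more — the
confinement the model asserts. Counts are negative binomial (dispersion
0.3, a standard bulk RNA-seq overdispersion figure) around log-normal
base means (meanlog log 100, sdlog 1); draws of zero in an expressing
cell are bumped to one so "expressed" is never silent. Families descend
from one ancestor by i.i.d. per-site substitution at rate 1 − identity
(star phylogeny, no indels — the clustering criterion is identity, not
topology). All randomness derives from one root seed through fixed
per-stage stream offsets, so outputs are byte-identical under a fixed
config and stages are individually reproducible.

Deliberately not emulated: sequencing error profiles, splice isoforms,
rRNA/poly-A artifacts, strand-specific libraries, chimeric assembly,
between-sample library-size variation. Passing tests therefore
demonstrate the statistical machinery — GC/tau recovery, filter
boundaries, family recovery — not robustness to assembly pathology.

# Numerical choices and degenerate inputs

* GC and read-pair GC round half to even at two decimals; filters
  compare the rounded value, so the 46.00/45.99 boundary is sharp.
* N50 is the "sort descending, accumulate to half the total" convention;
  always a member of the input lengths.
* FPKM on a zero-total column returns zeros rather than NaN.
* Tau on an all-zero row, empty sequences, empty length sets, and
  desynchronized mate files are errors with named causes, not silent
  results.
* Biostrings' affine convention charges opening + extension for the
  first gap column; the test-suite oracle implements the same convention
  so score agreement is exact.
* PCA requests beyond the matrix rank are truncated with a warning.

# Problem sizes in the test suite

The suite exercises the full default generator (2,000 + 2,000
transcripts, 22 samples) once for parameter recovery, and elsewhere uses
reduced instances chosen to keep each property readable and the suite
fast: oracle equivalence runs 100 random filter instances of ≤50
transcripts (k = 10 on 60-nt sequences — the same combinatorics as
100-mers on kilobase transcripts at a fraction of the cost) and 100
random match graphs of ≤200 nodes; clustering recovery uses 10 families
of 6 members at 1 kb. These sizes are the package's own trade-off
between coverage and turnaround.

# Known limitations

* FPKM uses within-matrix column totals, not mapped-read totals; with
  very uneven mapping rates the two differ.
* The all-vs-all aligner is exact and quadratic in the number of
  sequences; it is sized for filtered symbiont sets (10^3–10^4
  sequences), not raw assemblies.
* The k-mer filter is exact for the ≥k identical-stretch rule but holds
  all k-mers in memory; billion-read scale would need a disk-backed
  index.
* Classification accuracy on real data is bounded by the hits table
  supplied; the package deliberately never queries a taxonomy service.
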