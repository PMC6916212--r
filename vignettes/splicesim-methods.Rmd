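---
title: "Simulation models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicesim)
```

`splicesim` generates a gene family — genes with exon-intron structure
plus their sets of alternative transcripts — along a rooted guide tree,
and tracks enough ground truth (homology of every nucleotide, the full
event history, transcript lineages) to benchmark spliced-sequence analysis
methods. This vignette explains the models, the tunable parameters, the
numerical choices, and what the package's tests do and do not establish.

## The linear-rates model

Branch lengths of the guide tree are expected **codon substitutions per
codon** on that branch. All other event classes are tied linearly to this
rate: along a branch of length $t$,

* EIC (exon-intron structure change) events per exon: $k_{eic}\,t$,
  split into exon loss / gain / duplication by the relative frequencies
  $(eic_{el}, eic_{eg}, eic_{ed})$;
* TC (transcript change) events per transcript: $k_{tc}\,t$, split by
  $(tc_{rs}, tc_{a5}, tc_{a3}, tc_{es}, tc_{me}, tc_{ir}, tc_{tl})$ over
  creation by random selection, the five elementary alternative-splicing
  types, and transcript loss;
* indel events per codon (exons) or per nucleotide, times $k_{intron}$,
  (introns): $k_{indel}\,t$, split $ci:cd$ into insertions and deletions.

So, e.g., a gene with $n$ exons expects $n\,eic_{el}\,k_{eic}\,t$ exon
losses on the branch. Realized counts are Poisson draws with these
expectations — the natural continuous-process reading of an expected
count, and the same convention for every event class.

Defaults: $k_{nbexons}=1.5$, $k_{eic}=k_{tc}=5$,
$eic=(0.4,0.5,0.1)$, $tc=(0.05,0.1,0.1,0.2,0.1,0.05,0.4)$. These make
exon and transcript counts grow slowly from root to leaves and reflect the
relative prevalence of splicing event types in eukaryotes (exon skipping
most common, intron retention rarest). $k_{indel}=0.1$ (a typical
indel:substitution ratio), $k_{intron}=1.5$ (introns evolve faster than
exons), $ci=cd=0.5$ are package defaults where the calibration source
gives no value; all are exposed as parameters of `sim_params()`.

## Root synthesis

Gene architecture at the root is drawn from four empirical distributions
summarized by their moments (mean, sd): exons per transcript
$(9.62, 8.54)$, transcripts per gene $(1.45, 1.08)$, exon length
$(170.36, 258.86)$ nt, intron length $(3730.30, 20126.39)$ nt. Only the
moments are available, so each law is a **log-normal surrogate**,
moment-matched and then discretized: exon lengths round to multiples of 3
(floor 3 — the model imposes codon-aligned exons), intron lengths to
integers with floor 20 nt (room for both splice-site dinucleotides),
counts to integers with floor 1. For the count laws and exon lengths the
discretization visibly shifts the moments (for transcripts per gene the
naive rounding inflates the mean by ~8%), so the underlying $(\mu,\sigma)$
are recalibrated numerically (Nelder-Mead on the exact discretized-law
moments) until the discretized law itself matches the targets; the
calibration is deterministic and cached. For intron lengths the
discretization bias is negligible relative to the mean and the continuous
moment match is used directly.

One caveat, verified by direct calculation: with std $\gg$ mean the intron
law is so heavy-tailed ($\sigma \approx 1.85$ on the log scale) that the
*sample* standard deviation of even $10^6$ draws fluctuates by tens of
percent (its sampling variance is driven by $e^{8\sigma^2}$). Tests
therefore check the intron surrogate's moments analytically at the law
level and its sample *mean* empirically; a tight sample-std assertion
would test the random number generator, not the model.

The number of exons of the root gene is $\lceil k_{nbexons} \cdot m
\rceil$ where $m$ is a draw of the exons-per-transcript law ($m$ is kept
as the gene's maximum exons per cDNA). The ceiling guarantees an
$m$-exon isoform always exists. Exon sequences are chains of independent
codons from three chained Markov models (position 1 marginal; position 2
conditional on 1; position 3 conditional on the first dinucleotide),
fitted to empirical codon-position frequencies; the printed tables carry
two decimals and one row sums to 0.99, so each row is proportionally
renormalized at construction (shifts of $\le 0.3$ points, within the
sampling noise any consumer of the tables can resolve). Stop codons are
*not* filtered: the chains are sampled faithfully, and a substitution
event that lands on a stop codon redraws uniformly from the 61 sense
codons. Intron sequences are i.i.d. draws from the empirical intron base
composition, then the terminal dinucleotides are overwritten by a draw
from the splice-site distribution (GT-AG 0.98, GC-AG 0.01, "other" 0.01,
the latter uniform over the remaining dinucleotide pairs).

Root transcripts: the count comes from the transcripts-per-gene law; the
first transcript is always a random isoform (also when $tc_{rs}=0$), the
rest are random isoforms or single splicing events applied to a uniformly
chosen existing transcript, with probabilities proportional to the
creation frequencies. "All possible isoforms" is never enumerated —
a random isoform is drawn as (size from the truncated exons-per-transcript
pmf, then a uniform exon subset of that size), which has the same support
without the $2^n$ blowup. Duplicate transcripts are rejected with bounded
retries (20).

## Structure and transcript evolution

Per branch the phases are fixed: **structure → transcripts → sequences**,
and within structure: losses, then gains, then duplications, each phase's
Poisson expectation recomputed from the current exon count. Exon loss
deletes the exon segment and its upstream intron (downstream for the
first exon) — the alternation invariant forces one flanking intron out,
and the upstream choice is a deterministic minimal rule. Losing an exon
removes every transcript containing it. Two guards keep leaves
non-degenerate: the last exon of a gene cannot be lost, and if a loss
cascade would empty the transcript set one random isoform is regenerated
(both logged). Exon gain splits a uniformly chosen intron at a uniform
interior point (both halves keep $\ge 4$ nt; fresh splice sites at the
two new extremities) and inserts a freshly generated exon; duplication
copies an exon in tandem behind a freshly generated intron. Gained and
duplicated exons start **absent** — they join transcripts only through
later creation events, keeping gene-level and transcript-level processes
separate; exon status (absent / alternative / constitutive) is purely a
function of (gene, transcript set).

Transcript creations start from a uniformly chosen template. Alternative
5′/3′ splice-site selection shifts one exon boundary by $3G$ nt
($G \sim$ Geometric(0.5), sign uniform: extension into the flanking
intron or truncation), clipped to keep $\ge 3$ nt of exon and $\ge 4$ nt
of intron; the magnitude law is a package choice (small frame-preserving
shifts dominate in real data). An extension rewrites the dinucleotide at
the new boundary with a draw from the splice-site distribution, so the
new site is a known splice-site type. Mutually exclusive exons swap
membership within a pair of gene-consecutive exons of which the template
contains exactly one. Intron retention includes an intron verbatim
between two gene-adjacent transcript exons — retained introns may break
the reading frame; only exons are frame-constrained. Boundary
adjustments into a retained intron are void (the whole intron is already
in the cDNA).

## Sequence evolution and the homology ledger

Per segment and branch: deletions, then insertions, then substitutions.
Indels follow a **length-proportional event process** over the branch
(exponential waiting times at rate = current length × per-unit rate):
this is exactly "dynamic length adjustment" — after every event the
process rate reflects the new length, so long indel runs neither
over- nor under-shoot the expected count. Indel lengths follow a
truncated power law $P(k) \propto k^{-1.7}$, $k \le 10$ (codons in
exons, nt in introns), the classic empirical indel-length shape.
Deletions clip at segment ends (no cross-segment indels; segments evolve
independently), exons never shrink below one codon, introns never below
4 nt, and the four splice-site positions are immutable — splice-site
evolution is deliberately not modelled, so freezing the terminal
dinucleotides is the only consistent treatment. Substitution counts are
Poisson($n t$) (codons) or Poisson($k_{intron} L t$) (nucleotides);
codon targets are drawn from the substitution-matrix row of the current
codon, intron bases from the composition law excluding the current base.

The 61×61 codon substitution matrix is a **synthetic mechanistic
surrogate** built in code (no published empirical matrix is bundled):
weight $\kappa^{\#transitions} \cdot 0.01^{\#diffs-1} \cdot
\omega^{[nonsyn]}$ with $\kappa = 2$, $\omega = 0.2$, rows normalized,
zero diagonal (an event always changes the codon). It reproduces the
qualitative structure of empirical codon exchange matrices — transition
bias, purifying selection, strong multi-hit damping — and is replaceable
via `codon_substitution_matrix()` arguments.

Every nucleotide is assigned a global **column id** at birth;
substitutions preserve ids, deletions drop them, insertions mint fresh
ones. The true alignments are built at output time by an anchored merge:
each tree node's full column vector (pre-order) is folded into a global
order in which inherited columns act as anchors and mutually unalignable
independent insertion blocks are interleaved deterministically by
traversal rank. Folding in pre-order guarantees consistency: a child's
inherited columns always appear in its parent's (hence the master's)
order, so every sequence maps to a strictly increasing set of columns —
violated only by a genuine ledger bug, which the alignment builder treats
as an internal error. Per-segment RNG sub-streams are derived by hashing
(seed, node, segment id), so per-branch sequence evolution is reproducible
independent of segment iteration order.

## Outputs, orthology, and metrics

Splicing-ortholog groups are lineages: every transcript creation starts a
fresh lineage id, inheritance along a branch preserves it, so leaf
transcripts grouped by lineage are exactly the sets with no splicing
event anywhere in their history; the groups partition the leaf
transcripts by construction, which the tests re-verify. Exon coordinates
are emitted in GTF convention (1-based inclusive, strand `+`; the
simulation is strandless), alignments as multi-FASTA with gap `-`.

Alignment precision is the fraction of residue pairs of the estimated
alignment present in the true one, recall the converse, F their harmonic
mean, with $0/0 \to 1$ for precision/recall on empty pair sets and
$F = 0$ when $P + R = 0$. The Rand index is the fraction of item pairs on
which two clusterings agree. Both are character-agnostic and are tested
against independent brute-force enumerations.

## Problem sizes in the test-suite

The packaged checks use: $2\times10^5$ draws for Markov-chain cell
recovery (three binomial SDs plus the tables' two-decimal rounding),
$10^6$ draws for length-sampler means (2% relative), $10^4$ replicates
for the first-order exon-count growth check on a 10-exon gene
($t = 0.02$, where the first-order expansion
$n(1 + (eic_{eg}+eic_{ed}-eic_{el})k_{eic}t)$ and the exact phase product
differ by well under the assertion width), 100 random small-tree
simulations for the structural property suite, and 30 families on each of
three reference species trees (primates; primates+rodents; amniotes) for
the end-to-end invariant sweep. Structural unit tests run on scaled-down
generative models (short exons/introns); all end-to-end checks run at the
full default parameters.

## What the tests do not show

The generator emulates gene-architecture statistics and a homogeneous
substitution/indel process. It does not model: splice-site sequence
evolution, motif conservation, within-segment rate heterogeneity,
codon dependence within exons, intron gain/loss as structure events, or
gene duplication/loss at the tree level. Passing tests certify internal
consistency and calibration to the packaged distributions — not realism
of any particular biological family. Benchmarks built with `splicesim`
share these assumptions, and conclusions about aligners or clusterers
should be read accordingly (e.g. aligners exploiting splice-site motifs
gain no advantage here by construction).
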