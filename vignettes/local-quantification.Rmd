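---
title: "Local quantification of novel transcripts with minimum spanning bundles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local quantification of novel transcripts with minimum spanning bundles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Expression atlases precompute abundances for known gene models, but a newly
assembled transcript — typically a lncRNA with no functional annotation —
is absent from them, and re-quantifying whole RNA-Seq libraries for every
query is far too slow for interactive use. `msbquant` exploits the locality
of RNA-Seq quantification: fragments can only inform the abundance of
transcripts they could have come from, so the genome decomposes into
independent units of estimation, and a single novel transcript only ever
requires work inside one such unit.

## Bundles and the minimum spanning bundle

A **bundle** is a maximal continuous genomic region covered by overlapping
fragments and/or known gene models, where gaps of at most 50 bp are
tolerated ("covered" is judged on the fragment's span, i.e. leftmost to
rightmost aligned base over both mates). Formally, `build_bundle_index()`
takes the union of fragment spans and transcript spans on each chromosome
and merges transitively: two intervals join when they overlap or when the
gap between them — `c - b` for `[a,b)` followed by `[c,d)` — is `<= 50`.
A gap of exactly 50 bp merges; 51 bp splits. Two properties follow:

* distinct bundles are separated by more than the gap threshold, so no
  fragment span can touch two bundles — expression estimation inside one
  bundle is independent of all others;
* merging is monotone: growing the threshold never increases the bundle
  count.

The **minimum spanning bundle (MSB)** of a novel transcript is obtained by
`infer_msb()`: start from the transcript's genomic span, merge in every
indexed bundle that overlaps it or lies within the gap threshold, and
iterate to a fixed point. The fixed point makes the MSB exactly the bundle
that would exist had the transcript's span been part of the interval set
when bundles were built — the property the test suite checks against an
independent re-merge oracle, and the reason the local result can equal the
global one. Merging within-threshold neighbours (not only overlapping
bundles) keeps the MSB consistent with the bundle definition itself.

Bundles are strand-agnostic (the bundle definition involves only genomic
continuity) and are built internally from the alignment plus the reference
annotation rather than by invoking an external assembler: this removes a
binary dependency, and makes the whole pipeline hermetic and testable.
The index is persisted as a small versioned TSV per sample
(`save_bundle_index()` / `load_bundle_index()`), so the expensive whole-file
pass happens once per sample, not once per query.

## Within-MSB abundance estimation

`quantify_in_msb()` fetches the fragments overlapping the MSB and runs an
expectation–maximisation mixture model over the novel transcript together
with the reference transcripts inside the MSB.

**Compatibility.** A fragment is compatible with a transcript iff all its
aligned blocks lie in the transcript's exon union and every splice gap in
its alignment equals a transcript intron exactly; for paired fragments both
mates must satisfy this, in which case the fragment's implied length on the
transcript's mature sequence is well defined. The inner mate gap is
unobserved sequence and may span any mixture of exons and introns.

**Likelihood.** Conditional on arising from transcript $t$ with mature
length $L_t$, a compatible paired fragment $f$ with implied length
$\ell_t(f)$ has weight

$$w_t(f) = \frac{\phi(\ell_t(f);\mu,\sigma)/Z_t}{\max(L_t-\ell_t(f)+1,\,1)}$$

where $\phi$ is the normal fragment-length density, $Z_t$ truncates it to
the lengths observable on $t$, and the denominator counts the start
positions that could have produced the fragment. The implied-length term is
essential: a fragment whose mates straddle an exon skipped by one isoform
but retained by another implies very different insert sizes on the two,
and this is the dominant signal separating isoforms that share all their
exon sequence. Unpaired fragments carry no insert information and fall
back to $1/\mathrm{efflen}(t)$; weights are floored at $10^{-15}$ so a
compatible fragment is never silently dropped; with $\sigma = 0$ the
length term is disabled entirely and the weights reduce to pure
$1/\mathrm{efflen}$ compatibility weights (useful for closed-form checks).

**EM.** Mixture weights $\theta_t$ (the fraction of fragments originating
from $t$) start uniform over transcripts with at least one compatible
fragment — there is no randomness anywhere in quantification, and
transcripts with identical evidence split exactly equally. Fragments are
collapsed into equivalence classes by their weight pattern (which leaves
the fixed point unchanged), the E-step distributes each class
proportionally to $\theta_t w_t$, the M-step re-estimates $\theta$, and
iteration stops when $\max_t |\Delta\theta_t| < 10^{-10}$ or after 5000
iterations. The tight default matters: likelihoods near isoform ambiguity
have long shallow ridges along which a loose `theta`-change criterion stops
visibly short of the MLE. The expected fragment count is
$\theta_t \times N$ with $N$ the number of assignable fragments, so counts
are conserved by construction; the log-likelihood is recorded per
iteration and is non-decreasing.

**Fragment-length model.** The insert-size distribution is estimated
inside the MSB from paired fragments whose implied length is unambiguous —
compatible with at least one transcript and implying the *same* length on
every compatible transcript. Restricting instead to uniquely-assignable
fragments would condition on junction-straddling evidence, which selects
longer-than-average inserts and biases the mean upward by several percent.
When fewer than 20 usable fragments exist the model falls back to a fixed
mean 200 bp / sd 50 bp, which keeps single-end data and sparse regions
working.

## From relative to corrected FPKM

The within-MSB **relative FPKM** of a transcript uses the local fragment
total as its depth denominator:

$$\mathrm{relFPKM}_t =
  \frac{\hat{c}_t}{(\mathrm{efflen}_t/10^3)\,\times\,(N_\mathrm{local}/10^6)}$$

with effective length $\max(1, L_t - \mathrm{round}(\mu) + 1)$ (the
mean-length formula; the full distribution integral is deliberately not
used — the difference is negligible at these insert sizes and the simple
form is exactly invertible in tests). Rescaling by the depth ratio gives
the **corrected FPKM**,

$$\mathrm{FPKM}_t = \mathrm{relFPKM}_t \times
  \frac{N_\mathrm{local}}{N_\mathrm{global}},$$

which is algebraically the FPKM a whole-transcriptome run would report,
because the local and global estimates of $\hat c_t$ coincide (bundle
independence) and the $N_\mathrm{local}$ factors cancel. Totals are
fragment *counts* by default; `mode = "bases"` uses summed aligned base
totals instead, whose ratio differs from the count ratio only by the
local/global mean fragment length — both are carried through the index and
the per-transcript records, so the choice is explicit rather than baked in.
Fragments that overlap the MSB but are compatible with none of its
transcripts still count toward $N_\mathrm{local}$: the local total plays
the sequencing-depth role, not the assigned-count role.

## Across samples

`geometric_normalize()` implements median-of-ratios size factors over
reference-transcript corrected FPKMs: per reference transcript that is
nonzero in every sample, compute its geometric mean across samples; a
sample's factor is the median ratio to those geometric means, rescaled so
the factors have unit geometric mean (hence their product is exactly 1).
With one sample all factors are 1; when no reference transcript is nonzero
everywhere the factors default to 1 with a warning. Replicates of the same
cell type are averaged arithmetically **after** normalisation
(`average_replicates()`); averaging before would mix library depths into
the biological signal. Size factors should be driven by reference
transcripts, not the novel queries — `geometric_normalize()` accepts a
separate reference matrix for exactly that purpose.

## The synthetic-data generator

`simulate_rnaseq()` produces a self-contained experiment on an artificial
single-chromosome genome: genes laid left to right with an explicit list of
intergenic gaps that must include values on both sides of the 50 bp
threshold (so bundle fusion and separation are both exercised); 2–4
isoforms per gene built as exon-chain subsets (first and last exon always
retained, subsets distinct); exon lengths 150–400 bp, intron lengths
100–500 bp; truth abundances log-normal (meanlog 1, sdlog 1); paired
75 bp reads from fragments whose lengths are normal with mean 200 bp and
sd 50 bp, clamped to the isoform; fragment start positions uniform on the
mature sequence. Expected fragment counts are proportional to
abundance × effective length and realised multinomially, so the truth
table's `true_fpkm`, recomputed from the realised counts, is the exact
value an ideal quantifier would report. Outputs are a GTF, a sorted and
indexed BAM (plus the SAM text), a per-transcript truth table, a
per-fragment source table and a JSON config echo — all deterministic given
the config seed. A separate `frag_seed` redraws only the sequencing noise,
which is how replicate samples of one cell type are produced.

The generator emulates what the estimator assumes — uniform start
positions, a clean insert-size distribution, perfect alignments, no
sequencing error, no positional or GC bias, a single chromosome. Passing
tests therefore demonstrate the correctness of the locality argument and
of the estimation machinery on model-faithful data; they do not
demonstrate robustness to alignment artefacts or bias patterns of real
libraries.

## The hold-out evaluation and problem sizes

The validation protocol re-submits known transcripts as novel:
`holdout_protocol()` removes a uniform sample of transcripts from the
annotation and returns them as queries. Two distinct questions are asked:

* **Local–global equivalence** (the core claim): with 50 of ~59
  transcripts removed at once, each query's corrected FPKM from the
  MSB-local path is compared with a whole-file quantification of the same
  reduced annotation plus that one transcript. These must agree to
  relative $10^{-6}$ — same estimator, same bundle, different route.
* **Abundance recovery**: each query is quantified against the annotation
  minus that one transcript (leave-one-out) and compared with truth. The
  leave-one-out form matters at desk scale: removing 50 of 59 transcripts
  simultaneously leaves an 85%-incomplete reference whose missing isoforms'
  fragments *must* be misassigned by any estimator, a regime the
  genome-scale setting this emulates (hundreds removed from hundreds of
  thousands) never approaches.

The shipped evaluation uses 20 genes (~60 isoforms), 200,000 paired
fragments and 50 held-out transcripts; smaller configurations (3 genes,
20,000 fragments) back the per-module tests. At these sizes recovery is
tight for well-identified transcripts, while a minority isoform that shares
every exon and junction with abundant siblings can still carry a relative
error slightly above 10% — that residual is MLE sampling variance under
genuine non-identifiability (it persists when the estimator is handed the
true fragment-length model), not estimator bias.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GTF (1-based inclusive)
  and SAM (1-based) convert at the boundary. Fragment counting uses
  primary alignments only, one count per query name; strand is ignored for
  counting (unstranded protocol assumed) and retained for reporting.
* Region fetches pad the query window by 5 kb and filter on the
  mate-merged span, so a mate outside the region whose inner gap covers it
  is still found; for bundle-consistent regions this is exact.
* An MSB on a chromosome absent from the index is the transcript span
  alone; with no overlapping fragments every FPKM is 0. A zero global
  total raises an error (depth undefined) rather than returning 0.
* Transcripts inside a quantified set are processed in sorted id order, so
  results are independent of caller-supplied ordering down to floating
  point.
* Effective length is floored at 1 bp; relative FPKM is defined as 0
  whenever either denominator is 0.

## Limitations

Single-end libraries lose the implied-length signal and will separate
nested isoforms poorly. CRAM input, stranded protocols, multi-mapping
reads beyond primary-alignment counting, GC/positional bias correction,
uncertainty intervals, and novel isoform *assembly* are all out of scope.
Numeric agreement with any particular external quantifier is not a goal;
internal local/global consistency is.
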