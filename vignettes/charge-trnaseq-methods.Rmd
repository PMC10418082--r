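---
title: "Methods: from charge tRNA-Seq reads to aminoacylation levels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from charge tRNA-Seq reads to aminoacylation levels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnacharge)
```

## The measurement

Charge tRNA-Seq turns a chemical distinction into a sequence distinction.
The amino acid esterified to the 3'-terminal A of a charged tRNA protects
the 3' cis-diol from periodate oxidation; uncharged tRNAs are oxidized and
lose their terminal base by β-elimination. After adapter ligation and
sequencing, a charged molecule reads out ending in `...CCA` and an
uncharged one in `...CC`. Charge of a species is then simply

$$\mathrm{charge} = 100 \cdot \frac{n_{CCA}}{n_{CCA} + n_{CC}}\ \%$$

computed over *raw* read counts: charge is a ratio, so PCR duplication
inflates numerator and denominator alike and UMI correction is
intentionally not applied there. Relative expression (RPM) by contrast
counts molecules and is UMI-corrected: reads with identical sequence *and*
UMI count once.

Everything else in the package exists to make those two numbers reliable
for a gene family that is short, repetitive, and riddled with RT-hostile
modifications.

## Read processing

Merged reads carry `UMI (10 nt) + tRNA portion + adapter barcode + splint
context`. Demultiplexing assigns a read to an adapter when its 3' end
contains a substring within Hamming distance 1 of that adapter's
barcode + splint-context sequence; two adapters matching makes the read
ambiguous, and adapter tables are validated so that equal-length search
sequences are pairwise more than distance 2 apart, making distance-1
assignment unambiguous by construction. The search is restricted to a 3'
window of the search-sequence length plus 4 bases: the matching rule says
"substring", and an unbounded search would occasionally hit spurious
internal matches in the tRNA body. Only substitutions are tolerated
(Hamming, not edit distance) — indels inside a 5–8 nt barcode are rare and
indistinguishable from a neighbouring barcode in practice.

The first 10 bases of the trimmed read are the UMI (a purine plus 9 random
nucleotides on the RT oligo, hence $2 \times 4^9 = 524{,}288$ possible
sequences). 5' non-template bases added by the RT are *not* trimmed: the
local alignment soft-clips them for free. UMIs containing up to 2 Ns stay
in UMI-corrected counting; beyond that the UMI is uninformative and the
read contributes to charge only.

As a complexity QC, the observed number of distinct UMIs is compared with
the occupancy expectation for $n$ uniform draws from $k$ labels,
$E[X] = k\,(1-((k-1)/k)^n)$. The same formula with the roles of $n$ and $k$
exchanged circulates in write-ups of this QC; the two are numerically close
while $n \ll k$ but only the occupancy form tracks simulation once the UMI
space saturates, which is exactly when the QC matters. We therefore default
to the occupancy form and keep the swapped-role variant behind
`literal_roles = TRUE`. `expected_unique_umis(1000, 524288)` agrees with a
10,000-replicate Monte-Carlo to well under 1%.

Downsampling to a fixed cap (default 2 × 10⁶ reads) uses a seeded uniform
`sample.int` on the in-memory read vector; a streaming reservoir would give
the same distribution and is unnecessary here.

## Alignment to a masked reference

tRNA references are small (hundreds of sequences), so heuristic seeding
buys nothing and risks missing the true best hit for heavily modified
reads. The aligner is exhaustive Smith–Waterman with affine gaps, written
in C++ and verified cell-for-cell against an independent plain-R dynamic
program in the test suite. Scoring defaults: match +1, mismatch −3, and a
flat 0 for any column whose *reference* base is N — masked positions can
neither help nor hurt. Gap penalties are interpreted as
$\mathrm{cost}(L) = \mathrm{open} + \mathrm{ext}\,(L-1)$ with open = 6,
ext = 3; what matters for correctness is that the implementation and its
oracle share one convention, and they do.

Design choices worth stating explicitly:

- The e-value threshold a database-search engine would use is replaced by a
  raw score floor (`min_score`, default 20). E-values model random-database
  statistics that are meaningless for a fixed few-hundred-sequence
  reference, and a score floor is deterministic.
- Ties among transcripts at the best score are merged into the annotation
  (up to 3 reported). Uniqueness flags at transcript / anticodon /
  amino-acid level are computed over *all* tied transcripts, not the
  reported 3, so truncation can never manufacture uniqueness. More than 3
  ties flags the read over-tied.
- Traceback ties are broken diagonal > deletion > insertion, and the
  first-scanned end cell wins on score ties, so misincorporation profiles
  are bit-reproducible.
- Plus strand only: the assay's read structure fixes the orientation.

The 3'-end call is a reconstruction from the assay design (no published
rule exists): a read is `CCA` when its 3'-terminal base aligns as a match
to the reference's terminal A and the last three aligned columns are
matches; `CC` when its terminal base matches the penultimate C; everything
else — truncated ends, terminal mismatches (which local alignment clips) —
is `other`. `other` reads are excluded from charge (they are uninformative
about protection) but kept in RPM (they are real molecules). Because the
call requires terminal *matches*, the three CCA positions are never
maskable.

## Misincorporation profiles

Modifications leave fingerprints: mismatches, small gaps, and RT stops.
For each read with a unique transcript annotation the package re-runs
Smith–Waterman against the *unmasked* transcript under a softer scheme
(match +1, mismatch −2, gap open 3, extend 2) that keeps
modification-induced errors inside the alignment instead of clipping them.
Per position, with UMI-corrected counts: the mismatch fraction, the gap
fraction (a deletion is attributed to its 5'-most deleted base, an
insertion to the reference index 3' of it — an arbitrary but fixed and
testable convention), and the RT-stop percentage.

RT stops need a direction and a denominator, neither of which is standard.
cDNA synthesis starts at the tRNA 3' end, so coverage is non-increasing
moving 3'→5' and falloff truncates the 5' side of reads. We define

$$\mathrm{rt\_stop}(p) = 100 \cdot \frac{\mathrm{cov}(p+1) - \mathrm{cov}(p)}{\max_q \mathrm{cov}(q)}$$

the percentage of molecules (relative to maximal 3'-side coverage) whose
alignment terminates before reaching $p$. Re-alignments spanning fewer than
10 reference positions are excluded as spurious micro-alignments.

## Reference masking

A hypermutated position costs a read 4 score points against its true
transcript (losing a +1 match, gaining a −3 mismatch), which is often
exactly enough to tie it with a sibling transcript — collapsing transcript-
and sometimes anticodon-level resolution. Masking converts such positions
to N (scored 0), removing the penalty without rewarding the wrong
reference.

Mask construction: position-wise mismatch frequencies from the unmasked
re-alignments, filtered to ≥ 200 (UMI-corrected) observations per
transcript and ≥ 100 per position; positions with frequency ≥
`min_mut_freq` are masked ("minimum ... to trigger" is read as inclusive,
and the transcript-observation filter uses UMI-corrected counts, consistent
with the profiles they derive from). An abundant transcript then donates
masked positions to highly similar low-coverage ones: for ordered pairs
whose pairwise alignment score reaches `frac_max_score` times the *smaller*
of the two self-alignment scores (normalizing by the smaller self-score
keeps the ratio ≤ 1 for unequal lengths), a donor position is copied iff
both sequences carry the same nucleotide there and the acceptor position
has fewer than 100 observations. Because masking shifts annotations, the
whole cycle iterates `iteration` times.

The four tuning parameters are grid-searched (defaults: `unique_anno` ∈
{T, F}, `min_mut_freq` ∈ {0.05, 0.10, 0.15, 0.20}, `frac_max_score` ∈
{0.85, 0.90, 0.95, 1.00}, `iteration` ∈ {1, 2, 3}) with the objective of
minimizing the percentage of reads assigned to transcripts with multiple
anticodons. Minimizing multi-*transcript* reads instead is tempting but
degenerate: it rewards masks that leave only one member of a family
alignable, handing truncated reads a unique annotation they have not
earned. Ties go to the smaller mask, then stable grid order. A
`unique_anno_float`-style fractional weighting of multi-annotation reads
has been described informally; the boolean form is implemented (when
`unique_anno = FALSE`, a read tied among up to three transcripts counts
toward each).

## The titration model

Mixing intact RNA A with deacylated RNA B at nominal percentages does not
guarantee transcript $i$ is mixed at those percentages: deacylation
depletes some species. With $T_i^A$, $T_i^B$ the replicate-mean charges of
pure A and pure B, and $F_i$ the concentration of $i$ in B relative to A,

$$T_i^{AB}(p) = \frac{p\,T_i^A + (100-p)\,T_i^B F_i}{p + (100-p) F_i}.$$

At $p = 100$ and $p = 0$ this returns the endpoints for any $F$, so the two
endpoint mixtures define $T^A$ and $T^B$ and the six interior ratios (of
the eight-point design 100/0, 85/15, 70/30, 55/45, 40/60, 25/75, 10/90,
0/100) carry all information about $F_i$. The fit pools all interior
replicates into one sum of squared residuals (fitting replicate means would
discard the replicate weighting) and minimizes over $F_i \in [0.25, 4]$.
Errors (measured − predicted) binned by adapter barcode expose ligation
bias; a +3 pp planted bias is recovered by its bin median in simulation.

## The decay model

Aminoacylation decays in first order under fixed buffer conditions:

$$N(t) = N_0 \left(\tfrac{1}{2}\right)^{t/t_{1/2}} + N_\infty,$$

with bounds $N_0 \in [0, 100]$ %, $t_{1/2} \in [1, 10^5]$ min,
$N_\infty \in [0, 3.5]$ %. $N_\infty$ absorbs the small CCA-ending fraction
that survives full deacylation. Note the model's value at $t = 0$ is
$N_0 + N_\infty$, although $N_0$ alone is often loosely called "charge at
time zero"; the fit reports both ($N_0$ and `charge_t0`) rather than
guessing which a reader wants. The default design is $t = 0$ plus 4, 8, 16,
32 min, 1, 2, 4, 8, 16, 40 h — 11 timepoints, 4 replicates.

"BFGS with bounds" is realized as L-BFGS-B (`stats::optim`): plain BFGS has
no bound support, and a projected quasi-Newton is the standard equivalent.
Fits are multi-start (a data-driven start from endpoint means and a
half-crossing estimate of $t_{1/2}$, a bounds-midpoint start, and two
perturbations); convergence tolerance is `factr = 1e2` (≈ 1e-14 relative)
with 500 iterations max, and non-convergence or a bound-pinned $t_{1/2}$
(the signature of a non-decaying series) is flagged, never silent.

Bootstrap CIs resample replicate noise at fixed design points: each of
1000 iterates draws one replicate value per timepoint, refits, and the 95%
CI is the 2.5/97.5 percentile band. This is deliberately *not*
case-resampling — the design (timepoints) is fixed by the experiment; only
measurement noise is random. Bootstrap refits start from the group's point
estimate; with a fixed seed the CIs are bit-reproducible. On 50 simulated
groups with half-lives log-uniform in [20, 2000] min and 1 pp noise, the
$t_{1/2}$ CI covers the truth for ≥ 90% of groups.

## What the simulator does and does not emulate

`simulate_reads()` reproduces the *informational* structure of the assay:
transcript sampling by abundance, CCA/CC ends by true charge (genuinely
binomial), geometric RT falloff from the 3' end, hotspot mismatches/gaps
with per-position probabilities, uniform sequencing error, purine-led UMIs,
barcoded adapters, and optional UMI-preserving duplication. The model-level
simulators (`simulate_titration`, `simulate_decay`) add Gaussian noise
clipped to [0, 100] — matching the residual structure the least-squares
fits assume, whereas the read-level simulator produces true binomial charge
noise.

Not emulated: quality-score structure (qualities are constant), ligation
sequence preferences beyond a configurable per-adapter offset, PCR
chimeras, context-dependent error profiles, and the correlated
modification patterns of real tRNAs. Passing tests therefore demonstrate
that the *computational* path is correct and well-calibrated under the
stated noise model — not that any particular biological sample will behave
this way.

## Problem sizes and numerical notes

The test suite and the acceptance script run at sizes chosen to make the
statistical checks sharp while staying quick on one core: 8-transcript
references with 50,000 reads for charge recovery (≥ 1000 reads per
transcript gives 3-SE bands of about ±2–4 pp), 3,000 reads on a
two-transcript confusable pair for masking efficacy, 240 random pairs for
the alignment oracle, 10,000 Monte-Carlo replicates for the UMI
expectation, and 50 groups × 1000 bootstrap iterates for CI coverage.
Reference-scale behaviour (hundreds of transcripts, millions of reads) uses
the same code paths; the aligner and demultiplexer are compiled and scale
linearly in reads × reference size.

Degenerate inputs are handled explicitly: empty references and FASTA files
error; reads at or below UMI length are rejected with a category of their
own; zero-coverage positions carry `NA` fractions rather than silent zeros;
a charge group with an empty denominator is flagged, not dropped; masks
referencing out-of-range positions name the transcript and position in the
error.

## Known limitations

- CCA/CC calling requires the terminal bases to survive sequencing error;
  terminal errors push reads to `other`, slightly shrinking the charge
  denominator (unbiased, but a loss of power at high error rates).
- Mask donation maps positions through a single optimal pairwise alignment;
  for families with ambiguous internal alignments the mapped position can
  differ from a structural alignment's choice.
- The grid search re-runs the full masking cycle per combination; with the
  default 96-combination grid on large read sets this is the dominant cost
  and is best run once per reference, not per sample.
- `N_\infty` is unidentifiable when the sampled window never approaches the
  asymptote; the fit then reports a wide bootstrap CI rather than refusing.
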