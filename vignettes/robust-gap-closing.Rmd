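---
title: "Closing genome gaps by robust regression of read coordinates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closing genome gaps by robust regression of read coordinates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regapcloser)
```

## The problem

Draft genome scaffolds carry N-runs ("gaps") where the assembler could order
contigs but not reconstruct the sequence between them. Local assembly of the
paired-end reads that originate in a gap can recover that sequence, but two
things routinely break greedy overlap-layout-consensus assembly there:
tandem repeats, whose unit-shifted self-alignments create false overlaps
that collapse or expand the copy number, and chimeric reads, which connect
distant loci. This package treats gap-filling as a robust statistics
problem: false overlaps are outliers in a linear model, and the layout is an
M-estimate that bounds their influence.

## The model

Set a coordinate axis along the gap with origin 0 at the last base of the
left flanking contig. Each collected read $r_i$ has an unknown coordinate
$\beta_i$, defined as the position of its **ending (rightmost) base** on
that axis. A significant pairwise alignment between reads $i$ and $j$
observes their coordinate difference:

$$ y^{(i,j)} = \beta_j - \beta_i + \varepsilon^{(i,j)} . $$

Stacking the $m$ observations gives $Y = X\beta + \varepsilon$, where each
row of the sparse design matrix $X$ holds exactly one $-1$ and one $+1$:
$X$ is the oriented incidence matrix of the overlap graph. Its weakly
connected components are the contigs of the local assembly; each component's
incidence block has rank $n_k - 1$, so one read per component is anchored at
a fixed coordinate to make the block full column rank. Sequencing errors
make $\varepsilon$ essentially zero for true overlaps of short reads, while
false overlaps produce gross errors at multiples of the repeat unit.

Coordinates are estimated in two steps:

1. **Huber M-estimation.** Minimise
   $\sum_i \rho_H(y_i - x_i^\top \beta)$ with
   $\rho_H(\varepsilon) = \varepsilon^2/2$ for $|\varepsilon| \le c$ and
   $c|\varepsilon| - c^2/2$ beyond. The loss is convex, so iteratively
   reweighted least squares (weights $1$ inside the knot, $c/|\varepsilon|$
   outside) converges to the global optimum from the ordinary
   least-squares start; each iteration solves the sparse weighted normal
   equations $X^\top W X \beta = X^\top W Y$. Residuals enter in raw base
   pairs — no robust-scale standardisation — so the tuning constant $c$ is
   in the data's units, and the derivative of the loss being bounded means
   no single false overlap can displace the layout arbitrarily.
2. **Trimmed refit.** Observations with $|$residual$| > r_o$ at the
   M-estimate are flagged as outliers and an ordinary least-squares refit is
   computed on the rest. Trimming can disconnect a component; each resulting
   sub-component is re-anchored and fitted on its own rows. Final
   coordinates are rounded to the nearest integer (ties away from zero).

Before any of this, two devices keep the outlier fraction low. Each read
gets a **prior coordinate** $p_i$ from its mate's mapping position and the
library insert size, and only pairs with $|p_i - p_j| < \Delta d$ are
aligned — this turns the all-against-all quadratic alignment into a linear
sweep and removes overlaps between distant repeat units outright. And when
one pair of reads has several significant alignments (the signature of a
tandem repeat), the pattern whose implied offset is **closest to the prior
difference** is selected, not the highest-scoring one.

Two **pseudo reads** cut from the flanking contigs join the model: the left
one anchors the axis at 0; the right one's fitted coordinate, when both land
in one component, measures the gap length. If both pseudo reads end up in
one component the gap is closed with the consensus strictly between them;
if only one does, the corresponding flank is extended; layouts containing
neither are discarded as unreliable.

## Overlap enumeration

`align_pair()` enumerates *all* significant overlap configurations of two
reads, not just the best one, by Waterman–Eggert suboptimal alignment: run
a local affine-gap Smith–Waterman, report the optimum, mask its aligned base
pairs, and repeat until the score drops below `min_score` (or
`max_patterns` alignments have been produced). Masking is what makes the
enumeration meaningful: without it, a strong alignment spawns a cloud of
"patterns" that are merely the same path with a trailing gap, landing on
neighbouring offset diagonals with near-identical scores and swamping the
prior-compatible selection. On a tandem repeat the masked enumeration
returns exactly one pattern per unit shift. Patterns must further look like
genuine overlap/dovetail/containment configurations: at each end of the
alignment the unaligned overhang on the side where both reads continue is
capped at `max_hang` (5 bp), and both aligned spans must reach
`min_overlap`. Remaining patterns within 2 bp of a higher-scoring one's
offset are suppressed as rounding duplicates.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `c` (`huber-c`) | 2 bp | loss knot; smaller resists outliers harder at some efficiency cost |
| `r_o` | 10 bp | trimming threshold; must sit *below* the gross-error magnitude, so for repeat units shorter than ~10 bp use `r_o < u` |
| `alpha` | 2 bp | IRLS stop: max coordinate change |
| `delta_d` | `3·sqrt(v_i² + v_j²)`, 10 bp floor | candidate window from the libraries' insert SDs |
| `match/mismatch/gap open/extend` | +1 / −2 / −4 / −1 | alignment scores |
| `min_score`, `min_overlap` | 15, 15 | overlap significance |
| `flank_len` | 150 bp | pseudo-read length |
| recruitment window | `mu + 3v` | how far from a breakpoint an anchoring mate may map |

A resolution limit worth stating explicitly: discriminating repeat units of
size $u$ requires the *prior difference* noise, roughly $\sqrt{2}\,v$, to
stay clearly below $u/2$ — otherwise the prior-compatible selection picks
the wrong unit for read pairs wholly inside the repeat array, and once the
false overlaps across a graph cut outnumber the true ones no robust
estimator can recover the cut (a consistently shifted placement is
observationally equivalent to the truth). With a tight modern paired-end
library ($v \approx 5\%$ of the insert) a 69 bp unit is comfortably inside
this limit; with $v \gtrsim u/2$ it is not, regardless of coverage.

## The simulator, and what it does not emulate

`simulate_genome()` / `make_draft()` / `simulate_paired_reads()` generate a
uniform-composition genome with tandem repeats implanted verbatim, a draft
whose N-runs may mis-state the true gap size (`size_error`), and FR read
pairs with truncated-normal insert sizes (outer-distance convention, which
the documentation states explicitly because conventions differ), uniform
substitution errors with the matching flat Phred score, and a fixture SAM
that places every read at its true draft coordinate, flagging reads from
gap interiors as unmapped with their mate's coordinates — the behaviour a
mapper exhibits for reads originating inside N-runs. Defaults follow the
study conditions exercised by the tests: 100 bp reads, 30× coverage,
μ = 500, v = 50, 1% substitution errors for the end-to-end genome; an
84×-class error-free library for the tandem-repeat worked examples.

What the simulator deliberately does not model: indel sequencing errors
(short-read errors are overwhelmingly substitutions at this scale, and the
observational errors of true overlaps are then exactly zero), chimeric
fragments, coverage bias, quality decay along the read, and multi-scaffold
drafts with inter-scaffold repeats. Passing tests therefore demonstrate the
statistical machinery — recruitment geometry, overlap selection,
robust layout, consensus — under clean mapping, not robustness to mapper
artefacts on real data, where an external aligner (e.g. bwa) should produce
the input SAM.

## Numerical choices

* The weighted normal equations are solved by `Matrix`'s sparse Cholesky
  factorisation. Per-gap systems have at most a few thousand unknowns, where
  a direct sparse solve is exact and faster to reason about than an
  iterative Krylov solver with tolerances; anchored coordinates are
  eliminated into the right-hand side, so anchors hold exactly and each
  component's reduced system is nonsingular by construction.
* IRLS starts at the (initially weighted) least-squares solution, caps at
  100 iterations, and declares convergence when no coordinate moves by
  `alpha`. For oracle comparisons in the tests `alpha` is dropped to 1e−7;
  the default 2 bp is all the consensus stage needs, because its banded
  (±3 columns) re-alignment absorbs residual one-to-two bp offsets.
* Insert-size statistics use median and 1.4826×MAD (chimera-resistant),
  with the SD floored at 1 bp.
* Gap sizes from spanning pairs: the raw rule `median(mu − d_L − d_R)` is
  biased because a pair is only *observed* spanning when its insert exceeds
  the gap plus both read lengths; the estimator corrects this with the
  closed-form conditional mean of a truncated, length-weighted normal,
  iterated to a fixed point. The raw rule remains available
  (`correct_bias = FALSE`).
* Duplicate observations for the same read pair are kept as independent
  rows; a read pair observed by two libraries is two measurements.
* One-sided extensions are capped at the N-run length when spliced, so an
  overshooting extension can never duplicate bases of the opposite flank.
* Consensus posteriors use a uniform base prior with per-read error
  probabilities from Phred scores, error spread evenly over the three
  wrong bases; ties break lexicographically; output Phred is capped at 60.
  A count-based mode (`use_qualities = FALSE`) exists for data with
  uninformative qualities.

## Design choices made where the design was open

* **Anchoring precedence.** When both pseudo reads share a component, only
  the left one anchors (at 0); the right one's coordinate is *estimated*,
  which is precisely how the gap length is measured. A component with no
  fixed-coordinate member is anchored at its smallest-prior member's prior.
* **Both flanks extended.** When the two pseudo reads survive in two
  different components, the present implementation emits the larger
  component's one-sided extension (ties prefer the left) rather than both;
  the conservative single-status result keeps splicing unambiguous.
* **Unmapped-mate orientation.** The fixture SAM stores raw as-sequenced
  bases for unmapped reads. A recruit anchored on the left flank is
  therefore reverse-complemented onto the gap axis (its anchor being the
  forward mate means it was sequenced in reverse), while right-flank
  recruits and all mapped recruits are already in forward orientation.
* **Iteration.** Between rounds the pipeline re-derives everything — gaps,
  insert statistics' use, recruitment — from the current genome, re-placing
  reads with an exact-match internal mapper (`place_reads_exact`); it stops
  early when a round neither closes nor extends anything. This is stricter
  than stopping when nothing *closes*, so a round that only extends a flank
  still earns the next round, which is what lets a gap become closable
  after its neighbour's extension.
* **"Uniquely mapped"** is operationalised as MAPQ ≥ 20.

## Problem sizes in the tests

The unit and acceptance tests run entirely on simulated data: a 50 kb
genome with ten gaps (three spanning tandem repeats) at 30× / 1% errors for
the end-to-end check, 4–6 kb genomes at 40–80× for the tandem-repeat worked
examples, 50 random instances with up to 25 reads and 80 observations for
the IRLS-vs-convex-oracle equivalence, and 30-read chains with 20%
unit-offset outliers for the robustness contrast. These sizes keep the full
suite within a few minutes while still exercising every code path at
realistic per-gap scale (a few hundred reads, tens of thousands of
observations).

## Known limitations

* Gaps whose N-run touches a scaffold end have only one flank and are left
  untouched.
* Units larger than the read length cannot be phased by read-to-read
  overlaps at all; and per the resolution limit above, wide-insert-SD
  libraries cannot phase short units either.
* The consensus is substitution-aware but not indel-aware (no partial-order
  alignment); real indel-rich data would need the banded re-alignment
  replaced by a gapped one.
* RF (outward-facing) libraries are accepted but normalised to FR at
  ingest; no explicit mate-pair chimera filtering is performed beyond MAPQ
  and the robust regression itself.
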