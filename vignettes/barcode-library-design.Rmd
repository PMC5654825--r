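---
title: "Designing large DNA barcode libraries with barcodeforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing large DNA barcode libraries with barcodeforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(barcodeforge)
```

## The model

A barcode library is a set of $N$ sequences over $\{A,C,G,T\}$ of length $L$
satisfying four user constraints: minimum pairwise Hamming distance $d$,
maximum homopolymer run $m$, GC-content bounds, and a blacklist of forbidden
subsequences. `barcodeforge` builds each barcode as

$$L = \ell_b + 2 + \ell_t,$$

a *batch code* of length $\ell_b$, a 2-bp *linker*, and a *target code* of
length $\ell_t$. The library is the cross product of $n_b$ linked batch
codes and $n_t$ target codes. Because the Hamming distance between two
assembled barcodes is the sum of the component distances,

$$d(B_i t_a,\, B_j t_b) = d(B_i, B_j) + d(t_a, t_b),$$

pairwise screening is needed only inside the two component sets: roughly
$n_b^2/2 + n_t^2/2 + (\text{proposals} \times n_t)$ comparisons instead of
$N(N-1)/2$. With $N = n_b n_t$ the advantage is largest when
$n_b \approx n_t$, which is why `split_library_size()` defaults to
$n_b = \lceil\sqrt N\rceil$ when the user fixes neither count.

Candidates are drawn from an order-$m$ Markov chain: after a trailing run of
$h$ identical bases (capped at $\min(m, k)$ at position $k$, which also
handles the start of the sequence), the next base repeats with probability
$\delta^h$ and is each alternative with probability $(1-\delta^h)/3$. The
first base is uniform — the natural closure of the transition rule, and the
choice that makes $\delta = 1/4$, $m = 1$ exactly the uniform i.i.d.
generator. $\delta = 0$ forbids adjacent repeats; $\delta = 1$ emits
constant sequences.

```{r}
transition_distribution("ACGTT", markov_params(delta = 0.5, order_m = 2))
```

## Generation workflow

1. **Batch phase.** Batch-code cores are proposed uniformly
   ($\delta = 1/4$, order 1), a linker is appended (first base different
   from the last core base, second different from the first — so every
   linked code ends in a run of exactly 1 and no run can continue into a
   target), and the *linked* code must pass the composition filters and be
   $\ge d_b$ from every previously accepted linked code. The halving rule
   sets $d_b = \lfloor d/2\rfloor$ for $\ell_b \le \ell_t$, else
   $\lfloor (d-1)/2 \rfloor$.
2. **Grid search (Framework B).** $\delta$ is evaluated on $r$ points
   $i/(r-1)$; at each point, $s$ target candidates per trial are checked
   against *every* linked batch code (composition filters only — no targets
   exist yet, so no Hamming screen), averaged over $t$ trials. The argmax is
   kept, ties going to the smaller $\delta$ because smaller $\delta$ also
   reduces downstream homopolymer risk. Framework A skips this and uses
   uniform candidates.
3. **Target phase.** Candidates are drawn at the chosen $\delta$ with order
   $m$, from an empty context (targets must work after every batch), and
   accepted iff they are $\ge d_t$ from all accepted targets and every
   concatenation `linked batch + candidate` passes the homopolymer, GC, and
   blacklist filters — evaluated on the full concatenation so
   junction-spanning violations are caught. The per-candidate order is
   Hamming → homopolymer → GC → blacklist; order changes only speed and
   rejection attribution, both of which the statistics report.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `d` | min pairwise Hamming distance (bp mismatches) | 4 | tolerates one sequencing/synthesis error with margin |
| `m` | max homopolymer run (bp) | 2 | strictest value used in the shipped benchmark configurations |
| `gc_min`, `gc_max` | GC-content bounds (fractions, inclusive) | 0.35–0.65 | standard synthesis/sequencing comfort zone |
| `budget_mode` | how `d` splits into $(d_b, d_t)$ | `"split"` | see below |
| `r`, `s`, `t` | grid points, candidates/trial, trials | 11, 200, 3 | 0.1-resolution over $[0,1]$; ~6,600 candidate evaluations cost seconds and give per-point standard errors ≈ 0.02 |
| `max_attempts_per_code` | proposal cap before declaring infeasibility | $10^6$ | keeps hopeless constraint sets from looping forever; the error names the dominant failing filter |

**The $d_t$ question.** The halving rule pins $d_b$ but nothing in the
construction pins $d_t$. Under the default `split` policy
($d_t = d - d_b$), two barcodes differing in both components are $\ge d$
apart; but two barcodes sharing a target code differ by only $d_b$, and two
sharing a batch code by $d_t < d$. The alternative `strict` policy
($d_t = d$) restores the full guarantee for the dominant within-batch pair
class, at a heavy acceptance cost when $4^{\ell_t}$ is small relative to
$n_t$ (at $\ell_t = 13$, $d_t = 4$, $n_t = 10^4$ the accepted set's
radius-3 balls cover enough of the proposal distribution to reject most
candidates late in the run). Neither policy yields a library whose *overall*
minimum equals $d$ — the validator therefore reports the realized minima for
all three pair classes rather than a single number, and
`glance(validate_library(...))` says which guarantees hold.

## The validator

`validate_library()` has two modes that agree exactly wherever both run
(property-tested on randomized libraries up to $20 \times 20$):
`exhaustive` computes all pairwise assembled distances; `structured` uses
the additive decomposition, reducing the Hamming cost to the two component
matrices, and scans every assembled concatenation for composition
violations (exact, and cheap enough for $10^6$–$10^7$ barcodes). Injected
faults — a corrupted base creating a long run, an inserted blacklist site —
are located by batch/target index and filter.

## What the junction screen implies at scale

Scanning concatenations means a target candidate dies if its first bases
complete a blacklisted word begun by any batch tail. With a handful of
batches this is a mild percent-level effect; with hundreds to thousands of
batch codes the realized batch tails eventually contain, for *every*
possible first base, some $(|e|-1)$- or $(|e|-2)$-prefix of a blacklist
entry $e$ — at which point **no** target candidate can pass and generation
is infeasible (the package verifies this empirically: at
$n_b = 1000$ with a 6-mer-rich blacklist the exact pass probability is 0).
It also makes the acceptance rate noticeably seed-dependent at
$n_b = 100$: whether a particular 5-bp prefix lands in the batch tails
shifts the pooled rate by tens of percent between otherwise identical runs.
`generate_batch_codes(screen_tails = TRUE)` (or
`generate_library(screen_batch_tails = TRUE)`) closes the loophole by
rejecting batch candidates whose linked code ends with such a long prefix.
It is off by default — the plain construction applies no such screen — but
recommended, and used by the package's own large-scale demonstration
($1{,}000 \times 10{,}000$ at $L = 50$ with the restriction-site preset).

## Baseline and benchmarking

`generate_naive()` draws uniform full-length candidates and screens them
against the whole accepted set; runs can be budgeted by candidate count, and
incomplete runs are extrapolated by OLS on
$\log(\text{elapsed}) \sim \log(\text{codes generated})$ — exact on power
laws, and slope-accurate under multiplicative noise. `run_benchmark()`
executes any subset of {naive, A, B} across $(m, L)$ configurations and
reports pooled and per-phase acceptance rates, the chosen $\delta$,
instrumented Hamming-comparison counts, and elapsed/extrapolated times.

Acceptance rates are defined as accepted/proposed pooled over the batch and
target phases (the target phase dominates when $n_t \gg n_b$); grid-search
samples are not counted as proposals. Per-phase rates are always reported
alongside.

## Numerical and edge-case choices

* GC bounds are inclusive and compared as exact integer counts against
  `bound × length` (with only a $10^{-9}$ guard for the float multiply);
  no rounding of thresholds.
* Input sequences are canonicalized to uppercase; any non-ACGT character is
  an error. Blacklist matching is forward-strand exact substring; a
  documented `revcomp` option also screens reverse complements (off by
  default).
* Rejected candidates are replaced by completely fresh proposals (no
  partial repair), so the accepted set is exchangeable given the filter
  constraints.
* All randomness flows through R's RNG: a single seed replays a whole run
  bit-identically, including the C++ rejection loops.
* Hot loops (packed 2-bit Hamming via XOR/popcount, rejection sampling,
  concatenation scanning) are in C++; junction checks use per-batch
  metadata (tail run, GC count, boundary windows) and are property-tested
  against full-concatenation oracles.

## Scale of the shipped checks

The test suite regenerates everything programmatically: the full
$100 \times 10{,}000$ benchmark configurations at $L = 25$–$100$ (seconds to
tens of seconds each), a $1{,}000 \times 10{,}000$ run at $L = 50$ as the
scaled stand-in for the billion-barcode use case (validated by the
structured oracle, then streamed to disk in batch-major order with
memory bounded by one target set), and exact-enumeration oracles at
$\ell_t \le 6$ where all $4^{\ell_t}$ candidates can be weighted by their
Markov probabilities.

## What the generator does and does not emulate

The synthetic inputs are the benchmark conditions themselves: parameterized
constraint sets and seeds — there is no external data. Passing tests
therefore demonstrate internal correctness (filters, distances,
reproducibility, the claimed comparison-count savings) and calibration of
the generator against its own analytic transition probabilities. They say
nothing about wet-lab behavior of the resulting oligos: no melting
temperature, secondary structure, cross-hybridization, or indel-error
modeling is included (indel-aware distances are out of scope by design).
Reported acceptance rates are also specific to the realized batch set, as
described above; run-to-run spread at $n_b = 100$ is substantial even at
fixed parameters.

## Known limitations

* Hamming distance only; libraries are not protected against
  insertions/deletions.
* The grid search optimizes a composition-only pass rate; it cannot
  anticipate target–target Hamming pressure under `strict` budgets.
* `validate_library(mode = "exhaustive")` is quadratic in $N$ and intended
  for small libraries; the structured mode is exact and preferred at scale.
* The $\delta^{\alpha}$ generalization of the transition rule is
  deliberately not implemented.
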