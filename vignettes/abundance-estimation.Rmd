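---
title: "Abundance estimation by elimination and correction: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Abundance estimation by elimination and correction: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the estimator it implements: the
model, its assumptions, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where more than one reasonable option existed.

## The estimation problem

A metagenomic sample is sequenced and its reads aligned against a reference
set of genomes. The evidence available to any homology-based profiler is the
hit table: per (read, genome) pair, the best alignment score. Two structural
problems stand between that table and the composition of the sample:

* **Spurious genomes.** A reference genome similar to a truly present one
  receives many high-scoring hits without being in the sample.
* **Count mixing.** Among genomes that are present, shared sequence causes
  reads to be co-assigned, so raw counts systematically overstate similar
  genomes and the distortion depends on who else is in the sample.

`taec()` addresses the first by *elimination* and the second by *correction*.

## Elimination

Every genome has regions unique to it within the reference set; if the
genome is present and coverage is adequate, some reads must map best to it
and to nothing else. Conversely, a genome all of whose reads are equally
well explained by other genomes has no evidence of its own.

Each read is assigned to the genome(s) attaining its maximum score, giving
a binary matrix $A \in \{0,1\}^{K \times N}$ over $K$ reads and $N$ genomes.
The greedy pass then repeats: select the column with maximal $L^1$ norm, let
that genome *claim* its reads (zeroing those rows in all other columns), and
stop when the maximal remaining norm falls below a user minimum $c$
(default 1). Unselected genomes are eliminated. The package provides the
procedure twice — `eliminate_iterative()` (the form used by the pipeline)
and `eliminate_matrix_form()`, the literal sequence
$A_j = (A_{j-1} P_j S_j)_+$ of permutation, column-subtraction and clamp
steps. The two are cross-checked for exact agreement on randomized inputs in
the test suite; keeping both makes the algebraic description executable.

Because sequencing and alignment errors scatter a few reads onto random
genomes, a raw claimed count is not enough; robustness is assessed by a
non-parametric bootstrap over reads (`bootstrap_eliminate()`). In each of
`n_bootstraps` (default 100) replicates the rows of $A$ are resampled with
replacement and the greedy pass is rerun; a genome is *below cutoff* in a
replicate when it is eliminated there or its claimed count is less than
`cutoff_frac` (default 0.0005, i.e. 0.05%) of the replicate's maximum
claimed count. Genomes below cutoff in more than `occurrence_frac` (default
5%) of replicates are removed. Within a replicate the pass is run with
$c = 1$ and the cutoff applied to its claimed counts afterwards; deriving a
larger $c$ from the cutoff inside the replicate gives provably identical
decisions (raising $c$ only stops the pass earlier, and every genome
selected past that point is below cutoff either way), so the cheaper form is
used. The bootstrap resamples *reads*, the sampling unit of the experiment,
not hits; and it reruns the full greedy pass rather than merely re-counting,
since selection order can change under resampling.

Two deterministic tie rules are fixed so results are reproducible across
platforms: columns tying on the norm select the lexicographically smallest
genome id (C collation), and scores tying within $10^{-9}$ count as equal —
bit scores are computed floating-point values, so exact equality would be
brittle.

## Correction

Let $m$ genomes survive elimination. Reads are recounted over the survivors
with the $\alpha$-threshold rule: a read counts towards every retained
genome whose score is at least $\alpha \cdot \max_j s_{ij}$, the maximum
taken over the *retained* genomes (the recount is a reassignment to the
surviving reference set, so the threshold must be relative to it). This is
the same rule used to build the similarity matrix, with the same $\alpha$,
so the count vector $b$ and the matrix $W$ measure the same assignment
process; `taec()` warns if the two $\alpha$s are decoupled.

With $t_j$ the number of reads genome $j$ receives due to its own presence,
the expected counts satisfy

$$ b_j = t_j + \sum_{j' \ne j} w_{j',j}\, t_{j'} \qquad\text{i.e.}\qquad
   b = W^\top t, $$

where $w_{j,j'}$ estimates the probability that a read originating from
genome $j$ is assigned to genome $j'$. Off-diagonal similarities are
strictly below 1 for distinguishable genomes, so $W^\top$ is invertible and
`correct_abundance()` solves the dense system directly. Genomes with
$t_j \le 0$ are dropped and the reduced system re-solved until all solutions
are positive; the loop terminates in at most $m$ passes. Relative abundances
are $t_j / \sum t$ over the survivors.

Numerical choices here:

* The drop boundary includes $t_j = 0$: a genome contributing zero reads of
  its own is not present. All non-positive genomes in a pass are dropped
  simultaneously (default); `drop = "one"` removes only the most negative
  per pass for sensitivity analysis.
* No regularization is applied. Instead a reciprocal-condition-number guard
  (condition number at most $10^{12}$) rejects systems whose genomes are
  practically indistinguishable at the chosen $\alpha$; the remedy is a
  larger $\alpha$ or merging the genomes, not a biased solve.

## The similarity matrix

`estimate_similarity()` simulates $K_0$ error-free reads (default 30,000)
of the target read length from uniform positions of each genome, aligns
them against all genomes, applies the $\alpha$-threshold rule, and sets
$w_{j,j'} = n_{j \to j'} / n_{j \to j}$ — co-assignments normalized by the
source genome's self-assigned count. This makes the diagonal exactly 1 and
keeps the matrix consistent with the invertibility argument above. The
alternative normalization by $K_0$ (which differs only through the rare
reads that fail to map back to their source) is available as
`normalize = "k0"`. Entries below `threshold` (default 0.001) are zeroed:
similarities that small are indistinguishable from simulation noise at the
default $K_0$ and would only inject noise into the solve.

Similarity reads are simulated error-free: $W$ is a property of the genome
sequences and the assignment rule, not of a sequencing platform. Because
similarity depends on read length, matrices are built per read length;
`select_matrix_by_read_length()` picks the nearest available one (ties to
the shorter length, the conservative direction since shorter reads
co-assign more). Parameter defaults ($\alpha = 0.96$, $K_0 = 30{,}000$,
threshold 0.001) are the method's standard operating point: $\alpha$ in
the 0.90–0.99 range trades specificity of co-assignment against robustness
to small score fluctuations, and 0.96 sits at the empirical optimum of the
calibration design the defaults descend from.

## The synthetic-data module

The generator exists so every stage is testable end to end, in process,
with known truth:

* `generate_genome()` — i.i.d. uniform bases; independent genomes share
  essentially no 16-mers, giving exactly dissimilar references.
* `mutate_genome()` — per-position substitution with probability $r$ to a
  different base, giving controlled pairwise similarity (strain analogues).
* `synthetic_community()` / `simulate_reads()` — read counts follow the
  requested proportions *exactly* via deterministic largest-remainder
  allocation (a multinomial mode exists behind a flag), so truth carries no
  allocation noise and error measures reflect the estimator alone. Starts
  are uniform on the forward strand; genomes are linear (no circular wrap);
  errors are substitution-only at a per-base rate.
* `naive_align()` — a deterministic seed-and-extend aligner: shared k-mers
  (default $k = 16$) propose diagonals, each scored as a full-length
  ungapped alignment (match $+1$, mismatch $-2$ by default; only score
  *ratios* matter to the $\alpha$-rule), best positive score reported.

What this emulates well: score ties between identical regions, graded score
loss with divergence, co-assignment of reads from shared regions — the
phenomena the estimator actually consumes. What it does not emulate:
indels and gapped alignment, reverse-strand sampling, platform-specific
error and quality profiles, variable read lengths, chimeras. Passing tests
therefore demonstrate the correctness of the estimator's logic under its
model assumptions, not robustness to every artifact of real sequencing
data; with real data the alignment step is delegated to a real aligner
(BLAST tabular input via `parse_blast_tabular()`), whose gapped scores the
method accepts unchanged.

## Problem sizes and tolerances in the test suite

The randomized cross-checks use 1,000 matrices of up to 50 reads × 10
genomes (elimination equivalence) and 500 random similarity systems of up
to 10 genomes (correction round trip, recovery to $10^{-8}$). The
end-to-end benchmark simulates five 50 kb genomes with 150,000 reads of
100 bp at abundance ratios up to 1:20 and requires MAXRE below 5%; the
two-strain recovery check uses a 5% divergent mutant pair, 30,000 reads,
$K_0 = 3{,}000$, and requires relative abundances within 2 percentage
points. These sizes were chosen so the full suite exercises every stage at
realistic per-genome coverage (≈ 4–300×) while remaining quick to run.

## Known limitations

* Genomes absent from the reference cannot be detected; their reads inflate
  similar references instead (common to all homology-based profilers).
* Genomes below the bootstrap cutoff (0.05% of the most abundant genome's
  support by default) are indistinguishable from similarity leakage and are
  removed regardless of their true presence.
* A similarity matrix built at a very different read length than the
  sample's biases the correction; match the read length (or rebuild).
* Reads absent from the alignment output are invisible: all counts and
  proportions are relative to alignable reads.
* Near-identical genomes make $W^\top$ ill-conditioned; the package refuses
  to solve past the condition guard rather than return unstable counts.
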