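# taec

Genome relative abundance estimation for metagenomic samples by
**elimination and correction**.

## The problem

Homology-based taxonomic profiling aligns the reads of a metagenomic sample
against a reference database and counts how many reads each genome receives.
When closely related species or strains are present — or merely present in
the database — this raw count is misleading twice over: genomes that are not
in the sample at all collect reads purely because they resemble genomes that
are (false positives), and genuinely present genomes exchange reads with
their relatives, distorting their counts. Both effects grow worse at low
taxonomic ranks, exactly where species/strain-level questions live.

`taec` addresses both with a two-stage estimator that uses genome-to-genome
sequence similarity in addition to the alignment result:

1. **Elimination.** Each read is assigned to the genome(s) attaining its top
   alignment score, giving a binary read-by-genome matrix *A*. The genome
   whose column holds the most reads is selected and claims them; claimed
   reads are removed from every other column; this repeats until no genome
   holds at least *c* reads. Genomes never selected have no uniquely
   attributable support — every read they received is equally well explained
   by a selected genome — and are removed. The whole pass is repeated over
   bootstrap resamples of the reads: a genome whose claimed count falls below
   0.05% of the most abundant genome's in more than 5% of 100 replicates is
   discarded as a false positive.
2. **Correction.** Over the retained genomes, each read is re-assigned to
   every genome scoring at least α · (its maximum score); the resulting
   counts *b* satisfy *b = Wᵀ t*, where *W* is the similarity matrix —
   *w(j, j′)* estimates the probability that a read from genome *j* is
   assigned to genome *j′* under the same α-rule — and *t* is the vector of
   reads each genome receives *due to its own presence*. Solving
   *Wᵀ t = b* (dropping genomes with non-positive solutions and re-solving)
   yields the corrected counts and relative abundances.

*W* is estimated per reference set and read length by simulating *K₀* reads
from each genome (default 30,000), aligning them against all genomes, and
counting α-threshold co-assignments. Defaults: α = 0.96, similarity
threshold 0.001, bootstrap cutoff 0.05%, occurrence 5%.

The package also ships a synthetic-data module (random genomes, mutants at a
controlled substitution rate, exact-count read simulation, and a
deterministic k-mer seed-and-extend aligner) so the whole pipeline runs and
is testable without external aligners or reference downloads, plus the three
standard benchmark measures RRMSE, AVGRE and MAXRE.

## Worked example

Two strains at 5% sequence divergence plus one unrelated species:

```r
library(taec)
base  <- generate_genome(20000, seed = 1, id = "strainA")
near  <- mutate_genome(base, 0.05, seed = 2, id = "strainB")
other <- generate_genome(20000, seed = 3, id = "speciesC")
genomes <- c(base, near, other)

com  <- synthetic_community(genomes, c(0.6, 0.3, 0.1), 20000,
                            read_length = 100, seed = 4)
hits <- naive_align(simulate_reads(com), genomes)
W    <- estimate_similarity(genomes, read_length = 100, K0 = 2000, seed = 5)
round(W$W, 3)
#>          strainA strainB speciesC
#> strainA    1.000   0.051        0
#> strainB    0.056   1.000        0
#> speciesC   0.000   0.000        1

fit <- taec(hits, W, control = taec_control(n_bootstraps = 100, seed = 6))
fit
#> Genome abundance estimate (elimination + similarity correction)
#>   reads: 20000   genomes in alignment: 3   retained: 3   dropped in correction: 0
#>  genome_id corrected_count relative_abundance
#>    strainA        11997.09             0.5989
#>    strainB         6034.15             0.3012
#>   speciesC         2000.00             0.0998

error_measures(coef(fit), com$true_counts)
#> Error over 3 true genomes: RRMSE 0.329%, AVGRE 0.198%, MAXRE 0.569%
```

The similarity matrix shows the two strains co-attract about 5% of each
other's reads at α = 0.96, while the unrelated species is orthogonal; the
corrected counts recover the true 60/30/10 composition to within a fraction
of a percent. `coef()`, `fitted()`, `residuals()`, `summary()` and `plot()`
work as for any fitted model; `run_estimate()` drives the same pipeline from
a BLAST tabular file and a stored similarity matrix, and `exec/taec`
exposes `estimate`, `build-similarity`, `simulate` and `evaluate`
subcommands for shell use.

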