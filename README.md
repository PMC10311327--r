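# panseed

Alignment-free diploid genotyping with spaced seeds, in R.

`panseed` genotypes a sample at a panel of known variants without aligning
reads.  Canonical spaced k-mers — characters sampled at the *care*
positions of a binary seed pattern such as
`111011100101010011010011111110010110010101001110111` — are counted
directly in the raw reads and matched against k-mers unique to the alleles
of pangenome *bubbles*; a Li–Stephens haplotype-pair hidden Markov model
over the phased panel converts counts into genotypes and propagates
linkage disequilibrium into bubbles that own no unique k-mers.  Spaced
seeds make exact k-mer matching robust: a sequencing error under a
*don't-care* (`0`) column leaves the spaced k-mer intact, and a
palindromic pattern guarantees forward- and reverse-strand k-mers share a
canonical form.

The package is aimed at method developers and teaching: it contains the
full surrounding toolbox — seed algebra and combinatorics
(`count_palindromic_seeds`, `mirror_extend`), exact seed sensitivity by
dynamic programming (`hit_probability`), an overlap-complexity
hill-climbing designer (`design_palindromic_seed`), a spaced k-mer counter
(`count_reads`), the bubble-graph genotyper (`build_graph`,
`index_unique_kmers`, `genotype`), strict benchmarking metrics
(`compare_callsets`, `weighted_genotype_concordance`, `wilcoxon_exact`)
and a diploid read/panel simulator with LD structure (`simulate_panel`,
`simulate_reads`, `leave_one_out_run`) — so the whole pipeline runs on
synthetic data with no external downloads.

## The model in brief

* A seed `s` over `{1,0}` has length `l` and weight `w` (count of `1`s);
  admissible palindromic seeds number
  `choose(floor(l/2)-1, floor(w/2)-1)`.
* Seed sensitivity = P(at least one of the `L-l+1` placements matches at
  every care position) in an i.i.d. Bernoulli(`p`) region; computed
  exactly by DP over seed-compatible suffix states (cost `~ 2^(l-w)`).
* Genotyping: hidden state = pair of panel haplotypes; transitions switch
  each haplotype with probability `1 - exp(-rho*d)`; emissions are
  Poisson over unique-k-mer counts with mean `copies * c/2` (`epsilon*c`
  for absent alleles); genotype = max-posterior unordered allele pair from
  forward–backward marginals.
* Scoring: strict TP/FP/FN (a genotype mismatch costs one FN *and* one
  FP), precision/recall/F, and weighted genotype concordance — the mean
  of per-class concordances over `0|0`, `0|1`, `1|1`.

See `vignettes/spaced-seed-genotyping.Rmd` for the full account.

## Worked example

Simulate a 20 kb panel of 5 diploid samples, then run the leave-one-out
benchmark comparing the palindromic spaced seed S1 (weight 31, length 51)
against the contiguous 31-mer seed at 5× coverage with 1% read errors:

```r
library(panseed)

cfg <- simulation_config(coverage = 5, error_rate = 0.01, rng_seed = 1)
tr  <- simulate_panel(cfg)
tr
#> <simulated_truth: 20000 bp reference, 10 haplotypes (5 samples), 40 variants (34 SNV, 6 indel, 0 SV)>

S1 <- mirror_extend("11101110010101001101001111")
S1
#> <spaced_seed 111011100101010011010011111110010110010101001110111 (l=51, w=31)>
hit_probability("11101110010101001101001111", similarity_model(p = 0.95, L = 76))
#> [1] 0.9996716

rep <- leave_one_out_run(tr, list(S1 = S1, C = contiguous_seed(31)))
aggregate(cbind(recall, precision, wGC) ~ seed + class, rep, mean) |>
  subset(class == "all")
#>  seed class    recall precision       wGC
#>     C   all 0.8405887 0.9065746 0.8387927
#>    S1   all 0.8534919 0.9206140 0.8528023

loo_wilcoxon(rep, "S1", "C") |> subset(class == "all")
#>  class    metric    mean_a    mean_b p.value
#>    all precision 0.9206140 0.9065746     0.5
#>    all    recall 0.8534919 0.8405887     0.5
#>    all         F 0.8846001 0.8711538     0.5
#>    all       wGC 0.8528023 0.8387927     0.5
```

At this scale the spaced seed recovers slightly more of the held-out
genotypes than the contiguous control at the same weight (recall 0.853 vs
0.841, wGC 0.853 vs 0.839), though with five samples the exact Wilcoxon
test cannot call the difference significant (p = 0.5).  On an i.i.d.
random reference the comparison isolates the error-tolerance mechanism
only; the additional uniqueness advantage of longer spaced spans requires
repetitive genomes (see the vignette's simulator section).

A thin command-line wrapper over the same functions is installed at
`inst/cli/panseed.R` (`count`, `design-seed`, `genotype`, `evaluate`,
`simulate` subcommands).

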