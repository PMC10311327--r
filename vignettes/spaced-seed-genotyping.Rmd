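---
title: "Alignment-free diploid genotyping with spaced seeds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free diploid genotyping with spaced seeds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panseed)
```

# The problem

Pangenome-based genotypers type a sample at a set of known variants without
aligning reads: k-mers unique to the alleles of each variant "bubble" are
counted directly in the raw reads, and a hidden Markov model over a phased
haplotype panel converts counts into diploid genotypes, using linkage
disequilibrium (LD) to fill in loci whose alleles own no unique k-mers.
Exact k-mer matching is brittle under sequencing errors: one substitution
corrupts every k-mer whose window covers it.  Spaced seeds — binary
patterns of *care* (`1`) and *don't-care* (`0`) positions — relax this:
errors under don't-care columns leave the spaced k-mer intact, and longer
spans make k-mers more specific in repetitive genomes.  `panseed`
implements this pipeline end to end: seed algebra and design, canonical
spaced k-mer counting, bubble-graph genotyping, benchmarking metrics, and
a simulator so everything runs on synthetic data.

# Seeds

A seed $s$ is a string over $\{1, 0\}$ of length $l$ with $w$ care
positions (its weight); the first and last positions must be `1`.  Applied
to a window of length $l$, it reads off the $w$ characters at care
positions (a *spaced k-mer*, $k = w$).  A contiguous seed ($l = w$)
recovers the ordinary k-mer.

Counting uses *canonical* k-mers (lexicographic minimum of a k-mer and its
reverse complement).  For spaced k-mers this is only strand-consistent if
the seed is *palindromic* (equal to its own reversal): then the spaced
k-mer of a reverse-complemented window is the reverse complement of the
window's spaced k-mer, and forward/reverse observations of a locus
collapse onto one representative.  This is asserted as a property test
(identical count tables on reverse-complemented read sets).

Admissible palindromic seeds of length $l$ and weight $w$ number
$\binom{\lfloor l/2\rfloor - 1}{\lfloor w/2\rfloor - 1}$: only half the
pattern is free, the endpoint is pinned, and the centre position is forced
by the parity of $w$.  The count is computed with an exact multiplicative
scheme (every partial product is an integer), since the values of interest
exceed $10^6$ and the tests demand equality; a parity guard returns 0 for
the impossible even-length/odd-weight combination, which the closed form
alone would miss.

`mirror_extend()` turns any base seed into a palindromic one by appending
the reversed base without its last position: length $2l-1$, weight
$2w-1$.  We place no parity restriction on the base length; the result's
length is always odd, which we document rather than forbid.

# Seed sensitivity and design

The *sensitivity* of a seed is the probability that it matches at least
once — all care positions on matches — among all fully contained
placements in an i.i.d. Bernoulli($p$) match/mismatch region of length
$L$.  Defaults follow common practice for Illumina-scale data: $p = 0.95$
(the similarity level of homologous regions) and $L = 76$ (half a read
length).  The convention that the seed must fit entirely inside the $L$
positions ($L - l + 1$ placements) is declared explicitly; it makes
sensitivity 0 when $l > L$.

Sensitivity is computed exactly, not by simulation, with a dynamic program
over "longest seed-compatible suffix" states: a binary string $b$ is a
compatible prefix when every care position falling inside it holds a
match, and the automaton state after each character is the longest
compatible suffix of the text, with an absorbing state on a full-length
hit.  This is the classic Aho–Corasick construction over the $2^{l-w}$
hit patterns, so cost is exponential only in $l - w$ (practical to
$l - w \approx 16$; the shipped 26/16 base seed needs a few thousand
states).  The DP runs in linear space with per-step accumulation — the
probabilities involved are near 1 and never underflow at these sizes —
and is verified against exhaustive enumeration of all $2^L$ strings for
every admissible seed with $l \le 8$.

Searching for good seeds by sensitivity alone is expensive, so the
designer optimizes *overlap complexity*,
$\mathrm{OC}(s) = \sum_{i=-(l-1)}^{l-1} 2^{\sigma(i)}$ with $\sigma(i)$
the number of care positions shared by the seed and its copy shifted by
$i$.  Low OC correlates with high sensitivity; contiguous and highly
periodic patterns score worst.  The shift range includes $i = 0$, which
adds a constant $2^w$ at fixed weight and so never changes the search
ranking.  `optimize_seed()` hill-climbs from a random admissible seed,
swapping one interior care with one interior don't-care position,
scanning neighbours in randomized order and accepting the first strict OC
decrease; `iterations` bounds the number of neighbour evaluations and the
search is deterministic given `rng_seed`.  `design_palindromic_seed()`
repeats the climb over a user-supplied range of base lengths (how many
and which lengths to try is left to the user, since there is no canonical
choice), scores each optimized base by exact sensitivity, and
mirror-extends the best.  A base of weight 16 yields a palindromic seed
of weight 31, the weight used throughout the genotyping comparisons.

# Counting

`count_reads()` scans every length-$l$ window of every read, skips a
window only when a non-ACGT symbol sits on a care position (don't-care
columns tolerate anything), upper-cases input, ignores base qualities,
and counts canonical spaced k-mers in an in-memory hash table (a small
C++ kernel; the dump format is a lexicographically sorted TSV with a
`#seed=` header, bit-identical across runs).  Each position of a sequence
can be covered by at most $w$ distinct k-mers — one per care position —
which bounds the evidence available for a SNV and motivates keeping
$l$ below the read length.

# The pangenome graph and unique k-mers

`build_graph()` anchors a phased panel VCF on the reference: records
whose reference spans lie closer than $l$ are merged into one bubble
(their windows would share k-mers), whose alleles are the distinct
panel-haplotype subsequences over the merged span; allele 0 is always the
reference subsequence, every haplotype maps to exactly one allele, and
each allele remembers the per-record allele indices it was built from so
calls can be decomposed back to the original records on output.  Records
with unphased or missing genotypes are dropped at ingestion.

A k-mer is *unique* to a (bubble, allele) when its total multiplicity —
occurrences in the full reference plus occurrences across all
alternative-allele paths (each allele plus $l-1$ flanking reference bases
per side) — is exactly one.  Reference-allele paths are substrings of the
reference and are therefore counted through it, not double-counted;
without this convention no reference allele could ever own a unique
k-mer.  The rule gets the boundary cases right: flank-only k-mers (shared
by all alleles) are excluded, k-mers of a bubble sitting in repeated
sequence are excluded for every allele, and two bubbles with identical
alleles in identical contexts exclude each other's k-mers.

# The genotyping HMM

The hidden state at bubble $b$ is a pair of panel haplotypes; the sample's
genotype at $b$ is the allele pair that state induces.  Components:

* **Transitions** (Li–Stephens): between consecutive bubbles at reference
  distance $d$, each haplotype independently switches with probability
  $\theta = 1 - e^{-\rho d}$, landing uniformly on the $H$ panel
  haplotypes.  Default $\rho = 10^{-5}$ per base — switch lengths of
  $\sim$100 kb, a typical LD-block scale; larger values weaken LD
  propagation, smaller values over-commit to single panel haplotypes.
* **Emissions**: for every allele $a$ owning unique k-mers, the observed
  counts are modelled as independent Poisson with mean
  $\mathrm{copies}(a) \cdot c/2$, where $c$ is the diploid k-mer coverage
  and copies $\in \{0, 1, 2\}$ is the allele's multiplicity in the state;
  zero-copy alleles use mean $\epsilon c$ (default $\epsilon = 0.01$,
  the error-leak rate: roughly the chance a read error fabricates a
  specific absent k-mer).  Poisson was chosen over negative binomial for
  parameter economy at the scales tested; both `epsilon` and `rho` are
  exposed.
* **Posteriors**: forward–backward state marginals summed over states
  inducing the same unordered allele pair; the argmax genotype is
  reported with its posterior.  Ties break toward genotypes with more
  reference alleles, then lexicographically, so outputs are
  deterministic.

Emission products over 30-plus k-mer counts underflow linear space, so
emissions are computed in log space, max-subtracted per bubble, and the
recursions rescaled per step — the standard numerically equivalent
formulation.  The implementation is verified against brute-force
enumeration of all $H^{2B}$ state paths for small systems ($B \le 3$,
$H \le 4$) to $10^{-9}$.

A bubble with no unique k-mer on any allele gets a uniform emission and is
genotyped from linkage alone; if the graph is that single bubble, there is
no LD context and the call is *undefined* (`./.` on output).  An entirely
empty count table is interpreted as "no evidence" (uniform emissions
everywhere, calls from the panel prior), not as "every k-mer was observed
zero times".

**Coverage estimation.**  With `coverage = "auto"`, $c$ is estimated as
the mode of the non-zero count histogram over unique k-mers of alleles
carried by at least half the panel (error k-mers cluster at 1 and are
excluded by the restriction).  Those counts form two clusters — $c/2$ for
single-copy and $c$ for two-copy alleles in the sample — so when the
histogram holds substantial mass (at least half the modal mass) near
twice the mode, the upper cluster is taken.  Note the estimated quantity
is k-mer coverage, which is lower than base coverage by the
window-containment factor $(R - l + 1)/R$ for read length $R$; at
$R = 150$, $l = 31$ a 30× run yields $c \approx 24$.

# Evaluation

`compare_callsets()` implements the strict benchmarking convention:
sites matched by (chrom, pos, ref, alt) inside a fixed universe of known
variants; genotypes compared unordered and unphased; truth-undefined
sites removed from both sets; a matching non-absent genotype is a TP, a
missed/absent/undefined/mismatched non-absent truth genotype an FN, and a
spurious or mismatched non-absent prediction an FP — one mismatch costs
one FN *and* one FP.  A prediction of "undefined" is never a positive
claim, so it contributes no FP at truth-absent sites.  Precision, recall
and F define 0/0 as 0.  Weighted genotype concordance averages per-class
concordances $T_{x|y}/(T_{x|y}+F_{x|y})$ over `0|0`, `0|1`, `1|1`
(classed by the truth genotype's count of reference alleles); classes with
no sites are excluded from the mean rather than scored 0 or 1.  Size
classes: SNV (equal length), indel (length difference 1–49 bp), SV
(≥ 50 bp).

`wilcoxon_exact()` provides the exact two-sided signed-rank test for the
small paired designs these benchmarks produce ($n$ of a few samples):
zero differences dropped, average ranks on ties, and the exact null
distribution of the positive-rank sum built by generating-function
convolution over doubled ranks — equivalent to enumerating all $2^n$
sign assignments, ties included.  At $n = 9$ the smallest attainable
two-sided p is $2 \cdot 2^{-9} \approx 0.004$; with 24 planned tests a
Bonferroni bound (`bonferroni_bound()`) can never reach 5%, which is why
reports carry uncorrected p-values with the bound available.
`improvement_correlation()` computes the Pearson correlation of two
methods' improvements over a shared baseline.

# The simulator

`simulate_panel()` emulates the study system so the full pipeline runs
with no external data: an i.i.d. uniform random reference; variant sites
Poisson-placed and made non-overlapping by rejection (SNVs, indels with
geometric lengths capped at 49 bp, SVs geometric above 50 bp); founder
haplotypes each carrying a site's alternative allele with probability
1/2; panel haplotypes built as crossover mosaics of the founders
(crossovers Poisson at `recomb_rate`), which induces LD between nearby
sites — the property the genotyping HMM exploits; and consecutive
haplotype pairs as diploid truth samples.  `simulate_reads()` draws
single-end fixed-length reads uniformly from both haplotypes and strands
with i.i.d. substitution errors (no indel errors: the mechanism of
interest is k-mer corruption, which substitutions exercise; pairing is
irrelevant to a bag-of-k-mers genotyper).  `downsample_reads()` thins a
read set by independent Bernoulli keeps.  Everything is bit-reproducible
from `rng_seed`.

Default parameters, chosen once as desk-scale analogues of a human
benchmark: reference 20 kb; 4 founders; 10 haplotypes (5 samples);
per-base rates $2\times10^{-3}$ SNV, $3.5\times10^{-4}$ indel,
$1.2\times10^{-5}$ SV (roughly the 163:29:1 ratio of variant classes in
human panel callsets); crossover rate $10^{-4}$ (LD blocks of
$\sim$10 kb, several inter-variant distances); read length 150; coverage
30 (5 after downsampling for low-coverage runs); error rate $10^{-3}$
(Illumina-like, raised to $10^{-2}$ in stress comparisons).

What the simulator deliberately does *not* emulate: repeat families and
segmental duplications, GC and platform biases, indel sequencing errors,
realistic allele-frequency spectra.  The first omission matters for
interpretation: much of the real-data advantage of spaced seeds comes
from longer spans staying unique in repetitive genomes, a mechanism an
i.i.d. reference cannot express.  On such data the spaced/contiguous
comparison isolates the error-tolerance mechanism only (errors under
don't-care columns), and the measured differences are correspondingly
small; passing the directional check here shows the machinery behaves
correctly, not that effect sizes on real genomes are reproduced.

# Leave-one-out protocol

`leave_one_out_run()` scores each sample against a panel built from the
others: the sample's two haplotypes are removed; variants carried by
neither the held-out haplotypes nor the remaining panel are dropped (they
are invisible to both truth and pangenome); the graph is rebuilt, reads
counted with each seed under test, genotypes called and compared per
variant class; `loo_wilcoxon()` pairs per-sample metrics between two
seeds for the exact test.

# Problem sizes and numerical choices

The shipped tests run the exhaustive oracles at small sizes chosen for
completeness: all $2^{l-2}$ palindromic candidates to $l = 15$; all
admissible seeds to $l = 8$ against all $2^{12}$ match strings; all
$H^{2B}$ HMM paths at $H = 4$, $B = 3$; pipeline simulations on 12–20 kb
references with 6–10 haplotypes, and the spaced-versus-contiguous
comparison over five simulation seeds at 5× coverage with 1% errors.
Degenerate inputs are defined rather than rejected where a convention is
defensible: the weight-1 seed `"1"` is a valid (single-base) seed, empty
read sets give empty tables, an empty panel gives a graph with zero
bubbles, and chromosome breaks between bubbles are treated as free
recombination.

# Limitations

Genotyping quality is bounded by the panel: alleles absent from every
remaining panel haplotype cannot be called.  The Poisson emission ignores
count overdispersion; coverage estimation assumes a visible het/hom
cluster structure and can be misled at very low coverage (a numeric
`coverage` can always be supplied).  The counter is single-threaded and
in-memory, sized for desk-scale experiments, not production genomes.
Exact Wilcoxon enumeration is limited to 25 non-zero pairs, ample for
the intended sample sizes.
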