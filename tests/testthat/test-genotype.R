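# helper: graph with B well-separated SNP bubbles over H haplotypes
snp_graph <- function(B, hap, l = 9L, seq_seed = 1L) {
  ref <- c(chr1 = random_seq(200L * (B + 1L), seed = seq_seed))
  pos <- 150L + 200L * (0:(B - 1L))
  panel <- toy_panel(ref[[1]], pos, hap)
  build_graph(ref, panel, strrep("1", l))
}

fake_counts <- function(kv, seed_pattern) {
  counts <- kv[order(names(kv), method = "radix")]
  structure(list(seed = parse_seed(seed_pattern), counts = counts,
                 windows_total = sum(counts), windows_skipped = 0),
            class = "kmer_counts")
}

test_that("single-bubble genotyping reduces to the Poisson Bayes rule", {
  pat <- strrep("1", 9)
  g <- snp_graph(1, matrix(c(0L, 1L), 1))
  idx <- index_unique_kmers(g, pat)
  ref_km <- idx$kmers[[1]][[1]]
  alt_km <- idx$kmers[[1]][[2]]
  c <- 30; eps <- 0.01
  kv <- setNames(rep(15, length(ref_km) + length(alt_km)), c(ref_km, alt_km))
  counts <- fake_counts(kv, pat)
  calls <- genotype(g, counts, genotyping_params(pat, coverage = c, epsilon = eps))
  expect_equal(calls$allele1, 0L)
  expect_equal(calls$allele2, 1L)
  # hand-computed posterior: states (ref,ref),(ref,alt),(alt,ref),(alt,alt)
  lik <- function(mu_ref, mu_alt)
    prod(dpois(kv[ref_km], mu_ref)) * prod(dpois(kv[alt_km], mu_alt))
  l_rr <- lik(c, eps * c); l_ra <- lik(c / 2, c / 2); l_aa <- lik(eps * c, c)
  expect_equal(calls$posterior, 2 * l_ra / (l_rr + 2 * l_ra + l_aa),
               tolerance = 1e-9)
})

test_that("per-bubble genotype posteriors sum to one", {
  set.seed(12)
  hap <- matrix(rbinom(3 * 4, 1, 0.5), nrow = 3)
  hap[1, ] <- c(0L, 1L, 0L, 1L)
  g <- snp_graph(3, hap)
  pat <- strrep("1", 9)
  idx <- index_unique_kmers(g, pat)
  kv <- unlist(lapply(seq_len(3), function(b)
    setNames(rpois(sum(lengths(idx$kmers[[b]])), 10),
             unlist(idx$kmers[[b]]))))
  counts <- fake_counts(kv, pat)
  brute <- brute_hmm_posteriors(g, idx, counts, c = 20, eps = 0.01, rho = 1e-5)
  for (b in 1:3) expect_equal(sum(brute[[b]]), 1, tolerance = 1e-9)
})

test_that("forward-backward marginals equal brute-force path enumeration", {
  set.seed(33)
  for (trial in 1:3) {
    H <- 4L; B <- 3L
    hap <- matrix(rbinom(B * H, 1, 0.5), nrow = B)
    hap[cbind(seq_len(B), sample(H, B, replace = TRUE))] <- 1L  # keep segregating
    g <- snp_graph(B, hap, seq_seed = 100 + trial)
    pat <- strrep("1", 9)
    idx <- index_unique_kmers(g, pat)
    km <- unlist(idx$kmers, recursive = TRUE)
    kv <- setNames(rpois(length(km), 8), km)
    counts <- fake_counts(kv, pat)
    params <- genotyping_params(pat, coverage = 14, epsilon = 0.02, rho = 1e-4)
    calls <- genotype(g, counts, params, index = idx)
    brute <- brute_hmm_posteriors(g, idx, counts, c = 14, eps = 0.02, rho = 1e-4)
    for (b in seq_len(B)) {
      key <- paste(calls$allele1[b], calls$allele2[b], sep = "/")
      expect_equal(calls$posterior[b], unname(brute[[b]][key]), tolerance = 1e-9)
      expect_equal(unname(brute[[b]][key]), max(brute[[b]]), tolerance = 1e-9)
    }
  }
})

test_that("linkage fills in bubbles that lack unique k-mers", {
  # two haplotype groups in perfect LD across three SNPs
  hap <- matrix(rep(c(1L, 1L, 0L, 0L), 3), nrow = 3, byrow = TRUE)
  g <- snp_graph(3, hap)
  pat <- strrep("1", 9)
  idx <- index_unique_kmers(g, pat)
  idx$kmers[[2]] <- lapply(idx$kmers[[2]], function(x) character(0))  # starve bubble 2
  c <- 20
  kv <- c(setNames(rep(c / 2, length(unlist(idx$kmers[[1]]))), unlist(idx$kmers[[1]])),
          setNames(rep(c / 2, length(unlist(idx$kmers[[3]]))), unlist(idx$kmers[[3]])))
  counts <- fake_counts(kv, pat)
  calls <- genotype(g, counts, genotyping_params(pat, coverage = c), index = idx)
  # flanking bubbles heterozygous -> LD implies the middle one is too
  expect_equal(calls$allele1, rep(0L, 3))
  expect_equal(calls$allele2, rep(1L, 3))
  brute <- brute_hmm_posteriors(g, idx, counts, c = c, eps = 0.01, rho = 1e-5)
  expect_equal(calls$posterior[2], unname(brute[[2]]["0/1"]), tolerance = 1e-9)
})

test_that("empty counts fall back to the panel prior; lone starved bubble is undefined", {
  hap <- matrix(c(1L, 1L, 1L, 0L,
                  0L, 1L, 0L, 0L), nrow = 2, byrow = TRUE)
  g <- snp_graph(2, hap)
  pat <- strrep("1", 9)
  counts <- fake_counts(setNames(numeric(0), character(0)), pat)
  calls <- genotype(g, counts, genotyping_params(pat, coverage = 10))
  # most frequent unordered allele pair per bubble among the H^2 prior states
  prior_argmax <- function(pa) {
    keys <- outer(pa, pa, function(a, b) paste(pmin(a, b), pmax(a, b), sep = "/"))
    tb <- table(keys)
    names(tb)[which.max(tb)]
  }
  for (b in 1:2) {
    expect_equal(paste(calls$allele1[b], calls$allele2[b], sep = "/"),
                 prior_argmax(g$bubbles[[b]]$panel_alleles))
  }
  # a single-bubble graph with no unique k-mers has no LD context: undefined
  g1 <- snp_graph(1, matrix(c(0L, 1L), 1))
  idx1 <- index_unique_kmers(g1, pat)
  idx1$kmers[[1]] <- lapply(idx1$kmers[[1]], function(x) character(0))
  calls1 <- genotype(g1, counts, genotyping_params(pat, coverage = 10), index = idx1)
  expect_true(is.na(calls1$allele1))
  expect_identical(calls1$class, "*|*")
})

test_that("coverage estimation finds the count histogram mode", {
  pat <- strrep("1", 9)
  g <- snp_graph(1, matrix(c(1L, 1L, 1L, 0L), 1))  # alt carried by 3/4 haplotypes
  idx <- index_unique_kmers(g, pat)
  alt_km <- idx$kmers[[1]][[2]]
  kv <- setNames(rep(30, length(alt_km)), alt_km)
  expect_equal(estimate_coverage(idx, fake_counts(kv, pat)), 30)
  kv2 <- setNames(c(rep(30, 5), rep(31, 3), 1), alt_km[1:9])
  expect_equal(estimate_coverage(idx, fake_counts(kv2, pat)), 30)
  expect_error(estimate_coverage(idx, fake_counts(setNames(numeric(0), character(0)), pat)),
               "observed")
})

test_that("calls decompose to per-variant genotypes and round-trip through VCF", {
  ref <- c(chr1 = random_seq(300, seed = 9))
  pos <- c(150L, 153L)
  hap <- matrix(c(0L, 1L, 1L, 0L,
                  0L, 0L, 1L, 0L), nrow = 2, byrow = TRUE)
  panel <- toy_panel(ref[[1]], pos, hap)
  pat <- strrep("1", 31)
  g <- build_graph(ref, panel, pat)        # one merged bubble, 3 alleles
  counts <- fake_counts(setNames(numeric(0), character(0)), pat)
  calls <- genotype(g, counts, genotyping_params(pat, coverage = 10))
  calls$allele1 <- 1L; calls$allele2 <- 2L  # force a known decomposition
  calls$posterior <- 0.9
  cs <- calls_to_callset(calls, g)
  expect_equal(nrow(cs), 2L)
  expect_identical(cs$gt, c("1/1", "0/1"))  # alt1 on both branches, alt2 on one
  path <- withr::local_tempfile(fileext = ".vcf")
  write_calls(calls, g, path)
  back <- read_callset_vcf(path)
  expect_identical(back$gt, cs$gt)
  # undefined calls are written ./. and read back as NA
  calls$allele1 <- NA_integer_; calls$allele2 <- NA_integer_
  calls$posterior <- NA_real_
  write_calls(calls, g, path)
  expect_true(all(is.na(read_callset_vcf(path)$gt)))
})
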