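test_that("zero variant rates give a panel identical to the reference", {
  cfg <- simulation_config(ref_length = 2000, snv_rate = 0, indel_rate = 0,
                           sv_rate = 0, n_haplotypes = 4, rng_seed = 2)
  tr <- simulate_panel(cfg)
  expect_equal(nrow(tr$variants), 0L)
  expect_identical(haplotype_sequence(tr, 1), tr$reference[[1]])
})

test_that("panel simulation is reproducible from the seed", {
  cfg <- simulation_config(ref_length = 5000, rng_seed = 77, n_haplotypes = 6)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$reference, b$reference)
  expect_identical(a$variants, b$variants)
  expect_identical(a$panel, b$panel)
  c2 <- simulate_panel(simulation_config(ref_length = 5000, rng_seed = 78,
                                         n_haplotypes = 6))
  expect_false(identical(a$reference, c2$reference))
})

test_that("variant counts follow the Poisson placement rates", {
  cfg <- simulation_config(ref_length = 1e5, snv_rate = 1e-3, indel_rate = 0,
                           sv_rate = 0, rng_seed = 123)
  tr <- simulate_panel(cfg)
  n_snv <- sum(variant_class(tr$variants) == "snv")
  expect_true(abs(n_snv - 100) < 4 * sqrt(100))
  expect_true(all(tr$variants$ref != tr$variants$alt))
  # sites are sorted and non-overlapping
  ends <- tr$variants$pos + nchar(tr$variants$ref) - 1L
  expect_true(all(diff(tr$variants$pos) > 0))
  expect_true(all(tr$variants$pos[-1] > ends[-length(ends)]))
})

test_that("variant classes respect the 50 bp size boundary", {
  cfg <- simulation_config(ref_length = 2e5, snv_rate = 5e-4, indel_rate = 3e-4,
                           sv_rate = 1e-4, rng_seed = 5)
  tr <- simulate_panel(cfg)
  cls <- variant_class(tr$variants)
  d <- abs(nchar(tr$variants$alt) - nchar(tr$variants$ref))
  expect_true(all(d[cls == "snv"] == 0))
  expect_true(all(d[cls == "indel"] >= 1 & d[cls == "indel"] < 50))
  expect_true(all(d[cls == "sv"] >= 50))
  expect_true(all(cls %in% c("snv", "indel", "sv")))
  expect_gt(sum(cls == "sv"), 0)
})

test_that("truth genotypes are recomputable from the haplotype sequences", {
  cfg <- simulation_config(ref_length = 8000, rng_seed = 13, n_haplotypes = 4,
                           indel_rate = 1e-3)
  tr <- simulate_panel(cfg)
  for (h in 1:2) {
    hapseq <- haplotype_sequence(tr, h)
    offset <- 0L
    for (v in seq_len(nrow(tr$variants))) {
      allele <- if (tr$panel[v, h] == 1L) tr$variants$alt[v] else tr$variants$ref[v]
      got <- substr(hapseq, tr$variants$pos[v] + offset,
                    tr$variants$pos[v] + offset + nchar(allele) - 1L)
      expect_identical(got, allele)
      if (tr$panel[v, h] == 1L)
        offset <- offset + nchar(tr$variants$alt[v]) - nchar(tr$variants$ref[v])
    }
  }
})

test_that("mosaic haplotypes carry more LD than a site-shuffled control", {
  cfg <- simulation_config(ref_length = 6e4, rng_seed = 4, n_haplotypes = 12,
                           n_founders = 4)
  tr <- simulate_panel(cfg)
  adj_cor <- function(panel) {
    r <- vapply(seq_len(nrow(panel) - 1L), function(v) {
      suppressWarnings(abs(cor(panel[v, ], panel[v + 1L, ])))
    }, numeric(1))
    mean(r, na.rm = TRUE)
  }
  set.seed(1)
  shuffled <- t(apply(tr$panel, 1L, sample))
  expect_gt(adj_cor(tr$panel), adj_cor(shuffled))
})

test_that("error-free reads are exact haplotype substrings; counts are exact", {
  cfg <- simulation_config(ref_length = 2000, error_rate = 0, coverage = 4,
                           read_length = 100, rng_seed = 3, n_haplotypes = 4)
  tr <- simulate_panel(cfg)
  h1 <- haplotype_sequence(tr, 1); h2 <- haplotype_sequence(tr, 2)
  reads <- simulate_reads(h1, h2, cfg, rng_seed = 17)
  expect_equal(length(reads),
               round(4 * (nchar(h1) + nchar(h2)) / (2 * 100)))
  hay <- paste(h1, h2, reverse_complement(h1), reverse_complement(h2),
               sep = "NNN")
  expect_true(all(vapply(reads, grepl, TRUE, x = hay, fixed = TRUE)))
  expect_identical(simulate_reads(h1, h2, cfg, rng_seed = 17), reads)
})

test_that("substitution errors appear at the configured rate", {
  cfg <- simulation_config(ref_length = 2000, error_rate = 0.01, coverage = 30,
                           read_length = 100, rng_seed = 3, n_haplotypes = 4)
  hap <- strrep("A", 2000)  # errors are exactly the non-A / non-T bases
  reads <- simulate_reads(hap, hap, cfg, rng_seed = 23)
  n_err <- sum(vapply(reads, function(r) {
    min(sum(strsplit(r, "")[[1]] != "A"), sum(strsplit(r, "")[[1]] != "T"))
  }, numeric(1)))
  total <- sum(nchar(reads))
  expect_true(abs(n_err - 0.01 * total) < 4 * sqrt(total * 0.01 * 0.99))
})

test_that("downsampling is Bernoulli thinning, deterministic per seed", {
  reads <- setNames(rep("ACGT", 600), paste0("r", 1:600))
  expect_identical(downsample_reads(reads, 1, 9), reads)
  kept <- downsample_reads(reads, 1/6, 9)
  expect_true(abs(length(kept) - 100) < 4 * sqrt(600 * (1/6) * (5/6)))
  expect_identical(downsample_reads(reads, 1/6, 9), kept)
  expect_true(all(names(kept) %in% names(reads)))
})

test_that("truth files round-trip through FASTA/VCF", {
  cfg <- simulation_config(ref_length = 3000, rng_seed = 19, n_haplotypes = 4)
  tr <- simulate_panel(cfg)
  dir <- withr::local_tempdir()
  write_truth(tr, dir)
  ref <- Biostrings::readDNAStringSet(file.path(dir, "ref.fa"))
  expect_identical(as.character(ref[[1]]), tr$reference[[1]])
  panel <- read_panel_vcf(file.path(dir, "panel.vcf"))
  expect_equal(panel$variants$pos, tr$variants$pos)
  expect_identical(panel$variants$ref, tr$variants$ref)
  expect_equal(unname(panel$hap), unname(tr$panel))
  cs <- read_callset_vcf(file.path(dir, "truth.sample1.vcf"))
  expect_identical(cs$gt, truth_callset(tr, 1)$gt)
})
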