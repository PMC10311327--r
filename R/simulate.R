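#' Simulation configuration
#'
#' Parameters of the synthetic study system: a uniform random reference, a
#' phased panel whose haplotypes are recombination mosaics of a few founder
#' haplotypes (which induces linkage disequilibrium), diploid truth samples
#' made of consecutive haplotype pairs, and uniform-coverage reads with
#' i.i.d. substitution errors.  Variant rates are per reference base and
#' cover the three benchmark size classes: SNVs, indels (< 50 bp) and SVs
#' (>= 50 bp).
#'
#' @param ref_length Reference length in bases.
#' @param n_founders Founder haplotype count (LD block donors).
#' @param n_haplotypes Panel haplotype count; even, two per diploid sample.
#' @param snv_rate,indel_rate,sv_rate Variant site rates per base.
#' @param indel_len Mean indel length (geometric, capped at 49 bp).
#' @param sv_len_min Minimum SV length (50 bp size-class boundary).
#' @param sv_len_mean Mean SV length (geometric above `sv_len_min`).
#' @param recomb_rate Founder-mosaic crossover rate per base.
#' @param read_length Read length in bases.
#' @param coverage Diploid fold coverage of simulated reads.
#' @param error_rate Per-base substitution error probability.
#' @param rng_seed Integer seed; all outputs are reproducible from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(ref_length = 20000L,
                              n_founders = 4L,
                              n_haplotypes = 10L,
                              snv_rate = 2e-3,
                              indel_rate = 3.5e-4,
                              sv_rate = 1.2e-5,
                              indel_len = 5,
                              sv_len_min = 50L,
                              sv_len_mean = 100,
                              recomb_rate = 1e-4,
                              read_length = 150L,
                              coverage = 30,
                              error_rate = 0.001,
                              rng_seed = 1L) {
  cfg <- list(ref_length = as.integer(ref_length), n_founders = as.integer(n_founders),
              n_haplotypes = as.integer(n_haplotypes), snv_rate = snv_rate,
              indel_rate = indel_rate, sv_rate = sv_rate, indel_len = indel_len,
              sv_len_min = as.integer(sv_len_min), sv_len_mean = sv_len_mean,
              recomb_rate = recomb_rate, read_length = as.integer(read_length),
              coverage = coverage, error_rate = error_rate,
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$ref_length >= 10L * cfg$read_length, cfg$coverage > 0,
            cfg$n_haplotypes %% 2L == 0L, cfg$n_founders >= 2L,
            cfg$snv_rate >= 0, cfg$indel_rate >= 0, cfg$sv_rate >= 0,
            cfg$error_rate >= 0, cfg$error_rate < 1)
  structure(cfg, class = "simulation_config")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

#' Simulate a reference, phased panel and diploid truth samples
#'
#' Variant sites are Poisson-placed along an i.i.d. uniform reference and
#' made non-overlapping by rejection; each founder haplotype carries each
#' site's alternative allele with probability 1/2 (sites carried by no
#' founder are redrawn); panel haplotypes are crossover mosaics of the
#' founders, giving adjacent sites correlated alleles (LD).  Consecutive
#' haplotype pairs form the diploid truth samples.
#'
#' @param config A [simulation_config()].
#' @return A `simulated_truth` object: `reference` (named character),
#'   `variants` (data frame chrom/pos/ref/alt, 1-based, anchored like VCF),
#'   `panel` (sites x haplotypes 0/1 matrix), `samples` (names), `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$rng_seed)
  n <- config$ref_length
  ref <- random_dna(n)

  margin <- config$read_length + config$sv_len_min + 10L
  n_snv <- rpois(1L, config$snv_rate * n)
  n_ind <- rpois(1L, config$indel_rate * n)
  n_sv  <- rpois(1L, config$sv_rate * n)

  draw_site <- function(type) {
    pos <- sample.int(n - 2L * margin, 1L) + margin
    refb <- substr(ref, pos, pos)
    if (type == "snv") {
      alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
      return(list(pos = pos, ref = refb, alt = alt))
    }
    len <- if (type == "indel") {
      min(49L, 1L + rgeom(1L, 1 / config$indel_len))
    } else {
      config$sv_len_min + rgeom(1L, 1 / (config$sv_len_mean - config$sv_len_min + 1))
    }
    if (runif(1L) < 0.5) {  # insertion after the anchor base
      list(pos = pos, ref = refb, alt = paste0(refb, random_dna(len)))
    } else {                # deletion of len bases after the anchor
      list(pos = pos, ref = substr(ref, pos, pos + len), alt = refb)
    }
  }

  types <- rep(c("snv", "indel", "sv"), c(n_snv, n_ind, n_sv))
  sites <- lapply(types, draw_site)
  if (length(sites)) {
    pos <- vapply(sites, `[[`, numeric(1L), "pos")
    end <- pos + vapply(sites, function(s) nchar(s$ref), numeric(1L)) - 1L
    ord <- order(pos)
    keep <- logical(length(ord))
    last_end <- -1
    for (i in ord) {  # greedy non-overlap filter, 1 bp guard band
      if (pos[i] > last_end + 1L) { keep[i] <- TRUE; last_end <- end[i] }
    }
    if (sum(keep) < length(sites) / 2)
      stop("variant rates too high: could not place non-overlapping variants")
    sites <- sites[ord[keep[ord]]]
  }

  variants <- data.frame(
    chrom = rep("chr1", length(sites)),
    pos = vapply(sites, `[[`, numeric(1L), "pos"),
    ref = vapply(sites, `[[`, character(1L), "ref"),
    alt = vapply(sites, `[[`, character(1L), "alt"),
    stringsAsFactors = FALSE)

  nv <- nrow(variants)
  founders <- matrix(0L, nrow = nv, ncol = config$n_founders)
  if (nv) {
    for (v in seq_len(nv)) {
      repeat {  # every site segregates among the founders
        carriers <- rbinom(config$n_founders, 1L, 0.5)
        if (any(carriers == 1L)) break
      }
      founders[v, ] <- carriers
    }
  }

  H <- config$n_haplotypes
  panel <- matrix(0L, nrow = nv, ncol = H)
  for (h in seq_len(H)) {
    n_x <- rpois(1L, config$recomb_rate * n)
    breaks <- sort(runif(n_x, 1, n))
    donors <- sample.int(config$n_founders, n_x + 1L, replace = TRUE)
    if (nv) {
      seg <- findInterval(variants$pos, breaks) + 1L
      panel[, h] <- founders[cbind(seq_len(nv), donors[seg])]
    }
  }
  colnames(panel) <- paste0("hap", seq_len(H))

  drop <- if (nv) rowSums(panel) == 0L else logical(0)  # absent from the panel
  variants <- variants[!drop, , drop = FALSE]
  panel <- panel[!drop, , drop = FALSE]
  rownames(variants) <- NULL

  structure(list(reference = c(chr1 = ref), variants = variants, panel = panel,
                 samples = paste0("sample", seq_len(H %/% 2L)), config = config),
            class = "simulated_truth")
}

#' @export
print.simulated_truth <- function(x, ...) {
  cls <- variant_class(x$variants)
  cat(sprintf("<simulated_truth: %d bp reference, %d haplotypes (%d samples), %d variants (%d SNV, %d indel, %d SV)>\n",
              nchar(x$reference[[1L]]), ncol(x$panel), length(x$samples),
              nrow(x$variants), sum(cls == "snv"), sum(cls == "indel"),
              sum(cls == "sv")))
  invisible(x)
}

#' Variant size class
#'
#' `snv` for single-base substitutions, `indel` for length differences of
#' 1-49 bp, `sv` for length differences of 50 bp or more.
#'
#' @param variants Data frame with `ref` and `alt` columns.
#' @return Character vector of classes.
#' @export
variant_class <- function(variants) {
  d <- abs(nchar(variants$alt) - nchar(variants$ref))
  ifelse(d == 0, "snv", ifelse(d < 50, "indel", "sv"))
}

#' Build a haplotype sequence from carried variants
#'
#' Applies, right to left, every variant whose allele is 1, replacing the
#' reference span by the alternative allele.
#'
#' @param truth A `simulated_truth`.
#' @param hap Haplotype column index (or name) in the panel.
#' @return The haplotype sequence (character scalar).
#' @export
haplotype_sequence <- function(truth, hap) {
  seq <- truth$reference[[1L]]
  carried <- which(truth$panel[, hap] == 1L)
  for (v in rev(carried)) {
    pos <- truth$variants$pos[v]
    ref <- truth$variants$ref[v]
    seq <- paste0(substr(seq, 1L, pos - 1L),
                  truth$variants$alt[v],
                  substr(seq, pos + nchar(ref), nchar(seq)))
  }
  seq
}

#' Truth callset of a diploid sample
#'
#' @param truth A `simulated_truth`.
#' @param sample Sample index (haplotypes `2*sample-1` and `2*sample`).
#' @return Callset data frame (`chrom`, `pos`, `ref`, `alt`, `gt`) over all
#'   panel variants, genotypes like `"0/1"`.
#' @export
truth_callset <- function(truth, sample) {
  a1 <- truth$panel[, 2L * sample - 1L]
  a2 <- truth$panel[, 2L * sample]
  gt <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  cbind(truth$variants, data.frame(gt = gt, stringsAsFactors = FALSE))
}

#' Simulate error-bearing reads from a diploid sample
#'
#' `round(coverage * (len1 + len2) / (2 * read_length))` single-end reads
#' of fixed length are drawn uniformly from the two haplotypes and both
#' strands; each base is substituted independently with `error_rate`.
#'
#' @param hap1,hap2 The two haplotype sequences.
#' @param config A [simulation_config()] (read length, coverage, error rate).
#' @param rng_seed Integer seed (defaults to the config's).
#' @return Named character vector of read sequences.
#' @export
simulate_reads <- function(hap1, hap2, config, rng_seed = config$rng_seed) {
  set.seed(rng_seed)
  rl <- config$read_length
  lens <- c(nchar(hap1), nchar(hap2))
  if (rl > min(lens)) stop("read length exceeds haplotype length")
  n_reads <- round(config$coverage * sum(lens) / (2 * rl))
  hap_of <- sample.int(2L, n_reads, replace = TRUE)
  starts <- floor(runif(n_reads) * (lens[hap_of] - rl + 1)) + 1L
  seqs <- character(n_reads)
  for (h in 1:2) {
    idx <- hap_of == h
    seqs[idx] <- substring(if (h == 1) hap1 else hap2,
                           starts[idx], starts[idx] + rl - 1L)
  }
  rev_strand <- runif(n_reads) < 0.5
  if (any(rev_strand)) seqs[rev_strand] <- reverse_complement(seqs[rev_strand])
  if (config$error_rate > 0) {
    n_err <- rbinom(n_reads, rl, config$error_rate)
    for (i in which(n_err > 0L)) {
      at <- sample.int(rl, n_err[i])
      ch <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
      for (j in at) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1L)
      seqs[i] <- paste(ch, collapse = "")
    }
  }
  setNames(seqs, paste0("read", seq_len(n_reads)))
}

#' Randomly downsample a read set
#'
#' Each read is kept independently with probability `fraction`.
#'
#' @param reads Named character vector of reads.
#' @param fraction Keep probability in (0, 1].
#' @param rng_seed Integer seed.
#' @return The retained subset, order preserved.
#' @export
downsample_reads <- function(reads, fraction, rng_seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  set.seed(rng_seed)
  reads[runif(length(reads)) < fraction]
}

#' Write simulated truth to disk
#'
#' Emits `ref.fa`, the phased `panel.vcf`, and one `truth.<sample>.vcf`
#' per diploid sample.
#'
#' @param truth A `simulated_truth`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(truth$reference),
    file.path(dir, "ref.fa"))
  gt <- matrix(paste(truth$panel[, seq(1L, ncol(truth$panel), 2L), drop = FALSE],
                     truth$panel[, seq(2L, ncol(truth$panel), 2L), drop = FALSE],
                     sep = "|"),
               nrow = nrow(truth$panel))
  colnames(gt) <- truth$samples
  write_vcf(truth$variants, gt, file.path(dir, "panel.vcf"),
            contigs = setNames(nchar(truth$reference), names(truth$reference)))
  for (s in seq_along(truth$samples)) {
    cs <- truth_callset(truth, s)
    write_vcf(cs[, c("chrom", "pos", "ref", "alt")],
              matrix(sub("/", "|", cs$gt), ncol = 1L,
                     dimnames = list(NULL, truth$samples[s])),
              file.path(dir, paste0("truth.", truth$samples[s], ".vcf")),
              contigs = setNames(nchar(truth$reference), names(truth$reference)))
  }
  invisible(dir)
}

#' Write reads to FASTQ
#'
#' Constant quality string (qualities are never used by the genotyper).
#'
#' @param reads Named character vector of reads.
#' @param path Output FASTQ path (`.gz` for gzip).
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(reads))
    writeLines(paste0("@", names(reads), "\n", reads, "\n+\n",
                      vapply(nchar(reads), function(n) strrep("I", n), "")),
               con)
  invisible(path)
}
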