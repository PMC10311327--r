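#' Genotyping parameters
#'
#' @param seed A `spaced_seed` or pattern string; must match the counts.
#' @param coverage Diploid k-mer coverage `c`, or `"auto"` to estimate it
#'   from the counts with [estimate_coverage()].
#' @param epsilon Expected fraction of `c` observed for k-mers of alleles
#'   the sample does not carry (sequencing-error leakage), in (0, 1).
#' @param rho Per-base recombination switch rate of the Li-Stephens model.
#' @return A `genotyping_params` object.
#' @export
genotyping_params <- function(seed, coverage = "auto", epsilon = 0.01, rho = 1e-5) {
  seed <- as_seed(seed)
  if (!identical(coverage, "auto"))
    stopifnot(is.numeric(coverage), coverage > 0)
  stopifnot(epsilon > 0, epsilon < 1, rho >= 0)
  structure(list(seed = seed, coverage = coverage, epsilon = epsilon, rho = rho),
            class = "genotyping_params")
}

#' Estimate diploid k-mer coverage from counts
#'
#' Mode of the non-zero count histogram restricted to unique k-mers of
#' alleles carried by at least half the panel haplotypes (robust against
#' sequencing-error k-mers, which cluster at count 1).  Counts of such
#' alleles form two clusters — `c/2` for single-copy and `c` for two-copy
#' alleles in the sample — so when the histogram carries substantial mass
#' near twice the modal value, the upper cluster is taken as the diploid
#' coverage.  Falls back to the mean when the histogram is flat.
#'
#' @param index A `unique_kmer_index`.
#' @param counts A `kmer_counts` from the same seed.
#' @return Estimated diploid coverage `c`.
#' @export
estimate_coverage <- function(index, counts) {
  stopifnot(inherits(index, "unique_kmer_index"), inherits(counts, "kmer_counts"))
  if (index$seed$pattern != counts$seed$pattern)
    stop("seed mismatch between index and counts")
  half <- index$n_haplotypes / 2
  km <- unlist(lapply(seq_along(index$kmers), function(b) {
    keep <- index$carriers[[b]] >= half
    unlist(index$kmers[[b]][keep])
  }))
  if (!length(km)) stop("no unique k-mers on majority alleles")
  cnt <- counts$counts[km]
  cnt[is.na(cnt)] <- 0
  cnt <- cnt[cnt > 0]
  if (!length(cnt)) stop("no unique k-mer of a majority allele was observed")
  tb <- table(cnt)
  if (length(unique(as.vector(tb))) == 1L) return(mean(cnt))
  vals <- as.numeric(names(tb))
  m1 <- vals[which.max(tb)]
  lo_mass <- sum(tb[vals >= 0.75 * m1 & vals <= 1.25 * m1])
  hi <- vals >= 1.5 * m1 & vals <= 2.5 * m1
  if (any(hi) && sum(tb[hi]) >= 0.5 * lo_mass) {
    hi_vals <- vals[hi]
    return(hi_vals[which.max(tb[hi])])
  }
  m1
}

#' Genotype a sample from spaced k-mer counts
#'
#' Li-Stephens haplotype-pair hidden Markov model over the bubble chain.
#' The hidden state at a bubble is a pair of panel haplotypes; between
#' consecutive bubbles each haplotype independently switches with
#' probability `theta = 1 - exp(-rho * d)` (d = reference distance),
#' spread uniformly over the panel.  The emission at a bubble multiplies,
#' over every unique k-mer of every allele, a Poisson likelihood of the
#' observed count with mean `copies * c/2` (copy number of the allele in
#' the state), or `epsilon * c` for zero-copy alleles.  Genotype posteriors
#' are forward-backward state marginals summed over states inducing the
#' same unordered allele pair; the maximum-posterior genotype is reported,
#' ties broken toward more reference alleles.  Emissions are computed in
#' log space and the recursions rescaled per bubble.
#'
#' A bubble with no unique k-mer on any allele has a uniform emission and
#' is genotyped from linkage alone; if the graph consists of that single
#' bubble there is no linkage context and the call is undefined.
#'
#' @param graph A `pangenome_graph`.
#' @param counts A `kmer_counts` produced with `params$seed`.
#' @param params A [genotyping_params()].
#' @param index Optional precomputed [index_unique_kmers()] result.
#' @return A `genotype_calls` data frame: `bubble`, `chrom`, `pos`,
#'   `allele1`, `allele2` (`NA` when undefined), `posterior`, `class`.
#' @export
genotype <- function(graph, counts, params, index = NULL) {
  stopifnot(inherits(graph, "pangenome_graph"), inherits(counts, "kmer_counts"),
            inherits(params, "genotyping_params"))
  if (params$seed$pattern != counts$seed$pattern)
    stop("seed mismatch between counts and params")
  if (is.null(index)) index <- index_unique_kmers(graph, params$seed)
  # an empty table means no k-mer evidence at all (not "every count is 0"):
  # emissions are uniform and calls come from the panel prior / linkage alone
  no_data <- length(counts$counts) == 0L
  cvg <- if (no_data || !identical(params$coverage, "auto")) {
    if (identical(params$coverage, "auto")) 1 else params$coverage
  } else estimate_coverage(index, counts)
  if (cvg <= 0) stop("coverage must be positive")

  B <- length(graph$bubbles)
  if (B == 0L) return(empty_calls())
  H <- length(graph$haplotypes)
  eps <- params$epsilon

  # log-emission table per bubble: alleles x copy-number (0,1,2)
  log_emit_allele <- function(b) {
    alleles <- graph$bubbles[[b]]$alleles
    out <- matrix(0, nrow = length(alleles), ncol = 3L)
    if (no_data) return(out)
    for (a in seq_along(alleles)) {
      km <- index$kmers[[b]][[a]]
      if (!length(km)) next
      cnt <- counts$counts[km]
      cnt[is.na(cnt)] <- 0
      for (cp in 0:2) {
        mu <- if (cp == 0L) eps * cvg else cp * cvg / 2
        out[a, cp + 1L] <- sum(dpois(cnt, mu, log = TRUE))
      }
    }
    out
  }

  # per-bubble H x H matrix of exp(log emission - max), by ordered hap pair
  emissions <- vector("list", B)
  has_kmers <- logical(B)
  for (b in seq_len(B)) {
    pa <- graph$bubbles[[b]]$panel_alleles + 1L
    le_allele <- log_emit_allele(b)
    has_kmers[b] <- !no_data && any(lengths(index$kmers[[b]]) > 0L)
    nA <- nrow(le_allele)
    lp <- matrix(0, nA, nA)  # log emission for allele pair (i,j)
    for (i in seq_len(nA)) for (j in i:nA) {
      copies <- tabulate(c(i, j), nbins = nA)
      v <- sum(le_allele[cbind(seq_len(nA), copies + 1L)])
      lp[i, j] <- v
      lp[j, i] <- v
    }
    m <- lp[pa, pa, drop = FALSE]
    emissions[[b]] <- exp(m - max(m))
  }

  transition_apply <- function(mat, theta) {
    # per-haplotype kernel A = (1-theta) I + (theta/H) J applied to both axes
    a <- 1 - theta
    bb <- theta / H
    rs <- rowSums(mat); cs <- colSums(mat); tot <- sum(mat)
    a * a * mat +
      a * bb * matrix(rs, H, H, byrow = FALSE) +  # switch second haplotype
      a * bb * matrix(cs, H, H, byrow = TRUE) +   # switch first haplotype
      bb * bb * tot
  }

  d <- bubble_distances(graph)
  theta <- 1 - exp(-params$rho * d)

  fwd <- vector("list", B)
  f <- matrix(1 / (H * H), H, H) * emissions[[1L]]
  fwd[[1L]] <- f / sum(f)
  for (b in seq_len(B)[-1L]) {
    f <- transition_apply(fwd[[b - 1L]], theta[b - 1L]) * emissions[[b]]
    fwd[[b]] <- f / sum(f)
  }
  bwd <- vector("list", B)
  bwd[[B]] <- matrix(1, H, H)
  if (B > 1L) for (b in (B - 1L):1L) {
    g <- transition_apply(bwd[[b + 1L]] * emissions[[b + 1L]], theta[b])
    bwd[[b]] <- g / sum(g)
  }

  calls <- vector("list", B)
  for (b in seq_len(B)) {
    post <- fwd[[b]] * bwd[[b]]
    post <- post / sum(post)
    pa <- graph$bubbles[[b]]$panel_alleles
    a1 <- pmin(pa[row(post)], pa[col(post)])
    a2 <- pmax(pa[row(post)], pa[col(post)])
    gkey <- paste(a1, a2, sep = "/")
    gp <- rowsum(as.vector(post), gkey)
    gposts <- setNames(as.vector(gp), rownames(gp))
    best <- pick_genotype(gposts)
    undefined <- B == 1L && !has_kmers[b]
    al <- as.integer(strsplit(best, "/", fixed = TRUE)[[1L]])
    calls[[b]] <- data.frame(
      bubble = b, chrom = graph$bubbles[[b]]$chrom,
      pos = graph$bubbles[[b]]$start + 1L,
      allele1 = if (undefined) NA_integer_ else al[1L],
      allele2 = if (undefined) NA_integer_ else al[2L],
      posterior = if (undefined) NA_real_ else unname(gposts[best]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, calls)
  out$class <- genotype_call_class(out$allele1, out$allele2)
  class(out) <- c("genotype_calls", "data.frame")
  attr(out, "coverage") <- cvg
  out
}

empty_calls <- function() {
  out <- data.frame(bubble = integer(0), chrom = character(0), pos = integer(0),
                    allele1 = integer(0), allele2 = integer(0),
                    posterior = numeric(0), class = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("genotype_calls", "data.frame")
  out
}

bubble_distances <- function(graph) {
  B <- length(graph$bubbles)
  if (B < 2L) return(numeric(0))
  d <- numeric(B - 1L)
  for (b in 2:B) {
    prev <- graph$bubbles[[b - 1L]]
    cur <- graph$bubbles[[b]]
    d[b - 1L] <- if (identical(prev$chrom, cur$chrom))
      max(1, cur$start - prev$end) else 1e9  # chromosome break: free recombination
  }
  d
}

# argmax with deterministic tie-break: more reference alleles first, then
# lexicographically smaller allele pair
pick_genotype <- function(gposts) {
  keys <- names(gposts)
  nref <- vapply(strsplit(keys, "/", fixed = TRUE),
                 function(a) sum(a == "0"), numeric(1L))
  ord <- order(-gposts, -nref, keys, method = "radix")
  keys[ord[1L]]
}

genotype_call_class <- function(a1, a2) {
  ifelse(is.na(a1), "*|*",
    ifelse(a1 == 0L & a2 == 0L, "0|0",
      ifelse(a1 == 0L, "0|1",
        ifelse(a1 == a2, "1|1", "multiallelic het"))))
}

#' @export
print.genotype_calls <- function(x, ...) {
  cat(sprintf("<genotype_calls: %d bubbles (coverage %.2f)>\n",
              nrow(x), attr(x, "coverage") %||% NA_real_))
  print.data.frame(head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Decompose bubble calls into a per-variant callset
#'
#' Merged bubbles are mapped back to the original panel records via the
#' allele decomposition recorded at graph construction; undefined bubbles
#' yield undefined genotypes at all their records.
#'
#' @param calls A `genotype_calls`.
#' @param graph The `pangenome_graph` the calls were made on.
#' @return Callset data frame (`chrom`, `pos`, `ref`, `alt`, `gt`).
#' @export
calls_to_callset <- function(calls, graph) {
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    b <- graph$bubbles[[calls$bubble[i]]]
    v <- graph$variants[b$var_ids, , drop = FALSE]
    if (is.na(calls$allele1[i])) {
      gt <- rep(NA_character_, nrow(v))
    } else {
      d1 <- b$decomp[[calls$allele1[i] + 1L]]
      d2 <- b$decomp[[calls$allele2[i] + 1L]]
      gt <- paste(pmin(d1, d2), pmax(d1, d2), sep = "/")
    }
    data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt, gt = gt,
               posterior = calls$posterior[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- data.frame(chrom = character(0), pos = integer(0),
                                      ref = character(0), alt = character(0),
                                      gt = character(0), posterior = numeric(0))
  out
}

#' Write genotype calls to VCF
#'
#' VCF 4.2 with `GT` and `GQ`; undefined genotypes are written `./.`.
#' Merged bubbles are decomposed back to the original panel records.
#'
#' @param calls A `genotype_calls`.
#' @param graph The `pangenome_graph` the calls were made on.
#' @param path Output VCF path.
#' @param sample Sample column name.
#' @export
write_calls <- function(calls, graph, path, sample = "sample") {
  cs <- calls_to_callset(calls, graph)
  gt <- ifelse(is.na(cs$gt), "./.", cs$gt)
  gq <- ifelse(is.na(cs$posterior), 0L,
               pmin(99L, as.integer(round(-10 * log10(pmax(1e-10, 1 - cs$posterior))))))
  write_vcf(cs[, c("chrom", "pos", "ref", "alt")],
            matrix(gt, ncol = 1L, dimnames = list(NULL, sample)),
            path,
            contigs = setNames(nchar(graph$reference), names(graph$reference)),
            gq = matrix(gq, ncol = 1L))
  invisible(path)
}
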