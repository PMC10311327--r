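# Independent brute-force oracles used across the test files.  These stay
# deliberately naive: exhaustive enumeration, direct formulas, no reuse of
# the package's own algorithmic paths.

# Exhaustive seed sensitivity: enumerate all 2^L match/mismatch strings.
brute_hit_probability <- function(pattern, p, L) {
  seed <- parse_seed(pattern)
  if (seed$l > L) return(0)
  bits <- t(vapply(0:(2^L - 1), function(m) as.integer(intToBits(m))[1:L],
                   integer(L)))
  hit <- rep(FALSE, nrow(bits))
  for (o in 0:(L - seed$l)) {
    sub <- bits[, o + seed$care, drop = FALSE]
    hit <- hit | rowSums(sub) == seed$w
  }
  k <- rowSums(bits)
  sum((p^k * (1 - p)^(L - k))[hit])
}

# Exhaustive count of palindromic patterns with '1' endpoints.
brute_palindromic_count <- function(l, w) {
  if (l == 1) return(as.integer(w == 1))
  if (l == 2) return(as.integer(w == 2))
  n_int <- l - 2
  count <- 0L
  for (m in 0:(2^n_int - 1)) {
    bits <- c(1L, as.integer(intToBits(m))[seq_len(n_int)], 1L)
    if (identical(bits, rev(bits)) && sum(bits) == w) count <- count + 1L
  }
  count
}

# Direct enumeration of window placements whose care mask covers a marked
# position of an (effectively infinite) sequence.
brute_kmers_covering <- function(pattern) {
  seed <- parse_seed(pattern)
  marked <- 10L * seed$l                      # far from any boundary
  hits <- 0L
  for (start in (marked - seed$l + 1L):marked)
    if ((marked - start + 1L) %in% seed$care) hits <- hits + 1L
  hits
}

# R-native spaced k-mer extraction (no shared code with the C++ kernel).
r_spaced_kmers <- function(sequence, pattern, canonical = FALSE) {
  seed <- parse_seed(pattern)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < seed$l) return(character(0))
  out <- character(0)
  for (start in 1:(n - seed$l + 1L)) {
    km <- chars[start + seed$care - 1L]
    if (!all(km %in% c("A", "C", "G", "T"))) next
    km <- paste(km, collapse = "")
    if (canonical) km <- canonicalize(km)
    out <- c(out, km)
  }
  out
}

r_count_kmers <- function(reads, pattern) {
  km <- unlist(lapply(reads, r_spaced_kmers, pattern = pattern, canonical = TRUE))
  tb <- table(km)
  setNames(as.numeric(tb), names(tb))[order(names(tb), method = "radix")]
}

# Exact Wilcoxon two-sided p by literal enumeration of sign assignments.
brute_wilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(m) {
    sum(r[as.logical(intToBits(m))[seq_len(n)]])
  }, numeric(1))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Brute-force posterior genotype marginals of the haplotype-pair HMM by
# enumerating every ordered-pair state path.  Emissions recomputed from
# the model definition: Poisson(count; copies * c/2), epsilon*c at copies 0.
brute_hmm_posteriors <- function(graph, index, counts, c, eps, rho) {
  H <- length(graph$haplotypes)
  B <- length(graph$bubbles)
  states <- expand.grid(i = 1:H, j = 1:H)
  emis <- function(b, i, j) {
    bub <- graph$bubbles[[b]]
    a_i <- bub$panel_alleles[i]
    a_j <- bub$panel_alleles[j]
    out <- 1
    for (a in seq_along(bub$alleles)) {
      km <- index$kmers[[b]][[a]]
      if (!length(km)) next
      cnt <- counts$counts[km]
      cnt[is.na(cnt)] <- 0
      copies <- sum(c(a_i, a_j) == a - 1L)
      mu <- if (copies == 0) eps * c else copies * c / 2
      out <- out * prod(dpois(cnt, mu))
    }
    out
  }
  d <- numeric(0)
  if (B > 1) for (b in 2:B)
    d[b - 1] <- max(1, graph$bubbles[[b]]$start - graph$bubbles[[b - 1]]$end)
  theta <- 1 - exp(-rho * d)
  A <- lapply(theta, function(th) (1 - th) * diag(H) + th / H * matrix(1, H, H))
  paths <- expand.grid(rep(list(seq_len(nrow(states))), B))
  post <- lapply(seq_len(B), function(b) numeric(0))
  geno_key <- function(b, s) {
    pa <- graph$bubbles[[b]]$panel_alleles
    a <- sort(pa[c(states$i[s], states$j[s])])
    paste(a, collapse = "/")
  }
  acc <- lapply(seq_len(B), function(b) list())
  total <- 0
  for (pi in seq_len(nrow(paths))) {
    path <- as.integer(paths[pi, ])
    pr <- 1 / H^2 * emis(1, states$i[path[1]], states$j[path[1]])
    if (B > 1) for (b in 2:B) {
      pr <- pr * A[[b - 1]][states$i[path[b - 1]], states$i[path[b]]] *
        A[[b - 1]][states$j[path[b - 1]], states$j[path[b]]] *
        emis(b, states$i[path[b]], states$j[path[b]])
    }
    total <- total + pr
    for (b in seq_len(B)) {
      k <- geno_key(b, path[b])
      acc[[b]][[k]] <- (acc[[b]][[k]] %||% 0) + pr
    }
  }
  lapply(acc, function(x) {
    v <- unlist(x) / total
    v[order(names(v))]
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny deterministic toy panel: biallelic SNPs at given positions
toy_panel <- function(refseq, positions, hap_matrix, alts = NULL) {
  ref <- vapply(positions, function(p) substr(refseq, p, p), "")
  if (is.null(alts))
    alts <- vapply(ref, function(b) setdiff(c("A", "C", "G", "T"), b)[1L], "")
  list(variants = data.frame(chrom = "chr1", pos = positions, ref = ref,
                             alt = alts, stringsAsFactors = FALSE),
       hap = hap_matrix)
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
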