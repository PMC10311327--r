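#' Similarity model for seed sensitivity
#'
#' I.i.d. Bernoulli model of a homologous region: each of the `L` positions
#' matches independently with probability `p` (the similarity level).
#'
#' @param p Per-position match probability in `[0,1]` (e.g. `0.95`).
#' @param L Region length in positions (e.g. `76`, half a read length).
#' @return A `similarity_model` object.
#' @export
similarity_model <- function(p = 0.95, L = 76) {
  stopifnot(length(p) == 1L, p >= 0, p <= 1, length(L) == 1L, L >= 1)
  structure(list(p = p, L = as.integer(L)), class = "similarity_model")
}

# Automaton over "longest seed-compatible suffix" states for exact seed
# sensitivity.  A binary string b (1 = match) is a compatible prefix when
# every care position of the seed that falls inside b holds a 1.  States are
# the reachable compatible strings of length <= l-1, plus an absorbing hit
# state entered when a full length-l window matches at all care positions.
# State count is bounded by l * 2^(l-w); practical for l - w up to ~16.
seed_automaton <- function(seed) {
  care <- seed$care
  l <- seed$l
  compat <- function(v) {
    idx <- care[care <= length(v)]
    !length(idx) || all(v[idx] == 1L)
  }
  longest_suffix <- function(v) {
    # longest compatible suffix of length <= l-1
    from <- max(1L, length(v) - l + 2L)
    for (k in from:(length(v) + 1L)) {
      s <- if (k > length(v)) integer(0) else v[k:length(v)]
      if (compat(s)) return(s)
    }
  }
  key <- function(v) paste0("s", paste(v, collapse = ""))
  ids <- new.env(parent = emptyenv())
  states <- list(integer(0))
  assign(key(integer(0)), 1L, envir = ids)
  to0 <- integer(0); to1 <- integer(0)  # 0 encodes the absorbing hit state
  i <- 1L
  while (i <= length(states)) {
    v <- states[[i]]
    for (ch in 0:1) {
      nxt <- c(v, ch)
      if (length(nxt) == l && compat(nxt)) {
        dest <- 0L
      } else {
        s <- longest_suffix(nxt)
        k <- key(s)
        dest <- ids[[k]]
        if (is.null(dest)) {
          states[[length(states) + 1L]] <- s
          dest <- length(states)
          assign(k, dest, envir = ids)
        }
      }
      if (ch == 0) to0[i] <- dest else to1[i] <- dest
    }
    i <- i + 1L
  }
  list(n = length(states), to0 = to0, to1 = to1)
}

#' Exact seed sensitivity (hit probability)
#'
#' Probability that, in an i.i.d. match/mismatch string of length `L` with
#' per-position match probability `p`, at least one of the `L - l + 1`
#' fully contained placements of the seed matches at every care position.
#' Computed exactly by dynamic programming over seed-compatible suffix
#' states (cost exponential only in `l - w`), not by simulation.
#'
#' @param seed A `spaced_seed` or pattern string.
#' @param model A [similarity_model()].
#' @return Hit probability in `[0,1]`; `0` when `l > L`.
#' @examples
#' hit_probability("11", similarity_model(p = 0.9, L = 2))  # 0.81
#' @export
hit_probability <- function(seed, model) {
  seed <- parse_seed(seed)
  stopifnot(inherits(model, "similarity_model"))
  if (seed$l > model$L) return(0)
  aut <- seed_automaton(seed)
  p <- model$p
  v <- numeric(aut$n)
  v[1L] <- 1
  hit <- 0
  for (step in seq_len(model$L)) {
    contrib <- c(v * (1 - p), v * p)
    dest <- c(aut$to0, aut$to1)
    hit <- hit + sum(contrib[dest == 0L])
    keep <- dest > 0L & contrib > 0
    v <- numeric(aut$n)
    if (any(keep)) {
      s <- rowsum(contrib[keep], dest[keep])
      v[as.integer(rownames(s))] <- s
    }
  }
  min(1, hit)
}

#' Overlap complexity of a seed
#'
#' Heuristic seed-quality score: for every shift `i` in
#' `-(l-1), ..., l-1` let `sigma(i)` be the number of positions at which
#' both the seed and its shifted copy have a care position; the overlap
#' complexity is `sum(2^sigma(i))`.  Low values correlate with high
#' sensitivity; contiguous seeds are among the worst at fixed weight.
#'
#' @param seed A `spaced_seed` or pattern string.
#' @return Numeric score (exact for weights below 26 or so).
#' @export
overlap_complexity <- function(seed) {
  seed <- parse_seed(seed)
  care <- seed$care
  shifts <- seq.int(-(seed$l - 1L), seed$l - 1L)
  sum(vapply(shifts, function(i) 2^sum((care + i) %in% care), numeric(1L)))
}

#' Optimize a seed by overlap-complexity hill climbing
#'
#' Starts from a random admissible seed (endpoints pinned to `'1'`) and
#' repeatedly swaps one interior care position with one interior don't-care
#' position, scanning neighbours in randomized order and accepting the
#' first swap that strictly decreases overlap complexity.  Stops at a local
#' optimum or when `iterations` neighbour evaluations are exhausted.
#'
#' @param w Seed weight, `2 <= w <= l`.
#' @param l Seed length.
#' @param model Optional [similarity_model()] (unused by the climb itself;
#'   accepted for interface symmetry with [design_palindromic_seed()]).
#' @param iterations Budget of neighbour evaluations.
#' @param rng_seed Integer; the search is deterministic given this value.
#' @return The best `spaced_seed` found.
#' @export
optimize_seed <- function(w, l, model = NULL, iterations = 2000L, rng_seed = 1L) {
  stopifnot(w >= 2, w <= l)
  if (w == l) return(contiguous_seed(w))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(rng_seed)
  interior <- 2:(l - 1L)
  pat <- integer(l)
  pat[c(1L, l)] <- 1L
  pat[sample(interior, w - 2L)] <- 1L
  oc <- overlap_complexity(pattern_to_seed(pat))
  evals <- 0L
  repeat {
    ones <- interior[pat[interior] == 1L]
    zeros <- interior[pat[interior] == 0L]
    moves <- expand.grid(one = ones, zero = zeros)
    moves <- moves[sample(nrow(moves)), , drop = FALSE]
    improved <- FALSE
    for (m in seq_len(nrow(moves))) {
      if (evals >= iterations) break
      cand <- pat
      cand[moves$one[m]] <- 0L
      cand[moves$zero[m]] <- 1L
      evals <- evals + 1L
      oc_cand <- overlap_complexity(pattern_to_seed(cand))
      if (oc_cand < oc) {
        pat <- cand
        oc <- oc_cand
        improved <- TRUE
        break
      }
    }
    if (!improved || evals >= iterations) break
  }
  pattern_to_seed(pat)
}

pattern_to_seed <- function(bits) parse_seed(paste(bits, collapse = ""))

#' Design a palindromic spaced seed
#'
#' For each candidate base length, runs [optimize_seed()] on the base
#' weight, scores the optimized base by exact [hit_probability()] under the
#' similarity model, selects the most sensitive base, and mirror-extends it
#' into a palindromic seed of weight `2*w_base - 1`.
#'
#' @param w_base Base weight (final weight is `2*w_base - 1`).
#' @param l_range Candidate base lengths to try (each `>= w_base`).
#' @param model A [similarity_model()].
#' @param rng_seed Integer seed controlling the searches.
#' @param iterations Hill-climbing budget per candidate length.
#' @return The palindromic `spaced_seed`, with attribute `"candidates"`:
#'   a data frame of (length, pattern, oc, sensitivity) for every base.
#' @export
design_palindromic_seed <- function(w_base, l_range, model = similarity_model(),
                                    rng_seed = 1L, iterations = 2000L) {
  stopifnot(w_base >= 2)
  l_range <- sort(unique(as.integer(l_range[l_range >= w_base])))
  if (!length(l_range)) stop("no candidate length is >= w_base")
  cand <- lapply(seq_along(l_range), function(i) {
    s <- optimize_seed(w_base, l_range[i], model,
                       iterations = iterations, rng_seed = rng_seed + i)
    data.frame(length = l_range[i], pattern = s$pattern,
               oc = overlap_complexity(s),
               sensitivity = hit_probability(s, model))
  })
  cand <- do.call(rbind, cand)
  best <- which.max(cand$sensitivity)
  out <- mirror_extend(cand$pattern[best])
  attr(out, "candidates") <- cand
  out
}
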