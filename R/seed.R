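#' Parse a spaced seed pattern
#'
#' A seed is a binary pattern over `'1'` (care) and `'0'` (don't-care)
#' positions.  Length `l` counts all positions, weight `w` the care
#' positions.  The first and last positions must be care positions, so that
#' every don't-care column is flanked by sampled columns.
#'
#' @param text Pattern string over `{"0","1"}`, e.g. `"1101"`.  A
#'   `spaced_seed` object is passed through unchanged.
#' @return An object of class `spaced_seed` with elements `pattern`, `l`,
#'   `w` and `care` (1-based care-position indices).
#' @examples
#' parse_seed("1101")
#' @export
parse_seed <- function(text) {
  if (inherits(text, "spaced_seed")) return(text)
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("seed pattern must be a single non-empty string")
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% c("0", "1")))
    stop("seed pattern may contain only '0' and '1': ", text)
  if (chars[1L] != "1" || chars[length(chars)] != "1")
    stop("seed pattern must start and end with a care position '1': ", text)
  care <- which(chars == "1")
  structure(list(pattern = text, l = length(chars), w = length(care), care = care),
            class = "spaced_seed")
}

#' @export
format.spaced_seed <- function(x, ...) {
  sprintf("<spaced_seed %s (l=%d, w=%d%s)>", x$pattern, x$l, x$w,
          if (x$w == x$l) ", contiguous" else "")
}

#' @export
print.spaced_seed <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.character.spaced_seed <- function(x, ...) x$pattern

#' Is a seed palindromic?
#'
#' A palindromic seed reads the same in both directions, which guarantees
#' that spaced k-mers extracted from a window and from its reverse
#' complement are reverse complements of each other, so canonical counting
#' is strand symmetric.
#'
#' @param seed A `spaced_seed` or pattern string.
#' @return `TRUE` iff the pattern equals its reversal.
#' @export
is_palindromic <- function(seed) {
  seed <- parse_seed(seed)
  chars <- strsplit(seed$pattern, "", fixed = TRUE)[[1L]]
  identical(chars, rev(chars))
}

#' Mirror-extend a seed into a palindromic seed
#'
#' Appends to the base pattern the reversal of the base pattern with its
#' final position removed.  The result has length `2*l - 1`, weight
#' `2*w - 1` (the shared centre position is counted once) and is always
#' palindromic.
#'
#' @param base A `spaced_seed` or pattern string (must end in `'1'`).
#' @return The extended `spaced_seed`.
#' @examples
#' mirror_extend("101")$pattern  # "10101"
#' @export
mirror_extend <- function(base) {
  base <- parse_seed(base)
  chars <- strsplit(base$pattern, "", fixed = TRUE)[[1L]]
  ext <- c(chars, rev(chars[-length(chars)]))
  parse_seed(paste(ext, collapse = ""))
}

#' Count admissible palindromic seeds
#'
#' Number of distinct palindromic seeds of length `l` and weight `w` whose
#' first and last positions are care positions:
#' `choose(floor(l/2) - 1, floor(w/2) - 1)`.  Only the free half of the
#' pattern can be chosen; the other half is forced by symmetry and the
#' endpoints are pinned to `'1'`.
#'
#' @param l Seed length (total positions).
#' @param w Seed weight (care positions), `w <= l`.
#' @return Exact integer-valued count (as a double; exact below 2^53).
#' @examples
#' count_palindromic_seeds(41, 31)  # 11628
#' @export
count_palindromic_seeds <- function(l, w) {
  stopifnot(length(l) == 1L, length(w) == 1L, w >= 1)
  if (w > l) return(0)
  if (w < 2L) return(as.numeric(l == 1L))  # endpoints are care positions
  if (l %% 2L == 0L && w %% 2L == 1L) return(0)  # even-length palindromes have even weight
  n <- l %/% 2L - 1L
  k <- w %/% 2L - 1L
  if (k > n) return(0)
  # multiplicative formula; every partial product is an exact integer
  out <- 1
  if (k > 0L) for (i in seq_len(k)) out <- out * (n - k + i) / i
  if (out > 2^53) warning("count exceeds exact double precision")
  round(out)
}

#' Contiguous seed of a given weight
#'
#' The all-care seed with `l = w = k`; the classical contiguous k-mer.
#'
#' @param k Weight (and length), `k >= 1`.
#' @return A contiguous `spaced_seed`.
#' @export
contiguous_seed <- function(k) {
  stopifnot(length(k) == 1L, k >= 1)
  parse_seed(strrep("1", as.integer(k)))
}

#' Read seeds from a file
#'
#' Plain text, one pattern per line; blank lines and lines starting with
#' `'#'` are ignored.
#'
#' @param path File path.
#' @return List of `spaced_seed` objects.
#' @export
read_seed_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parse_seed)
}

#' Resolve a seed argument
#'
#' Accepts a `spaced_seed`, an inline pattern string, or a path to a seed
#' file (first seed taken).  Used by the command-line wrappers.
#'
#' @param x Seed, pattern, or file path.
#' @return A `spaced_seed`.
#' @export
as_seed <- function(x) {
  if (inherits(x, "spaced_seed")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x) &&
      !grepl("^[01]+$", x))
    return(read_seed_file(x)[[1L]])
  parse_seed(x)
}
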