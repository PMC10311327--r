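#' Extract spaced k-mers from a sequence
#'
#' Slides the seed over every length-`l` window of the sequence (left to
#' right) and reads off the characters at the care positions.  Windows with
#' a non-ACGT symbol at a care position are omitted; don't-care columns may
#' hold any symbol.  K-mers are returned in window order and are *not*
#' canonicalized.
#'
#' @param sequence Nucleotide string (case-insensitive; `N` allowed).
#' @param seed A `spaced_seed` or pattern string.
#' @return Character vector of spaced k-mers (possibly empty).
#' @examples
#' extract_spaced_kmers("ACTGA", "1101")  # "ACG" "CTA"
#' @export
extract_spaced_kmers <- function(sequence, seed) {
  seed <- parse_seed(seed)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  cpp_spaced_kmers(sequence, seed$pattern, FALSE)
}

#' Reverse complement of plain character sequences
#' @param x Character vector over ACGT.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  flipped <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1L))
}

#' Canonical form of a k-mer
#'
#' The lexicographically smaller (A < C < G < T) of the k-mer and its
#' reverse complement; forward and reverse strand observations of the same
#' locus collapse onto one representative.
#'
#' @param kmer Character vector of k-mers over ACGT.
#' @return Character vector of canonical k-mers.
#' @export
canonicalize <- function(kmer) {
  if (!all(grepl("^[ACGT]+$", kmer)))
    stop("k-mers must be over the alphabet {A,C,G,T}")
  rc <- reverse_complement(kmer)
  ifelse(rc < kmer, rc, kmer)
}

#' Count canonical spaced k-mers in a read set
#'
#' Pools canonical spaced k-mer counts across all reads; both mates of
#' paired data are simply further reads.  Base qualities are ignored.
#'
#' @param reads Character vector of read sequences, a
#'   [Biostrings::DNAStringSet], or a path (or vector of paths) to
#'   FASTA/FASTQ files, plain or gzipped.
#' @param seed A `spaced_seed` or pattern string.
#' @return A `kmer_counts` object: list with `seed`, `counts` (named
#'   numeric vector, lexicographically sorted keys), `windows_total` and
#'   `windows_skipped`.
#' @export
count_reads <- function(reads, seed) {
  seed <- as_seed(seed)
  seqs <- load_sequences(reads)
  res <- cpp_spaced_count(seqs, seed$pattern, TRUE)
  counts <- setNames(res$count, res$kmer)
  counts <- counts[order(names(counts), method = "radix")]
  structure(list(seed = seed, counts = counts,
                 windows_total = res$windows_total,
                 windows_skipped = res$windows_skipped),
            class = "kmer_counts")
}

load_sequences <- function(reads) {
  if (inherits(reads, "DNAStringSet")) return(as.character(reads))
  if (!is.character(reads)) stop("reads must be sequences, files or a DNAStringSet")
  if (length(reads) && all(file.exists(reads))) {
    seqs <- unlist(lapply(reads, function(f) {
      fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", f, ignore.case = TRUE))
        "fastq" else "fasta"
      as.character(Biostrings::readDNAStringSet(f, format = fmt))
    }))
    return(unname(seqs))
  }
  reads
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat(sprintf("<kmer_counts: %d distinct canonical %d-mers, seed %s>\n",
              length(x$counts), x$seed$w, x$seed$pattern))
  cat(sprintf("  windows scanned %d, skipped %d, k-mers counted %d\n",
              x$windows_total, x$windows_skipped, sum(x$counts)))
  invisible(x)
}

#' Number of k-mers that can cover one sequence position
#'
#' The number of window placements in which a fixed position of the
#' sequence falls on a care position of the seed — one per care position,
#' i.e. the seed weight.  This is the maximum number of distinct k-mers
#' whose counts can evidence a single-nucleotide variant.
#'
#' @param seed A `spaced_seed` or pattern string.
#' @return Integer, `seed$w`.
#' @export
kmers_covering_position <- function(seed) {
  parse_seed(seed)$w
}

#' Write a k-mer count table to TSV
#'
#' Two tab-separated columns `kmer`, `count`, sorted lexicographically so
#' dumps are bit-identical across runs; header line `#seed=<pattern>`.
#'
#' @param x A `kmer_counts` object.
#' @param path Output file.
#' @export
write_kmer_counts <- function(x, path) {
  stopifnot(inherits(x, "kmer_counts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#seed=", x$seed$pattern), con)
  if (length(x$counts))
    writeLines(paste(names(x$counts), format(x$counts, scientific = FALSE, trim = TRUE),
                     sep = "\t"), con)
  invisible(path)
}

#' Read a k-mer count table written by [write_kmer_counts()]
#' @param path TSV file with a `#seed=` header.
#' @return A `kmer_counts` object (window tallies unknown, set to `NA`).
#' @export
read_kmer_counts <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "#seed="))
    stop("missing '#seed=' header in ", path)
  seed <- parse_seed(sub("^#seed=", "", lines[1L]))
  body <- lines[-1L]
  body <- body[nzchar(body)]
  counts <- numeric(0)
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    counts <- setNames(as.numeric(vapply(parts, `[[`, "", 2L)),
                       vapply(parts, `[[`, "", 1L))
  }
  structure(list(seed = seed, counts = counts,
                 windows_total = NA_real_, windows_skipped = NA_real_),
            class = "kmer_counts")
}
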