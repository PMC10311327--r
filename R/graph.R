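#' Build a pangenome bubble graph
#'
#' Combines a reference with a phased variant panel into an ordered list of
#' bubbles.  Variants whose reference spans are closer than the seed length
#' `l` are merged into one bubble (their windows would share spaced
#' k-mers), whose alleles are the distinct panel-haplotype subsequences
#' over the merged span; allele 0 is always the reference subsequence.
#' Every haplotype maps to exactly one allele per bubble.
#'
#' @param reference Named character vector of chromosome sequences, or a
#'   FASTA path.
#' @param panel Output of [read_panel_vcf()], a path to a phased VCF, or a
#'   list with `variants` (chrom/pos/ref/alt) and `hap` (allele-index
#'   matrix, sites x haplotypes).
#' @param seed A `spaced_seed` or pattern string; its length sets the
#'   merging radius.
#' @return A `pangenome_graph`: list with `reference`, `bubbles`,
#'   `haplotypes`, `seed_length` and the original `variants` table.
#' @export
build_graph <- function(reference, panel, seed) {
  seed <- as_seed(seed)
  if (is.character(reference) && length(reference) == 1L && file.exists(reference))
    reference <- setNames(
      as.character(Biostrings::readDNAStringSet(reference)),
      sub("\\s.*$", "", names(Biostrings::readDNAStringSet(reference))))
  if (is.character(panel) && length(panel) == 1L) panel <- read_panel_vcf(panel)
  variants <- panel$variants
  hap <- panel$hap
  H <- ncol(hap)
  if (H < 2L) stop("panel must contain at least two haplotypes")
  l <- seed$l

  # alleles per record: REF then comma-separated ALTs
  alleles_of <- strsplit(paste(variants$ref, variants$alt, sep = ","), ",", fixed = TRUE)
  if (nrow(variants) && any(apply(hap, 1L, max) + 1L > lengths(alleles_of)))
    stop("haplotype allele index exceeds the ALT list")

  bubbles <- list()
  for (chrom in unique(variants$chrom)) {
    refseq <- reference[[chrom]]
    if (is.null(refseq)) stop("chromosome missing from reference: ", chrom)
    idx <- which(variants$chrom == chrom)
    idx <- idx[order(variants$pos[idx])]
    start0 <- variants$pos[idx] - 1L
    end0 <- start0 + nchar(variants$ref[idx])
    for (i in seq_along(idx)) {
      v <- idx[i]
      have <- substr(refseq, start0[i] + 1L, end0[i])
      if (!identical(have, variants$ref[v]))
        stop(sprintf("REF mismatch at %s:%d (VCF '%s', reference '%s')",
                     chrom, variants$pos[v], variants$ref[v], have))
    }
    cluster_id <- cumsum(c(1L, as.integer(start0[-1L] - end0[-length(end0)] >= l)))
    for (cl in split(seq_along(idx), cluster_id)) {
      vids <- idx[cl]
      cs <- start0[cl[1L]]
      ce <- max(end0[cl])
      if (any(start0[cl][-1L] < end0[cl][-length(cl)]))
        stop("overlapping variant records cannot be merged at ",
             chrom, ":", variants$pos[vids[1L]])
      ref_allele <- substr(refseq, cs + 1L, ce)
      hap_seq <- character(H)
      hap_dec <- vector("list", H)
      for (h in seq_len(H)) {
        a <- hap[vids, h]
        hap_dec[[h]] <- a
        s <- ref_allele
        for (j in rev(seq_along(vids))) {
          if (a[j] == 0L) next
          off <- start0[cl[j]] - cs
          s <- paste0(substr(s, 1L, off),
                      alleles_of[[vids[j]]][a[j] + 1L],
                      substr(s, off + nchar(variants$ref[vids[j]]) + 1L, nchar(s)))
        }
        hap_seq[h] <- s
      }
      alleles <- ref_allele
      decomp <- list(rep(0L, length(vids)))
      panel_alleles <- integer(H)
      for (h in seq_len(H)) {
        m <- match(hap_seq[h], alleles)
        if (is.na(m)) {
          alleles <- c(alleles, hap_seq[h])
          decomp[[length(alleles)]] <- hap_dec[[h]]
          m <- length(alleles)
        }
        panel_alleles[h] <- m - 1L
      }
      bubbles[[length(bubbles) + 1L]] <-
        list(chrom = chrom, start = cs, end = ce, alleles = alleles,
             panel_alleles = panel_alleles, var_ids = vids, decomp = decomp)
    }
  }
  structure(list(reference = reference, bubbles = bubbles,
                 haplotypes = colnames(hap) %||% paste0("hap", seq_len(H)),
                 seed_length = l, variants = variants),
            class = "pangenome_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pangenome_graph <- function(x, ...) {
  nall <- vapply(x$bubbles, function(b) length(b$alleles), numeric(1L))
  cat(sprintf("<pangenome_graph: %d chromosome(s), %d bubbles (%d merged), %d haplotypes>\n",
              length(x$reference), length(x$bubbles),
              sum(vapply(x$bubbles, function(b) length(b$var_ids), numeric(1L)) > 1L),
              length(x$haplotypes)))
  if (length(nall)) cat(sprintf("  alleles per bubble: %s\n",
                                paste(range(nall), collapse = "-")))
  invisible(x)
}

#' Index spaced k-mers unique to bubble alleles
#'
#' Enumerates canonical spaced k-mers of every allele path (the allele
#' sequence plus `l - 1` flanking reference bases on each side) and of the
#' full reference; a k-mer is assigned to a (bubble, allele) iff its total
#' multiplicity — occurrences in the whole reference plus occurrences
#' across all alternative-allele paths — is exactly one.  Such a k-mer's
#' read count evidences that one allele and nothing else.
#'
#' @param graph A `pangenome_graph`.
#' @param seed A `spaced_seed` or pattern string (length must match the
#'   graph's merging radius).
#' @return A `unique_kmer_index`: per-bubble list of per-allele canonical
#'   k-mer vectors, plus carrier counts and the seed.
#' @export
index_unique_kmers <- function(graph, seed) {
  seed <- as_seed(seed)
  if (seed$l != graph$seed_length)
    stop("seed length does not match the graph's merging radius")
  l <- seed$l
  flank <- l - 1L
  path_kmers <- lapply(graph$bubbles, function(b) {
    refseq <- graph$reference[[b$chrom]]
    lf <- substr(refseq, max(1L, b$start - flank + 1L), b$start)
    rf <- substr(refseq, b$end + 1L, min(nchar(refseq), b$end + flank))
    lapply(b$alleles, function(a)
      cpp_spaced_kmers(paste0(lf, a, rf), seed$pattern, TRUE))
  })
  ref_tab <- cpp_spaced_count(unname(graph$reference), seed$pattern, TRUE)
  ref_counts <- setNames(ref_tab$count, ref_tab$kmer)

  alt_kmers <- unlist(lapply(path_kmers, function(pk) unlist(pk[-1L])))
  keys <- unique(c(names(ref_counts), alt_kmers))
  mult <- setNames(numeric(length(keys)), keys)
  mult[names(ref_counts)] <- ref_counts
  if (length(alt_kmers)) {
    tb <- table(alt_kmers)
    mult[names(tb)] <- mult[names(tb)] + as.numeric(tb)
  }

  kmers <- lapply(path_kmers, function(pk)
    lapply(pk, function(k) unique(k[mult[k] == 1])))
  carriers <- lapply(graph$bubbles, function(b)
    vapply(seq_along(b$alleles) - 1L,
           function(a) sum(b$panel_alleles == a), numeric(1L)))
  structure(list(seed = seed, kmers = kmers, carriers = carriers,
                 n_haplotypes = length(graph$haplotypes)),
            class = "unique_kmer_index")
}

#' @export
print.unique_kmer_index <- function(x, ...) {
  per_bubble <- vapply(x$kmers, function(b) sum(lengths(b)), numeric(1L))
  cat(sprintf("<unique_kmer_index: %d bubbles, %d unique k-mers (%d bubbles without any), seed %s>\n",
              length(x$kmers), sum(per_bubble), sum(per_bubble == 0),
              x$seed$pattern))
  invisible(x)
}
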