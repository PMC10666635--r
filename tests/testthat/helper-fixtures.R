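# In-code fixture builders shared across test files.

make_genes <- function(starts, stops, strands, replicon = "chr",
                       locus = NULL, ...) {
  if (is.null(locus)) locus <- sprintf("g%03d", seq_along(starts))
  gene_table(tibble::tibble(
    replicon_id = replicon, start = starts, stop = stops, strand = strands,
    locus_tag = locus, ...
  ))
}

# Forward-strand serial genes laid out so consecutive intergenic distances
# equal `d` exactly (gene length fixed).
genes_with_distances <- function(d, strand = "+", replicon = "chr",
                                 len = 300L) {
  n <- length(d) + 1L
  start <- integer(n); stop <- integer(n)
  start[1] <- 101L; stop[1] <- start[1] + len - 1L
  for (i in seq_along(d)) {
    start[i + 1] <- stop[i] + 1L + d[i]
    stop[i + 1] <- start[i + 1] + len - 1L
  }
  make_genes(start, stop, rep(strand, n), replicon = replicon)
}

# Reverse-complement a whole replicon's annotation: coordinates are mirrored
# about the sequence of length L and strands flipped.
flip_replicon <- function(genes, L = max(genes$stop) + 50L) {
  flipped <- genes
  flipped$start <- L + 1L - genes$stop
  flipped$stop <- L + 1L - genes$start
  flipped$strand <- ifelse(genes$strand == "+", "-", "+")
  flipped
}

# Independent brute-force oracle for overlap feasibility at constrained k:
# enumerate every DNA string of the minimal motif length and keep those
# carrying a start codon and a stop codon in the geometry implied by k
# (start-codon first base minus stop-codon last base minus 1 equals k, and
# the two codons jointly cover the string).
brute_force_motifs <- function(k, starts, stops) {
  L <- 3L + abs(k + 3L)
  alphabet <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid, c(rep(list(alphabet), L),
                                 stringsAsFactors = FALSE))
  strings <- apply(grid, 1, paste, collapse = "")
  ok <- vapply(strings, function(s) {
    for (i in 1:(L - 2)) {          # start codon position
      for (j in 1:(L - 2)) {        # stop codon position
        if (i - (j + 2L) - 1L != k) next
        if (min(i, j) != 1L || max(i, j) + 2L != L) next
        if (substr(s, i, i + 2) %in% starts &&
              substr(s, j, j + 2) %in% stops) return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  sort(unique(strings[ok]))
}
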