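# Core pair computation: cleanup, adjacent-pair extraction, orientation
# classification, intergenic distance, overlap phase, and codon-level
# feasibility of short overlaps.

#' Start/stop codon sets
#'
#' Canonical prokaryotic defaults: starts ATG/GTG/TTG, stops TAA/TAG/TGA.
#' `extended_start_codons` admits rare non-canonical initiators such as ATT,
#' which is the only way a 5-nt overlap can be realized.
#'
#' @param start_codons character vector of 3-letter DNA start codons.
#' @param stop_codons character vector of 3-letter DNA stop codons.
#' @param extended_start_codons optional additional start codons.
#' @return object of class `codon_sets`.
#' @export
codon_sets <- function(start_codons = c("ATG", "GTG", "TTG"),
                       stop_codons = c("TAA", "TAG", "TGA"),
                       extended_start_codons = character(0)) {
  all_codons <- c(start_codons, stop_codons, extended_start_codons)
  ok <- grepl("^[ACGT]{3}$", all_codons)
  if (!all(ok)) {
    stop("codons must be 3-letter strings over {A,C,G,T}: ",
         paste(all_codons[!ok], collapse = ", "), call. = FALSE)
  }
  structure(
    list(start_codons = unique(start_codons),
         stop_codons = unique(stop_codons),
         extended_start_codons = unique(extended_start_codons)),
    class = "codon_sets"
  )
}

#' Keep only protein-coding gene records
#'
#' Stable-RNA genes (rRNAs, tRNAs, ...) are excluded before pairing, so
#' some distances spanning an excluded RNA gene are larger than the true
#' spacing; no correction is attempted.
#'
#' @param genes gene table.
#' @return gene table restricted to `is_protein_coding` records, original
#'   order preserved.
#' @export
filter_protein_coding <- function(genes) {
  genes[genes$is_protein_coding, , drop = FALSE]
}

#' Remove gene-internal transposase records
#'
#' When a transposon inserts into a gene, the host gene is split into two
#' fragments with the transposase gene located between them; records flagged
#' `transposase_internal` are removed before pairing so the fragments become
#' neighbors again. Surviving records are never altered.
#'
#' @param genes gene table.
#' @return gene table without flagged records.
#' @export
remove_transposase_insertions <- function(genes) {
  genes[!genes$transposase_internal, , drop = FALSE]
}

#' Extract coordinate-adjacent gene pairs per replicon
#'
#' Genes are sorted along each replicon by start position (ties broken by
#' stop, then locus tag — a deterministic stable sort) and consecutive genes
#' form pairs: a replicon with n genes yields exactly n−1 pairs; pairs never
#' span replicons. Replicons are treated as linear; no pair is formed across
#' a circular origin.
#'
#' @param genes gene table.
#' @return pair table: one row per adjacent pair, with `first_*` /
#'   `second_*` columns for the gene with the smaller / larger start.
#' @export
extract_adjacent_pairs <- function(genes) {
  genes <- tibble::as_tibble(genes)
  key <- paste(genes$replicon_id, genes$start, genes$stop, genes$strand,
               genes$locus_tag, sep = "\r")
  if (anyDuplicated(key) > 0) {
    stop("duplicate gene record(s): ",
         paste(utils::head(genes$locus_tag[duplicated(key)], 5),
               collapse = ", "), call. = FALSE)
  }
  genes <- dplyr::arrange(genes, .data$replicon_id, .data$start, .data$stop,
                          .data$locus_tag)
  n <- nrow(genes)
  if (n < 2) return(empty_pair_table())
  i <- seq_len(n - 1)
  same <- genes$replicon_id[i] == genes$replicon_id[i + 1]
  i <- i[same]
  g1 <- genes[i, , drop = FALSE]
  g2 <- genes[i + 1, , drop = FALSE]
  tibble::tibble(
    replicon_id = g1$replicon_id,
    first_locus = g1$locus_tag, second_locus = g2$locus_tag,
    first_start = g1$start, first_stop = g1$stop,
    second_start = g2$start, second_stop = g2$stop,
    first_strand = g1$strand, second_strand = g2$strand,
    first_name = g1$gene_name, second_name = g2$gene_name,
    first_cog = g1$cog_id, second_cog = g2$cog_id,
    first_truncated_start = g1$truncated_start,
    first_truncated_stop = g1$truncated_stop,
    second_truncated_start = g2$truncated_start,
    second_truncated_stop = g2$truncated_stop
  )
}

empty_pair_table <- function() {
  tibble::tibble(
    replicon_id = character(0),
    first_locus = character(0), second_locus = character(0),
    first_start = integer(0), first_stop = integer(0),
    second_start = integer(0), second_stop = integer(0),
    first_strand = character(0), second_strand = character(0),
    first_name = character(0), second_name = character(0),
    first_cog = character(0), second_cog = character(0),
    first_truncated_start = logical(0), first_truncated_stop = logical(0),
    second_truncated_start = logical(0), second_truncated_stop = logical(0)
  )
}

#' Classify pair orientation and set transcription order
#'
#' Serially encoded (unidirectional, same strand), convergent (+ then −) or
#' divergent (− then +). For serial pairs the transcriptionally upstream /
#' downstream loci and names are set: on the forward strand the upstream
#' gene is the one with the smaller start; on the reverse strand it is the
#' one with the larger start.
#'
#' @param pairs pair table from [extract_adjacent_pairs()].
#' @return pair table with `orientation`, `upstream_locus`,
#'   `downstream_locus`, `upstream_name`, `downstream_name` columns.
#' @export
classify_orientation <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  s1 <- pairs$first_strand
  s2 <- pairs$second_strand
  orientation <- dplyr::case_when(
    s1 == s2 ~ "serial",
    s1 == "+" & s2 == "-" ~ "convergent",
    s1 == "-" & s2 == "+" ~ "divergent"
  )
  serial <- orientation == "serial"
  fwd <- serial & s1 == "+"
  rev <- serial & s1 == "-"
  pick <- function(first_col, second_col) {
    out <- rep(NA_character_, nrow(pairs))
    out[fwd] <- pairs[[first_col]][fwd]
    out[rev] <- pairs[[second_col]][rev]
    out
  }
  pairs$orientation <- orientation
  pairs$upstream_locus <- pick("first_locus", "second_locus")
  pairs$downstream_locus <- pick("second_locus", "first_locus")
  pairs$upstream_name <- pick("first_name", "second_name")
  pairs$downstream_name <- pick("second_name", "first_name")
  pairs$upstream_cog <- pick("first_cog", "second_cog")
  pairs$downstream_cog <- pick("second_cog", "first_cog")
  pairs
}

#' Drop serial pairs whose distance-defining termini are truncated
#'
#' Terminally truncated pseudogenes lack a start and/or stop codon, so the
#' distance between them is undefined. A serial pair is removed iff the
#' upstream gene lacks its stop codon or the downstream gene lacks its start
#' codon — the two termini that define the distance. Non-serial pairs are
#' passed through unchanged.
#'
#' @param pairs classified pair table.
#' @return pair table with affected serial pairs removed.
#' @export
drop_truncated_pairs <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  if (!"orientation" %in% names(pairs)) {
    stop("pairs must be classified first (classify_orientation)", call. = FALSE)
  }
  serial <- pairs$orientation == "serial"
  fwd <- pairs$first_strand == "+"
  up_trunc_stop <- ifelse(fwd, pairs$first_truncated_stop,
                          pairs$second_truncated_stop)
  down_trunc_start <- ifelse(fwd, pairs$second_truncated_start,
                             pairs$first_truncated_start)
  drop <- serial & (up_trunc_stop | down_trunc_start)
  pairs[!drop, , drop = FALSE]
}

#' Intergenic distance of serial gene pairs
#'
#' The distance between the stop codon of the upstream gene and the start
#' codon of the downstream gene; negative values denote overlaps. In the
#' internal coordinate format the same formula
#' `second_start − first_stop − 1` is valid on both strands, anchored so
#' that the ATGA boundary motif gives −4, TAATG gives −1, abutting genes
#' give 0 and one spacer nucleotide gives +1.
#'
#' Distances more negative than −60 nt are flagged in the returned
#' `anomalous_overlap` column (same-strand overlaps that long are known to
#' arise almost entirely from start/stop misannotation) but are never
#' dropped.
#'
#' @param pairs classified pair table; all rows must be serial.
#' @return the pair table with integer `distance`, `phase` and logical
#'   `anomalous_overlap` columns added.
#' @export
intergenic_distance <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  if (!"orientation" %in% names(pairs) || any(pairs$orientation != "serial")) {
    stop("intergenic_distance is defined for serial pairs only", call. = FALSE)
  }
  d <- pairs$second_start - pairs$first_stop - 1L
  pairs$distance <- as.integer(d)
  pairs$phase <- overlap_phase(d)
  pairs$anomalous_overlap <- d < -60L
  pairs
}

#' Reading-frame phase of an intergenic distance
#'
#' For non-overlapping genes (k ≥ 0) the phase is k − 3⌊k/3⌋; for
#' overlapping genes (k < 0) it is k + 3⌈−k/3⌉. Both branches equal the
#' nonnegative residue of k modulo 3. Long overlaps in phase 1 (−8, −11,
#' −14, ...) and phase 2 (−7, −10, −13, ...) behave very differently in
#' genomes because only phase-2 overlaps can mutate into the favored −4/−1
#' configurations.
#'
#' @param k integer vector of distances (nt).
#' @return integer vector of phases in {0, 1, 2}.
#' @export
overlap_phase <- function(k) {
  k <- as.numeric(k)
  p <- ifelse(k >= 0, k - 3 * floor(k / 3), k + 3 * ceiling(-k / 3))
  as.integer(p)
}

#' Codon-level feasibility of a short gene overlap
#'
#' For overlaps of −5 to −1 nt the downstream start codon and the upstream
#' stop codon share bases, so only some boundary motifs are compatible with
#' the codon sets. This enumerates every DNA string that carries a start
#' codon and a stop codon in the geometry implied by `k`; an empty motif set
#' means the overlap is infeasible. With canonical codons, −2 is infeasible
#' (an NTG start would imply an NNT stop, and a TRR stop would imply an RRN
#' start) and −5 is infeasible (all start codons have G in the third
#' position while all stop codons begin with T) — the ATT extended start
#' rescues −5 (ATTGA, ATTAG, ATTAA). At −3 the start codon would have to
#' coincide base-for-base with the stop codon, which no codon set allows;
#' such phase-0 overlaps are impossible on reading-frame grounds anyway.
#'
#' For k ≥ 0 or k ≤ −6 the two codons do not collide and the result is the
#' sentinel status `"unconstrained"`, with a template pattern such as
#' ATGNNTGA for k = −8.
#'
#' @param k integer scalar distance (nt).
#' @param codons a [codon_sets()] object.
#' @return object of class `overlap_feasibility` with fields `k`, `status`
#'   (`"constrained"`/`"unconstrained"`), `motifs` (character, sorted;
#'   empty = infeasible) and, when unconstrained, `pattern`.
#' @export
overlap_feasibility <- function(k, codons = codon_sets()) {
  stopifnot(length(k) == 1, is.finite(k))
  k <- as.integer(k)
  starts <- c(codons$start_codons, codons$extended_start_codons)
  stops <- codons$stop_codons
  if (k >= 0 || k <= -6) {
    pattern <- if (k >= 0) {
      paste0(stops[1], strrep("N", k), starts[1])
    } else {
      paste0(starts[1], strrep("N", -k - 6L), stops[1])
    }
    return(structure(list(k = k, status = "unconstrained",
                          motifs = character(0), pattern = pattern),
                     class = "overlap_feasibility"))
  }
  geom <- overlap_geometry(k)
  motifs <- character(0)
  for (s in starts) {
    for (x in stops) {
      m <- place_codons(s, x, geom)
      if (!is.na(m)) motifs <- c(motifs, m)
    }
  }
  structure(list(k = k, status = "constrained",
                 motifs = sort(unique(motifs)), pattern = NA_character_),
            class = "overlap_feasibility")
}

# Motif geometry for a constrained overlap (−5 <= k <= −1): 1-based
# positions of the start and stop codons within the boundary motif. The
# downstream start codon's first base sits at offset k + 4 relative to a
# stop codon at 1..3; both are shifted so the motif begins at 1.
overlap_geometry <- function(k) {
  stopifnot(k >= -5, k <= -1)
  s1 <- k + 4L  # start-codon first base relative to stop codon at 1..3
  shift <- 1L - min(1L, s1)
  start_pos <- (s1 + shift):(s1 + shift + 2L)
  stop_pos <- (1L + shift):(3L + shift)
  list(start_pos = start_pos, stop_pos = stop_pos,
       length = max(start_pos[3], stop_pos[3]))
}

place_codons <- function(start_codon, stop_codon, geom) {
  m <- rep(NA_character_, geom$length)
  m[geom$start_pos] <- strsplit(start_codon, "")[[1]]
  xc <- strsplit(stop_codon, "")[[1]]
  clash <- !is.na(m[geom$stop_pos]) & m[geom$stop_pos] != xc
  if (any(clash)) return(NA_character_)
  m[geom$stop_pos] <- xc
  paste(m, collapse = "")  # shared bases cover the whole motif at -5..-1
}

#' @export
print.overlap_feasibility <- function(x, ...) {
  if (x$status == "unconstrained") {
    cat(sprintf("k = %d: unconstrained (pattern %s)\n", x$k, x$pattern))
  } else if (length(x$motifs) == 0) {
    cat(sprintf("k = %d: infeasible (no boundary motif)\n", x$k))
  } else {
    cat(sprintf("k = %d: %s\n", x$k, paste(x$motifs, collapse = ", ")))
  }
  invisible(x)
}

#' Serial gene pairs with distances, end to end
#'
#' Convenience pipeline: protein-coding filter, transposase-insertion
#' cleanup, adjacent-pair extraction, orientation classification,
#' truncated-termini cleanup, then distance and phase for the serial pairs.
#'
#' @param genes gene table.
#' @return serial pair table with `distance` and `phase`.
#' @export
serial_gene_pairs <- function(genes) {
  genes |>
    filter_protein_coding() |>
    remove_transposase_insertions() |>
    extract_adjacent_pairs() |>
    classify_orientation() |>
    drop_truncated_pairs() |>
    dplyr::filter(.data$orientation == "serial") |>
    intergenic_distance()
}

#' Boundary motif of short-overlap serial pairs
#'
#' Extracts, from replicon sequences, the DNA motif spanning the union of
#' the upstream stop codon and downstream start codon for serial pairs with
#' −5 ≤ distance ≤ −1 (reverse-complemented for reverse-strand pairs, so the
#' motif reads in the transcription direction). Other pairs yield `NA`.
#'
#' @param pairs serial pair table with `distance`.
#' @param sequences named character vector of replicon sequences
#'   (names matching `replicon_id`).
#' @return character vector of motifs (NA outside the constrained regime).
#' @export
boundary_motif <- function(pairs, sequences) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot("distance" %in% names(pairs))
  out <- rep(NA_character_, nrow(pairs))
  idx <- which(pairs$distance >= -5L & pairs$distance <= -1L &
                 pairs$orientation == "serial")
  for (i in idx) {
    seqc <- sequences[[pairs$replicon_id[i]]]
    lo <- min(pairs$second_start[i], pairs$first_stop[i] - 2L)
    hi <- max(pairs$first_stop[i], pairs$second_start[i] + 2L)
    motif <- substr(seqc, lo, hi)
    if (pairs$first_strand[i] == "-") motif <- revcomp(motif)
    out[i] <- motif
  }
  out
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
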