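# Synthetic annotations and multi-phylum observation tables with the
# statistical structure the analysis assumes: configurable intergenic
# distance mixtures, boundary sequences consistent with start/stop codon
# constraints, shared-stem gene names enriched at short distances, and
# additive COG-pair + phylum distance observations with known truth.

#' Distance-mixture components
#'
#' A distance mixture is a list of weighted components; each draw picks a
#' component by weight and then a distance within it. `dist_point` is a
#' point mass at one integer distance, `dist_range` a uniform draw over an
#' inclusive integer range, and `dist_points` a uniform draw over an
#' explicit set of integers (used for phase-restricted long-overlap tails).
#'
#' @param at integer distance of the point mass.
#' @param lo,hi inclusive integer range bounds.
#' @param values integer vector of admissible distances.
#' @param weight positive mixture weight.
#' @return a mixture-component list.
#' @name distance_mixture
NULL

#' @rdname distance_mixture
#' @export
dist_point <- function(at, weight) {
  list(type = "point", values = as.integer(at), weight = weight)
}

#' @rdname distance_mixture
#' @export
dist_range <- function(lo, hi, weight) {
  stopifnot(lo <= hi)
  list(type = "range", values = as.integer(lo:hi), weight = weight)
}

#' @rdname distance_mixture
#' @export
dist_points <- function(values, weight) {
  list(type = "points", values = as.integer(values), weight = weight)
}

validate_mixture <- function(mixture) {
  w <- vapply(mixture, function(m) m$weight, numeric(1))
  if (any(w <= 0) || abs(sum(w) - 1) > 1e-8) {
    stop("mixture weights must be positive and sum to 1 (got ",
         format(sum(w)), ")", call. = FALSE)
  }
  invisible(mixture)
}

#' Default intergenic-distance mixture
#'
#' Emulates the distance-distribution shape seen in prokaryotic genomes:
#' dominant point masses at −4 and −1 with a secondary −8 component, a run
#' of very short positive spacings (0..+6), a narrow +9..+12 component, a
#' broad +50..+150 component of independently transcribed genes, a +13..+49
#' shoulder, a longer-distance remainder, and long-overlap tails restricted
#' to phases 1 and 2 (phase-0 overlaps cannot exist: the genes would share
#' a reading frame with the upstream stop codon in-frame).
#'
#' @return a validated mixture list.
#' @export
default_distance_mixture <- function() {
  validate_mixture(list(
    dist_point(-4L, 0.20),
    dist_point(-1L, 0.08),
    dist_point(-8L, 0.04),
    dist_range(0L, 6L, 0.10),
    dist_range(9L, 12L, 0.05),
    dist_range(13L, 49L, 0.10),
    dist_range(50L, 150L, 0.33),
    dist_range(151L, 300L, 0.02),
    dist_points(seq(-11L, -59L, by = -3L), 0.06),  # phase-1 tail
    dist_points(seq(-10L, -58L, by = -3L), 0.02)   # phase-2 tail
  ))
}

draw_from_mixture <- function(mixture, n) {
  w <- vapply(mixture, function(m) m$weight, numeric(1))
  comp <- sample.int(length(mixture), n, replace = TRUE, prob = w)
  vapply(seq_len(n), function(i) {
    v <- mixture[[comp[i]]]$values
    if (length(v) == 1) v else sample(v, 1)
  }, integer(1))
}

mixture_support <- function(mixture) {
  sort(unique(unlist(lapply(mixture, function(m) m$values))))
}

#' Genome-simulation specification
#'
#' Defines the study conditions the generator emulates. Genes are laid out
#' sequentially on each replicon; strand runs follow a Markov switch so
#' serial, convergent and divergent pairs all occur; the spacing between
#' consecutive genes is an i.i.d. draw from `distance_mixture` (for serial
#' pairs this is exactly the intergenic distance); gene lengths are uniform
#' 300–3,000 nt in whole codons. Shared-stem complex names (xyzA/xyzB) are
#' planted on serial pairs with probability `complex_pair_prob_short` when
#' the distance falls in the short (−8..+10) bin and
#' `complex_pair_prob_long` otherwise; the defaults are the complex
#' fractions observed genome-wide (35.5% vs 22.5%).
#'
#' With `emit_sequences = TRUE`, every serial boundary with a constrained
#' overlap (−5 ≤ d ≤ −1) carries a boundary motif drawn uniformly from
#' [overlap_feasibility()]; a mixture that puts mass on an infeasible
#' overlap (−2, −3, or −5 without an extended start) is rejected at spec
#' validation.
#'
#' @param n_genes genes per replicon.
#' @param n_replicons number of replicons.
#' @param strand_switch_prob probability that consecutive genes are on
#'   opposite strands.
#' @param distance_mixture mixture list (see [default_distance_mixture()]).
#' @param complex_pair_prob_short,complex_pair_prob_long probabilities of a
#'   shared-stem name pair at short vs other distances.
#' @param emit_sequences also generate boundary-consistent replicon
#'   sequences.
#' @param codons a [codon_sets()] object.
#' @param seed integer seed.
#' @return object of class `genome_sim_spec`.
#' @export
genome_sim_spec <- function(n_genes = 1000L, n_replicons = 1L,
                            strand_switch_prob = 0.25,
                            distance_mixture = default_distance_mixture(),
                            complex_pair_prob_short = 0.355,
                            complex_pair_prob_long = 0.225,
                            emit_sequences = FALSE,
                            codons = codon_sets(),
                            seed = 1L) {
  validate_mixture(distance_mixture)
  probs <- c(strand_switch_prob, complex_pair_prob_short,
             complex_pair_prob_long)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must be in [0, 1]", call. = FALSE)
  }
  if (emit_sequences) {
    support <- mixture_support(distance_mixture)
    constrained <- support[support >= -5 & support <= -1]
    for (k in constrained) {
      if (length(overlap_feasibility(k, codons)$motifs) == 0) {
        stop("spec validation error: distance mixture puts mass at k = ", k,
             ", which admits no boundary motif under the given codon sets",
             call. = FALSE)
      }
    }
  }
  structure(
    list(n_genes = as.integer(n_genes), n_replicons = as.integer(n_replicons),
         strand_switch_prob = strand_switch_prob,
         distance_mixture = distance_mixture,
         complex_pair_prob_short = complex_pair_prob_short,
         complex_pair_prob_long = complex_pair_prob_long,
         emit_sequences = emit_sequences, codons = codons,
         seed = as.integer(seed)),
    class = "genome_sim_spec"
  )
}

# unique lowercase 3+-letter stems: "aaa", "aab", ... deterministic in index
stem_name <- function(idx) {
  vapply(idx, function(i) {
    i <- i - 1L
    s <- character(0)
    repeat {
      s <- c(letters[(i %% 26L) + 1L], s)
      i <- i %/% 26L
      if (i == 0 && length(s) >= 3) break
      if (i == 0) { s <- c("a", s) } # pad to 3 letters
    }
    paste(s, collapse = "")
  }, character(1))
}

#' Simulate a genome annotation
#'
#' @param spec a [genome_sim_spec()].
#' @return list with `genes` (a gene table) and, when the spec emits
#'   sequences, `sequences` (named character vector suitable for
#'   [write_replicon_fasta()]); fully reproducible from the spec's seed.
#' @export
simulate_genome_annotation <- function(spec) {
  stopifnot(inherits(spec, "genome_sim_spec"))
  set.seed(spec$seed)
  gene_list <- vector("list", spec$n_replicons)
  sequences <- if (spec$emit_sequences) character(spec$n_replicons) else NULL
  stem_counter <- 0L

  for (r in seq_len(spec$n_replicons)) {
    rid <- sprintf("replicon_%02d", r)
    n <- spec$n_genes
    # strand runs: Markov switch
    flips <- stats::runif(n - 1) < spec$strand_switch_prob
    strand <- character(n)
    strand[1] <- sample(c("+", "-"), 1)
    for (i in seq_len(n - 1)) {
      strand[i + 1] <- if (flips[i]) setdiff(c("+", "-"), strand[i]) else strand[i]
    }
    len <- 3L * sample(100:1000, n, replace = TRUE)
    d <- draw_from_mixture(spec$distance_mixture, n - 1L)
    start <- integer(n); stop <- integer(n)
    start[1] <- 101L
    stop[1] <- start[1] + len[1] - 1L
    for (i in seq_len(n - 1)) {
      start[i + 1] <- stop[i] + 1L + d[i]
      stop[i + 1] <- start[i + 1] + len[i + 1] - 1L
    }

    # shared-stem names on serial boundaries, bin-dependent probability
    name <- rep(NA_character_, n)
    serial <- strand[-n] == strand[-1]
    bin <- bin_by_distance(d)
    p <- ifelse(bin == "short", spec$complex_pair_prob_short,
                spec$complex_pair_prob_long)
    plant <- serial & stats::runif(n - 1L) < p
    for (i in which(plant)) {
      if (!is.na(name[i]) || !is.na(name[i + 1])) next
      stem_counter <- stem_counter + 1L
      stem <- stem_name(stem_counter)
      up <- if (strand[i] == "+") i else i + 1L
      dn <- if (strand[i] == "+") i + 1L else i
      name[up] <- paste0(stem, "A")
      name[dn] <- paste0(stem, "B")
    }
    # the rest get unique stems (no accidental shared-stem pairs)
    unnamed <- which(is.na(name))
    named_alone <- unnamed[stats::runif(length(unnamed)) < 0.5]
    for (i in named_alone) {
      stem_counter <- stem_counter + 1L
      name[i] <- paste0(stem_name(stem_counter), "A")
    }

    genes <- gene_table(tibble::tibble(
      replicon_id = rid, start = start, stop = stop, strand = strand,
      locus_tag = sprintf("SYN%02d_%05d", r, seq_len(n)),
      gene_name = name
    ))
    gene_list[[r]] <- genes

    if (spec$emit_sequences) {
      sequences[r] <- simulate_replicon_sequence(genes, d, spec$codons)
      names(sequences)[r] <- rid
    }
  }
  genes <- dplyr::bind_rows(gene_list)
  out <- list(genes = genes)
  if (spec$emit_sequences) out$sequences <- sequences
  out
}

# Random sequence with start/stop codons stamped at every gene terminus
# (strand-aware) and feasibility-drawn motifs stamped over constrained
# serial boundaries (the motif jointly encodes both colliding codons).
simulate_replicon_sequence <- function(genes, d, codons) {
  L <- max(genes$stop) + 100L
  seqv <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  starts <- codons$start_codons
  stops <- codons$stop_codons
  put <- function(pos, s) {
    seqv[pos:(pos + nchar(s) - 1L)] <<- strsplit(s, "")[[1]]
  }
  for (i in seq_len(nrow(genes))) {
    sc <- sample(starts, 1)
    xc <- sample(stops, 1)
    if (genes$strand[i] == "+") {
      put(genes$start[i], sc)
      put(genes$stop[i] - 2L, xc)
    } else {
      put(genes$stop[i] - 2L, revcomp(sc))
      put(genes$start[i], revcomp(xc))
    }
  }
  serial <- genes$strand[-nrow(genes)] == genes$strand[-1]
  for (i in which(serial & d >= -5L & d <= -1L)) {
    motifs <- overlap_feasibility(d[i], codons)$motifs
    motif <- if (length(motifs) == 1) motifs else sample(motifs, 1)
    first_stop <- genes$stop[i]
    second_start <- genes$start[i + 1L]
    lo <- min(second_start, first_stop - 2L)
    if (genes$strand[i] == "-") motif <- revcomp(motif)
    put(lo, motif)
  }
  paste(seqv, collapse = "")
}

#' Multi-phylum simulation specification
#'
#' Generative twin of the additive distance model: every observation is
#' `round(C_i + P_j + Normal(0, noise_sd))`, with true COG-pair effects
#' `C_i` drawn from a normal with the given mean/sd, true phylum effects
#' `P_j` drawn with mean 0 and the reference phylum pinned to exactly 0.
#' True effects are rounded to whole nucleotides (annotated distances are
#' integral), so noise-free data are recovered exactly by the fit;
#' observations are rounded after noise is added.
#'
#' Per-COG-pair complex flags are drawn with a distance-bin-dependent
#' probability so a known enrichment is planted: `complex_fraction_short`
#' for COG pairs whose true effect falls in the short (−8..+10) bin,
#' `complex_fraction_long` otherwise. Defaults follow the genome-wide
#' study conditions: 214 COG pairs, 49 phyla, effect sds 38.2 and 2.9 nt,
#' complex fractions 35.5% and 22.5%.
#'
#' @param n_cog_pairs number of COG pairs.
#' @param n_phyla number of phyla (first one is the reference).
#' @param C_mean,C_sd distribution of true COG-pair effects (nt).
#' @param P_sd sd of true phylum effects (nt; mean 0, reference pinned 0).
#' @param obs_per_cell observations per (COG pair, phylum) cell: a single
#'   integer or an inclusive range `c(lo, hi)` sampled per cell.
#' @param noise_sd residual sd (nt).
#' @param complex_fraction_short,complex_fraction_long planted complex-flag
#'   probabilities by bin.
#' @param seed integer seed.
#' @return object of class `multi_phylum_sim_spec`.
#' @export
multi_phylum_sim_spec <- function(n_cog_pairs = 214L, n_phyla = 49L,
                                  C_mean = 5, C_sd = 38.2, P_sd = 2.9,
                                  obs_per_cell = 26L, noise_sd = 10,
                                  complex_fraction_short = 0.355,
                                  complex_fraction_long = 0.225,
                                  seed = 1L) {
  if (C_sd < 0 || P_sd < 0 || noise_sd < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  probs <- c(complex_fraction_short, complex_fraction_long)
  if (any(probs < 0 | probs > 1)) {
    stop("complex fractions must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_cog_pairs = as.integer(n_cog_pairs),
         n_phyla = as.integer(n_phyla),
         C_mean = C_mean, C_sd = C_sd, P_sd = P_sd,
         obs_per_cell = as.integer(obs_per_cell), noise_sd = noise_sd,
         complex_fraction_short = complex_fraction_short,
         complex_fraction_long = complex_fraction_long,
         seed = as.integer(seed)),
    class = "multi_phylum_sim_spec"
  )
}

#' Simulate a multi-phylum distance-observation dataset
#'
#' @param spec a [multi_phylum_sim_spec()].
#' @return list with `observations` (tibble `cog_pair_id`, `phylum`,
#'   `distance`), `C_true` and `P_true` (named effect vectors;
#'   `P_true[reference] == 0`), `reference_phylum`, and `complex_flags`
#'   (tibble `cog_pair_id`, `complex_flag`, `true_bin`, `gene_pair_count`).
#' @export
simulate_multi_phylum_dataset <- function(spec) {
  stopifnot(inherits(spec, "multi_phylum_sim_spec"))
  set.seed(spec$seed)
  nI <- spec$n_cog_pairs
  nJ <- spec$n_phyla
  cog_ids <- sprintf("CP%04d", seq_len(nI))
  phyla <- sprintf("Phylum%02d", seq_len(nJ))
  C_true <- stats::setNames(
    round(stats::rnorm(nI, spec$C_mean, spec$C_sd)), cog_ids)
  P_true <- stats::setNames(round(stats::rnorm(nJ, 0, spec$P_sd)), phyla)
  P_true[1] <- 0  # reference phylum pinned exactly

  opc <- spec$obs_per_cell
  n_cell <- if (length(opc) == 2) {
    sample(opc[1]:opc[2], nI * nJ, replace = TRUE)
  } else {
    rep(opc, nI * nJ)
  }
  i <- rep(rep(seq_len(nI), each = nJ), times = n_cell)
  j <- rep(rep(seq_len(nJ), times = nI), times = n_cell)
  n_obs <- length(i)
  distance <- round(C_true[i] + P_true[j] + stats::rnorm(n_obs, 0, spec$noise_sd))

  observations <- tibble::tibble(
    cog_pair_id = cog_ids[i],
    phylum = phyla[j],
    distance = as.integer(unname(distance))
  )
  true_bin <- bin_by_distance(unname(C_true))
  p_flag <- ifelse(true_bin == "short", spec$complex_fraction_short,
                   spec$complex_fraction_long)
  complex_flags <- tibble::tibble(
    cog_pair_id = cog_ids,
    complex_flag = stats::runif(nI) < p_flag,
    true_bin = true_bin,
    gene_pair_count = as.integer(tabulate(i, nI))
  )
  list(observations = observations, C_true = C_true, P_true = P_true,
       reference_phylum = phyla[1], complex_flags = complex_flags)
}

#' COG-pair table for the bootstrap, from observations and flags
#'
#' Summarizes observations per COG pair (median distance, default on the
#' taxonomically adjusted scale when present), bins the summaries, and joins
#' the complex flags and gene-pair counts into the table consumed by
#' [bootstrap_enrichment()].
#'
#' @param observations observation tibble (optionally with
#'   `adjusted_distance`).
#' @param complex_flags tibble with `cog_pair_id`, `complex_flag`.
#' @param statistic summary statistic (see [summarize_cog_pair()]).
#' @param ... bin bounds passed to [bin_by_distance()].
#' @return tibble with `cog_pair_id`, `complex_flag`, `distance_bin`,
#'   `gene_pair_count`, `summary_distance`.
#' @export
cog_pair_enrichment_table <- function(observations, complex_flags,
                                      statistic = "median", ...) {
  summ <- summarize_cog_pair(observations, statistic = statistic)
  summ$distance_bin <- bin_by_distance(summ$summary_distance, ...)
  out <- dplyr::inner_join(
    summ, tibble::as_tibble(complex_flags)[, c("cog_pair_id", "complex_flag")],
    by = "cog_pair_id")
  tibble::tibble(
    cog_pair_id = out$cog_pair_id,
    complex_flag = out$complex_flag,
    distance_bin = out$distance_bin,
    gene_pair_count = out$n_pairs,
    summary_distance = out$summary_distance
  )
}
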