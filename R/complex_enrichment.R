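# Heteromeric-complex enrichment: shared-stem name heuristic, distance
# binning, 2x2 contingency table, enrichment ratio, chi-squared test, and a
# double-resampling bootstrap (COG pairs resampled without replacement at a
# fixed inclusion probability, then gene pairs resampled with replacement).

#' Shared-stem heteromeric-complex heuristic
#'
#' Two neighboring genes are inferred to encode subunits of the same
#' heteromeric complex when their names share a stem and differ only in a
#' single trailing uppercase letter (xyzA upstream / xyzB downstream). The
#' heuristic is conservative and not fully accurate — shared stems also name
#' pathway enzymes — but is applied uniformly across genomes.
#'
#' @param name_up,name_down character vectors of gene names (NA allowed).
#' @return logical vector; `FALSE` wherever a name is missing.
#' @export
shared_stem_complex_flag <- function(name_up, name_down) {
  n <- max(length(name_up), length(name_down))
  name_up <- rep_len(as.character(name_up), n)
  name_down <- rep_len(as.character(name_down), n)
  ok <- !is.na(name_up) & !is.na(name_down)
  pat <- "^(.+)([A-Z])$"
  m_up <- ok & grepl(pat, name_up)
  m_dn <- ok & grepl(pat, name_down)
  stem_up <- sub(pat, "\\1", name_up)
  stem_dn <- sub(pat, "\\1", name_down)
  let_up <- sub(pat, "\\2", name_up)
  let_dn <- sub(pat, "\\2", name_down)
  m_up & m_dn & stem_up == stem_dn & stem_up != "" & let_up != let_dn
}

#' Bin distances into short / long / excluded classes
#'
#' Short distances (default −8 to +10 nt) are predictive of translational
#' coupling by termination–reinitiation; long distances (default > +20 nt)
#' of independent translation. The in-between window (+11 to +20 by default)
#' is excluded because coupling there is highly gene-specific, and distances
#' below the short bound (long overlaps) are excluded as well.
#'
#' @param distance numeric vector of distances or per-COG-pair summary
#'   distances (nt).
#' @param short_lo,short_hi inclusive bounds of the short bin.
#' @param long_gt exclusive lower bound of the long bin.
#' @return factor with levels `short`, `long`, `excluded`.
#' @export
bin_by_distance <- function(distance, short_lo = -8, short_hi = 10,
                            long_gt = 20) {
  if (short_lo > short_hi || short_hi > long_gt) {
    stop("invalid bins: need short_lo <= short_hi <= long_gt", call. = FALSE)
  }
  out <- ifelse(distance >= short_lo & distance <= short_hi, "short",
                ifelse(distance > long_gt, "long", "excluded"))
  factor(out, levels = c("short", "long", "excluded"))
}

#' 2x2 complex-by-distance contingency table
#'
#' @param a complex & short count.
#' @param b non-complex & short count.
#' @param c complex & long count.
#' @param d non-complex & long count.
#' @return object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  structure(as.list(counts), class = "contingency_2x2")
}

#' Build the contingency table from binned pairs
#'
#' Excluded pairs are never counted.
#'
#' @param bins factor from [bin_by_distance()].
#' @param complex_flags logical vector, same length.
#' @return `contingency_2x2`.
#' @export
contingency_table <- function(bins, complex_flags) {
  stopifnot(length(bins) == length(complex_flags))
  complex_flags <- as.logical(complex_flags)
  contingency_2x2(
    a = sum(bins == "short" & complex_flags, na.rm = TRUE),
    b = sum(bins == "short" & !complex_flags, na.rm = TRUE),
    c = sum(bins == "long" & complex_flags, na.rm = TRUE),
    d = sum(bins == "long" & !complex_flags, na.rm = TRUE)
  )
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("            complex  no-complex   sum\n"))
  cat(sprintf("short      %8d  %10d  %5d\n", x$a, x$b, x$a + x$b))
  cat(sprintf("long       %8d  %10d  %5d\n", x$c, x$d, x$c + x$d))
  invisible(x)
}

#' Enrichment of complex formation at short distances
#'
#' The fraction of complex-encoding pairs in the short-distance group
#' divided by that fraction in the long-distance group:
#' `(a/(a+b)) / (c/(c+d))`. Invariant to scaling all four counts by the same
#' positive factor.
#'
#' @param table `contingency_2x2`.
#' @return dimensionless ratio; `Inf` with a warning when the long group has
#'   no complex pairs.
#' @export
enrichment_ratio <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  if (table$a + table$b == 0 || table$c + table$d == 0) {
    stop("empty distance group; enrichment undefined", call. = FALSE)
  }
  short_frac <- table$a / (table$a + table$b)
  long_frac <- table$c / (table$c + table$d)
  if (long_frac == 0) {
    warning("no complex pairs in the long-distance group; ratio is infinite",
            call. = FALSE)
    return(Inf)
  }
  short_frac / long_frac
}

#' Pearson chi-squared test on the 2x2 table
#'
#' Without continuity correction, df = 1; the p-value is the chi-squared
#' survival function of the statistic. Counts of genome-scale magnitude make
#' the correction negligible.
#'
#' @param table `contingency_2x2`.
#' @return list with `chi2` and `p`.
#' @export
chi_square_test <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  m <- matrix(c(table$a, table$b, table$c, table$d), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate table: zero marginal", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(ht$statistic), p = ht$p.value)
}

#' Double-resampling bootstrap of the enrichment ratio
#'
#' Resampling respects the two-level structure of the data (gene pairs
#' nested in COG pairs): on each replicate, (1) every COG pair is included
#' independently with probability `inclusion_prob` (default 1 − e⁻¹ ≈ 0.63,
#' the asymptotic inclusion probability of an ordinary bootstrap); (2) the
#' full number of gene pairs is drawn with replacement from the included COG
#' pairs, weighted by each pair's gene-pair count; (3) the enrichment ratio
#' is computed on the resampled 2x2 table. The z-score is the mean of the
#' replicate log-ratios divided by their standard deviation (base-invariant;
#' natural logs used), and the p-value is the upper-tail standard-normal
#' probability.
#'
#' Degenerate replicates — ones whose resampled table yields a nonpositive
#' or infinite ratio (e.g., no complex pairs left in the long group) — are
#' excluded and counted; a warning is raised when they exceed 10% of
#' replicates.
#'
#' @param cog_pair_table tibble with one row per COG pair: `cog_pair_id`,
#'   `complex_flag` (logical), `distance_bin` (`"short"`/`"long"`; other
#'   bins are dropped), `gene_pair_count`.
#' @param n_reps number of replicates (default 1000).
#' @param inclusion_prob per-COG-pair inclusion probability.
#' @param seed optional integer seed for full reproducibility.
#' @return object of class `bootstrap_enrichment`: `replicate_ratios`,
#'   `n_reps`, `n_degenerate`, `z`, `p_normal`, `seed`, `inclusion_prob`.
#' @export
bootstrap_enrichment <- function(cog_pair_table, n_reps = 1000L,
                                 inclusion_prob = 1 - exp(-1), seed = NULL) {
  tbl <- tibble::as_tibble(cog_pair_table)
  required <- c("cog_pair_id", "complex_flag", "distance_bin",
                "gene_pair_count")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    stop("cog_pair_table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (n_reps < 2) stop("n_reps must be >= 2", call. = FALSE)
  tbl <- tbl[as.character(tbl$distance_bin) %in% c("short", "long"), ,
             drop = FALSE]
  if (nrow(tbl) == 0 || sum(tbl$gene_pair_count) == 0) {
    stop("no gene pairs in the short/long bins", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  flag <- as.logical(tbl$complex_flag)
  short <- as.character(tbl$distance_bin) == "short"
  w <- as.numeric(tbl$gene_pair_count)
  n_total <- sum(w)
  n_cog <- nrow(tbl)
  # cell membership of every COG pair: a (complex,short), b, c, d
  cell_a <- flag & short
  cell_b <- !flag & short
  cell_c <- flag & !short

  ratios <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    keep <- stats::runif(n_cog) < inclusion_prob
    if (!any(keep)) next
    counts <- numeric(n_cog)
    counts[keep] <- stats::rmultinom(1, size = n_total, prob = w[keep])
    a <- sum(counts[cell_a]); b <- sum(counts[cell_b])
    cc <- sum(counts[cell_c])
    dd <- n_total - a - b - cc
    if (a + b == 0 || cc + dd == 0 || cc == 0 || a == 0) next
    ratios[r] <- (a / (a + b)) / (cc / (cc + dd))
  }
  ok <- is.finite(ratios) & ratios > 0
  n_degenerate <- sum(!ok)
  if (n_degenerate > 0.1 * n_reps) {
    warning(n_degenerate, " of ", n_reps,
            " bootstrap replicates were degenerate and excluded",
            call. = FALSE)
  }
  lr <- log(ratios[ok])
  z <- mean(lr) / stats::sd(lr)
  structure(
    list(replicate_ratios = ratios[ok], n_reps = as.integer(n_reps),
         n_degenerate = as.integer(n_degenerate), z = z,
         p_normal = stats::pnorm(z, lower.tail = FALSE),
         seed = seed, inclusion_prob = inclusion_prob),
    class = "bootstrap_enrichment"
  )
}

#' @export
print.bootstrap_enrichment <- function(x, ...) {
  cat(sprintf(
    "bootstrap enrichment: %d replicates (%d degenerate), median ratio %.3f\n",
    x$n_reps, x$n_degenerate, stats::median(x$replicate_ratios)))
  cat(sprintf("z = %.2f, one-sided normal p = %.3g\n", x$z, x$p_normal))
  invisible(x)
}

#' Full enrichment report for a 2x2 table
#'
#' Assembles the short/long complex fractions, the enrichment ratio, the
#' chi-squared test, and (optionally) the bootstrap into one object.
#'
#' @param table `contingency_2x2`.
#' @param bootstrap optional `bootstrap_enrichment` result.
#' @return object of class `enrichment_report`.
#' @export
enrichment_report <- function(table, bootstrap = NULL) {
  chi <- chi_square_test(table)
  structure(
    list(
      table = table,
      short_fraction = table$a / (table$a + table$b),
      long_fraction = table$c / (table$c + table$d),
      enrichment = enrichment_ratio(table),
      chi2 = chi$chi2,
      p_chi2 = chi$p,
      bootstrap = bootstrap
    ),
    class = "enrichment_report"
  )
}

#' @export
print.enrichment_report <- function(x, ...) {
  print(x$table)
  cat(sprintf(
    "complex fraction: %.1f%% (short) vs %.1f%% (long) -> %.1f-fold enrichment\n",
    100 * x$short_fraction, 100 * x$long_fraction, x$enrichment))
  cat(sprintf("chi-squared = %.1f, p = %.3g\n", x$chi2, x$p_chi2))
  if (!is.null(x$bootstrap)) print(x$bootstrap)
  invisible(x)
}
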