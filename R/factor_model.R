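# Two-factor additive decomposition of intergenic distances across species:
# the distance of the k-th observation in COG pair i and phylum j is modeled
# as d = C_i + P_j + e, with the reference phylum's effect pinned to 0.
# Fitting minimizes the sum of squared deviations over all observations.

check_observations <- function(observations) {
  observations <- tibble::as_tibble(observations)
  required <- c("cog_pair_id", "phylum", "distance")
  missing_cols <- setdiff(required, names(observations))
  if (length(missing_cols) > 0) {
    stop("observations missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(observations$cog_pair_id) | observations$cog_pair_id == "" |
            is.na(observations$phylum) | observations$phylum == "")) {
    stop("cog_pair_id and phylum must be non-empty", call. = FALSE)
  }
  observations
}

#' Restrict observations to widely occurring COG pairs
#'
#' Keeps only observations whose COG pair occurs in at least `min_phyla`
#' distinct phyla, so that pair-specific effects are estimated across a
#' taxonomically broad sample.
#'
#' @param observations tibble with `cog_pair_id`, `phylum`, `distance`.
#' @param min_phyla minimum number of distinct phyla (default 25).
#' @return the qualifying subset of `observations`.
#' @export
select_widespread_cog_pairs <- function(observations, min_phyla = 25L) {
  observations <- check_observations(observations)
  keep <- observations |>
    dplyr::group_by(.data$cog_pair_id) |>
    dplyr::summarise(n_phyla = dplyr::n_distinct(.data$phylum)) |>
    dplyr::filter(.data$n_phyla >= min_phyla)
  observations[observations$cog_pair_id %in% keep$cog_pair_id, , drop = FALSE]
}

#' Fit the additive COG-pair + phylum distance model
#'
#' Minimizes the sum of squared residuals of `distance = C[cog_pair] +
#' P[phylum] + e` subject to `P[reference_phylum] = 0`. The default solver
#' is alternating minimization with exact coordinate updates (each factor's
#' effect set to the mean residual over its observations, the reference
#' pinned to 0 after every sweep); `method = "direct"` solves the
#' dummy-coded sparse least-squares system instead and exists mainly as an
#' independent route for verification.
#'
#' The COG-pair/phylum incidence graph must be connected, otherwise the
#' effects are not identifiable and an error lists the components.
#'
#' @param observations tibble with `cog_pair_id`, `phylum`, `distance`.
#' @param reference_phylum phylum whose effect is pinned to 0; default the
#'   phylum with the most observations.
#' @param method `"alternating"` (default) or `"direct"`.
#' @param tol relative sse-improvement convergence threshold for the
#'   alternating solver; the default 0 iterates to the floating-point fixed
#'   point (the sweep at which the sse stops improving), which keeps the
#'   effect estimates themselves converged, not just the sse.
#' @param max_sweeps sweep cap for the alternating solver.
#' @return object of class `factor_fit`: named effect vectors `C` and `P`
#'   (reference included as 0), `residuals`, `sse`, `sd_C`, `sd_P`,
#'   `reference_phylum`, `sse_trace`, `sweeps`.
#' @export
fit_two_factor_model <- function(observations, reference_phylum = NULL,
                                 method = c("alternating", "direct"),
                                 tol = 0, max_sweeps = 10000L) {
  method <- match.arg(method)
  observations <- check_observations(observations)
  if (nrow(observations) == 0) stop("no observations", call. = FALSE)

  cog <- factor(observations$cog_pair_id)
  phy <- factor(observations$phylum)
  d <- as.numeric(observations$distance)

  if (is.null(reference_phylum)) {
    reference_phylum <- names(which.max(table(phy)))
  }
  if (!reference_phylum %in% levels(phy)) {
    stop("reference phylum '", reference_phylum,
         "' not present among observations", call. = FALSE)
  }
  check_incidence_connected(cog, phy)

  if (method == "alternating") {
    fit <- fit_alternating(d, cog, phy, reference_phylum, tol, max_sweeps)
  } else {
    fit <- fit_direct(d, cog, phy, reference_phylum)
  }
  C <- fit$C; P <- fit$P
  resid <- d - C[as.integer(cog)] - P[as.integer(phy)]
  structure(
    list(
      C = stats::setNames(C, levels(cog)),
      P = stats::setNames(P, levels(phy)),
      residuals = resid,
      sse = sum(resid^2),
      sd_C = stats::sd(C),
      sd_P = stats::sd(P),
      reference_phylum = reference_phylum,
      method = method,
      sse_trace = fit$sse_trace,
      sweeps = fit$sweeps
    ),
    class = "factor_fit"
  )
}

check_incidence_connected <- function(cog, phy) {
  edges <- unique(data.frame(from = paste0("cog:", as.character(cog)),
                             to = paste0("phy:", as.character(phy))))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    sizes <- paste(comp$csize, collapse = ", ")
    members <- split(names(comp$membership), comp$membership)
    preview <- vapply(members, function(m)
      paste(utils::head(m, 3), collapse = ","), character(1))
    stop("COG-pair/phylum incidence graph is disconnected (", comp$no,
         " components of sizes ", sizes, "; e.g. ",
         paste(preview, collapse = " | "), "); effects not identifiable",
         call. = FALSE)
  }
  invisible(TRUE)
}

fit_alternating <- function(d, cog, phy, reference_phylum, tol, max_sweeps) {
  i <- as.integer(cog)
  j <- as.integer(phy)
  nI <- nlevels(cog); nJ <- nlevels(phy)
  ref <- match(reference_phylum, levels(phy))
  n_i <- tabulate(i, nI)
  n_j <- tabulate(j, nJ)
  # init: C at per-COG-pair means, P at 0
  C <- as.numeric(rowsum(d, i)[, 1] / n_i)
  P <- numeric(nJ)
  sse <- sum((d - C[i] - P[j])^2)
  trace <- sse
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    P <- as.numeric(rowsum(d - C[i], j)[, 1] / n_j)
    C <- as.numeric(rowsum(d - P[j], i)[, 1] / n_i)
    # pin the reference: pure gauge shift, leaves fitted values and sse alone
    shift <- P[ref]
    P <- P - shift
    C <- C + shift
    sse_new <- sum((d - C[i] - P[j])^2)
    trace <- c(trace, sse_new)
    done <- sweeps >= max_sweeps ||
      (sse - sse_new) <= tol * max(sse, .Machine$double.eps) ||
      sse_new < 1e-18
    sse <- sse_new
    if (done) break
  }
  list(C = C, P = P, sse_trace = trace, sweeps = sweeps)
}

fit_direct <- function(d, cog, phy, reference_phylum) {
  i <- as.integer(cog)
  j <- as.integer(phy)
  nI <- nlevels(cog); nJ <- nlevels(phy)
  ref <- match(reference_phylum, levels(phy))
  n <- length(d)
  # columns: nI COG-pair indicators, then nJ-1 phylum indicators (ref dropped)
  jmap <- match(j, setdiff(seq_len(nJ), ref))  # NA for reference rows
  rows <- c(seq_len(n), which(!is.na(jmap)))
  cols <- c(i, nI + jmap[!is.na(jmap)])
  X <- Matrix::sparseMatrix(i = rows, j = cols, x = 1,
                            dims = c(n, nI + nJ - 1L))
  beta <- as.numeric(Matrix::solve(Matrix::crossprod(X),
                                   Matrix::crossprod(X, d)))
  C <- beta[seq_len(nI)]
  P <- numeric(nJ)
  P[setdiff(seq_len(nJ), ref)] <- beta[(nI + 1L):(nI + nJ - 1L)]
  list(C = C, P = P, sse_trace = numeric(0), sweeps = 0L)
}

#' @export
print.factor_fit <- function(x, ...) {
  cat(sprintf(
    "two-factor distance fit: %d COG-pair effects (sd %.2f nt), %d phylum effects (sd %.2f nt)\n",
    length(x$C), x$sd_C, length(x$P), x$sd_P))
  cat(sprintf("reference phylum: %s; sse = %.6g over %d observations (%s)\n",
              x$reference_phylum, x$sse, length(x$residuals), x$method))
  invisible(x)
}

#' Taxonomically adjusted distances
#'
#' Subtracts the fitted phylum effect from each observed distance; distances
#' in the reference phylum are unchanged since its effect is 0.
#'
#' @param observations tibble with `cog_pair_id`, `phylum`, `distance`.
#' @param fit a [fit_two_factor_model()] result covering all phyla present.
#' @return the observations with an `adjusted_distance` column.
#' @export
adjust_distances <- function(observations, fit) {
  observations <- check_observations(observations)
  unseen <- setdiff(unique(observations$phylum), names(fit$P))
  if (length(unseen) > 0) {
    stop("phylum (-a) not covered by the fit: ",
         paste(unseen, collapse = ", "), call. = FALSE)
  }
  observations$adjusted_distance <-
    observations$distance - unname(fit$P[observations$phylum])
  observations
}

#' Per-COG-pair summary of (adjusted) distances
#'
#' @param observations tibble with `cog_pair_id` and a distance column; the
#'   `adjusted_distance` column is used when present, otherwise `distance`.
#' @param statistic `"median"` (default, matching how pairs are assigned to
#'   distance bins) or `"mean"`.
#' @return tibble with `cog_pair_id`, `summary_distance`, `n_pairs`.
#' @export
summarize_cog_pair <- function(observations, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  observations <- tibble::as_tibble(observations)
  val <- if ("adjusted_distance" %in% names(observations)) {
    observations$adjusted_distance
  } else {
    observations$distance
  }
  f <- if (statistic == "median") stats::median else mean
  tibble::tibble(cog_pair_id = observations$cog_pair_id, value = val) |>
    dplyr::group_by(.data$cog_pair_id) |>
    dplyr::summarise(summary_distance = f(.data$value),
                     n_pairs = dplyr::n()) |>
    dplyr::ungroup()
}

#' Standard deviations of the two effect vectors
#'
#' Sample standard deviations of the fitted COG-pair effects and of the
#' phylum effects (reference included as 0). The ratio sd_C/sd_P measures
#' how strongly distance variation is gene-specific rather than
#' taxon-specific.
#'
#' @param fit a `factor_fit`.
#' @return named numeric vector `c(sd_C = ..., sd_P = ...)`.
#' @export
factor_dispersion <- function(fit) {
  stopifnot(inherits(fit, "factor_fit"))
  c(sd_C = stats::sd(fit$C), sd_P = stats::sd(fit$P))
}
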