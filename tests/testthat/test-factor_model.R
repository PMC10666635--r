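make_obs <- function(cog, phylum, distance) {
  tibble::tibble(cog_pair_id = cog, phylum = phylum, distance = distance)
}

test_that("widespread-COG-pair filter applies the distinct-phylum threshold", {
  obs <- dplyr::bind_rows(
    make_obs("wide", sprintf("P%02d", 1:25), 0L),
    make_obs("narrow", sprintf("P%02d", 1:24), 0L),
    make_obs("narrow", "P01", 5L)  # repeat phylum: still 24 distinct
  )
  kept <- select_widespread_cog_pairs(obs, min_phyla = 25L)
  expect_equal(unique(kept$cog_pair_id), "wide")
  expect_equal(select_widespread_cog_pairs(obs, min_phyla = 1L), obs)

  # brute-force distinct-phylum count oracle
  set.seed(3)
  obs <- make_obs(sample(sprintf("cp%02d", 1:20), 500, replace = TRUE),
                  sample(sprintf("P%02d", 1:30), 500, replace = TRUE),
                  sample(-10:50, 500, replace = TRUE))
  kept <- select_widespread_cog_pairs(obs, min_phyla = 12L)
  oracle <- vapply(split(obs$phylum, obs$cog_pair_id),
                   function(p) length(unique(p)), integer(1))
  expect_setequal(unique(kept$cog_pair_id), names(oracle)[oracle >= 12])
})

test_that("single-cell fit is the cell mean with the reference pinned", {
  obs <- make_obs("cp1", "RefPhylum", c(-4L, -1L, 0L))
  fit <- fit_two_factor_model(obs, reference_phylum = "RefPhylum")
  expect_equal(unname(fit$C["cp1"]), -5 / 3)
  expect_identical(unname(fit$P["RefPhylum"]), 0)
})

test_that("noise-free effects are recovered exactly, both solvers agree", {
  spec <- multi_phylum_sim_spec(n_cog_pairs = 30L, n_phyla = 8L,
                                C_mean = 0, C_sd = 30, P_sd = 4,
                                obs_per_cell = 3L, noise_sd = 0, seed = 21L)
  sim <- simulate_multi_phylum_dataset(spec)
  fit <- fit_two_factor_model(sim$observations,
                              reference_phylum = sim$reference_phylum)
  expect_equal(fit$C, sim$C_true, tolerance = 1e-8)
  expect_equal(fit$P, sim$P_true, tolerance = 1e-8)
  expect_lt(fit$sse, 1e-12)

  direct <- fit_two_factor_model(sim$observations,
                                 reference_phylum = sim$reference_phylum,
                                 method = "direct")
  expect_equal(direct$C, fit$C, tolerance = 1e-8)
  expect_equal(direct$P, fit$P, tolerance = 1e-8)
})

test_that("alternating and direct solvers agree on unbalanced noisy data", {
  for (seed in c(1L, 2L)) {
    set.seed(seed)
    n <- 800L
    obs <- make_obs(
      sample(sprintf("cp%02d", 1:50), n, replace = TRUE),
      sample(sprintf("P%02d", 1:10), n, replace = TRUE),
      0L
    )
    # drop ~30% of cells entirely to make the design unbalanced
    cells <- unique(obs[, c("cog_pair_id", "phylum")])
    dropped <- cells[sample(nrow(cells), floor(0.3 * nrow(cells))), ]
    obs <- dplyr::anti_join(obs, dropped, by = c("cog_pair_id", "phylum"))
    obs$distance <- round(rnorm(nrow(obs), 10, 25))

    alt <- fit_two_factor_model(obs, reference_phylum = "P01",
                                method = "alternating")
    dir <- fit_two_factor_model(obs, reference_phylum = "P01",
                                method = "direct")
    expect_equal(alt$C, dir$C, tolerance = 1e-6)
    expect_equal(alt$P, dir$P, tolerance = 1e-6)
    expect_equal(alt$sse, dir$sse, tolerance = 1e-8)
  }
})

test_that("sse never increases across alternating sweeps", {
  spec <- multi_phylum_sim_spec(n_cog_pairs = 40L, n_phyla = 10L,
                                obs_per_cell = c(1L, 8L), noise_sd = 15,
                                seed = 4L)
  sim <- simulate_multi_phylum_dataset(spec)
  fit <- fit_two_factor_model(sim$observations,
                              reference_phylum = sim$reference_phylum)
  expect_true(all(diff(fit$sse_trace) <= 1e-9 * max(fit$sse_trace)))
})

test_that("the fit is a local sse optimum in every COG-pair effect", {
  spec <- multi_phylum_sim_spec(n_cog_pairs = 10L, n_phyla = 5L,
                                obs_per_cell = 4L, noise_sd = 8, seed = 6L)
  sim <- simulate_multi_phylum_dataset(spec)
  obs <- sim$observations
  fit <- fit_two_factor_model(obs, reference_phylum = sim$reference_phylum)
  sse_at <- function(C, P) {
    sum((obs$distance - C[obs$cog_pair_id] - P[obs$phylum])^2)
  }
  for (i in seq_along(fit$C)) {
    for (delta in c(-0.1, 0.1)) {
      C_pert <- fit$C
      C_pert[i] <- C_pert[i] + delta
      expect_gt(sse_at(C_pert, fit$P), fit$sse)
    }
  }
})

test_that("disconnected incidence graphs and missing references error", {
  obs <- dplyr::bind_rows(
    make_obs("cp1", "P01", c(0L, 1L)),
    make_obs("cp2", "P02", c(5L, 6L))  # no phylum shared with cp1
  )
  expect_error(fit_two_factor_model(obs, reference_phylum = "P01"),
               "disconnected")
  expect_error(
    fit_two_factor_model(make_obs("cp1", "P01", 0L),
                         reference_phylum = "Proteobacteria"),
    "reference phylum"
  )
})

test_that("taxonomic adjustment subtracts the phylum effect", {
  obs <- dplyr::bind_rows(
    make_obs("cp1", "Ref", c(0L, 2L)),
    make_obs("cp1", "X", c(13L, 15L))   # shifted +13 relative to Ref
  )
  fit <- fit_two_factor_model(obs, reference_phylum = "Ref")
  adj <- adjust_distances(obs, fit)
  # reference phylum unchanged
  expect_equal(adj$adjusted_distance[adj$phylum == "Ref"],
               as.numeric(obs$distance[obs$phylum == "Ref"]))
  expect_equal(adj$adjusted_distance[adj$phylum == "X"],
               obs$distance[obs$phylum == "X"] - unname(fit$P["X"]))

  expect_error(
    adjust_distances(make_obs("cp1", "Unseen", 0L), fit), "Unseen")
})

test_that("refitting on adjusted noise-free distances zeroes phylum effects", {
  spec <- multi_phylum_sim_spec(n_cog_pairs = 15L, n_phyla = 6L,
                                C_sd = 20, P_sd = 5, obs_per_cell = 2L,
                                noise_sd = 0, seed = 12L)
  sim <- simulate_multi_phylum_dataset(spec)
  fit <- fit_two_factor_model(sim$observations,
                              reference_phylum = sim$reference_phylum)
  adj <- adjust_distances(sim$observations, fit)
  adj$distance <- adj$adjusted_distance
  refit <- fit_two_factor_model(adj, reference_phylum = sim$reference_phylum)
  expect_true(all(abs(refit$P) < 1e-6))
})

test_that("per-COG-pair summaries match a brute-force group-by", {
  obs <- make_obs("cp1", "P01", c(-4L, -4L, -1L))
  expect_equal(summarize_cog_pair(obs, "mean")$summary_distance, -3)
  expect_equal(summarize_cog_pair(obs, "median")$summary_distance, -4)

  single <- make_obs("cp9", "P01", 7L)
  expect_equal(summarize_cog_pair(single, "mean")$summary_distance, 7)
  expect_equal(summarize_cog_pair(single, "median")$summary_distance, 7)

  set.seed(8)
  obs <- make_obs(sample(sprintf("cp%02d", 1:12), 300, replace = TRUE),
                  "P01", sample(-20:100, 300, replace = TRUE))
  out <- summarize_cog_pair(obs, "median")
  oracle <- vapply(split(obs$distance, obs$cog_pair_id), median, numeric(1))
  expect_equal(setNames(out$summary_distance, out$cog_pair_id),
               oracle[out$cog_pair_id])

  # adjusted distances take precedence when present
  adj <- make_obs("cp1", "P01", c(10L, 10L))
  adj$adjusted_distance <- c(1, 3)
  expect_equal(summarize_cog_pair(adj, "mean")$summary_distance, 2)
})

test_that("factor dispersions are sample sds with the reference included", {
  obs <- dplyr::bind_rows(
    make_obs("cp1", c("Ref", "X"), c(10L, 10L)),
    make_obs("cp2", c("Ref", "X"), c(10L, 10L)),
    make_obs("cp3", c("Ref", "X"), c(10L, 10L))
  )
  fit <- fit_two_factor_model(obs, reference_phylum = "Ref")
  disp <- factor_dispersion(fit)
  expect_equal(unname(disp["sd_C"]), 0)
  expect_equal(unname(disp["sd_P"]), 0)
  expect_length(fit$P, 2)
})
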