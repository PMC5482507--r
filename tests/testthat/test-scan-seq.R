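seq_obs <- function(net, x) {
  ids <- net$metabolites$id
  as_mns_obs(tibble::tibble(
    metabolite = rep(ids, ncol(x)),
    frame = rep(seq_len(ncol(x)), each = length(ids)),
    value = as.vector(x)
  ))
}

test_that("sequential mode requires at least two frames", {
  net <- chain_network(3)
  obs <- obs_from_values(net$metabolites$id, c(-1, 0, 1))
  model <- manual_model(c(-1, 0, 1), c(1, 1, 1))
  expect_error(find_lambda_ranges(mns_mrf(net, obs, model)),
               "at least 2 frames")
})

test_that("constant-in-time data puts the lambda2 ceiling at the first value", {
  net <- chain_network(4)
  x <- matrix(rep(c(-1, -1, 1, 1), 3), ncol = 3)
  model <- manual_model(c(-1, 0, 1), c(1, 1, 1))
  mrf <- mns_mrf(net, seq_obs(net, x), model)
  cfg <- mns_seq_config()
  r <- find_lambda_ranges(mrf, cfg)
  expect_equal(r$lambda2_max, cfg$lambda_start)
})

test_that("lambda2 ceiling brackets the closed-form switch crossover", {
  # node A switches (-1 -> +1) between two frames, node B stays at 0.
  # with lambda1 = 0, keeping the switch (labels 1 -> 3) costs +lambda2 in
  # sequence energy with a perfect observation fit; the best constant
  # labeling (middle label) costs 1 in observation energy and -lambda2 in
  # sequence energy. Crossover: lambda2 = 1 - lambda2, i.e. lambda2* = 0.5
  net <- mns_network(data.frame(reaction_id = "R1", substrate = "A",
                                product = "B"))
  x <- matrix(c(-1, 0, 1, 0), ncol = 2)
  model <- manual_model(c(-1, 0, 1), c(1, 1, 1))
  obs <- seq_obs(net, x)
  low <- mns_mrf(net, obs, model, lambda1 = 0, lambda2 = 0.5 - 0.01)
  high <- mns_mrf(net, obs, model, lambda1 = 0, lambda2 = 0.5 + 0.01)
  expect_equal(nrow(extract_fractures(net, mrf_map(low))$sequence), 1)
  expect_equal(nrow(extract_fractures(net, mrf_map(high))$sequence), 0)

  r <- find_lambda_ranges(mns_mrf(net, obs, model), mns_seq_config())
  # first doubling of 0.0625 strictly past the crossover is 1 (at exactly
  # 0.5 the tie resolves toward the lexicographically lower switch labeling)
  expect_equal(r$lambda2_max, 1)
})

test_that("lambda2 = 0 decomposes into frame-wise univariate inference", {
  sim <- simulate_dataset(n_metabolites = 8, frames = 3,
                          perturbed_edges = "M04~M05", event_boundaries = 2,
                          seed = 9)
  model <- fit_observation_model(sim$obs, 3, "kmeans", "all_data", seed = 1)
  joint <- mrf_map(mns_mrf(sim$network, sim$obs, model, lambda1 = 0.8,
                           lambda2 = 0))
  for (s in 1:3) {
    frame_obs <- tibble::as_tibble(sim$obs) |>
      dplyr::filter(.data$frame == s) |>
      dplyr::mutate(frame = 1L)
    frame_obs <- as_mns_obs(frame_obs[!is.na(frame_obs$value), ])
    uni <- mrf_map(mns_mrf(sim$network, frame_obs, model, lambda1 = 0.8))
    expect_identical(joint$label[joint$frame == s], uni$label)
  }
})

test_that("evaluate_score matches a term-by-term manual evaluation", {
  net <- chain_network(3)
  x <- matrix(c(-1, -1, 1, 1, 1, 1), ncol = 2)
  model <- manual_model(c(-1, 0, 1), c(1, 1, 1))
  mrf <- mns_mrf(net, seq_obs(net, x), model)
  entry <- evaluate_score(mrf, lambda1 = 0.25, lambda2 = 0.25,
                          w_s = 0.1, w_n = 0.2)
  # at these weak weights MAP follows the observations exactly
  lab <- matrix(c(1, 1, 3, 3, 3, 3), ncol = 2)
  psi <- mean(observation_potential(as.vector(x), as.vector(lab), model))
  expect_equal(entry$mean_obs_potential, psi, tolerance = 1e-12)
  expect_equal(entry$n_seq_fractures, 2)    # M01 and M02 switch 1 -> 3
  expect_equal(entry$n_neigh_fractures, 1)  # M02~M03 at frame 1
  max_seq <- 3 * 1
  max_neigh <- 2 * 2
  expect_equal(entry$score,
               psi - 0.1 * 2 / max_seq - 0.2 * 1 / max_neigh,
               tolerance = 1e-12)
  expect_false(entry$excluded)

  # a fracture-free labeling is excluded
  flat <- mns_mrf(net, seq_obs(net, matrix(0.1, 3, 2)), model)
  expect_true(evaluate_score(flat, 5, 5)$excluded)
})

test_that("weight sweep selects, normalizes and reports orderings", {
  sim <- simulate_dataset(n_metabolites = 12, frames = 5, noise_sd = 0.1,
                          fraction_measured = 1,
                          perturbed_edges = c("M04~M05", "M08~M09"),
                          event_boundaries = c(2, 4), seed = 2)
  model <- fit_observation_model(sim$obs, 3, "fixed", "fix", seed = 1,
                                 fixed_means = c(-1, 0, 1), fixed_stds = 0.5)
  cfg <- mns_seq_config(grid_size_l1 = 8, grid_size_l2 = 8)
  res <- mns_segment_seq(sim$network, sim$obs, model, cfg)

  sel <- res$selection
  expect_equal(nrow(sel), nrow(cfg$weights))
  expect_false(any(sel$all_excluded))
  # selected points are non-excluded score maxima, normalized into [0, 1]
  expect_true(all(sel$score_norm >= 0 & sel$score_norm <= 1))
  # at w = (0, 0) the selection maximizes the raw observation potential
  ok <- !res$surface$excluded
  expect_equal(sel$score[1], max(res$surface$mean_obs_potential[ok]),
               tolerance = 1e-12)
  # fracture counts nonincreasing along the equal-weight sweep
  tot <- sel$n_seq_fractures + sel$n_neigh_fractures
  expect_true(all(diff(tot) <= 0))
  # ordering table recovers the planted boundary order
  o <- res$ordering
  fA <- o$first_frame[o$fracture == "M04~M05" & o$type == "neighborhood"]
  fB <- o$first_frame[o$fracture == "M08~M09" & o$type == "neighborhood"]
  expect_lt(fA, fB)
  # pseudo-steady-state intervals cover the whole sweep
  expect_equal(sum(res$pseudo_steady_states$n_points), nrow(sel))
  expect_s3_class(autoplot(res, w_s = 0.1, w_n = 0.1), "gg")
  expect_s3_class(tidy(res), "tbl_df")
})

test_that("score normalization maps the non-excluded range onto [0, 1]", {
  sim <- simulate_dataset(n_metabolites = 10, frames = 3,
                          fraction_measured = 1, perturbed_edges = "M05~M06",
                          event_boundaries = 2, seed = 7)
  model <- fit_observation_model(sim$obs, 3, "kmeans", "all_data", seed = 1)
  cfg <- mns_seq_config(grid_size_l1 = 6, grid_size_l2 = 6)
  res <- mns_segment_seq(sim$network, sim$obs, model, cfg)
  b <- res$surface
  ok <- !b$excluded
  w <- cfg$weights[5, ]
  sc <- b$mean_obs_potential -
    w$w_s * b$n_seq_fractures / (10 * 2) -
    w$w_n * b$n_neigh_fractures / (nrow(sim$network$edges) * 3)
  norm <- (sc - min(sc[ok])) / diff(range(sc[ok]))
  expect_equal(min(norm[ok]), 0)
  expect_equal(max(norm[ok]), 1)
})
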