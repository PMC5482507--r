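test_that("ceiling search: flat data stops at the first tested value", {
  net <- chain_network(6)
  obs <- obs_from_values(net$metabolites$id, rep(0.4, 6))
  model <- manual_model(c(-1, 0, 1), c(1, 1, 1))
  mrf <- mns_mrf(net, obs, model)
  cfg <- mns_scan_config()
  expect_equal(find_lambda1_ceiling(mrf, cfg), cfg$lambda1_start)
})

test_that("ceiling brackets the closed-form two-node crossover", {
  # two metabolites, x = (-3, +3), mu = (-3, 0, 3), sigma = 1: the split
  # labeling (1, 3) costs lambda1/2; the best uniform labeling (middle) costs
  # (9 + 9)/2 = 9; the exact crossover is lambda1* = 18
  net <- mns_network(data.frame(reaction_id = "R1", substrate = "A",
                                product = "B"))
  obs <- obs_from_values(c("A", "B"), c(-3, 3))
  model <- manual_model(c(-3, 0, 3), c(1, 1, 1))
  mrf_lo <- mns_mrf(net, obs, model, lambda1 = 18 - 0.01)
  mrf_hi <- mns_mrf(net, obs, model, lambda1 = 18 + 0.01)
  expect_equal(nrow(extract_fractures(net, mrf_map(mrf_lo))$neighborhood), 1)
  expect_equal(nrow(extract_fractures(net, mrf_map(mrf_hi))$neighborhood), 0)

  cfg <- mns_scan_config()
  ceiling_l1 <- find_lambda1_ceiling(mns_mrf(net, obs, model), cfg)
  # first doubling of 0.0625 past 18 is 32; and MAP stays fracture-free above
  expect_equal(ceiling_l1, 32)
  mrf2 <- mns_mrf(net, obs, model, lambda1 = 2 * ceiling_l1)
  expect_equal(nrow(extract_fractures(net, mrf_map(mrf2))$neighborhood), 0)
})

test_that("scan scores: flat data all zero, planted step maximal at the middle", {
  model <- manual_model(c(-2, 0, 2), c(1, 1, 1))
  net <- chain_network(6)
  flat <- obs_from_values(net$metabolites$id, rep(0.1, 6))
  cfg <- mns_scan_config(grid_size = 25)
  s <- scan_lambda1(net, flat, model, cfg)
  expect_true(all(s$max_lambda1 == 0))
  expect_true(all(s$n_fractures == 0))

  step <- obs_from_values(net$metabolites$id, c(-2, -2, -2, 2, 2, 2))
  s <- scan_lambda1(net, step, model, cfg)
  mid <- which(s$edge_id == "M03~M04")
  expect_equal(s$max_lambda1[mid], max(s$max_lambda1))
  expect_equal(s$n_fractures[mid], max(s$n_fractures))
  expect_true(all(s$n_fractures <= cfg$grid_size))
  # n_fractures = 0 iff max_lambda1 = 0
  expect_equal(s$n_fractures == 0, s$max_lambda1 == 0)
  # both ranking criteria put the planted edge first
  expect_equal(rank_reactions(s, "max_lambda1")$edge_id[1], "M03~M04")
  expect_equal(rank_reactions(s, "n_fractures")$edge_id[1], "M03~M04")
})

test_that("rank_reactions orders descending with average-rank ties", {
  fake <- tibble::tibble(edge_id = c("e1", "e2", "e3"),
                         max_lambda1 = c(3, 1, 0),
                         n_fractures = c(40L, 10L, 0L))
  rk <- rank_reactions(fake, "max_lambda1")
  expect_equal(rk$edge_id, c("e1", "e2", "e3"))
  expect_equal(rk$rank, c(1, 2, 3))

  zeros <- tibble::tibble(edge_id = paste0("e", 1:5),
                          max_lambda1 = rep(0, 5))
  rk <- rank_reactions(zeros, "max_lambda1")
  expect_true(all(rk$rank == 3))  # (5 + 1) / 2
})

test_that("permutation p-values follow the counting estimator", {
  sim <- simulate_dataset(n_metabolites = 10, seed = 2)
  model <- fit_observation_model(sim$obs, 3, "kmeans", "all_data", seed = 1)
  cfg <- mns_scan_config(grid_size = 20, n_permutations = 200, seed = 5)
  scan <- scan_lambda1(sim$network, sim$obs, model, cfg)
  pt <- permutation_test(scan)
  # p in {0, 1/n, ..., 1}: n * p is an exact integer count
  expect_true(all(abs(pt$p_max_lambda1 * 200 - round(pt$p_max_lambda1 * 200)) < 1e-9))
  expect_true(all(pt$p_max_lambda1 >= 0 & pt$p_max_lambda1 <= 1))
  # an edge that never fractures has p = 1 (every permutation reaches >= 0)
  never <- pt$max_lambda1 == 0
  expect_true(any(never))
  expect_true(all(pt$p_max_lambda1[never] == 1))
  expect_true(all(pt$p_n_fractures[never] == 1))
  # pseudocount estimator is (k + 1) / (n + 1)
  pt2 <- permutation_test(scan, pseudocount = TRUE)
  k <- round(pt$p_max_lambda1 * 200)
  expect_equal(pt2$p_max_lambda1, (k + 1) / 201)
  # bit-exact reproducibility under the same seed
  pt3 <- permutation_test(scan)
  expect_identical(pt$p_max_lambda1, pt3$p_max_lambda1)
  expect_identical(pt$p_n_fractures, pt3$p_n_fractures)
})

test_that("scan statistics are invariant to common rescaling of data and model", {
  sim <- simulate_dataset(n_metabolites = 12, seed = 6)
  model <- fit_observation_model(sim$obs, 3, "kmeans", "all_data", seed = 1)
  cfg <- mns_scan_config(grid_size = 20)
  s1 <- scan_lambda1(sim$network, sim$obs, model, cfg)

  c0 <- 2.5
  obs2 <- as_mns_obs(dplyr::mutate(tibble::as_tibble(sim$obs),
                                   value = .data$value * c0))
  model2 <- manual_model(model$means * c0, model$stds * c0)
  s2 <- scan_lambda1(sim$network, obs2, model2, cfg)
  expect_equal(s1$max_lambda1, s2$max_lambda1)
  expect_equal(s1$n_fractures, s2$n_fractures)
})

test_that("null permutation p-values are valid (conservative)", {
  # label-permuted data: P(p <= t) must not exceed t (up to MC error)
  ps <- vapply(1:60, function(s) {
    sim <- simulate_dataset(n_metabolites = 10, seed = 400 + s)
    obs <- sim$obs
    obs$value <- withr::with_seed(500 + s, sample(obs$value))
    obs <- as_mns_obs(obs)
    model <- fit_observation_model(obs, 3, "kmeans", "all_data", seed = 1)
    cfg <- mns_scan_config(grid_size = 20, n_permutations = 100,
                           seed = 600 + s)
    pt <- permutation_test(scan_lambda1(sim$network, obs, model, cfg))
    pt$p_max_lambda1[5]
  }, numeric(1))
  for (t in c(0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(ps <= t), t + 3 * sqrt(t * (1 - t) / 60))
  }
})

test_that("rank products are geometric means with permutation significance", {
  r1 <- tibble::tibble(edge_id = c("a", "b", "c", "d"), rank = c(1, 2, 3, 4))
  r2 <- tibble::tibble(edge_id = c("a", "b", "c", "d"), rank = c(1, 8, 2, 4))
  rp <- rank_product_combine(list(r1, r2), n_permutations = 200, seed = 1)
  expect_equal(rp$edge_id[1], "a")
  expect_equal(rp$rank_product[rp$edge_id == "a"], 1)
  expect_equal(rp$rank_product[rp$edge_id == "b"], 4)  # sqrt(2 * 8)
  expect_equal(rp$rank_product[rp$edge_id == "c"], sqrt(6))
  # identical predictors preserve the common order
  rp2 <- rank_product_combine(list(r1, r1), n_permutations = 50, seed = 1)
  expect_equal(rp2$edge_id, c("a", "b", "c", "d"))
  expect_equal(rp2$rank_product, c(1, 2, 3, 4))
  # consistently top-ranked edges get small rp_p
  expect_lt(rp2$rp_p[1], rp2$rp_p[4])
  # mismatched edge sets error
  r3 <- tibble::tibble(edge_id = c("a", "b"), rank = c(1, 2))
  expect_error(rank_product_combine(list(r1, r3)), "same edge set")
})

test_that("mns_segment returns ranks and p-values for every edge", {
  sim <- simulate_dataset(n_metabolites = 10, seed = 3)
  model <- fit_observation_model(sim$obs, 3, "kmeans", "all_data", seed = 1)
  seg <- mns_segment(sim$network, sim$obs, model,
                     mns_scan_config(grid_size = 15, n_permutations = 50))
  expect_equal(nrow(seg), nrow(sim$network$edges))
  expect_true(all(c("rank_max_lambda1", "rank_n_fractures", "p_max_lambda1",
                    "p_n_fractures") %in% names(seg)))
  expect_s3_class(glance(seg), "tbl_df")
  expect_s3_class(autoplot(seg), "gg")
})
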