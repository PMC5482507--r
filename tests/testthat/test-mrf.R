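test_that("potential point values match hand evaluation", {
  # neighborhood: exp(-lambda1 * (unique-1)/size)
  expect_equal(neighborhood_potential(c(2, 2), 5), 1)
  expect_equal(neighborhood_potential(c(1, 2), 1), exp(-1 / 2),
               tolerance = 1e-12)
  expect_equal(neighborhood_potential(c(1, 2, 3), 3), exp(-2),
               tolerance = 1e-12)
  # sequence: exp(-lambda2 * f), f = -1 equal / +1 different
  expect_equal(sequence_potential(1, 1, 0), 1)
  expect_equal(sequence_potential(2, 2, 1), exp(1), tolerance = 1e-12)
  expect_equal(sequence_potential(1, 2, 1), exp(-1), tolerance = 1e-12)
})

test_that("exp(-energy) equals the product of potential factors", {
  model <- manual_model(c(-1, 0, 1), c(0.8, 1, 1.2))
  for (seed in 1:5) {
    net <- random_network(5, 0.5, seed = seed)
    ids <- net$metabolites$id
    vals <- withr::with_seed(seed, rnorm(length(ids)))
    vals[1] <- NA  # one unmeasured node
    obs <- obs_from_values(ids[!is.na(vals)], vals[!is.na(vals)])
    lab <- withr::with_seed(seed + 100,
                            matrix(sample(3, length(ids), TRUE), ncol = 1))
    mrf <- mns_mrf(net, obs, model, lambda1 = 0.7)
    en <- mrf_energy(mrf, lab)

    prod_psi <- 1
    for (cl in net$cliques) {
      prod_psi <- prod_psi * neighborhood_potential(lab[match(cl, ids), 1], 0.7)
    }
    for (i in seq_along(ids)) {
      if (!is.na(vals[i])) {
        prod_psi <- prod_psi * observation_potential(vals[i], lab[i, 1], model)
      }
    }
    expect_equal(exp(-en), prod_psi, tolerance = 1e-10)
    # and against the independent R summation oracle
    x <- matrix(vals, ncol = 1)
    expect_equal(en, energy_oracle(net, x, model, lab, 0.7), tolerance = 1e-10)
  }
})

test_that("sequential energy includes the frame-boundary terms", {
  net <- chain_network(3)
  ids <- net$metabolites$id
  model <- manual_model(c(-1, 0, 1), c(1, 1, 1))
  obs <- as_mns_obs(tibble::tibble(
    metabolite = rep(ids, 2), frame = rep(1:2, each = 3),
    value = c(-1, 0, 1, -1, 1, 1)
  ))
  mrf <- mns_mrf(net, obs, model, lambda1 = 0.5, lambda2 = 0.3)
  lab <- matrix(c(1, 2, 3, 1, 3, 3), ncol = 2)
  expect_equal(mrf_energy(mrf, lab),
               energy_oracle(net, matrix(c(-1, 0, 1, -1, 1, 1), ncol = 2),
                             model, lab, 0.5, 0.3),
               tolerance = 1e-10)
})

test_that("decoupled model (lambda1 = 0) reduces MAP to per-node argmax", {
  net <- random_network(8, 0.4, seed = 2)
  ids <- net$metabolites$id
  vals <- withr::with_seed(3, runif(8, -2, 2))
  model <- manual_model(c(-1.5, 0, 1.5), c(1, 1, 1))
  obs <- obs_from_values(ids, vals)
  mrf <- mns_mrf(net, obs, model, lambda1 = 0)
  lab <- mrf_map(mrf, method = "local")
  expected <- vapply(vals, function(v) which.min((v - model$means)^2),
                     integer(1))
  expect_equal(lab$label, unname(expected))
})

test_that("dominant smoothing (lambda1 = 1e6) yields a uniform labeling", {
  sim <- simulate_dataset(n_metabolites = 15, seed = 4)
  model <- fit_observation_model(sim$obs, 3, "kmeans", "all_data", seed = 1)
  mrf <- mns_mrf(sim$network, sim$obs, model, lambda1 = 1e6)
  lab <- mrf_map(mrf, method = "local")
  expect_equal(length(unique(lab$label)), 1)
  expect_equal(nrow(extract_fractures(sim$network, lab)$neighborhood), 0)
})

test_that("local-search MAP attains the exhaustive optimum on random instances", {
  # 200 seeded instances, <= 10 nodes, K = 3, lambda1 in [0, 5]
  model <- manual_model(c(-1, 0, 1), c(1, 1, 1))
  n_match <- 0
  for (seed in 1:200) {
    pars <- withr::with_seed(seed, {
      list(n = sample(4:10, 1), p = runif(1, 0.25, 0.6),
           l1 = runif(1, 0, 5))
    })
    net <- random_network(pars$n, pars$p, seed = seed)
    ids <- net$metabolites$id
    vals <- withr::with_seed(seed + 1000, {
      v <- rnorm(length(ids), sd = 1.2)
      v[runif(length(v)) < 0.15] <- NA  # partial coverage
      v
    })
    if (all(is.na(vals))) vals[1] <- 0
    obs <- obs_from_values(ids[!is.na(vals)], vals[!is.na(vals)])
    mrf <- mns_mrf(net, obs, model, lambda1 = pars$l1)
    e_local <- attr(mrf_map(mrf, method = "local"), "energy")
    e_exact <- attr(mrf_map(mrf, method = "exact"), "energy")
    if (abs(e_local - e_exact) < 1e-9) n_match <- n_match + 1
  }
  expect_equal(n_match, 200)
})

test_that("exact mode agrees with the R enumeration oracle on tiny instances", {
  model <- manual_model(c(-1, 1), c(1, 1))
  net <- chain_network(4)
  ids <- net$metabolites$id
  vals <- c(-1.2, -0.8, 0.9, 1.4)
  obs <- obs_from_values(ids, vals)
  for (l1 in c(0, 0.5, 2)) {
    mrf <- mns_mrf(net, obs, model, lambda1 = l1)
    expect_equal(attr(mrf_map(mrf, method = "exact"), "energy"),
                 map_oracle_energy(net, matrix(vals, ncol = 1), model, l1),
                 tolerance = 1e-10)
  }
})

test_that("MAP is invariant to metabolite input order", {
  base <- data.frame(reaction_id = paste0("R", 1:5),
                     substrate = c("A", "B", "C", "D", "B"),
                     product = c("B", "C", "D", "E", "D"))
  vals <- c(A = -2, B = -1.8, C = 0.1, D = 1.9, E = 2.1)
  model <- manual_model(c(-2, 0, 2), c(1, 1, 1))
  lab1 <- {
    net <- mns_network(base)
    mrf <- mns_mrf(net, obs_from_values(names(vals), vals), model, 1)
    mrf_map(mrf, method = "local")
  }
  lab2 <- {
    net <- mns_network(base[c(4, 2, 5, 1, 3), ])
    perm <- c(3, 5, 1, 2, 4)
    mrf <- mns_mrf(net, obs_from_values(names(vals)[perm], vals[perm]),
                   model, 1)
    mrf_map(mrf, method = "local")
  }
  expect_equal(dplyr::arrange(lab1, metabolite),
               dplyr::arrange(lab2, metabolite))
})

test_that("single-frame results ignore lambda2 entirely", {
  sim <- simulate_dataset(n_metabolites = 10, seed = 8)
  model <- fit_observation_model(sim$obs, 3, "kmeans", "all_data", seed = 1)
  m0 <- mns_mrf(sim$network, sim$obs, model, lambda1 = 1, lambda2 = 0)
  m9 <- mns_mrf(sim$network, sim$obs, model, lambda1 = 1, lambda2 = 9)
  expect_equal(mrf_map(m0), mrf_map(m9))
})

test_that("local search never degrades its initializations", {
  sim <- simulate_dataset(n_metabolites = 20, seed = 12)
  model <- fit_observation_model(sim$obs, 3, "kmeans", "all_data", seed = 1)
  for (l1 in c(0.2, 1, 5, 50)) {
    mrf <- mns_mrf(sim$network, sim$obs, model, lambda1 = l1)
    e_map <- attr(mrf_map(mrf, method = "local"), "energy")
    M <- nrow(sim$network$metabolites)
    for (k in 1:3) {
      e_unif <- mrf_energy(mrf, matrix(k, nrow = M, ncol = 1))
      expect_lte(e_map, e_unif + 1e-9)
    }
    greedy <- vapply(mrf$x[, 1], function(v) {
      if (is.na(v)) 2L else which.min((v - model$means)^2 / model$stds^2)
    }, integer(1))
    expect_lte(e_map, mrf_energy(mrf, matrix(greedy, ncol = 1)) + 1e-9)
  }
})

test_that("fracture extraction matches a direct recount", {
  net <- chain_network(3)
  lab <- tibble::tibble(metabolite = net$metabolites$id, frame = 1L,
                        label = c(1L, 1L, 2L))
  fr <- extract_fractures(net, lab)
  expect_equal(fr$neighborhood$edge_id, "M02~M03")
  expect_equal(nrow(fr$sequence), 0)

  # random labeling on a random graph, two frames
  net <- random_network(9, 0.4, seed = 21)
  ids <- net$metabolites$id
  lab <- withr::with_seed(22, tibble::tibble(
    metabolite = rep(ids, 2), frame = rep(1:2, each = length(ids)),
    label = sample(3, 2 * length(ids), TRUE)
  ))
  fr <- extract_fractures(net, lab)
  recount <- 0
  for (s in 1:2) {
    for (r in seq_len(nrow(net$edges))) {
      la <- lab$label[lab$metabolite == net$edges$substrate[r] & lab$frame == s]
      lb <- lab$label[lab$metabolite == net$edges$product[r] & lab$frame == s]
      if (la != lb) recount <- recount + 1
    }
  }
  expect_equal(nrow(fr$neighborhood), recount)
  seq_recount <- sum(vapply(ids, function(m) {
    lab$label[lab$metabolite == m & lab$frame == 1] !=
      lab$label[lab$metabolite == m & lab$frame == 2]
  }, logical(1)))
  expect_equal(nrow(fr$sequence), seq_recount)
})

test_that("uniform labelings have no fractures and zero neighborhood energy", {
  net <- triangle_network()
  obs <- obs_from_values(c("A", "B", "C"), c(0, 0.1, -0.1))
  model <- manual_model(c(-1, 0, 1), c(1, 1, 1))
  mrf <- mns_mrf(net, obs, model, lambda1 = 3)
  lab <- matrix(2L, nrow = 3, ncol = 1)
  en <- mrf_energy(mrf, lab)
  # only observation terms remain
  expect_equal(en, sum(c(0, 0.1, -0.1)^2 / 2), tolerance = 1e-10)
})
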