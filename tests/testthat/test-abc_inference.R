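# small toy reference tables built directly from known distributions
toy_table <- function(n, mu_by_group, seed = 1) {
  set.seed(seed)
  nm <- summary_stat_names()
  stats <- do.call(rbind, lapply(mu_by_group, function(mu)
    matrix(rnorm(n * length(nm), mu), n, length(nm))))
  colnames(stats) <- nm
  labels <- data.frame(
    category = rep(names(mu_by_group), each = n),
    submodel = "NeHom.MHom", stringsAsFactors = FALSE)
  new_reference_table(stats, labels)
}

test_that("reference tables are built with correct shape, labels and
           determinism", {
  models <- enumerate_models()[c(1, 9), ]  # two models, different categories
  specs <- tiny_specs(20, 300)
  pr <- default_priors(ne_range = c(1e3, 1e5),
                       tsplit_outer_range = c(1e4, 1e6))
  tab <- build_reference_table(models, 5, specs, c(4, 4, 4),
                               priors = pr, rng_seed = 3)
  expect_s3_class(tab, "abc_reftable")
  expect_equal(nrow(tab$stats), 10)
  expect_equal(as.integer(table(tab$labels$category)), c(5L, 5L))
  expect_false(anyNA(tab$stats))
  expect_equal(colnames(tab$stats), summary_stat_names())
  expect_equal(colnames(tab$params), param_names())
  tab2 <- build_reference_table(models, 5, specs, c(4, 4, 4),
                                priors = pr, rng_seed = 3)
  expect_identical(tab$stats, tab2$stats)
  expect_identical(tab$params, tab2$params)
  expect_error(build_reference_table(models, 0, specs), "n_per_model")
})

test_that("classification recovers the separable and degenerate limits", {
  tab <- toy_table(400, c(AM.SI = 0, SC.SI = 8))
  obs <- tab$stats[1, ]  # a training row of group AM.SI
  r <- classify(tab, obs, "category", num_trees = 300, rng_seed = 2)
  expect_equal(r$winner, "AM.SI")
  expect_lt(r$oob_error, 0.01)
  expect_gt(r$posterior, 0.95)
  expect_equal(unname(rowSums(r$votes)), 1)

  # identical generating model: coin-flip accuracy, posterior near 1/2
  tab0 <- toy_table(400, c(AM.SI = 0, SC.SI = 0), seed = 3)
  r0 <- classify(tab0, obs, "category", num_trees = 300, rng_seed = 2)
  expect_lt(abs(r0$oob_error - 0.5), 0.1)
  expect_lt(abs(r0$posterior - 0.5), 0.1)

  one <- toy_table(50, c(AM.SI = 0))
  expect_error(classify(one, obs), "fewer than 2 groups")
})

test_that("hierarchical inference answers both questions and is
           permutation-invariant", {
  mus <- setNames(1:8, enumerate_models()$category[!duplicated(
    enumerate_models()$category)])
  tab <- toy_table(60, as.list(mus), seed = 4)
  obs <- colMeans(tab$stats[tab$labels$category == "AM.GF23", ])
  h <- hierarchical_inference(tab, obs, num_trees = 200, rng_seed = 5)
  expect_equal(h$question1$winner, "AM")
  expect_equal(h$question2$winner, "GF23")
  expect_equal(h$category, "AM.GF23")

  perm <- sample(nrow(tab$stats))
  tabp <- new_reference_table(tab$stats[perm, ], tab$labels[perm, ])
  hp <- hierarchical_inference(tabp, obs, num_trees = 200, rng_seed = 5)
  expect_equal(hp$category, h$category)

  missing <- new_reference_table(tab$stats[tab$labels$category != "AM.SI", ],
                                 tab$labels[tab$labels$category != "AM.SI", ])
  expect_error(hierarchical_inference(missing, obs), "missing")
})

test_that("parameter estimation handles constants, intervals and
           normalization", {
  set.seed(6)
  nm <- summary_stat_names()
  n <- 600
  truthT <- runif(n, 1e4, 1e6)
  stats <- matrix(rnorm(n * length(nm)), n, length(nm),
                  dimnames = list(NULL, nm))
  # make two statistics informative about T
  stats[, "mean_dxy_P1P3"] <- truthT * 2e-9 + rnorm(n, 0, 1e-4)
  stats[, "mean_fst_P1P3"] <- truthT / 1e6 + rnorm(n, 0, 0.02)
  params <- cbind(N_P1 = rep(5e4, n), T_split123 = truthT)
  tab <- new_reference_table(stats,
                             data.frame(category = rep("AM.SI", n),
                                        submodel = "NeHom.MHom"),
                             params = params)
  obs <- stats[5, ]
  est <- estimate_parameters(tab, obs, category = "AM.SI", num_trees = 300,
                             rng_seed = 7)
  # constant parameter: exact value, zero-width interval
  expect_equal(est$estimate[est$parameter == "N_P1"], 5e4)
  expect_equal(est$lower[est$parameter == "N_P1"],
               est$upper[est$parameter == "N_P1"])
  row <- est[est$parameter == "T_split123", ]
  expect_true(row$lower <= row$estimate && row$estimate <= row$upper)
  expect_lt(abs(row$estimate - truthT[5]) / truthT[5], 0.5)

  estn <- estimate_parameters(tab, obs, category = "AM.SI", num_trees = 300,
                              rng_seed = 7, normalize = TRUE)
  expect_identical(estn$estimate[estn$parameter == "N_P1"], 1)
  expect_equal(estn$estimate[estn$parameter == "T_split123"],
               row$estimate / (4 * 5e4))
  expect_error(estimate_parameters(tab, obs, category = "SC.SI"), "no reference")
})

test_that("posterior predictive check flags gross misfit and passes
           self-consistent data", {
  specs <- tiny_specs(60, 400)
  est <- c(N_P1 = 2e4, N_P2 = 2e4, N_P3 = 2e4, N_anc12 = 2e4,
           N_anc123 = 2e4, N_found_P1 = 2e4, N_found_P2 = 2e4,
           N_found_P3 = 2e4, T_change_P1 = 0, T_change_P2 = 0,
           T_change_P3 = 0, T_split12 = 1e5, T_split123 = 4e5,
           T_trans12 = 1e5, M12 = 0, M13 = 0, M23 = 0)
  draw <- abctrio:::.draw_from_values(est, "AM.SI", "NeHom.MHom")
  sim <- simulate_dataset_stats(draw, specs, c(6, 6, 4), "theta",
                                rng_seed = 8)
  obs <- dataset_summary(sim$stats)
  ppc <- posterior_predictive_check(est, "AM.SI", "NeHom.MHom", obs, specs,
                                    c(6, 6, 4), n_rep = 60, rng_seed = 9)
  expect_equal(nrow(ppc), length(summary_stat_names()))
  expect_true(all(ppc$tail_prob >= 0 & ppc$tail_prob <= 1))
  # observed drawn from the model itself: central statistics not extreme
  expect_gt(ppc$tail_prob[ppc$statistic == "mean_pi_P1"], 0.01)

  obs_bad <- obs
  obs_bad[grep("^mean_pi", names(obs_bad))] <-
    obs_bad[grep("^mean_pi", names(obs_bad))] * 10
  ppc_bad <- posterior_predictive_check(est, "AM.SI", "NeHom.MHom", obs_bad,
                                        specs, c(6, 6, 4), n_rep = 60,
                                        rng_seed = 9)
  expect_lt(ppc_bad$tail_prob[ppc_bad$statistic == "mean_pi_P1"], 0.05)

  # n_rep = 1 is degenerate but defined
  ppc1 <- posterior_predictive_check(est, "AM.SI", "NeHom.MHom", obs, specs,
                                     c(6, 6, 4), n_rep = 1, rng_seed = 10)
  expect_true(all(ppc1$tail_prob %in% c(0, 1)))
})
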