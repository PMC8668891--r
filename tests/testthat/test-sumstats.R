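test_that("definitional cases of the per-locus statistics", {
  # identical sequences: zero diversity
  m0 <- matrix(0L, 4, 0)
  expect_equal(pi_stat(cbind(m0, matrix(0L, 4, 3)), 100), 0)
  # two sequences differing at 3 of 100 sites
  m <- rbind(c(1, 1, 1), c(0, 0, 0))
  expect_equal(pi_stat(m, 100), 0.03)
  expect_error(pi_stat(matrix(0L, 1, 2), 100), "at least 2")

  expect_equal(theta_w(7, 2, 100), 0.07)
  expect_equal(theta_w(4, 5, 100), 4 / (sum(1 / (1:4)) * 100))
  expect_equal(theta_w(0, 5, 100), 0)
  expect_error(theta_w(3, 1, 100), "n must be")

  # zero numerator: pi_total exactly S/a_n
  a9 <- sum(1 / (1:9))
  expect_equal(tajima_d(16 / a9, 16, 10), 0)
  expect_true(is.na(tajima_d(0, 0, 10)))

  # reciprocally fixed sequences
  mx <- rbind(c(1, 1), c(1, 1)); my <- rbind(c(0, 0), c(0, 0))
  expect_equal(unname(divergence(mx, my, 100)), c(0.02, 0.02))
  expect_equal(fst(mx, my, 100), 1)
  # identical composition: small negative bias -1/(2n-2) of this estimator
  same <- random_pooled_matrix(10, 4)
  expect_equal(fst(same, same, 100), -1 / 18, tolerance = 1e-12)
  expect_true(is.na(fst(my, my, 100)))  # pooled monomorphic

  # ABBA-BABA limits
  expect_equal(abba_baba_d(c(0.2, 0.7), c(0.2, 0.7), c(0.5, 0.9))$D, 0)
  expect_equal(abba_baba_d(c(0, 0), c(1, 1), c(1, 1))$D, 1)
  expect_true(is.na(abba_baba_d(numeric(0), numeric(0), numeric(0))$D))

  # one site of each pattern kind: shared, exclusive-x, exclusive-y, fixed
  mx <- rbind(c(0, 1, 0, 0), c(1, 0, 0, 0))
  my <- rbind(c(0, 0, 1, 1), c(1, 0, 0, 1))
  expect_equal(site_pattern_counts(mx, my),
               c(ss = 1, sf = 1, sx_x = 1, sx_y = 1))
  # reciprocally fixed site
  expect_equal(unname(site_pattern_counts(rbind(1, 1), rbind(0, 0))["sf"]), 1)
})

test_that("statistics match brute-force oracles on random matrices", {
  set.seed(77)
  for (rep in 1:200) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1); n3 <- sample(2:6, 1)
    S <- sample(1:10, 1); L <- sample(50:200, 1)
    snp <- random_pooled_matrix(n1 + n2 + n3, S)
    m1 <- snp[1:n1, , drop = FALSE]
    m2 <- snp[n1 + (1:n2), , drop = FALSE]
    m3 <- snp[n1 + n2 + (1:n3), , drop = FALSE]

    st <- locus_stats(snp, c(n1, n2, n3), L)
    expect_equal(st[["pi_P1"]], brute_pi(m1, L), tolerance = 1e-12)
    expect_equal(st[["pi_P3"]], brute_pi(m3, L), tolerance = 1e-12)
    cs <- colSums(m2)
    expect_equal(st[["thetaW_P2"]],
                 brute_theta_w(sum(cs > 0 & cs < n2), n2, L),
                 tolerance = 1e-12)
    td <- brute_tajima_d(m1)
    if (is.na(td)) expect_true(is.na(st[["tajD_P1"]]))
    else expect_equal(st[["tajD_P1"]], td, tolerance = 1e-12)
    expect_equal(st[["dxy_P1P2"]], brute_dxy(m1, m2, L), tolerance = 1e-12)
    expect_equal(st[["da_P1P3"]], brute_da(m1, m3, L), tolerance = 1e-12)
    f <- brute_fst(m2, m3, L)
    if (is.na(f)) expect_true(is.na(st[["fst_P2P3"]]))
    else expect_equal(st[["fst_P2P3"]], f, tolerance = 1e-12)
    dd <- brute_abba_baba(m1, m2, m3)
    if (is.na(dd)) expect_true(is.na(st[["dstat"]]))
    else expect_equal(st[["dstat"]], dd, tolerance = 1e-12)
    expect_equal(unname(st[c("ss_P1P2", "sf_P1P2", "sxA_P1P2", "sxB_P1P2")]),
                 unname(brute_patterns(m1, m2)), tolerance = 1e-12)

    # exported R statistics agree with the bulk C++ path
    expect_equal(pi_stat(m1, L), st[["pi_P1"]], tolerance = 1e-12)
    expect_equal(unname(divergence(m1, m2, L)[["dxy"]]), st[["dxy_P1P2"]],
                 tolerance = 1e-12)
    if (!is.na(f)) expect_equal(fst(m2, m3, L), st[["fst_P2P3"]],
                                tolerance = 1e-12)
  }
})

test_that("hudson-style FST option divides by dxy instead of pooled pi", {
  set.seed(5)
  mx <- random_pooled_matrix(4, 6); my <- random_pooled_matrix(4, 6)
  piw <- (brute_pi(mx, 100) + brute_pi(my, 100)) / 2
  expect_equal(fst(mx, my, 100, estimator = "hudson"),
               1 - piw / brute_dxy(mx, my, 100), tolerance = 1e-12)
})

test_that("dataset summary aggregates with the stated conventions", {
  set.seed(8)
  tab <- matrix(NA_real_, 2, 33, dimnames = list(NULL, locus_stat_names()))
  tab[1, ] <- 0; tab[2, ] <- 0
  tab[, "pi_P1"] <- c(0.01, 0.03)
  tab[, "dstat_num"] <- c(1, 2); tab[, "dstat_den"] <- c(2, 2)
  sv <- dataset_summary(tab)
  expect_equal(sv[["mean_pi_P1"]], 0.02)
  expect_equal(sv[["sd_pi_P1"]], 0.01)        # population SD
  expect_equal(sv[["dstat_total"]], 3 / 4)

  # single locus: means equal the locus, SDs zero
  sv1 <- dataset_summary(tab[1, , drop = FALSE])
  expect_equal(sv1[["mean_pi_P1"]], 0.01)
  expect_true(all(sv1[paste0("sd_", locus_stat_names())] == 0))

  # missing values are skipped, never imputed
  tab2 <- tab
  tab2[1, "tajD_P1"] <- NA; tab2[2, "tajD_P1"] <- -1.5
  sv2 <- dataset_summary(tab2)
  expect_equal(sv2[["mean_tajD_P1"]], -1.5)
  expect_equal(sv2[["sd_tajD_P1"]], 0)

  # a statistic missing everywhere falls back to 0 (keeps tables complete)
  tab3 <- tab
  tab3[, "fst_P1P2"] <- NA
  expect_equal(dataset_summary(tab3)[["mean_fst_P1P2"]], 0)

  expect_error(dataset_summary(tab[0, , drop = FALSE]), "no loci")
})

test_that("dataset summary is invariant to locus order and matches a
           spreadsheet-style recomputation", {
  set.seed(13)
  d <- sample_parameters("SC.GF23", "NeHom.MHom", rng_seed = 13)
  sim <- simulate_dataset_stats(d, tiny_specs(100, 300), c(6, 6, 4),
                                "theta", rng_seed = 14)
  tab <- sim$stats
  sv <- dataset_summary(tab)
  perm <- tab[sample(nrow(tab)), ]
  expect_equal(dataset_summary(perm), sv)
  # independent aggregation: plain colMeans / sqrt of mean square deviation
  for (nm in c("pi_P2", "fst_P1P3", "dxy_P2P3")) {
    x <- tab[, nm]; x <- x[!is.na(x)]
    expect_equal(sv[[paste0("mean_", nm)]], sum(x) / length(x))
    expect_equal(sv[[paste0("sd_", nm)]],
                 sqrt(sum((x - sum(x) / length(x))^2) / length(x)))
  }
})

test_that("per-locus and summary tables round-trip through TSV", {
  d <- sample_parameters("AM.SI", rng_seed = 15)
  sim <- simulate_dataset_stats(d, tiny_specs(20), c(4, 4, 4), "theta",
                                rng_seed = 16)
  tab <- as.data.frame(sim$stats)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stats_table(tab, path)
  expect_equal(as.matrix(read_stats_table(path)), as.matrix(tab),
               tolerance = 1e-12)
  sv <- dataset_summary(sim$stats)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_stats_table(sv, path2)
  back <- read_stats_table(path2)
  expect_equal(unlist(back[1, ]), sv, tolerance = 1e-12,
               ignore_attr = TRUE)
})
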