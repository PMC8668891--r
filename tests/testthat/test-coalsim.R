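test_that("homogeneous sub-models yield all-ones genomic factors", {
  f <- draw_genomic_factors("NeHom.MHom", n_loci = 100, rng_seed = 1)
  expect_identical(f$ne, rep(1, 100))
  expect_identical(f$mig, rep(1, 100))
  expect_error(draw_genomic_factors("NeHom.MHom", n_loci = 0), "n_loci")
})

test_that("heterogeneous factors follow rescaled-Beta laws", {
  set.seed(3)
  f <- draw_genomic_factors("NeHet.MHet", shapes_ne = c(2, 2),
                            shapes_m = c(1, 1), n_loci = 10000)
  # Ne factors rescaled to mean 1
  expect_lt(abs(mean(f$ne) - 1), 0.02)
  expect_true(all(f$ne >= 0))
  # Beta(1,1) migration factors are uniform on [0,1]
  expect_true(all(f$mig >= 0 & f$mig <= 1))
  expect_lt(abs(mean(f$mig) - 0.5), 0.01)
  expect_gt(ks.test(f$mig, "punif")$p.value, 0.01)
})

test_that("a genealogy of n sequences has exactly n - 1 coalescences", {
  d <- sample_parameters("SC.GF1323", rng_seed = 8)
  g <- simulate_genealogy(d, c(3, 4, 2), rng_seed = 1)
  expect_equal(length(g$parent), 2 * 9 - 1)
  expect_equal(sum(g$parent == -1), 1)           # single root
  expect_true(all(diff(g$time[10:17]) >= 0))     # nodes created forward in time
  # one sequence per population: exactly 2 coalescences
  g2 <- simulate_genealogy(d, c(1, 1, 1), rng_seed = 2)
  expect_equal(length(g2$parent), 5)
  tr <- as_phylo(g2)
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 3)
})

test_that("pairwise TMRCA in a constant-size population averages 2N", {
  set.seed(5)
  N <- 1000
  d <- single_pop_draw(N)
  tm <- replicate(10000, max(simulate_genealogy(d, c(2, 0, 0))$time))
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2 * N), 3 * se)
})

test_that("without migration, cross-species coalescence waits for the root", {
  set.seed(6)
  d <- isolation_draw(500, t12 = 2000, t123 = 30000)
  tm <- replicate(1000, max(simulate_genealogy(d, c(1, 0, 1))$time))
  expect_true(all(tm >= 30000))
  # sister-species pair only needs the inner split
  tm12 <- replicate(1000, max(simulate_genealogy(d, c(1, 1, 0))$time))
  expect_true(all(tm12 >= 2000))
  expect_lt(min(tm12), 30000)
})

test_that("theta-mode mutation counts follow Watterson's expectation", {
  set.seed(9)
  N <- 1000; L <- 500; n <- 10
  theta_locus <- 10                       # 4 N mu L
  mu <- theta_locus / (4 * N * L)
  d <- single_pop_draw(N)
  S <- replicate(4000, {
    g <- simulate_genealogy(d, c(n, 0, 0))
    ncol(mutate_theta(g, L, mu)$snp)
  })
  a9 <- sum(1 / seq_len(n - 1))
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - theta_locus * a9), 3 * se)
})

test_that("theta mode at mu = 0 is always monomorphic", {
  g <- simulate_genealogy(single_pop_draw(100), c(5, 0, 0), rng_seed = 2)
  lc <- mutate_theta(g, 100, mu = 0)
  expect_true(lc$monomorphic)
  expect_equal(ncol(lc$snp), 0)
})

test_that("fixed-SNP mode forces the segregating-site count", {
  g <- simulate_genealogy(single_pop_draw(200), c(4, 3, 3), rng_seed = 3)
  for (s in c(1, 5, 91)) {
    lc <- mutate_fixed(g, s, 500, rng_seed = s)
    expect_equal(ncol(lc$snp), s)
    cs <- colSums(lc$snp)
    expect_true(all(cs > 0 & cs < 10))   # every column segregating
  }
  expect_error(mutate_fixed(g, 0, 500), "s_obs")
})

test_that("fixed-SNP placements match branch-length proportions", {
  # hand-built 3-leaf genealogy: ((t0:1, t1:1):2, t2:3)
  g <- structure(list(parent = c(3L, 3L, 4L, 4L, -1L),
                      time = c(0, 0, 0, 1, 3),
                      n_tip = 3L, n_seq = c(1L, 1L, 1L)),
                 class = "genealogy")
  bl <- c(1, 1, 3, 2)  # tips 0,1,2 then internal node 3
  set.seed(4)
  lc <- mutate_fixed(g, 5000, 10000)
  # identify the branch of each mutation from its derived carriers
  pat <- apply(lc$snp, 2, paste, collapse = "")
  counts <- c(sum(pat == "100"), sum(pat == "010"),
              sum(pat == "001"), sum(pat == "110"))
  expect_equal(sum(counts), 5000)
  p <- chisq.test(counts, p = bl / sum(bl))$p.value
  expect_gt(p, 0.01)
})

test_that("simulated datasets honour the mode contracts and determinism", {
  d <- isolation_draw(2000, 5e4, 2e5)
  specs <- tiny_specs(50, 400)
  specs$s_obs <- sample(1:10, 50, replace = TRUE)
  ds <- simulate_dataset(d, specs, c(4, 4, 4), "fixed_snp", rng_seed = 10)
  expect_equal(n_loci(ds), 50)
  ns <- vapply(ds$loci, function(l) ncol(l$snp), 1L)
  expect_identical(unname(ns), specs$s_obs)

  # tiny theta: far fewer loci survive, none monomorphic
  d2 <- single_pop_draw(50)
  ds2 <- simulate_dataset(d2, tiny_specs(200, 100), c(4, 4, 4), "theta",
                          mu = 1e-8, rng_seed = 11)
  expect_lt(n_loci(ds2), 100)
  if (n_loci(ds2) > 0)
    expect_true(all(vapply(ds2$loci, function(l) ncol(l$snp), 1L) > 0))

  a <- simulate_dataset(d, specs, c(4, 4, 4), "fixed_snp", rng_seed = 12)
  b <- simulate_dataset(d, specs, c(4, 4, 4), "fixed_snp", rng_seed = 12)
  expect_identical(a, b)
  expect_error(simulate_dataset(d, specs[0, ], c(4, 4, 4)), "empty")
})

test_that("every simulated locus is segregating in the pooled sample", {
  d <- sample_parameters("SC.GF1323", "NeHet.MHet", rng_seed = 21)
  ds <- simulate_dataset(d, tiny_specs(40), c(6, 6, 4), "theta",
                         rng_seed = 22)
  for (lc in ds$loci) {
    cs <- colSums(lc$snp)
    expect_true(all(cs > 0 & cs < nrow(lc$snp)))
  }
})

test_that("Ne heterogeneity inflates across-locus variance of pi", {
  set.seed(30)
  d <- single_pop_draw(5000)
  specs <- tiny_specs(2000, 300)
  hom <- simulate_dataset_stats(d, specs, c(8, 0, 0), "theta", mu = 1e-7)
  het_f <- draw_genomic_factors("NeHet.MHom", shapes_ne = c(0.5, 0.5),
                                shapes_m = NULL, n_loci = 2000)
  het <- simulate_dataset_stats(d, specs, c(8, 0, 0), "theta", mu = 1e-7,
                                factors = het_f)
  v_hom <- var(hom$stats[, "pi_P1"])
  v_het <- var(het$stats[, "pi_P1"])
  expect_gt(v_het, v_hom)
})

test_that("fixed differences increase with split time under strict isolation", {
  set.seed(31)
  splits <- c(1e3, 1e4, 1e5, 1e6, 5e6)
  sf <- vapply(splits, function(t123) {
    d <- isolation_draw(1000, t123 / 10, t123)
    specs <- tiny_specs(500, 300)
    specs$s_obs <- 20L
    s <- simulate_dataset_stats(d, specs, c(4, 4, 4), "fixed_snp", mu = 3e-9,
                                rng_seed = as.integer(t123 %% 1e6))
    mean(s$stats[, "sf_P1P3"])
  }, 1)
  expect_true(all(diff(sf) > 0))
})
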