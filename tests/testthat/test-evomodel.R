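test_that("Pagel transforms behave at their identity and limits", {
  for (seed in 1:50) {
    rt <- random_tree(7, seed)
    expect_equal(transform_covariance(rt, 1, 1, 1), phylo_vcv(rt))
  }
  rt <- random_tree(8, 3)
  Cl <- transform_covariance(rt, lambda = 0)
  expect_equal(max(abs(Cl[upper.tri(Cl)])), 0)
  expect_equal(diag(Cl), diag(phylo_vcv(rt)))

  single <- read_newick("(A:4);")
  expect_equal(unname(transform_covariance(single, kappa = 0.5)[1, 1]), 2) # 4^0.5
  expect_error(transform_covariance(rt, lambda = 1.2), "lambda")
  expect_error(transform_covariance(rt, kappa = -1), "kappa")
})

test_that("bm_loglik matches closed forms and a dense MVN oracle", {
  # single tip at the root state
  single <- read_newick("(A:3);")
  C1 <- phylo_vcv(single)
  expect_equal(bm_loglik(c(A = 5), C1, alpha = 2, root_state = 5),
               -0.5 * log(2 * pi * 2 * 3))
  # two independent tips: sum of univariate normal log-densities
  star <- read_newick("(A:2,B:5);")
  C2 <- phylo_vcv(star)
  ll <- bm_loglik(c(A = 1, B = -1), C2, alpha = 0.5, root_state = 0.3)
  expect_equal(ll, dnorm(1, 0.3, sqrt(0.5 * 2), log = TRUE) +
                   dnorm(-1, 0.3, sqrt(0.5 * 5), log = TRUE))
  # seeded 5-taxon instance vs the dense oracle
  rt <- random_tree(5, 11)
  C <- phylo_vcv(rt)
  x <- withr::with_seed(4, rnorm(5))
  names(x) <- rownames(C)
  p <- diag(C)
  expect_equal(
    bm_loglik(x, C, alpha = 1.3, root_state = 0.2, beta = 0.05, paths = p),
    dense_mvn_loglik(x, 0.2 + 0.05 * p, 1.3 * C),
    tolerance = 1e-8
  )
  # invariant to taxon ordering
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bm_loglik(x[perm], C[perm, perm], 1.3, 0.2),
               bm_loglik(x, C, 1.3, 0.2))
})

test_that("fit_ml profiles the root correctly and maximises the likelihood", {
  star <- read_newick("(A:1,B:1,C:1,D:1);")
  x <- c(A = 1, B = 3, C = 2, D = 6)
  dat <- tibble::tibble(taxon = names(x), value = unname(x))
  fit <- fit_ml(dat, star, "value")
  expect_equal(evo_param(fit, "root_state"), mean(x))

  rt <- random_tree(15, 2)
  sim <- simulate_bm(rt, alpha = 1, root_state = 0, seed = 9)
  dat2 <- tibble::tibble(taxon = sim$tips$taxon, value = sim$tips$value)
  fit2 <- fit_ml(dat2, rt, "value")
  C <- phylo_vcv(rt)[dat2$taxon, dat2$taxon]
  draws <- withr::with_seed(21, replicate(100, {
    bm_loglik(setNames(dat2$value, dat2$taxon), C,
              alpha = runif(1, 0.1, 5), root_state = runif(1, -3, 3))
  }))
  expect_true(all(fit2$loglik >= draws))
})

test_that("fit_ml recovers the diffusion rate within chi-square sampling bounds", {
  alphas <- vapply(1:20, function(seed) {
    cfg <- sim_config(n_extant = 100, n_fossils = 0, seed = seed, height = 1)
    tr <- simulate_tree(cfg)
    sim <- simulate_bm(tr, alpha = 1, root_state = 0, seed = seed + 300)
    dat <- tibble::tibble(taxon = sim$tips$taxon, value = sim$tips$value)
    evo_param(fit_ml(dat, tr, "value"), "alpha")
  }, numeric(1))
  expect_true(all(alphas > 0.7 & alphas < 1.4))
})

test_that("directional fit needs path-length variation and recovers drift sign", {
  cfg <- sim_config(n_extant = 20, n_fossils = 0, seed = 5)
  ultra <- simulate_tree(cfg)
  sim <- simulate_bm(ultra, alpha = 0.01, seed = 1)
  dat <- tibble::tibble(taxon = sim$tips$taxon, value = sim$tips$value)
  expect_error(fit_ml(dat, ultra, "value", directional = TRUE), "path-length variation")

  signs <- vapply(1:20, function(seed) {
    cfg <- sim_config(n_extant = 20, n_fossils = 8, seed = seed)
    tr <- simulate_tree(cfg)
    sim <- simulate_bm(tr, alpha = 0.01, root_state = 0, beta = 0.2, seed = seed + 40)
    dat <- tibble::tibble(taxon = sim$tips$taxon, value = sim$tips$value)
    sign(evo_param(fit_ml(dat, tr, "value", directional = TRUE), "beta"))
  }, numeric(1))
  expect_gte(sum(signs > 0), 18)
})

test_that("pgls is exact on noise-free lines and equals OLS under identity covariance", {
  for (seed in 1:5) {
    rt <- random_tree(10, seed)
    x <- withr::with_seed(seed, rnorm(10))
    dat <- tibble::tibble(taxon = rt$tip.label, x = x, y = 1 + 2 * x)
    fit <- pgls(dat, y ~ x, rt)
    expect_equal(fit$intercept, 1, tolerance = 1e-10)
    expect_equal(fit$slope, 2, tolerance = 1e-10)
    expect_equal(fit$r_squared, 1, tolerance = 1e-10)
    expect_equal(max(abs(fit$residuals$residual)), 0, tolerance = 1e-10)
  }
  # star tree with unit branches -> identity covariance -> OLS
  star <- read_newick("(A:1,B:1,C:1,D:1,E:1,F:1);")
  dat <- withr::with_seed(8, tibble::tibble(taxon = star$tip.label,
                                            x = rnorm(6), y = rnorm(6)))
  fit <- pgls(dat, y ~ x, star)
  ols <- lm(y ~ x, data = dat)
  expect_equal(fit$intercept, unname(coef(ols)[1]), tolerance = 1e-10)
  expect_equal(fit$slope, unname(coef(ols)[2]), tolerance = 1e-10)
  expect_equal(fit$t_statistic, unname(summary(ols)$coefficients[2, "t value"]),
               tolerance = 1e-8)
  expect_error(pgls(dplyr::mutate(dat, x = 1), y ~ x, star), "constant")
})

test_that("pgls recovers the generating slope at n = 200", {
  slopes <- vapply(1:20, function(seed) {
    cfg <- sim_config(n_extant = 200, n_fossils = 0, seed = seed)
    tr <- simulate_tree(cfg)
    sim <- simulate_traits(tr, cfg)
    pgls(sim$traits, log10_brain ~ log10_body, tr)$slope
  }, numeric(1))
  expect_true(all(abs(slopes - 0.684) < 0.05))
})

test_that("likelihood-ratio tests map onto the chi-square df 1 tail", {
  eq <- lr_test(-10, -10)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)

  lr8 <- lr_test(-26, -30)
  expect_equal(lr8$statistic, 8)
  expect_equal(lr8$p_value, 0.004677735, tolerance = 1e-6)

  # the published kappa test pairs LR = 8.132 with P = 0.004 at df 1
  expect_equal(round(pchisq(8.132, 1, lower.tail = FALSE), 3), 0.004)
  expect_error(lr_test(-30, -26), "optimization failure")
})

test_that("scaling-parameter estimation detects a strong kappa signal", {
  # data generated under kappa = 0 (equal effective branch lengths)
  cfg <- sim_config(n_extant = 40, n_fossils = 0, seed = 6)
  tr <- simulate_tree(cfg)
  kt <- tr
  kt$edge.length <- rep(1, nrow(tr$edge))
  sim <- simulate_bm(kt, alpha = 1, seed = 12)
  dat <- tibble::tibble(taxon = sim$tips$taxon, value = sim$tips$value)
  free <- fit_ml(dat, tr, "value", estimate_kappa = TRUE)
  fixed <- fit_ml(dat, tr, "value")
  expect_lt(evo_param(free, "kappa"), 0.5)
  expect_lt(lr_test(free, fixed)$p_value, 0.05)
})

test_that("tidy and glance expose fit summaries", {
  rt <- random_tree(8, 4)
  dat <- withr::with_seed(2, tibble::tibble(taxon = rt$tip.label, x = rnorm(8),
                                            y = rnorm(8)))
  fit <- pgls(dat, y ~ x, rt)
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "x"))
  gl <- glance(fit)
  expect_true(all(c("r.squared", "logLik", "kappa") %in% names(gl)))
  expect_equal(nrow(augment(fit)), 8)
})
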