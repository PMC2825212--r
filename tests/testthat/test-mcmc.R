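fixture_20 <- function() {
  cfg <- sim_config(n_extant = 16, n_fossils = 4, seed = 11)
  tree <- simulate_tree(cfg)
  sim <- simulate_traits(tree, cfg)
  list(tree = tree, traits = sim$traits)
}

test_that("chains are deterministic under a fixed seed and respect their settings", {
  fx <- fixture_20()
  st <- quick_settings(seed = 42, iterations = 4000, burn_in = 1500)
  r1 <- mcmc_fit(fx$traits, fx$tree, "log10_body", settings = st)
  r2 <- mcmc_fit(fx$traits, fx$tree, "log10_body", settings = st)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$node_draws, r2$node_draws)
  expect_equal(nrow(r1$trace), st$iterations %/% st$thin)
  expect_true(all(r1$trace$root_state >= st$prior[1] & r1$trace$root_state <= st$prior[2]))
  expect_true(all(r1$node_draws >= st$prior[1] & r1$node_draws <= st$prior[2]))
  expect_true(all(r1$trace$alpha > 0))
})

test_that("burn-in tuning lands parameter and node acceptance in the target band", {
  fx <- fixture_20()
  st <- quick_settings(seed = 7, iterations = 12000, burn_in = 10000)
  run <- mcmc_fit(fx$traits, fx$tree, "log10_body", settings = st)
  expect_true(all(run$acceptance$params >= 0.20 & run$acceptance$params <= 0.40))
  expect_true(run$acceptance$nodes >= 0.20 && run$acceptance$nodes <= 0.40)
})

test_that("posterior node means track the ML conditional expectations", {
  fx <- fixture_20()
  st <- quick_settings(seed = 3, iterations = 30000, burn_in = 8000)
  run <- mcmc_fit(fx$traits, fx$tree, "log10_body", settings = st)
  est <- asr_mcmc(run)
  ml <- asr_ml(fx$traits, fx$tree, "log10_body")
  j <- dplyr::inner_join(est, ml, by = "node", suffix = c("_mcmc", "_ml"))
  mcses <- vapply(as.character(j$node), function(n) mcse(run$node_draws[, n]), numeric(1))
  expect_true(all(abs(j$estimate_mcmc - j$estimate_ml) <= 3 * mcses))
  expect_gt(congruence(est, ml)$r_s, 0.99)
})

test_that("two-tip symmetric posterior centres between the tip values", {
  tr <- read_newick("(A:1,B:1);")
  dat <- trait_frame(c(A = 0, B = 2))
  st <- quick_settings(seed = 5, iterations = 20000, burn_in = 5000)
  # two tips barely constrain alpha, so its acceptance can drift out of the
  # diagnostic band; that warning is expected here
  run <- suppressWarnings(mcmc_fit(dat, tr, "value", settings = st))
  est <- asr_mcmc(run)
  expect_lte(abs(est$estimate - 1), 3 * mcse(run$node_draws[, 1]))
})

test_that("credible intervals widen from shallow to deep nodes on an ultrametric tree", {
  cfg <- sim_config(n_extant = 20, n_fossils = 0, seed = 9)
  tr <- simulate_tree(cfg)
  sim <- simulate_bm(tr, alpha = 0.01, seed = 4)
  dat <- tibble::tibble(taxon = sim$tips$taxon, value = sim$tips$value)
  st <- quick_settings(seed = 2, iterations = 20000, burn_in = 8000)
  est <- asr_mcmc(mcmc_fit(dat, tr, "value", settings = st))
  width <- est$ci95_high - est$ci95_low
  expect_gt(cor(rank(est$age), rank(width)), 0)
  # the root interval is the widest of all
  expect_equal(which.max(width), which.max(est$age))
  expect_true(all(est$ci95_low <= est$estimate & est$estimate <= est$ci95_high))
})

test_that("asr_mcmc validates its inputs", {
  fx <- fixture_20()
  st <- quick_settings(seed = 1, iterations = 2000, burn_in = 500)
  run <- mcmc_fit(fx$traits, fx$tree, "log10_body", settings = st)
  expect_error(asr_mcmc(run, nodes = 1), "not internal")
  st$sample_nodes <- FALSE
  run2 <- mcmc_fit(fx$traits, fx$tree, "log10_body", settings = st)
  expect_error(asr_mcmc(run2), "sample_nodes")
  st$sample_nodes <- TRUE
  expect_error(mcmc_fit(fx$traits, fx$tree, "log10_body", settings = st, lambda = 0.5),
               "lambda = delta = 1")
  expect_error(mcmc_fit(fx$traits, fx$tree, "log10_body", settings = st,
                        estimate_scaling = "kappa"),
               "sample_nodes = FALSE")
})

test_that("directional chains require fossil path-length variation", {
  cfg <- sim_config(n_extant = 10, n_fossils = 0, seed = 2)
  tr <- simulate_tree(cfg)
  sim <- simulate_bm(tr, alpha = 0.01, seed = 3)
  dat <- tibble::tibble(taxon = sim$tips$taxon, value = sim$tips$value)
  expect_error(
    mcmc_fit(dat, tr, "value", directional = TRUE, settings = quick_settings()),
    "path-length variation"
  )
})

test_that("marginal and latent-node samplers agree on the posterior of the root", {
  fx <- fixture_20()
  stA <- quick_settings(seed = 31, iterations = 30000, burn_in = 8000)
  stB <- quick_settings(seed = 32, iterations = 30000, burn_in = 8000, sample_nodes = FALSE)
  rA <- mcmc_fit(fx$traits, fx$tree, "log10_body", settings = stA)
  rB <- mcmc_fit(fx$traits, fx$tree, "log10_body", settings = stB)
  tol <- 3 * (mcse(rA$trace$root_state) + mcse(rB$trace$root_state))
  expect_lte(abs(mean(rA$trace$root_state) - mean(rB$trace$root_state)), tol)
})

test_that("tidy and glance summarise runs", {
  fx <- fixture_20()
  st <- quick_settings(seed = 13, iterations = 3000, burn_in = 1000)
  run <- mcmc_fit(fx$traits, fx$tree, "log10_body", settings = st)
  td <- tidy(run)
  expect_true(all(c("alpha", "root_state") %in% td$term))
  gl <- glance(run)
  expect_equal(gl$n_draws, 300)
  expect_true(is.finite(gl$log_hm))
})
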