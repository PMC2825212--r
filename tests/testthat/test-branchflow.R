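test_that("branch changes populate deltas, rates, and decrease flags", {
  tr <- read_newick("(A:2,B:2);")
  # parent (node 3) = 100 g, child A = 200 g, child B = 100 g
  vals <- tibble::tibble(node = c(1, 2, 3), value = log10(c(200, 100, 100)))
  ch <- branch_changes(vals, tr)
  a <- ch[ch$child_label == "A", ]
  expect_equal(a$delta_log, log10(2), tolerance = 1e-12)
  expect_equal(a$delta_abs, 100)
  expect_equal(a$rate_abs, 50)
  expect_equal(a$prop_change, 1) # a doubling is a 100% increase
  expect_false(a$decrease)
  b <- ch[ch$child_label == "B", ]
  expect_equal(b$delta_log, 0)
  expect_equal(b$delta_abs, 0)
  expect_false(b$decrease)
  expect_error(branch_changes(vals[-3, ], tr), "missing values")
})

test_that("log changes telescope along root-to-tip paths", {
  tr <- read_newick("((((A:1,B:1):1,C:2):1,D:3):1,E:4);")
  n_all <- ape::Ntip(tr) + tr$Nnode
  vals <- tibble::tibble(node = seq_len(n_all),
                         value = withr::with_seed(3, rnorm(n_all)))
  ch <- branch_changes(vals, tr)
  root <- ape::Ntip(tr) + 1
  # walk the 4-branch chain down to tip A
  path_sum <- 0
  node <- match("A", tr$tip.label)
  while (node != root) {
    e <- which(ch$child == node)
    path_sum <- path_sum + ch$delta_log[e]
    node <- ch$parent[e]
  }
  expect_equal(path_sum, vals$value[match("A", tr$tip.label)] - vals$value[root],
               tolerance = 1e-12)
  # decrease flags agree between log and raw scales
  expect_identical(ch$decrease, ch$delta_abs < 0)
})

test_that("quartile summaries follow the interpolated-rank convention", {
  tr <- read_newick("(A:1,B:1,C:1,D:1);")
  vals <- tibble::tibble(node = 1:5, value = c(1, 2, 3, 4, 0))
  ch <- branch_changes(vals, tr, raw = FALSE)
  qs <- quartile_summary(ch)
  expect_equal(qs$mean, mean(c(1, 2, 3, 4)))
  expect_equal(qs$upper_quartile_threshold, unname(quantile(c(1, 2, 3, 4), 0.75)))
  expect_true(qs$upper_quartile_threshold > 3 && qs$upper_quartile_threshold < 4)
  expect_equal(qs$upper_branches$delta_log, 4)

  vals_eq <- tibble::tibble(node = 1:5, value = c(1, 1, 1, 1, 0))
  qs_eq <- quartile_summary(branch_changes(vals_eq, tr, raw = FALSE))
  expect_equal(nrow(qs_eq$upper_branches), 0)

  # seeded 70-branch instance vs a sort-based percentile oracle
  x <- withr::with_seed(9, rnorm(70))
  fake <- tibble::tibble(delta_log = x, child = seq_along(x), parent = 0,
                         child_label = as.character(seq_along(x)))
  thr <- quartile_summary(fake)$upper_quartile_threshold
  s <- sort(x)
  h <- (70 - 1) * 0.75 + 1
  expect_equal(thr, s[floor(h)] + (h - floor(h)) * (s[floor(h) + 1] - s[floor(h)]))
})

test_that("the decrease census counts branches, time, and brain/body ratios", {
  tr <- read_newick("(A:1,B:1,C:1,D:1);")
  brain <- branch_changes(tibble::tibble(node = 1:5, value = c(-1, 1, 1, 1, 0)), tr, raw = FALSE)
  body <- branch_changes(tibble::tibble(node = 1:5, value = c(-2, 1, 2, 1, 0)), tr, raw = FALSE)
  cen <- decrease_census(brain, body)
  expect_equal(cen$summary$fraction_branches[cen$summary$trait == "brain"], 0.25)
  expect_equal(cen$summary$fraction_time[cen$summary$trait == "brain"], 0.25)
  expect_equal(nrow(cen$ratios), 1)
  expect_equal(cen$ratios$ratio, 0.5) # -1 / -2

  none <- branch_changes(tibble::tibble(node = 1:5, value = c(1, 1, 1, 1, 0)), tr, raw = FALSE)
  cen0 <- decrease_census(none, body)
  expect_equal(cen0$summary$n_decreasing[1], 0L)
  expect_equal(nrow(cen0$ratios), 0)

  # seeded instance vs hand enumeration
  rt <- random_tree(11, 4)
  n_all <- ape::Ntip(rt) + rt$Nnode
  vb <- withr::with_seed(5, rnorm(n_all)); vy <- withr::with_seed(6, rnorm(n_all))
  chb <- branch_changes(tibble::tibble(node = 1:n_all, value = vb), rt, raw = FALSE)
  chy <- branch_changes(tibble::tibble(node = 1:n_all, value = vy), rt, raw = FALSE)
  cen2 <- decrease_census(chb, chy)
  dec <- vb[rt$edge[, 2]] - vb[rt$edge[, 1]] < 0
  expect_equal(cen2$summary$n_decreasing[1], sum(dec))
  expect_equal(cen2$summary$fraction_time[1],
               sum(rt$edge.length[dec]) / sum(rt$edge.length))
})

test_that("the decrease ratio is exact and unit-invariant", {
  expect_equal(round(decrease_ratio(-0.398, -0.55278), 3), 0.720)
  expect_equal(decrease_ratio(-0.3, -0.3), 1)
  # converting both masses g -> mg shifts both logs by 3; deltas are unchanged
  pb <- log10(c(500, 200)); bb <- log10(c(60000, 20000))
  r_g <- decrease_ratio(diff(pb), diff(bb))
  r_mg <- decrease_ratio(diff(pb + 3), diff(bb + 3))
  expect_equal(r_g, r_mg, tolerance = 1e-12)
  expect_error(decrease_ratio(-0.1, 0), "zero body")
})

test_that("a positive brain trend makes brain decreases rarer than body decreases", {
  fx <- primate_fixture(beta_brain = 0.005)
  est_brain <- asr_ml(fx$traits, fx$tree, "log10_brain")
  est_body <- asr_ml(fx$traits, fx$tree, "log10_body")
  nv <- function(est, tips) dplyr::bind_rows(
    tibble::tibble(node = match(fx$traits$taxon, fx$tree$tip.label), value = tips),
    dplyr::select(est, "node", value = "estimate")
  )
  chb <- branch_changes(nv(est_brain, fx$traits$log10_brain), fx$tree)
  chy <- branch_changes(nv(est_body, fx$traits$log10_body), fx$tree)
  cen <- decrease_census(chb, chy)
  s <- cen$summary
  expect_lt(s$fraction_branches[s$trait == "brain"],
            s$fraction_branches[s$trait == "body"])
})
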