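hominin_line <- allometry_line(2.18, 0.684, brain_unit = "mg")

test_that("evaluate_scenario reproduces the published H. erectus dwarfism row", {
  # ancestor masses recovered by inverting the published row:
  # brain 380 g and dLog(brain) = -0.398 -> ancestor brain = 380 * 10^0.398;
  # ratio 0.720 at a 16 kg descendant -> ancestor body = 16 kg * 10^(0.398/0.720)
  anc_brain <- 380 * 10^0.398
  anc_body <- 16000 * 10^(0.398 / 0.720)
  expect_equal(anc_brain, 950.1, tolerance = 1e-3)
  expect_equal(anc_body / 1000, 57.10, tolerance = 1e-3)
  res <- evaluate_scenario("H. erectus", anc_brain, anc_body, 380, 16000, hominin_line)
  expect_equal(round(res$ratio, 3), 0.720)
  expect_equal(round(res$delta_log_brain, 3), -0.398)
  expect_equal(round(res$delta_rel, 3), -0.020)
})

test_that("scenario statistics are unit-invariant and obey the scaling identity", {
  res_g <- evaluate_scenario("x", 950.1, 57100, 380, 16000, hominin_line)
  res_mg <- evaluate_scenario("x", 950.1e3, 57100e3, 380e3, 16000e3, hominin_line)
  expect_equal(res_g$ratio, res_mg$ratio, tolerance = 1e-12)
  expect_equal(res_g$delta_log_brain, res_mg$delta_log_brain, tolerance = 1e-12)
  expect_equal(res_g$delta_rel, res_mg$delta_rel, tolerance = 1e-12)

  # proportional dwarfing of both masses by k: delta_rel = (1 - slope) * log10(k)
  k <- 0.4
  res_k <- evaluate_scenario("k", 1000, 50000, 1000 * k, 50000 * k, hominin_line)
  expect_equal(res_k$delta_rel, (1 - 0.684) * log10(k), tolerance = 1e-12)
  expect_equal(res_k$ratio, 1)
  expect_error(evaluate_scenario("bad", 1000, 50000, 380, 50000, hominin_line),
               "undefined")
  expect_error(evaluate_scenario("bad", -1, 50000, 380, 16000, hominin_line),
               "positive")
})

test_that("the per-cell identity reconstructs published table cells from printed inputs", {
  cells <- tibble::tibble(
    label = c("H. erectus 16", "H. erectus 32", "Ngandong 16", "Dmanisi 16",
              "Argue tree 1 16", "Argue tree 2 16"),
    delta_log_brain = c(-0.398, -0.398, -0.450, -0.216, -0.171, -0.173),
    ratio = c(0.720, 1.586, 0.784, 0.437, 0.400, 0.428),
    printed_delta_rel = c(-0.020, -0.226, -0.058, 0.122, 0.121, 0.104)
  )
  got <- relative_change_from_ratio(cells$delta_log_brain, cells$ratio, slope = 0.684)
  # printed ratios are rounded to 3 dp, so agreement is to one unit in the
  # last printed digit
  expect_true(all(abs(got - cells$printed_delta_rel) <= 0.001))
  expect_error(relative_change_from_ratio(-0.1, 0), "undefined")
})

test_that("scenario grids expand ancestors by body mass with constant brain change", {
  anc <- tibble::tibble(
    ancestor = c("H. erectus", "Ngandong", "Dmanisi", "H. habilis"),
    brain_g = c(950.1, 1071.2, 625.0, 522.0),
    body_g = c(57100, 60000, 40000, 34000)
  )
  grid <- scenario_grid(anc, descendant_brain_g = 380,
                        descendant_body_kg = c(16, 24, 32), line = hominin_line)
  expect_equal(nrow(grid), 12)
  per_anc <- dplyr::summarise(dplyr::group_by(grid, ancestor),
                              n = dplyr::n_distinct(round(delta_log_brain, 12)))
  expect_true(all(per_anc$n == 1))
  # ratio and delta_rel are monotone in descendant body mass for a fixed ancestor
  he <- dplyr::arrange(grid[grid$ancestor == "H. erectus", ], descendant_body_kg)
  expect_true(all(diff(he$ratio) > 0))
  expect_true(all(diff(he$delta_rel) < 0))
})

test_that("envelope flags classify scenarios as inside or outside observed decreases", {
  env <- primate_decrease_envelope()
  expect_equal(c(env$ratio_min, env$ratio_max), c(0.006, 0.825))
  within <- evaluate_scenario("in", 950.1, 57100, 380, 16000, hominin_line, env)
  expect_true(within$within_ratio_range)   # 0.720 in [0.006, 0.825]
  expect_false(within$within_brain_range)  # -0.398 beyond -0.273
  outside <- evaluate_scenario("out", 950.1, 57100, 380, 32000, hominin_line, env)
  expect_false(outside$within_ratio_range) # 1.586 outside
  no_env <- evaluate_scenario("na", 950.1, 57100, 380, 16000, hominin_line)
  expect_true(is.na(no_env$within_ratio_range))
})

test_that("expected brain decreases scale ratios onto a body-mass decrease", {
  expect_equal(expected_brain_decrease(-0.4, 0.5)$predictions$predicted_delta_log_brain,
               -0.2)
  out <- expected_brain_decrease(-0.5, c(0.006, 0.825))
  expect_equal(out$predictions$predicted_delta_log_brain, c(-0.003, -0.4125))
  expect_equal(unname(out$summary["min"]), -0.4125)
  expect_equal(expected_brain_decrease(-0.5, 0)$predictions$predicted_delta_log_brain, 0)
  expect_error(expected_brain_decrease(0.1, 0.5), "decrease")
})

test_that("an envelope can be built from a computed census", {
  tr <- read_newick("(A:1,B:1,C:1,D:1);")
  brain <- branch_changes(tibble::tibble(node = 1:5, value = c(-1, -0.2, 1, 1, 0)), tr, raw = FALSE)
  body <- branch_changes(tibble::tibble(node = 1:5, value = c(-2, -1, 2, 1, 0)), tr, raw = FALSE)
  env <- as_decrease_envelope(decrease_census(brain, body))
  expect_equal(env$ratio_min, 0.2)
  expect_equal(env$ratio_max, 0.5)
  expect_equal(env$delta_log_brain_min, -1)
})
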