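test_that("binning groups trials by half-open age year, condition, object", {
  tr <- tibble::tibble(
    child_id = c("a", "b", "c", "d"),
    age = c(2.1, 2.9, 3.0, 3.5),
    experiment = "exp3",
    condition = c("congruent", "congruent", "incongruent", "incongruent"),
    object_id = c("obj01", "obj01", "obj02", "obj02"),
    correct = c(1L, 0L, 1L, 1L)
  )
  b <- bin_responses(tr)
  cell <- b[b$condition == "congruent", ]
  expect_equal(nrow(cell), 1)
  expect_equal(cell$n_trials, 2L)
  expect_equal(cell$observed_rate, 0.5)
  # age 3.0 belongs to bin 3, not bin 2
  expect_setequal(b$age_bin[b$condition == "incongruent"], 3)
  # partition-complete: every trial lands in exactly one cell
  expect_equal(sum(b$n_trials), nrow(tr))
  expect_error(bin_responses(tr[0, ]), class = "pragword_config_error")
})

test_that("pearson_r matches the textbook formula", {
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 3))$r, 1)
  x <- c(0.1, 0.6, 0.8)
  expect_equal(pearson_r(-x, x - mean(x))$r, -1)

  p <- c(0.2, 0.5, 0.9); o <- c(0.1, 0.6, 0.8)
  hand <- sum((p - mean(p)) * (o - mean(o))) /
    sqrt(sum((p - mean(p))^2) * sum((o - mean(o))^2))
  got <- pearson_r(p, o)
  expect_equal(got$r, hand, tolerance = 1e-12)
  expect_equal(got$r_squared, hand^2)

  set.seed(8)
  a <- runif(50); b <- a + rnorm(50, 0, 0.2)
  brute <- mean((a - mean(a)) * (b - mean(b))) /
    (sqrt(mean((a - mean(a))^2)) * sqrt(mean((b - mean(b))^2)))
  expect_equal(pearson_r(a, b)$r, brute, tolerance = 1e-12)

  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)),
               class = "pragword_domain_error")
  expect_error(pearson_r(1:2, 1:2), class = "pragword_domain_error")
})

test_that("hdi finds the shortest contiguous interval", {
  expect_equal(hdi(rep(2.5, 200)), tibble::tibble(lower = 2.5, upper = 2.5))

  set.seed(21)
  u <- runif(10000)
  h <- hdi(u)
  expect_gt(h$upper - h$lower, 0.94)
  expect_lt(h$upper - h$lower, 0.96)

  x <- rnorm(500)
  full <- hdi(x, mass = 1)
  expect_equal(c(full$lower, full$upper), range(x))

  expect_warning(hdi(c(rnorm(500, -8), rnorm(500, 8))),
                 class = "pragword_hdi_warning")
  expect_error(hdi(rnorm(50)), class = "pragword_domain_error")
})

test_that("comparison report aligns cells and attaches evidence", {
  obs <- tibble::tibble(age_bin = rep(2:4, each = 2),
                        condition = rep(c("congruent", "incongruent"), 3),
                        object_id = "obj01",
                        n_trials = 10L,
                        observed_rate = c(0.5, 0.4, 0.7, 0.5, 0.9, 0.6))
  pred <- dplyr::transmute(obs, age_bin, condition, object_id,
                           predicted_mean = observed_rate * 0.9 + 0.05,
                           predicted_hdi_low = predicted_mean - 0.1,
                           predicted_hdi_high = predicted_mean + 0.1)
  rep2 <- compare_report(obs, list(m1 = pred, m2 = pred))
  expect_equal(nrow(rep2), 2)
  expect_equal(rep2$r[1], rep2$r[2])
  expect_equal(rep2$n_cells, c(6L, 6L))

  ev <- list(m1 = pragword:::new_evidence(log(c(0.1, 0.1)), "m1"),
             m2 = pragword:::new_evidence(log(c(0.01, 0.01)), "m2"))
  rep3 <- compare_report(obs, list(m1 = pred, m2 = pred), evidence = ev)
  expect_equal(rep3$log10_bf, c(0, -1), tolerance = 1e-10)

  # a single model degenerates to a trivial self-comparison
  rep1 <- compare_report(obs, list(only = pred),
                         evidence = ev["m1"] |> setNames("only"))
  expect_equal(rep1$log10_bf, 0)

  expect_error(compare_report(obs, list(bad = pred[-1, ])),
               class = "pragword_config_error")
  expect_error(compare_report(obs, list(pred)),
               class = "pragword_config_error")

  w <- compare_report(obs, list(m1 = pred), weighted = TRUE)
  expect_equal(w$r, rep2$r[1], tolerance = 1e-10)  # equal n per cell
})

test_that("binned predictions expose the lesion signatures", {
  fx <- fixture_prediction_fit()
  grid <- prediction_grid()

  # no common ground: congruent and incongruent columns coincide
  nocg <- posterior_predict(fx$fit, grid, model = "no_common_ground")
  wide <- tidyr::pivot_wider(nocg[, c("age", "condition", "object_id",
                                      ".pred")],
                             names_from = "condition", values_from = ".pred")
  expect_equal(wide$congruent, wide$incongruent, tolerance = 1e-12)

  # no speaker informativeness: prediction is the condition prior itself,
  # so the two alignments are complementary
  nosi <- posterior_predict(fx$fit, grid, model = "no_speaker_informativeness")
  wide2 <- tidyr::pivot_wider(nosi[, c("age", "condition", "object_id",
                                       ".pred")],
                              names_from = "condition", values_from = ".pred")
  expect_equal(wide2$congruent + wide2$incongruent,
               rep(1, nrow(wide2)), tolerance = 1e-10)
  # and it does not depend on the object
  expect_equal(length(unique(round(wide2$congruent, 12))), 3)

  # integration predictions rise with age in the congruent condition
  int <- posterior_predict(fx$fit, grid, model = "integration")
  cong <- int[int$condition == "congruent", ] |>
    dplyr::group_by(age) |>
    dplyr::summarise(p = mean(.pred))
  expect_true(all(diff(cong$p) > 0))
})

test_that("binned prediction cells mirror the data cells", {
  fx <- fixture_prediction_fit()
  tr3 <- dplyr::filter(fx$trials, experiment == "exp3")
  obs <- bin_responses(tr3)
  pred <- bin_predictions(fx$fit, tr3, model = "integration")
  expect_setequal(
    paste(obs$age_bin, obs$condition, obs$object_id),
    paste(pred$age_bin, pred$condition, pred$object_id))
  expect_true(all(pred$predicted_hdi_low <= pred$predicted_mean + 1e-12))
  expect_true(all(pred$predicted_hdi_high >= pred$predicted_mean - 1e-12))
  rep1 <- compare_report(obs, list(integration = pred))
  expect_equal(rep1$n_cells, 72L)
})
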