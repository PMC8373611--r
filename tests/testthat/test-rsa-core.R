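test_that("literal listener applies the lexicon-uncertainty mixture", {
  known <- literal_listener("familiar_word", theta = 1)
  expect_equal(known$p_familiar, 1)
  expect_equal(known$p_novel, 0)

  novel <- literal_listener("novel_word", theta = 0.3)
  expect_equal(novel$p_novel, 0.5)

  half <- literal_listener("familiar_word", theta = 0.5)
  expect_equal(half$p_familiar, 0.75)
  expect_equal(half$p_novel, 0.25)

  expect_error(literal_listener("familiar_word", theta = 1.2),
               class = "pragword_domain_error")
  expect_error(literal_listener("some_word", theta = 0.5),
               class = "pragword_domain_error")
})

test_that("speaker soft-maximises informativity", {
  s <- speaker("familiar_object", alpha = 1, theta = 1)
  expect_equal(s$p_familiar_word, 2 / 3)
  expect_equal(s$p_novel_word, 1 / 3)

  flat <- speaker(c("familiar_object", "novel_object"), alpha = 0, theta = 0.7)
  expect_equal(flat$p_novel_word, c(0.5, 0.5))

  argmax <- speaker("familiar_object", alpha = 200, theta = 1)
  expect_gt(argmax$p_familiar_word, 1 - 1e-10)

  expect_error(speaker("familiar_object", alpha = -1, theta = 0.5),
               class = "pragword_domain_error")
})

test_that("rational integration reproduces the worked posterior values", {
  expect_equal(pragmatic_listener(1, 1, 0.5)$p_novel, 0.75)
  # alpha = 0: likelihood is flat, posterior equals the prior
  expect_equal(pragmatic_listener(0, 0.9, 0.8)$p_novel, 0.8)
  # theta = 0: no word is informative, posterior equals the prior
  expect_equal(pragmatic_listener(1, 0, 0.3)$p_novel, 0.3)

  expect_equal(mutual_exclusivity(1, 1)$p_novel, 0.75)
  expect_equal(mutual_exclusivity(0, 1)$p_novel, 0.5)
  # brute-force enumeration value for a sharper speaker
  expect_equal(mutual_exclusivity(2, 1)$p_novel, 5 / 6)
  expect_equal(mutual_exclusivity(2, 1)$p_novel,
               oracle_l1_p_novel(2, 1, 0.5))
})

test_that("exact 0/1 priors propagate exactly, including extreme alpha", {
  expect_identical(pragmatic_listener(1, 0.5, 0)$p_novel, 0)
  expect_identical(pragmatic_listener(1, 0.5, 1)$p_novel, 1)
  # alpha large enough to underflow the familiar-referent likelihood
  expect_identical(pragmatic_listener(3000, 0.9, 0)$p_novel, 0)
  expect_equal(pragmatic_listener(3000, 0.9, 0.5)$p_novel, 1)
})

test_that("biased mixture is a convex combination bounded by its parts", {
  expect_equal(biased_mix(1, 0.75, 0.9)$p_novel, 0.75)
  expect_equal(biased_mix(0, 0.75, 0.9)$p_novel, 0.9)
  expect_equal(biased_mix(0.65, 0.75, 0.5)$p_novel, 0.6625)

  set.seed(11)
  phi <- runif(200); me <- runif(200); prior <- runif(200)
  p <- biased_mix(phi, me, prior)$p_novel
  expect_true(all(p >= pmin(me, prior) - 1e-12))
  expect_true(all(p <= pmax(me, prior) + 1e-12))

  expect_error(biased_mix(1.3, 0.5, 0.5), class = "pragword_domain_error")
})

test_that("predict_choice dispatches the six variants correctly", {
  ps <- tibble::tibble(alpha = 1, theta = 1, prior_novel = 0.7)
  expect_equal(
    predict_choice(ps, "no_speaker_informativeness")$p_choice, 0.7)
  expect_equal(predict_choice(
    tibble::tibble(alpha = 1, theta = 1, prior_novel = 0.5),
    "integration")$p_choice, 0.75)

  # the no-common-ground lesion is blind to the condition prior
  hi <- predict_choice(tibble::tibble(alpha = 1, theta = 1, prior_novel = 0.9),
                       "no_common_ground")$p_choice
  lo <- predict_choice(tibble::tibble(alpha = 1, theta = 1, prior_novel = 0.1),
                       "no_common_ground")$p_choice
  expect_equal(hi, 0.75)
  expect_identical(hi, lo)

  pooled <- predict_choice(
    tibble::tibble(alpha = 1, theta = 0.9, theta_pooled = 0.4,
                   prior_novel = 0.5),
    "no_word_knowledge")$p_choice
  expect_equal(pooled, oracle_l1_p_novel(1, 0.4, 0.5))

  expect_error(predict_choice(ps, "biased"), class = "pragword_config_error")
  expect_error(
    predict_choice(tibble::tibble(alpha = 1, theta = 1, prior_novel = 0.5,
                                  phi = 0.5), "integration"),
    class = "pragword_config_error")
  expect_error(predict_choice(ps, "no_word_knowledge"),
               class = "pragword_config_error")
})

test_that("closed forms agree with brute-force enumeration on random draws", {
  set.seed(42)
  n <- 1000
  alpha <- runif(n, 0, 5); theta <- runif(n); prior <- runif(n)
  got <- pragmatic_listener(alpha, theta, prior)$p_novel
  want <- vapply(seq_len(n),
                 function(i) oracle_l1_p_novel(alpha[i], theta[i], prior[i]),
                 numeric(1))
  expect_lt(max(abs(got - want)), 1e-10)

  sp <- speaker(rep("novel_object", n), alpha, theta)$p_novel_word
  sp_want <- vapply(seq_len(n),
                    function(i) oracle_s1(alpha[i], theta[i])["novel_word", 1],
                    numeric(1))
  expect_lt(max(abs(sp - sp_want)), 1e-10)

  l0 <- literal_listener(rep("familiar_word", n), theta)$p_novel
  l0_want <- vapply(theta, function(t) oracle_l0(t)["familiar_word", 1],
                    numeric(1))
  expect_lt(max(abs(l0 - l0_want)), 1e-10)
})

test_that("all emitted distributions normalise to one on a parameter grid", {
  grid <- tidyr::expand_grid(alpha = seq(0, 5, by = 0.5),
                             theta = seq(0, 1, by = 0.1),
                             prior = seq(0, 1, by = 0.1))
  l1 <- pragmatic_listener(grid$alpha, grid$theta, grid$prior)
  expect_lt(max(abs(l1$p_novel + l1$p_familiar - 1)), 1e-12)
  s <- speaker("novel_object", grid$alpha, grid$theta)
  expect_lt(max(abs(s$p_novel_word + s$p_familiar_word - 1)), 1e-12)
  l0 <- literal_listener("familiar_word", seq(0, 1, by = 0.01))
  expect_lt(max(abs(l0$p_novel + l0$p_familiar - 1)), 1e-12)
})

test_that("integration posterior is monotone in alpha, theta and the prior", {
  a_grid <- seq(0, 5, length.out = 21)
  t_grid <- seq(0, 1, length.out = 21)
  q_grid <- seq(0, 1, length.out = 21)
  p_a <- pragmatic_listener(a_grid, 0.7, 0.6)$p_novel
  p_t <- pragmatic_listener(1.5, t_grid, 0.6)$p_novel
  p_q <- pragmatic_listener(1.5, 0.7, q_grid)$p_novel
  expect_true(all(diff(p_a) >= -1e-12))
  expect_true(all(diff(p_t) >= -1e-12))
  expect_true(all(diff(p_q) >= -1e-12))
})

test_that("integration dominates the lesions when all cues point the same way", {
  set.seed(7)
  n <- 400
  alpha <- runif(n, 0.05, 4)
  theta <- runif(n, 0.05, 0.95)
  prior <- runif(n, 0.55, 0.999)
  int <- pragmatic_listener(alpha, theta, prior)$p_novel
  no_cg <- mutual_exclusivity(alpha, theta)$p_novel
  no_si <- prior
  expect_true(all(int > no_cg))
  expect_true(all(int > no_si))
  # the no-word-knowledge lesion is dominated wherever it underestimates the
  # object-specific knowledge
  pooled <- pmax(0.001, theta - runif(n, 0.01, 0.3))
  no_wk <- pragmatic_listener(alpha, pooled, prior)$p_novel
  expect_true(all(int > no_wk))
})
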