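test_that("session plans have exact marginals for every seed", {
  for (seed in c(1, 7, 100, 4242)) {
    plan <- build_session(seed)
    expect_equal(nrow(plan), 16)
    expect_equal(as.vector(table(plan$label)), rep(4L, 4))
    expect_equal(as.vector(table(plan$label, plan$order)), rep(2L, 8))
  }
  expect_identical(build_session(5)$label, build_session(5)$label)
  expect_identical(build_session(5), build_session(5))
})

test_that("the ideal observer decodes the sign of delta-IBI", {
  feat <- function(dibi, ok = TRUE) {
    structure(list(label = "D1.0", order = "+", delta_sp = 1,
                   delta_ibi = dibi, delta_afr = 0, ibi_defined = ok),
              class = "pair_features")
  }
  expect_equal(as.character(ideal_observer(feat(0))), "same")
  expect_equal(as.character(ideal_observer(feat(200), tau = 30)), "first_coarser")
  expect_equal(as.character(ideal_observer(feat(-200), tau = 30)), "second_coarser")
  expect_equal(as.character(ideal_observer(feat(40), tau = 50)), "same")
  g <- ideal_observer(feat(NA, ok = FALSE), seed = 3)
  expect_true(attr(g, "guessed"))
  expect_identical(as.character(g),
                   as.character(ideal_observer(feat(NA, ok = FALSE), seed = 3)))
  expect_error(ideal_observer(feat(0), tau = 0), "positive")
})

test_that("the noise-free observer discriminates a full session set perfectly", {
  trials <- run_sessions(n_sessions = 2, seed = 11)
  sc <- score_trials(trials)
  expect_equal(sc$n_trials, 32)
  expect_equal(sc$proportion_correct, 1)
  fd <- fraction_different_by_dsp(trials)
  expect_equal(fd$fraction_different[fd$abs_delta_sp == 0], 0)
  expect_true(all(fd$fraction_different[fd$abs_delta_sp > 0] == 1))
  # order symmetry of the "different" fractions
  fp <- fraction_different_by_dsp(trials[trials$order == "+", ])
  fm <- fraction_different_by_dsp(trials[trials$order == "-", ])
  expect_equal(fp$fraction_different, fm$fraction_different)
})

test_that("scoring reproduces the published proportions", {
  # 77 of 80 correct: 96% to the printed precision
  mk <- function(n_correct, n_total) {
    lab <- rep(c("D1.0"), n_total)
    resp <- ifelse(seq_len(n_total) <= n_correct, "first_coarser", "same")
    data.frame(label = lab, order = "+", delta_sp = 1, response = resp)
  }
  amp <- score_trials(mk(77, 80))
  expect_equal(amp$proportion_correct, 0.9625)
  expect_equal(round(100 * amp$proportion_correct), 96)
  intact <- score_trials(mk(107, 138))
  expect_gt(intact$proportion_correct, 0.77)
  wrong <- score_trials(mk(0, 10))
  expect_equal(wrong$proportion_correct, 0)
  expect_equal(sum(amp$confusion), 80)
  expect_true(all(rowSums(amp$confusion) == table(paste0(mk(77, 80)$label, "+"))))
})

test_that("Clopper-Pearson bounds match the beta-quantile closed form", {
  cases <- expand.grid(k = c(0, 1, 5, 39, 77, 80), n = c(80, 138))
  cases <- cases[cases$k <= cases$n, ]
  for (i in seq_len(nrow(cases))) {
    k <- cases$k[i]; n <- cases$n[i]
    ci <- clopper_pearson(k, n, 0.05)
    lo <- if (k == 0) 0 else qbeta(0.025, k, n - k + 1)
    hi <- if (k == n) 1 else qbeta(0.975, k + 1, n - k)
    expect_lt(abs(ci["lower"] - lo), 1e-9)
    expect_lt(abs(ci["upper"] - hi), 1e-9)
    expect_true(ci["lower"] <= k / n && k / n <= ci["upper"])
  }
  expect_equal(unname(clopper_pearson(80, 80)["upper"]), 1)
  expect_equal(unname(clopper_pearson(0, 80)["lower"]), 0)
  expect_error(clopper_pearson(5, 4), "<= n")
  expect_error(clopper_pearson(-1, 4), "<= n")
})

test_that("Clopper-Pearson intervals reach nominal coverage", {
  set.seed(21)
  p_true <- 0.6
  n <- 50
  hits <- replicate(2000, {
    k <- rbinom(1, n, p_true)
    ci <- clopper_pearson(k, n, 0.05)
    ci["lower"] <= p_true && p_true <= ci["upper"]
  })
  expect_gte(mean(hits), 0.945)
})

test_that("logistic fits recover exact curves and flag degenerate input", {
  x <- c(0, 0.5, 1, 1.5, 2, 2.5)
  frac <- 1 / (1 + exp(-(-2 + 2 * x)))
  f <- logistic_fit(x, frac, 1000)
  expect_equal(f$r_squared, 1, tolerance = 1e-6)
  expect_equal(f$intercept, -2, tolerance = 0.01)
  expect_equal(f$slope, 2, tolerance = 0.01)

  g <- logistic_fit(x, rep(0.5, 6), 100)
  expect_true(is.na(g$r_squared))

  # complete separation: capped coefficients, flagged
  h <- logistic_fit(c(0, 0, 1, 1), c(0, 0, 1, 1), 50)
  expect_false(h$converged)
  expect_lte(abs(h$slope), 50)
  expect_error(logistic_fit(1:2, c(0, 1), 10), "3 points")
  expect_error(logistic_fit(1:3, c(0, 1, 2), 10), "\\[0, 1\\]")
})

test_that("decision noise degrades observer performance monotonically", {
  dibis <- rep(c(0, 100, -100, 200, -200, 250, -250, 0), 5)
  dsp <- dibis / 100
  prop_correct <- sapply(c(0, 40, 120, 400), function(ns) {
    mean(sapply(seq_len(25), function(r) {
      resp <- vapply(seq_along(dibis), function(i) {
        f <- structure(list(delta_sp = dsp[i], delta_ibi = dibis[i],
                            delta_afr = 0, ibi_defined = TRUE,
                            label = "x", order = "+"),
                       class = "pair_features")
        as.character(ideal_observer(f, tau = 50, decision_noise_sd = ns,
                                    seed = derive_seed(r, i + 1000 * ns)))
      }, character(1))
      trials <- data.frame(label = "x", order = "+", delta_sp = dsp,
                           response = resp)
      score_trials(trials)$proportion_correct
    }))
  })
  expect_equal(prop_correct[1], 1)
  expect_true(all(diff(prop_correct) < 0))
})
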