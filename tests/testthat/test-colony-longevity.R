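# Occupancy spells and the censored Weibull AFT likelihood.

test_that("spell extraction sets durations and censoring flags by rule", {
  # occ, occ, unocc -> duration 2, fully observed (start bounds the span?
  # no: first observed year occupied means the true start is unknown)
  ser <- make_series(list(
    s1 = c(`2004` = "unoccupied", `2005` = "occupied", `2006` = "occupied",
           `2007` = "unoccupied"),
    s2 = c(`2005` = "occupied", `2006` = "occupied", `2007` = "occupied",
           `2008` = "occupied", `2009` = "occupied", `2010` = "occupied",
           `2011` = "occupied"),
    s3 = c(`2005` = "unoccupied", `2006` = "occupied",
           `2007` = "unknown")))
  sp <- extract_spells(ser)

  s1 <- sp[sp$series_id == "s1", ]
  expect_equal(s1$duration, 2L)
  expect_false(s1$left_censored)
  expect_false(s1$right_censored)
  expect_true(s1$event)

  # all seven years occupied: censored on both ends by the study window
  s2 <- sp[sp$series_id == "s2", ]
  expect_equal(s2$duration, 7L)
  expect_true(s2$left_censored)
  expect_true(s2$right_censored)

  # known start, unknown end
  s3 <- sp[sp$series_id == "s3", ]
  expect_equal(s3$duration, 1L)
  expect_false(s3$left_censored)
  expect_true(s3$right_censored)
})

test_that("an unknown year splits a run and flags the adjacent ends", {
  ser <- make_series(list(
    s1 = c(`2005` = "occupied", `2006` = "unknown", `2007` = "occupied",
           `2008` = "unoccupied")))
  sp <- extract_spells(ser)
  expect_equal(nrow(sp), 2L)
  expect_true(sp$right_censored[1])   # run before the unknown year
  expect_true(sp$left_censored[2])    # run after it
  expect_false(sp$right_censored[2])  # ends in a known unoccupied year
})

test_that("exponential fit reduces to the closed-form rate", {
  # 5 events totalling 10 years -> rate 0.5, mu = log(1/rate)
  sp <- data.frame(substrate = "cattail-marsh", duration = c(2, 2, 2, 2, 2),
                   left_censored = FALSE, right_censored = FALSE)
  fit <- fit_weibull_aft(sp, use_substrate = FALSE,
                         distribution = "exponential")
  expect_equal(fit$scale, 1)
  expect_equal(unname(fit$coefficients[1]), log(10 / 5), tolerance = 1e-6)
  # and the analytic exponential log-likelihood at the MLE
  rate <- 0.5
  expect_equal(fit$loglik, sum(log(rate) - rate * sp$duration),
               tolerance = 1e-6)
})

test_that("Weibull with sigma free agrees with the exponential when data are exponential-shaped", {
  sp <- simulate_weibull_spells(400, mu = 1.0, sigma = 1.0,
                                prob_censor = 0.2, seed = 5)
  w <- fit_weibull_aft(sp, use_substrate = FALSE)
  e <- fit_weibull_aft(sp, use_substrate = FALSE,
                       distribution = "exponential")
  expect_gte(w$loglik - e$loglik, -1e-6)   # nesting
  expect_equal(w$scale, 1, tolerance = 0.1)
})

test_that("censored MLE matches brute-force grid search and recovers truth", {
  sp <- simulate_weibull_spells(500, mu = 1.355, sigma = 0.436,
                                prob_censor = 0.3, seed = 31)
  fit <- fit_weibull_aft(sp, use_substrate = FALSE)
  expect_lt(abs(unname(fit$coefficients[1]) - 1.355), 0.05)
  expect_lt(abs(fit$scale - 0.436), 0.05)

  grid <- grid_search_weibull(sp$duration, sp$event,
                              mu_range = fit$coefficients[1] + c(-0.2, 0.2),
                              sigma_range = fit$scale * c(0.8, 1.2),
                              n_grid = 201)
  expect_lt(abs(fit$loglik - grid$ll), 1e-3)
  expect_gte(fit$loglik, grid$ll - 1e-9)   # MLE at least as good as grid
})

test_that("censored MLE agrees with survreg as an independent check", {
  sp <- simulate_weibull_spells(300, mu = 1.2, sigma = 0.5,
                                prob_censor = 0.3, seed = 77)
  sp$substrate <- rep(c("cattail-marsh", "grain-field"), length.out = 300)
  sp$duration[sp$substrate == "grain-field"] <-
    sp$duration[sp$substrate == "grain-field"] * exp(-0.8)
  fit <- fit_weibull_aft(sp)
  sr <- survival::survreg(
    survival::Surv(duration, event) ~ relevel(factor(substrate),
                                              "cattail-marsh"),
    data = sp, dist = "weibull")
  expect_equal(unname(fit$coefficients), unname(coef(sr)), tolerance = 1e-4)
  expect_equal(fit$scale, sr$scale, tolerance = 1e-4)
  expect_equal(fit$loglik, sr$loglik[2], tolerance = 1e-4)
})

test_that("left-censored spells enter as lower bounds and can be excluded", {
  sp <- simulate_weibull_spells(200, mu = 1.3, sigma = 0.45,
                                prob_censor = 0, seed = 9)
  sp$left_censored[1:50] <- TRUE
  sp$event <- !sp$left_censored & !sp$right_censored
  fit_all <- fit_weibull_aft(sp, use_substrate = FALSE)
  fit_sub <- fit_weibull_aft(sp, use_substrate = FALSE,
                             include_left_censored = FALSE)
  expect_equal(fit_all$n, 200L)
  expect_equal(fit_sub$n, 150L)
  expect_equal(fit_all$n_events, 150L)
})

test_that("increasing a censored duration never lowers the location estimate", {
  sp <- simulate_weibull_spells(120, mu = 1.0, sigma = 0.5,
                                prob_censor = 0.4, seed = 13)
  fit0 <- fit_weibull_aft(sp, use_substrate = FALSE)
  i <- which(sp$right_censored)[1]
  mus <- vapply(c(1, 2, 4, 8), function(mult) {
    sp2 <- sp
    sp2$duration[i] <- sp2$duration[i] * mult
    unname(fit_weibull_aft(sp2, use_substrate = FALSE)$coefficients[1])
  }, numeric(1))
  expect_true(all(diff(mus) >= -1e-8))
  expect_gte(mus[1], unname(fit0$coefficients[1]) - 1e-8)
})

test_that("all-censored input and degenerate LRT orderings error", {
  sp <- data.frame(substrate = "cattail-marsh", duration = c(3, 4),
                   left_censored = FALSE, right_censored = TRUE)
  expect_error(fit_weibull_aft(sp, use_substrate = FALSE), "censored")

  ok <- simulate_weibull_spells(100, 1, 0.5, 0.2, seed = 2)
  fit <- fit_weibull_aft(ok, use_substrate = FALSE)
  expect_error(likelihood_ratio_test(fit, fit), "more parameters")
})

test_that("likelihood-ratio test: identical nested fits give chi2 = 0, p = 1", {
  sp <- simulate_weibull_spells(200, mu = 1.2, sigma = 0.5,
                                prob_censor = 0.3, seed = 21)
  sp$substrate <- rep(c("cattail-marsh", "thistle"), 100)  # no real effect
  full <- fit_weibull_aft(sp)
  reduced <- fit_weibull_aft(sp, use_substrate = FALSE)
  lrt <- likelihood_ratio_test(full, reduced)
  expect_equal(lrt$df, 1L)
  expect_gte(lrt$chi2, 0)
  expect_equal(lrt$p, pchisq(lrt$chi2, 1, lower.tail = FALSE))
})

test_that("survivorship follows the closed form and substrate ordering", {
  sp <- simulate_weibull_spells(300, mu = 1.355, sigma = 0.436,
                                prob_censor = 0.2, seed = 14)
  sp$substrate <- rep(c("cattail-marsh", "grain-field"), length.out = 300)
  sp$duration[sp$substrate == "grain-field"] <-
    sp$duration[sp$substrate == "grain-field"] * exp(-0.805)
  fit <- fit_weibull_aft(sp)

  expect_equal(survivorship(fit, "cattail-marsh", 0), 1)
  # direct formula evaluation
  mu <- unname(fit$coefficients[1])
  tt <- 1:5
  expect_equal(survivorship(fit, "cattail-marsh", tt),
               exp(-(tt / exp(mu))^(1 / fit$scale)), tolerance = 1e-12)
  s_cat <- survivorship(fit, "cattail-marsh", tt)
  s_tri <- survivorship(fit, "grain-field", tt)
  expect_true(all(diff(s_cat) < 0))            # non-increasing
  expect_true(all(s_tri < s_cat))              # shorter-lived everywhere
  expect_error(survivorship(fit, "willow", 1), "unknown substrate")
})

test_that("sigma = 1 closed form: exponential survivor function", {
  sp <- data.frame(substrate = "x", duration = rep(2, 10),
                   left_censored = FALSE, right_censored = FALSE)
  fit <- fit_weibull_aft(sp, use_substrate = FALSE,
                         distribution = "exponential")
  # lambda = 2, t = 2 -> exp(-1)
  expect_equal(survivorship(fit, t = 2), exp(-1), tolerance = 1e-6)
})
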