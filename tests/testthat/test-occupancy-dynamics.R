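# Transition scoring, turnover rates with exact binomial CIs, the logit
# mixed models and the variance-partition effect sizes.

test_that("transition scoring matches hand enumeration of the rules", {
  ser <- make_series(list(
    s1 = c(`2005` = "occupied", `2006` = "unoccupied"),
    s2 = c(`2006` = "unknown", `2007` = "occupied"),
    s3 = c(`2005` = "occupied", `2006` = "unoccupied", `2007` = "unknown",
           `2008` = "occupied", `2009` = "occupied")))
  tr <- score_transitions(ser, colonization_start_year = 2006L)

  # s1: one possible cessation, realised
  t1 <- tr[tr$series_id == "s1", ]
  expect_equal(t1$type, "cessation")
  expect_equal(t1$year, 2006L)

  # s2: t-1 unknown, nothing scored
  expect_equal(nrow(tr[tr$series_id == "s2", ]), 0L)

  # s3: cessation in 2006, persistence in 2009; 2007 unknown blocks the
  # 2007 colonization denominator and 2008's t-1 is unknown
  t3 <- tr[tr$series_id == "s3", ]
  expect_equal(t3$type[t3$year == 2006], "cessation")
  expect_equal(t3$type[t3$year == 2009], "persistence")
  expect_equal(nrow(t3), 2L)
  expect_false(any(t3$type %in% c("colonization", "non_colonization")))
})

test_that("colonizations are only scored from the start year onwards", {
  ser <- make_series(list(
    s1 = c(`2005` = "unoccupied", `2006` = "occupied", `2007` = "unoccupied",
           `2008` = "occupied")))
  tr <- score_transitions(ser, colonization_start_year = 2008L)
  col <- tr[tr$type %in% c("colonization", "non_colonization"), ]
  expect_equal(col$year, 2008L)
  # the suppressed 2006 pair is not rescored as anything else
  expect_equal(sort(tr$year), c(2007L, 2008L))
})

test_that("empty and length-1 series contribute nothing", {
  empty <- make_records(character(0), integer(0), character(0))
  expect_equal(nrow(score_transitions(build_occupancy_series(empty))), 0L)
  ser <- make_series(list(s1 = c(`2005` = "occupied")))
  expect_equal(nrow(score_transitions(ser)), 0L)
})

test_that("conservation: events + non-events = possible events, per substrate", {
  cfg <- default_sim_config(seed = 11, monitoring_prob = 0.8)
  sim <- simulate_metapopulation(cfg)
  ser <- build_occupancy_series(sim$survey)
  tr <- score_transitions(ser)
  for (sub in unique(tr$substrate)) {
    ti <- tr[tr$substrate == sub, ]
    expect_equal(sum(ti$type == "cessation") + sum(ti$type == "persistence"),
                 sum(ti$type %in% c("cessation", "persistence")))
    expect_equal(sum(ti$type == "colonization") +
                   sum(ti$type == "non_colonization"),
                 sum(ti$type %in% c("colonization", "non_colonization")))
  }
})

test_that("adding an unknown year never increases possible-event counts", {
  base <- list(s1 = c(`2005` = "occupied", `2006` = "unoccupied",
                      `2007` = "occupied", `2008` = "occupied"))
  n_possible <- function(st) nrow(score_transitions(make_series(st)))
  full <- n_possible(base)
  for (yr in names(base$s1)) {
    st <- base
    st$s1[yr] <- "unknown"
    expect_lte(n_possible(st), full)
  }
})

test_that("turnover rates and Clopper-Pearson CIs match the binom.test oracle", {
  ser <- make_series(list(
    a1 = c(`2005` = "occupied", `2006` = "occupied"),
    a2 = c(`2005` = "occupied", `2006` = "occupied"),
    a3 = c(`2005` = "occupied", `2006` = "occupied", `2007` = "unoccupied"),
    a4 = c(`2005` = "occupied", `2006` = "unoccupied",
           `2007` = "unoccupied")))
  tr <- score_transitions(ser, colonization_start_year = 2006L)
  tv <- substrate_turnover_rates(tr, ser, min_records = 5L)
  # 7 occupied of 10 surveyed site-years
  expect_equal(tv$occupancy_mean, 0.7)
  expect_equal(tv$n_occupancy, 10L)
  oracle <- binom.test(7, 10)$conf.int
  expect_equal(c(tv$occupancy_lo, tv$occupancy_hi), as.numeric(oracle),
               tolerance = 1e-12)
  # 2 cessations (a3 2007, a4 2006) of 5 possible
  expect_equal(tv$n_possible_cessations, 5L)
  expect_equal(tv$cessation_rate, 0.4)
  oracle_c <- binom.test(2, 5)$conf.int
  expect_equal(c(tv$cessation_lo, tv$cessation_hi), as.numeric(oracle_c),
               tolerance = 1e-12)
  # colonization: only 1 possible (< min_records) -> absent, never 0/0
  expect_equal(tv$n_possible_colonizations, 1L)
  expect_true(is.na(tv$colonization_rate))
})

test_that("a zero-event cell gives rate 0 with CI lower bound 0", {
  expect_equal(clopper_pearson_ci(0, 5)[1], 0)
  expect_equal(clopper_pearson_ci(5, 5)[2], 1)
  oracle <- binom.test(0, 5)$conf.int
  expect_equal(clopper_pearson_ci(0, 5), as.numeric(oracle),
               tolerance = 1e-12)
})

test_that("binary GLMM recovers group logits on balanced synthetic data", {
  set.seed(42)
  n <- 500
  d <- data.frame(
    substrate = rep(c("cattail-marsh", "blackberry"), each = n),
    year = rep(2005:2009, length.out = 2 * n))
  p <- ifelse(d$substrate == "cattail-marsh", 0.5, 0.8)
  d$occupied <- as.numeric(runif(2 * n) < p)
  fit <- fit_binary_glmm(d, "occupied")
  est <- setNames(fit$fixed_effects$estimate, fit$fixed_effects$term)
  se <- setNames(fit$fixed_effects$se, fit$fixed_effects$term)
  # oracle: closed-form logits of the observed group frequencies
  p_cm <- mean(d$occupied[d$substrate == "cattail-marsh"])
  p_bb <- mean(d$occupied[d$substrate == "blackberry"])
  expect_lt(abs(est[["(Intercept)"]] - qlogis(p_cm)),
            2 * se[["(Intercept)"]])
  expect_lt(abs(est[["substrateblackberry"]] - (qlogis(p_bb) - qlogis(p_cm))),
            2 * se[["substrateblackberry"]])
  # and the design values (logit 0.5 = 0, logit 0.8 - logit 0.5 ~ 1.386)
  # are inside the same bands up to sampling error of the frequencies
  expect_lt(abs(qlogis(p_cm) - qlogis(0.5)), 3 * sqrt(1 / (0.25 * n)))
  expect_lt(abs(qlogis(p_bb) - qlogis(0.8)), 3 * sqrt(1 / (0.16 * n)))
  expect_true(fit$ranef_variance >= 0)
  expect_false(fit$separation)
})

test_that("single-substrate GLMM reduces to intercept = pooled logit", {
  set.seed(7)
  d <- data.frame(substrate = "cattail-marsh",
                  year = rep(2005:2009, each = 60))
  d$occupied <- as.numeric(runif(nrow(d)) < 0.6)
  fit <- fit_binary_glmm(d, "occupied")
  if (fit$ranef_variance < 1e-8) {
    expect_equal(unname(fit$fixed_effects$estimate[1]),
                 qlogis(mean(d$occupied)), tolerance = 1e-3)
  } else {
    expect_equal(unname(plogis(fit$fixed_effects$estimate[1])),
                 mean(d$occupied), tolerance = 0.1)
  }
})

test_that("complete separation is flagged with a warning", {
  set.seed(1)
  d <- data.frame(
    substrate = rep(c("cattail-marsh", "mustard"), each = 40),
    year = rep(2005:2008, 20))
  d$occupied <- ifelse(d$substrate == "mustard", 0,
                       as.numeric(runif(80) < 0.5))
  expect_warning(fit <- fit_binary_glmm(d, "occupied"), "separation")
  expect_true(fit$separation)
})

test_that("eta_squared reproduces published-scale arithmetic and bounds", {
  expect_equal(round(eta_squared(8.52, 109.55), 2), 0.07)
  expect_equal(round(eta_squared(2.93, 23.07), 2), 0.11)
  expect_equal(eta_squared(0, 5), 0)
  expect_equal(eta_squared(5, 0), 1)
  expect_error(eta_squared(0, 0), "undefined")
  expect_error(eta_squared(-1, 5), "non-negative")
  # strictly increasing in ss_effect for fixed ss_error
  ss <- seq(0, 10, by = 0.5)
  expect_true(all(diff(eta_squared(ss, 4)) > 0))
})

test_that("anova_partition satisfies the h2 identity and degenerate case", {
  set.seed(3)
  d <- data.frame(
    substrate = rep(c("cattail-marsh", "blackberry"), each = 100),
    year = rep(2005:2008, 50))
  d$occupied <- as.numeric(runif(200) < ifelse(d$substrate == "blackberry",
                                               0.9, 0.3))
  fit <- fit_binary_glmm(d, "occupied")
  a <- anova_partition(fit)
  err <- a$ss[a$term == "Error"]
  eff <- a[a$term != "Error", ]
  expect_equal(eff$eta_sq, eff$ss / (eff$ss + err))
  expect_true(all(a$ss >= 0))

  # one-factor balanced data with zero residual variance -> h2 = 1
  d2 <- data.frame(substrate = rep(c("cattail-marsh", "blackberry"),
                                   each = 50),
                   year = rep(2005:2006, 50))
  d2$occupied <- as.numeric(d2$substrate == "blackberry")
  suppressWarnings(fit2 <- fit_binary_glmm(d2, "occupied"))
  suppressWarnings(a2 <- anova_partition(fit2))  # perfect-fit F is degenerate
  expect_equal(a2$eta_sq[a2$term == "substrate"], 1)
})

test_that("occupancy-cessation correlation matches the definitional formula", {
  # perfectly decreasing line -> r = -1
  tv <- data.frame(substrate = letters[1:4],
                   occupancy_mean = c(0.2, 0.4, 0.6, 0.8),
                   cessation_rate = c(0.8, 0.6, 0.4, 0.2))
  cc <- correlate_occupancy_cessation(tv)
  expect_equal(cc$r, -1)

  set.seed(99)
  tv2 <- data.frame(substrate = letters[1:6],
                    occupancy_mean = runif(6),
                    cessation_rate = runif(6))
  cc2 <- correlate_occupancy_cessation(tv2)
  x <- tv2$cessation_rate; y <- tv2$occupancy_mean
  r_def <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cc2$r, r_def, tolerance = 1e-12)

  expect_error(correlate_occupancy_cessation(tv[1:2, ]), "at least 3")
})
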