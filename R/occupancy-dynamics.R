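# Scoring cessation-of-use and colonization events, per-substrate turnover
# rates with exact binomial CIs, the logit-link mixed models and their
# variance-partition effect sizes.

#' Score cessation and colonization events
#'
#' Walks every occupancy series year pair (t-1, t) and records the
#' transition events that the turnover analyses count:
#' \itemize{
#'   \item a site occupied in year t-1 and surveyed in year t is a
#'     *possible cessation*; the event is a `cessation` if the site was
#'     unoccupied in year t, otherwise a `persistence`;
#'   \item a site known unoccupied in year t-1 that was surveyed in year t
#'     (with `t >= colonization_start_year`) is a *possible colonization*;
#'     the event is a `colonization` if the site was occupied in year t,
#'     otherwise a `non_colonization`.
#' }
#' An unknown status at either end of the pair contributes nothing: this
#' "possible event" bookkeeping is what keeps incomplete monitoring from
#' biasing the rates.  A site-year pair can be a possible cessation or a
#' possible colonization, never both.
#'
#' @param series an `occupancy_series` data frame from
#'   [build_occupancy_series()].
#' @param colonization_start_year first year for which colonizations are
#'   scored (colonization needs a known-unoccupied prior year, which the
#'   first survey year cannot supply).
#' @return data.frame of class `"transition_table"` with columns
#'   `series_id`, `site_id`, `substrate`, `year` (the year t of the pair)
#'   and `type` in `cessation`, `persistence`, `colonization`,
#'   `non_colonization`.
#' @export
score_transitions <- function(series, colonization_start_year = 2006L) {
  stopifnot(inherits(series, "data.frame"))
  empty <- data.frame(series_id = character(), site_id = character(),
                      substrate = character(), year = integer(),
                      type = character(), stringsAsFactors = FALSE)
  class(empty) <- c("transition_table", "data.frame")
  if (nrow(series) == 0L) return(empty)

  ord <- order(series$series_id, series$year)
  s <- as.data.frame(series)[ord, , drop = FALSE]
  n <- nrow(s)
  same <- s$series_id[-1L] == s$series_id[-n] & s$year[-1L] == s$year[-n] + 1L
  prev <- s$status[-n]
  cur <- s$status[-1L]
  idx <- which(same & cur != "unknown" & prev != "unknown")
  if (length(idx) == 0L) return(empty)
  i2 <- idx + 1L  # row of year t
  type <- ifelse(prev[idx] == "occupied",
                 ifelse(cur[idx] == "unoccupied", "cessation", "persistence"),
                 ifelse(cur[idx] == "occupied", "colonization",
                        "non_colonization"))
  out <- data.frame(series_id = s$series_id[i2], site_id = s$site_id[i2],
                    substrate = s$substrate[i2], year = s$year[i2],
                    type = type, stringsAsFactors = FALSE)
  drop_col <- out$type %in% c("colonization", "non_colonization") &
    out$year < colonization_start_year
  out <- out[!drop_col, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("transition_table", "data.frame")
  out
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf_level confidence level.
#' @return numeric vector `c(lower, upper)`.
#' @export
clopper_pearson_ci <- function(x, n, conf_level = 0.95) {
  stopifnot(length(x) == 1L, length(n) == 1L, n >= 1, x >= 0, x <= n,
            conf_level > 0, conf_level < 1)
  alpha <- 1 - conf_level
  lo <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(lo, hi)
}

#' Per-substrate occupancy and turnover rates
#'
#' Summarizes an occupancy series set and its scored transitions into
#' per-substrate rates:
#' \itemize{
#'   \item occupancy: occupied site-years / surveyed site-years;
#'   \item cessation rate: cessations / possible cessations;
#'   \item colonization rate: colonizations / possible colonizations.
#' }
#' Each rate is reported only when its denominator reaches `min_records`
#' (small cells give unreliable estimates); otherwise it and its interval
#' are `NA`.  Confidence intervals are exact binomial (Clopper-Pearson),
#' appropriate because several substrate cells have fewer than 10 events.
#'
#' @param transitions a `transition_table` from [score_transitions()].
#' @param series the `occupancy_series` the transitions came from.
#' @param min_records minimum denominator for a rate to be reported.
#' @param conf_level confidence level for the binomial intervals.
#' @return data.frame of class `"substrate_turnover"`, one row per
#'   substrate, with the three rates, their intervals and denominators.
#' @export
substrate_turnover_rates <- function(transitions, series, min_records = 5L,
                                     conf_level = 0.95) {
  stopifnot(inherits(series, "data.frame"))
  s <- as.data.frame(series)
  s <- s[s$status != "unknown" & !is.na(s$substrate), , drop = FALSE]
  tr <- as.data.frame(transitions)
  substrates <- sort(unique(c(s$substrate, tr$substrate)))

  one <- function(sub) {
    si <- s[s$substrate == sub, , drop = FALSE]
    ti <- tr[tr$substrate == sub, , drop = FALSE]
    n_occ <- nrow(si)
    x_occ <- sum(si$status == "occupied")
    n_cess <- sum(ti$type %in% c("cessation", "persistence"))
    x_cess <- sum(ti$type == "cessation")
    n_col <- sum(ti$type %in% c("colonization", "non_colonization"))
    x_col <- sum(ti$type == "colonization")
    rate <- function(x, n) {
      if (n >= min_records) {
        ci <- clopper_pearson_ci(x, n, conf_level)
        c(x / n, ci)
      } else c(NA_real_, NA_real_, NA_real_)
    }
    occ <- rate(x_occ, n_occ); ces <- rate(x_cess, n_cess)
    col <- rate(x_col, n_col)
    data.frame(substrate = sub,
               occupancy_mean = occ[1], occupancy_lo = occ[2],
               occupancy_hi = occ[3], n_occupancy = n_occ,
               cessation_rate = ces[1], cessation_lo = ces[2],
               cessation_hi = ces[3], n_possible_cessations = n_cess,
               colonization_rate = col[1], colonization_lo = col[2],
               colonization_hi = col[3], n_possible_colonizations = n_col,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(substrates, one))
  rownames(out) <- NULL
  class(out) <- c("substrate_turnover", "data.frame")
  out
}

.aicc <- function(fit) {
  ll <- logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  as.numeric(-2 * ll + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1))
}

.relevel_substrate <- function(x, reference) {
  f <- factor(x)
  if (!reference %in% levels(f)) {
    stop("reference substrate '", reference, "' not present in the data")
  }
  relevel(f, ref = reference)
}

#' Fit a binomial (logit-link) mixed model for occupancy or turnover
#'
#' Fits the logistic mixed model used for occupancy, cessation and
#' colonization analyses: a binary site-year outcome with substrate as a
#' treatment-coded fixed effect (reference level `reference_substrate`), an
#' optional fixed year effect, and a random intercept for year to absorb the
#' repeated-measures structure.  The occupancy analysis uses both the fixed
#' and the random year term; the cessation and colonization analyses use
#' substrate only as fixed (year variation is weak there and only substrate
#' improves the information criterion).
#'
#' The estimation backend is [lme4::glmer()]; this function's contract is
#' the model specification, coding and reporting.  Complete separation (a
#' substrate with all-0 or all-1 outcomes) yields a warning and a
#' `separation` flag on the result, since its Wald standard errors are
#' meaningless; non-convergence is an error, never a silent fallback.
#'
#' @param data data.frame with the outcome column plus `substrate` and
#'   `year`.
#' @param outcome name of the binary (0/1 or logical) outcome column.
#' @param include_year_fixed add year (as a factor) to the fixed effects.
#' @param reference_substrate treatment-coding reference level.
#' @param reference_year reference level for the fixed year factor (defaults
#'   to the earliest year).
#' @return object of class `"habv_glmm"`: a list with `fixed_effects`
#'   (term, estimate, se, z, p on the logit scale), `ranef_variance`,
#'   `ranef_sd`, `aicc`, `n_obs`, `n_groups`, `separation`, the fitted
#'   `model` and the analysis `data`.
#' @export
fit_binary_glmm <- function(data, outcome,
                            include_year_fixed = FALSE,
                            reference_substrate = "cattail-marsh",
                            reference_year = NULL) {
  stopifnot(is.data.frame(data), outcome %in% names(data),
            all(c("substrate", "year") %in% names(data)))
  d <- data.frame(y = as.numeric(data[[outcome]]),
                  substrate = data$substrate, year = data$year)
  d <- d[complete.cases(d), , drop = FALSE]
  if (!all(d$y %in% c(0, 1))) stop("outcome must be binary (0/1)")
  d$substrate <- .relevel_substrate(d$substrate, reference_substrate)
  d$year_f <- factor(d$year)
  if (!is.null(reference_year)) {
    if (!as.character(reference_year) %in% levels(d$year_f)) {
      stop("reference year ", reference_year, " not present in the data")
    }
    d$year_f <- relevel(d$year_f, ref = as.character(reference_year))
  }

  rhs <- if (nlevels(d$substrate) >= 2L) "substrate" else "1"
  if (include_year_fixed && nlevels(d$year_f) >= 2L) {
    rhs <- paste(rhs, "+ year_f")
  }
  form <- as.formula(paste("y ~", rhs, "+ (1 | year_f)"))
  fit <- lme4::glmer(form, data = d, family = binomial(link = "logit"),
                     control = lme4::glmerControl(calc.derivs = TRUE))
  conv <- fit@optinfo$conv$opt
  if (!is.null(conv) && conv != 0) {
    stop("GLMM optimizer did not converge (code ", conv, ")")
  }
  cf <- summary(fit)$coefficients
  fixed <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                      z = cf[, 3], p = cf[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  re_var <- vc$vcov[1]
  separation <- any(abs(fixed$estimate) > 10 | fixed$se > 50)
  if (separation) {
    warning("possible complete separation: at least one substrate is all-0 ",
            "or all-1; Wald standard errors are inflated")
  }
  structure(list(
    fixed_effects = fixed,
    ranef_variance = re_var, ranef_sd = sqrt(re_var),
    aicc = .aicc(fit), n_obs = nrow(d),
    n_groups = nlevels(droplevels(d$year_f)),
    separation = separation,
    formula = deparse(form), outcome = outcome,
    reference_substrate = reference_substrate,
    include_year_fixed = include_year_fixed,
    model = fit, data = d
  ), class = "habv_glmm")
}

#' @export
print.habv_glmm <- function(x, ...) {
  cat("Binomial mixed model (logit link):", x$formula, "\n")
  cat(sprintf("  %d observations in %d year groups; AICc = %.2f\n",
              x$n_obs, x$n_groups, x$aicc))
  cat(sprintf("  random year intercept: variance %.5f (sd %.5f)\n",
              x$ranef_variance, x$ranef_sd))
  if (x$separation) cat("  WARNING: possible complete separation\n")
  print(x$fixed_effects, digits = 3)
  invisible(x)
}

#' Partial eta-squared from sums of squares
#'
#' The variance-partition effect size h^2 = SS_effect / (SS_effect +
#' SS_error): the proportion of variance attributed to a fixed effect.
#'
#' @param ss_effect effect sum of squares (>= 0).
#' @param ss_error error sum of squares (>= 0).
#' @return proportion in \[0, 1\] (vectorized over `ss_effect`).
#' @export
eta_squared <- function(ss_effect, ss_error) {
  if (any(ss_effect < 0) || any(ss_error < 0)) {
    stop("sums of squares must be non-negative")
  }
  if (any(ss_effect + ss_error == 0)) {
    stop("eta-squared is undefined when both sums of squares are zero")
  }
  ss_effect / (ss_effect + ss_error)
}

#' ANOVA-style variance partition for a mixed-model analysis
#'
#' Companion effect-size table for [fit_binary_glmm()] and [fit_rs_lmm()]:
#' a sequential sum-of-squares partition of the observed response over the
#' model's fixed-effect terms, with partial eta-squared per effect.  The
#' partition is computed on the response scale (for binary outcomes, the
#' 0/1 values), matching how ANOVA-style summaries of these models are
#' conventionally reported; the mean squared error of a binary outcome is
#' then approximately p(1-p).
#'
#' @param fit a `"habv_glmm"` or `"habv_lmm"` object.
#' @return data.frame of class `"habv_anova"` with one row per fixed effect
#'   (`term`, `ss`, `df`, `ms`, `f`, `p`, `eta_sq`) plus an `Error` row.
#' @export
anova_partition <- function(fit) {
  stopifnot(inherits(fit, c("habv_glmm", "habv_lmm")))
  d <- fit$data
  rhs <- c()
  if ("substrate" %in% names(d) && nlevels(factor(d$substrate)) >= 2L) {
    rhs <- c(rhs, "substrate")
  }
  if (isTRUE(fit$include_year_fixed) && nlevels(factor(d$year_f)) >= 2L) {
    rhs <- c(rhs, "year_f")
  }
  if (isTRUE(fit$include_observer) && nlevels(factor(d$observer)) >= 2L) {
    rhs <- c(rhs, "observer")
  }
  if (length(rhs) == 0L) rhs <- "1"
  lm_fit <- lm(as.formula(paste("y ~", paste(rhs, collapse = " + "))),
               data = d)
  a <- anova(lm_fit)
  terms <- rownames(a)
  err <- a["Residuals", "Sum Sq"]
  eff <- terms[terms != "Residuals"]
  out <- data.frame(
    term = sub("^year_f$", "year", eff),
    ss = a[eff, "Sum Sq"], df = a[eff, "Df"], ms = a[eff, "Mean Sq"],
    f = a[eff, "F value"], p = a[eff, "Pr(>F)"],
    eta_sq = vapply(a[eff, "Sum Sq"], eta_squared, numeric(1),
                    ss_error = err),
    stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(
    term = "Error", ss = err, df = a["Residuals", "Df"],
    ms = a["Residuals", "Mean Sq"], f = NA_real_, p = NA_real_,
    eta_sq = NA_real_, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("habv_anova", "data.frame")
  out
}

#' Correlation between occupancy and cessation rate across substrates
#'
#' Pearson correlation of the per-substrate cessation rate against mean
#' occupancy, with a one-tailed p-value for a negative association (the
#' directional hypothesis: substrates that empty out more often are less
#' occupied on average).
#'
#' @param turnover a `substrate_turnover` data frame.
#' @return list with `r`, `p_one_tailed` and `n` (substrates used).
#' @export
correlate_occupancy_cessation <- function(turnover) {
  t <- as.data.frame(turnover)
  ok <- !is.na(t$occupancy_mean) & !is.na(t$cessation_rate)
  if (sum(ok) < 3L) {
    stop("need at least 3 substrates with both occupancy and cessation rate")
  }
  ct <- cor.test(t$cessation_rate[ok], t$occupancy_mean[ok],
                 alternative = "less", method = "pearson")
  list(r = unname(ct$estimate), p_one_tailed = ct$p.value, n = sum(ok))
}
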