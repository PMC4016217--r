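# Reproductive-success estimators (RS, RSS, proportion of successful
# nests), the bird<->nest conversion constants, per-substrate summaries and
# the pooled mixed model.

#' Convert breeding-bird counts to nest counts
#'
#' One male breeds on average with two females, so each two nests have
#' three birds associated with them: nests = birds * 2/3.  Exact, no
#' rounding.
#'
#' @param n_breeding_birds count(s) >= 0.
#' @return estimated nests (real-valued).
#' @export
nests_from_birds <- function(n_breeding_birds) {
  if (any(is.na(n_breeding_birds)) || any(n_breeding_birds < 0)) {
    stop("n_breeding_birds must be non-negative")
  }
  n_breeding_birds * (2 / 3)
}

#' Convert nest counts to breeding-bird counts
#'
#' Inverse of [nests_from_birds()]: birds = nests * 1.5.
#'
#' @param n_nests count(s) >= 0.
#' @return estimated breeding birds (real-valued).
#' @export
birds_from_nests <- function(n_nests) {
  if (any(is.na(n_nests)) || any(n_nests < 0)) {
    stop("n_nests must be non-negative")
  }
  n_nests * 1.5
}

#' Reproductive success (chicks per nest) from colony-level counts
#'
#' RS is the number of young fledged divided by the estimated number of
#' nests constructed, with nests estimated from the breeding-bird count via
#' [nests_from_birds()].
#'
#' @param n_breeding_birds breeding-bird count(s) > 0.
#' @param n_fledglings fledgling count(s) >= 0.
#' @return RS, chicks per nest.
#' @export
reproductive_success <- function(n_breeding_birds, n_fledglings) {
  if (any(is.na(n_breeding_birds)) || any(n_breeding_birds <= 0)) {
    stop("n_breeding_birds must be positive: RS is undefined for an empty colony")
  }
  if (any(is.na(n_fledglings)) || any(n_fledglings < 0)) {
    stop("n_fledglings must be non-negative")
  }
  n_fledglings / nests_from_birds(n_breeding_birds)
}

#' Nest-sample success metrics
#'
#' From a sample of per-nest chick counts (chicks alive at roughly 7-9 days
#' after first hatch), computes:
#' \itemize{
#'   \item `prop_successful`: fraction of nests with at least one chick;
#'   \item `rss`: mean chicks among successful nests only (`NA` if none
#'     succeeded);
#'   \item `rs`: mean chicks over all nests, zeros included.
#' }
#' These satisfy `rs = rss * prop_successful` exactly -- the algebraic
#' decomposition of overall success into failure rate and conditional
#' brood size.
#'
#' @param nest_chicks non-empty numeric vector of per-nest chick counts.
#' @return list with `rss`, `prop_successful`, `rs`, `n_nests`.
#' @export
success_metrics <- function(nest_chicks) {
  if (length(nest_chicks) == 0L || any(is.na(nest_chicks))) {
    stop("nest_chicks must be a non-empty vector without NA")
  }
  if (any(nest_chicks < 0)) stop("chick counts must be non-negative")
  succ <- nest_chicks > 0
  list(rss = if (any(succ)) mean(nest_chicks[succ]) else NA_real_,
       prop_successful = mean(succ),
       rs = mean(nest_chicks),
       n_nests = length(nest_chicks))
}

#' Per-substrate reproductive-success summary
#'
#' Raw per-substrate means of RS, RSS and proportion of successful nests
#' over reproduction records, with standard deviations and standard errors,
#' keeping only substrates with at least `min_records` RS values (smaller
#' samples give unreliable estimates).  The proportional SD of RS reported
#' here (`rs_sd / rs_mean`) is the `s2` ingredient of the habitat-value
#' index.
#'
#' @param records data.frame with `substrate`, `rs` and optionally `rss`,
#'   `prop_successful` columns (e.g. the reproduction output of
#'   [simulate_metapopulation()], or records derived from survey tables).
#' @param min_records minimum number of RS values per substrate.
#' @return data.frame of class `"substrate_rs"` with per-substrate columns
#'   `rs_mean`, `rs_sd`, `rs_se`, `rss_mean`, `rss_se`,
#'   `prop_successful_mean`, `n_records`.
#' @export
substrate_rs_summary <- function(records, min_records = 5L) {
  r <- as.data.frame(records)
  stopifnot(all(c("substrate", "rs") %in% names(r)))
  r <- r[!is.na(r$rs) & !is.na(r$substrate), , drop = FALSE]
  if (!"rss" %in% names(r)) r$rss <- NA_real_
  if (!"prop_successful" %in% names(r)) r$prop_successful <- NA_real_
  out <- lapply(split(r, r$substrate), function(g) {
    n <- nrow(g)
    if (n < min_records) return(NULL)
    rss <- g$rss[!is.na(g$rss)]
    data.frame(substrate = g$substrate[1L],
               rs_mean = mean(g$rs), rs_sd = sd(g$rs),
               rs_se = sd(g$rs) / sqrt(n),
               rss_mean = if (length(rss)) mean(rss) else NA_real_,
               rss_se = if (length(rss) > 1L) sd(rss) / sqrt(length(rss))
                        else NA_real_,
               prop_successful_mean = mean(g$prop_successful, na.rm = TRUE),
               n_records = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) stop("no substrate reaches min_records = ", min_records)
  rownames(out) <- NULL
  class(out) <- c("substrate_rs", "data.frame")
  out
}

#' Linear mixed model for reproductive success across substrates
#'
#' Fits the pooled reproduction model: RS (or RSS) on its natural scale
#' with substrate as a treatment-coded fixed effect and colony identity as
#' a random intercept to absorb repeated measurements of the same colony.
#' Observer identity and year are assessed as additional fixed effects and
#' kept only if they lower the small-sample-corrected information criterion
#' (AICc); with the data that motivated this package both are dropped, but
#' the model re-tests rather than assumes that.  Substrates with fewer than
#' `min_records` responses are excluded before fitting.
#'
#' A singular random-effect fit (variance estimated at zero) is reported
#' with a warning, not an error: one record per colony legitimately gives a
#' zero colony variance.
#'
#' @param records data.frame with the response column plus `substrate`,
#'   `site_id` (colony identity) and optionally `year`, `observer`.
#' @param response `"rs"` or `"rss"`.
#' @param min_records minimum responses per substrate.
#' @param reference treatment-coding reference substrate.
#' @return object of class `"habv_lmm"`: list with `fixed_effects` (term,
#'   estimate, se, t), `ranef_variance`, `ranef_sd`, `aicc`, `n_obs`,
#'   `n_groups`, `covariates_tested` (AICc with/without observer and year),
#'   the fitted `model`, analysis `data`, and an `anova` variance-partition
#'   table from [anova_partition()].
#' @export
fit_rs_lmm <- function(records, response = c("rs", "rss"), min_records = 5L,
                       reference = "blackberry") {
  response <- match.arg(response)
  r <- as.data.frame(records)
  stopifnot(all(c("substrate", "site_id") %in% names(r)),
            response %in% names(r))
  d <- data.frame(y = r[[response]], substrate = r$substrate,
                  colony = r$site_id,
                  year = if ("year" %in% names(r)) r$year else NA,
                  observer = if ("observer" %in% names(r)) r$observer else NA,
                  stringsAsFactors = FALSE)
  d <- d[!is.na(d$y) & !is.na(d$substrate), , drop = FALSE]
  keep <- names(which(table(d$substrate) >= min_records))
  d <- d[d$substrate %in% keep, , drop = FALSE]
  if (length(keep) < 2L) {
    stop("need at least 2 substrates with >= ", min_records, " records")
  }
  d$substrate <- .relevel_substrate(d$substrate, reference)
  d$colony <- factor(d$colony)

  # one record per colony is legitimate (variance then estimated at 0), so
  # relax lme4's levels-vs-observations guard
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.rankZ = "ignore",
                            check.nobs.vs.nRE = "ignore")
  fit_one <- function(rhs) {
    form <- as.formula(paste("y ~", rhs, "+ (1 | colony)"))
    suppressMessages(lme4::lmer(form, data = d, REML = FALSE,
                                control = ctrl))
  }
  base <- fit_one("substrate")
  tested <- data.frame(term = "none", aicc = .aicc(base), kept = TRUE,
                       stringsAsFactors = FALSE)
  include_observer <- FALSE
  if (!all(is.na(d$observer)) && length(unique(na.omit(d$observer))) > 1L) {
    cand <- fit_one("substrate + observer")
    keep_obs <- .aicc(cand) < .aicc(base)
    tested <- rbind(tested, data.frame(term = "observer",
                                       aicc = .aicc(cand), kept = keep_obs))
    if (keep_obs) {
      base <- cand
      include_observer <- TRUE
    }
  }
  include_year <- FALSE
  if (!all(is.na(d$year)) && length(unique(na.omit(d$year))) > 1L) {
    d$year_f <- factor(d$year)
    rhs <- if (include_observer) "substrate + observer + year_f" else
      "substrate + year_f"
    cand <- fit_one(rhs)
    keep_year <- .aicc(cand) < .aicc(base)
    tested <- rbind(tested, data.frame(term = "year",
                                       aicc = .aicc(cand), kept = keep_year))
    if (keep_year) {
      base <- cand
      include_year <- TRUE
    }
  }

  if (lme4::isSingular(base)) {
    warning("singular random-effect fit: colony variance estimated at zero")
  }
  cf <- summary(base)$coefficients
  fixed <- data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
                      t = cf[, 3], row.names = NULL, stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(base))
  re_var <- vc$vcov[vc$grp == "colony"]
  res <- structure(list(
    fixed_effects = fixed,
    ranef_variance = re_var, ranef_sd = sqrt(re_var),
    aicc = .aicc(base), n_obs = nrow(d),
    n_groups = nlevels(droplevels(d$colony)),
    covariates_tested = tested,
    response = response, reference = reference,
    include_year_fixed = include_year, include_observer = include_observer,
    model = base, data = d
  ), class = "habv_lmm")
  res$anova <- anova_partition(res)
  res
}

#' @export
print.habv_lmm <- function(x, ...) {
  cat(sprintf("Linear mixed model for %s: %d observations in %d colonies; AICc = %.2f\n",
              toupper(x$response), x$n_obs, x$n_groups, x$aicc))
  cat(sprintf("  colony random intercept: variance %.4f (sd %.4f)\n",
              x$ranef_variance, x$ranef_sd))
  print(x$fixed_effects, digits = 3)
  invisible(x)
}
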