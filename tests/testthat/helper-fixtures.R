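# Shared fixtures built in code: tiny record tables and occupancy series
# used across test files.

# A minimal survey_records data.frame from parallel vectors.
make_records <- function(site_id, year, status,
                         substrate = "cattail-marsh",
                         n_breeding_birds = NA_real_,
                         n_fledglings = NA_real_,
                         dataset_tag = "portal") {
  n <- length(site_id)
  out <- data.frame(site_id = site_id, year = as.integer(year),
                    substrate = rep_len(substrate, n),
                    status = status,
                    n_breeding_birds = rep_len(n_breeding_birds, n),
                    n_nests = rep_len(NA_real_, n),
                    n_fledglings = rep_len(n_fledglings, n),
                    rss = rep_len(NA_real_, n),
                    prop_successful = rep_len(NA_real_, n),
                    dataset_tag = rep_len(dataset_tag, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("survey_records", "data.frame")
  out
}

# An occupancy_series data.frame directly from a year->status map for one
# or more sites; statuses is a named list site_id -> character vector with
# names as years.
make_series <- function(statuses, substrate = "cattail-marsh") {
  out <- do.call(rbind, lapply(names(statuses), function(sid) {
    st <- statuses[[sid]]
    data.frame(series_id = sid, site_id = sid,
               substrate = substrate,
               year = as.integer(names(st)), status = unname(st),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("occupancy_series", "data.frame")
  out
}

# Simulated spells with known Weibull AFT parameters under independent
# right-censoring: censoring times follow the same Weibull shifted in
# location so that P(censored) = prob_censor exactly (the location
# difference of two minimum-extreme-value variates is logistic).
simulate_weibull_spells <- function(n, mu, sigma, prob_censor = 0.3,
                                    substrate = "cattail-marsh",
                                    seed = 1) {
  set.seed(seed)
  t_true <- exp(mu + sigma * log(rweibull(n, 1, 1)))  # mu + sigma*W
  if (prob_censor > 0) {
    delta <- sigma * log((1 - prob_censor) / prob_censor)
    c_time <- exp(mu + delta + sigma * log(rweibull(n, 1, 1)))
  } else {
    c_time <- rep(Inf, n)
  }
  cens <- c_time < t_true
  obs <- pmin(t_true, c_time)
  data.frame(series_id = sprintf("s%04d", seq_len(n)),
             site_id = sprintf("s%04d", seq_len(n)),
             substrate = rep_len(substrate, n),
             start_year = 2005L, duration = obs,
             left_censored = FALSE, right_censored = cens,
             event = !cens, stringsAsFactors = FALSE)
}

# Independent dense grid-search maximizer of the censored Weibull AFT
# log-likelihood for an intercept-only model; restates the likelihood from
# its definition (density for events, survivor for censored) without using
# package internals.
grid_search_weibull <- function(duration, event, mu_range, sigma_range,
                                n_grid = 201, n_refine = 2) {
  logt <- log(duration)
  scan <- function(mu_lo, mu_hi, sig_lo, sig_hi) {
    mu_grid <- seq(mu_lo, mu_hi, length.out = n_grid)
    sig_grid <- seq(sig_lo, sig_hi, length.out = n_grid)
    best <- list(ll = -Inf, mu = NA, sigma = NA)
    for (sig in sig_grid) {
      z <- outer(logt, mu_grid, function(lt, m) (lt - m) / sig)
      ll_obs <- sweep(z - exp(z), 1, log(sig) + logt, "-")
      ll_cen <- -exp(z)
      ll <- colSums(ifelse(matrix(event, nrow(z), ncol(z)), ll_obs, ll_cen))
      k <- which.max(ll)
      if (ll[k] > best$ll) best <- list(ll = ll[k], mu = mu_grid[k],
                                        sigma = sig)
    }
    best
  }
  best <- scan(mu_range[1], mu_range[2], sigma_range[1], sigma_range[2])
  dmu <- diff(mu_range) / (n_grid - 1)
  dsig <- diff(sigma_range) / (n_grid - 1)
  for (r in seq_len(n_refine)) {   # zoom on the incumbent cell
    best <- scan(best$mu - 2 * dmu, best$mu + 2 * dmu,
                 max(best$sigma - 2 * dsig, 1e-3), best$sigma + 2 * dsig)
    dmu <- 4 * dmu / (n_grid - 1)
    dsig <- 4 * dsig / (n_grid - 1)
  }
  best
}
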