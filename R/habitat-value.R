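# The headline index: predicted chick production per average colony and
# per substrate, its propagated standard deviation, the occupancy-adjusted
# time-averaged output, and decadal frequency/size summaries.

#' Predicted chicks per colony of average size
#'
#' `x = RS * nests`, where the nest count of an average colony is derived
#' from its bird count via [nests_from_birds()] because RS is defined per
#' nest while colony sizes are counted in birds.  The conversion can be
#' switched off (`bird_to_nest = FALSE`) to treat RS as per-bird, for
#' sensitivity analysis.
#'
#' @param rs_mean mean chicks per nest (>= 0).
#' @param mean_colony_birds mean colony size in birds (>= 0).
#' @param bird_to_nest apply the 2/3 bird-to-nest conversion.
#' @return predicted chicks per colony.
#' @export
chicks_per_colony <- function(rs_mean, mean_colony_birds,
                              bird_to_nest = TRUE) {
  if (any(rs_mean < 0) || any(mean_colony_birds < 0)) {
    stop("rs_mean and mean_colony_birds must be non-negative")
  }
  units <- if (bird_to_nest) nests_from_birds(mean_colony_birds) else
    mean_colony_birds
  rs_mean * units
}

#' Propagated standard deviation of predicted chick production
#'
#' First-order (delta-method) standard deviation of a product of two
#' independent estimates expressed through their coefficients of
#' variation: `sd = x * sqrt(s1^2 + s2^2)`, where `s1` is the proportional
#' SD of colony size and `s2` the proportional SD of reproductive success.
#'
#' @param x predicted chicks per colony (>= 0).
#' @param s1 proportional SD (SD/mean) of colony size (>= 0).
#' @param s2 proportional SD of RS (>= 0).
#' @return standard deviation in chicks.
#' @export
propagate_sd <- function(x, s1, s2) {
  if (any(x < 0) || any(s1 < 0) || any(s2 < 0)) {
    stop("x, s1 and s2 must be non-negative")
  }
  x * sqrt(s1^2 + s2^2)
}

#' Occupancy-adjusted reproductive output
#'
#' Multiplies predicted chick production per colony by the fraction of
#' years a site of that substrate is occupied, giving the time-averaged
#' expected chicks per site per year -- the habitat-value index.
#'
#' @param x predicted chicks per colony.
#' @param occupancy proportion of site-years occupied, in \[0, 1\].
#' @return chicks per site per year.
#' @export
occupancy_adjusted_output <- function(x, occupancy) {
  if (any(occupancy < 0 | occupancy > 1)) {
    stop("occupancy must lie in [0, 1]")
  }
  x * occupancy
}

.decade_label <- function(year) {
  ifelse(year < 1990, "1980-1989",
         ifelse(year < 2000, "1990-1999",
                ifelse(year < 2010, "2000-2009", "2010-11")))
}

#' Decadal substrate frequencies and colony sizes
#'
#' Summarizes statewide colony records per decade: the proportion of
#' records in each substrate and the mean log colony size (ln birds) with
#' its standard error.  Colony sizes span orders of magnitude, so the log
#' scale is the natural one for averaging; for the recent window (default
#' 2000-2011) both the arithmetic mean of birds and the back-transformed
#' mean of ln(birds) (geometric mean) are reported, clearly labelled,
#' since they answer different questions.  Records with zero or missing
#' bird counts are excluded before taking logs and counted.
#'
#' @param records data.frame with `year`, `substrate`, `n_breeding_birds`
#'   (a statewide `survey_records` table works directly).
#' @param recent_window inclusive year range for the recent size summary.
#' @return list of class `"decadal_summary"`: `decades` (decade, substrate,
#'   n_records, proportion, mean_log_size, se_log_size), `recent`
#'   (substrate, n, mean_birds, sd_birds, geom_mean_birds, mean_log,
#'   se_log) and `n_excluded`.
#' @export
decadal_summary <- function(records, recent_window = c(2000L, 2011L)) {
  r <- as.data.frame(records)
  stopifnot(all(c("year", "substrate", "n_breeding_birds") %in% names(r)))
  bad <- is.na(r$n_breeding_birds) | r$n_breeding_birds <= 0 |
    is.na(r$substrate)
  n_excluded <- sum(bad)
  r <- r[!bad, , drop = FALSE]
  if (nrow(r) == 0L) stop("no usable records (all sizes missing or zero)")
  r$decade <- .decade_label(r$year)
  r$log_size <- log(r$n_breeding_birds)

  decades <- do.call(rbind, lapply(split(r, r$decade), function(g) {
    do.call(rbind, lapply(split(g, g$substrate), function(h) {
      data.frame(decade = g$decade[1L], substrate = h$substrate[1L],
                 n_records = nrow(h), proportion = nrow(h) / nrow(g),
                 mean_log_size = mean(h$log_size),
                 se_log_size = if (nrow(h) > 1L)
                   sd(h$log_size) / sqrt(nrow(h)) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(decades) <- NULL

  rec <- r[r$year >= recent_window[1] & r$year <= recent_window[2], ,
           drop = FALSE]
  recent <- do.call(rbind, lapply(split(rec, rec$substrate), function(h) {
    data.frame(substrate = h$substrate[1L], n = nrow(h),
               mean_birds = mean(h$n_breeding_birds),
               sd_birds = if (nrow(h) > 1L) sd(h$n_breeding_birds)
                          else NA_real_,
               geom_mean_birds = exp(mean(h$log_size)),
               mean_log = mean(h$log_size),
               se_log = if (nrow(h) > 1L) sd(h$log_size) / sqrt(nrow(h))
                        else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(recent) <- NULL

  structure(list(decades = decades, recent = recent,
                 n_excluded = n_excluded, recent_window = recent_window),
            class = "decadal_summary")
}

#' @export
print.decadal_summary <- function(x, ...) {
  cat("Decadal substrate summary (", x$n_excluded,
      " zero/missing-size records excluded)\n", sep = "")
  print(x$decades, digits = 3)
  cat(sprintf("Recent (%d-%d) colony sizes:\n",
              x$recent_window[1], x$recent_window[2]))
  print(x$recent, digits = 4)
  invisible(x)
}

#' Habitat-value table: time-averaged reproductive output per substrate
#'
#' Composes the index per substrate from its three ingredients:
#' \enumerate{
#'   \item predicted chicks per average colony,
#'     `x = rs_mean * (2/3) * mean_birds` ([chicks_per_colony()]);
#'   \item its propagated SD, `x * sqrt(s1^2 + s2^2)` ([propagate_sd()]),
#'     with `s1` the proportional SD of colony size and `s2` that of RS;
#'   \item the occupancy adjustment, `x * occupancy`
#'     ([occupancy_adjusted_output()]).
#' }
#' Substrates missing any ingredient (no RS summary, no size summary, or no
#' occupancy estimate) are omitted with a message.  RS ingredients are the
#' raw per-substrate means; sizes are arithmetic means of recent colony
#' sizes; occupancy is the pooled site-year proportion per substrate.
#'
#' @param rs_summary a `substrate_rs` table ([substrate_rs_summary()]).
#' @param size_summary the `recent` element of a [decadal_summary()] (or
#'   any data frame with `substrate`, `mean_birds`, `sd_birds`).
#' @param turnover a `substrate_turnover` table
#'   ([substrate_turnover_rates()]).
#' @param bird_to_nest apply the 2/3 bird-to-nest conversion inside the
#'   chick prediction.
#' @return data.frame of class `"habitat_value"`, one row per substrate:
#'   `mean_colony_birds`, `mean_nests`, `rs_mean`, `chicks_per_colony`,
#'   `s1`, `s2`, `chicks_sd`, `occupancy`, `chicks_per_site_year`, ordered
#'   by decreasing `chicks_per_site_year`.
#' @export
habitat_value_table <- function(rs_summary, size_summary, turnover,
                                bird_to_nest = TRUE) {
  rs <- as.data.frame(rs_summary)
  sz <- as.data.frame(size_summary)
  if (inherits(size_summary, "decadal_summary")) sz <- size_summary$recent
  tv <- as.data.frame(turnover)
  stopifnot("substrate" %in% names(rs), "substrate" %in% names(sz),
            "substrate" %in% names(tv))

  all_subs <- unique(c(rs$substrate, sz$substrate, tv$substrate))
  subs <- Reduce(intersect, list(rs$substrate, sz$substrate,
                                 tv$substrate[!is.na(tv$occupancy_mean)]))
  omitted <- setdiff(all_subs, subs)
  if (length(omitted) > 0L) {
    message("omitting substrate(s) with missing ingredients: ",
            paste(sort(omitted), collapse = ", "))
  }
  if (length(subs) == 0L) {
    stop("no substrate has all three ingredients (RS, size, occupancy)")
  }
  subs <- sort(subs)
  rs <- rs[match(subs, rs$substrate), , drop = FALSE]
  sz <- sz[match(subs, sz$substrate), , drop = FALSE]
  tv <- tv[match(subs, tv$substrate), , drop = FALSE]

  x <- chicks_per_colony(rs$rs_mean, sz$mean_birds, bird_to_nest)
  s1 <- ifelse(is.na(sz$sd_birds) | sz$mean_birds == 0, 0,
               sz$sd_birds / sz$mean_birds)
  s2 <- ifelse(is.na(rs$rs_sd) | rs$rs_mean == 0, 0, rs$rs_sd / rs$rs_mean)
  out <- data.frame(
    substrate = subs,
    mean_colony_birds = sz$mean_birds,
    mean_nests = nests_from_birds(sz$mean_birds),
    rs_mean = rs$rs_mean,
    chicks_per_colony = x,
    s1 = s1, s2 = s2,
    chicks_sd = propagate_sd(x, s1, s2),
    occupancy = tv$occupancy_mean,
    chicks_per_site_year = occupancy_adjusted_output(x, tv$occupancy_mean),
    stringsAsFactors = FALSE)
  out <- out[order(-out$chicks_per_site_year), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("habitat_value", "data.frame")
  out
}
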