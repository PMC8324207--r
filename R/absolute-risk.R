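# Absolute risk projection: attributable-risk calibration of baseline
# hazards and cause-specific cumulative incidence under competing
# mortality with piecewise-constant hazards.

#' Age-banded hazard table
#'
#' Holds baseline incidence and competing (non-colorectal) mortality
#' hazards over contiguous half-open age bands `[start, end)`. Internal
#' unit is events per person-year; registry tables published per
#' 100,000 person-years are converted with `per100k = TRUE`.
#'
#' @param age_start,age_end band bounds in years; bands must be
#'   contiguous and non-overlapping.
#' @param incidence incidence hazard per band (>= 0, finite).
#' @param mortality competing mortality hazard per band (>= 0, finite).
#' @param sex optional sex label.
#' @param per100k if `TRUE`, `incidence` and `mortality` are given per
#'   100,000 person-years and divided by 1e5 on construction.
#' @return `data.frame` of class `rate_table`.
#' @export
rate_table <- function(age_start, age_end, incidence, mortality,
                       sex = NA_character_, per100k = FALSE) {
  stopifnot(length(age_start) == length(age_end),
            length(incidence) == length(age_start),
            length(mortality) == length(age_start))
  o <- order(age_start)
  age_start <- age_start[o]; age_end <- age_end[o]
  incidence <- incidence[o]; mortality <- mortality[o]
  if (any(age_end <= age_start)) {
    stop("each band must have age_end > age_start", call. = FALSE)
  }
  if (length(age_start) > 1 &&
      any(abs(age_start[-1] - age_end[-length(age_end)]) > 1e-9)) {
    stop("age bands must be contiguous and non-overlapping", call. = FALSE)
  }
  if (any(!is.finite(incidence)) || any(incidence < 0) ||
      any(!is.finite(mortality)) || any(mortality < 0)) {
    stop("hazards must be finite and non-negative", call. = FALSE)
  }
  scale <- if (per100k) 1e5 else 1
  structure(data.frame(age_start = age_start, age_end = age_end,
                       incidence = incidence / scale,
                       mortality = mortality / scale,
                       sex = sex, stringsAsFactors = FALSE),
            class = c("rate_table", "data.frame"))
}

#' Risk-profile distribution for attributable-risk calibration
#'
#' Describes the population mixture of risk profiles: per profile a
#' prevalence `P_g` and relative risk `RR_g` (reference profile RR = 1),
#' optionally varying by age band (and carrying a standard error of the
#' log relative risk for uncertainty propagation). Within each band the
#' prevalences must sum to 1.
#'
#' @param profile profile labels.
#' @param prevalence profile prevalences `P_g`.
#' @param rr relative risks `RR_g` (> 0).
#' @param se_log_rr optional standard errors of `log(RR_g)` (`NA` for
#'   none; the reference profile's is 0).
#' @param age_start,age_end optional band bounds for age-specific
#'   parameters; omit for age-constant parameters.
#' @param sex optional sex label.
#' @return `data.frame` of class `risk_distribution`.
#' @export
risk_distribution <- function(profile, prevalence, rr, se_log_rr = NA_real_,
                              age_start = NULL, age_end = NULL,
                              sex = NA_character_) {
  n <- length(profile)
  stopifnot(length(prevalence) == n, length(rr) == n)
  se_log_rr <- rep_len(se_log_rr, n)
  if (any(prevalence < 0 | prevalence > 1)) {
    stop("prevalences must lie in [0, 1]", call. = FALSE)
  }
  if (any(rr <= 0) || any(!is.finite(rr))) {
    stop("relative risks must be positive and finite", call. = FALSE)
  }
  banded <- !is.null(age_start)
  d <- data.frame(profile = as.character(profile), prevalence = prevalence,
                  rr = rr, se_log_rr = se_log_rr, sex = sex,
                  stringsAsFactors = FALSE)
  if (banded) {
    stopifnot(length(age_start) == n, length(age_end) == n)
    d$age_start <- age_start
    d$age_end <- age_end
    key <- paste(d$age_start, d$age_end)
  } else {
    key <- rep("all", n)
  }
  sums <- tapply(d$prevalence, key, sum)
  if (any(abs(sums - 1) > 1e-9)) {
    stop("profile prevalences must sum to 1 within each age band",
         call. = FALSE)
  }
  structure(d, class = c("risk_distribution", "data.frame"))
}

# Sum_g P_g RR_g for the band [a0, a1); uses the distribution's matching
# band when it is age-specific, the single set otherwise.
mean_rr <- function(dist, a0, a1) {
  if (!is.null(dist$age_start)) {
    hit <- dist$age_start <= a0 & dist$age_end >= a1
    d <- dist[hit, , drop = FALSE]
    if (nrow(d) == 0) {
      stop("risk distribution has no band covering [", a0, ", ", a1, ")",
           call. = FALSE)
    }
  } else {
    d <- dist
  }
  sum(d$prevalence * d$rr)
}

#' Calibrate baseline hazards to a risk-profile distribution
#'
#' Divides the composite (population-average) incidence hazard in each
#' band by `sum_g P_g RR_g`, yielding the hazard `h1(a)` of the
#' reference (RR = 1) profile. By construction the prevalence-weighted
#' average of the profile hazards `RR_g h1(a)` reproduces the composite
#' hazard exactly; `1 - 1 / sum_g P_g RR_g` is the attributable risk.
#'
#' @param rates composite [rate_table()].
#' @param dist a [risk_distribution()].
#' @return A [rate_table()] with `incidence` replaced by the baseline
#'   hazard `h1(a)`; attribute `mean_rr` records `sum P_g RR_g` per
#'   band.
#' @export
calibrate_baseline <- function(rates, dist) {
  stopifnot(inherits(rates, "rate_table"),
            inherits(dist, "risk_distribution"))
  m <- vapply(seq_len(nrow(rates)), function(i) {
    mean_rr(dist, rates$age_start[i], rates$age_end[i])
  }, numeric(1))
  if (any(m <= 0)) {
    stop("invalid distribution: sum of prevalence x RR must be positive",
         call. = FALSE)
  }
  out <- rates
  out$incidence <- rates$incidence / m
  attr(out, "mean_rr") <- m
  out
}

#' Cause-specific cumulative incidence over an age interval
#'
#' Probability of developing the lesion during `[age, age + horizon)`
#' for a person with relative risk `rr`, given baseline incidence
#' hazards `h1(a)` and competing mortality hazards `m(a)` that are
#' piecewise constant over the rate table's age bands. Each band
#' contributes in closed form
#' `S * lambda / (lambda + mu) * (1 - exp(-(lambda + mu) * width))`
#' with `lambda = rr * h1`, `mu = m`, and `S` the probability of still
#' being alive and lesion-free at band entry; there is no quadrature
#' error. The degenerate band `lambda + mu = 0` contributes
#' `S * lambda * width = 0`.
#'
#' @param age exact starting age in years.
#' @param horizon projection length in years (> 0).
#' @param rr relative risk multiplier on the baseline incidence (> 0);
#'   either a scalar or one value per rate-table band (age-specific
#'   relative risks).
#' @param rates [rate_table()] whose `incidence` is the baseline hazard
#'   (see [calibrate_baseline()]) and `mortality` the competing hazard.
#' @return Probability in `[0, 1]`.
#' @export
#' @examples
#' rt <- rate_table(50, 60, incidence = 0.01, mortality = 0.02)
#' project_risk(50, 10, 1, rt)  # (1/3) * (1 - exp(-0.3))
project_risk <- function(age, horizon, rr, rates) {
  stopifnot(inherits(rates, "rate_table"))
  if (horizon <= 0) stop("horizon must be positive", call. = FALSE)
  if (any(rr <= 0) || any(!is.finite(rr))) {
    stop("rr must be positive", call. = FALSE)
  }
  if (!length(rr) %in% c(1L, nrow(rates))) {
    stop("rr must be a scalar or one value per band", call. = FALSE)
  }
  rr <- rep_len(rr, nrow(rates))
  a_end <- age + horizon
  if (age < min(rates$age_start) - 1e-9 ||
      a_end > max(rates$age_end) + 1e-9) {
    stop("coverage error: bands cover [", min(rates$age_start), ", ",
         max(rates$age_end), ") but projection needs [", age, ", ",
         a_end, ")", call. = FALSE)
  }
  surv <- 1
  risk <- 0
  for (i in seq_len(nrow(rates))) {
    lo <- max(age, rates$age_start[i])
    hi <- min(a_end, rates$age_end[i])
    if (hi <= lo) next
    width <- hi - lo
    lambda <- rr[i] * rates$incidence[i]
    mu <- rates$mortality[i]
    total <- lambda + mu
    if (total == 0) next  # limit lambda * width * surv = 0
    risk <- risk + surv * (lambda / total) * (1 - exp(-total * width))
    surv <- surv * exp(-total * width)
  }
  risk
}

#' Absolute-risk table over risk profiles with bootstrap intervals
#'
#' Projects the absolute risk over `[age, age + horizon)` for every
#' profile of the risk distribution, after attributable-risk
#' calibration of the composite rate table. Confidence intervals come
#' from a parametric bootstrap over the relative-risk uncertainty: each
#' draw samples every profile's log relative risk from a normal with
#' the profile's estimated mean and standard error, re-runs calibration
#' and projection, and the 2.5/97.5 percentiles over the draws form the
#' interval. With `n_boot = 0` (or all standard errors missing) only
#' point estimates are returned.
#'
#' @param age,horizon projection window in years.
#' @param dist a [risk_distribution()]; bootstrap requires finite
#'   `se_log_rr` for every non-reference profile.
#' @param rates composite [rate_table()].
#' @param n_boot bootstrap draws (default 2000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return `data.frame` of class `absolute_risk_table`: `profile`,
#'   `rr`, `risk`, `ci_low`, `ci_high`, `age_start`, `horizon`.
#' @export
project_profile_table <- function(age, horizon, dist, rates,
                                  n_boot = 2000, seed = 1L, conf = 0.95) {
  stopifnot(inherits(dist, "risk_distribution"),
            inherits(rates, "rate_table"))
  banded <- !is.null(dist$age_start)
  profiles <- unique(dist$profile)
  nb <- nrow(rates)

  # rr (and se) per rate band x profile; age-constant parameters are
  # broadcast across bands
  rr_of <- function(col) {
    m <- matrix(NA_real_, nrow = nb, ncol = length(profiles),
                dimnames = list(NULL, profiles))
    for (i in seq_len(nb)) {
      if (banded) {
        hit <- dist$age_start <= rates$age_start[i] &
          dist$age_end >= rates$age_end[i]
        d <- dist[hit, , drop = FALSE]
        if (nrow(d) == 0) {
          stop("risk distribution has no band covering [",
               rates$age_start[i], ", ", rates$age_end[i], ")",
               call. = FALSE)
        }
      } else {
        d <- dist
      }
      m[i, d$profile] <- d[[col]]
    }
    m
  }
  rr_m <- rr_of("rr")
  point_rr <- if (banded) rr_m[1, ] else dist$rr[match(profiles,
                                                       dist$profile)]

  base <- calibrate_baseline(rates, dist)
  point <- vapply(profiles, function(g) {
    project_risk(age, horizon, rr_m[, g], base)
  }, numeric(1))
  out <- data.frame(profile = profiles, rr = unname(point_rr),
                    risk = unname(point),
                    ci_low = NA_real_, ci_high = NA_real_,
                    age_start = age, horizon = horizon,
                    stringsAsFactors = FALSE)
  if (n_boot > 0) {
    se_m <- rr_of("se_log_rr")
    se_m[rr_m == 1 & is.na(se_m)] <- 0
    if (anyNA(se_m)) {
      bad <- profiles[apply(se_m, 2, anyNA)]
      stop("uncertainty requested but se_log_rr missing for profile(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    local_rng(seed)
    draws <- matrix(NA_real_, nrow = n_boot, ncol = length(profiles))
    dist_b <- dist
    for (b in seq_len(n_boot)) {
      # one draw per distribution row so banded parameters stay coherent
      dist_b$rr <- exp(stats::rnorm(nrow(dist), mean = log(dist$rr),
                                    sd = ifelse(dist$rr == 1 &
                                                  is.na(dist$se_log_rr), 0,
                                                dist$se_log_rr)))
      base_b <- calibrate_baseline(rates, dist_b)
      rr_b <- {
        m <- matrix(NA_real_, nrow = nb, ncol = length(profiles),
                    dimnames = list(NULL, profiles))
        for (i in seq_len(nb)) {
          if (banded) {
            hit <- dist_b$age_start <= rates$age_start[i] &
              dist_b$age_end >= rates$age_end[i]
            d <- dist_b[hit, , drop = FALSE]
          } else d <- dist_b
          m[i, d$profile] <- d$rr
        }
        m
      }
      draws[b, ] <- vapply(profiles, function(g) {
        project_risk(age, horizon, rr_b[, g], base_b)
      }, numeric(1))
    }
    alpha <- (1 - conf) / 2
    out$ci_low <- apply(draws, 2, stats::quantile, probs = alpha)
    out$ci_high <- apply(draws, 2, stats::quantile, probs = 1 - alpha)
  }
  structure(out, class = c("absolute_risk_table", "data.frame"))
}
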