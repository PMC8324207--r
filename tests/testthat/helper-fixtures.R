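# Shared fixtures and independent oracles for the test suite.

# Small three-SNP panel with fixed parameters.
tiny_panel <- function(f = c(0, 0, 0)) {
  snp_panel(c("rs1", "rs2", "rs3"), c("A", "C", "G"),
            raf = c(0.3, 0.5, 0.7), weight = c(0.10, 0.20, 0.05),
            inbreeding_f = f)
}

# Brute-force oracle 1: pure forward Euler on a fine grid. Carries its
# own O(dt) discretization error; used at a loose tolerance to catch
# formula-level mistakes in the closed form.
euler_risk <- function(age, horizon, rr, rates, dt = 1e-3) {
  t <- seq(age, age + horizon - dt, by = dt)
  band <- findInterval(t, rates$age_start)
  lam <- rep_len(rr, nrow(rates))[band] * rates$incidence[band]
  mu <- rates$mortality[band]
  S_prev <- c(1, cumprod(1 - (lam + mu) * dt)[-length(t)])
  sum(S_prev * lam * dt)
}

# Brute-force oracle 2: fine-grid integration with exact exponential
# updates per sub-interval, the grid aligned on band boundaries. Shares
# no band-walk logic with project_risk (per-point band lookup instead of
# interval intersection), so it catches mistakes in band traversal and
# survival accumulation; agreement is limited only by floating point.
finegrid_risk <- function(age, horizon, rr, rates, dt = 1e-3) {
  cuts <- sort(unique(c(seq(age, age + horizon, by = dt), age + horizon,
                        rates$age_start, rates$age_end)))
  cuts <- cuts[cuts >= age & cuts <= age + horizon]
  lo <- cuts[-length(cuts)]
  hi <- cuts[-1]
  mid <- (lo + hi) / 2
  band <- findInterval(mid, rates$age_start)
  lam <- rep_len(rr, nrow(rates))[band] * rates$incidence[band]
  mu <- rates$mortality[band]
  tot <- lam + mu
  S <- 1
  risk <- 0
  for (i in seq_along(lo)) {
    if (tot[i] == 0) next
    risk <- risk + S * (lam[i] / tot[i]) * (1 - exp(-tot[i] * (hi[i] - lo[i])))
    S <- S * exp(-tot[i] * (hi[i] - lo[i]))
  }
  risk
}

# Random age-banded rate table in realistic registry ranges
# (incidence up to 500/100k, competing mortality up to 2,000/100k).
random_rate_table <- function() {
  k <- sample(1:6, 1)
  w <- sample(2:10, k, replace = TRUE)
  a0 <- sample(40:60, 1)
  starts <- a0 + cumsum(c(0, w[-k]))
  rate_table(starts, starts + w,
             incidence = stats::runif(k, 1e-5, 5e-3),
             mortality = stats::runif(k, 1e-4, 2e-2))
}

# Four-profile risk distribution over the combined lifestyle/PRS cells.
four_cell_dist <- function(rr = c(1, 2.0, 1.7, 2.9),
                           se = c(0, 0.30, 0.14, 0.29),
                           prevalence = c(0.45, 0.05, 0.40, 0.10)) {
  risk_distribution(c("favorable_lower", "favorable_higher",
                      "unfavorable_lower", "unfavorable_higher"),
                    prevalence = prevalence, rr = rr, se_log_rr = se)
}
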