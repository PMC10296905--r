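# Small in-code fixtures shared across test files.

# A minimal eligible patient row; override fields via ...
patient_row <- function(id, ...) {
  row <- list(id = id, age = 60L, race = "white", stage = "I",
              grade = "moderate", er_status = "positive",
              pr_status = "positive", subtype = "luminalA",
              ln_status = "negative", rs = 20L, chemo = "no_unknown",
              time_months = 60, event = "censored")
  mods <- list(...)
  row[names(mods)] <- mods
  as.data.frame(row, stringsAsFactors = FALSE)
}

cohort_of <- function(...) do.call(rbind, list(...))

# Cohort with given rs values, otherwise identical eligible rows.
rs_cohort <- function(rs) {
  do.call(rbind, lapply(seq_along(rs), function(i)
    patient_row(sprintf("R%03d", i), rs = rs[i])))
}

# Two-arm exponential survival data in cohort form: covariate carried by
# the chemo column, true log-HR `beta`, optional exponential censoring.
two_arm_cohort <- function(n, beta, base_rate = 0.05, censor_rate = 0) {
  arm <- rep(c(0L, 1L), length.out = n)
  t_ev <- stats::rexp(n, base_rate * exp(beta * arm))
  t_c <- if (censor_rate > 0) stats::rexp(n, censor_rate) else rep(Inf, n)
  do.call(rbind, lapply(seq_len(n), function(i)
    patient_row(sprintf("T%05d", i),
                chemo = if (arm[i] == 1L) "yes" else "no_unknown",
                time_months = min(t_ev[i], t_c[i]),
                event = if (t_ev[i] <= t_c[i]) "bcss_death" else "censored")))
}

# Independent Harrell concordance by O(n^2) pair enumeration: usable pairs
# are those where the member with the shorter observed time had an event;
# prediction ties count 1/2.
brute_force_concordance <- function(time, status, risk) {
  conc <- disc <- tied <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) {
        if (status[i] + status[j] != 1) next
        first <- if (status[i] == 1) i else j
        second <- if (first == i) j else i
      } else {
        first <- if (time[i] < time[j]) i else j
        second <- if (first == i) j else i
        if (status[first] == 0) next
      }
      if (risk[first] > risk[second]) conc <- conc + 1
      else if (risk[first] < risk[second]) disc <- disc + 1
      else tied <- tied + 1
    }
  }
  if (conc + disc + tied == 0) return(NA_real_)
  (conc + tied / 2) / (conc + disc + tied)
}

# Independent local-linear tricube smoother via lm.wfit (oracle for
# smooth_curve): bandwidth = distance to the floor(n * span)-th nearest
# point.
oracle_local_regression <- function(x, y, span, grid) {
  n <- length(x)
  q <- floor(n * span)
  vapply(grid, function(x0) {
    d <- abs(x - x0)
    h <- sort(d)[q]
    if (h == 0) return(mean(y[d == 0]))
    w <- pmax(0, 1 - (d / h)^3)^3
    keep <- w > 0
    fit <- stats::lm.wfit(cbind(1, x[keep] - x0), y[keep], w[keep])
    unname(fit$coefficients[1])
  }, numeric(1))
}

# Forward scan oracle for find_crossing: first grid index whose value is
# non-positive through the end of the grid with at least persistence + 1
# points in the run, interpolated at the entry.
oracle_crossing <- function(grid, value, persistence = 5) {
  m <- length(grid)
  for (i in seq_len(m)) {
    if (all(value[i:m] <= 0) && (m - i + 1) >= persistence + 1) {
      if (i == 1) return(grid[1])
      y1 <- value[i - 1]; y2 <- value[i]
      if (y1 > 0) return(grid[i - 1] + (grid[i] - grid[i - 1]) * y1 / (y1 - y2))
      return(grid[i])  # unreachable given first-index scan, kept for clarity
    }
  }
  NA_real_
}

# Negative log Cox partial likelihood (no ties assumed) for grid oracles.
neg_log_partial_likelihood <- function(beta, time, status, x) {
  ord <- order(time)
  time <- time[ord]; status <- status[ord]; x <- x[ord]
  eta <- beta * x
  nll <- 0
  for (i in seq_along(time)) {
    if (status[i] == 1) {
      at_risk <- time >= time[i]
      nll <- nll - eta[i] + log(sum(exp(eta[at_risk])))
    }
  }
  nll
}
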