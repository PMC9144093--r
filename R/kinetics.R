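# Closed-form kinetics for two-compartment intravenous infusion.
#
# Concentration in the central compartment is a sum of (at most) two
# exponential terms with macro rate constants alpha > beta > 0 derived from
# CL, V1, Q, V2.  Doses superpose; steady state uses the geometric
# accumulation of each exponential term, never repeated-dose simulation.
# All times in hours, amounts in mg, volumes in L, concentrations in mg/L.

#' Define a dosing regimen
#'
#' @param doses A `data.frame` with columns `time` (start of infusion, h),
#'   `amt` (mg) and `dur` (infusion duration, h).  Defaults to a single
#'   1000 mg dose infused over 1 h starting at time 0 (the standard
#'   simulated vancomycin regimen here).
#' @param tau Dosing interval in hours (required when `steady_state`).
#' @param steady_state If `TRUE`, the first row of `doses` defines a dose
#'   repeated every `tau` hours since the indefinite past; concentrations
#'   are periodic with period `tau` and `time = 0` is a dose start.
#' @return An object of class `regimen`.
#' @export
#' @examples
#' regimen()                                  # 1000 mg / 1 h, single dose
#' regimen(tau = 12, steady_state = TRUE)     # same dose at steady state
regimen <- function(doses = data.frame(time = 0, amt = 1000, dur = 1),
                    tau = 12, steady_state = FALSE) {
  stopifnot(is.data.frame(doses),
            all(c("time", "amt", "dur") %in% names(doses)))
  if (any(doses$dur <= 0)) stop("infusion durations must be > 0")
  if (any(doses$amt < 0)) stop("dose amounts must be >= 0")
  if (is.unsorted(doses$time)) stop("dose times must be non-decreasing")
  if (steady_state) {
    if (!is.finite(tau) || tau <= 0) stop("tau must be > 0 for steady state")
    if (doses$dur[1] > tau) stop("infusion duration exceeds the dosing interval")
  }
  structure(list(doses = doses, tau = tau, steady_state = steady_state),
            class = "regimen")
}

# (1 - exp(-lam * u)) / lam, stable for small lam * u; u >= 0.
.e1 <- function(lam, u) {
  out <- -expm1(-lam * u) / lam
  small <- lam * u < 1e-12
  if (any(small)) out[small] <- (u * (1 - lam * u / 2))[small]
  out
}

# Macro-constants and coefficients for the biexponential solution.
# Returns list of vectors l1, l2 (1/h) and c1, c2 (1/L); the second term has
# c2 = 0 (with a dummy positive l2) when Q = 0, i.e. one-compartment kinetics.
macro_constants <- function(cl, v1, q, v2) {
  k10 <- cl / v1
  k12 <- q / v1
  k21 <- q / v2
  s <- k10 + k12 + k21
  disc2 <- s^2 - 4 * k10 * k21
  # alpha ~ beta degeneracy: nudge k21 so the partial-fraction coefficients
  # stay finite; the perturbation is far below parameter uncertainty.
  deg <- q > 0 & disc2 < (1e-10 * s)^2
  if (any(deg)) {
    k21[deg] <- k21[deg] * (1 + 1e-6)
    s <- k10 + k12 + k21
    disc2 <- s^2 - 4 * k10 * k21
  }
  disc <- sqrt(pmax(disc2, 0))
  alpha <- (s + disc) / 2
  beta <- pmax((s - disc) / 2, 0)
  one_cmt <- q <= 0 | beta <= 0
  c1 <- (alpha - k21) / (v1 * (alpha - beta))
  c2 <- (k21 - beta) / (v1 * (alpha - beta))
  if (any(one_cmt)) {
    c1[one_cmt] <- 1 / v1[one_cmt]
    c2[one_cmt] <- 0
    beta[one_cmt] <- 1 # dummy; multiplied by c2 = 0
    alpha[one_cmt] <- k10[one_cmt]
  }
  list(l1 = alpha, l2 = beta, c1 = c1, c2 = c2)
}

# One exponential term's concentration at u = time since dose start (>= 0 or
# negative for "not yet dosed"), for an infusion of rate r0 over dur.
.term_conc <- function(lam, cc, r0, u, dur) {
  w1 <- pmin(pmax(u, 0), dur)
  w2 <- pmax(u - dur, 0)
  cc * r0 * .e1(lam, w1) * exp(-lam * w2)
}

# Integral of .term_conc from u = 0 to u (u >= 0).
.term_cum <- function(lam, cc, r0, u, dur) {
  w1 <- pmin(pmax(u, 0), dur)
  w2 <- pmax(u - dur, 0)
  cc * r0 * ((w1 - .e1(lam, w1)) / lam + .e1(lam, w1) * .e1(lam, w2))
}

# Steady-state tail from all previous doses (dose every tau since -Inf),
# valid for t in [0, tau] when dur <= tau.
.term_ss_tail <- function(lam, cc, r0, t, dur, tau) {
  rho <- exp(-lam * tau) / (-expm1(-lam * tau))
  cc * r0 * .e1(lam, dur) * exp(-lam * (t - dur)) * rho
}

.term_ss_tail_cum <- function(lam, cc, r0, t, dur, tau) {
  rho <- exp(-lam * tau) / (-expm1(-lam * tau))
  cc * r0 * .e1(lam, dur) * exp(lam * dur) * rho * .e1(lam, t)
}

.conc_grid <- function(mc, reg, times, FUN_once, FUN_tail) {
  n <- length(mc$l1)
  out <- matrix(0, n, length(times))
  if (reg$steady_state) {
    amt <- reg$doses$amt[1]
    dur <- reg$doses$dur[1]
    r0 <- amt / dur
    tau <- reg$tau
    tr <- times %% tau
    for (j in seq_along(times)) {
      out[, j] <-
        FUN_once(mc$l1, mc$c1, r0, tr[j], dur) +
        FUN_once(mc$l2, mc$c2, r0, tr[j], dur) +
        FUN_tail(mc$l1, mc$c1, r0, tr[j], dur, tau) +
        FUN_tail(mc$l2, mc$c2, r0, tr[j], dur, tau)
    }
  } else {
    for (d in seq_len(nrow(reg$doses))) {
      amt <- reg$doses$amt[d]
      if (amt == 0) next
      dur <- reg$doses$dur[d]
      r0 <- amt / dur
      t0 <- reg$doses$time[d]
      for (j in seq_along(times)) {
        u <- times[j] - t0
        if (u <= 0) next
        out[, j] <- out[, j] +
          FUN_once(mc$l1, mc$c1, r0, u, dur) +
          FUN_once(mc$l2, mc$c2, r0, u, dur)
      }
    }
  }
  out
}

#' Concentration-time profiles for many parameter sets
#'
#' Evaluates the analytic two-compartment infusion solution at the given
#' times for each row of individual parameters.
#'
#' @param params `data.frame` (or list) with vectors `CL`, `V1`, `Q`, `V2`.
#' @param reg A [regimen()].
#' @param times Numeric vector of times (h, from first dose; for
#'   steady-state regimens times are folded into the dosing interval).
#' @return Matrix of concentrations (mg/L), patients in rows, times in
#'   columns.
#' @export
concentration_profile <- function(params, reg, times) {
  stopifnot(inherits(reg, "regimen"))
  cl <- as.numeric(params$CL); v1 <- as.numeric(params$V1)
  q <- as.numeric(params$Q); v2 <- as.numeric(params$V2)
  if (any(cl <= 0 | v1 <= 0 | q < 0 | v2 <= 0)) {
    stop("PK parameters must be positive (Q may be zero)")
  }
  if (any(times < 0)) stop("times must be >= 0")
  mc <- macro_constants(cl, v1, q, v2)
  .conc_grid(mc, reg, times, .term_conc, .term_ss_tail)
}

#' Concentration at time t (scalar-parameter convenience wrapper)
#'
#' @inheritParams concentration_profile
#' @param t Time(s) in hours.
#' @return Numeric vector of concentrations, one per time.
#' @export
concentration <- function(params, reg, t) {
  drop(concentration_profile(as.data.frame(as.list(params)[PK_PARAMS]), reg, t))
}

# Cumulative AUC from time 0 (first dose) to each time; steady-state
# regimens use the exact periodic extension: full intervals contribute
# amt/CL each.
.cum_auc <- function(params, reg, times) {
  cl <- as.numeric(params$CL); v1 <- as.numeric(params$V1)
  q <- as.numeric(params$Q); v2 <- as.numeric(params$V2)
  mc <- macro_constants(cl, v1, q, v2)
  if (reg$steady_state) {
    tau <- reg$tau
    k <- floor(times / tau + 1e-12)
    tr <- times - k * tau
    per_interval <- reg$doses$amt[1] / cl # exact steady-state mass balance
    part <- .conc_grid(mc, reg, tr, .term_cum, .term_ss_tail_cum)
    part + outer(per_interval, k)
  } else {
    .conc_grid(mc, reg, times, .term_cum, .term_ss_tail_cum)
  }
}

#' Area under the concentration-time curve over a window
#'
#' Exact analytic integral of the biexponential solution over `[t1, t2]`,
#' per parameter row.  For steady-state regimens the profile is periodic, so
#' a window of one dosing interval equals `amt / CL` exactly.
#'
#' @inheritParams concentration_profile
#' @param t1,t2 Window bounds in hours, `0 <= t1 < t2`.
#' @return Numeric vector of AUC values (mg.h/L), one per parameter row.
#' @export
auc_interval <- function(params, reg, t1 = 12, t2 = 24) {
  stopifnot(inherits(reg, "regimen"), t1 >= 0, t2 > t1)
  params <- as.data.frame(as.list(params)[PK_PARAMS])
  if (any(params$CL <= 0 | params$V1 <= 0 | params$Q < 0 | params$V2 <= 0)) {
    stop("PK parameters must be positive (Q may be zero)")
  }
  cum <- .cum_auc(params, reg, c(t1, t2))
  drop(cum[, 2] - cum[, 1])
}

# Scalar-parameter fast path for iterative estimation: dose-event geometry
# (infusion/elapsed-time splits) is precomputed once per patient, so each
# objective evaluation is a handful of exp() calls.
.precompute_events <- function(reg, times) {
  if (reg$steady_state) {
    tr <- times %% reg$tau
    dur <- reg$doses$dur[1]
    list(ss = TRUE, r0 = reg$doses$amt[1] / dur, dur = dur, tau = reg$tau,
         w1 = pmin(pmax(tr, 0), dur), w2 = pmax(tr - dur, 0), tr = tr)
  } else {
    ev <- list()
    for (d in seq_len(nrow(reg$doses))) {
      u <- times - reg$doses$time[d]
      dur <- reg$doses$dur[d]
      if (all(u <= 0) || reg$doses$amt[d] == 0) next
      ev[[length(ev) + 1L]] <- list(r0 = reg$doses$amt[d] / dur,
                                    w1 = pmin(pmax(u, 0), dur),
                                    w2 = pmax(u - dur, 0))
    }
    list(ss = FALSE, events = ev)
  }
}

.conc_fast <- function(cl, v1, q, v2, pre) {
  k10 <- cl / v1; k12 <- q / v1; k21 <- q / v2
  s <- k10 + k12 + k21
  disc2 <- s^2 - 4 * k10 * k21
  if (q > 0 && disc2 < (1e-10 * s)^2) {
    k21 <- k21 * (1 + 1e-6)
    s <- k10 + k12 + k21
    disc2 <- s^2 - 4 * k10 * k21
  }
  disc <- sqrt(max(disc2, 0))
  l1 <- (s + disc) / 2
  l2 <- (s - disc) / 2
  if (q <= 0 || l2 <= 0) {
    l1 <- k10; l2 <- 1
    c1 <- 1 / v1; c2 <- 0
  } else {
    c1 <- (l1 - k21) / (v1 * (l1 - l2))
    c2 <- (k21 - l2) / (v1 * (l1 - l2))
  }
  term <- function(lam, cc) {
    if (cc == 0) return(0)
    if (pre$ss) {
      rho <- exp(-lam * pre$tau) / (-expm1(-lam * pre$tau))
      cc * pre$r0 / lam * (
        (-expm1(-lam * pre$w1)) * exp(-lam * pre$w2) +
        (-expm1(-lam * pre$dur)) * exp(-lam * (pre$tr - pre$dur)) * rho)
    } else {
      out <- 0
      for (ev in pre$events) {
        out <- out + cc * ev$r0 / lam * (-expm1(-lam * ev$w1)) * exp(-lam * ev$w2)
      }
      out
    }
  }
  term(l1, c1) + term(l2, c2)
}

#' Add residual unexplained variability to true concentrations
#'
#' Observed concentration = true + Normal(0, sd) noise with combined
#' variance `add^2 + (prop * true)^2`, floored at a small positive value so
#' downstream concentration-ratio features stay defined.
#'
#' @param true Numeric vector or matrix of noise-free concentrations (mg/L).
#' @param residual List with `add` (mg/L) and `prop` (fraction) sds.
#' @param floor Lower bound applied to the noisy values (mg/L).
#' @param seed Optional integer seed for the draw (uses the current RNG
#'   stream when `NULL`).
#' @return Observed concentrations, same shape as `true`.
#' @export
apply_residual_error <- function(true, residual, floor = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sd <- sqrt(residual$add^2 + (residual$prop * true)^2)
  obs <- true + stats::rnorm(length(true), 0, sd)
  obs <- pmax(obs, floor)
  if (is.matrix(true)) dim(obs) <- dim(true)
  obs
}
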