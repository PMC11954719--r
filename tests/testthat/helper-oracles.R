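# Independent oracles and fixture builders used across the suite.

ator <- function() default_analyte_table()[["atorvastatin"]]

# profile from explicit vectors, atorvastatin analyte, 10 mg dose
make_profile <- function(time, conc, blq = rep(FALSE, length(time)),
                         occasion = "baseline", dose_ng = 1e7,
                         subject = "S01", analyte = ator()) {
  concentration_profile(subject, analyte, occasion, dose_ng,
                        time = time, conc = conc, blq = blq)
}

# numerical-integrator oracle for the two-compartment zero-order-input
# model (independent of the package's closed-form route)
oracle_2cpt_zo_desolve <- function(times, famt, dur, cl, vc, q, vp,
                                   rtol = 1e-10, atol = 1e-12) {
  k10 <- cl / vc; k12 <- q / vc; k21 <- q / vp
  rhs <- function(t, y, parms) {
    rate <- if (t > 0 && t <= dur) famt / dur else 0
    list(c(rate - (k10 + k12) * y[1] + k21 * y[2],
           k12 * y[1] - k21 * y[2]))
  }
  tt <- sort(unique(c(0, dur, times[times >= 0])))
  out <- deSolve::lsoda(c(0, 0), tt, rhs, NULL, rtol = rtol, atol = atol)
  conc <- out[match(times, tt), 2] / vc / 1000
  conc[times <= 0] <- 0
  conc
}

# numerical-integrator oracle for the enzyme turnover ODE under a
# square-wave presence covering [start, end) intervals
oracle_enzyme_desolve <- function(times, k_deg, k_inact, intervals,
                                  origin = 0, rtol = 1e-10, atol = 1e-12) {
  rhs <- function(t, y, parms) {
    r <- 0
    if (nrow(intervals)) {
      for (k in seq_len(nrow(intervals))) {
        if (t >= intervals[k, 1] && t < intervals[k, 2]) r <- 1
      }
    }
    list(k_deg * (1 - y) - k_inact * r * y)
  }
  tt <- sort(unique(c(origin, as.vector(intervals), times)))
  out <- deSolve::lsoda(1, tt, rhs, NULL, rtol = rtol, atol = atol)
  out[match(times, tt), 2]
}

# dense-grid trapezoid AUC of a concentration function over [t0, t1]
oracle_dense_auc <- function(f, t0, t1, dt = 0.001) {
  tt <- seq(t0, t1, by = dt)
  cc <- f(tt)
  sum(diff(tt) * (cc[-1] + cc[-length(cc)]) / 2)
}
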