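# Independent fixed-step RK4 integrator of the scaled field, used as an
# oracle against the event-detecting adaptive integrator. Records the
# state at each requested output time; `times` must be reachable by an
# integer number of steps of size `h_step` (asserted).
rk4_flow <- function(state0, a, times, h_step = 1e-4) {
  f <- function(s) rhs_scaled(s, a)
  out <- matrix(NA_real_, nrow = length(times), ncol = 2)
  out[1, ] <- s <- as.numeric(state0)
  for (i in seq_len(length(times) - 1)) {
    span <- times[i + 1] - times[i]
    n <- round(span / h_step)
    stopifnot(abs(n * h_step - span) < 1e-12)
    hh <- span / n
    for (k in seq_len(n)) {
      k1 <- f(s)
      k2 <- f(s + hh / 2 * k1)
      k3 <- f(s + hh / 2 * k2)
      k4 <- f(s + hh * k3)
      s <- s + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[i + 1, ] <- s
  }
  out
}

# Reference control set used throughout: the periodic regime.
ctrl_periodic <- function() control_params(p = 0.3, q = 0.5, h2 = 1.6)
ctrl_extinction <- function() control_params(p = 0.65, q = 0.5, h2 = 1.6)
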