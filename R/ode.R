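# Internal stiff-capable ODE integrator.
#
# Adaptive implicit-midpoint rule with Newton iteration and step-doubling
# (Richardson) error control. The implicit midpoint rule is A-stable and
# symmetric, so its local error expansion contains only even powers of the
# step size; the step-doubling comparison therefore both controls the error
# and yields a 4th-order extrapolated accepted value. For the affine systems
# solved in this package the Newton iteration converges in a single
# correction, but the integrator is written for a general right-hand side.

# One implicit midpoint step from (t, y) over h.
# f(t, y) -> dy/dt; jac(t, y) -> Jacobian matrix of f.
.imp_midpoint_step <- function(f, jac, t, y, h, atol, rtol) {
  d <- length(y)
  z <- y + h * f(t, y)                       # explicit Euler predictor
  tm <- t + h / 2
  for (it in seq_len(25L)) {
    ym <- (y + z) / 2
    g <- z - y - h * f(tm, ym)
    M <- diag(d) - (h / 2) * jac(tm, ym)
    dz <- solve(M, g)
    z <- z - dz
    if (max(abs(dz) / (atol + rtol * pmax(abs(z), abs(y)))) < 1e-2)
      return(z)
  }
  stop("implicit midpoint Newton iteration failed to converge at t = ",
       format(t), ", h = ", format(h), call. = FALSE)
}

# Integrate y' = f(t, y) from times[1], returning the solution at `times`.
# Returns a length(times) x d matrix.
.ode_solve <- function(f, jac, y0, times, rtol = 1e-8, atol = 1e-10) {
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("'times' must be strictly increasing with at least two points",
         call. = FALSE)
  d <- length(y0)
  out <- matrix(NA_real_, length(times), d)
  out[1L, ] <- y0
  t <- times[1L]
  y <- y0
  t_end <- times[length(times)]
  h_free <- min(1e-3, (times[2L] - times[1L]))
  i_next <- 2L
  max_steps <- 500000L
  for (step in seq_len(max_steps)) {
    h <- min(h_free, times[i_next] - t)
    capped <- h < h_free
    repeat {
      yB <- .imp_midpoint_step(f, jac, t, y, h, atol, rtol)
      y1 <- .imp_midpoint_step(f, jac, t, y, h / 2, atol, rtol)
      yS <- .imp_midpoint_step(f, jac, t + h / 2, y1, h / 2, atol, rtol)
      errv <- (yS - yB) / 3
      sc <- atol + rtol * pmax(abs(y), abs(yS))
      en <- sqrt(mean((errv / sc)^2))
      if (is.finite(en) && en <= 1) break
      h <- h * max(0.1, 0.9 * en^(-1 / 3))
      capped <- FALSE
      if (h < 1e-13 * max(1, abs(t)))
        stop("step size underflow at t = ", format(t), call. = FALSE)
    }
    y <- yS + errv                            # 4th-order extrapolation
    t <- t + h
    if (!capped)
      h_free <- h * min(4, max(0.3, 0.9 * max(en, 1e-10)^(-1 / 3)))
    while (i_next <= length(times) &&
           t >= times[i_next] - 1e-12 * max(1, abs(times[i_next]))) {
      out[i_next, ] <- y
      i_next <- i_next + 1L
    }
    if (i_next > length(times) || t >= t_end) break
  }
  if (anyNA(out))
    stop("integration did not reach all requested output times",
         call. = FALSE)
  out
}
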