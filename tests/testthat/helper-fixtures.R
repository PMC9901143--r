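# Shared fixtures: small rate tables, smooth hazard sets, and independent
# numerical oracles (hand-rolled natural spline, fine-step RK4 integrator).

default_bands <- function() {
  data.frame(age_lo = as.integer(seq(0, 95, 5)),
             age_hi = c(as.integer(seq(5, 95, 5)), NA_integer_))
}

mk_table <- function(values, measure, bands = default_bands(),
                     disease = "synthetic", sex = "male", year = 2015,
                     se = NA_real_) {
  rate_table(data.frame(disease = disease, sex = sex, year = year,
                        age_lo = bands$age_lo, age_hi = bands$age_hi,
                        measure = measure, value = values, se = se))
}

## A gently varying, mutually consistent hazard set (slopes mild enough
## that the single-year discretisation error stays well below 1e-3).
smooth_hazards <- function(ki = 0.05, i0 = 5e-5, r0 = 0.1,
                           f0 = 0.05, kf = 0.01, m0 = 2e-5, km = 0.09) {
  a <- 0:99
  hazard_set(i = i0 * exp(ki * a), r = rep(r0, 100),
             f = f0 * exp(kf * a), m = m0 * exp(km * a))
}

## Independent natural cubic spline oracle: solves the standard tridiagonal
## second-derivative system with base solve(), then evaluates piecewise.
nat_spline_oracle <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  A <- matrix(0, n, n)
  b <- numeric(n)
  A[1, 1] <- 1; A[n, n] <- 1          # natural: M_1 = M_n = 0
  for (j in 2:(n - 1)) {
    A[j, j - 1] <- h[j - 1] / 6
    A[j, j] <- (h[j - 1] + h[j]) / 3
    A[j, j + 1] <- h[j] / 6
    b[j] <- (y[j + 1] - y[j]) / h[j] - (y[j] - y[j - 1]) / h[j - 1]
  }
  M <- solve(A, b)
  vapply(xout, function(xx) {
    j <- findInterval(xx, x, rightmost.closed = TRUE)
    j <- min(max(j, 1), n - 1)
    d <- x[j + 1] - x[j]
    t1 <- x[j + 1] - xx; t2 <- xx - x[j]
    (M[j] * t1^3 + M[j + 1] * t2^3) / (6 * d) +
      (y[j] / d - M[j] * d / 6) * t1 +
      (y[j + 1] / d - M[j + 1] * d / 6) * t2
  }, numeric(1))
}

## Fine-step classical RK4 integrator for the full four-state system with
## piecewise-constant hazards; independent of the closed-form stepper.
rk4_solve <- function(h, p0 = 0, nstep = 100L) {
  deriv <- function(y, i, r, f, m) {
    c(-(i + m) * y[1] + r * y[2],
      i * y[1] - (r + f + m) * y[2],
      f * y[2],
      m * (y[1] + y[2]))
  }
  y <- c(1 - p0, p0, 0, 0)
  out <- matrix(NA_real_, 100, 4)
  dt <- 1 / nstep
  for (a in 1:100) {
    out[a, ] <- y
    i <- h$i[a]; r <- h$r[a]; f <- h$f[a]; m <- h$m[a]
    for (s in seq_len(nstep)) {
      k1 <- deriv(y, i, r, f, m)
      k2 <- deriv(y + dt / 2 * k1, i, r, f, m)
      k3 <- deriv(y + dt / 2 * k2, i, r, f, m)
      k4 <- deriv(y + dt * k3, i, r, f, m)
      y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
  }
  colnames(out) <- c("S", "C", "D_cause", "D_other")
  out
}
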