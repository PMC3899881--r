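# Independent numerical oracles. These deliberately avoid the package's own
# solution paths: plain bisection for roots, and a finite-difference solve of
# the spherical Poisson problem for pressure profiles.

bisection_root <- function(f, lo, hi, tol = 1e-15, maxit = 200L) {
  flo <- f(lo)
  if (flo == 0) return(lo)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0 || (hi - lo) / 2 < tol) return(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

# Thomas solve for the oracle's tridiagonal systems.
thomas_solve <- function(lower, diagv, upper, rhs) {
  m <- length(diagv)
  cp <- numeric(m); dp <- numeric(m)
  cp[1] <- upper[1] / diagv[1]; dp[1] <- rhs[1] / diagv[1]
  for (j in 2:m) {
    den <- diagv[j] - lower[j] * cp[j - 1]
    cp[j] <- if (j < m) upper[j] / den else 0
    dp[j] <- (rhs[j] - lower[j] * dp[j - 1]) / den
  }
  x <- numeric(m)
  x[m] <- dp[m]
  for (j in (m - 1):1) x[j] <- dp[j] - cp[j] * x[j + 1]
  x
}

# Finite-difference solution of p'' + (2/r) p' = a*Omega/D on the oxygenated
# domain. With a core: Dirichlet p(r_n) = 0, p(r_o) = p_o. Without: Neumann
# p'(0) = 0, Dirichlet p(r_o) = p_o. Returns data.frame(r, p).
fd_pressure_oracle <- function(r_o, r_n, a, params, n = 10000L) {
  src <- a * params$Omega / params$D
  if (r_n > 0) {
    r <- seq(r_n, r_o, length.out = n + 1L)
    h <- r[2] - r[1]
    i <- 2:n
    lower <- c(0, 1 / h^2 - 1 / (h * r[i]))
    diagv <- c(1, rep(-2 / h^2, n - 1L))
    upper <- c(0, 1 / h^2 + 1 / (h * r[i]))
    rhs <- c(0, rep(src, n - 1L))
    # interior unknowns p[2..n]; boundary values folded into rhs
    rhs[n] <- rhs[n] - (1 / h^2 + 1 / (h * r[n])) * params$p_o
    p <- c(0, thomas_solve(lower[-1], diagv[-1], upper[-1], rhs[-1]),
           params$p_o)
  } else {
    r <- seq(0, r_o, length.out = n + 1L)
    h <- r[2] - r[1]
    i <- 2:n
    lower <- c(0, 1 / h^2 - 1 / (h * r[i]))
    diagv <- c(-6 / h^2, rep(-2 / h^2, n - 1L))
    upper <- c(6 / h^2, 1 / h^2 + 1 / (h * r[i]))
    rhs <- rep(src, n)
    rhs[n] <- rhs[n] - (1 / h^2 + 1 / (h * r[n])) * params$p_o
    p <- c(thomas_solve(lower, diagv, upper, rhs), params$p_o)
    p <- pmax(p, 0)
  }
  data.frame(r = r, p = p)
}
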