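# Azzalini skew-normal distribution: density, CDF (via Owen's T), quantiles,
# mode and random draws. Parameterised by location xi, scale omega > 0 and
# shape alpha (alpha = 0 recovers the Normal).

# Owen's T function T(h, a) = (1/2pi) * Int_0^a exp(-h^2 (1+t^2)/2)/(1+t^2) dt.
# Reduced to |a| <= 1 via the standard identities, then evaluated with
# 48-point Gauss-Legendre quadrature (absolute error << 1e-12 on |a| <= 1).
.gl48 <- local({
  gl <- NULL
  function() {
    if (is.null(gl)) {
      # nodes/weights for Legendre polynomial degree 48 on [-1, 1],
      # computed once by Newton iteration on the recurrence
      n <- 48L
      x <- cos(pi * (seq_len(n) - 0.25) / (n + 0.5))
      for (it in 1:100) {
        p0 <- rep(1, n); p1 <- x
        for (k in 2:n) {
          p2 <- ((2 * k - 1) * x * p1 - (k - 1) * p0) / k
          p0 <- p1; p1 <- p2
        }
        dp <- n * (x * p1 - p0) / (x^2 - 1)
        x1 <- x - p1 / dp
        if (max(abs(x1 - x)) < 1e-15) { x <- x1; break }
        x <- x1
      }
      p0 <- rep(1, n); p1 <- x
      for (k in 2:n) {
        p2 <- ((2 * k - 1) * x * p1 - (k - 1) * p0) / k
        p0 <- p1; p1 <- p2
      }
      dp <- n * (x * p1 - p0) / (x^2 - 1)
      gl <<- list(nodes = x, weights = 2 / ((1 - x^2) * dp^2))
    }
    gl
  }
})

.owen_t_core <- function(h, a) {
  # |a| <= 1 assumed; scalar h, a
  if (a == 0) return(0)
  gl <- .gl48()
  t <- 0.5 * a * (gl$nodes + 1)           # map [-1,1] -> [0,a]
  w <- 0.5 * a * gl$weights
  sum(w * exp(-0.5 * h^2 * (1 + t^2)) / (1 + t^2)) / (2 * pi)
}

#' Owen's T function
#'
#' @param h,a numeric scalars or vectors (recycled).
#' @return numeric vector of T(h, a) values.
#' @keywords internal
owen_t <- function(h, a) {
  n <- max(length(h), length(a))
  h <- rep_len(h, n); a <- rep_len(a, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    hi <- abs(h[i]); ai <- a[i]          # T(-h, a) = T(h, a)
    sgn <- sign(ai); ai <- abs(ai)       # T(h, -a) = -T(h, a)
    if (!is.finite(ai)) {
      v <- 0.5 * pnorm(-hi)              # T(h, Inf) = (1 - Phi(|h|))/2
    } else if (ai <= 1) {
      v <- .owen_t_core(hi, ai)
    } else {
      # T(h, a) = (Phi(h) + Phi(ah))/2 - Phi(h) Phi(ah) - T(ah, 1/a), a > 0
      ah <- ai * hi
      v <- 0.5 * (pnorm(hi) + pnorm(ah)) - pnorm(hi) * pnorm(ah) -
        .owen_t_core(ah, 1 / ai)
    }
    out[i] <- sgn * v
  }
  out
}

#' The skew-normal distribution
#'
#' Density, distribution function, quantile function, mode and random
#' generation for the skew-normal distribution with location `xi`, scale
#' `omega` and shape `alpha`. The CDF is computed as
#' `pnorm(z) - 2 * T(z, alpha)` with Owen's T function; quantiles by
#' root-finding on the CDF; the mode numerically (it has no closed form for
#' `alpha != 0`).
#'
#' @param x,q numeric vector of quantiles.
#' @param p numeric vector of probabilities.
#' @param n number of draws.
#' @param xi location parameter.
#' @param omega scale parameter, > 0.
#' @param alpha shape parameter; positive values skew right.
#' @return numeric vector (`sn_mode` returns a scalar).
#' @export
dsn <- function(x, xi = 0, omega = 1, alpha = 0) {
  stopifnot(omega > 0)
  z <- (x - xi) / omega
  2 / omega * dnorm(z) * pnorm(alpha * z)
}

#' @rdname dsn
#' @export
psn <- function(q, xi = 0, omega = 1, alpha = 0) {
  stopifnot(omega > 0)
  z <- (q - xi) / omega
  pmin(1, pmax(0, pnorm(z) - 2 * owen_t(z, alpha)))
}

#' @rdname dsn
#' @export
qsn <- function(p, xi = 0, omega = 1, alpha = 0) {
  stopifnot(omega > 0, all(p > 0), all(p < 1))
  vapply(p, function(pp) {
    f <- function(z) psn(z, 0, 1, alpha) - pp
    r <- uniroot(f, lower = -9, upper = 9, extendInt = "yes", tol = 1e-10)
    xi + omega * r$root
  }, numeric(1))
}

#' @rdname dsn
#' @export
sn_mode <- function(xi = 0, omega = 1, alpha = 0) {
  stopifnot(omega > 0)
  if (alpha == 0) return(xi)
  opt <- optimize(function(z) dsn(z, 0, 1, alpha),
                  interval = c(-1.6, 1.6), maximum = TRUE, tol = 1e-10)
  xi + omega * opt$maximum
}

#' @rdname dsn
#' @export
rsn <- function(n, xi = 0, omega = 1, alpha = 0) {
  stopifnot(omega > 0)
  # Azzalini's stochastic representation: z = delta|u0| + sqrt(1-delta^2) u1
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- rnorm(n); u1 <- rnorm(n)
  xi + omega * (delta * abs(u0) + sqrt(1 - delta^2) * u1)
}
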