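`%||%` <- function(a, b) if (is.null(a)) b else a

## Saturating Hill activation x^n / (theta^n + x^n), computed in the
## 1 / (1 + (theta/x)^n) form so that x = Inf and large n cannot overflow.
.hill <- function(x, theta, n) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- 1 / (1 + (theta / x[pos])^n)
  out
}

## Euclidean norm of the RHS, scaled by the state magnitude so the root
## tolerance is relative.
.rhsNorm <- function(f, state) {
  sqrt(sum(f^2)) / (1 + sqrt(sum(state^2)))
}

.assertScalarNonNeg <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop(sprintf("%s must be a finite non-negative scalar", what),
         call. = FALSE)
  invisible(x)
}

## Lognormal multipliers with mean exactly 1 and coefficient of variation cv.
.lognormMult <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

## Damped Newton iteration for steady states of fn (R^4 -> R^4), with
## numerical Jacobians and projection onto the non-negative orthant.
## Hand-rolled because no dedicated nonlinear-solver package is a
## dependency; dimension is 4 and fn is smooth, so this is adequate.
.newtonRoot <- function(fn, x0, tol = 1e-8, maxit = 60L) {
  x <- pmax(x0, 0)
  f <- fn(x)
  for (it in seq_len(maxit)) {
    nrm <- .rhsNorm(f, x)
    if (nrm < tol) return(list(root = x, norm = nrm, converged = TRUE))
    J <- pracma::jacobian(fn, x)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      return(list(root = x, norm = nrm, converged = FALSE))
    lambda <- 1
    repeat {
      xn <- pmax(x + lambda * step, 0)
      fn1 <- fn(xn)
      if (all(is.finite(fn1)) && .rhsNorm(fn1, xn) < nrm) break
      lambda <- lambda / 2
      if (lambda < 1e-6) break
    }
    if (lambda < 1e-6) {
      ## stalled: accept only if already essentially converged
      return(list(root = x, norm = nrm, converged = nrm < tol * 10))
    }
    x <- pmax(x + lambda * step, 0)
    f <- fn(x)
  }
  nrm <- .rhsNorm(f, x)
  list(root = x, norm = nrm, converged = nrm < tol)
}

## Deterministic number formatting for CSV output (byte-identical reruns).
.fmtNum <- function(x) {
  formatC(x, digits = 12, format = "g")
}

## Derive a reproducible child seed (kept below 2^31) from a base seed and
## a stream index.
.childSeed <- function(seed, k) {
  (as.integer(seed) %% 100000L) * 10000L + 777L * as.integer(k) %% 10000L +
    as.integer(k)
}
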