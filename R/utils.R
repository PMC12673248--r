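# Numerical helpers shared across the likelihood and metric code.

# log(1 - exp(x)) for x <= 0, accurate near both ends.
log1mexp <- function(x) {
  out <- numeric(length(x))
  small <- x > -log(2)
  out[small] <- log(-expm1(x[small]))
  out[!small] <- log1p(-exp(x[!small]))
  out
}

# Stable log(Phi(zu) - Phi(zl)) for zl < zu, vectorized. Works far in the
# tails where the plain CDF difference underflows: the interval is reflected
# so that its midpoint is non-positive, then computed as a log-space
# difference of lower-tail log-CDFs.
log_pnorm_diff <- function(zl, zu) {
  n <- max(length(zl), length(zu))
  zl <- rep_len(zl, n)
  zu <- rep_len(zu, n)
  out <- numeric(n)

  both_inf <- is.infinite(zl) & is.infinite(zu)
  full <- both_inf & zl < 0 & zu > 0
  out[full] <- 0
  empty <- zl >= zu
  out[empty & !both_inf] <- -Inf

  todo <- !both_inf & !empty
  if (any(todo)) {
    a <- zl[todo]
    b <- zu[todo]
    swap <- (a + b) > 0
    swap[is.na(swap)] <- is.infinite(b[is.na(swap)]) # b = +Inf, a finite
    tmp <- a[swap]
    a[swap] <- -b[swap]
    b[swap] <- -tmp
    la <- pnorm(a, log.p = TRUE)
    lb <- pnorm(b, log.p = TRUE)
    out[todo] <- lb + log1mexp(pmin(la - lb, 0))
  }
  out
}

# Gauss-Hermite nodes/weights (weight function exp(-x^2)) via the
# Golub-Welsch eigendecomposition of the Jacobi matrix.
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) {
    return(list(nodes = 0, weights = sqrt(pi)))
  }
  i <- seq_len(n - 1)
  jac <- matrix(0, n, n)
  off <- sqrt(i / 2)
  jac[cbind(i, i + 1)] <- off
  jac[cbind(i + 1, i)] <- off
  e <- eigen(jac, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) {
    return(m)
  }
  m + log(sum(exp(x - m)))
}

# Sum x within integer groups 1..n_groups, keeping empty groups as 0.
group_sum <- function(x, g, n_groups) {
  out <- numeric(n_groups)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s
  out
}

# Nearest odd integer to k, never below `floor_odd` (itself odd).
nearest_odd <- function(k, floor_odd = 1) {
  lo <- 2 * floor((k + 1) / 2) - 1
  hi <- lo + 2
  odd <- if (lo >= 1 && (k - lo) <= (hi - k)) lo else hi
  max(odd, floor_odd)
}

`%not_in%` <- function(x, table) !(x %in% table)
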