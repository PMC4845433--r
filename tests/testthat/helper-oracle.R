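# Independent convex-programming oracle for the weighted l1 problems, used
# to validate the homotopy solver. Proximal gradient (FISTA) on
#   min_a 1/2 ||y - X' a||^2 + sum_i pen_i |a_i|
# -- a different algorithm and code path from the implementation under test.

# one FISTA solve given precomputed Gram pieces
.fista_core <- function(G, Xty, L, pen, iters = 4000L, tol = 1e-14) {
  n <- length(Xty)
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)
  a <- numeric(n); z <- a; tk <- 1
  for (i in seq_len(iters)) {
    grad <- as.numeric(G %*% z) - Xty
    a_new <- soft(z - grad / L, pen / L)
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- a_new + ((tk - 1) / t_new) * (a_new - a)
    if (max(abs(a_new - a)) < tol && i > 50) { a <- a_new; break }
    a <- a_new; tk <- t_new
  }
  a
}

fista_lasso <- function(x, y, pen, iters = 4000L) {
  G <- tcrossprod(x)
  Xty <- as.numeric(x %*% y)
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  if (L <= 0) return(numeric(nrow(x)))
  .fista_core(G, Xty, L, pen, iters)
}

# penalized objective
lasso_obj <- function(x, y, a, pen) {
  0.5 * sum((y - as.numeric(crossprod(x, a)))^2) + sum(pen * abs(a))
}

# oracle for the constrained problem: its own bisection over the FISTA
# penalized solver (structurally parallel to, but independent of, the
# implementation under test)
fista_constrained <- function(x, y, w, epsilon, steps = 50L) {
  if (sqrt(sum(y^2)) <= epsilon) return(numeric(nrow(x)))
  G <- tcrossprod(x)
  Xty <- as.numeric(x %*% y)
  Lip <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  res_of <- function(a) sqrt(sum((y - as.numeric(crossprod(x, a)))^2))
  lam_hi <- max(abs(Xty) / w)
  lam_lo <- min(abs(Xty)[abs(Xty) > 0] / w[abs(Xty) > 0]) * 1e-10
  best <- NULL
  lo <- log(lam_lo); hi <- log(lam_hi)
  for (i in seq_len(steps)) {
    mid <- exp((lo + hi) / 2)
    a <- .fista_core(G, Xty, Lip, mid * w)
    if (res_of(a) <= epsilon) {
      best <- a; lo <- (lo + hi) / 2
    } else hi <- (lo + hi) / 2
  }
  best
}
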