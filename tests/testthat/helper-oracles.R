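# Independent numerical oracles used by the tests. These deliberately avoid
# the package's matrix-exponential code path.

# Fixed-step classical RK4 integration of dx/dt = A x from x0 over time t.
# For a linear system the RK4 step is the degree-4 Taylor matrix, applied
# n_steps times by repeated squaring (n_steps a power of two).
rk4_propagate <- function(A, x0, t, n_steps = 2^17) {
  h <- t / n_steps
  n <- nrow(A)
  hA <- h * A
  M <- diag(n) + hA + hA %*% hA / 2 + hA %*% hA %*% hA / 6 +
    hA %*% hA %*% hA %*% hA / 24
  k <- log2(n_steps)
  stopifnot(k == round(k))
  for (i in seq_len(k)) M <- M %*% M
  as.vector(M %*% x0)
}

# oracle concentrations for a single dose at t = 0, constant clearances
oracle_conc <- function(p, dose, times, mult = 1) {
  A <- build_system(p, mult, mult)
  x0 <- numeric(nrow(A))
  x0[1] <- dose * p$F
  pc <- p$NTR + 2
  mc <- p$NTR + 5
  t(vapply(times, function(tt) {
    x <- rk4_propagate(A, x0, tt)
    c(parent = x[pc] / p$V1_P, metab = x[mc] / p$V1_M)
  }, numeric(2)))
}

# random valid parameter set (for property tests; caller fixes the RNG seed)
random_params <- function() {
  structural_params(
    CL_P = runif(1, 0.5, 10), V1_P = runif(1, 20, 300),
    V2_P = runif(1, 100, 3000), V3_P = runif(1, 1000, 30000),
    Q2_P = runif(1, 1, 60), Q3_P = runif(1, 0.5, 10),
    CL_M = runif(1, 1, 15), V1_M = runif(1, 50, 800),
    V2_M = runif(1, 500, 20000), Q_M = runif(1, 0.5, 10),
    MTT = runif(1, 1, 6), NTR = sample(0:6, 1), KA = runif(1, 0.2, 2))
}

# Gauss-Hermite nodes/weights by Golub-Welsch (physicists' convention:
# integral of f(x) exp(-x^2) dx = sum w_i f(x_i))
gauss_hermite <- function(n) {
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(1:(n - 1), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# exhaustive terminal-slope selection (independent of fit_lambda_z)
brute_lambda_z <- function(times, conc) {
  imax <- which.max(conc)
  keep <- seq_along(times) > imax & conc > 0
  tt <- times[keep]; cc <- log(conc[keep])
  m <- length(tt)
  if (m < 3) return(NULL)
  best <- NULL
  for (n in 3:m) {
    i <- (m - n + 1):m
    fit <- stats::lm(cc[i] ~ tt[i])
    sl <- coef(fit)[2]
    if (!is.finite(sl) || sl >= 0) next
    ar2 <- summary(fit)$adj.r.squared
    if (is.null(best) || ar2 > best$adj_r2 + 1e-12 ||
        (abs(ar2 - best$adj_r2) <= 1e-12 && n > best$n)) {
      best <- list(lambda_z = -unname(sl), n = n, adj_r2 = ar2)
    }
  }
  best
}

# small fast parameter set (1-cmt parent + 1-cmt metabolite limit) used by
# estimation toys
toy_params <- function(CL_P = 5, V1_P = 50, CL_M = 8, V1_M = 60, KA = 1) {
  structural_params(CL_P = CL_P, V1_P = V1_P, V2_P = 1, V3_P = 1,
                    Q2_P = 0, Q3_P = 0, CL_M = CL_M, V1_M = V1_M,
                    V2_M = 1, Q_M = 0, MTT = 1, NTR = 0L, KA = KA)
}

fixture_params <- function() bdq_like_params()
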