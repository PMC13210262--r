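# Independent oracles used across the suite. Everything here is written
# directly from definitions (brute force, quadrature, ODE integration) and
# never calls the package's own implementation of the quantity it checks.

# Gauss-Hermite nodes/weights (weight exp(-x^2)) by Golub-Welsch
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# direct transcription of the per-subject -2 log joint density
oracle_neg2_joint <- function(pop, eta, dose, w, t, y) {
  om <- eta_cov(pop)
  v <- pop$tv_v * exp(eta[1]) * (w / pop$ref_weight)^pop$exp_v
  cl <- pop$tv_cl * exp(eta[2]) * (w / pop$ref_weight)^pop$exp_cl
  ka <- pop$tv_ka * exp(eta[3])
  ke <- cl / v
  f <- dose * ka / (v * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
  g <- pop$sigma_prop * f
  sum(log(2 * pi * g^2) + (y - f)^2 / g^2) +
    drop(t(eta) %*% solve(om) %*% eta) + log(det(2 * pi * om))
}

# adaptive Gauss-Hermite -2 log marginal likelihood for one subject
oracle_agq_neg2ll <- function(pop, dose, w, t, y, nodes = 9) {
  h <- function(eta) oracle_neg2_joint(pop, eta, dose, w, t, y)
  opt <- stats::optim(c(0, 0, 0), h, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  mode <- opt$par
  d <- 1e-4
  H <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3) {
    ea <- eb <- rep(0, 3); ea[a] <- d; eb[b] <- d
    H[a, b] <- (h(mode + ea + eb) - h(mode + ea - eb) -
                h(mode - ea + eb) + h(mode - ea - eb)) / (4 * d^2)
  }
  H <- (H + t(H)) / 2
  Lc <- t(chol(solve(H / 2)))
  gh <- gauss_hermite(nodes)
  idx <- as.matrix(expand.grid(1:nodes, 1:nodes, 1:nodes))
  total <- 0
  for (r in seq_len(nrow(idx))) {
    z <- gh$nodes[idx[r, ]]
    wgt <- prod(gh$weights[idx[r, ]])
    eta <- mode + sqrt(2) * drop(Lc %*% z)
    total <- total + wgt * exp(-0.5 * h(eta) + sum(z^2))
  }
  -2 * log(total * sqrt(2)^3 * det(Lc))
}

oracle_agq_dataset <- function(pop, dataset, nodes = 9) {
  sum(vapply(unique(dataset$ID), function(id) {
    sub <- dataset[dataset$ID == id, ]
    obs <- sub[sub$EVID == 0, ]
    oracle_agq_neg2ll(pop, sub$AMT[sub$EVID == 1], sub$WT[1],
                      obs$TIME, obs$DV, nodes = nodes)
  }, numeric(1)))
}

# all-pairs Cliff's delta
oracle_cliffs_delta <- function(x, y) {
  s <- 0
  for (xi in x) s <- s + sum(xi > y) - sum(xi < y)
  s / (length(x) * length(y))
}

# exhaustive-threshold two-sample KS D
oracle_ks_D <- function(x, y) {
  thr <- c(x, y)
  max(vapply(thr, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# two-state first-order-absorption ODE solved numerically
oracle_conc_ode <- function(times, dose, v, cl, ka) {
  rhs <- function(t, state, parms) {
    list(c(-ka * state[1], ka * state[1] - (cl / v) * state[2]))
  }
  out <- deSolve::lsoda(c(depot = dose, central = 0), c(0, times), rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  unname(out[-1, "central"] / v)
}
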