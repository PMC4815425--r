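# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive each quantity from its definition rather than
# calling the code paths under test.

# Restricted log-likelihood of the intercept-only random-effects model.
restricted_ll <- function(tau2, theta, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * theta) / sum(w)
  -0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (theta - mu)^2))
}

# Two-stage grid search of the restricted likelihood (coarse 1e-2 over
# [0, upper], then 1e-5 around the coarse optimum).
reml_grid_oracle <- function(theta, v, upper = 10) {
  coarse <- seq(0, upper, by = 1e-2)
  ll <- vapply(coarse, restricted_ll, numeric(1), theta = theta, v = v)
  best <- coarse[which.max(ll)]
  fine <- seq(max(0, best - 2e-2), best + 2e-2, by = 1e-5)
  ll2 <- vapply(fine, restricted_ll, numeric(1), theta = theta, v = v)
  fine[which.max(ll2)]
}

# Literal step-up definition of the BH adjustment.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  po <- p[o]
  qo <- vapply(seq_len(m), function(i) {
    j <- i:m
    min(pmin(1, (m / j) * po[j]))
  }, numeric(1))
  q <- numeric(m)
  q[o] <- qo
  q
}

# Generalized least squares at a fixed tau^2 (meta-regression oracle).
gls_oracle <- function(y, v, X, tau2) {
  W <- diag(1 / (v + tau2))
  V <- solve(t(X) %*% W %*% X)
  b <- V %*% t(X) %*% W %*% y
  list(beta = drop(b), vcov = V)
}

# Brute-force effect size and variance from raw replicates.
lnr_oracle <- function(treated, control) {
  y1 <- mean(treated); y2 <- mean(control)
  list(lnr = log(y1 / y2),
       v = var(treated) / (length(treated) * y1^2) +
         var(control) / (length(control) * y2^2))
}

# Random effect-size fixture for one gene.
random_effects_fixture <- function(k, seed) {
  set.seed(seed)
  v <- runif(k, 0.02, 0.4)
  theta <- rnorm(k, rnorm(1, 0, 0.5), sqrt(0.1 + v))
  list(theta = theta, v = v)
}

# Small annotated two-study collection built in code (no files).
toy_two_study <- function(seed = 1, g = 6) {
  set.seed(seed)
  mk <- function(study, part, method, n = 2) {
    ids <- sprintf("%s_%s%d", study, c(rep("t", n), rep("c", n)),
                   c(seq_len(n), seq_len(n)))
    list(ids = ids,
         sheet = data.frame(sample_id = ids, study_id = study,
                            arm = c(rep("treated", n), rep("control", n)),
                            part = part, method = method,
                            replicate_index = c(seq_len(n), seq_len(n))))
  }
  a <- mk("ST1", "root", "water_withholding")
  b <- mk("ST2", "shoot", "mannitol")
  mat <- matrix(rnorm(g * 8, 8, 0.5), g, 8,
                dimnames = list(sprintf("g%02d", seq_len(g)),
                                c(a$ids, b$ids)))
  expression_study(mat, rbind(a$sheet, b$sheet))
}
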