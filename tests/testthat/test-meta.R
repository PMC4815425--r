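test_that("DerSimonian-Laird tau^2 matches its closed form", {
  # no heterogeneity
  expect_equal(dl_tau2(c(1, 1, 1), c(0.5, 1, 2)), 0)
  # hand-evaluated: w=(1,1), mu=1, Q=2, c = 2 - 2/2 = 1 -> tau2 = 1
  expect_equal(dl_tau2(c(0, 2), c(1, 1)), 1)
  # truncation branch: Q = 0.005 < K-1
  expect_equal(dl_tau2(c(0, 0.1), c(1, 1)), 0)
  # single contrast: zero with a warning
  expect_warning(t2 <- dl_tau2(0.4, 0.1), "single")
  expect_equal(t2, 0)
})

test_that("REML tau^2 agrees with a grid search of the restricted likelihood", {
  for (i in 1:25) {
    k <- sample(2:6, 1)
    fx <- random_effects_fixture(k, seed = 100 + i)
    est <- reml_tau2(fx$theta, fx$v)
    expect_lt(abs(est - reml_grid_oracle(fx$theta, fx$v)), 1e-4)
  }
  # degenerate: identical effects -> boundary solution at 0
  expect_equal(as.numeric(reml_tau2(c(0.3, 0.3, 0.3), c(0.1, 0.1, 0.1))), 0)
})

test_that("REML tau^2 is scale equivariant", {
  fx <- random_effects_fixture(5, seed = 7)
  base <- as.numeric(reml_tau2(fx$theta, fx$v))
  for (cc in c(0.5, 2, 5)) {
    centred <- fx$theta - mean(fx$theta)
    scaled <- as.numeric(reml_tau2(mean(fx$theta) + cc * centred,
                                   cc^2 * fx$v))
    expect_equal(scaled, cc^2 * base, tolerance = 1e-6)
  }
})

test_that("DL and REML agree with an independent reference implementation", {
  skip_if_not_installed("metafor")
  for (i in 1:10) {
    k <- sample(3:8, 1)
    fx <- random_effects_fixture(k, seed = 300 + i)
    ref_dl <- metafor::rma(yi = fx$theta, vi = fx$v, method = "DL")
    expect_equal(dl_tau2(fx$theta, fx$v), ref_dl$tau2, tolerance = 1e-8)
    ref_reml <- metafor::rma(yi = fx$theta, vi = fx$v, method = "REML",
                             control = list(threshold = 1e-10))
    expect_equal(as.numeric(reml_tau2(fx$theta, fx$v)), ref_reml$tau2,
                 tolerance = 1e-6)
  }
})

test_that("the random-effects fit reproduces the weighted-mean closed forms", {
  cfg <- run_config(tau2_method_meta = "dl")
  # K=1 passes through: mu = theta, s2 = v
  eff1 <- data.frame(gene_id = "g", contrast_id = "c1", lnr = 0.5, v = 0.04)
  f1 <- suppressWarnings(suppressMessages(fit_random_effects(eff1, cfg)))
  expect_equal(f1$mu_hat, 0.5)
  expect_equal(f1$se_mu^2, 0.04)
  expect_true(f1$single_contrast)

  # hand-evaluated: theta=(1,3), v=(1,1) -> tau2 = 1 (DL), w_i = 1/2,
  # mu = 2, s2 = 1/sum(w) = 1, CI = 2 +/- 12.706 * 1 (t_{0.025}[1]).
  eff2 <- data.frame(gene_id = "g", contrast_id = c("c1", "c2"),
                     lnr = c(1, 3), v = c(1, 1))
  f2 <- suppressMessages(fit_random_effects(eff2, cfg))
  expect_equal(f2$tau2, 1)
  expect_equal(f2$mu_hat, 2)
  expect_equal(f2$ci_lo, 2 - qt(0.975, 1) * f2$se_mu)
  expect_equal(qt(0.975, 1), 12.7062047, tolerance = 1e-6)

  # the same fixture with tau2 held at 0 is the classic fixed-effect case:
  # equal weights, mu = 2, s2 = 0.5, t-multiplier 12.706
  f2fe <- suppressMessages(fit_random_effects(eff2, cfg, tau2_fixed = 0))
  expect_equal(f2fe$mu_hat, 2)
  expect_equal(f2fe$se_mu^2, 0.5)
  expect_equal(f2fe$ci_hi, 2 + qt(0.975, 1) * sqrt(0.5))

  # forcing tau2 = 0 (no heterogeneity) reproduces the fixed-effect estimate
  eff3 <- data.frame(gene_id = "g", contrast_id = c("c1", "c2", "c3"),
                     lnr = c(0.2, 0.21, 0.19), v = c(0.04, 0.01, 0.02))
  f3 <- suppressMessages(fit_random_effects(eff3, cfg))
  expect_equal(f3$tau2, 0)  # Q below K-1 truncates
  w <- 1 / eff3$v
  expect_equal(f3$mu_hat, sum(w * eff3$lnr) / sum(w))
  expect_equal(f3$se_mu^2, 1 / sum(w))

  # equal v and tau2 = 0 -> mu is the arithmetic mean
  eff4 <- data.frame(gene_id = "g", contrast_id = c("c1", "c2"),
                     lnr = c(0.1, 0.1), v = c(1, 1))
  f4 <- suppressMessages(fit_random_effects(eff4, cfg))
  expect_equal(f4$mu_hat, 0.1)
  expect_equal(f4$se_mu^2, 0.5)
})

test_that("precision dominance and permutation invariance hold", {
  set.seed(41)
  eff <- do.call(rbind, lapply(1:30, function(g) {
    k <- sample(2:8, 1)
    fx <- random_effects_fixture(k, seed = 500 + g)
    data.frame(gene_id = sprintf("g%02d", g),
               contrast_id = sprintf("c%d", seq_len(k)),
               lnr = fx$theta, v = fx$v)
  }))
  cfg <- run_config()
  fit <- suppressMessages(fit_random_effects(eff, cfg))
  by_gene <- split(eff, eff$gene_id)
  for (g in names(by_gene)) {
    row <- fit[fit$gene_id == g, ]
    expect_lte(row$se_mu^2,
               min(by_gene[[g]]$v + row$tau2) + 1e-12)
  }
  perm <- eff[sample(nrow(eff)), ]
  fit_perm <- suppressMessages(fit_random_effects(perm, cfg))
  fit_perm <- fit_perm[match(fit$gene_id, fit_perm$gene_id), ]
  rownames(fit_perm) <- NULL
  expect_equal(fit_perm$mu_hat, fit$mu_hat)
  expect_equal(fit_perm$tau2, fit$tau2)
  expect_equal(fit_perm$p, fit$p)
})

test_that("normal and Student-t test references are both available", {
  eff <- data.frame(gene_id = "g", contrast_id = sprintf("c%d", 1:5),
                    lnr = c(0.4, 0.5, 0.3, 0.45, 0.35),
                    v = rep(0.01, 5))
  fn <- suppressMessages(fit_random_effects(eff, run_config()))
  ft <- suppressMessages(
    fit_random_effects(eff, run_config(test_distribution = "student_t")))
  expect_equal(fn$z, ft$z)
  expect_equal(fn$p, 2 * pnorm(-abs(fn$z)))
  expect_equal(ft$p, 2 * pt(-abs(ft$z), 4))
  expect_gt(ft$p, fn$p)  # heavier tails
  fci <- suppressMessages(
    fit_random_effects(eff, run_config(ci_distribution = "normal")))
  expect_equal(fci$ci_hi - fci$mu_hat, qnorm(0.975) * fci$se_mu)
})

test_that("mean-effect and tau^2 recovery on synthetic data at K = 8", {
  set.seed(77)
  G <- 800; K <- 8; tau2 <- 0.05
  mu <- rnorm(G, 0, 0.3)
  v <- matrix(runif(G * K, 0.005, 0.02), G, K)
  eff <- data.frame(
    gene_id = rep(sprintf("g%04d", 1:G), each = K),
    contrast_id = rep(sprintf("c%d", 1:K), G),
    lnr = as.vector(t(mu + matrix(rnorm(G * K, 0, sqrt(tau2 + v)), G, K))),
    v = as.vector(t(v)))
  fit <- suppressMessages(fit_random_effects(eff, run_config()))
  expect_lt(abs(mean(fit$mu_hat - mu)), 0.02)
  expect_lt(abs(median(fit$tau2) / tau2 - 1), 0.25)
})
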