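test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(61)
  for (i in 1:1000) {
    m <- sample(1:40, 1)
    p <- runif(m)^sample(c(1, 2, 4), 1)   # mix of flat and signal-like
    p[p == 0] <- 1e-12
    expect_identical(bh_adjust(p), bh_bruteforce(p))
  }
})

test_that("BH validates its input and preserves ordering properties", {
  expect_error(bh_adjust(c(0.1, 0, 0.2)), "index 2")
  expect_error(bh_adjust(c(0.1, 1.3)), "index 2")
  expect_error(bh_adjust(c(NA, 0.1)), "index 1")
  set.seed(62)
  p <- runif(200)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in raw p
  # discoveries never increase when alpha tightens
  expect_lte(sum(q < 0.01), sum(q < 0.05))
})

fake_fits <- function(mu, lo, hi, p, id = NULL) {
  data.frame(gene_id = if (is.null(id)) sprintf("g%02d", seq_along(mu))
             else id,
             mu_hat = mu, ci_lo = lo, ci_hi = hi, p = p)
}

test_that("gene calls follow the sign/FDR rule and ci_gap definition", {
  fits <- fake_fits(mu = c(0.3, -0.4, 0.2, 1.5),
                    lo = c(0.1, -0.6, -0.1, -0.2),
                    hi = c(0.5, -0.2, 0.5, 3.2),
                    p = c(1e-4, 1e-4, 0.5, 0.4))
  calls <- suppressMessages(classify_genes(fits, alpha = 0.05))
  expect_identical(calls$call, c("up", "down", "ns", "ns"))
  expect_equal(calls$ci_gap, c(0.1, 0.2, 0, 0))
  expect_true(all((calls$ci_gap == 0) ==
                    (calls$ci_lo <= 0 & calls$ci_hi >= 0)))
  # q = 0.2 stays ns regardless of a large mean
  fits2 <- fake_fits(0.9, 0.1, 1.7, 0.2)
  expect_identical(suppressMessages(classify_genes(fits2))$call, "ns")
})

test_that("calls agree with CI exclusion when test and CI share a reference", {
  set.seed(63)
  G <- 300; K <- 6
  theta <- matrix(rnorm(G * K, rep(rnorm(G, 0, 0.4), K), 0.3), G, K)
  eff <- data.frame(gene_id = rep(sprintf("g%03d", 1:G), K),
                    contrast_id = rep(sprintf("c%d", 1:K), each = G),
                    lnr = as.vector(theta), v = 0.04)
  cfg <- run_config(test_distribution = "student_t",
                    ci_distribution = "student_t")
  calls <- suppressMessages(
    classify_genes(fit_random_effects(eff, cfg), alpha = 0.05))
  # every called gene's interval excludes zero (BH threshold <= alpha)
  called <- calls$call != "ns"
  expect_true(all(calls$ci_gap[called] > 0))
})

test_that("forest orderings follow the two published sorting schemes", {
  fits <- fake_fits(mu = c(2.0, 0.01, 0.5, -0.8),
                    lo = c(-0.5, 0.001, 0.1, -1.0),
                    hi = c(4.5, 0.019, 0.9, -0.6),
                    p = c(0.2, 0.01, 0.01, 0.001),
                    id = c("gA", "gB", "gC", "gD"))
  calls <- suppressMessages(classify_genes(fits))
  by_gap <- sort_forest(calls, "ci_gap")
  # CI-excluders first by descending gap (gD: 0.6, gC: 0.1, gB: 0.001),
  # then the spanning gene gA despite its big mean
  expect_identical(by_gap$gene_id, c("gD", "gC", "gB", "gA"))
  by_mu <- sort_forest(calls, "mu_magnitude")
  expect_identical(by_mu$gene_id, c("gA", "gD", "gC", "gB"))

  # random tables: mu ordering equals the (-|mu|, gene_id) key sort
  set.seed(64)
  mu <- round(rnorm(50, 0, 1), 1)   # rounding forces ties
  rfits <- fake_fits(mu, mu - 0.2, mu + 0.2, runif(50, 0.001, 1))
  rcalls <- suppressMessages(classify_genes(rfits))
  got <- sort_forest(rcalls, "mu_magnitude")$gene_id
  want <- rcalls$gene_id[order(-abs(rcalls$mu_hat), rcalls$gene_id,
                               method = "radix")]
  expect_identical(got, want)
})

test_that("set comparison reports intersections, support and small effects", {
  meta <- suppressMessages(classify_genes(fake_fits(
    mu = c(0.4, 0.02, -0.6, 0.1),
    lo = c(0.2, 0.01, -0.9, -0.1),
    hi = c(0.6, 0.03, -0.3, 0.3),
    p = c(1e-5, 1e-5, 1e-5, 0.9),
    id = c("a", "b", "c", "d"))))
  mk_calls <- function(sig) {
    data.frame(gene_id = c("a", "b", "c", "d"),
               q = ifelse(c("a", "b", "c", "d") %in% sig, 0.01, 0.9))
  }
  cmp <- compare_gene_sets(meta, list(C1 = mk_calls(c("a", "c")),
                                      C2 = mk_calls(c("a", "d")),
                                      C3 = mk_calls(character())))
  expect_identical(cmp$per_contrast$n_deg, c(2L, 2L, 0L))
  expect_identical(cmp$per_contrast$n_intersect_meta, c(2L, 1L, 0L))
  expect_identical(sort(cmp$both), c("a", "c"))
  expect_identical(cmp$meta_only, "b")
  expect_identical(cmp$t_only, "d")
  # gene a found by two contrasts
  expect_identical(cmp$support$n_contrasts[cmp$support$gene_id == "a"], 2L)
  # the meta-only gene has an extremely small mean effect and is flagged
  expect_true(cmp$meta_only_small$small_effect)
  # mismatched universes are fatal
  expect_error(
    compare_gene_sets(meta, list(C1 = mk_calls("a")[1:3, ])), "universe")
})
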