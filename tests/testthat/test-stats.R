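make_outcome <- function(r, coefs = NULL, axis = "valence", state = "high") {
  n <- length(r)
  out <- data.frame(participant = seq_len(n), r = r, mse = 1 - r^2,
                    intercept = 0,
                    theta = if (is.null(coefs)) rnorm(n) else coefs[, 1],
                    alpha = if (is.null(coefs)) rnorm(n) else coefs[, 2],
                    beta = if (is.null(coefs)) rnorm(n) else coefs[, 3],
                    gamma = if (is.null(coefs)) rnorm(n) else coefs[, 4],
                    defined = TRUE)
  attr(out, "axis") <- axis
  attr(out, "state") <- state
  class(out) <- c("regression_outcome", "data.frame")
  out
}

test_that("Fisher z, t and p match the closed-form oracle to 1e-10", {
  r <- c(0.1, 0.2, 0.3)
  want <- fisher_t_oracle(r)
  expect_equal(want$z, c(0.100335, 0.202733, 0.309520), tolerance = 1e-5)
  gs <- group_significance(list(c1 = make_outcome(r)))
  expect_equal(gs$t, want$t, tolerance = 1e-10)
  expect_equal(gs$p_raw, want$p, tolerance = 1e-10)
  expect_equal(gs$mean_r, want$mean_r, tolerance = 1e-10)
})

test_that("all-zero correlations give t = 0 and p = 0.5", {
  # zero variance across folds: p decided by the sign of the mean
  expect_warning(
    gs <- group_significance(list(c1 = make_outcome(c(0, 0, 0, 0)))),
    "zero variance")
  expect_equal(gs$t, 0)
  expect_equal(gs$p_raw, 0.5)
  expect_false(gs$significant)
  gs2 <- group_significance(list(c1 = make_outcome(c(-1e-4, 0, 1e-4, 2e-5))))
  expect_equal(gs2$p_raw,
               pt(gs2$t, df = 3, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("back-transformed mean of equal correlations is exact", {
  # equal folds also have zero z variance, which is warned about
  expect_warning(
    gs <- group_significance(list(c1 = make_outcome(c(0.5, 0.5, 0.5)))),
    "zero variance")
  expect_equal(gs$mean_r, 0.5, tolerance = 1e-12)
})

test_that("perfect fold correlations are clamped with a warning", {
  expect_warning(gs <- group_significance(list(c1 = make_outcome(c(1, 0.5, 0.6)))),
                 "clamped")
  expect_true(is.finite(gs$t))
  expect_true(gs$mean_r < 1)
})

test_that("Holm adjustment matches hand-worked and trivial cases", {
  h1 <- holm_bonferroni(0.01, alpha = 0.025)
  expect_equal(h1$adjusted, 0.01)
  expect_true(h1$reject)
  h3 <- holm_bonferroni(c(0.001, 0.02, 0.04), alpha = 0.05)
  expect_equal(h3$adjusted, c(0.003, 0.04, 0.04), tolerance = 1e-12)
  expect_true(all(h3$reject))
  # with 7 families the smallest p is multiplied by 7
  p7 <- c(0.004, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7)
  h7 <- holm_bonferroni(p7, alpha = 0.025)
  expect_equal(h7$adjusted[1], 7 * 0.004, tolerance = 1e-12)
  expect_equal(h7$reject, c(FALSE, rep(FALSE, 6)))  # 0.028 > 0.025
  expect_error(holm_bonferroni(c(0.5, 1.2)), "0, 1")
})

test_that("Holm matches brute-force enumeration and p.adjust on random sets", {
  set.seed(42)
  for (i in 1:40) {
    m <- sample(1:5, 1)
    p <- round(runif(m), 3)
    alpha <- sample(c(0.01, 0.025, 0.05), 1)
    got <- holm_bonferroni(p, alpha)
    want <- holm_brute_force(p, alpha)
    expect_equal(got$adjusted, want$adjusted, tolerance = 1e-12)
    expect_equal(got$reject, want$reject)
    expect_equal(got$adjusted, unname(p.adjust(p, "holm")),
                 tolerance = 1e-12)
    expect_true(all(got$adjusted >= p - 1e-15))
  }
})

test_that("group significance corrects within the family and keeps order", {
  set.seed(2)
  outs <- list(a = make_outcome(c(0.6, 0.55, 0.62, 0.58)),
               b = make_outcome(c(0.01, -0.03, 0.02, 0.05)),
               c = make_outcome(c(0.2, 0.25, 0.15, 0.22)))
  gs <- group_significance(outs, alpha = 0.025)
  expect_equal(gs$cluster, c("a", "b", "c"))
  expect_equal(gs$p_holm,
               holm_brute_force(gs$p_raw, 0.025)$adjusted,
               tolerance = 1e-12)
  expect_true(all(gs$p_holm >= gs$p_raw))
  expect_true(gs$significant[1])
  expect_false(gs$significant[2])
})

test_that("undefined folds are dropped from the family test", {
  oc <- make_outcome(c(0.3, 0.35, 0.4, NA))
  oc$defined[4] <- FALSE
  gs <- group_significance(list(c1 = oc))
  expect_equal(gs$n_folds, 3L)
  expect_error(group_significance(list(c1 = make_outcome(c(0.1, 0.2)))),
               "3 usable folds")
})

test_that("coefficient summaries report band order, mean and sample SD", {
  co <- cbind(c(-0.1, -0.14), c(0.2, 0.2), c(0, 0.02), c(-0.05, 0.05))
  oc <- make_outcome(c(0.3, 0.4), coefs = co)
  cs <- coefficient_summary(oc)
  expect_equal(cs$band, c("theta", "alpha", "beta", "gamma"))
  expect_equal(cs$mean[1], -0.12, tolerance = 1e-12)
  expect_equal(cs$sd[1], sd(c(-0.1, -0.14)), tolerance = 1e-12)
  expect_equal(cs$sd[1], 0.0283, tolerance = 1e-3)
  expect_equal(cs$sd[2], 0)
})
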