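test_that("ordered quantile normalization maps ranks to normal quantiles", {
  expect_equal(order_quantile_normalize(c(1, 2, 3)),
               qnorm(c(0.25, 0.5, 0.75)), tolerance = 1e-12)
  expect_equal(round(order_quantile_normalize(c(1, 2, 3)), 4),
               c(-0.6745, 0, 0.6745))

  # median of an odd-length tie-free vector maps to 0
  set.seed(1)
  x <- sample(stats::rnorm(21))
  expect_equal(order_quantile_normalize(x)[which(x == stats::median(x))], 0)

  # strict monotonicity
  x <- sort(stats::rexp(50))
  expect_true(all(diff(order_quantile_normalize(x)) > 0))

  # NA passes through, ranks computed over finite values
  y <- order_quantile_normalize(c(5, NA, 1, 3))
  expect_true(is.na(y[2]))
  expect_equal(y[c(1, 3, 4)], qnorm(c(3, 1, 2) / 4), tolerance = 1e-12)

  expect_error(order_quantile_normalize(c(2, 2, 2)), "identical")
  expect_error(order_quantile_normalize(c(1, 2)), "3 finite")
})

test_that("normalized output looks normal for tie-free data", {
  set.seed(42)
  for (raw in list(stats::rexp(80), stats::rcauchy(120),
                   stats::runif(60)^3)) {
    z <- order_quantile_normalize(raw)
    expect_gt(stats::shapiro.test(z)$p.value, 0.01)
  }
})

test_that("metrics model recovers noise-free coefficients exactly", {
  set.seed(2)
  n <- 60
  tab <- data.frame(aspl = stats::runif(n, 1, 8), bc = stats::runif(n),
                    nc = stats::runif(n, 1, 20))
  tab$phylop_norm <- 0.5 - 1.2 * tab$aspl + 3 * tab$bc + 0.1 * tab$nc
  res <- suppressWarnings(fit_metrics_model(tab))  # lm warns on R2 = 1
  est <- stats::setNames(res$coefficients$estimate, res$coefficients$term)
  expect_equal(unname(est[c("(Intercept)", "aspl", "bc", "nc")]),
               c(0.5, -1.2, 3, 0.1), tolerance = 1e-6)
  expect_equal(res$r_squared, 1, tolerance = 1e-9)
})

test_that("model F and R2 agree with a normal-equations oracle", {
  set.seed(3)
  n <- 200
  tab <- data.frame(aspl = stats::rnorm(n, 4), bc = stats::runif(n),
                    nc = stats::rnorm(n, 10))
  tab$phylop_norm <- -0.3 * tab$aspl + 1.1 * tab$bc + stats::rnorm(n)
  res <- fit_metrics_model(tab)

  X <- cbind(1, tab$aspl, tab$bc, tab$nc)
  y <- tab$phylop_norm
  beta <- solve(t(X) %*% X, t(X) %*% y)
  rss <- sum((y - X %*% beta)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  p <- ncol(X) - 1
  f_stat <- (tss - rss) / p / (rss / (n - p - 1))
  expect_equal(res$r_squared, r2, tolerance = 1e-8)
  expect_equal(res$F, f_stat, tolerance = 1e-8)
  expect_equal(res$df_model, p)
  expect_equal(res$df_resid, n - p - 1)
})

test_that("Cohen's f is consistent with R2", {
  expect_equal(cohens_f(0.0855), 0.3058, tolerance = 5e-4)
  for (r2 in c(0, 0.01, 0.0855, 0.5, 0.99)) {
    f <- cohens_f(r2)
    expect_equal(f^2 * (1 - r2), r2, tolerance = 1e-12)
  }
  set.seed(4)
  tab <- data.frame(aspl = stats::rnorm(50), bc = stats::runif(50),
                    nc = stats::rnorm(50))
  tab$phylop_norm <- tab$aspl + stats::rnorm(50)
  res <- fit_metrics_model(tab)
  expect_equal(res$cohens_f^2 * (1 - res$r_squared), res$r_squared,
               tolerance = 1e-12)
})

test_that("effect magnitude ladder covers the extended range", {
  expect_equal(effect_magnitude(c(0.1, -0.3, 0.6, 1.0, -1.5, 2.5)),
               c("negligible", "small", "medium", "large", "very large",
                 "huge"))
})

test_that("category model detects planted class differences", {
  set.seed(5)
  n <- 200
  tab <- data.frame(
    phylop_norm = c(stats::rnorm(n, 1), stats::rnorm(n, 0),
                    stats::rnorm(n, -1)),
    label = rep(c("H", "I", "P"), each = n))
  res <- fit_category_model(tab)
  expect_lt(res$model$p, 1e-10)
  expect_true(all(res$contrasts$p_adjusted < 0.05))
  hp <- res$contrasts[res$contrasts$pair == "H - P", ]
  expect_equal(hp$cohens_d, 2, tolerance = 0.3)
  expect_true(hp$magnitude %in% c("very large", "huge"))
  expect_equal(nrow(res$contrasts), 3)
})

test_that("identical values split across labels give F of zero", {
  y <- stats::rnorm(50)
  tab <- data.frame(phylop_norm = rep(y, 3),
                    label = rep(c("H", "I", "P"), each = 50))
  res <- fit_category_model(tab)
  expect_equal(res$model$F, 0, tolerance = 1e-20)
})

test_that("category model input validation", {
  expect_error(fit_category_model(
    data.frame(phylop_norm = stats::rnorm(10),
               label = rep(c("H", "uncertain"), 5))), "uncertain")
  expect_error(fit_category_model(
    data.frame(phylop_norm = stats::rnorm(3), label = c("H", "H", "I"))),
    ">= 2 nodes")
})

test_that("hibernation model finds a planted direction effect with power", {
  set.seed(6)
  reps <- 50
  rejected <- 0
  for (r in seq_len(reps)) {
    tab <- data.frame(
      phylop_norm = c(stats::rnorm(9, 0.5, 0.2), stats::rnorm(9, 0, 0.2)),
      label = sample(rep(c("I", "P"), 9)),
      direction = rep(c("accelerated", "decelerated"), each = 9))
    res <- fit_hibernation_model(tab)
    dir_p <- res$contrasts$p_adjusted[res$contrasts$factor == "direction"]
    rejected <- rejected + (dir_p < 0.05)
  }
  expect_gte(rejected / reps, 0.9)
})

test_that("hibernation model is calibrated when directions are shuffled", {
  set.seed(7)
  reps <- 200
  rejected <- 0
  for (r in seq_len(reps)) {
    tab <- data.frame(
      phylop_norm = stats::rnorm(18),
      label = sample(rep(c("I", "P"), 9)),
      direction = sample(rep(c("accelerated", "decelerated"), 9)))
    res <- fit_hibernation_model(tab)
    dir_p <- res$contrasts$p_adjusted[res$contrasts$factor == "direction"]
    rejected <- rejected + (dir_p < 0.05)
  }
  ci <- stats::qbinom(c(0.025, 0.975), reps, 0.05)
  expect_gte(rejected, ci[1])
  expect_lte(rejected, ci[2])
})

test_that("a single-level factor is dropped with a warning, not silently", {
  tab <- data.frame(phylop_norm = stats::rnorm(12),
                    label = rep(c("I", "P"), 6),
                    direction = "accelerated")
  expect_warning(res <- fit_hibernation_model(tab), "direction")
  expect_true(all(res$contrasts$factor == "label"))
})
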