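test_that("contract violations are rejected", {
  y <- c(0, 0, 1, 1)
  expect_error(fit_logistic(matrix(1, 4, 1), y), "constant")
  expect_error(fit_logistic(matrix(rnorm(4), 4, 1), c(1, 1, 1, 1)),
               "single class")
  expect_error(fit_logistic(matrix(numeric(0), 4, 0), y), "empty")
})

test_that("an uninformative predictor recovers the null log-likelihood", {
  # y alternates; x is orthogonal to it, so the MLE is the intercept model
  y <- rep(c(0, 1), 50)
  x <- matrix(rep(c(-1, -1, 1, 1), 25), ncol = 1)
  fit <- fit_logistic(x, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$coefficients[2]), 1e-6)
  expect_equal(fit$log_likelihood, 100 * log(0.5), tolerance = 1e-8)
  expect_equal(aic(fit), 2 * 2 - 2 * 100 * log(0.5), tolerance = 1e-6)
})

test_that("aic applies 2k - 2logL and grows by ~2 per useless parameter", {
  fake <- structure(list(log_likelihood = -10, n_parameters = 3),
                    class = "logistic_fit")
  expect_equal(aic(fake), 26.0)

  withr::with_seed(31, {
    n <- 400
    x1 <- rnorm(n)
    y <- rbinom(n, 1, plogis(x1))
    f1 <- fit_logistic(cbind(x1 = x1), y)
    # craft a predictor whose ML coefficient is zero: orthogonalize noise
    # against the first fit's working residuals, so the joint optimum keeps
    # it at zero and the likelihood is unchanged
    eta <- f1$coefficients[1] + f1$coefficients[2] * x1
    r <- y - plogis(eta)
    x2 <- rnorm(n)
    x2 <- x2 - r * sum(x2 * r) / sum(r * r)
    f2 <- fit_logistic(cbind(x1 = x1, x2 = x2), y)
    expect_equal(aic(f2) - aic(f1), 2, tolerance = 1e-3)
  })
})

test_that("perfect separation is detected and matches glm's divergence", {
  x <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_logistic(x, y)
  expect_true(fit$separation_detected)
  w <- NULL
  suppressWarnings(withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(cond) w <<- conditionMessage(cond)))
  expect_true(!is.null(w))  # glm flags the same input
})

test_that("coefficients, likelihoods, standard errors and Wald p-values match glm", {
  for (s in 1:20) {
    withr::with_seed(s, {
      n <- 60 + 5 * s
      p <- 1 + s %% 3
      x <- matrix(rlnorm(n * p), n, p,
                  dimnames = list(NULL, paste0("c", 1:p)))
      y <- rbinom(n, 1, plogis(scale(x[, 1])))
      if (length(unique(y)) < 2) next
      fit <- fit_logistic(x, y)
      g <- stats::glm(y ~ x, family = stats::binomial(),
                      control = stats::glm.control(epsilon = 1e-14,
                                                   maxit = 100))
      expect_equal(fit$log_likelihood, as.numeric(stats::logLik(g)),
                   tolerance = 1e-8)
      expect_equal(unname(fit$coefficients), unname(stats::coef(g)),
                   tolerance = 1e-6)
      expect_equal(unname(fit$standard_errors),
                   unname(stats::summary.glm(g)$coefficients[, 2]),
                   tolerance = 1e-6)
      expect_equal(wald_pvalues(fit),
                   unname(stats::summary.glm(g)$coefficients[-1, 4]),
                   tolerance = 1e-6)
    })
  }
})

test_that("replicating the data doubles the log-likelihood, not the coefficients", {
  withr::with_seed(44, {
    n <- 50
    x <- matrix(rlnorm(2 * n), n, 2)
    y <- rbinom(n, 1, plogis(scale(x[, 1]) - 0.3))
    f1 <- fit_logistic(x, y)
    f2 <- fit_logistic(rbind(x, x), c(y, y))
    expect_equal(f2$log_likelihood, 2 * f1$log_likelihood, tolerance = 1e-7)
    expect_equal(f2$coefficients, f1$coefficients, tolerance = 1e-6)
  })
})

test_that("wald p-values follow the normal approximation and its edge cases", {
  fake <- structure(list(
    coefficients = c(`(Intercept)` = 0, a = 1.96, b = 0, c = 5),
    standard_errors = c(0.1, 1.0, 2.0, Inf)
  ), class = "logistic_fit")
  p <- wald_pvalues(fake)
  expect_equal(p[1], 0.05, tolerance = 1e-3)
  expect_equal(p[2], 1.0)
  expect_equal(p[3], 1.0)  # infinite SE is conservatively non-significant
})

test_that("children that merely reparameterize the node never win the AIC comparison", {
  withr::with_seed(51, {
    n <- 120
    node <- rlnorm(n)
    y <- rbinom(n, 1, plogis(scale(node)))
    # two children that are each exactly node/2
    kids <- cbind(a = node / 2, b = node / 2)
    cmp <- compare_models(node, kids, y)
    expect_false(cmp$expand)
    expect_equal(cmp$aic_expanded - cmp$aic_collapsed, 2, tolerance = 1e-6)

    # c proportional children: penalty exactly 2(c-1), equal likelihoods
    for (c_n in 2:4) {
      w <- seq_len(c_n) / sum(seq_len(c_n))
      kids_c <- vapply(w, function(wi) node * wi, numeric(n))
      colnames(kids_c) <- paste0("k", seq_len(c_n))
      cmp_c <- compare_models(node, kids_c, y)
      expect_false(cmp_c$expand)
      expect_equal(cmp_c$aic_expanded - cmp_c$aic_collapsed, 2 * (c_n - 1),
                   tolerance = 1e-6)
    }
  })
})

test_that("a genuinely informative child drives expansion; its noise sibling does not", {
  res <- t(sapply(1:100, function(s) {
    withr::with_seed(1000 + s, {
      n <- 200
      child1 <- rlnorm(n); child2 <- rlnorm(n)
      y <- rbinom(n, 1, plogis(3 * scale(child1)))
      if (length(unique(y)) < 2) return(c(NA, NA, NA))
      cmp <- compare_models(child1 + child2, cbind(c1 = child1, c2 = child2), y)
      c(cmp$expand, cmp$significant_children)
    })
  }))
  res <- res[stats::complete.cases(res), ]
  expect_gte(mean(res[, 1] & res[, 2]), 0.95)  # expand with child1 retained
  expect_lte(mean(res[, 3]), 0.15)             # child2 kept at ~alpha rate
})

test_that("the null expansion rate stays near AIC's one-parameter allowance", {
  expands <- vapply(1:500, function(s) {
    withr::with_seed(2000 + s, {
      n <- 200
      child1 <- rlnorm(n); child2 <- rlnorm(n)
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) return(NA)
      compare_models(child1 + child2, cbind(child1, child2), y)$expand
    })
  }, logical(1))
  expect_lt(mean(expands, na.rm = TRUE), 0.25)  # theory: P(chisq_1 > 2) ~ 0.157
})

test_that("the expanded model's likelihood dominates the collapsed one when children span the parent", {
  for (s in 1:25) {
    withr::with_seed(3000 + s, {
      n <- 80
      k <- 2 + s %% 3
      kids <- matrix(rlnorm(n * k), n, k, dimnames = list(NULL, paste0("k", 1:k)))
      node <- rowSums(kids)
      y <- rbinom(n, 1, plogis(0.5 * scale(kids[, 1])))
      if (length(unique(y)) < 2) next
      f0 <- fit_logistic(cbind(node), y)
      f1 <- fit_logistic(kids, y)
      expect_gte(f1$log_likelihood, f0$log_likelihood - 1e-6)
    })
  }
})

test_that("constant children are dropped from the design and marked non-significant", {
  withr::with_seed(61, {
    n <- 100
    c1 <- rlnorm(n)
    czero <- rep(0, n)
    y <- rbinom(n, 1, plogis(2 * scale(c1)))
    cmp <- compare_models(c1 + czero, cbind(c1 = c1, czero = czero), y)
    expect_false(cmp$significant_children[2])
    expect_equal(cmp$p_values[2], 1)
    # only one varying child: expanded equals collapsed, tie keeps collapsed
    expect_false(cmp$expand)
    expect_equal(cmp$aic_expanded, cmp$aic_collapsed, tolerance = 1e-6)
  })
})

test_that("the children-sum precondition is enforced", {
  withr::with_seed(71, {
    n <- 30
    kids <- matrix(rlnorm(2 * n), n, 2)
    y <- rep(c(0, 1), 15)
    expect_error(compare_models(rowSums(kids) + 0.01, kids, y), "sum")
  })
})
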