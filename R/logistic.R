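# The decision engine: unpenalized maximum-likelihood logistic regression
# (Newton/IRLS), AIC, and per-coefficient Wald tests.
#
# Written in-package because the algorithm's expand-or-keep decisions depend
# on details a generic fitter does not expose the way we need them: explicit
# separation flags, a gradient-based convergence contract, and a parameter
# count that includes aliased (collinear) predictors so that exact
# reparameterizations of a clade pay the full AIC penalty. stats::glm serves
# as an independent cross-check in the test suite.

log1pexp <- function(x) {
  # numerically stable log(1 + exp(x))
  out <- numeric(length(x))
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  out[!lo] <- x[!lo] + exp(-x[!lo])
  out
}

binom_loglik <- function(eta, y) sum(y * eta - log1pexp(eta))

#' Fit a binary logistic regression
#'
#' Unpenalized maximum-likelihood fit with an intercept, by Newton/IRLS with
#' step halving. Predictors are standardized internally (which leaves the
#' log-likelihood, AIC and Wald z-statistics unchanged); reported
#' coefficients are on the standardized scale. Collinear (aliased) columns
#' are dropped from the fit, get `NA` coefficients and infinite standard
#' errors, but still count towards `n_parameters` (see Details).
#'
#' @details `n_parameters` equals `1 + ncol(x)`: every presented predictor
#' counts, whether or not it was estimable. This makes the AIC of a model
#' whose predictors merely reparameterize another model's single predictor
#' exceed that model's AIC by exactly twice the number of extra columns —
#' the behavior the clade expansion rule relies on. `separation_detected` is
#' set when the fit fails to converge or any standardized coefficient
#' exceeds `coef_cap` in magnitude.
#'
#' @param x numeric samples x predictors matrix (no intercept column); no
#'   column may be constant
#' @param y binary 0/1 vector with both classes present
#' @param max_iter maximum Newton iterations (default 100)
#' @param tol convergence tolerance on the maximum absolute score (gradient)
#'   component (default 1e-8)
#' @param coef_cap standardized-coefficient magnitude beyond which the fit is
#'   flagged as separated (default 30)
#' @return an object of class `logistic_fit`: `coefficients` (intercept
#'   first), `standard_errors`, `log_likelihood`, `n_parameters`,
#'   `converged`, `separation_detected`, `n_samples`, `rank`
#' @export
fit_logistic <- function(x, y, max_iter = 100L, tol = 1e-8, coef_cap = 30) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("nrow(x) != length(y)", call. = FALSE)
  if (ncol(x) < 1L) stop("empty predictor matrix", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("`y` must be 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("`y` contains a single class; cannot fit", call. = FALSE)
  }
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    stop("constant predictor column(s): ",
         paste(head(colnames(x)[sds == 0], 10L), collapse = ", "),
         "; drop constant columns upstream", call. = FALSE)
  }
  xs <- scale(x)
  n <- nrow(x); p <- ncol(x)
  X <- cbind(`(Intercept)` = 1, xs)

  # identify aliased columns once, on the unweighted design
  qrX <- qr(X)
  rank <- qrX$rank
  kept <- sort(qrX$pivot[seq_len(rank)])
  Xk <- X[, kept, drop = FALSE]

  beta <- numeric(length(kept))
  eta <- drop(Xk %*% beta)
  ll <- binom_loglik(eta, y)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- plogis(eta)
    grad <- crossprod(Xk, y - mu)
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-12)
    XtWX <- crossprod(Xk * sqrt(w))
    delta <- tryCatch(solve(XtWX, grad),
                      error = function(e) NULL)
    if (is.null(delta)) break
    step <- 1
    repeat {
      beta_new <- beta + step * drop(delta)
      eta_new <- drop(Xk %*% beta_new)
      ll_new <- binom_loglik(eta_new, y)
      if (ll_new >= ll - 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    beta <- beta_new; eta <- eta_new; ll <- ll_new
  }

  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  XtWX <- crossprod(Xk * sqrt(w))
  cov <- tryCatch(solve(XtWX), error = function(e) NULL)
  se_k <- if (is.null(cov)) rep(Inf, length(kept)) else sqrt(pmax(diag(cov), 0))

  # back-transform to the original predictor scale (fitting was on
  # standardized columns for numerical stability; the optimum is the same)
  coefs <- rep(NA_real_, p + 1L)
  ses <- rep(Inf, p + 1L)
  coefs[kept] <- beta
  ses[kept] <- se_k
  ctr <- attr(xs, "scaled:center")
  scl <- attr(xs, "scaled:scale")
  slope_idx <- seq_len(p) + 1L
  est <- !is.na(coefs[slope_idx])
  coefs[1L] <- coefs[1L] -
    sum((coefs[slope_idx] * ctr / scl)[est])
  coefs[slope_idx] <- coefs[slope_idx] / scl
  ses[slope_idx] <- ses[slope_idx] / scl
  # intercept SE on the original scale: delta method over the kept block
  if (!is.null(cov)) {
    a <- c(1, -(ctr / scl)[match(kept[-1L], slope_idx)])
    ses[1L] <- sqrt(max(drop(t(a) %*% cov %*% a), 0))
  }
  names(coefs) <- names(ses) <-
    c("(Intercept)", colnames(x) %||% paste0("x", seq_len(p)))

  separation <- !converged || any(abs(beta[-1L]) > coef_cap)
  structure(list(
    coefficients = coefs,
    standard_errors = ses,
    log_likelihood = ll,
    n_parameters = p + 1L,
    rank = rank,
    converged = converged,
    separation_detected = separation,
    n_samples = n
  ), class = "logistic_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Akaike Information Criterion of a fit
#'
#' `2 * n_parameters - 2 * log_likelihood`; the intercept is counted, so
#' absolute values are conventional (it cancels in comparisons).
#'
#' @param fit a `logistic_fit`
#' @return numeric AIC
#' @export
aic <- function(fit) {
  2 * fit$n_parameters - 2 * fit$log_likelihood
}

#' @export
logLik.logistic_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_parameters,
            nobs = object$n_samples, class = "logLik")
}

#' Two-sided Wald p-values for the non-intercept coefficients
#'
#' Normal-approximation p-values `2 * pnorm(-|coef/se|)`. A coefficient with
#' an infinite or missing standard error (separation, aliasing) gets p = 1,
#' which is conservative: such a child is pruned.
#'
#' @param fit a `logistic_fit`
#' @return numeric vector, one p-value per predictor
#' @export
wald_pvalues <- function(fit) {
  b <- fit$coefficients[-1L]
  se <- fit$standard_errors[-1L]
  z <- b / se
  p <- 2 * pnorm(-abs(z))
  p[!is.finite(z)] <- 1
  unname(ifelse(is.na(p), 1, p))
}

#' Compare the collapsed and expanded models at a node
#'
#' Fits one logistic regression treating the node's aggregated abundance as
#' a single feature and one using the node's children as separate features,
#' and compares them by AIC. The node is expanded only when the children
#' model has strictly lower AIC *and* its fit is stable (converged, no
#' separation); exact ties keep the node collapsed (parsimony). Children
#' whose Wald coefficient in the expanded model is not significant at
#' `alpha` are marked non-significant; constant (e.g. all-zero) children are
#' dropped from the expanded design, excluded from its parameter count, and
#' marked non-significant.
#'
#' @param node_abund numeric vector: the node's aggregated abundance per
#'   sample
#' @param child_abunds samples x children matrix; columns must sum per
#'   sample to `node_abund` (tolerance 1e-9)
#' @param y binary 0/1 labels
#' @param alpha Wald significance level (default 0.05)
#' @param use_log apply `log()` to the (strictly positive) abundances before
#'   fitting
#' @param check_sum verify the children-sum precondition (default TRUE)
#' @return an object of class `model_comparison`: `aic_collapsed`,
#'   `aic_expanded`, `expand`, `significant_children` (logical, one per
#'   column of `child_abunds`), `p_values`, `fallback_reason` (`NA` unless
#'   the expanded fit was unusable and the node was kept collapsed)
#' @export
compare_models <- function(node_abund, child_abunds, y, alpha = 0.05,
                           use_log = FALSE, check_sum = TRUE) {
  child_abunds <- as.matrix(child_abunds)
  n_child <- ncol(child_abunds)
  if (check_sum) {
    dev <- max(abs(rowSums(child_abunds) - node_abund))
    if (dev > 1e-9) {
      stop("children do not sum to the node abundance (max deviation ",
           format(dev), ")", call. = FALSE)
    }
  }
  if (use_log) {
    node_abund <- log(node_abund)
    child_abunds <- log(child_abunds)
  }

  # collapsed model: intercept + node aggregate (intercept-only in the
  # degenerate case of a constant aggregate)
  if (sd(node_abund) == 0) {
    n1 <- sum(y); n0 <- length(y) - n1
    ll0 <- n1 * log(n1 / length(y)) + n0 * log(n0 / length(y))
    aic_col <- 2 * 1 - 2 * ll0
  } else {
    fit_col <- fit_logistic(matrix(node_abund, ncol = 1L,
                                   dimnames = list(NULL, "node")), y)
    aic_col <- aic(fit_col)
  }

  varying <- apply(child_abunds, 2L, sd) > 0
  significant <- rep(FALSE, n_child)
  p_values <- rep(NA_real_, n_child)
  p_values[!varying] <- 1

  if (!any(varying)) {
    cmp <- list(aic_collapsed = aic_col, aic_expanded = NA_real_,
                expand = FALSE, significant_children = significant,
                p_values = p_values,
                fallback_reason = "no varying children")
    return(structure(cmp, class = "model_comparison"))
  }

  fit_exp <- fit_logistic(child_abunds[, varying, drop = FALSE], y)
  aic_exp <- aic(fit_exp)
  p_values[varying] <- wald_pvalues(fit_exp)
  significant[varying] <- p_values[varying] < alpha
  fallback <- NA_character_
  if (!fit_exp$converged) {
    expand <- FALSE
    fallback <- "expanded fit did not converge"
  } else if (fit_exp$separation_detected) {
    expand <- FALSE
    fallback <- "separation in expanded fit"
  } else {
    expand <- aic_exp < aic_col
  }
  structure(list(aic_collapsed = aic_col, aic_expanded = aic_exp,
                 expand = expand, significant_children = significant,
                 p_values = p_values, fallback_reason = fallback),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> AIC collapsed ", format(x$aic_collapsed),
      " vs expanded ", format(x$aic_expanded), " -> ",
      if (x$expand) "expand" else "keep collapsed",
      if (!is.na(x$fallback_reason)) paste0(" (", x$fallback_reason, ")"),
      "\n", sep = "")
  invisible(x)
}
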