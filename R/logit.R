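#' Logistic regression by iteratively reweighted least squares
#'
#' Fits a binomial logistic regression with the canonical logit link by
#' iteratively reweighted least squares (IRLS), the Fisher-scoring form of
#' Newton's method. Categorical predictors use treatment (dummy) coding
#' against the first factor level, so odds ratios for non-reference levels
#' are `exp(coefficient)`. The covariance of the estimates is the inverse
#' Fisher information at the optimum, which underlies the Wald confidence
#' intervals and p-values reported by [adjusted_or()] and
#' [association_screen()].
#'
#' Rows with a missing response or missing predictors are dropped
#' (complete-case). Convergence is declared when the largest absolute
#' coefficient change falls below `tol`; non-convergence within `max_iter`
#' iterations is an error carrying the iteration trace. Quasi-complete
#' separation (fitted probabilities numerically at 0 or 1 alongside a
#' diverging coefficient) is detected and reported as an error naming the
#' offending term.
#'
#' @param formula Model formula; the response must be logical, 0/1 numeric,
#'   or a two-level factor (second level = event).
#' @param data A data.frame (a `"cohort"` works; categorical columns are
#'   treated as factors with their observed or declared level order).
#' @param max_iter Maximum IRLS iterations (default 25).
#' @param tol Convergence tolerance on the max absolute coefficient change
#'   (default 1e-8).
#' @return An object of class `"logit_fit"` with components `coefficients`,
#'   `vcov`, `converged`, `n_iter`, `n_used`, `fitted.values`, `deviance`,
#'   `null_deviance`, `terms`, `xlevels`, `call`. Supports `print()`,
#'   `summary()`, `coef()`, `vcov()`, `confint()`, `predict()`,
#'   `residuals()`, `fitted()`, `simulate()`, and `logLik()`.
#' @examples
#' d <- expand_printed_table(
#'   matrix(c(20, 10, 10, 20), nrow = 2, byrow = TRUE,
#'          dimnames = list(c("ref", "exposed"), c("n_no", "n_yes"))))
#' fit <- logit_fit(outcome ~ exposure, d)
#' exp(coef(fit))["exposureexposed"]  # cross-product odds ratio 4
#' @export
logit_fit <- function(formula, data, max_iter = 25, tol = 1e-8) {
  cl <- match.call()
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  # character columns become factors keeping first-appearance order is
  # fragile; use explicit factor() order when already a factor, else sort
  # by codebook-style declaration is the caller's job. Here: factor() with
  # unique() order so expanded printed tables keep their printed order.
  vars <- all.vars(formula)
  for (v in vars) {
    if (is.character(data[[v]])) {
      data[[v]] <- factor(data[[v]], levels = unique(data[[v]][!is.na(data[[v]])]))
    }
  }
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit,
                           drop.unused.levels = TRUE)
  y <- stats::model.response(mf)
  if (is.factor(y)) {
    if (nlevels(y) != 2) stop("response factor must have exactly 2 levels", call. = FALSE)
    y <- as.numeric(y) - 1
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) {
    stop("response must be logical, 0/1, or a two-level factor", call. = FALSE)
  }
  tt <- attr(mf, "terms")
  X <- stats::model.matrix(tt, mf)
  p <- ncol(X)
  n <- nrow(X)
  if (n < 10 * p) {
    warning(sprintf(
      "only %d complete cases for %d design columns (< 10 per column); estimates may be unstable",
      n, p
    ), call. = FALSE)
  }

  beta <- rep(0, p)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0
  repeat {
    it <- it + 1
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    fit_ls <- stats::lm.fit(X * sw, z * sw)
    beta_new <- fit_ls$coefficients
    if (anyNA(beta_new)) {
      stop("design matrix is rank deficient; drop aliased terms", call. = FALSE)
    }
    delta <- max(abs(beta_new - beta))
    trace <- c(trace, delta)
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }

  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  extreme <- mu < 1e-10 | mu > 1 - 1e-10
  if (p > 1 && any(extreme) && max(abs(beta[-1])) > 10) {
    worst <- names(beta)[-1][which.max(abs(beta[-1]))]
    stop(sprintf(
      "separation detected: fitted probabilities at 0/1 with diverging coefficient for term '%s'",
      worst
    ), call. = FALSE)
  }
  if (!converged) {
    stop(sprintf(
      "IRLS did not converge in %d iterations; coefficient-change trace: %s",
      max_iter, paste(signif(trace, 3), collapse = ", ")
    ), call. = FALSE)
  }

  w <- mu * (1 - mu)
  info <- crossprod(X * sqrt(w))
  vc <- tryCatch(solve(info), error = function(e) {
    stop("Fisher information is singular at the optimum", call. = FALSE)
  })
  dimnames(vc) <- list(colnames(X), colnames(X))
  dev <- -2 * sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  pbar <- mean(y)
  null_dev <- if (pbar %in% c(0, 1)) 0 else
    -2 * sum(y * log(pbar) + (1 - y) * log(1 - pbar))

  structure(list(
    coefficients = stats::setNames(as.numeric(beta), colnames(X)),
    vcov = vc,
    converged = converged,
    n_iter = it,
    n_used = n,
    fitted.values = mu,
    y = y,
    deviance = dev,
    null_deviance = null_dev,
    trace = trace,
    terms = tt,
    xlevels = stats::.getXlevels(tt, mf),
    call = cl
  ), class = "logit_fit")
}

#' @export
coef.logit_fit <- function(object, ...) object$coefficients

#' @export
vcov.logit_fit <- function(object, ...) object$vcov

#' @export
fitted.logit_fit <- function(object, ...) object$fitted.values

#' @export
logLik.logit_fit <- function(object, ...) {
  structure(-object$deviance / 2,
            df = length(object$coefficients),
            nobs = object$n_used, class = "logLik")
}

#' @export
print.logit_fit <- function(x, digits = 4, ...) {
  cat("Logistic regression (IRLS)\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("n = %d, converged in %d iterations, deviance = %.2f\n",
              x$n_used, x$n_iter, x$deviance))
  print(round(x$coefficients, digits))
  invisible(x)
}

#' @rdname logit_fit
#' @param object,x A `"logit_fit"` object.
#' @param ... Unused.
#' @export
summary.logit_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  p <- 2 * stats::pnorm(-abs(z))
  tab <- cbind(
    Estimate = object$coefficients, `Std. Error` = se,
    `z value` = z, `Pr(>|z|)` = p,
    OR = exp(object$coefficients)
  )
  structure(list(coefficients = tab, n_used = object$n_used,
                 n_iter = object$n_iter, deviance = object$deviance,
                 null_deviance = object$null_deviance, call = object$call),
            class = "summary.logit_fit")
}

#' @export
print.summary.logit_fit <- function(x, ...) {
  cat("Logistic regression (IRLS)\n")
  cat("Call: ", deparse(x$call), "\n\n", sep = "")
  stats::printCoefmat(x$coefficients[, 1:4, drop = FALSE], P.values = TRUE,
                      has.Pvalue = TRUE)
  cat(sprintf("\nNull deviance: %.2f; Residual deviance: %.2f; n = %d\n",
              x$null_deviance, x$deviance, x$n_used))
  invisible(x)
}

#' @export
confint.logit_fit <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  if (missing(parm)) parm <- names(cf)
  se <- sqrt(diag(object$vcov))[parm]
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(cf[parm] - zq * se, cf[parm] + zq * se)
  colnames(out) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  out
}

#' @export
predict.logit_fit <- function(object, newdata = NULL,
                              type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- stats::qlogis(object$fitted.values)
  } else {
    newdata <- as.data.frame(newdata, stringsAsFactors = FALSE)
    for (v in names(object$xlevels)) {
      newdata[[v]] <- factor(newdata[[v]], levels = object$xlevels[[v]])
    }
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, na.action = stats::na.pass,
                             xlev = object$xlevels)
    X <- stats::model.matrix(tt, mf)
    eta <- drop(X %*% object$coefficients)
  }
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
residuals.logit_fit <- function(object,
                                type = c("deviance", "pearson", "response"),
                                ...) {
  type <- match.arg(type)
  y <- object$y
  mu <- object$fitted.values
  switch(type,
    response = y - mu,
    pearson = (y - mu) / sqrt(mu * (1 - mu)),
    deviance = sign(y - mu) * sqrt(pmax(
      -2 * (y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300))),
      0
    ))
  )
}

#' @export
simulate.logit_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n_used
  out <- as.data.frame(replicate(nsim, stats::rbinom(n, 1, object$fitted.values)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
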