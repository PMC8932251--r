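#' Logistic disease models on verified participants
#'
#' The multiple-imputation path models Pr(disease = 1 | test results) on
#' the verified subset with a logistic regression on the K binary test
#' results (main effects by default).  Two fitters are provided:
#' [fit_ml()], ordinary maximum likelihood, and [fit_firth()], Firth's
#' penalized likelihood, which adds half the log-determinant of the Fisher
#' information to the log-likelihood.  The penalty removes the
#' leading-order small-sample bias of the ML coefficients, vanishes as the
#' sample grows, and — its defining practical property — yields finite
#' estimates under complete separation, where ML diverges.  With few
#' events per variable (EPV below 10) the penalized fit is the
#' recommended default.
#'
#' @name logistic_disease_model
NULL

new_logistic_model <- function(coefficients, penalized, converged,
                               iterations, log_likelihood, term_names,
                               separation = FALSE, vcov = NULL) {
  structure(list(coefficients = coefficients, penalized = penalized,
                 converged = converged, iterations = iterations,
                 log_likelihood = log_likelihood, term_names = term_names,
                 separation = separation, vcov = vcov),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("%s logistic model (%s, %d iterations)\n",
              if (x$penalized) "Firth-penalized" else "Maximum-likelihood",
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  if (x$separation) cat("  separation detected in the data\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

design_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) > 0 && is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  cbind(`(Intercept)` = 1, x)
}

loglik_logit <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

#' Maximum-likelihood logistic fit
#'
#' Iteratively reweighted least squares via [stats::glm()], with an added
#' separation diagnostic: if any coefficient exceeds 15 in magnitude and
#' either the score has not vanished or fitted probabilities have hit the
#' 0/1 boundary, the fit is flagged non-converged with `separation = TRUE`
#' rather than returning spurious finite numbers.
#'
#' @param x matrix or data frame of covariates over the verified records
#'   (no intercept column; one is added).
#' @param y 0/1 outcome vector (disease status).
#' @return A `logistic_model` object.
#' @export
fit_ml <- function(x, y) {
  X <- design_matrix(x)
  y <- as.numeric(y)
  if (all(y == 1) || all(y == 0))
    stop("outcome has no events or no non-events: the maximum-likelihood ",
         "fit is undefined; use fit_firth()", call. = FALSE)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(maxit = 100)))
  beta <- fit$coefficients
  p <- fit$fitted.values
  score <- drop(crossprod(X, y - p))
  # diverging coefficients signal separation whether the score is still
  # moving or has numerically vanished at the boundary (fitted 0/1 probs)
  sep <- any(abs(beta) > 15) &&
    (sqrt(sum(score^2)) > 1e-4 || any(p < 1e-8 | p > 1 - 1e-8))
  conv <- fit$converged && !sep
  W <- p * (1 - p)
  info <- crossprod(X * sqrt(W))
  vc <- tryCatch(solve(info), error = function(e) NULL)
  new_logistic_model(beta, penalized = FALSE, converged = conv,
                     iterations = fit$iter,
                     log_likelihood = loglik_logit(X, y, beta),
                     term_names = colnames(X), separation = sep, vcov = vc)
}

#' Firth-penalized logistic fit
#'
#' Maximizes `loglik + 0.5 * log det(X' W X)` by Newton steps on the
#' modified score, in which the residual `y - p` is replaced by
#' `y - p + h (1/2 - p)` with `h` the hat-matrix leverages, with
#' step-halving whenever a step fails to increase the penalized
#' log-likelihood.
#'
#' @inheritParams fit_ml
#' @param max_iter iteration cap (default 100).
#' @param tol convergence tolerance on the penalized-score norm
#'   (default 1e-8).
#' @param max_halvings step-halvings allowed per iteration (default 20).
#' @return A `logistic_model` object with `penalized = TRUE`.
#' @export
fit_firth <- function(x, y, max_iter = 100, tol = 1e-8, max_halvings = 20) {
  X <- design_matrix(x)
  y <- as.numeric(y)
  p_dim <- ncol(X)
  beta <- numeric(p_dim)

  pen_ll <- function(beta) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    W <- pmax(p * (1 - p), .Machine$double.eps)
    info <- crossprod(X * sqrt(W))
    sum(y * eta - log1p(exp(eta))) +
      0.5 * determinant(info, logarithm = TRUE)$modulus
  }

  ll_old <- pen_ll(beta)
  converged <- FALSE
  iter <- 0L
  info <- NULL
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    W <- pmax(p * (1 - p), .Machine$double.eps)
    XW <- X * sqrt(W)
    info <- crossprod(XW)
    # leverages of the weighted design
    U <- XW %*% solve(info)
    h <- rowSums(U * XW)
    score <- drop(crossprod(X, y - p + h * (0.5 - p)))
    if (sqrt(sum(score^2)) < tol) { converged <- TRUE; break }
    step <- solve(info, score)
    ll_new <- pen_ll(beta + step)
    halvings <- 0L
    while (ll_new < ll_old && halvings < max_halvings) {
      step <- step / 2
      halvings <- halvings + 1L
      ll_new <- pen_ll(beta + step)
    }
    beta <- beta + step
    ll_old <- pen_ll(beta)
    if (iter >= max_iter) break
  }
  if (!converged)
    stop(sprintf(
      paste("Firth fit did not converge in %d iterations",
            "(coefficient trace: %s)"),
      max_iter, paste(round(beta, 3), collapse = ", ")), call. = FALSE)
  vc <- tryCatch(solve(info), error = function(e) NULL)
  new_logistic_model(stats::setNames(beta, colnames(X)), penalized = TRUE,
                     converged = TRUE, iterations = iter,
                     log_likelihood = as.numeric(pen_ll(beta)),
                     term_names = colnames(X), vcov = vc)
}

#' Predicted disease probability from a fitted logistic model
#'
#' Inverse-logit of the linear predictor for new covariate rows.
#'
#' @param model a `logistic_model`.
#' @param newdata matrix or data frame of covariates (no intercept column),
#'   with as many columns as the model has non-intercept terms.
#' @return Vector of probabilities strictly inside (0, 1).
#' @export
predict_prob <- function(model, newdata) {
  X <- design_matrix(newdata)
  if (ncol(X) != length(model$coefficients))
    stop(sprintf("model has %d terms but newdata provides %d",
                 length(model$coefficients) - 1L, ncol(X) - 1L))
  stats::plogis(drop(X %*% model$coefficients))
}

interaction_design <- function(tests, order = 3) {
  tests <- as.matrix(tests)
  K <- ncol(tests)
  nm <- colnames(tests)
  out <- tests
  if (order >= 2 && K >= 2) {
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
      out <- cbind(out, tests[, i] * tests[, j])
      colnames(out)[ncol(out)] <- paste(nm[i], nm[j], sep = ":")
    }
  }
  if (order >= 3 && K >= 3) {
    cmb <- utils::combn(K, 3)
    for (c_ in seq_len(ncol(cmb))) {
      ijk <- cmb[, c_]
      out <- cbind(out, tests[, ijk[1]] * tests[, ijk[2]] * tests[, ijk[3]])
      colnames(out)[ncol(out)] <- paste(nm[ijk], collapse = ":")
    }
  }
  out
}

#' Screen pairwise and three-way test interactions in the disease model
#'
#' Fits the logistic model expanded with pairwise (and, for three or more
#' tests, three-way) product terms on the verified records and reports a
#' Wald statistic and p-value per interaction.  Interactions that are not
#' significant at `alpha` are recommended for removal; the typical result
#' on conditionally independent tests is a main-effects-only model.
#'
#' @param data a `screening_data` object (verified records are used), or a
#'   covariate matrix if `y` is supplied.
#' @param y optional outcome vector when `data` is a plain matrix.
#' @param alpha significance level for retention (default 0.05).
#' @param penalized fit the expanded model by Firth's method (default
#'   `TRUE`, the sensible choice when events are few).
#' @return A list of class `interaction_screen`: per-term data frame
#'   (`term`, `estimate`, `se`, `z`, `p`, `estimable`), the recommended
#'   term set, and the fitted expanded model (or `NULL` if not estimable).
#' @export
interaction_screen <- function(data, y = NULL, alpha = 0.05,
                               penalized = TRUE) {
  if (inherits(data, "screening_data")) {
    ver <- data[data$verified == 1L, , drop = FALSE]
    tests <- as.matrix(ver[test_names(data)])
    y <- ver$disease
  } else {
    tests <- as.matrix(data)
  }
  Xfull <- interaction_design(tests)
  main <- colnames(tests)
  inter <- setdiff(colnames(Xfull), main)

  not_estimable <- function(reason) {
    structure(list(
      terms = data.frame(term = inter, estimate = NA_real_, se = NA_real_,
                         z = NA_real_, p = NA_real_, estimable = FALSE,
                         stringsAsFactors = FALSE),
      recommended = main, model = NULL, alpha = alpha, reason = reason),
      class = "interaction_screen")
  }
  if (sum(y == 1) == 0 || sum(y == 0) == 0)
    return(not_estimable("no events (or no non-events) among verified"))
  fit <- tryCatch(
    if (penalized) fit_firth(Xfull, y) else fit_ml(Xfull, y),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || is.null(fit$vcov))
    return(not_estimable("expanded model not identifiable"))

  se <- sqrt(diag(fit$vcov))
  names(se) <- fit$term_names
  est <- fit$coefficients[inter]
  se_i <- se[inter]
  z <- est / se_i
  pval <- 2 * stats::pnorm(-abs(z))
  terms <- data.frame(term = inter, estimate = unname(est),
                      se = unname(se_i), z = unname(z), p = unname(pval),
                      estimable = is.finite(pval), stringsAsFactors = FALSE)
  keep <- inter[is.finite(pval) & pval < alpha]
  structure(list(terms = terms, recommended = c(main, keep), model = fit,
                 alpha = alpha, reason = NULL),
            class = "interaction_screen")
}

#' @export
print.interaction_screen <- function(x, ...) {
  cat("Interaction screen (alpha =", x$alpha, ")\n")
  if (!is.null(x$reason)) cat("  not estimable:", x$reason, "\n")
  print(x$terms, row.names = FALSE, digits = 4)
  cat("recommended design:", paste(x$recommended, collapse = " + "), "\n")
  invisible(x)
}
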