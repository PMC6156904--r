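# Linear model fitting with an optional polygenic random effect
# (covariance sigma_g^2 * 2*phi + sigma_e^2 * I), returning coefficients and
# their covariance matrix for downstream estimators.

new_model_fit <- function(coefficients, vcov, sigma2_e, sigma2_g, n,
                          logreml = NA_real_, method = "ols") {
  structure(list(coefficients = coefficients, vcov = vcov,
                 sigma2_e = sigma2_e, sigma2_g = sigma2_g, n = n,
                 logreml = logreml, method = method),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("model_fit (", x$method, "), n = ", x$n,
      ", sigma2_e = ", signif(x$sigma2_e, 4),
      ", sigma2_g = ", signif(x$sigma2_g, 4), "\n", sep = "")
  print(data.frame(estimate = x$coefficients,
                   se = sqrt(diag(x$vcov))))
  invisible(x)
}

check_design <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X))
  if (anyNA(X) || anyNA(y)) stop("design or response contains missing values")
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  if (nrow(X) <= ncol(X)) stop("need more observations than parameters")
  X
}

#' Ordinary least squares fit
#'
#' Fits by QR decomposition; the coefficient covariance is the classical
#' `sigma2_e * (X'X)^{-1}` with `sigma2_e = RSS / (n - p)`.
#'
#' @param design numeric design matrix (include the intercept column);
#'   must be full column rank.
#' @param response numeric response vector.
#' @return A `model_fit` with elements `coefficients`, `vcov`, `sigma2_e`,
#'   `sigma2_g` (0 for OLS), `n`.
#' @export
fit_ols <- function(design, response) {
  X <- check_design(design, response)
  q <- qr(X)
  beta <- qr.coef(q, response)
  res <- response - X %*% beta
  n <- nrow(X); p <- ncol(X)
  sigma2 <- sum(res^2) / (n - p)
  XtX_inv <- chol2inv(qr.R(q))
  dimnames(XtX_inv) <- list(colnames(X), colnames(X))
  new_model_fit(stats::setNames(as.numeric(beta), colnames(X)),
                sigma2 * XtX_inv, sigma2, 0, n, method = "ols")
}

#' Linear mixed model with a polygenic random effect, fitted by REML
#'
#' The model is `y = X b + g + e` with `g ~ N(0, sigma_g^2 * K)`,
#' `K = 2 * phi` the expected additive relationship matrix, and
#' `e ~ N(0, sigma_e^2 * I)`. After a spectral decomposition `K = U D U'`,
#' the restricted likelihood is profiled down to the variance ratio
#' `lambda = sigma_g^2 / sigma_e^2`, which is maximised on a log-spaced grid
#' refined by bounded 1-D optimisation. Coefficients are generalised least
#' squares at the optimum with covariance `(X' V^{-1} X)^{-1}`,
#' `V = sigma_g^2 K + sigma_e^2 I`.
#'
#' @param design numeric design matrix (with intercept), full column rank.
#' @param response numeric response vector.
#' @param relationship a [kinship_matrix()] aligned to the rows of `design`,
#'   or a plain relationship matrix `K = 2 * phi`; must be positive
#'   semi-definite.
#' @param lambda_bounds search interval for `lambda` (ratio scale).
#' @return A `model_fit`; `logreml` holds the restricted log-likelihood (up
#'   to an additive constant) at the optimum.
#' @export
fit_lmm_reml <- function(design, response, relationship,
                         lambda_bounds = c(1e-6, 1e6)) {
  X <- check_design(design, response)
  K <- if (inherits(relationship, "kinship_matrix"))
    2 * relationship$phi else as.matrix(relationship)
  n <- nrow(X); p <- ncol(X)
  stopifnot(nrow(K) == n)
  ev <- eigen(K, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1))
    stop("relationship matrix is not positive semi-definite")
  d <- pmax(ev$values, 0)
  yt <- crossprod(ev$vectors, response)
  Xt <- crossprod(ev$vectors, X)

  # profiled restricted log-likelihood of log(lambda), up to a constant
  profile <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (lam * d + 1)
    XtWX <- crossprod(Xt, Xt * w)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xt, yt * w)))
    rss <- sum(w * (yt - Xt %*% beta)^2)
    s2 <- rss / (n - p)
    -0.5 * ((n - p) * log(s2) + sum(log(lam * d + 1)) +
              2 * sum(log(diag(ch))) + (n - p))
  }
  lb <- log(lambda_bounds)
  grid <- seq(lb[1], lb[2], length.out = 41)
  vals <- vapply(grid, profile, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(profile, c(lo, hi), maximum = TRUE, tol = 1e-8)
  # a boundary grid optimum may beat the refined interior one
  if (vals[i] > opt$objective) {
    loglam <- grid[i]; logreml <- vals[i]
  } else {
    loglam <- opt$maximum; logreml <- opt$objective
  }
  lam <- exp(loglam)
  if (loglam >= lb[2] - 1e-6)
    warning("variance-ratio estimate at the upper search bound")
  # treat a boundary solution at the lower bound as lambda = 0
  if (loglam <= lb[1] + 1e-6) lam <- 0

  w <- 1 / (lam * d + 1)
  XtWX <- crossprod(Xt, Xt * w)
  XtWX_inv <- chol2inv(chol(XtWX))
  beta <- as.numeric(XtWX_inv %*% crossprod(Xt, yt * w))
  rss <- sum(w * (yt - Xt %*% beta)^2)
  sigma2_e <- rss / (n - p)
  vc <- sigma2_e * XtWX_inv
  dimnames(vc) <- list(colnames(X), colnames(X))
  new_model_fit(stats::setNames(beta, colnames(X)), vc,
                sigma2_e, lam * sigma2_e, n, logreml, method = "lmm")
}

# Fit dispatcher used by the screening and mediation stages: LMM when a
# kinship matrix is available (and mode allows), OLS otherwise.
fit_model <- function(design, response, kinship = NULL,
                      mode = c("auto", "ols", "lmm")) {
  mode <- match.arg(mode)
  if (mode == "ols" || (mode == "auto" && is.null(kinship)))
    return(fit_ols(design, response))
  if (is.null(kinship)) stop("lmm mode requires a kinship matrix")
  fit_lmm_reml(design, response, kinship)
}

# Wald summary for one coefficient against the standard normal reference.
wald_row <- function(fit, term, label = term) {
  est <- fit$coefficients[[term]]
  se <- sqrt(fit$vcov[term, term])
  z <- est / se
  data.frame(term = label, estimate = est, se = se, z = z,
             p = 2 * stats::pnorm(-abs(z)), n = fit$n,
             stringsAsFactors = FALSE)
}
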