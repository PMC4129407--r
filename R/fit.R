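#' Covariate design matrix with collection structure
#'
#' Builds the covariate block of the additive-dosage logistic model: an
#' intercept, an indicator for each data-set collection (one collection is
#' absorbed into the intercept), collection-specific principal-component
#' columns (the PC value where the sample belongs to collection k, zero
#' elsewhere; K x L columns), and any conditioning dosage columns. The
#' collection indicators and collection-specific PC slopes give every
#' collection its own intercept and ancestry adjustment within one pooled
#' (fixed-effects) regression.
#'
#' Constant non-intercept columns (e.g. a PC that never varies, or a
#' conditioning dosage fixed at zero) carry no information and are dropped
#' with a warning.
#'
#' @param cohort a [cohort_table()].
#' @param conditioning a [dosage_matrix()], a plain numeric matrix with
#'   rownames matching sample IDs, or NULL.
#' @param pcs `"by_collection"` (default; PC-by-collection interaction
#'   columns) or `"pooled"` (one column per PC).
#' @return numeric design matrix with rownames = sample IDs and an attribute
#'   `"dropped"` naming any removed columns.
#' @export
build_design <- function(cohort, conditioning = NULL,
                         pcs = c("by_collection", "pooled")) {
  pcs <- match.arg(pcs)
  n <- nrow(cohort)
  X <- matrix(1, n, 1, dimnames = list(cohort$sample_id, "(Intercept)"))
  lev <- levels(cohort$collection)
  for (k in lev[-1])
    X <- cbind(X, `colnames<-`(matrix(as.numeric(cohort$collection == k)),
                               paste0("collection", k)))
  L <- n_pcs(cohort)
  if (L > 0) {
    P <- pc_matrix(cohort)
    if (pcs == "pooled") {
      X <- cbind(X, P)
    } else {
      for (k in lev) {
        ind <- as.numeric(cohort$collection == k)
        block <- P * ind
        colnames(block) <- paste0("PC", seq_len(L), ".", k)
        X <- cbind(X, block)
      }
    }
  }
  if (!is.null(conditioning)) {
    C <- if (inherits(conditioning, "dosage_matrix")) conditioning$dosages
         else as.matrix(conditioning)
    if (ncol(C) > 0) {
      if (is.null(rownames(C)))
        stop_hfm("conditioning matrix needs sample rownames", "hlafinemap_validation_error")
      idx <- match(cohort$sample_id, rownames(C))
      if (anyNA(idx))
        stop_hfm("conditioning matrix missing some cohort samples", "hlafinemap_validation_error")
      X <- cbind(X, C[idx, , drop = FALSE])
    }
  }
  const <- apply(X[, -1, drop = FALSE], 2, function(v) diff(range(v)) == 0)
  dropped <- colnames(X)[-1][const]
  if (length(dropped)) {
    warning("dropping constant design column(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
    X <- X[, !c(FALSE, const), drop = FALSE]
  }
  attr(X, "dropped") <- dropped
  X
}

Z975 <- 1.959964  # normal quantile used for all 95% CIs

#' Fit the additive-dosage logistic model
#'
#' Maximum-likelihood logistic regression fitted by iteratively reweighted
#' least squares (convergence when the relative deviance change falls below
#' 1e-8, at most 100 iterations). This is the workhorse behind every
#' association, conditional and multivariate fit in the package.
#'
#' Columns that are collinear with earlier columns are dropped (their
#' coefficients reported as `NA`) with a warning. Complete or quasi-complete
#' separation does not raise an error: the fit is returned with
#' `reliable = FALSE` and its Wald standard errors should not be trusted
#' (likelihood-ratio quantities remain usable).
#'
#' @param y binary response vector (0/1), no missing values.
#' @param X numeric design matrix (including the intercept), e.g. from
#'   [build_design()], with variant dosage columns appended.
#' @return An object of class `hla_fit` with components `coefficients`,
#'   `vcov`, `logLik`, `deviance`, `null_deviance`, `converged`, `reliable`,
#'   `n`, `rank`, `fitted`, `y`, `X`. Methods: `print`, `summary`, `coef`,
#'   `vcov`, `logLik`, `confint`, `predict`, `residuals`, `simulate`.
#' @examples
#' x <- rep(0:1, each = 100)
#' y <- c(rep(0:1, 50), rep(0:1, c(25, 75)))
#' f <- fit_logistic(y, cbind(1, dosage = x))
#' coef(f)["dosage"]  # log odds ratio, ln 3
#' @export
fit_logistic <- function(y, X) {
  X <- as.matrix(X)
  if (length(y) != nrow(X))
    stop_hfm("response and design dimensions differ", "hlafinemap_validation_error")
  if (anyNA(y) || anyNA(X))
    stop_hfm("missing values are not allowed", "hlafinemap_validation_error")
  if (!all(y %in% c(0, 1)))
    stop_hfm("phenotype must be binary 0/1", "hlafinemap_validation_error")
  if (length(unique(y)) < 2L)
    stop_hfm("phenotype is constant", "hlafinemap_degenerate")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  is_icpt <- apply(X, 2, function(v) all(v == v[1]) && v[1] != 0)
  const <- apply(X, 2, function(v) diff(range(v)) == 0) & !is_icpt
  if (any(const))
    stop_hfm(paste0("constant predictor column(s): ",
                    paste(colnames(X)[const], collapse = ", ")),
             "hlafinemap_degenerate")
  # drop collinear columns (R^2 with retained span > 1 - 1e-8), keep-first order
  qx <- qr(X, tol = 1e-7)
  keep <- sort(qx$pivot[seq_len(qx$rank)])
  dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
  if (length(dropped))
    warning("dropping collinear column(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
  Xk <- X[, keep, drop = FALSE]

  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(Xk, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  mu <- fit$fitted.values
  if (any(mu < 1e-8) || any(mu > 1 - 1e-8)) sep <- TRUE
  ll <- sum(stats::dbinom(y, 1, mu, log = TRUE))
  w <- mu * (1 - mu)
  info <- crossprod(Xk * sqrt(w))
  V <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
  reliable <- fit$converged && !sep && !is.null(V)
  if (is.null(V)) V <- matrix(NA_real_, ncol(Xk), ncol(Xk))
  dimnames(V) <- list(colnames(Xk), colnames(Xk))

  beta <- rep(NA_real_, ncol(X))
  names(beta) <- colnames(X)
  beta[colnames(Xk)] <- fit$coefficients

  structure(list(coefficients = beta, vcov = V, logLik = ll,
                 deviance = fit$deviance, null_deviance = fit$null.deviance,
                 converged = fit$converged, separated = sep,
                 reliable = reliable, n = length(y), rank = qx$rank,
                 dropped = dropped, fitted = mu, y = y, X = Xk),
            class = "hla_fit")
}

#' @export
print.hla_fit <- function(x, ...) {
  cat(sprintf("Additive-dosage logistic fit: n = %d, rank = %d, logLik = %.3f\n",
              x$n, x$rank, x$logLik))
  if (!x$converged) cat("  WARNING: IRLS did not converge\n")
  if (x$separated) cat("  WARNING: separation detected; Wald SEs unreliable\n")
  print(round(stats::na.omit(x$coefficients), 4))
  invisible(x)
}

#' @export
coef.hla_fit <- function(object, ...) object$coefficients

#' @export
vcov.hla_fit <- function(object, ...) object$vcov

#' @export
logLik.hla_fit <- function(object, ...) {
  structure(object$logLik, df = object$rank, nobs = object$n, class = "logLik")
}

#' @export
summary.hla_fit <- function(object, ...) {
  est <- object$coefficients[colnames(object$X)]
  se <- sqrt(diag(object$vcov))
  z <- est / se
  tab <- cbind(estimate = est, se = se, z = z,
               p = 2 * stats::pnorm(-abs(z)),
               or = exp(est),
               or_lo = exp(est - Z975 * se), or_hi = exp(est + Z975 * se))
  structure(list(coefficients = tab, n = object$n, logLik = object$logLik,
                 converged = object$converged, reliable = object$reliable),
            class = "summary.hla_fit")
}

#' @export
print.summary.hla_fit <- function(x, ...) {
  cat(sprintf("n = %d, logLik = %.3f%s\n", x$n, x$logLik,
              if (x$reliable) "" else "  [unreliable fit]"))
  stats::printCoefmat(x$coefficients[, 1:4, drop = FALSE], P.values = TRUE,
                      has.Pvalue = TRUE)
  invisible(x)
}

#' @export
confint.hla_fit <- function(object, parm, level = 0.95, ...) {
  est <- object$coefficients[colnames(object$X)]
  se <- sqrt(diag(object$vcov))
  z <- if (level == 0.95) Z975 else stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(lower = est - z * se, upper = est + z * se)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.hla_fit <- function(object, newdata = NULL,
                            type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "response") return(object$fitted)
    newdata <- object$X
  }
  newdata <- as.matrix(newdata)[, colnames(object$X), drop = FALSE]
  eta <- drop(newdata %*% object$coefficients[colnames(object$X)])
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
residuals.hla_fit <- function(object,
                              type = c("deviance", "pearson", "response"), ...) {
  type <- match.arg(type)
  mu <- object$fitted; y <- object$y
  switch(type,
    response = y - mu,
    pearson = (y - mu) / sqrt(mu * (1 - mu)),
    deviance = sign(y - mu) *
      sqrt(-2 * (y * log(mu) + (1 - y) * log(1 - mu))))
}

#' @export
simulate.hla_fit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    out <- replicate(nsim, stats::rbinom(object$n, 1, object$fitted))
    out <- as.data.frame(out)
    names(out) <- paste0("sim_", seq_len(nsim))
    rownames(out) <- rownames(object$X)
    out
  })
}
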