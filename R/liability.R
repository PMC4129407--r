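#' Liability-scale variance explained by one risk variant
#'
#' Computes the proportion of liability-scale phenotypic variance
#' attributable to a biallelic risk variant under a liability threshold
#' model. Genotypes (0, 1, 2 copies at population frequency `freq`, under
#' Hardy-Weinberg proportions) carry multiplicative disease risks
#' proportional to `or^g`; per-genotype penetrances are calibrated so the
#' population prevalence equals `prevalence`. Each genotype class is then
#' assigned the mean liability (on a latent standard-normal scale with
#' threshold `qnorm(1 - prevalence)`) that reproduces its penetrance, and the
#' variance of these genotype means is the variant's liability-scale
#' contribution.
#'
#' At a prevalence of a few percent the odds ratio closely approximates the
#' genotype relative risk, so by default the OR is used as the relative risk
#' directly; `rr_correction = TRUE` instead converts it via
#' `RR = OR / (1 - K + K * OR)`. By default the between-genotype variance is
#' reported on the unit-residual liability scale; `scale = "proportion"`
#' normalises by the total liability variance `V + 1`.
#'
#' @param freq population allele frequency in (0, 1) (in case-control data,
#'   the control frequency is the standard stand-in at low prevalence).
#' @param or per-allele odds ratio (> 0).
#' @param prevalence disease prevalence K in (0, 1).
#' @param rr_correction convert OR to relative risk via prevalence
#'   (default FALSE).
#' @param scale `"variance"` (default) or `"proportion"` (V / (V + 1)).
#' @return proportion of liability variance explained (e.g. 0.049 for 4.9%).
#' @examples
#' variance_explained_liability(freq = 0.093, or = 3.26, prevalence = 0.02)
#' @export
variance_explained_liability <- function(freq, or, prevalence,
                                         rr_correction = FALSE,
                                         scale = c("variance", "proportion")) {
  scale <- match.arg(scale)
  if (!is.finite(freq) || freq <= 0 || freq >= 1)
    stop_hfm("freq must lie in (0, 1)", "hlafinemap_validation_error")
  if (!is.finite(or) || or <= 0)
    stop_hfm("or must be positive", "hlafinemap_validation_error")
  if (!is.finite(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop_hfm("prevalence must lie in (0, 1)", "hlafinemap_validation_error")
  if (or == 1) return(0)
  K <- prevalence
  rr <- if (rr_correction) or / (1 - K + K * or) else or
  f <- c((1 - freq)^2, 2 * freq * (1 - freq), freq^2)
  rel <- rr^(0:2)
  pen <- K * rel / sum(f * rel)
  if (any(pen >= 1))
    stop_hfm("penetrance exceeds 1: effect too large for this prevalence",
             "hlafinemap_validation_error")
  thr <- stats::qnorm(1 - K)
  mu <- thr - stats::qnorm(1 - pen)
  V <- sum(f * mu^2) - sum(f * mu)^2
  if (scale == "proportion") V / (V + 1) else V
}

#' Combined liability-scale variance explained by a set of risk variants
#'
#' Sums per-variant liability-threshold contributions (computed with
#' [variance_explained_liability()] from each variant's population frequency
#' and multivariate odds ratio), assuming independence across variants.
#' A Monte-Carlo joint estimator is available as a sensitivity check: it
#' simulates genotypes at all loci independently, adds the per-genotype mean
#' liability shifts, and reports the variance of the summed shifts on the
#' same scale.
#'
#' @param table an `hla_mvfit` object, or a data.frame with columns
#'   `freq_control` (or `freq`) and `or`; reference rows (`reference ==
#'   TRUE` or non-finite OR) are skipped.
#' @param prevalence disease prevalence K in (0, 1).
#' @param method `"sum"` (default) or `"simulation"`.
#' @param n_sim individuals simulated for `method = "simulation"`.
#' @param seed RNG seed for `method = "simulation"`.
#' @inheritParams variance_explained_liability
#' @return total proportion of liability variance explained.
#' @export
variance_explained_joint <- function(table, prevalence,
                                     method = c("sum", "simulation"),
                                     rr_correction = FALSE,
                                     scale = c("variance", "proportion"),
                                     n_sim = 1e6, seed = 1) {
  method <- match.arg(method); scale <- match.arg(scale)
  if (inherits(table, "hla_mvfit")) table <- table$table
  tab <- as.data.frame(table)
  if (!"freq" %in% names(tab) && "freq_control" %in% names(tab))
    tab$freq <- tab$freq_control
  if (!all(c("freq", "or") %in% names(tab)))
    stop_hfm("table needs columns freq (or freq_control) and or",
             "hlafinemap_validation_error")
  if ("reference" %in% names(tab)) tab <- tab[!tab$reference, , drop = FALSE]
  tab <- tab[is.finite(tab$or) & is.finite(tab$freq), , drop = FALSE]
  if (method == "sum")
    return(sum(mapply(variance_explained_liability, tab$freq, tab$or,
                      MoreArgs = list(prevalence = prevalence,
                                      rr_correction = rr_correction,
                                      scale = scale))))
  # joint Monte-Carlo: sum per-variant genotype liability shifts
  K <- prevalence
  shifts <- lapply(seq_len(nrow(tab)), function(i) {
    p <- tab$freq[i]; or <- tab$or[i]
    rr <- if (rr_correction) or / (1 - K + K * or) else or
    f <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    pen <- K * rr^(0:2) / sum(f * rr^(0:2))
    mu <- stats::qnorm(1 - K) - stats::qnorm(1 - pen)
    mu - sum(f * mu)
  })
  with_seed(seed, {
    total <- numeric(n_sim)
    for (i in seq_len(nrow(tab))) {
      g <- stats::rbinom(n_sim, 2, tab$freq[i])
      total <- total + shifts[[i]][g + 1]
    }
    V <- stats::var(total)
    if (scale == "proportion") V / (V + 1) else V
  })
}

#' Variance explained by a fitted multivariate model
#'
#' Convenience wrapper: applies [variance_explained_joint()] to the
#' non-reference rows of an [fit_full_multivariate()] table, using the
#' control-sample frequencies as population frequencies.
#'
#' @param object an `hla_mvfit` object.
#' @param prevalence disease prevalence.
#' @param ... passed to [variance_explained_joint()].
#' @export
variance_explained <- function(object, prevalence, ...) {
  variance_explained_joint(object, prevalence, ...)
}
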