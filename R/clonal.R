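#' @keywords internal
validateDoseResponse <- function(table) {
  need <- c("dose", "tested", "responding")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("dose-response table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(table$dose <= 0)) stop("doses must be positive")
  if (any(table$responding < 0 | table$responding > table$tested))
    stop("need 0 <= responding <= tested")
  invisible(table)
}

# Single-hit log-likelihood and derivatives on theta = log(f).
.shLogLik <- function(theta, d, n, r) {
  f <- exp(theta)
  sum(r * log(-expm1(-d * f)) - (n - r) * d * f)
}

.shScoreInfo <- function(theta, d, n, r) {
  f <- exp(theta)
  u <- exp(-d * f)
  dldf <- sum(r * d * u / (1 - u)) - sum((n - r) * d)
  d2ldf2 <- -sum(r * d^2 * u / (1 - u)^2)
  list(score = f * dldf, hess = f^2 * d2ldf2 + f * dldf)
}

#' Single-hit limiting dilution frequency estimate
#'
#' Maximum-likelihood fit of the single-hit Poisson model
#' `P(response at dose d) = 1 - exp(-d f)` to a dose-response table,
#' maximising `sum(r log(1 - exp(-d f)) - (n - r) d f)` over `log f` by
#' bounded search with Newton polishing. For a single dose with a partial
#' response the fit reproduces the closed form
#' `f = -log(1 - r/n) / d`. The 95% CI is Wald on `log f` by default;
#' `ci = "profile"` gives the profile-likelihood interval instead.
#'
#' @param table `data.frame` with columns `dose`, `tested`, `responding`.
#' @param ci `"wald"` (default) or `"profile"`.
#' @return an [LDAEstimate-class] object.
#' @examples
#' fitSingleHit(data.frame(dose = 1000, tested = 5, responding = 3))
#' @export
fitSingleHit <- function(table, ci = c("wald", "profile")) {
  ci <- match.arg(ci)
  validateDoseResponse(table)
  d <- table$dose; n <- table$tested; r <- table$responding
  if (all(r == 0)) stop("no responses: frequency not estimable (f -> 0)")
  if (all(r == n)) stop("saturated: all animals responded at every dose (f unbounded)")
  lo <- log(1e-9); hi <- log(1 - 1e-9)
  opt <- optimize(.shLogLik, c(lo, hi), d = d, n = n, r = r,
                  maximum = TRUE, tol = 1e-10)
  theta <- opt$maximum
  for (i in 1:5) {  # Newton polish to full relative precision
    si <- .shScoreInfo(theta, d, n, r)
    if (!is.finite(si$hess) || si$hess >= 0) break
    step <- si$score / si$hess
    theta_new <- min(max(theta - step, lo), hi)
    if (abs(theta_new - theta) < 1e-14 * max(1, abs(theta))) { theta <- theta_new; break }
    theta <- theta_new
  }
  f_hat <- exp(theta)
  ll <- .shLogLik(theta, d, n, r)
  info <- -.shScoreInfo(theta, d, n, r)$hess
  if (ci == "wald") {
    se <- if (info > 0) 1 / sqrt(info) else NA_real_
    lo_ci <- exp(theta - qnorm(0.975) * se)
    hi_ci <- min(exp(theta + qnorm(0.975) * se), 1 - 1e-12)
  } else {
    drop <- stats::qchisq(0.95, 1) / 2
    g <- function(th) .shLogLik(th, d, n, r) - (ll - drop)
    lo_ci <- exp(if (g(lo) < 0) uniroot(g, c(lo, theta), tol = 1e-10)$root else lo)
    hi_ci <- exp(if (g(hi) < 0) uniroot(g, c(theta, hi), tol = 1e-10)$root else hi)
  }
  new("LDAEstimate", fHat = f_hat, oneIn = 1 / f_hat,
      ciLower = lo_ci, ciUpper = hi_ci, logLik = ll,
      table = as.data.frame(table))
}

#' Likelihood-ratio comparison of two limiting-dilution frequencies
#'
#' Tests equality of the single-hit frequencies underlying two
#' dose-response tables: twice the log-likelihood gain of separate fits
#' over a pooled fit, referred to chi-squared with 1 df.
#'
#' @param tableA,tableB dose-response `data.frame`s (see
#'   [fitSingleHit()]).
#' @return list with `p`, `statistic`, and the two [LDAEstimate-class]
#'   fits `fitA`, `fitB`.
#' @export
compareFrequencies <- function(tableA, tableB) {
  fitA <- fitSingleHit(tableA)
  fitB <- fitSingleHit(tableB)
  pooled <- fitSingleHit(rbind(tableA[c("dose", "tested", "responding")],
                               tableB[c("dose", "tested", "responding")]))
  stat <- max(0, 2 * (fitA@logLik + fitB@logLik - pooled@logLik))
  list(p = pchisq(stat, df = 1, lower.tail = FALSE), statistic = stat,
       fitA = fitA, fitB = fitB)
}
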