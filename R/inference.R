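#' Censored-exponential lifetime estimate at one force
#'
#' Maximum-likelihood estimate of the characteristic lifetime tau of an
#' exponential survival process from dwell times with optional right
#' censoring: `tau = (sum of all dwells, censored included) / (number of
#' uncensored ruptures)`, the closed-form censored-exponential MLE. The
#' rupture rate is `k = 1/tau`. If every record is censored the estimate is
#' unbounded and flagged rather than raised as an error.
#'
#' @param dwells a [dwell_records()] data frame (all at one force), or a
#'   numeric vector of dwell times
#' @param censored logical vector when `dwells` is numeric
#' @param force force label in pN (taken from the records if present)
#' @return an object of class `lifetime_estimate`
#' @examples
#' fit_lifetime(dwell_records(45, c(2, 2, 2)))
#' @export
fit_lifetime <- function(dwells, censored = FALSE, force = NA_real_) {
  if (inherits(dwells, "data.frame")) {
    censored <- dwells$censored %||% rep(FALSE, nrow(dwells))
    if (is.na(force) && !is.null(dwells$force_pN))
      force <- unique(dwells$force_pN)[1]
    dwells <- dwells$dwell_s
  }
  if (length(censored) == 1L) censored <- rep(censored, length(dwells))
  n_unc <- sum(!censored)
  total <- sum(dwells)
  unbounded <- n_unc == 0L
  tau <- if (unbounded) Inf else total / n_unc
  structure(list(force_pN = force, tau_s = tau,
                 k_rupture = 1 / tau,
                 se_tau = if (unbounded) NA_real_ else tau / sqrt(n_unc),
                 n_obs = length(dwells), n_censored = sum(censored),
                 unbounded = unbounded),
            class = "lifetime_estimate")
}

#' @export
print.lifetime_estimate <- function(x, ...) {
  if (isTRUE(x$unbounded)) {
    cat(sprintf("<lifetime_estimate> force %g pN: all %d record(s) censored; tau unbounded\n",
                x$force_pN, x$n_obs))
    return(invisible(x))
  }
  se <- x$tau_se %||% x$se_tau
  cat(sprintf("<lifetime_estimate> force %g pN: tau = %.4g s (se %.3g), k = %.4g /s, n = %d (%d censored)\n",
              x$force_pN, x$tau_s, se, x$k_rupture, x$n_obs, x$n_censored))
  invisible(x)
}

#' Bootstrap configuration
#'
#' @param n_resamples number of bootstrap resamples M (>= 2; default 20)
#' @param rng_seed integer seed or `NULL`
#' @return an object of class `bootstrap_config`
#' @export
bootstrap_config <- function(n_resamples = 20, rng_seed = NULL) {
  if (n_resamples < 2) stop("'n_resamples' must be >= 2")
  structure(list(n_resamples = as.integer(n_resamples), rng_seed = rng_seed),
            class = "bootstrap_config")
}

# Single-resample rate estimate. "mle": censored-exponential closed form.
# "ecdf": least-squares fit of the empirical cumulative rupture probability
# P(t) = 1 - exp(-k t) on the uncensored dwells (the figure-style fit).
resample_rate <- function(dwell_s, censored, estimator) {
  if (estimator == "mle") {
    return(sum(!censored) / sum(dwell_s))
  }
  t_unc <- sort(dwell_s[!censored])
  n <- length(t_unc)
  P <- seq_len(n) / n
  k0 <- 1 / mean(t_unc)
  fit <- tryCatch(
    stats::nls(P ~ 1 - exp(-k * t_unc), start = list(k = k0),
               control = stats::nls.control(warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) k0 else stats::coef(fit)[["k"]]
}

#' Bootstrap estimate of the rupture rate and lifetime at one force
#'
#' Resampling procedure for dwell-time data: draw `M` resamples of size `N`
#' (the original sample size) with replacement, estimate the rupture rate
#' `k` on each, and report the mean, standard deviation and standard error
#' (sd/sqrt(M)) of both `k` and `tau = 1/k` over the M values. Resamples in
#' which every record is censored cannot be fitted and are redrawn (the
#' number of redraws is recorded).
#'
#' @param dwells a [dwell_records()] data frame at one force
#' @param cfg a [bootstrap_config()]
#' @param estimator `"mle"` (censored-exponential closed form, default) or
#'   `"ecdf"` (fit of the empirical cumulative rupture probability
#'   `P(t) = 1 - exp(-k t)`)
#' @return a `lifetime_estimate` with bootstrap fields `k_mean`, `k_sd`,
#'   `k_se`, `tau_mean`, `tau_sd`, `tau_se`, the resample values `boot_k`,
#'   and `redraws`
#' @export
bootstrap_rates <- function(dwells, cfg = bootstrap_config(),
                            estimator = c("mle", "ecdf")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(dwells, "data.frame"))
  N <- nrow(dwells)
  if (N < 2) stop("need at least 2 dwell records to bootstrap")
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  M <- cfg$n_resamples
  cens <- dwells$censored %||% rep(FALSE, N)
  ks <- numeric(M); redraws <- 0L
  for (m in seq_len(M)) {
    repeat {
      idx <- sample.int(N, N, replace = TRUE)
      if (any(!cens[idx])) break
      redraws <- redraws + 1L
      if (redraws > 1000L) stop("could not draw a resample with an uncensored record")
    }
    ks[m] <- resample_rate(dwells$dwell_s[idx], cens[idx], estimator)
  }
  taus <- 1 / ks
  point <- fit_lifetime(dwells)
  est <- structure(list(
    force_pN = point$force_pN, tau_s = point$tau_s,
    k_rupture = point$k_rupture,
    k_mean = mean(ks), k_sd = stats::sd(ks), k_se = stats::sd(ks) / sqrt(M),
    tau_mean = mean(taus), tau_sd = stats::sd(taus),
    tau_se = stats::sd(taus) / sqrt(M),
    boot_k = ks, n_obs = N, n_censored = sum(cens),
    M = M, estimator = estimator, seed = cfg$rng_seed,
    redraws = redraws, unbounded = point$unbounded),
    class = "lifetime_estimate")
  est
}

#' Fit the Bell model to force-dependent rupture rates
#'
#' Weighted least squares of `log k` against force: the slope is
#' `delta / kBT` and the intercept `log k0`. Weights default to inverse
#' squared standard errors of `log k` (delta method: `se(log k) = se/k`)
#' when `se` is supplied.
#'
#' @param points data frame with columns `force_pN`, `k` and optionally
#'   `se` (standard error of `k`); at least 2 forces
#' @param env a [polymer_env()]
#' @param weights `"se"` (default; falls back to equal weights when `se` is
#'   absent) or `"equal"`
#' @return an object of class `bell_fit` with components `params`
#'   ([bell_params()]), `se` (named standard errors of `k0` and `delta`),
#'   `cov` (covariance of `(log k0, delta)`), and the underlying `lm` fit
#' @examples
#' f <- c(10, 20, 30, 40)
#' k <- bell_rate(bell_params(1e-3, 0.5), f)
#' fit_bell(data.frame(force_pN = f, k = k))
#' @export
fit_bell <- function(points, env = polymer_env(),
                     weights = c("se", "equal")) {
  weights <- match.arg(weights)
  stopifnot(is.data.frame(points))
  if (length(unique(points$force_pN)) < 2)
    stop("need rates at >= 2 forces to fit the Bell model")
  if (any(points$k <= 0)) stop("rupture rates must be positive")
  w <- if (weights == "se" && !is.null(points$se) && all(points$se > 0))
    (points$k / points$se)^2 else rep(1, nrow(points))
  fit <- stats::lm(log(k) ~ force_pN, data = points, weights = w)
  co <- stats::coef(fit)
  V <- suppressWarnings(stats::vcov(fit))  # noiseless fits trip summary.lm
  k0 <- exp(co[[1]])
  delta <- co[[2]] * env$kBT
  se_logk0 <- sqrt(V[1, 1])
  se_delta <- sqrt(V[2, 2]) * env$kBT
  structure(list(params = bell_params(k0, delta),
                 se = c(k0 = k0 * se_logk0, delta = se_delta),
                 cov = V, lm = fit, env = env, points = points),
            class = "bell_fit")
}

#' @export
coef.bell_fit <- function(object, ...) {
  c(k0 = object$params$k0, delta = object$params$delta)
}

#' @export
print.bell_fit <- function(x, ...) {
  cat(sprintf("<bell_fit> k0 = %.4g /s (se %.3g), delta = %.4g nm (se %.3g)\n",
              x$params$k0, x$se[["k0"]], x$params$delta, x$se[["delta"]]))
  invisible(x)
}

#' @export
summary.bell_fit <- function(object, ...) {
  cat("Bell slip-bond fit: log k = log k0 + delta * f / kBT\n")
  print(object)
  cat(sprintf("  kBT = %g pN nm; %d force points\n",
              object$env$kBT, nrow(object$points)))
  if (!is.null(object$boot)) {
    cat(sprintf("  bootstrap (M = %d): k0 sd %.3g, delta sd %.3g nm\n",
                length(object$boot$k0), stats::sd(object$boot$k0),
                stats::sd(object$boot$delta)))
  }
  invisible(object)
}

#' Predict rupture rates or lifetimes from a Bell fit
#'
#' @param object a `bell_fit`
#' @param force forces in pN
#' @param type `"rate"` (1/s) or `"lifetime"` (s)
#' @param ... unused
#' @return numeric vector
#' @export
predict.bell_fit <- function(object, force, type = c("rate", "lifetime"), ...) {
  type <- match.arg(type)
  k <- bell_rate(object$params, force, object$env)
  if (type == "rate") k else 1 / k
}

#' @export
plot.bell_fit <- function(x, ...) {
  pts <- x$points
  graphics::plot(pts$force_pN, 1 / pts$k, log = "y", pch = 19,
                 xlab = "force (pN)", ylab = "lifetime (s)", ...)
  fgrid <- seq(min(pts$force_pN), max(pts$force_pN), length.out = 100)
  graphics::lines(fgrid, predict(x, fgrid, type = "lifetime"), col = "blue3")
  invisible(x)
}

#' Full dwell-table pipeline: per-force bootstrap plus Bell fit
#'
#' Runs the complete inference chain on a multi-force dwell table: a
#' censored-exponential point estimate and an M-resample bootstrap at each
#' force, then a weighted Bell fit of `log k` versus force. Bootstrap
#' uncertainties of `k0` and `delta` are propagated by refitting the line
#' to each bootstrap replicate of the per-force rates.
#'
#' @param dwells a [dwell_records()] data frame covering several forces
#' @param cfg a [bootstrap_config()]
#' @param env a [polymer_env()]
#' @param estimator passed to [bootstrap_rates()]
#' @return a `bell_fit` with extra components `estimates` (list of
#'   per-force `lifetime_estimate`s) and `boot` (data frame of bootstrap
#'   `k0`/`delta` replicates); `se` is replaced by the bootstrap standard
#'   deviations
#' @export
bell_from_dwells <- function(dwells, cfg = bootstrap_config(),
                             env = polymer_env(),
                             estimator = "mle") {
  stopifnot(inherits(dwells, "data.frame"))
  forces <- sort(unique(dwells$force_pN))
  if (length(forces) < 2) stop("need dwell data at >= 2 forces")
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  sub_cfg <- bootstrap_config(cfg$n_resamples, rng_seed = NULL)
  ests <- lapply(forces, function(f)
    bootstrap_rates(dwells[dwells$force_pN == f, , drop = FALSE],
                    sub_cfg, estimator = estimator))
  names(ests) <- as.character(forces)
  pts <- data.frame(force_pN = forces,
                    k = vapply(ests, `[[`, numeric(1), "k_rupture"),
                    se = vapply(ests, `[[`, numeric(1), "k_sd"))
  fit <- fit_bell(pts, env = env)
  M <- cfg$n_resamples
  boot <- data.frame(k0 = numeric(M), delta = numeric(M))
  for (m in seq_len(M)) {
    km <- vapply(ests, function(e) e$boot_k[m], numeric(1))
    bm <- fit_bell(data.frame(force_pN = forces, k = km), env = env,
                   weights = "equal")
    boot$k0[m] <- bm$params$k0
    boot$delta[m] <- bm$params$delta
  }
  fit$estimates <- ests
  fit$boot <- boot
  fit$se <- c(k0 = stats::sd(boot$k0), delta = stats::sd(boot$delta))
  fit$seed <- cfg$rng_seed
  fit
}

#' Gaussian fit of a rupture/refolding force histogram
#'
#' One- or two-component Gaussian fit of a force sample, as used to report
#' peak rupture and re-dimerization forces. The single-component fit is the
#' closed-form MLE; the two-component mixture is fitted by model-based
#' clustering (unequal variances, deterministic initialisation). Peaks are
#' returned sorted by ascending mean.
#'
#' @param forces numeric force sample in pN (>= 10 values)
#' @param n_components 1 or 2
#' @return an object of class `force_peaks`: data frame with columns
#'   `mean_pN`, `sd_pN`, `weight`
#' @export
fit_force_histogram <- function(forces, n_components = 1) {
  if (length(forces) < 10) stop("need at least 10 force values")
  if (!n_components %in% c(1, 2)) stop("'n_components' must be 1 or 2")
  if (stats::sd(forces) < 1e-12)
    stop("degenerate sample: zero spread, Gaussian sd undefined")
  if (n_components == 1) {
    out <- data.frame(mean_pN = mean(forces), sd_pN = stats::sd(forces),
                      weight = 1)
  } else {
    if (length(unique(forces)) < 2)
      stop("fewer distinct values than mixture components")
    bic <- mclust::mclustBIC(forces, G = 2, modelNames = "V", verbose = FALSE)
    mc <- mclust::Mclust(forces, G = 2, modelNames = "V", verbose = FALSE,
                         x = bic)
    if (is.null(mc)) stop("mixture fit failed")
    ord <- order(mc$parameters$mean)
    out <- data.frame(mean_pN = mc$parameters$mean[ord],
                      sd_pN = sqrt(mc$parameters$variance$sigmasq)[ord],
                      weight = mc$parameters$pro[ord])
  }
  rownames(out) <- NULL
  structure(out, class = c("force_peaks", "data.frame"))
}

#' Fit the re-dimerization probability curve
#'
#' Least-squares fit of the two-state logistic
#' \deqn{P_{re}(F) = \frac{1}{\exp((F - F_c)\Delta x/k_BT) + 1}}
#' to (force, probability) points; `Fc` is the force of half-maximal
#' re-dimerization (`P(Fc) = 0.5` exactly) and `delta_x > 0` the width
#' parameter. The complementary rupture probability is
#' `P_rupture = 1 - P_re`.
#'
#' @param points data frame with columns `force_pN` and `probability`
#'   (values in `[0, 1]`; >= 3 points)
#' @param env a [polymer_env()]
#' @return an object of class `redimer_fit` with `Fc`, `delta_x`, standard
#'   errors and the underlying `nls` fit
#' @export
fit_redimerization <- function(points, env = polymer_env()) {
  stopifnot(is.data.frame(points))
  if (nrow(points) < 3) stop("need at least 3 (force, probability) points")
  if (any(points$probability < 0 | points$probability > 1))
    stop("probabilities must lie in [0, 1]")
  kBT <- env$kBT
  Fc0 <- points$force_pN[which.min(abs(points$probability - 0.5))]
  fit <- minpack.lm::nlsLM(
    probability ~ 1 / (exp((force_pN - Fc) * dx / kBT) + 1),
    data = points, start = list(Fc = Fc0, dx = 1),
    lower = c(Fc = -Inf, dx = 1e-9))
  co <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(Fc = NA_real_, dx = NA_real_))
  structure(list(Fc = co[["Fc"]], delta_x = co[["dx"]],
                 se = c(Fc = unname(se[1]), delta_x = unname(se[2])),
                 nls = fit, env = env),
            class = "redimer_fit")
}

#' @export
print.redimer_fit <- function(x, ...) {
  cat(sprintf("<redimer_fit> Fc = %.4g pN (se %.3g), delta_x = %.4g nm (se %.3g)\n",
              x$Fc, x$se[["Fc"]], x$delta_x, x$se[["delta_x"]]))
  invisible(x)
}

#' @export
coef.redimer_fit <- function(object, ...) {
  c(Fc = object$Fc, delta_x = object$delta_x)
}

#' Predict re-dimerization or rupture probability
#'
#' @param object a `redimer_fit`
#' @param force forces in pN
#' @param type `"redimerization"` or `"rupture"` (its complement)
#' @param ... unused
#' @return probabilities in `[0, 1]`
#' @export
predict.redimer_fit <- function(object, force,
                                type = c("redimerization", "rupture"), ...) {
  type <- match.arg(type)
  p <- 1 / (exp((force - object$Fc) * object$delta_x / object$env$kBT) + 1)
  if (type == "redimerization") p else 1 - p
}

#' Two-component exponential mixture of dwell times
#'
#' EM fit of a mixture of exponentials, an exploratory option for dwell
#' populations with several coexisting sub-states (clustered lifetimes).
#' This automatic clustering goes beyond the per-cluster fitting of the
#' standard pipeline; assignments should be reviewed before use.
#'
#' @param dwell_s uncensored dwell times
#' @param k_components number of components (default 2)
#' @param max_iter,tol EM controls
#' @return list with `rates`, `weights`, `responsibilities`, `loglik`
#' @export
exp_mixture_fit <- function(dwell_s, k_components = 2, max_iter = 500,
                            tol = 1e-8) {
  x <- dwell_s
  n <- length(x)
  if (n < 2 * k_components) stop("too few dwells for the mixture")
  q <- stats::quantile(x, probs = (seq_len(k_components)) / (k_components + 1))
  lam <- sort(1 / as.numeric(q), decreasing = TRUE)
  w <- rep(1 / k_components, k_components)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k_components),
                   function(j) w[j] * stats::dexp(x, lam[j]), numeric(n))
    tot <- rowSums(dens)
    r <- dens / tot
    w <- colMeans(r)
    lam <- colSums(r) / colSums(r * x)
    ll <- sum(log(tot))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  ord <- order(lam, decreasing = TRUE)
  list(rates = lam[ord], weights = w[ord],
       responsibilities = r[, ord, drop = FALSE], loglik = ll)
}
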