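#' Fraction of labeled target bound at 1:1 stoichiometry
#'
#' Exact mass-action solution with target depletion: the fraction of the
#' fixed labeled species T bound by titrant L is the quadratic root
#' \deqn{f_b = \frac{(L+T+K_D) - \sqrt{(L+T+K_D)^2 - 4LT}}{2T}.}
#' This matters when T (here 50 nM) is not negligible against sub-uM K_D.
#' The hyperbolic approximation L/(L+K_D) is available via
#' `model = "hyperbolic"`.
#'
#' @param L titrant concentration(s), uM (vectorized)
#' @param T_conc fixed labeled-target concentration, uM
#' @param kd dissociation constant, uM
#' @param model "quadratic" (depletion, default) or "hyperbolic"
#' @return fraction bound in [0, 1)
#' @export
fraction_bound <- function(L, T_conc, kd, model = c("quadratic", "hyperbolic")) {
  model <- match.arg(model)
  if (any(L < 0)) stop("titrant concentration must be >= 0", call. = FALSE)
  if (T_conc <= 0) stop("target concentration must be > 0", call. = FALSE)
  if (kd <= 0) stop("dissociation constant must be > 0", call. = FALSE)
  if (model == "hyperbolic") return(L / (L + kd))
  s <- L + T_conc + kd
  disc <- pmax(s^2 - 4 * L * T_conc, 0)
  (s - sqrt(disc)) / (2 * T_conc)
}

# Profiled residual sum of squares: for fixed kd the model is linear in each
# replicate's (r_free, amplitude), solved by per-replicate least squares.
.kd_profile <- function(log10_kd, L, y, rep_id, T_conc, model) {
  fb <- fraction_bound(L, T_conc, 10^log10_kd, model = model)
  sse <- 0
  coefs <- list()
  for (r in unique(rep_id)) {
    sel <- rep_id == r
    fit <- stats::lm.fit(cbind(1, fb[sel]), y[sel])
    sse <- sse + sum(fit$residuals^2)
    coefs[[as.character(r)]] <- fit$coefficients
  }
  list(sse = sse, coefs = coefs, fb = fb)
}

#' Fit a 1:1 binding isotherm to a titration curve
#'
#' Least-squares fit of response(L) = r_free + (r_bound - r_free) * f_b(L)
#' with K_D optimized on a log10 scale (Brent, bounded to [1e-6, 1e6] uM).
#' Replicates share K_D; baseline and amplitude are fitted per replicate
#' (profiled out by linear least squares at each K_D).
#'
#' @param curve data.frame with columns `titrant_conc_uM`, `response`, and
#'   optionally `replicate` (defaults to a single replicate)
#' @param target_conc_uM fixed labeled-target concentration in uM
#'   (default 0.05, i.e. 50 nM)
#' @param model "quadratic" (default) or "hyperbolic"
#' @return object of class `binding_fit`: `kd_uM`, `r_free`, `r_bound`
#'   (named per-replicate vectors), `residual_sse`, `converged`, `n_points`
#' @export
fit_kd <- function(curve, target_conc_uM = 0.05,
                   model = c("quadratic", "hyperbolic")) {
  model <- match.arg(model)
  stopifnot(is.data.frame(curve),
            all(c("titrant_conc_uM", "response") %in% names(curve)))
  L <- curve$titrant_conc_uM
  y <- curve$response
  rep_id <- if ("replicate" %in% names(curve)) curve$replicate else rep(1L, length(L))
  if (any(L <= 0)) stop("titrant concentrations must be strictly positive", call. = FALSE)
  if (length(L) < 5L) stop("at least 5 titration points are required", call. = FALSE)
  if (stats::sd(y) == 0) {
    stop("responses are flat: K_D is not identifiable", call. = FALSE)
  }
  obj <- function(lk) .kd_profile(lk, L, y, rep_id, target_conc_uM, model)$sse
  opt <- stats::optim(par = log10(stats::median(L)), fn = obj,
                      method = "Brent", lower = -6, upper = 6)
  prof <- .kd_profile(opt$par, L, y, rep_id, target_conc_uM, model)
  r_free <- vapply(prof$coefs, `[[`, numeric(1), 1L)
  amp <- vapply(prof$coefs, `[[`, numeric(1), 2L)
  structure(list(
    kd_uM = 10^opt$par,
    r_free = r_free,
    r_bound = r_free + amp,
    residual_sse = prof$sse,
    converged = opt$convergence == 0L && is.finite(opt$value),
    n_points = length(L),
    model = model,
    target_conc_uM = target_conc_uM
  ), class = "binding_fit")
}

#' Residual-bootstrap confidence interval for a fitted K_D
#'
#' Resamples residuals of the fitted curve, refits, and reports percentile
#' bounds for K_D.
#'
#' @param fit a `binding_fit`
#' @param curve the data.frame that produced it
#' @param n_boot bootstrap replicates
#' @param level confidence level
#' @param seed RNG seed
#' @return named vector c(lower, upper) in uM
#' @export
kd_bootstrap_ci <- function(fit, curve, n_boot = 200L, level = 0.95, seed = 1L) {
  L <- curve$titrant_conc_uM
  rep_id <- if ("replicate" %in% names(curve)) curve$replicate else rep(1L, nrow(curve))
  fb <- fraction_bound(L, fit$target_conc_uM, fit$kd_uM, model = fit$model)
  pred <- fit$r_free[as.character(rep_id)] +
    (fit$r_bound[as.character(rep_id)] - fit$r_free[as.character(rep_id)]) * fb
  resid <- curve$response - pred
  kds <- with_preserved_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      yb <- pred + sample(resid, replace = TRUE)
      cb <- curve
      cb$response <- yb
      fit_kd(cb, target_conc_uM = fit$target_conc_uM, model = fit$model)$kd_uM
    }, numeric(1))
  })
  a <- (1 - level) / 2
  stats::quantile(kds, c(a, 1 - a), names = FALSE) |>
    stats::setNames(c("lower", "upper"))
}

#' Fold change between two dissociation constants
#'
#' Ratio max/min with a direction call: a variant with larger K_D binds
#' more weakly than the reference.
#'
#' @param kd_variant,kd_reference dissociation constants, uM
#' @return list with `ratio` (>= 1), `ratio_rounded` (one decimal, the
#'   conventional reporting style), `direction` ("stronger", "weaker" or
#'   "equal")
#' @export
fold_change <- function(kd_variant, kd_reference) {
  if (kd_variant <= 0 || kd_reference <= 0) {
    stop("dissociation constants must be positive", call. = FALSE)
  }
  ratio <- max(kd_variant, kd_reference) / min(kd_variant, kd_reference)
  direction <- if (kd_variant > kd_reference) "weaker"
               else if (kd_variant < kd_reference) "stronger"
               else "equal"
  list(ratio = ratio, ratio_rounded = round(ratio, 1), direction = direction)
}
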