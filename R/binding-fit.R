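# Levenberg-Marquardt least squares with numerical Jacobian.
# Written in-package because the noise-free recovery contract (kd to 1e-6
# relative on exact curves) needs a solver that is robust on zero-residual
# problems; returns list(theta, rss, converged, cov).
.lm_fit <- function(theta0, resid_fn, max_iter = 200L, ftol = 1e-14,
                    ptol = 1e-12) {
  theta <- theta0
  r <- resid_fn(theta)
  rss <- sum(r * r)
  lambda <- 1e-3
  converged <- FALSE
  np <- length(theta)
  jac <- function(th) {
    J <- matrix(0, length(r), np)
    for (j in seq_len(np)) {
      h <- max(1e-7, 1e-7 * abs(th[j]))
      tp <- th; tp[j] <- tp[j] + h
      tm <- th; tm[j] <- tm[j] - h
      J[, j] <- (resid_fn(tp) - resid_fn(tm)) / (2 * h)
    }
    J
  }
  for (it in seq_len(max_iter)) {
    J <- jac(theta)
    g <- crossprod(J, r)
    JtJ <- crossprod(J)
    improved <- FALSE
    for (sub in 1:25) {
      A <- JtJ + lambda * diag(pmax(diag(JtJ), 1e-12), np)
      delta <- tryCatch(solve(A, g), error = function(e) NULL)
      if (is.null(delta)) { lambda <- lambda * 10; next }
      cand <- theta - as.numeric(delta)
      rc <- resid_fn(cand)
      rssc <- sum(rc * rc)
      if (is.finite(rssc) && rssc <= rss) {
        step_small <- max(abs(as.numeric(delta)) /
                            pmax(abs(theta), 1)) < ptol
        rss_small <- (rss - rssc) <= ftol * (rss + 1e-300)
        theta <- cand; r <- rc; rss <- rssc
        lambda <- max(lambda / 10, 1e-12)
        improved <- TRUE
        if (step_small || rss_small) converged <- TRUE
        break
      }
      lambda <- lambda * 10
    }
    if (!improved || converged) {
      if (!improved) converged <- TRUE  # no downhill step exists: at minimum
      break
    }
  }
  J <- jac(theta)
  dof <- max(length(r) - np, 1L)
  s2 <- rss / dof
  cov <- tryCatch(solve(crossprod(J)) * s2, error = function(e) {
    matrix(NA_real_, np, np)
  })
  list(theta = theta, rss = rss, converged = converged, cov = cov)
}

# Fit one replicate; theta = (log kd, b, c, k[, log m]).
# With weights = NULL, iteratively reweighted least squares is used: an
# unweighted pass, then a pass weighted by the inverse squared fitted
# *signal* (mu_hat - c_hat, floored at 5% of the span) — close to the
# likelihood weighting for multiplicative (CV-type) fluorescence noise,
# while exactly invariant under affine rescaling f -> alpha f + beta
# (weights then scale by 1/alpha^2 uniformly). Explicit weights switch
# IRLS off.
.fit_one <- function(a, f, n, model, stoichiometry, weights,
                     rss_lin = Inf) {
  irls <- is.null(weights)
  w <- if (irls) rep(1, length(a)) else weights
  sw <- sqrt(w)
  resid_fn <- function(theta) {
    sw * (f - .eval_model(a, theta, n, model, stoichiometry))
  }
  span <- diff(range(f))
  c0 <- f[which.min(a)]
  b0 <- if (span > 0) span else 1
  # kd0: concentration at half the observed range
  half <- c0 + span / 2
  kd0 <- a[which.min(abs(f - half))]
  if (kd0 <= 0) kd0 <- max(a) / 10
  nt <- length(a)
  tail_idx <- unique(pmax(1L, (nt - 2L):nt))
  k0 <- if (length(tail_idx) >= 2) {
    stats::coef(stats::lm(f[tail_idx] ~ a[tail_idx]))[2L]
  } else 0
  if (!is.finite(k0)) k0 <- 0
  make_theta <- function(kd) {
    th <- c(log(kd), b0, c0, as.numeric(k0))
    if (stoichiometry) th <- c(th, 0)
    th
  }
  fit <- .lm_fit(make_theta(kd0), resid_fn)
  # Multistart over log-spaced kd0 when the first attempt is poor: not
  # converged, or no better than a straight line (a sign of a bad basin).
  if (!fit$converged || fit$rss > 0.5 * rss_lin) {
    for (kd_try in exp(seq(log(max(max(a) / 1000, 1e-3)), log(max(a) * 2),
                           length.out = 5))) {
      alt <- .lm_fit(make_theta(kd_try), resid_fn)
      if (alt$rss < fit$rss) fit <- alt
    }
  }
  if (irls) {
    mu <- .eval_model(a, fit$theta, n, model, stoichiometry)
    sig <- abs(mu - fit$theta[3L])
    floor_ <- 0.05 * max(max(sig), 1e-12)
    sw <- 1 / pmax(sig, floor_)
    refit <- .lm_fit(fit$theta, resid_fn)
    if (refit$converged) fit <- refit
  }
  fit
}

#' Fit a titration curve to the quadratic or hyperbolic binding model
#'
#' Estimates the dissociation constant K_D (with the optical constants b, c
#' and the linear drift k) from a fluorescence titration by weighted least
#' squares, using a log-parameterisation to keep `kd` positive. Each
#' replicate is fitted independently and the dissociation constant is
#' reported as mean +/- s.d. across replicates, matching how triplicate
#' experimental titrations are summarised. Optionally a stoichiometry
#' multiplier `m` scaling the varied-species concentration entering the
#' binding term (`a_eff = m * a`) is estimated as a fifth parameter.
#'
#' Initialisation: `kd0` at the concentration reaching half the observed
#' fluorescence range, `b0` the observed span, `c0` the zero-protein
#' fluorescence, `k0` the terminal slope; non-convergence triggers a
#' multistart over five log-spaced `kd0` values. A curve whose signal,
#' beyond a straight line in `a`, is indistinguishable from flat is flagged
#' `no_interaction` rather than producing an arbitrary K_D, and
#' non-convergence is flagged, not thrown.
#'
#' @param curve A [titration_curve()] (or data frame with columns
#'   `replicate`, `a_uM`, `fluorescence`).
#' @param model `"quadratic"` (exact, default) or `"hyperbolic"`
#'   (pseudo-first-order).
#' @param n_fixed Fixed peptide concentration (uM); defaults to the curve's
#'   `n_fixed` attribute.
#' @param stoichiometry If `TRUE`, also estimate the stoichiometry
#'   multiplier `m`.
#' @param weights Optional per-point weights (recycled across replicates).
#' @return An object of class `titration_fit` with components `model`,
#'   `estimates` (kd, b, c, k and optionally m, averaged across
#'   replicates), `se` (standard errors; across-replicate s.d. of kd when
#'   replicated, else from the fit covariance), `kd_replicates`, `kd_mean`,
#'   `kd_sd`, `rss`, `converged`, `no_interaction`, `replicate_fits`,
#'   and the data.
#' @examples
#' wt <- binding_presets()[["wt_fbw7g"]]$params
#' curve <- make_titration(wt, titration_design(seq(0, 200, length.out = 25),
#'                                              replicates = 1, noise_cv = 0))
#' fit <- fit_titration(curve)
#' coef(fit)["kd"]
#' @export
fit_titration <- function(curve, model = c("quadratic", "hyperbolic"),
                          n_fixed = NULL, stoichiometry = FALSE,
                          weights = NULL) {
  model <- match.arg(model)
  if (!inherits(curve, "titration_curve")) curve <- titration_curve(curve)
  n <- if (is.null(n_fixed)) attr(curve, "n_fixed") else n_fixed
  reps <- sort(unique(curve$replicate))
  a_all <- curve$a_uM
  if (length(unique(a_all)) < 5L) {
    stop("need at least 5 distinct protein concentrations")
  }
  if (all(a_all == 0)) stop("need at least one nonzero protein concentration")

  par_names <- c("kd", "b", "c", "k", if (stoichiometry) "m")
  rep_fits <- lapply(reps, function(r) {
    idx <- curve$replicate == r
    a <- curve$a_uM[idx]
    f <- curve$fluorescence[idx]
    # No-interaction screen: does the binding term improve on a line?
    lin <- stats::lm(f ~ a)
    rss_lin <- sum(stats::residuals(lin)^2)
    tss <- sum((f - mean(f))^2)
    if (diff(range(f)) == 0 || rss_lin <= 1e-12 * max(tss, 1e-300)) {
      return(list(no_interaction = TRUE, rss = rss_lin))
    }
    fit <- .fit_one(a, f, n, model, stoichiometry, weights,
                    rss_lin = rss_lin)
    est <- fit$theta
    est[1L] <- exp(est[1L])
    if (stoichiometry) est[5L] <- exp(est[5L])
    se <- sqrt(pmax(diag(fit$cov), 0))
    # delta method for the log-parameterised entries
    se[1L] <- se[1L] * est[1L]
    if (stoichiometry) se[5L] <- se[5L] * est[5L]
    list(no_interaction = FALSE, estimates = setNames(est, par_names),
         se = setNames(se, par_names), rss = fit$rss,
         converged = fit$converged)
  })
  names(rep_fits) <- paste0("replicate_", reps)

  no_int <- vapply(rep_fits, `[[`, logical(1), "no_interaction")
  if (all(no_int)) {
    out <- list(model = model, no_interaction = TRUE, converged = TRUE,
                estimates = setNames(rep(NA_real_, length(par_names)),
                                     par_names),
                se = setNames(rep(NA_real_, length(par_names)), par_names),
                kd_replicates = rep(NA_real_, length(reps)),
                kd_mean = NA_real_, kd_sd = NA_real_,
                rss = sum(vapply(rep_fits, `[[`, numeric(1), "rss")),
                n_fixed = n, stoichiometry = stoichiometry,
                replicate_fits = rep_fits, data = curve)
    class(out) <- "titration_fit"
    return(out)
  }
  ok <- rep_fits[!no_int]
  est_mat <- do.call(rbind, lapply(ok, `[[`, "estimates"))
  kd_reps <- est_mat[, "kd"]
  estimates <- colMeans(est_mat)
  se <- if (length(ok) > 1L) {
    apply(est_mat, 2L, sd)
  } else {
    ok[[1L]]$se
  }
  out <- list(model = model, no_interaction = FALSE,
              converged = all(vapply(ok, `[[`, logical(1), "converged")),
              estimates = estimates, se = se,
              kd_replicates = unname(kd_reps),
              kd_mean = mean(kd_reps),
              kd_sd = if (length(kd_reps) > 1L) sd(kd_reps) else NA_real_,
              rss = sum(vapply(ok, `[[`, numeric(1), "rss")),
              n_fixed = n, stoichiometry = stoichiometry,
              replicate_fits = rep_fits, data = curve)
  class(out) <- "titration_fit"
  out
}

#' @export
print.titration_fit <- function(x, ...) {
  cat("Titration fit (", x$model, " model, n_fixed = ", x$n_fixed,
      " uM)\n", sep = "")
  if (x$no_interaction) {
    cat("  No interaction detected (flat signal)\n")
    return(invisible(x))
  }
  cat(sprintf("  K_D = %.4g uM", x$kd_mean))
  if (!is.na(x$kd_sd)) cat(sprintf(" +/- %.2g (s.d., %d replicates)",
                                   x$kd_sd, length(x$kd_replicates)))
  cat("\n")
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
summary.titration_fit <- function(object, ...) {
  tab <- cbind(estimate = object$estimates, se = object$se)
  structure(list(fit = object, coefficients = tab),
            class = "summary.titration_fit")
}

#' @export
print.summary.titration_fit <- function(x, ...) {
  print(x$fit)
  if (!x$fit$no_interaction) {
    cat("\nCoefficients (replicate means):\n")
    print(signif(x$coefficients, 5))
    cat("\nResidual sum of squares:", format(x$fit$rss, digits = 4), "\n")
  }
  invisible(x)
}

#' @export
coef.titration_fit <- function(object, ...) object$estimates

#' @export
residuals.titration_fit <- function(object, ...) {
  object$data$fluorescence - predict(object)
}

#' Predicted fluorescence from a titration fit
#'
#' @param object A `titration_fit`.
#' @param newdata Optional numeric vector of protein concentrations (uM);
#'   defaults to the fitted concentrations.
#' @param ... Unused.
#' @return Predicted fluorescence values.
#' @export
predict.titration_fit <- function(object, newdata = NULL, ...) {
  if (object$no_interaction) stop("no-interaction fit has no model curve")
  a <- if (is.null(newdata)) object$data$a_uM else newdata
  e <- object$estimates
  p <- binding_params(kd = e[["kd"]], n = object$n_fixed, b = e[["b"]],
                      c = e[["c"]], k = e[["k"]])
  a_eff_scale <- if (object$stoichiometry) e[["m"]] else 1
  p$c + p$k * a + p$b *
    bound_complex(a_eff_scale * a, p$n, p$kd) / p$n
}

#' @export
plot.titration_fit <- function(x, ...) {
  d <- x$data
  plot(d$a_uM, d$fluorescence, xlab = "[protein] (uM)",
       ylab = "fluorescence (a.u.)", pch = as.integer(d$replicate), ...)
  if (!x$no_interaction) {
    aa <- seq(min(d$a_uM), max(d$a_uM), length.out = 200)
    graphics::lines(aa, predict(x, aa))
  }
  invisible(x)
}

#' Simulate replicate curves from a fitted titration model
#'
#' @param object A converged `titration_fit`.
#' @param nsim Number of replicate curves.
#' @param seed RNG seed.
#' @param noise_cv Multiplicative noise CV (default 0.02).
#' @param ... Unused.
#' @return A `titration_curve`.
#' @export
simulate.titration_fit <- function(object, nsim = 1, seed = NULL,
                                   noise_cv = 0.02, ...) {
  if (object$no_interaction) stop("cannot simulate from a no-interaction fit")
  e <- object$estimates
  p <- binding_params(kd = e[["kd"]], n = object$n_fixed, b = e[["b"]],
                      c = e[["c"]], k = e[["k"]])
  a <- sort(unique(object$data$a_uM))
  make_titration(p, titration_design(a, replicates = nsim,
                                     noise_cv = noise_cv, seed = seed))
}

#' Mutant / wild-type dissociation-constant fold change
#'
#' @param mutant,wt Converged `titration_fit` objects (or bare K_D values).
#' @return A list with `ratio` (kd_mutant / kd_wt) and `rounded` (one
#'   significant figure), e.g. 22.0/3.2 = 6.875 -> 7-fold.
#' @examples
#' fold_change(22.0, 3.2)$rounded  # 7
#' @export
fold_change <- function(mutant, wt) {
  kd_of <- function(x) {
    if (inherits(x, "titration_fit")) {
      if (x$no_interaction || !x$converged) {
        stop("fold_change needs converged, interacting fits")
      }
      x$kd_mean
    } else {
      stopifnot(is.numeric(x), length(x) == 1L)
      x
    }
  }
  kd_m <- kd_of(mutant)
  kd_w <- kd_of(wt)
  if (kd_w <= 0) stop("wild-type K_D must be positive")
  ratio <- kd_m / kd_w
  list(ratio = ratio, rounded = signif(ratio, 1))
}
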