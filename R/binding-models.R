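#' Binding-model parameter set
#'
#' Bundles the parameters of the equilibrium titration models: the
#' dissociation constant `kd`, the fixed (non-varied) species concentration
#' `n` (the dansylated peptide, held constant during a titration), the total
#' fluorescence change at saturation `b`, the fluorescence at zero protein
#' `c`, and the linear drift `k` describing the slope of the curve at high
#' protein concentration.
#'
#' @param kd Dissociation constant (uM). Must be positive.
#' @param n Total concentration of the non-varied species, i.e. the peptide
#'   (uM). Must be positive.
#' @param b Total fluorescence change at saturation (arbitrary units).
#' @param c Fluorescence at zero protein concentration (arbitrary units).
#' @param k Linear slope at high protein concentration (fluorescence units
#'   per uM). Non-negative by default use; negative values are allowed when
#'   constructing fitted parameter sets.
#' @return An object of class `binding_params` (a named list).
#' @examples
#' binding_params(kd = 3.2)
#' @export
binding_params <- function(kd, n = 5, b = 1, c = 0, k = 0.001) {
  stopifnot(is.numeric(kd), length(kd) == 1L, is.finite(kd), kd > 0)
  stopifnot(is.numeric(n), length(n) == 1L, is.finite(n), n > 0)
  stopifnot(is.finite(b), is.finite(c), is.finite(k))
  structure(list(kd = kd, n = n, b = b, c = c, k = k),
            class = "binding_params")
}

#' @export
print.binding_params <- function(x, ...) {
  cat("Binding parameters: kd =", x$kd, "uM, n =", x$n,
      "uM, b =", x$b, ", c =", x$c, ", k =", x$k, "per uM\n")
  invisible(x)
}

#' Equilibrium concentration of the bound complex
#'
#' Solves the bimolecular equilibrium A + P <-> AP for the complex
#' concentration at total varied-species concentration `a`, fixed-species
#' concentration `n` and dissociation constant `kd`:
#' `((n + a + kd) - sqrt((n + a + kd)^2 - 4 n a)) / 2`.
#' The result always lies in `[0, min(n, a)]`; the discriminant is clamped
#' at zero to guard against round-off for near-stoichiometric inputs.
#'
#' @param a Total varied-species (protein) concentration(s), uM, >= 0.
#' @param n Total non-varied species (peptide) concentration, uM, > 0.
#' @param kd Dissociation constant, uM, > 0.
#' @return Complex concentration(s), uM (vectorised over `a`).
#' @examples
#' bound_complex(200, n = 5, kd = 3.2)
#' @export
bound_complex <- function(a, n, kd) {
  stopifnot(all(a >= 0), n > 0, kd > 0)
  s <- n + a + kd
  disc <- pmax(s * s - 4 * n * a, 0)
  (s - sqrt(disc)) / 2
}

#' Quadratic (exact) titration model
#'
#' Observed fluorescence as a function of the varied-species concentration
#' under the exact two-species equilibrium:
#' `F(a) = c + k * a + b * bound_complex(a, n, kd) / n`.
#'
#' @param a Protein concentration(s), uM.
#' @param params A [binding_params()] object.
#' @return Fluorescence value(s), arbitrary units.
#' @seealso [hyperbolic_model()] for the pseudo-first-order simplification.
#' @examples
#' quadratic_model(200, binding_params(kd = 3.2))
#' @export
quadratic_model <- function(a, params) {
  stopifnot(inherits(params, "binding_params"))
  params$c + params$k * a +
    params$b * bound_complex(a, params$n, params$kd) / params$n
}

#' Hyperbolic (pseudo-first-order) titration model
#'
#' Simplification of the quadratic model valid when the varied species is in
#' large excess over the fixed species (n/kd -> 0):
#' `F(a) = c + k * a + b * a / (kd + a)`.
#'
#' @inheritParams quadratic_model
#' @return Fluorescence value(s), arbitrary units.
#' @examples
#' hyperbolic_model(3.2, binding_params(kd = 3.2, k = 0))  # c + b/2
#' @export
hyperbolic_model <- function(a, params) {
  stopifnot(inherits(params, "binding_params"))
  params$c + params$k * a + params$b * a / (params$kd + a)
}

# Shared evaluator used by the fitter: theta on the fitting scale
# (log kd, b, c, k[, log m]); `m` multiplies the varied-species
# concentration entering the binding term (stoichiometry multiplier).
.eval_model <- function(a, theta, n, model, stoichiometry) {
  # clamp the log-scale parameters so trial LM steps cannot overflow
  kd <- exp(min(max(theta[1L], -30), 30))
  b <- theta[2L]; cc <- theta[3L]; k <- theta[4L]
  a_eff <- if (stoichiometry) exp(min(max(theta[5L], -30), 30)) * a else a
  if (model == "quadratic") {
    cc + k * a + b * bound_complex(a_eff, n, kd) / n
  } else {
    cc + k * a + b * a_eff / (kd + a_eff)
  }
}
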