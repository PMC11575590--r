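## Thermodynamics layer: activity coefficients from any dimensionless Gibbs
## excess energy function by exact differentiation, plus the consistency
## checkers (pure-component limits, Gibbs-Duhem, identical components,
## permutation equivariance).
##
## For a binary mixture with gbar(x1, T) = g^E / (R T):
##   ln gamma_1 = gbar + (1 - x1) * dgbar/dx1
##   ln gamma_2 = gbar -      x1  * dgbar/dx1
## These are the unique relations compatible with gbar = x1 ln g1 + x2 ln g2
## and the Gibbs-Duhem equation at constant T and p.

#' Wrap a dimensionless Gibbs excess energy model
#'
#' A `ge_function` bundles `gbar(x1, T) = g^E/(R T)` with its exact first and
#' second composition derivatives, so analytic models and the neural network
#' share every downstream tool (activity coefficients, consistency checks,
#' phase diagrams).  Derivatives must be exact (closed form or automatic);
#' finite differences are only ever used in tests as an independent oracle.
#'
#' @param f Function `(x1, T) -> gbar` (vectorized in `x1`).
#' @param df Function `(x1, T) -> dgbar/dx1`.
#' @param d2f Function `(x1, T) -> d2gbar/dx1^2` (optional; needed by the
#'   Gibbs-Duhem checker and azeotrope classification).
#' @param label Human-readable tag.
#' @return An object of class `ge_function`.
#' @export
ge_function <- function(f, df, d2f = NULL, label = "ge") {
  stopifnot(is.function(f), is.function(df), is.null(d2f) || is.function(d2f))
  structure(list(f = f, df = df, d2f = d2f, label = label),
            class = "ge_function")
}

#' @export
print.ge_function <- function(x, ...) {
  cat(sprintf("<ge_function '%s'%s>\n", x$label,
              if (is.null(x$d2f)) " (no second derivative)" else ""))
  invisible(x)
}

#' Two-parameter Margules model as a `ge_function`
#'
#' `gbar = x1 x2 (A21 x1 + A12 x2)`; temperature-independent.
#'
#' @param A12,A21 Margules coefficients (dimensionless).
#' @return A [ge_function()].
#' @export
ge_margules <- function(A12, A21) {
  ge_function(
    f = function(x1, T) x1 * (1 - x1) * (A21 * x1 + A12 * (1 - x1)),
    df = function(x1, T) A21 * (2 * x1 - 3 * x1^2) +
      A12 * (1 - 4 * x1 + 3 * x1^2),
    d2f = function(x1, T) A21 * (2 - 6 * x1) + A12 * (6 * x1 - 4),
    label = sprintf("margules2(A12=%.4g, A21=%.4g)", A12, A21)
  )
}

#' NRTL model as a `ge_function`
#'
#' `gbar = x1 x2 (tau21 G21 / (x1 + x2 G21) + tau12 G12 / (x2 + x1 G12))`
#' with `Gij = exp(-alpha tau_ij)`; temperature-independent parameters.
#'
#' @param tau12,tau21 Interaction parameters.
#' @param alpha Non-randomness parameter, in (0, 1].
#' @return A [ge_function()].
#' @export
ge_nrtl <- function(tau12, tau21, alpha) {
  stopifnot(alpha > 0, alpha <= 1)
  G12 <- exp(-alpha * tau12)
  G21 <- exp(-alpha * tau21)
  FF <- function(x1) {
    tau21 * G21 / (x1 + (1 - x1) * G21) + tau12 * G12 / ((1 - x1) + x1 * G12)
  }
  FF1 <- function(x1) {
    -tau21 * G21 * (1 - G21) / (x1 + (1 - x1) * G21)^2 -
      tau12 * G12 * (G12 - 1) / ((1 - x1) + x1 * G12)^2
  }
  FF2 <- function(x1) {
    2 * tau21 * G21 * (1 - G21)^2 / (x1 + (1 - x1) * G21)^3 +
      2 * tau12 * G12 * (G12 - 1)^2 / ((1 - x1) + x1 * G12)^3
  }
  ge_function(
    f = function(x1, T) x1 * (1 - x1) * FF(x1),
    df = function(x1, T) (1 - 2 * x1) * FF(x1) + x1 * (1 - x1) * FF1(x1),
    d2f = function(x1, T) -2 * FF(x1) + 2 * (1 - 2 * x1) * FF1(x1) +
      x1 * (1 - x1) * FF2(x1),
    label = sprintf("nrtl(tau12=%.4g, tau21=%.4g, alpha=%.3g)",
                    tau12, tau21, alpha)
  )
}

#' Neural-network model for one system as a `ge_function`
#'
#' Fixes the component pair and exposes the network's `gbar(x1, T)` with its
#' exact first and second composition derivatives (forward-mode
#' differentiation through the network; SiLU is smooth, so the derivatives
#' exist everywhere on `[0, 1]`).
#'
#' @param model A `hanna` object.
#' @param smiles_1,smiles_2 Component identifiers.
#' @return A [ge_function()].
#' @export
ge_hanna <- function(model, smiles_1, smiles_2) {
  stopifnot(inherits(model, "hanna"))
  force(smiles_1); force(smiles_2)
  eval_ord <- function(x1, T, order) {
    n <- max(length(x1), length(T))
    hanna_eval_records(model, rep_len(smiles_1, n), rep_len(smiles_2, n),
                       rep_len(T, n), rep_len(x1, n), order = order)
  }
  ge_function(
    f = function(x1, T) eval_ord(x1, T, 0L)$gbar,
    df = function(x1, T) eval_ord(x1, T, 1L)$gbar1,
    d2f = function(x1, T) eval_ord(x1, T, 2L)$gbar2,
    label = sprintf("hanna(%s | %s)", smiles_1, smiles_2)
  )
}

#' Activity coefficients from a Gibbs excess energy model
#'
#' Exact differentiation of `gbar = g^E/(R T)`:
#' `ln gamma_1 = gbar + (1 - x1) gbar'`, `ln gamma_2 = gbar - x1 gbar'`.
#'
#' @param ge A [ge_function()].
#' @param x1 Mole fraction(s) in `[0, 1]`.
#' @param T Temperature(s), Kelvin.
#' @return Data frame with `x1`, `T`, `gE` (J/mol), `ln_gamma_1`,
#'   `ln_gamma_2`.
#' @examples
#' ge <- ge_margules(1, 1)
#' activity_coefficients(ge, x1 = 0.25, T = 298.15)
#' @export
activity_coefficients <- function(ge, x1, T) {
  stopifnot(inherits(ge, "ge_function"), all(x1 >= 0 & x1 <= 1), all(T > 0))
  n <- max(length(x1), length(T))
  x1 <- rep_len(x1, n)
  T <- rep_len(T, n)
  g <- ge$f(x1, T)
  g1 <- ge$df(x1, T)
  if (any(!is.finite(g)) || any(!is.finite(g1)))
    stop_hanna("non_finite_derivative",
               "gbar or its derivative is not finite")
  data.frame(x1 = x1, T = T, gE = g * .R_GAS * T,
             ln_gamma_1 = g + (1 - x1) * g1,
             ln_gamma_2 = g - x1 * g1)
}

#' Infinite-dilution activity coefficient
#'
#' `ln gamma_1^inf` is `ln gamma_1` at `x1 = 0`; `ln gamma_2^inf` is
#' `ln gamma_2` at `x1 = 1` (one-sided exact derivatives at the endpoints;
#' the models here are smooth on a neighborhood of `[0, 1]`).
#'
#' @param ge A [ge_function()].
#' @param component 1 or 2.
#' @param T Temperature, Kelvin.
#' @return `ln gamma_i^inf` (natural log, dimensionless).
#' @export
infinite_dilution <- function(ge, component, T) {
  stopifnot(component %in% c(1L, 2L))
  ac <- activity_coefficients(ge, x1 = if (component == 1L) 0 else 1, T = T)
  if (component == 1L) ac$ln_gamma_1 else ac$ln_gamma_2
}

#' Gibbs-Duhem residual
#'
#' Evaluates `r = x1 d(ln gamma_1)/dx1 + (1 - x1) d(ln gamma_2)/dx1` at
#' constant temperature (and pressure).  For activity coefficients derived
#' from a common `gbar` by exact differentiation the two terms cancel --
#' `d ln gamma_1/dx1 = (1 - x1) gbar''` and
#' `d ln gamma_2/dx1 = -x1 gbar''` -- so the residual vanishes to numerical
#' precision for ANY smooth model, trained or not.  Use [lngamma_pair()] to
#' check externally supplied (possibly inconsistent) activity coefficients.
#'
#' @param ge A [ge_function()] with a second derivative, or an
#'   [lngamma_pair()].
#' @param x1 Mole fraction(s) in (0, 1).
#' @param T Temperature, Kelvin.
#' @return Numeric vector of residuals.
#' @export
gibbs_duhem_residual <- function(ge, x1, T = 298.15) {
  UseMethod("gibbs_duhem_residual")
}

#' @export
gibbs_duhem_residual.ge_function <- function(ge, x1, T = 298.15) {
  stopifnot(all(x1 > 0 & x1 < 1))
  if (is.null(ge$d2f))
    stop_hanna("bad_input", "ge_function lacks a second derivative")
  n <- max(length(x1), length(T))
  x1 <- rep_len(x1, n)
  T <- rep_len(T, n)
  g2 <- ge$d2f(x1, T)
  if (any(!is.finite(g2)))
    stop_hanna("non_finite_derivative", "second derivative is not finite")
  dln1 <- (1 - x1) * g2
  dln2 <- -x1 * g2
  x1 * dln1 + (1 - x1) * dln2
}

#' Independently parameterized activity-coefficient pair
#'
#' Wraps two ln-gamma functions that were NOT derived from a common Gibbs
#' excess energy (the inconsistent construction the hard-constraint
#' architecture is designed to rule out).  Serves as the negative control for
#' [gibbs_duhem_residual()].
#'
#' @param ln_gamma_1,ln_gamma_2 Functions of `x1`.
#' @param d_ln_gamma_1,d_ln_gamma_2 Their exact derivatives in `x1`.
#' @return An object of class `lngamma_pair`.
#' @export
lngamma_pair <- function(ln_gamma_1, ln_gamma_2, d_ln_gamma_1, d_ln_gamma_2) {
  structure(list(ln_gamma_1 = ln_gamma_1, ln_gamma_2 = ln_gamma_2,
                 d_ln_gamma_1 = d_ln_gamma_1, d_ln_gamma_2 = d_ln_gamma_2),
            class = "lngamma_pair")
}

#' @export
gibbs_duhem_residual.lngamma_pair <- function(ge, x1, T = 298.15) {
  stopifnot(all(x1 > 0 & x1 < 1))
  x1 * ge$d_ln_gamma_1(x1) + (1 - x1) * ge$d_ln_gamma_2(x1)
}

#' Permutation-equivariance check
#'
#' Predicts ln gammas for `(comp1, comp2, x1)` and for the swapped query
#' `(comp2, comp1, 1 - x1)` and returns the largest absolute difference
#' between corresponding activity coefficients.  The deep-set sum aggregation
#' makes this zero to floating-point roundoff for any weights.
#'
#' @param model A `hanna` object.
#' @param smiles_1,smiles_2 Component identifiers.
#' @param T_K Temperature, Kelvin.
#' @param x1 Mole fraction grid.
#' @return Maximum absolute discrepancy (scalar).
#' @export
permutation_check <- function(model, smiles_1, smiles_2, T_K = 298.15,
                              x1 = seq(0.01, 0.99, length.out = 99L)) {
  a <- predict(model, data.frame(smiles_1 = smiles_1, smiles_2 = smiles_2,
                                 T_K = T_K, x_1 = x1))
  b <- predict(model, data.frame(smiles_1 = smiles_2, smiles_2 = smiles_1,
                                 T_K = T_K, x_1 = 1 - x1))
  max(abs(a$ln_gamma_1 - b$ln_gamma_2), abs(a$ln_gamma_2 - b$ln_gamma_1))
}

#' Thermodynamic consistency report for one system
#'
#' Checks, on a composition grid, every hard constraint the architecture
#' claims: pure-component limits (`ln gamma_i = 0` at its own endpoint),
#' identical-component ideality, Gibbs-Duhem residual, and permutation
#' equivariance.
#'
#' @param model A `hanna` object.
#' @param smiles_1,smiles_2 Component identifiers.
#' @param T_K Temperature, Kelvin.
#' @param n Grid size (default 99 interior points).
#' @param tolerances Named numeric vector of pass thresholds.
#' @param file Optional path; when given the report is also written there
#'   (`.csv` or `.json` by extension).
#' @return Data frame (criterion, grid, max_violation, tolerance, pass).
#' @export
consistency_report <- function(model, smiles_1, smiles_2, T_K = 298.15,
                               n = 99L,
                               tolerances = c(pure_component = 1e-12,
                                              identical_component = 1e-10,
                                              gibbs_duhem = 1e-6,
                                              permutation = 1e-10),
                               file = NULL) {
  grid <- seq(1 / (n + 1), n / (n + 1), length.out = n)
  pred_end <- predict(model, data.frame(
    smiles_1 = smiles_1, smiles_2 = smiles_2, T_K = T_K, x_1 = c(1, 0)))
  v_pure <- max(abs(pred_end$ln_gamma_1[1]), abs(pred_end$ln_gamma_2[2]))
  same <- predict(model, data.frame(
    smiles_1 = smiles_1, smiles_2 = smiles_1, T_K = T_K, x_1 = grid))
  v_same <- max(abs(same$ln_gamma_1), abs(same$ln_gamma_2))
  ge <- ge_hanna(model, smiles_1, smiles_2)
  v_gd <- max(abs(gibbs_duhem_residual(ge, grid, T_K)))
  v_perm <- permutation_check(model, smiles_1, smiles_2, T_K, grid)
  rep <- data.frame(
    criterion = c("pure_component", "identical_component", "gibbs_duhem",
                  "permutation"),
    grid = n,
    max_violation = c(v_pure, v_same, v_gd, v_perm),
    tolerance = as.numeric(tolerances[c("pure_component",
                                        "identical_component",
                                        "gibbs_duhem", "permutation")])
  )
  rep$pass <- rep$max_violation <= rep$tolerance
  if (!is.null(file)) {
    if (grepl("\\.json$", file))
      jsonlite::write_json(rep, file, auto_unbox = TRUE, digits = NA)
    else
      utils::write.csv(rep, file, row.names = FALSE)
  }
  rep
}
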