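## Isothermal vapor-liquid equilibrium prediction (p-x-y diagrams) from
## activity coefficients via extended Raoult's law with an ideal-gas vapor
## phase -- the direct inversion of the conversion used at data ingestion.

#' Bubble point from activity coefficients
#'
#' `p = x1 g1 pS1 + (1 - x1) g2 pS2`, `y1 = x1 g1 pS1 / p`.
#'
#' @param x1 Liquid mole fraction(s) of component 1.
#' @param ln_gamma_1,ln_gamma_2 Logarithmic activity coefficients at `x1`.
#' @param p_sat_1,p_sat_2 Pure-component vapor pressures, kPa.
#' @return Data frame with `x_1`, `p_kPa`, `y_1`.
#' @examples
#' bubble_point(0.5, 0, 0, 100, 50)  # ideal: p = 75 kPa, y1 = 2/3
#' @export
bubble_point <- function(x1, ln_gamma_1, ln_gamma_2, p_sat_1, p_sat_2) {
  stopifnot(all(is.finite(ln_gamma_1)), all(is.finite(ln_gamma_2)),
            all(p_sat_1 > 0), all(p_sat_2 > 0), all(x1 >= 0 & x1 <= 1))
  part1 <- x1 * exp(ln_gamma_1) * p_sat_1
  part2 <- (1 - x1) * exp(ln_gamma_2) * p_sat_2
  p <- part1 + part2
  data.frame(x_1 = x1, p_kPa = p, y_1 = part1 / p)
}

#' Isothermal p-x-y phase diagram
#'
#' Evaluates activity coefficients from a Gibbs excess energy model on a
#' composition grid, converts to bubble pressures and vapor compositions,
#' and locates an azeotrope if the `y1 = x1` line is crossed.
#'
#' @param ge A [ge_function()] (e.g. from [ge_hanna()] or [ge_margules()]).
#' @param T_K Temperature, Kelvin.
#' @param antoine_1,antoine_2 [antoine_params()] for the two components, or
#'   numeric vapor pressures in kPa.
#' @param n Grid size (default 101).
#' @return Data frame of class `pxy_diagram` with columns `x_1, y_1, p_kPa,
#'   ln_gamma_1, ln_gamma_2, gE_J_per_mol`; attributes `T_K`, `p_sat`, and
#'   `azeotrope` (NULL or list with `x1`, `p_kPa`, `type`).
#' @export
pxy_diagram <- function(ge, T_K, antoine_1, antoine_2, n = 101L) {
  stopifnot(inherits(ge, "ge_function"), n >= 51L)
  ps1 <- if (inherits(antoine_1, "antoine_params"))
    antoine_vapor_pressure(antoine_1, T_K) else as.numeric(antoine_1)
  ps2 <- if (inherits(antoine_2, "antoine_params"))
    antoine_vapor_pressure(antoine_2, T_K) else as.numeric(antoine_2)
  grid <- seq(0, 1, length.out = n)
  ac <- activity_coefficients(ge, grid, T_K)
  bp <- bubble_point(grid, ac$ln_gamma_1, ac$ln_gamma_2, ps1, ps2)
  out <- data.frame(x_1 = grid, y_1 = bp$y_1, p_kPa = bp$p_kPa,
                    ln_gamma_1 = ac$ln_gamma_1, ln_gamma_2 = ac$ln_gamma_2,
                    gE_J_per_mol = ac$gE)
  class(out) <- c("pxy_diagram", "data.frame")
  attr(out, "T_K") <- T_K
  attr(out, "p_sat") <- c(ps1, ps2)
  attr(out, "azeotrope") <- detect_azeotrope(out, ge = ge)
  out
}

#' Locate an azeotrope in a p-x-y diagram
#'
#' Searches the interior of the grid for a sign change of `y1 - x1` and
#' refines the crossing by bisection on the continuous model (tolerance 1e-6
#' in `x1`).  The crossing is classified low-boiling (pressure maximum,
#' `dp/dx1` changes sign from + to -) or high-boiling (pressure minimum) from
#' the exact pressure derivative.
#'
#' @param diagram A [pxy_diagram()].
#' @param ge The `ge_function` behind the diagram (required for refinement;
#'   taken from the call when used via [pxy_diagram()]).
#' @param tol Bisection tolerance in `x1`.
#' @return `NULL` if no crossing, else list with `x1`, `p_kPa`, `type`.
#' @export
detect_azeotrope <- function(diagram, ge, tol = 1e-6) {
  stopifnot(inherits(diagram, "pxy_diagram"))
  T_K <- attr(diagram, "T_K")
  ps <- attr(diagram, "p_sat")
  fdiff <- function(x1) {
    ac <- activity_coefficients(ge, x1, T_K)
    bubble_point(x1, ac$ln_gamma_1, ac$ln_gamma_2, ps[1], ps[2])$y_1 - x1
  }
  x <- diagram$x_1
  d <- diagram$y_1 - diagram$x_1
  interior <- seq.int(2L, length(x) - 1L)
  xi <- x[interior]
  di <- d[interior]
  hit <- which(di == 0)
  if (length(hit)) {
    root <- xi[hit[1]]  # crossing exactly on a grid node
  } else {
    flip <- which(di[-1] * di[-length(di)] < 0)
    if (!length(flip)) return(NULL)
    root <- stats::uniroot(fdiff, c(xi[flip[1]], xi[flip[1] + 1L]),
                           tol = tol)$root
  }
  ac <- activity_coefficients(ge, root, T_K)
  p_az <- bubble_point(root, ac$ln_gamma_1, ac$ln_gamma_2, ps[1], ps[2])$p_kPa
  ## dp/dx1 = g1 pS1 - g2 pS2 + x1 g1' pS1 + x2 g2' pS2 with
  ## gi' = gi * dln(gi)/dx1 and dln(g1)/dx1 = (1-x1) gbar'', etc.
  g2nd <- if (is.null(ge$d2f)) NULL else ge$d2f(root, T_K)
  slope <- if (is.null(g2nd)) {
    h <- 1e-5
    a <- activity_coefficients(ge, root + h, T_K)
    b <- activity_coefficients(ge, root - h, T_K)
    (bubble_point(root + h, a$ln_gamma_1, a$ln_gamma_2, ps[1], ps[2])$p_kPa -
     bubble_point(root - h, b$ln_gamma_1, b$ln_gamma_2, ps[1], ps[2])$p_kPa) /
      (2 * h)
  } else {
    g1 <- exp(ac$ln_gamma_1); g2 <- exp(ac$ln_gamma_2)
    g1 * ps[1] - g2 * ps[2] +
      root * g1 * (1 - root) * g2nd * ps[1] +
      (1 - root) * g2 * (-root * g2nd) * ps[2]
  }
  ## at a y = x crossing dp/dx1 is zero in theory; classify by curvature of
  ## p around the crossing instead of the (noisy) slope sign when tiny
  type <- if (abs(slope) < 1e-8) {
    pm <- max(diagram$p_kPa)
    if (abs(pm - p_az) <= abs(min(diagram$p_kPa) - p_az)) "low-boiling"
    else "high-boiling"
  } else if (slope < 0) "low-boiling" else "high-boiling"
  list(x1 = root, p_kPa = p_az, type = type)
}

#' @export
print.pxy_diagram <- function(x, ...) {
  az <- attr(x, "azeotrope")
  cat(sprintf("<pxy_diagram: T = %.2f K, %d points, pS = (%.4g, %.4g) kPa%s>\n",
              attr(x, "T_K"), nrow(x), attr(x, "p_sat")[1],
              attr(x, "p_sat")[2],
              if (is.null(az)) ", no azeotrope"
              else sprintf(", %s azeotrope at x1 = %.4f", az$type, az$x1)))
  invisible(x)
}

#' @export
plot.pxy_diagram <- function(x, ...) {
  rng <- range(x$p_kPa)
  graphics::plot(x$x_1, x$p_kPa, type = "l", xlab = "x1, y1",
                 ylab = "p / kPa", ylim = rng, ...)
  graphics::lines(x$y_1, x$p_kPa, lty = 2)
  az <- attr(x, "azeotrope")
  if (!is.null(az)) graphics::points(az$x1, az$p_kPa, pch = 4)
  graphics::legend("top", c("bubble (x1)", "dew (y1)"), lty = 1:2, bty = "n")
  invisible(x)
}

#' Write a p-x-y diagram to CSV
#'
#' @param diagram A [pxy_diagram()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pxy_csv <- function(diagram, path) {
  stopifnot(inherits(diagram, "pxy_diagram"))
  utils::write.csv(as.data.frame(diagram), path, row.names = FALSE)
  invisible(path)
}
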