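## The hard-constraint network core.
##
## Three sub-networks share a hidden width H:
##   f_theta : embedding D -> H -> H          (one hidden layer)
##   f_alpha : (H + 2) -> H -> H -> H         (two hidden layers; the two
##             extra inputs are the standardized temperature and the mole
##             fraction of the component that stream belongs to)
##   f_phi   : H -> H -> 1                    (one hidden layer)
## SiLU activations throughout.  The preliminary scalar ghat = f_phi(C_mix)
## is wrapped as
##   g^E = x1 (1 - x1) * d_cos(f_theta(E1), f_theta(E2)) * R * T * ghat
## which enforces the pure-component and identical-component zeros for any
## weights; permutation invariance comes from the sum aggregation
## C_mix = f_alpha(C1) + f_alpha(C2) with each stream carrying its own mole
## fraction.

#' Construct an (untrained) hard-constraint activity-coefficient model
#'
#' Builds the network with random weights (uniform fan-in initialization).
#' All thermodynamic hard constraints hold for arbitrary weights, so an
#' untrained model is already fully consistent -- just not accurate.
#'
#' @param backend Embedding backend (default [hash_backend()]).
#' @param hidden Hidden width H of all sub-networks (default 96).
#' @param scalers Optional prefitted [fit_scalers()] result.  By default an
#'   identity scaler (mean 0, std 1) is used until the model is trained.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `hanna`.
#' @seealso [hanna()] for fitting, [predict.hanna()], [ge_hanna()].
#' @export
hanna_model <- function(backend = hash_backend(), hidden = 96L,
                        scalers = NULL, seed = 1L) {
  stopifnot(inherits(backend, "hanna_backend"))
  hidden <- as.integer(hidden)
  D <- backend$dim
  if (is.null(scalers)) {
    scalers <- structure(
      list(embedding_mean = rep(0, D), embedding_std = rep(1, D),
           temperature_mean = 298.15, temperature_std = 1,
           degenerate_dims = integer(), std_convention = "population"),
      class = "scaler_set")
  }
  params <- with_seed(as.integer(seed), list(
    theta = mlp_init(c(D, hidden, hidden)),
    alpha = mlp_init(c(hidden + 2L, hidden, hidden, hidden)),
    phi   = mlp_init(c(hidden, hidden, 1L))
  ))
  structure(
    list(params = params, hidden = hidden, embed_dim = D,
         activation = "silu", backend = backend, scalers = scalers,
         trained = FALSE, control = NULL, history = NULL,
         cache = new.env(parent = emptyenv()), init_seed = as.integer(seed)),
    class = "hanna"
  )
}

#' Component embedding network f_theta
#'
#' Standardizes raw embedding vectors and passes them through the component
#' embedding network.
#'
#' @param E Numeric matrix of raw embeddings (rows = components) or a single
#'   vector.
#' @param model A `hanna` object.
#' @return Matrix of refined embeddings, `hidden` columns.
#' @export
theta_embed <- function(E, model) {
  stopifnot(inherits(model, "hanna"))
  E <- if (is.matrix(E)) E else matrix(E, nrow = 1L)
  if (ncol(E) != model$embed_dim)
    stop_hanna("shape_mismatch", sprintf(
      "embedding width %d, model expects %d", ncol(E), model$embed_dim))
  Z <- standardize(E, model$scalers, "embedding")
  mlp_forward(model$params$theta, Z)$out
}

#' Cosine distance between refined component embeddings
#'
#' `d = 1 - (u . v) / (||u|| ||v||)`, in `[0, 2]`.  The distance is the
#' identical-component switch of the hard-constraint wrapper: it vanishes
#' exactly when the two embeddings coincide.
#'
#' @param u,v Numeric vectors (or matrices with matching rows).
#' @param eps Norm floor; a vector with norm below `eps` raises a
#'   `zero_vector` error (a zero refined embedding is a pathological
#'   parameterization, not a valid mixture).
#' @return Numeric vector of distances.
#' @export
cosine_distance <- function(u, v, eps = 1e-12) {
  u <- if (is.matrix(u)) u else matrix(u, nrow = 1L)
  v <- if (is.matrix(v)) v else matrix(v, nrow = 1L)
  stopifnot(dim(u) == dim(v))
  ss1 <- rowSums(u * u)
  ss2 <- rowSums(v * v)
  if (any(ss1 < eps^2) || any(ss2 < eps^2))
    stop_hanna("zero_vector", "cosine distance undefined for zero vectors")
  1 - rowSums(u * v) / (sqrt(ss1) * sqrt(ss2))
}

## gradient of cosine_distance wrt u (and symmetrically v)
cosine_distance_grad <- function(u, v) {
  ss1 <- rowSums(u * u)
  ss2 <- rowSums(v * v)
  S <- rowSums(u * v)
  n12 <- sqrt(ss1) * sqrt(ss2)
  list(du = -v / n12 + (S / (ss1 * n12)) * u,
       dv = -u / n12 + (S / (ss2 * n12)) * v)
}

#' Permutation-invariant mixture embedding
#'
#' Applies the mixture embedding network to each per-component input and sums
#' the outputs: `C_mix = f_alpha(c1) + f_alpha(c2)`.  The sum makes the
#' result exactly invariant under exchange of the two inputs.
#'
#' @param c1_in,c2_in Per-component inputs (refined embedding with the
#'   standardized temperature and that component's mole fraction appended),
#'   vectors or matrices of width `hidden + 2`.
#' @param model A `hanna` object.
#' @return Matrix of mixture embeddings, `hidden` columns.
#' @export
mixture_embedding <- function(c1_in, c2_in, model) {
  stopifnot(inherits(model, "hanna"))
  c1_in <- if (is.matrix(c1_in)) c1_in else matrix(c1_in, nrow = 1L)
  c2_in <- if (is.matrix(c2_in)) c2_in else matrix(c2_in, nrow = 1L)
  if (ncol(c1_in) != model$hidden + 2L || ncol(c2_in) != model$hidden + 2L)
    stop_hanna("shape_mismatch", "per-component input width must be hidden + 2")
  mlp_forward(model$params$alpha, c1_in)$out +
    mlp_forward(model$params$alpha, c2_in)$out
}

## Core batch evaluation.
## Z1, Z2: standardized embeddings (N x D); tstar: standardized T (N);
## x1: mole fraction (N); T_K: absolute temperature (N).
## order: 0 -> gbar only; 1 -> + first x1-derivative (ln gammas);
##        2 -> + second derivative (Gibbs-Duhem checker).
## keep = TRUE retains all caches for backprop.
hanna_eval <- function(params, Z1, Z2, tstar, x1, T_K, order = 1L,
                       keep = FALSE, eps = 1e-12) {
  N <- length(x1)
  th1 <- mlp_forward(params$theta, Z1, keep = keep)
  th2 <- mlp_forward(params$theta, Z2, keep = keep)
  H1 <- th1$out
  H2 <- th2$out
  ss1 <- rowSums(H1 * H1)
  ss2 <- rowSums(H2 * H2)
  if (any(ss1 < eps^2) || any(ss2 < eps^2))
    stop_hanna("zero_vector",
               "f_theta produced a zero embedding; cosine distance undefined")
  d <- 1 - rowSums(H1 * H2) / (sqrt(ss1) * sqrt(ss2))

  Hn <- ncol(H1)
  x2 <- 1 - x1
  C1 <- cbind(H1, tstar, x1, deparse.level = 0L)
  C2 <- cbind(H2, tstar, x2, deparse.level = 0L)
  Cd <- matrix(0, N, Hn + 2L)
  Cd1 <- Cd; Cd1[, Hn + 2L] <- 1
  Cd2 <- Cd; Cd2[, Hn + 2L] <- -1
  a1 <- mlp_forward(params$alpha, C1, Xd = Cd1, order = order, keep = keep)
  a2 <- mlp_forward(params$alpha, C2, Xd = Cd2, order = order, keep = keep)
  M <- a1$out + a2$out
  Md <- if (order >= 1L) a1$out_d + a2$out_d
  Mdd <- if (order >= 2L) a1$out_dd + a2$out_dd
  ph <- mlp_forward(params$phi, M, Xd = Md, Xdd = Mdd, order = order,
                    keep = keep)
  ghat <- as.numeric(ph$out)
  ghat1 <- if (order >= 1L) as.numeric(ph$out_d)
  ghat2 <- if (order >= 2L) as.numeric(ph$out_dd)

  gbar <- x1 * x2 * d * ghat
  out <- list(gbar = gbar, gE = gbar * .R_GAS * T_K, d = d, ghat = ghat)
  if (order >= 1L) {
    gbar1 <- (1 - 2 * x1) * d * ghat + x1 * x2 * d * ghat1
    out$gbar1 <- gbar1
    out$ln_gamma_1 <- gbar + x2 * gbar1
    out$ln_gamma_2 <- gbar - x1 * gbar1
    out$ghat1 <- ghat1
  }
  if (order >= 2L) {
    out$gbar2 <- -2 * d * ghat + 2 * (1 - 2 * x1) * d * ghat1 +
      x1 * x2 * d * ghat2
  }
  if (keep) {
    out$caches <- list(theta1 = th1$cache, theta2 = th2$cache,
                       alpha1 = a1$cache, alpha2 = a2$cache, phi = ph$cache,
                       H1 = H1, H2 = H2, x1 = x1, Md = Md)
  }
  out
}

## Backprop: gL1, gL2 = dL/d(ln_gamma_1), dL/d(ln_gamma_2) (length N, zeros
## where a label is missing).  Returns the full parameter-gradient tree.
hanna_grad <- function(params, fw, gL1, gL2) {
  ca <- fw$caches
  x1 <- ca$x1
  x2 <- 1 - x1
  d <- fw$d
  ghat <- fw$ghat
  ghat1 <- fw$ghat1

  g_gbar <- gL1 + gL2
  g_gbar1 <- gL1 * x2 - gL2 * x1
  g_d <- x1 * x2 * ghat * g_gbar +
    ((1 - 2 * x1) * ghat + x1 * x2 * ghat1) * g_gbar1
  g_ghat <- x1 * x2 * d * g_gbar + (1 - 2 * x1) * d * g_gbar1
  g_ghat1 <- x1 * x2 * d * g_gbar1

  bp_phi <- mlp_backward(params$phi, ca$phi,
                         G = matrix(g_ghat, ncol = 1L),
                         Gd = matrix(g_ghat1, ncol = 1L))
  GM <- bp_phi$G_in
  GMd <- bp_phi$G_in_d
  bp_a1 <- mlp_backward(params$alpha, ca$alpha1, G = GM, Gd = GMd)
  bp_a2 <- mlp_backward(params$alpha, ca$alpha2, G = GM, Gd = GMd)

  Hn <- ncol(ca$H1)
  cg <- cosine_distance_grad(ca$H1, ca$H2)
  GH1 <- bp_a1$G_in[, seq_len(Hn), drop = FALSE] + g_d * cg$du
  GH2 <- bp_a2$G_in[, seq_len(Hn), drop = FALSE] + g_d * cg$dv
  bp_t1 <- mlp_backward(params$theta, ca$theta1, G = GH1)
  bp_t2 <- mlp_backward(params$theta, ca$theta2, G = GH2)

  list(theta = params_add(bp_t1$grads, bp_t2$grads),
       alpha = params_add(bp_a1$grads, bp_a2$grads),
       phi = bp_phi$grads)
}

## standardize inputs for a batch of records and evaluate
hanna_eval_records <- function(model, smiles_1, smiles_2, T_K, x1,
                               order = 1L, keep = FALSE) {
  E1 <- embed_components(smiles_1, model$backend, model$cache)
  E2 <- embed_components(smiles_2, model$backend, model$cache)
  Z1 <- standardize(E1, model$scalers, "embedding")
  Z2 <- standardize(E2, model$scalers, "embedding")
  tstar <- standardize(T_K, model$scalers, "temperature")
  hanna_eval(model$params, Z1, Z2, tstar, x1, T_K, order = order, keep = keep)
}

#' Preliminary (unconstrained) network output
#'
#' The scalar `ghat = f_phi(C_mix)` before the hard-constraint wrapper is
#' applied -- a dimensionless, unconstrained preliminary estimate of the
#' Gibbs excess energy.
#'
#' @param model A `hanna` object.
#' @param smiles_1,smiles_2 Component identifiers.
#' @param T_K Temperature(s) in Kelvin.
#' @param x1 Mole fraction(s) of component 1.
#' @return Numeric vector.
#' @export
g_excess_nn <- function(model, smiles_1, smiles_2, T_K, x1) {
  stopifnot(inherits(model, "hanna"))
  n <- max(length(T_K), length(x1))
  hanna_eval_records(model, rep_len(smiles_1, n), rep_len(smiles_2, n),
                     rep_len(T_K, n), rep_len(x1, n), order = 0L)$ghat
}

#' Molar Gibbs excess energy of a binary mixture
#'
#' Evaluates the hard-constraint wrapper
#' `g^E = x1 (1 - x1) d_cos R T ghat` (J/mol).  By construction the result
#' is exactly zero at `x1 = 0`, at `x1 = 1`, and whenever the two components
#' have identical embeddings -- for any network weights.
#'
#' @inheritParams g_excess_nn
#' @return Numeric vector, J/mol.
#' @examples
#' m <- hanna_model(hash_backend(dim = 16), hidden = 8, seed = 42)
#' g_excess(m, "SYN_A", "SYN_B", T_K = 300, x1 = c(0, 0.5, 1))
#' @export
g_excess <- function(model, smiles_1, smiles_2, T_K, x1) {
  stopifnot(inherits(model, "hanna"), all(x1 >= 0 & x1 <= 1), all(T_K > 0))
  n <- max(length(T_K), length(x1))
  hanna_eval_records(model, rep_len(smiles_1, n), rep_len(smiles_2, n),
                     rep_len(T_K, n), rep_len(x1, n), order = 0L)$gE
}

#' @export
print.hanna <- function(x, ...) {
  np <- params_count(x$params$theta) + params_count(x$params$alpha) +
    params_count(x$params$phi)
  cat(sprintf(
    "<hanna model: hidden %d, embedding dim %d (%s backend), %d parameters, %s>\n",
    x$hidden, x$embed_dim, x$backend$name, np,
    if (isTRUE(x$trained)) sprintf("trained (%d epochs, best val loss %.5g)",
                                   nrow(x$history), min(x$history$val_loss))
    else "untrained"))
  invisible(x)
}

#' @export
summary.hanna <- function(object, ...) {
  out <- list(
    hidden = object$hidden, embed_dim = object$embed_dim,
    backend = object$backend$name,
    n_params = params_count(object$params$theta) +
      params_count(object$params$alpha) + params_count(object$params$phi),
    trained = isTRUE(object$trained),
    history = object$history,
    control = object$control
  )
  class(out) <- "summary.hanna"
  out
}

#' @export
print.summary.hanna <- function(x, ...) {
  cat(sprintf("Hard-constraint activity-coefficient network\n"))
  cat(sprintf("  hidden width      : %d\n", x$hidden))
  cat(sprintf("  embedding backend : %s (dim %d)\n", x$backend, x$embed_dim))
  cat(sprintf("  parameters        : %d\n", x$n_params))
  if (x$trained && !is.null(x$history)) {
    best <- which.min(x$history$val_loss)
    cat(sprintf("  epochs run        : %d\n", nrow(x$history)))
    cat(sprintf("  best epoch        : %d (val loss %.6g)\n",
                best, x$history$val_loss[best]))
    cat(sprintf("  final lr          : %.3g\n",
                x$history$lr[nrow(x$history)]))
  } else {
    cat("  untrained (random weights; hard constraints still hold)\n")
  }
  invisible(x)
}

#' Predict activity coefficients and Gibbs excess energy
#'
#' @param object A `hanna` model.
#' @param newdata Data frame with columns `smiles_1`, `smiles_2`, `T_K`,
#'   `x_1`.
#' @param ... Unused.
#' @return `newdata` with columns `gE_J_per_mol`, `ln_gamma_1`, `ln_gamma_2`
#'   appended.  The derivatives behind the ln gammas are exact (forward-mode
#'   differentiation of the network), not finite differences.
#' @export
predict.hanna <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata),
            all(c("smiles_1", "smiles_2", "T_K", "x_1") %in% names(newdata)))
  if (any(newdata$x_1 < 0 | newdata$x_1 > 1))
    stop_hanna("bad_input", "x_1 must lie in [0, 1]")
  if (any(newdata$T_K <= 0))
    stop_hanna("bad_input", "T_K must be positive")
  fw <- hanna_eval_records(object, newdata$smiles_1, newdata$smiles_2,
                           newdata$T_K, newdata$x_1, order = 1L)
  if (any(!is.finite(fw$ln_gamma_1)) || any(!is.finite(fw$ln_gamma_2)))
    stop_hanna("non_finite_derivative",
               "model produced a non-finite activity coefficient")
  out <- newdata
  out$gE_J_per_mol <- fw$gE
  out$ln_gamma_1 <- fw$ln_gamma_1
  out$ln_gamma_2 <- fw$ln_gamma_2
  out
}

#' @export
fitted.hanna <- function(object, ...) {
  if (!isTRUE(object$trained))
    stop_hanna("bad_input", "model has not been fitted")
  object$fit$fitted
}

#' @export
residuals.hanna <- function(object, ...) {
  if (!isTRUE(object$trained))
    stop_hanna("bad_input", "model has not been fitted")
  object$fit$residuals
}

#' Plot method: training history or predicted curves for one system
#'
#' With only the model given, plots the training/validation loss history.
#' With a component pair and temperature, plots the predicted Gibbs excess
#' energy and logarithmic activity coefficients across the composition range.
#'
#' @param x A `hanna` model.
#' @param smiles_1,smiles_2 Optional component pair.
#' @param T_K Temperature in Kelvin (used with the component pair).
#' @param n Grid size.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hanna <- function(x, smiles_1 = NULL, smiles_2 = NULL, T_K = 298.15,
                       n = 101L, ...) {
  if (is.null(smiles_1)) {
    h <- x$history
    if (is.null(h)) stop_hanna("bad_input", "untrained model and no system given")
    graphics::plot(h$epoch, h$train_loss, type = "l", log = "y",
                   xlab = "epoch", ylab = "smooth-L1 loss", ...)
    graphics::lines(h$epoch, h$val_loss, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
    return(invisible(x))
  }
  grid <- seq(0, 1, length.out = n)
  nd <- data.frame(smiles_1 = smiles_1, smiles_2 = smiles_2,
                   T_K = T_K, x_1 = grid)
  pr <- predict(x, nd)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(grid, pr$gE_J_per_mol, type = "l", xlab = "x1",
                 ylab = "gE / J mol-1", ...)
  graphics::abline(h = 0, col = "grey70")
  rng <- range(pr$ln_gamma_1, pr$ln_gamma_2)
  graphics::plot(grid, pr$ln_gamma_1, type = "l", ylim = rng, xlab = "x1",
                 ylab = "ln gamma", ...)
  graphics::lines(grid, pr$ln_gamma_2, lty = 2)
  graphics::abline(h = 0, col = "grey70")
  graphics::legend("top", c("ln gamma 1", "ln gamma 2"), lty = 1:2, bty = "n")
  invisible(x)
}
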