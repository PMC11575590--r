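## Minimal dense-network engine.
##
## Every network is a list of layers list(W, b) with SiLU between layers
## (linear output).  Forward passes optionally carry forward-mode tangents
## with respect to the mole fraction x1: first-order tangents are needed for
## the exact differentiation of g^E that yields the activity coefficients,
## second-order tangents for the Gibbs-Duhem checker.  Training backpropagates
## through the tangent-augmented graph, so the loss can depend on d(gE)/dx1.

silu <- function(u) u * stats::plogis(u)

silu_d1 <- function(u) {
  s <- stats::plogis(u)
  s * (1 + u * (1 - s))
}

silu_d2 <- function(u) {
  s <- stats::plogis(u)
  s * (1 - s) * (2 + u * (1 - 2 * s))
}

## Uniform fan-in initialization, U(-1/sqrt(fan_in), 1/sqrt(fan_in)) for both
## weights and biases.  `sizes` is c(in, hidden..., out).
mlp_init <- function(sizes, seed = NULL) {
  draw <- function() {
    lapply(seq_len(length(sizes) - 1L), function(l) {
      fi <- sizes[l]
      k <- 1 / sqrt(fi)
      list(
        W = matrix(stats::runif(sizes[l + 1L] * fi, -k, k), sizes[l + 1L], fi),
        b = stats::runif(sizes[l + 1L], -k, k)
      )
    })
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

## Forward pass on a batch (rows = samples).  Xd / Xdd are the input tangents
## d(input)/dx1 and d2(input)/dx1^2 (NULL means identically zero).  `order`
## selects how many tangents to propagate; `keep = TRUE` stores what the
## backward pass needs.
mlp_forward <- function(layers, X, Xd = NULL, Xdd = NULL, order = 0L,
                        keep = FALSE) {
  nl <- length(layers)
  cache <- if (keep) list(inputs = vector("list", nl),
                          inputs_d = vector("list", nl),
                          pre = vector("list", nl),
                          pre_d = vector("list", nl))
  A <- X
  Ad <- if (order >= 1L) (if (is.null(Xd)) matrix(0, nrow(X), ncol(X)) else Xd)
  Add <- if (order >= 2L) (if (is.null(Xdd)) matrix(0, nrow(X), ncol(X)) else Xdd)
  for (l in seq_len(nl)) {
    W <- layers[[l]]$W
    b <- layers[[l]]$b
    if (keep) {
      cache$inputs[[l]] <- A
      cache$inputs_d[[l]] <- Ad
    }
    Z <- tcrossprod(A, W)
    Z <- sweep(Z, 2L, b, "+")
    Zd <- if (order >= 1L) tcrossprod(Ad, W)
    Zdd <- if (order >= 2L) tcrossprod(Add, W)
    if (l < nl) {
      if (keep) {
        cache$pre[[l]] <- Z
        cache$pre_d[[l]] <- Zd
      }
      s1 <- silu_d1(Z)
      A <- silu(Z)
      if (order >= 1L) Ad <- s1 * Zd
      if (order >= 2L) Add <- silu_d2(Z) * Zd^2 + s1 * Zdd
    } else {
      A <- Z
      Ad <- Zd
      Add <- Zdd
    }
  }
  list(out = A, out_d = Ad, out_dd = Add, cache = cache)
}

## Reverse pass through the (optionally tangent-augmented) forward graph.
## G   = dL/d(out), Gd = dL/d(out_d); both N x out matrices (Gd NULL if the
## forward ran with order = 0).  Returns per-layer parameter gradients and
## the gradients with respect to the batch input and its tangent.
mlp_backward <- function(layers, cache, G, Gd = NULL) {
  nl <- length(layers)
  grads <- vector("list", nl)
  for (l in rev(seq_len(nl))) {
    X <- cache$inputs[[l]]
    gW <- crossprod(G, X)
    if (!is.null(Gd)) gW <- gW + crossprod(Gd, cache$inputs_d[[l]])
    grads[[l]] <- list(W = gW, b = colSums(G))
    W <- layers[[l]]$W
    G <- G %*% W
    if (!is.null(Gd)) Gd <- Gd %*% W
    if (l > 1L) {
      Z <- cache$pre[[l - 1L]]
      s1 <- silu_d1(Z)
      if (!is.null(Gd)) {
        Gnew <- s1 * G + silu_d2(Z) * cache$pre_d[[l - 1L]] * Gd
        Gd <- s1 * Gd
        G <- Gnew
      } else {
        G <- s1 * G
      }
    }
  }
  list(grads = grads, G_in = G, G_in_d = Gd)
}

## elementwise map over two parameter trees of identical shape
params_map2 <- function(f, p, q) {
  Map(function(lp, lq) list(W = f(lp$W, lq$W), b = f(lp$b, lq$b)), p, q)
}

params_zero_like <- function(p) {
  lapply(p, function(l) list(W = l$W * 0, b = l$b * 0))
}

params_add <- function(p, q) params_map2(`+`, p, q)

## flatten to a single numeric vector (diagnostics / gradient checks)
params_flatten <- function(p) {
  unlist(lapply(p, function(l) c(as.numeric(l$W), l$b)), use.names = FALSE)
}

params_count <- function(p) {
  sum(vapply(p, function(l) length(l$W) + length(l$b), numeric(1)))
}
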