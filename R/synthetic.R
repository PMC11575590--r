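## Synthetic, thermodynamically consistent training data.
##
## Systems are drawn from analytic Gibbs excess energy models (two-parameter
## Margules with a mild A(T) = a + b/T temperature dependence, or NRTL), the
## labels are exact ln gammas plus optional i.i.d. Gaussian noise, and the
## component tags are plain strings routed to the hash-fallback embedding
## backend -- so the whole pipeline is testable without any external dataset
## or chemistry toolkit.

#' Two-parameter Margules activity coefficients
#'
#' `ln gamma_1 = x2^2 [A12 + 2 (A21 - A12) x1]`,
#' `ln gamma_2 = x1^2 [A21 + 2 (A12 - A21) x2]` -- the closed forms obtained
#' by differentiating `gbar = x1 x2 (A21 x1 + A12 x2)`.
#'
#' @param A12,A21 Margules coefficients.
#' @param x1 Mole fraction(s) in `[0, 1]`.
#' @return Data frame with `ln_gamma_1`, `ln_gamma_2`.
#' @export
margules_ln_gamma <- function(A12, A21, x1) {
  x2 <- 1 - x1
  data.frame(ln_gamma_1 = x2^2 * (A12 + 2 * (A21 - A12) * x1),
             ln_gamma_2 = x1^2 * (A21 + 2 * (A12 - A21) * x2))
}

#' NRTL activity coefficients
#'
#' Standard NRTL expressions with `Gij = exp(-alpha tau_ij)`.
#'
#' @param tau12,tau21 Interaction parameters.
#' @param alpha Non-randomness parameter, in (0, 1].
#' @param x1 Mole fraction(s) in `[0, 1]`.
#' @return Data frame with `ln_gamma_1`, `ln_gamma_2`.
#' @export
nrtl_ln_gamma <- function(tau12, tau21, alpha, x1) {
  stopifnot(alpha > 0, alpha <= 1)
  G12 <- exp(-alpha * tau12)
  G21 <- exp(-alpha * tau21)
  x2 <- 1 - x1
  d1 <- x1 + x2 * G21
  d2 <- x2 + x1 * G12
  data.frame(
    ln_gamma_1 = x2^2 * (tau21 * (G21 / d1)^2 + tau12 * G12 / d2^2),
    ln_gamma_2 = x1^2 * (tau12 * (G12 / d2)^2 + tau21 * G21 / d1^2)
  )
}

#' Draw a set of synthetic binary systems
#'
#' Component tags are `"SYN_001"`, `"SYN_002"`, ... from a shared pool;
#' each system is a distinct unordered pair.  Margules systems get
#' temperature-dependent coefficients `Aij(T) = a_ij + b_ij / T`; NRTL
#' systems are temperature-independent.
#'
#' @param n_systems Number of binary systems.
#' @param model_kind `"margules2"` or `"nrtl"`.
#' @param seed Integer seed.
#' @param n_components Size of the component pool (default `n_systems`,
#'   minimum 3 so distinct pairs exist).
#' @param a_range,b_range Ranges for the Margules `a` (dimensionless) and `b`
#'   (Kelvin) draws.
#' @param tau_range,alpha_range Ranges for the NRTL draws.
#' @return Data frame (one row per system) with the ground-truth parameters.
#' @export
synthetic_truth <- function(n_systems, model_kind = c("margules2", "nrtl"),
                            seed = 1L, n_components = max(n_systems, 3L),
                            a_range = c(-0.5, 2), b_range = c(-100, 100),
                            tau_range = c(-0.5, 1.5),
                            alpha_range = c(0.2, 0.47)) {
  model_kind <- match.arg(model_kind)
  stopifnot(n_systems >= 1, choose(n_components, 2L) >= n_systems)
  tags <- sprintf("SYN_%03d", seq_len(n_components))
  with_seed(as.integer(seed), {
    pairs <- t(utils::combn(tags, 2L))
    pick <- sample.int(nrow(pairs), n_systems)
    tr <- data.frame(system = seq_len(n_systems),
                     smiles_1 = pairs[pick, 1L], smiles_2 = pairs[pick, 2L],
                     model_kind = model_kind, stringsAsFactors = FALSE)
    if (model_kind == "margules2") {
      tr$a12 <- stats::runif(n_systems, a_range[1], a_range[2])
      tr$a21 <- stats::runif(n_systems, a_range[1], a_range[2])
      tr$b12 <- stats::runif(n_systems, b_range[1], b_range[2])
      tr$b21 <- stats::runif(n_systems, b_range[1], b_range[2])
    } else {
      tr$tau12 <- stats::runif(n_systems, tau_range[1], tau_range[2])
      tr$tau21 <- stats::runif(n_systems, tau_range[1], tau_range[2])
      tr$alpha <- stats::runif(n_systems, alpha_range[1], alpha_range[2])
    }
    tr
  })
}

#' Exact ln gammas of a synthetic system at given state points
#'
#' @param truth_row One row of a [synthetic_truth()] table.
#' @param x1 Mole fraction(s).
#' @param T_K Temperature(s), Kelvin.
#' @return Data frame with `ln_gamma_1`, `ln_gamma_2`.
#' @export
synthetic_ln_gamma <- function(truth_row, x1, T_K) {
  if (truth_row$model_kind == "margules2") {
    margules_ln_gamma(truth_row$a12 + truth_row$b12 / T_K,
                      truth_row$a21 + truth_row$b21 / T_K, x1)
  } else {
    nrtl_ln_gamma(truth_row$tau12, truth_row$tau21, truth_row$alpha, x1)
  }
}

#' Sample labeled records for given truth systems
#'
#' Draws `points_per_system` state points per system (`x1` uniform on (0,1),
#' `T` uniform on `T_range`), computes the exact ln gammas, and adds i.i.d.
#' Gaussian noise of standard deviation `noise_sd` to both labels.
#' Optionally appends noise-free infinite-dilution records at `x1 = 0` and
#' `x1 = 1` (one-sided, as such data naturally are).
#'
#' @param truth A [synthetic_truth()] table.
#' @param points_per_system State points per system.
#' @param T_range Temperature range in Kelvin.
#' @param noise_sd Label noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @param endpoints Append infinite-dilution records?
#' @return Data frame in the gamma CSV schema, `source` = `"synthetic"` (or
#'   `"infinite_dilution"` for endpoint rows).
#' @export
synthetic_records <- function(truth, points_per_system, T_range = c(290, 350),
                              noise_sd = 0.02, seed = 1L, endpoints = FALSE) {
  stopifnot(noise_sd >= 0, points_per_system >= 1)
  with_seed(as.integer(seed), {
    chunks <- lapply(seq_len(nrow(truth)), function(i) {
      tr <- truth[i, ]
      x1 <- stats::runif(points_per_system)
      T_K <- stats::runif(points_per_system, T_range[1], T_range[2])
      lg <- synthetic_ln_gamma(tr, x1, T_K)
      main <- data.frame(
        smiles_1 = tr$smiles_1, smiles_2 = tr$smiles_2, T_K = T_K, x_1 = x1,
        ln_gamma_1 = lg$ln_gamma_1 + stats::rnorm(points_per_system, 0, noise_sd),
        ln_gamma_2 = lg$ln_gamma_2 + stats::rnorm(points_per_system, 0, noise_sd),
        source = "synthetic", stringsAsFactors = FALSE)
      if (!endpoints) return(main)
      Te <- stats::runif(2L, T_range[1], T_range[2])
      inf <- data.frame(
        smiles_1 = tr$smiles_1, smiles_2 = tr$smiles_2, T_K = Te,
        x_1 = c(0, 1),
        ln_gamma_1 = c(synthetic_ln_gamma(tr, 0, Te[1])$ln_gamma_1, NA_real_),
        ln_gamma_2 = c(NA_real_, synthetic_ln_gamma(tr, 1, Te[2])$ln_gamma_2),
        source = "infinite_dilution", stringsAsFactors = FALSE)
      rbind(main, inf)
    })
    do.call(rbind, chunks)
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: draws systems with [synthetic_truth()] and samples
#' labeled records with [synthetic_records()].  When `dir` is given, writes
#' `gamma.csv` (the standard gamma schema) and the ground-truth sidecar
#' `truth.csv` for parameter-recovery studies.
#'
#' @inheritParams synthetic_truth
#' @inheritParams synthetic_records
#' @param dir Optional output directory.
#' @return List with `records` and `truth`.
#' @examples
#' ds <- generate_dataset(n_systems = 3, points_per_system = 5, seed = 7)
#' nrow(ds$records)  # 15
#' @export
generate_dataset <- function(n_systems = 20L, points_per_system = 15L,
                             T_range = c(290, 350), noise_sd = 0.02,
                             seed = 1L, model_kind = c("margules2", "nrtl"),
                             endpoints = FALSE, dir = NULL) {
  truth <- synthetic_truth(n_systems, model_kind, seed = seed)
  records <- synthetic_records(truth, points_per_system, T_range, noise_sd,
                               seed = seed + 1L, endpoints = endpoints)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_gamma_csv(records, file.path(dir, "gamma.csv"))
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  list(records = records, truth = truth)
}
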