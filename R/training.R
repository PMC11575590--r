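## Training protocol: system-wise splitting, smooth-L1 loss, AdamW with
## plateau learning-rate decay and early stopping on the validation loss.

#' Canonical unordered system key
#'
#' A binary system is the unordered pair of its components; the key is the
#' lexicographic sort of the two identifiers.  Splitting by key guarantees
#' all data points of a system land in a single partition.
#'
#' @param smiles_1,smiles_2 Character vectors.
#' @return Character vector of keys.
#' @export
system_key <- function(smiles_1, smiles_2) {
  ifelse(smiles_1 <= smiles_2,
         paste(smiles_1, smiles_2, sep = "||"),
         paste(smiles_2, smiles_1, sep = "||"))
}

#' Random system-wise train/validation/test split
#'
#' Seeded uniform shuffle of the unique keys, partitioned at
#' `floor(f1 n)` and `floor((f1 + f2) n)`.
#'
#' @param keys Character vector of system keys (duplicates allowed; the
#'   split acts on the unique set).
#' @param fractions Length-3 fractions summing to 1 (default 0.8/0.1/0.1).
#' @param seed Integer seed.
#' @return List of disjoint, exhaustive key sets `train`, `val`, `test`.
#' @export
split_systems <- function(keys, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8,
            all(fractions >= 0))
  uk <- unique(keys)
  n <- length(uk)
  if (n < 3L)
    stop_hanna("too_few_systems", "need at least 3 systems to split")
  shuffled <- with_seed(as.integer(seed), sample(uk))
  i1 <- floor(fractions[1] * n)
  i2 <- floor((fractions[1] + fractions[2]) * n)
  list(train = shuffled[seq_len(i1)],
       val = shuffled[seq.int(i1 + 1L, i2)],
       test = if (i2 < n) shuffled[seq.int(i2 + 1L, n)] else character())
}

#' Smooth-L1 (Huber-like) loss
#'
#' `0.5 r^2 / beta` for `|r| <= beta`, else `|r| - 0.5 beta`; continuous with
#' continuous first derivative at the crossover.  The quadratic core keeps
#' gradients smooth near zero; the linear tails damp experimental outliers.
#'
#' @param residual Numeric vector of residuals.
#' @param beta Crossover scale (> 0), default 0.25.
#' @return Elementwise loss values.
#' @export
smooth_l1 <- function(residual, beta = 0.25) {
  stopifnot(beta > 0)
  a <- abs(residual)
  ifelse(a <= beta, 0.5 * residual^2 / beta, a - 0.5 * beta)
}

## derivative wrt residual
smooth_l1_grad <- function(residual, beta) {
  pmax(pmin(residual / beta, 1), -1)
}

#' Training configuration
#'
#' Defaults follow the reference protocol: AdamW (decoupled weight decay
#' `lambda = 0.01`), initial learning rate 0.001, plateau decay by 0.1 after
#' 10 epochs without validation improvement, early stopping after 30, batch
#' size 512, smooth-L1 `beta = 0.25`.
#'
#' @param lr Initial learning rate.
#' @param weight_decay Decoupled weight-decay coefficient.
#' @param scheduler_factor Multiplicative learning-rate decay factor.
#' @param scheduler_patience Epochs without strict validation improvement
#'   before the learning rate decays.
#' @param early_stop_patience Epochs without strict validation improvement
#'   before training stops.
#' @param max_epochs Hard epoch cap.
#' @param batch_size Minibatch size.
#' @param smooth_l1_beta Loss crossover scale.
#' @param seed Seed for weight initialization and batch shuffling.
#' @return A list of class `hanna_control`.
#' @export
hanna_control <- function(lr = 0.001, weight_decay = 0.01,
                          scheduler_factor = 0.1, scheduler_patience = 10L,
                          early_stop_patience = 30L, max_epochs = 1000L,
                          batch_size = 512L, smooth_l1_beta = 0.25,
                          seed = 1L) {
  stopifnot(lr > 0, weight_decay >= 0, scheduler_factor > 0,
            scheduler_factor < 1, scheduler_patience >= 1,
            early_stop_patience >= 1, max_epochs >= 1, batch_size >= 1,
            smooth_l1_beta > 0)
  structure(list(lr = lr, weight_decay = weight_decay,
                 scheduler_factor = scheduler_factor,
                 scheduler_patience = as.integer(scheduler_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 smooth_l1_beta = smooth_l1_beta, seed = as.integer(seed)),
            class = "hanna_control")
}

## ---- AdamW -----------------------------------------------------------------

adamw_state <- function(params) {
  list(m = lapply(params, params_zero_like),
       v = lapply(params, params_zero_like), t = 0L)
}

## one decoupled-weight-decay Adam step over the nested parameter tree
adamw_step <- function(params, grads, state, lr, wd, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (net in names(params)) {
    for (l in seq_along(params[[net]])) {
      for (slot in c("W", "b")) {
        g <- grads[[net]][[l]][[slot]]
        m <- beta1 * state$m[[net]][[l]][[slot]] + (1 - beta1) * g
        v <- beta2 * state$v[[net]][[l]][[slot]] + (1 - beta2) * g^2
        state$m[[net]][[l]][[slot]] <- m
        state$v[[net]][[l]][[slot]] <- v
        w <- params[[net]][[l]][[slot]]
        params[[net]][[l]][[slot]] <-
          w - lr * ((m / bc1) / (sqrt(v / bc2) + eps) + wd * w)
      }
    }
  }
  list(params = params, state = state)
}

## ---- loss over a batch of standardized inputs -------------------------------

## batch: list(Z1, Z2, tstar, x1, T_K, y1, y2) with NA labels allowed
hanna_loss_grad <- function(params, batch, beta, grad = TRUE) {
  fw <- hanna_eval(params, batch$Z1, batch$Z2, batch$tstar, batch$x1,
                   batch$T_K, order = 1L, keep = grad)
  m1 <- !is.na(batch$y1)
  m2 <- !is.na(batch$y2)
  nl <- sum(m1) + sum(m2)
  r1 <- ifelse(m1, fw$ln_gamma_1 - batch$y1, 0)
  r2 <- ifelse(m2, fw$ln_gamma_2 - batch$y2, 0)
  loss <- (sum(smooth_l1(r1[m1], beta)) + sum(smooth_l1(r2[m2], beta))) / nl
  if (!grad) return(list(loss = loss))
  gL1 <- ifelse(m1, smooth_l1_grad(r1, beta), 0) / nl
  gL2 <- ifelse(m2, smooth_l1_grad(r2, beta), 0) / nl
  list(loss = loss, grads = hanna_grad(params, fw, gL1, gL2))
}

## assemble standardized batch tensors from gamma records
make_batch <- function(model, records) {
  E1 <- embed_components(records$smiles_1, model$backend, model$cache)
  E2 <- embed_components(records$smiles_2, model$backend, model$cache)
  list(Z1 = standardize(E1, model$scalers, "embedding"),
       Z2 = standardize(E2, model$scalers, "embedding"),
       tstar = standardize(records$T_K, model$scalers, "temperature"),
       x1 = records$x_1, T_K = records$T_K,
       y1 = records$ln_gamma_1, y2 = records$ln_gamma_2)
}

#' Fit the hard-constraint activity-coefficient network
#'
#' End-to-end training on activity-coefficient records: embeds the
#' components, fits the standardization scalers on the training split only,
#' and minimizes the smooth-L1 loss over every available ln-gamma label
#' (one-sided records contribute one term) with AdamW, plateau learning-rate
#' decay and early stopping on the validation loss.  The returned model is
#' the checkpoint with the best validation loss.
#'
#' @param data Training records in the gamma schema (`smiles_1, smiles_2,
#'   T_K, x_1, ln_gamma_1, ln_gamma_2[, source]`).
#' @param validation Either a fraction in (0, 1) -- a system-wise random
#'   split of `data` with the control seed -- or a data frame of validation
#'   records.
#' @param backend Embedding backend, default [hash_backend()].
#' @param hidden Hidden width of all sub-networks (default 96).
#' @param control A [hanna_control()].
#' @param verbose Print per-epoch progress?
#' @return A fitted `hanna` object; `$history` holds the per-epoch train
#'   loss, validation loss and learning rate.
#' @export
hanna <- function(data, validation = 0.1, backend = hash_backend(),
                  hidden = 96L, control = hanna_control(), verbose = FALSE) {
  stopifnot(inherits(control, "hanna_control"))
  data <- validate_gamma(data, "training data")
  if (is.data.frame(validation)) {
    val <- validate_gamma(validation, "validation data")
    train <- data
  } else {
    stopifnot(is.numeric(validation), validation > 0, validation < 1)
    keys <- system_key(data$smiles_1, data$smiles_2)
    parts <- split_systems(unique(keys), c(1 - validation, validation, 0),
                           seed = control$seed)
    train <- data[keys %in% parts$train, , drop = FALSE]
    val <- data[keys %in% parts$val, , drop = FALSE]
  }
  if (!nrow(val)) stop_hanna("too_few_systems", "empty validation set")

  model <- hanna_model(backend, hidden, seed = control$seed)
  E_train <- rbind(embed_components(train$smiles_1, backend, model$cache),
                   embed_components(train$smiles_2, backend, model$cache))
  model$scalers <- suppressWarnings(fit_scalers(E_train, train$T_K))
  tr_batch_all <- make_batch(model, train)
  val_batch <- make_batch(model, val)

  params <- model$params
  state <- adamw_state(params)
  n <- nrow(train)
  lr <- control$lr
  beta <- control$smooth_l1_beta
  best <- list(loss = Inf, params = params, epoch = 0L)
  sched_bad <- 0L   # plateau counter, resets after each lr decay
  stop_bad <- 0L    # early-stopping counter, resets only on improvement
  history <- vector("list", control$max_epochs)
  diverged <- FALSE

  for (epoch in seq_len(control$max_epochs)) {
    ord <- with_seed(control$seed + epoch, sample.int(n))
    starts <- seq.int(1L, n, by = control$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + control$batch_size - 1L, n)]
      b <- list(Z1 = tr_batch_all$Z1[idx, , drop = FALSE],
                Z2 = tr_batch_all$Z2[idx, , drop = FALSE],
                tstar = tr_batch_all$tstar[idx], x1 = tr_batch_all$x1[idx],
                T_K = tr_batch_all$T_K[idx], y1 = tr_batch_all$y1[idx],
                y2 = tr_batch_all$y2[idx])
      lg <- hanna_loss_grad(params, b, beta)
      if (!is.finite(lg$loss)) { diverged <- TRUE; break }
      ep_loss <- ep_loss + lg$loss * length(idx)
      upd <- adamw_step(params, lg$grads, state, lr, control$weight_decay)
      params <- upd$params
      state <- upd$state
    }
    if (diverged) {
      warn_hanna("diverged_loss",
                 sprintf("loss diverged at epoch %d; returning best checkpoint",
                         epoch))
      break
    }
    val_loss <- hanna_loss_grad(params, val_batch, beta, grad = FALSE)$loss
    history[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / n,
                                   val_loss = val_loss, lr = lr)
    if (verbose && (epoch %% 25L == 0L || epoch == 1L))
      message(sprintf("epoch %4d  train %.5f  val %.5f  lr %.2g",
                      epoch, ep_loss / n, val_loss, lr))
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      sched_bad <- 0L
      stop_bad <- 0L
    } else {
      sched_bad <- sched_bad + 1L
      stop_bad <- stop_bad + 1L
      if (sched_bad >= control$scheduler_patience) {
        lr <- lr * control$scheduler_factor
        sched_bad <- 0L
      }
      if (stop_bad >= control$early_stop_patience) break
    }
  }

  model$params <- best$params
  model$trained <- TRUE
  model$control <- control
  model$best_epoch <- best$epoch
  model$history <- do.call(rbind, history[!vapply(history, is.null, logical(1))])
  pr <- predict(model, train)
  res <- c(pr$ln_gamma_1 - train$ln_gamma_1, pr$ln_gamma_2 - train$ln_gamma_2)
  model$fit <- list(
    fitted = cbind(pr$ln_gamma_1, pr$ln_gamma_2),
    residuals = res[!is.na(res)],
    n_train = nrow(train), n_val = nrow(val)
  )
  model
}

#' System-wise evaluation of a fitted model
#'
#' Computes the mean absolute error of the predicted ln gammas per system
#' (over every available label), giving each system equal weight regardless
#' of its number of data points, plus summary statistics and the cumulative
#' fraction of systems below a threshold grid.
#'
#' @param model A `hanna` object.
#' @param records Data frame in the gamma schema.
#' @param thresholds MAE grid for the cumulative fraction.
#' @return List of class `hanna_eval`: `by_system` (system, n_points, mae),
#'   `mean_mae`, `median_mae`, and `cumulative` (threshold, fraction).
#' @export
evaluate_systemwise <- function(model, records,
                                thresholds = seq(0.01, 0.5, by = 0.01)) {
  records <- validate_gamma(records, "evaluation data")
  pr <- predict(model, records)
  key <- system_key(records$smiles_1, records$smiles_2)
  err <- data.frame(
    key = c(key, key),
    abs_err = c(abs(pr$ln_gamma_1 - records$ln_gamma_1),
                abs(pr$ln_gamma_2 - records$ln_gamma_2)))
  err <- err[!is.na(err$abs_err), , drop = FALSE]
  agg <- stats::aggregate(abs_err ~ key, err, mean)
  cnt <- stats::aggregate(abs_err ~ key, err, length)
  by_system <- data.frame(system = agg$key, n_points = cnt$abs_err,
                          mae = agg$abs_err, stringsAsFactors = FALSE)
  structure(list(
    by_system = by_system,
    mean_mae = mean(by_system$mae),
    median_mae = stats::median(by_system$mae),
    cumulative = data.frame(
      threshold = thresholds,
      fraction = vapply(thresholds,
                        function(t) mean(by_system$mae < t), numeric(1)))
  ), class = "hanna_eval")
}

#' @export
print.hanna_eval <- function(x, ...) {
  cat(sprintf("System-wise evaluation: %d systems\n", nrow(x$by_system)))
  cat(sprintf("  mean MAE(ln gamma)   : %.4f\n", x$mean_mae))
  cat(sprintf("  median MAE(ln gamma) : %.4f\n", x$median_mae))
  f01 <- x$cumulative$fraction[which.min(abs(x$cumulative$threshold - 0.1))]
  cat(sprintf("  systems with MAE < 0.1 : %.0f%%\n", 100 * f01))
  invisible(x)
}
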