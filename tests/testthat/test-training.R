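test_that("system keys are order-independent and admit pseudo-binaries", {
  expect_identical(system_key("CCO", "O"), system_key("O", "CCO"))
  expect_identical(system_key("CCO", "CCO"), system_key("CCO", "CCO"))
  expect_false(system_key("CCO", "O") == system_key("CCO", "CO"))
  # distinct pairs give distinct keys at scale
  set.seed(13)
  tags <- sprintf("S%03d", 1:40)
  pairs <- t(combn(tags, 2))[sample(choose(40, 2), 100), ]
  expect_equal(length(unique(system_key(pairs[, 1], pairs[, 2]))), 100L)
})

test_that("system-wise split is a seeded partition with the stated sizes", {
  keys <- sprintf("sys%02d", 1:10)
  sp <- split_systems(keys, c(0.8, 0.1, 0.1), seed = 4)
  expect_equal(lengths(sp), c(train = 8L, val = 1L, test = 1L))
  expect_length(intersect(sp$train, sp$val), 0L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_length(intersect(sp$val, sp$test), 0L)
  expect_setequal(c(sp$train, sp$val, sp$test), keys)
  expect_identical(sp, split_systems(keys, c(0.8, 0.1, 0.1), seed = 4))
  expect_false(identical(sp, split_systems(keys, c(0.8, 0.1, 0.1), seed = 5)))
  expect_error(split_systems(keys[1:2], seed = 1), class = "too_few_systems")
})

test_that("smooth-L1 matches its closed form and is C1 at the crossover", {
  expect_equal(smooth_l1(0, 0.25), 0)
  expect_equal(smooth_l1(0.25, 0.25), 0.125)
  expect_equal(smooth_l1(1, 0.25), 0.875)
  expect_equal(smooth_l1(-1, 0.25), 0.875)       # even function
  b <- 0.25; e <- 1e-9
  expect_equal(smooth_l1(b - e, b), smooth_l1(b + e, b), tolerance = 1e-7)
  # slope from both sides at |r| = beta is 1
  expect_equal((smooth_l1(b, b) - smooth_l1(b - 1e-6, b)) / 1e-6, 1,
               tolerance = 1e-4)
  expect_equal((smooth_l1(b + 1e-6, b) - smooth_l1(b, b)) / 1e-6, 1,
               tolerance = 1e-4)
})

test_that("analytic training gradients match numerical differentiation", {
  ds <- generate_dataset(n_systems = 3, points_per_system = 4, seed = 5)
  m <- hanna_model(hash_backend(dim = 6), hidden = 4, seed = 9)
  E <- rbind(embed_components(ds$records$smiles_1, m$backend, m$cache),
             embed_components(ds$records$smiles_2, m$backend, m$cache))
  m$scalers <- suppressWarnings(fit_scalers(E, ds$records$T_K))
  b <- hanna:::make_batch(m, ds$records)
  lg <- hanna:::hanna_loss_grad(m$params, b, 0.25)
  num_grad <- function(net, l, slot, i, e = 1e-6) {
    p <- m$params
    p[[net]][[l]][[slot]][i] <- p[[net]][[l]][[slot]][i] + e
    up <- hanna:::hanna_loss_grad(p, b, 0.25, grad = FALSE)$loss
    p[[net]][[l]][[slot]][i] <- p[[net]][[l]][[slot]][i] - 2 * e
    dn <- hanna:::hanna_loss_grad(p, b, 0.25, grad = FALSE)$loss
    (up - dn) / (2 * e)
  }
  set.seed(20)
  for (net in c("theta", "alpha", "phi")) {
    for (l in seq_along(m$params[[net]])) {
      for (slot in c("W", "b")) {
        n <- length(m$params[[net]][[l]][[slot]])
        for (i in sample(n, min(4L, n))) {
          expect_equal(lg$grads[[net]][[l]][[slot]][i],
                       num_grad(net, l, slot, i), tolerance = 1e-4)
        }
      }
    }
  }
})

test_that("short training run reduces the loss and honors the checkpoint contract", {
  ds <- generate_dataset(n_systems = 6, points_per_system = 10, seed = 21)
  ctl <- hanna_control(max_epochs = 60L, seed = 22L)
  fit <- hanna(ds$records, validation = 0.2, backend = hash_backend(dim = 16),
               hidden = 8, control = ctl)
  h <- fit$history
  expect_lt(mean(tail(h$train_loss, 5)), mean(head(h$train_loss, 5)))
  # learning rate is non-increasing and moves by the decay factor only
  expect_true(all(diff(h$lr) <= 0))
  ratios <- unique(round(h$lr[-1] / h$lr[-nrow(h)], 10))
  expect_true(all(ratios %in% c(1, 0.1)))
  # returned checkpoint has the minimal validation loss
  expect_equal(min(h$val_loss), h$val_loss[fit$best_epoch])
  expect_lte(min(h$val_loss), h$val_loss[nrow(h)])
  # config recorded verbatim, residuals/fitted available
  expect_identical(fit$control, ctl)
  expect_true(is.numeric(residuals(fit)))
  expect_equal(nrow(fitted(fit)), fit$fit$n_train)
  # trained predictions remain thermodynamically consistent
  k <- system_key(ds$records$smiles_1, ds$records$smiles_2)[1]
  s <- strsplit(k, "||", fixed = TRUE)[[1]]
  expect_lt(max(abs(gibbs_duhem_residual(ge_hanna(fit, s[1], s[2]),
                                         seq(0.05, 0.95, 0.05), 320))), 1e-6)
})

test_that("training uses every available label, including one-sided records", {
  ds <- generate_dataset(n_systems = 5, points_per_system = 6, seed = 31,
                         endpoints = TRUE)
  ctl <- hanna_control(max_epochs = 10L, seed = 32L)
  fit <- suppressWarnings(
    hanna(ds$records, validation = 0.2, backend = hash_backend(dim = 8),
          hidden = 6, control = ctl))
  expect_true(is.finite(min(fit$history$val_loss)))
})

test_that("system-wise evaluation weighs systems equally", {
  m <- test_model(seed = 41L)
  base <- data.frame(
    smiles_1 = rep(c("SYN_A", "SYN_C", "SYN_E"), each = 2),
    smiles_2 = rep(c("SYN_B", "SYN_D", "SYN_F"), each = 2),
    T_K = 300, x_1 = rep(c(0.3, 0.6), 3))
  pr <- predict(m, base)
  # perfect labels -> all MAEs zero, cumulative fraction one
  perfect <- base
  perfect$ln_gamma_1 <- pr$ln_gamma_1
  perfect$ln_gamma_2 <- pr$ln_gamma_2
  ev <- evaluate_systemwise(m, perfect)
  expect_equal(ev$by_system$mae, rep(0, 3))
  expect_true(all(ev$cumulative$fraction == 1))
  # one system with residuals {+0.1, -0.3} has MAE 0.2
  skew <- perfect
  idx <- which(skew$smiles_1 == "SYN_A")
  skew$ln_gamma_1[idx] <- skew$ln_gamma_1[idx] - c(0.1, -0.3)
  skew$ln_gamma_2[idx] <- NA
  ev2 <- evaluate_systemwise(m, skew)
  expect_equal(ev2$by_system$mae[ev2$by_system$system ==
                                   system_key("SYN_A", "SYN_B")], 0.2)
  # threshold counting: MAEs {0.2, 0, 0} -> fraction below 0.1 is 2/3
  i01 <- which.min(abs(ev2$cumulative$threshold - 0.1))
  expect_equal(ev2$cumulative$fraction[i01], 2 / 3)
  # duplicating one system's points leaves the others' MAEs unchanged
  dup <- rbind(skew, skew[idx, ])
  ev3 <- evaluate_systemwise(m, dup)
  other <- ev2$by_system$system != system_key("SYN_A", "SYN_B")
  expect_equal(ev3$by_system$mae[other], ev2$by_system$mae[other])
  expect_equal(stats::median(ev3$by_system$mae),
               stats::median(ev2$by_system$mae))
})
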