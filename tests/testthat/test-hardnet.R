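test_that("theta_embed matches the scalar SiLU formula for hand-set 1x1 layers", {
  m <- test_model(dim = 1L, hidden = 1L, seed = 5L)
  m$params$theta <- list(list(W = matrix(0.7, 1, 1), b = 0.2),
                         list(W = matrix(-1.3, 1, 1), b = 0.4))
  z <- 1.0  # identity scalers on an untrained model
  silu <- function(u) u / (1 + exp(-u))
  expect_equal(as.numeric(theta_embed(z, m)),
               -1.3 * silu(0.7 * 1.0 + 0.2) + 0.4, tolerance = 1e-14)
  # purity: identical inputs give identical outputs
  E <- matrix(rnorm(6), 3, 2)
  m2 <- test_model(dim = 2L, hidden = 4L, seed = 6L)
  expect_identical(theta_embed(E, m2), theta_embed(E, m2))
  # zero parameterization maps everything to zero
  m2$params$theta <- lapply(m2$params$theta,
                            function(l) list(W = l$W * 0, b = l$b * 0))
  expect_true(all(theta_embed(E, m2) == 0))
  expect_error(theta_embed(matrix(1, 1, 5), m2), class = "shape_mismatch")
})

test_that("cosine distance has the right geometry and rejects zero vectors", {
  expect_equal(cosine_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(c(1, 0), c(-1, 0)), 2)
  u <- rnorm(5); v <- rnorm(5)
  expect_equal(cosine_distance(u, v), cosine_distance(v, u))
  expect_error(cosine_distance(c(0, 0), c(1, 0)), class = "zero_vector")
})

test_that("mixture embedding is exactly exchange-invariant and zero under zero maps", {
  m <- test_model(dim = 8L, hidden = 6L, seed = 7L)
  set.seed(8)
  a <- matrix(rnorm(3 * (6 + 2)), 3, 6 + 2)
  b <- matrix(rnorm(3 * (6 + 2)), 3, 6 + 2)
  expect_identical(mixture_embedding(a, b, m), mixture_embedding(b, a, m))
  mz <- m
  mz$params$alpha <- lapply(mz$params$alpha,
                            function(l) list(W = l$W * 0, b = l$b * 0))
  expect_true(all(mixture_embedding(a, b, mz) == 0))
  expect_error(mixture_embedding(a[, 1:5], b[, 1:5], m),
               class = "shape_mismatch")
})

test_that("g_excess decomposes into the stated product of factors", {
  # gE = x1 (1-x1) * d_cos(f_theta(E1), f_theta(E2)) * R * T * ghat
  m <- test_model(dim = 12L, hidden = 8L, seed = 21L)
  x1 <- c(0.2, 0.5, 0.9)
  T_K <- 300
  gE <- g_excess(m, "SYN_A", "SYN_B", T_K, x1)
  E1 <- embed_component("SYN_A", m$backend)$embedding
  E2 <- embed_component("SYN_B", m$backend)$embedding
  d <- cosine_distance(theta_embed(E1, m), theta_embed(E2, m))
  ghat <- g_excess_nn(m, "SYN_A", "SYN_B", T_K, x1)
  expect_equal(gE, x1 * (1 - x1) * d * gas_constant() * T_K * ghat,
               tolerance = 1e-12)
  # arithmetic of the wrapper at the stub values of the factors
  expect_equal(0.5 * (1 - 0.5) * 1 * gas_constant() * 300 * 1, 623.5845,
               tolerance = 1e-7)
})

test_that("hard zeros hold at machine precision for arbitrary random weights", {
  for (seed in 1:5) {
    m <- test_model(dim = 10L, hidden = 6L, seed = seed)
    expect_identical(g_excess(m, "SYN_A", "SYN_B", 320, c(0, 1)), c(0, 0))
    pr <- predict(m, data.frame(smiles_1 = "SYN_A", smiles_2 = "SYN_B",
                                T_K = 320, x_1 = c(1, 0)))
    expect_identical(pr$ln_gamma_1[1], 0)  # pure component 1
    expect_identical(pr$ln_gamma_2[2], 0)  # pure component 2
    same <- predict(m, data.frame(smiles_1 = "SYN_C", smiles_2 = "SYN_C",
                                  T_K = 350, x_1 = seq(0.1, 0.9, 0.2)))
    expect_lt(max(abs(same$ln_gamma_1), abs(same$ln_gamma_2)), 1e-12)
  }
})

test_that("predictions are exactly permutation-invariant at dyadic compositions", {
  # at dyadic x1 the swapped query's mole fractions are bitwise identical,
  # so the deep-set sum must give bitwise-equal predictions
  for (seed in 1:5) {
    m <- test_model(dim = 10L, hidden = 6L, seed = seed + 40L)
    x1 <- c(0.25, 0.5, 0.75)
    a <- predict(m, data.frame(smiles_1 = "SYN_A", smiles_2 = "SYN_B",
                               T_K = 298.15, x_1 = x1))
    b <- predict(m, data.frame(smiles_1 = "SYN_B", smiles_2 = "SYN_A",
                               T_K = 298.15, x_1 = 1 - x1))
    expect_identical(a$ln_gamma_1, b$ln_gamma_2)
    expect_identical(a$ln_gamma_2, b$ln_gamma_1)
    expect_identical(a$gE_J_per_mol, b$gE_J_per_mol)
  }
})

test_that("g_excess is smooth: exact x1-derivatives match central differences", {
  m <- test_model(dim = 12L, hidden = 8L, seed = 77L)
  ge <- ge_hanna(m, "SYN_A", "SYN_B")
  x <- c(0.05, 0.31, 0.5, 0.77, 0.95)
  h <- 1e-6
  fd1 <- (ge$f(x + h, 310) - ge$f(x - h, 310)) / (2 * h)
  expect_equal(ge$df(x, 310), fd1, tolerance = 1e-5)
  fd2 <- (ge$df(x + h, 310) - ge$df(x - h, 310)) / (2 * h)
  expect_equal(ge$d2f(x, 310), fd2, tolerance = 1e-5)
})

test_that("model components are reproducible from the seed", {
  m1 <- test_model(dim = 8L, hidden = 4L, seed = 123L)
  m2 <- test_model(dim = 8L, hidden = 4L, seed = 123L)
  expect_identical(m1$params, m2$params)
  g1 <- g_excess(m1, "SYN_X", "SYN_Y", 300, 0.4)
  g2 <- g_excess(m2, "SYN_X", "SYN_Y", 300, 0.4)
  expect_identical(g1, g2)
})
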