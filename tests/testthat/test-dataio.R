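test_that("Antoine evaluation follows the stated form and units", {
  p <- antoine_params(A = 7, B = 1500, C = -50, T_unit = "K", p_unit = "kPa")
  expect_equal(antoine_vapor_pressure(p, 350), 100, tolerance = 1e-12)
  # B = 0 degenerates to a constant
  p0 <- antoine_params(A = 2, B = 0, C = 10)
  expect_equal(antoine_vapor_pressure(p0, c(300, 400)), c(100, 100))
  # monotone increasing in T for B > 0, C + T > 0
  Ts <- seq(300, 400, by = 10)
  expect_true(all(diff(antoine_vapor_pressure(p, Ts)) > 0))
  # unit conversions: bar -> kPa, Celsius input
  pb <- antoine_params(A = 7, B = 1500, C = 223.15, T_unit = "C",
                       p_unit = "bar")
  expect_equal(antoine_vapor_pressure(pb, 350), 100 * 100, tolerance = 1e-10)
  # validity range warning
  pr <- antoine_params(A = 7, B = 1500, C = -50, T_min = 320, T_max = 360)
  expect_warning(antoine_vapor_pressure(pr, 300), class = "range_warning")
})

test_that("Antoine parameter files require explicit unit metadata", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("smiles,A,B,C,T_unit,p_unit,log_base,T_min,T_max",
               "CCO,7,1500,-50,K,kPa,10,280,400"), f)
  ps <- read_antoine_csv(f)
  expect_named(ps, "CCO")
  expect_equal(antoine_vapor_pressure(ps$CCO, 350), 100)
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("smiles,A,B,C", "CCO,7,1500,-50"), f2)
  expect_error(read_antoine_csv(f2), class = "schema_error")
})

test_that("extended Raoult's law conversion gives the arithmetic result", {
  rec <- data.frame(smiles_1 = "S1", smiles_2 = "S2", T_K = 350,
                    p_kPa = 100, x_1 = 0.5, y_1 = 0.6)
  g <- vle_to_gamma(rec, p_sat_1 = 80, p_sat_2 = 100)
  expect_equal(exp(g$ln_gamma_1), 1.5, tolerance = 1e-12)
  expect_equal(g$ln_gamma_1, 0.405465, tolerance = 1e-5)
  expect_equal(exp(g$ln_gamma_2), 0.4 * 100 / (0.5 * 100), tolerance = 1e-12)
  expect_identical(g$source, "vle")
})

test_that("ideal and pure-component limits give unit activity coefficients", {
  # ideal: y_i p = x_i pS_i
  rec <- data.frame(smiles_1 = "S1", smiles_2 = "S2", T_K = 350,
                    p_kPa = 90, x_1 = 1 / 3, y_1 = 40 / 90)
  g <- vle_to_gamma(rec, p_sat_1 = 120, p_sat_2 = 75)
  expect_equal(g$ln_gamma_1, 0, tolerance = 1e-12)
  expect_equal(g$ln_gamma_2, 0, tolerance = 1e-12)
  # pure component: one-sided record with gamma_1 = 1
  pure <- data.frame(smiles_1 = "S1", smiles_2 = "S2", T_K = 350,
                     p_kPa = 80, x_1 = 1, y_1 = 1)
  gp <- vle_to_gamma(pure, p_sat_1 = 80, p_sat_2 = 60)
  expect_equal(gp$ln_gamma_1, 0)
  expect_true(is.na(gp$ln_gamma_2))
})

test_that("inconsistent raw data (non-positive gamma) is dropped with a warning", {
  rec <- data.frame(smiles_1 = "S1", smiles_2 = "S2", T_K = 350,
                    p_kPa = 100, x_1 = c(0.5, 0.4), y_1 = c(0, 0.5))
  expect_warning(g <- vle_to_gamma(rec, 80, 100),
                 class = "non_positive_gamma")
  expect_true(is.na(g$ln_gamma_1[1]))  # y1 = 0 at x1 > 0
  expect_equal(nrow(g), 2L)            # second gamma still defined
})

test_that("preprocessing filters drop by pressure, quality, and SMILES validity", {
  recs <- data.frame(
    smiles_1 = c("CCO", "CCO", "not_a_smiles((", "OCC", "CC(=O)O"),
    smiles_2 = c("O", "O", "O", "O", "O"),
    T_K = 350, p_kPa = c(100, 1500, 200, 999, 300),
    x_1 = 0.5, y_1 = 0.5
  )
  out <- suppressWarnings(apply_filters(recs))
  expect_equal(nrow(out$kept), 3L)
  expect_equal(out$report[["pressure_gt_10bar"]], 1L)  # 1500 kPa > 10 bar
  expect_equal(out$report[["invalid_smiles"]], 1L)
  expect_equal(sum(out$report) + nrow(out$kept), nrow(recs))
  # boundary: 999 kPa is kept, and kept SMILES are canonicalized
  expect_true(999 %in% out$kept$p_kPa)
  expect_true(all(out$kept$smiles_1 %in% c("CCO", "CC(=O)O")))
  # quality flag column
  recs$poor_quality <- c(FALSE, FALSE, FALSE, TRUE, FALSE)
  out2 <- suppressWarnings(apply_filters(recs))
  expect_equal(out2$report[["poor_quality"]], 1L)
  expect_equal(sum(out2$report) + nrow(out2$kept), nrow(recs))
  # synthetic tags pass through when canonicalization is off
  syn <- data.frame(smiles_1 = "SYN_001", smiles_2 = "SYN_002")
  expect_equal(nrow(apply_filters(syn, canonicalize = FALSE)$kept), 1L)
})

test_that("gamma CSV write/read round trip is lossless", {
  recs <- toy_gamma_records(10L)
  f <- tempfile(fileext = ".csv")
  write_gamma_csv(recs, f)
  back <- read_gamma_csv(f)
  expect_equal(back$ln_gamma_1, recs$ln_gamma_1, tolerance = 1e-12)
  expect_equal(back$ln_gamma_2, recs$ln_gamma_2, tolerance = 1e-12)
  expect_equal(back$T_K, recs$T_K, tolerance = 1e-12)
  expect_equal(back$x_1, recs$x_1, tolerance = 1e-12)
  expect_identical(back$smiles_1, recs$smiles_1)
})

test_that("gamma schema violations are rejected with informative conditions", {
  recs <- toy_gamma_records(4L)
  f <- tempfile(fileext = ".csv")
  utils::write.csv(recs[setdiff(names(recs), "x_1")], f, row.names = FALSE)
  expect_error(read_gamma_csv(f), class = "schema_error")
  # a row with both ln gammas blank is rejected, and the message names it
  recs$ln_gamma_1[2] <- NA
  recs$ln_gamma_2[2] <- NA
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(recs, f2, row.names = FALSE, na = "")
  expect_warning(back <- read_gamma_csv(f2), regexp = "2")
  expect_equal(nrow(back), 3L)
  # one-sided records are first-class
  one_sided <- data.frame(smiles_1 = "A", smiles_2 = "B", T_K = 300,
                          x_1 = 0, ln_gamma_1 = 0.8, ln_gamma_2 = NA,
                          source = "infinite_dilution")
  f3 <- tempfile(fileext = ".csv")
  write_gamma_csv(one_sided, f3)
  expect_equal(read_gamma_csv(f3)$ln_gamma_1, 0.8)
})
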