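make_cohort <- function(df, kinds = NULL) {
  if (is.null(kinds)) kinds <- rep("continuous", ncol(df))
  metas <- lapply(seq_along(df), function(k) {
    if (kinds[k] == "binary") {
      variable_meta(names(df)[k], "binary", scale_min = 0, scale_max = 1,
                    positive_rate = mean(df[[k]], na.rm = TRUE))
    } else {
      variable_meta(names(df)[k], "continuous", mean = 0, sd = 1)
    }
  })
  names(metas) <- names(df)
  cohort_table(df, metas, check_bounds = FALSE)
}

test_that("complete-case filter drops exactly the rows with any missing cell", {
  set.seed(1)
  df <- as.data.frame(matrix(rnorm(146 * 3), 146, 3))
  names(df) <- c("PainDETECT", "S_LANSS", "CSI")

  # 3 + 3 missing cells in six distinct rows
  d6 <- df; d6$PainDETECT[1:3] <- NA; d6$S_LANSS[4:6] <- NA
  res <- complete_case_filter(make_cohort(d6))
  expect_identical(res$dropped, 6L)
  expect_identical(nrow(res$table), 140L)
  expect_false(anyNA(res$table))

  # one overlapping row: 141 remain, 5 dropped
  d5 <- df; d5$PainDETECT[1:3] <- NA; d5$S_LANSS[3:5] <- NA
  res5 <- complete_case_filter(make_cohort(d5))
  expect_identical(res5$dropped, 5L)
  expect_identical(nrow(res5$table), 141L)

  # complete table is the identity
  res0 <- complete_case_filter(make_cohort(df))
  expect_identical(res0$dropped, 0L)
  expect_equal(as.data.frame(res0$table), df, ignore_attr = TRUE)

  # row order preserved
  expect_equal(res5$table$CSI, df$CSI[-(1:5)])

  all_na <- df; all_na[, 1] <- NA_real_
  expect_error(complete_case_filter(make_cohort(all_na)), "empty cohort")
})

test_that("pearson estimator matches the direct formula and flags degenerate input", {
  expect_equal(pearson_cor(1:5, 1:5), 1.0)
  expect_equal(pearson_cor(c(1, 2, 3), c(3, 2, 1)), -1.0)
  # hand-computed product-moment value for (1,2,3,4) vs (1,2,4,3):
  # cov = 4/3, var_x = var_y = 5/3 -> r = 0.8
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(1, 2, 4, 3)), 0.8)
  expect_error(pearson_cor(rep(1, 5), 1:5, xname = "flat"), "flat")
})

test_that("polyserial recovers the latent correlation lost to dichotomization", {
  set.seed(10)
  n <- 1e5
  rho <- 0.6
  x <- rnorm(n)
  latent <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  y <- as.numeric(latent > median(latent))

  est <- polyserial_cor(x, y)
  expect_lt(abs(est - rho), 0.02)
  # the point-biserial Pearson estimate is attenuated to about 2/pi * rho
  expect_lt(cor(x, y), 0.52)

  # independence
  y0 <- as.numeric(rnorm(n) > 0)
  expect_lt(abs(polyserial_cor(x, y0)), 0.02)

  # sign symmetry under class flip
  expect_equal(polyserial_cor(x, 1 - y), -est, tolerance = 1e-4)

  expect_error(polyserial_cor(x, rep(1, n)), "single class")
})

test_that("mixed matrix tags estimators per pair and stays PSD", {
  set.seed(11)
  n <- 400
  x <- matrix(rnorm(n * 3), n, 3)
  df <- data.frame(a = x[, 1], b = x[, 2] + 0.5 * x[, 1], c = x[, 3])
  S <- mixed_matrix(make_cohort(df))
  expect_true(all(S$method[upper.tri(S$method)] == "pearson"))
  # fully continuous: equals the textbook sample correlation matrix
  expect_equal(unname(S$values), unname(cor(as.matrix(df))), tolerance = 1e-12)

  dfb <- df; dfb$g <- as.numeric(x[, 1] + rnorm(n) > 0)
  Sb <- mixed_matrix(make_cohort(dfb, c(rep("continuous", 3), "binary")))
  expect_identical(Sb$method["g", "a"], "polyserial")
  expect_identical(Sb$method["a", "b"], "pearson")
  ev <- eigen(Sb$values, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0)

  # 2-variable table: off-diagonal equals the scalar estimator exactly
  S2 <- mixed_matrix(make_cohort(df[, 1:2]))
  expect_equal(S2$values[1, 2], pearson_cor(df$a, df$b))
  S2b <- mixed_matrix(make_cohort(dfb[, c("a", "g")],
                                  c("continuous", "binary")))
  expect_equal(S2b$values["a", "g"], polyserial_cor(dfb$a, dfb$g))

  # pearson-only sensitivity mode never uses the latent-scale estimator
  Sp <- mixed_matrix(make_cohort(dfb, c(rep("continuous", 3), "binary")),
                     mode = "pearson")
  expect_true(all(Sp$method[upper.tri(Sp$method)] == "pearson"))
  expect_lt(Sp$values["g", "a"], Sb$values["g", "a"])  # attenuation
})

test_that("mixed matrix is invariant to row order and affine rescaling", {
  set.seed(12)
  n <- 300
  df <- data.frame(a = rnorm(n), b = rnorm(n),
                   g = as.numeric(rnorm(n) > 0.2))
  df$b <- df$b + 0.4 * df$a
  kinds <- c("continuous", "continuous", "binary")
  S <- mixed_matrix(make_cohort(df, kinds))

  perm <- sample(n)
  S_perm <- mixed_matrix(make_cohort(df[perm, ], kinds))
  expect_equal(S_perm$values, S$values, tolerance = 1e-12)

  df2 <- df; df2$a <- 10 + 3 * df$a; df2$b <- -2 + 0.1 * df$b
  S_aff <- mixed_matrix(make_cohort(df2, kinds))
  expect_equal(S_aff$values, S$values, tolerance = 1e-9)
})

test_that("correlation matrix exports with labels and estimator tags", {
  set.seed(13)
  df <- data.frame(a = rnorm(50), g = as.numeric(rnorm(50) > 0))
  df$b <- df$a + rnorm(50)
  S <- mixed_matrix(make_cohort(df[, c("a", "b", "g")],
                                c("continuous", "continuous", "binary")))
  path <- file.path(tempdir(), "corr.csv")
  write_correlation_csv(S, path)
  back <- as.matrix(read.csv(path, row.names = 1))
  expect_equal(unname(back), unname(S$values), tolerance = 1e-12)
  tags <- as.matrix(read.csv(sub("\\.csv$", "_methods.csv", path),
                             row.names = 1))
  expect_identical(tags["g", "a"], "polyserial")
  unlink(c(path, sub("\\.csv$", "_methods.csv", path)))
})

test_that("nearest-PD repair projects indefinite matrices and fixes valid ones", {
  # PD input is a fixed point
  S <- matrix(c(1, 0.3, 0.3, 1), 2, 2)
  expect_equal(nearest_pd(S), S, tolerance = 1e-12)
  expect_equal(nearest_pd(diag(4)), diag(4))

  # infeasible 3x3: off-diagonals (0.9, 0.9, -0.9) cannot be a correlation
  M <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3, 3)
  expect_lt(min(eigen(M, symmetric = TRUE)$values), 0)
  R <- nearest_pd(M)
  expect_equal(unname(diag(R)), rep(1, 3))
  expect_true(isSymmetric(R))
  expect_gte(min(eigen(R, symmetric = TRUE)$values), 1e-8)
  # projection moved it as little as the constraints allow: still close
  expect_lt(max(abs(R - M)), 0.5)

  expect_error(nearest_pd(matrix(c(1, 0.5, 0.2, 1), 2, 2)), "symmetric")
})
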