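test_that("ground-truth construction enforces feasibility and symmetry", {
  # independence: no edges, identity precision
  gt0 <- build_ground_truth(data.frame(from = character(), to = character(),
                                       rho = numeric()),
                            labels = c("a", "b", "c"))
  expect_equal(gt0$partials, matrix(0, 3, 3, dimnames = list(letters[1:3],
                                                             letters[1:3])))
  expect_equal(unname(gt0$precision), diag(3))

  # default eight-edge network: implied precision strictly PD
  gt <- build_ground_truth()
  expect_true(isSymmetric(gt$partials))
  expect_equal(unname(diag(gt$partials)), rep(0, 14))
  ev <- eigen(gt$precision, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_equal(gt$partials["PainDETECT", "S_LANSS"], 0.388)
  expect_equal(gt$partials["PSQI", "EQ5D5L"], -0.162)

  # boundary: |rho| = 0.99 is feasible for two nodes, 1.0 is rejected
  e99 <- data.frame(from = "a", to = "b", rho = 0.99)
  expect_s3_class(build_ground_truth(e99, labels = c("a", "b")),
                  "ground_truth_network")
  e1 <- data.frame(from = "a", to = "b", rho = 1.0)
  expect_error(build_ground_truth(e1, labels = c("a", "b")), "rho")

  # infeasible triangle: three partials of +0.9 imply an indefinite precision
  tri <- data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
                    rho = c(0.9, 0.9, 0.9))
  expect_error(build_ground_truth(tri, labels = c("a", "b", "c")),
               "infeasible network")

  expect_error(build_ground_truth(rbind(e99, e99), labels = c("a", "b")),
               "duplicate")
})

test_that("latent sampling is seed-deterministic and hits planted partial correlations", {
  gt <- build_ground_truth(data.frame(from = "x1", to = "x2", rho = 0.5),
                           labels = c("x1", "x2", "x3"))
  X1 <- sample_latent(gt, 100, seed = 3)
  X2 <- sample_latent(gt, 100, seed = 3)
  expect_identical(X1, X2)

  # partial correlations from the inverse sample covariance at n = 1e5
  X <- sample_latent(gt, 1e5, seed = 42)
  K <- solve(cov(X))
  pc <- -K / sqrt(outer(diag(K), diag(K)))
  expect_lt(abs(pc["x1", "x2"] - 0.5), 0.02)
  expect_lt(abs(pc["x1", "x3"]), 0.02)

  # independence network: all pairwise partials near zero
  gt0 <- build_ground_truth(data.frame(from = character(), to = character(),
                                       rho = numeric()),
                            labels = paste0("v", 1:4))
  X0 <- sample_latent(gt0, 1e5, seed = 7)
  K0 <- solve(cov(X0))
  pc0 <- -K0 / sqrt(outer(diag(K0), diag(K0)))
  diag(pc0) <- 0
  expect_lt(max(abs(pc0)), 0.02)
})

test_that("full planted network is recovered from inverse sample covariance", {
  gt <- build_ground_truth()
  X <- sample_latent(gt, 1e5, seed = 9)
  K <- solve(cov(X))
  pc <- -K / sqrt(outer(diag(K), diag(K)))
  diag(pc) <- 0
  expect_lt(max(abs(pc - gt$partials)), 0.02)
})

test_that("realized cohorts match the published marginals", {
  gt <- build_ground_truth()
  metas <- default_variable_metas()
  X <- sample_latent(gt, 1e4, seed = 5)
  tab <- realize_cohort(X, metas)

  expect_lt(abs(mean(tab$CSI) - 33.9), 1)
  expect_lt(abs(mean(tab$Gender == 0) - 0.468), 0.02)  # male fraction
  expect_true(all(tab$CSI >= 0 & tab$CSI <= 100))
  expect_true(all(tab$CSI == round(tab$CSI)))           # integer Likert total
  expect_true(all(tab$EQ5D5L >= 0 & tab$EQ5D5L <= 1))
  expect_true(all(tab$Gender %in% c(0, 1)))
})

test_that("continuous mode is an exact affine map of the latent matrix", {
  gt <- build_ground_truth()
  metas <- default_variable_metas()
  X <- sample_latent(gt, 500, seed = 8)
  tab <- realize_cohort(X, metas, continuous = TRUE, binarize = FALSE)
  # affine invariance: all pairwise Pearson correlations preserved exactly
  expect_equal(unname(cor(as.matrix(tab))), unname(cor(X)), tolerance = 1e-12)
  # and the CSI column is exactly the rescaled latent column
  z <- (X[, "CSI"] - mean(X[, "CSI"])) / sd(X[, "CSI"])
  expect_equal(tab$CSI, 33.9 + 17.2 * z)
})

test_that("missingness injection places exactly the requested MCAR cells", {
  gt <- build_ground_truth()
  metas <- default_variable_metas()
  tab <- realize_cohort(sample_latent(gt, 146, seed = 1), metas)

  out <- inject_missingness(tab, default_missingness_spec(), seed = 2)
  expect_identical(sum(is.na(out)), 6L)
  expect_identical(sum(is.na(out$PainDETECT)), 3L)
  expect_identical(sum(is.na(out$S_LANSS)), 3L)

  # empty spec is the identity
  none <- inject_missingness(tab, missingness_spec(), seed = 2)
  expect_identical(as.data.frame(none), as.data.frame(tab))

  # boundary: count = n blanks the whole column
  all_gone <- inject_missingness(tab, missingness_spec(counts = c(CSI = 146)),
                                 seed = 3)
  expect_true(all(is.na(all_gone$CSI)))
  expect_error(inject_missingness(tab, missingness_spec(counts = c(CSI = 147)),
                                  seed = 3),
               "exceeds")

  # determinism
  expect_identical(
    as.data.frame(inject_missingness(tab, default_missingness_spec(), seed = 4)),
    as.data.frame(inject_missingness(tab, default_missingness_spec(), seed = 4))
  )
})

test_that("cohort CSV round-trips through the metadata sidecar", {
  tab <- simulate_cohort(n = 30, seed = 77)
  path <- file.path(tempdir(), "cohort_roundtrip.csv")
  write_cohort_csv(tab, path)
  back <- read_cohort_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  kinds <- vapply(attr(back, "metas"), `[[`, "", "kind")
  expect_identical(unname(kinds[names(back) == "Gender"]), "binary")
  unlink(c(path, paste0(path, ".meta.json")))
})
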