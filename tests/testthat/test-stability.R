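chain3_cohort <- function(n, seed) {
  gt <- build_ground_truth(
    data.frame(from = c("x1", "x2"), to = c("x2", "x3"), rho = c(0.45, 0.35)),
    labels = c("x1", "x2", "x3")
  )
  X <- sample_latent(gt, n, seed = seed)
  metas <- lapply(colnames(X), function(nm)
    variable_meta(nm, "continuous", mean = 0, sd = 1))
  names(metas) <- colnames(X)
  cohort_table(as.data.frame(X), metas, check_bounds = FALSE)
}

test_that("edge bootstrap separates planted edges from the planted zero", {
  tab <- chain3_cohort(5000, seed = 41)
  eb <- bootstrap_edges(tab, B = 200, seed = 42)
  ci <- eb$ci
  key <- paste(ci$from, ci$to)
  e12 <- ci[key == "x1 x2", ]
  e23 <- ci[key == "x2 x3", ]
  e13 <- ci[key == "x1 x3", ]
  expect_gt(e12$lower, 0)
  expect_gt(e23$lower, 0)
  expect_lte(e13$lower, 0)
  expect_gte(e13$upper, 0)
  expect_lt(abs(e12$point - 0.45), 0.05)
})

test_that("edge bootstrap is seed-deterministic and handles B = 1", {
  tab <- chain3_cohort(400, seed = 43)
  a <- bootstrap_edges(tab, B = 25, seed = 7)
  b <- bootstrap_edges(tab, B = 25, seed = 7)
  expect_identical(a$replicates, b$replicates)
  expect_identical(a$ci, b$ci)

  one <- bootstrap_edges(tab, B = 1, seed = 8)
  # degenerate interval at the single replicate
  expect_equal(one$ci$lower, one$ci$upper)
  expect_equal(one$ci$lower, one$replicates[, 1])
})

test_that("case-dropping correlations behave at the no-drop boundary and degrade on noise", {
  tab <- chain3_cohort(2000, seed = 44)
  cd0 <- case_dropping(tab, proportions = c(0, 0.2), B = 5, seed = 45)
  at0 <- cd0$correlations[cd0$correlations$proportion == 0, ]
  expect_true(all(at0$strength == 1))
  expect_true(all(at0$closeness == 1))
  expect_true(all(at0$betweenness == 1))

  # strong planted structure at large n: correlations stay near 1
  at2 <- cd0$correlations[cd0$correlations$proportion == 0.2, ]
  expect_gt(mean(at2$strength, na.rm = TRUE), 0.9)

  # determinism
  cd1 <- case_dropping(tab, proportions = c(0.1, 0.4), B = 10, seed = 46)
  cd2 <- case_dropping(tab, proportions = c(0.1, 0.4), B = 10, seed = 46)
  expect_identical(cd1$correlations, cd2$correlations)

  # independence data: strength stability degrades as more cases are dropped
  gt0 <- build_ground_truth(data.frame(from = character(), to = character(),
                                       rho = numeric()),
                            labels = paste0("v", 1:5))
  X0 <- sample_latent(gt0, 200, seed = 47)
  metas0 <- lapply(colnames(X0), function(nm)
    variable_meta(nm, "continuous", mean = 0, sd = 1))
  names(metas0) <- colnames(X0)
  noise <- cohort_table(as.data.frame(X0), metas0, check_bounds = FALSE)
  cdn <- case_dropping(noise, proportions = c(0.05, 0.75), B = 40, seed = 48)
  m <- tapply(abs(cdn$correlations$strength), cdn$correlations$proportion,
              function(v) mean(!is.na(v) & v >= 0.7))
  expect_lte(m[["0.75"]], m[["0.05"]])
})

test_that("cs coefficient reproduces hand-counted results on constructed tables", {
  # grid {0.1, 0.2}; at 0.1 exactly 47/50 = 94% of replicates pass, at 0.2 none
  build <- function(p1_pass) {
    data.frame(
      proportion = rep(c(0.1, 0.2), each = 50),
      replicate = rep(1:50, 2),
      strength = c(rep(0.9, p1_pass), rep(0.1, 50 - p1_pass), rep(0.1, 50)),
      closeness = rep(0, 100),
      betweenness = rep(1, 100)
    )
  }
  tab94 <- build(47)
  cs95 <- cs_coefficient(tab94, cor_threshold = 0.7, confidence = 0.95)
  expect_identical(cs95$strength, 0)
  cs90 <- cs_coefficient(tab94, cor_threshold = 0.7, confidence = 0.9)
  expect_identical(cs90$strength, 0.1)

  # all-pass and all-fail boundaries over the default grid
  grid <- seq(0.05, 0.75, by = 0.05)
  allpass <- data.frame(proportion = rep(grid, each = 10),
                        replicate = rep(1:10, length(grid)),
                        strength = 1, closeness = 1, betweenness = 1)
  cs1 <- cs_coefficient(allpass)
  expect_identical(cs1$strength, 0.75)
  allfail <- allpass
  allfail$strength <- allfail$closeness <- allfail$betweenness <- 0
  expect_identical(cs_coefficient(allfail)$strength, 0)

  # the qualifying run must be contiguous from the smallest proportion
  gap <- allpass
  gap$strength[gap$proportion == 0.10] <- 0
  expect_identical(cs_coefficient(gap)$strength, 0.05)

  # closeness fails everywhere, betweenness passes everywhere
  expect_identical(cs95$closeness, 0)
  expect_identical(cs95$betweenness, 0.2)
})

test_that("cs coefficient is non-increasing in threshold and confidence", {
  set.seed(49)
  grid <- seq(0.05, 0.5, by = 0.05)
  cors <- data.frame(
    proportion = rep(grid, each = 30),
    replicate = rep(1:30, length(grid)),
    strength = pmin(1, pmax(-1, 1 - rep(grid, each = 30) * 1.6 +
                              rnorm(30 * length(grid), 0, 0.15)))
  )
  cors$closeness <- cors$betweenness <- cors$strength
  for (conf in c(0.8, 0.9)) {
    cs_lo <- cs_coefficient(cors, cor_threshold = 0.5, confidence = conf)
    cs_hi <- cs_coefficient(cors, cor_threshold = 0.8, confidence = conf)
    expect_lte(cs_hi$strength, cs_lo$strength)
  }
  for (thr in c(0.5, 0.7)) {
    cs_lo <- cs_coefficient(cors, cor_threshold = thr, confidence = 0.7)
    cs_hi <- cs_coefficient(cors, cor_threshold = thr, confidence = 0.99)
    expect_lte(cs_hi$strength, cs_lo$strength)
  }
})

test_that("stability report serializes to JSON with all components", {
  tab <- chain3_cohort(400, seed = 50)
  eb <- bootstrap_edges(tab, B = 10, seed = 51)
  cd <- case_dropping(tab, proportions = c(0.1, 0.3), B = 5, seed = 52)
  cs <- cs_coefficient(cd)
  rep <- stability_report(eb, cd, cs)
  path <- file.path(tempdir(), "stab.json")
  write_stability_json(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(back$edge_bootstrap$B, 10L)
  expect_named(back$cs, c("strength", "closeness", "betweenness",
                          "cor_threshold", "confidence"))
  unlink(path)
})
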