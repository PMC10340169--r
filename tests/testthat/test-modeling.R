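# Scaling, random forests, linear fits and group comparisons.

test_that("scaleCenter standardizes columns and drops zero variance", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(-1, 0, 4))
  st <- scaleCenter(x)
  expect_equal(st$scaled[, "a"], c(-1, 0, 1), tolerance = 1e-12)
  expect_equal(st$dropped, "b")
  expect_equal(colMeans(st$scaled), c(a = 0, c = 0), tolerance = 1e-9)
  expect_equal(apply(st$scaled, 2, sd), c(a = 1, c = 1), tolerance = 1e-12)

  # re-applying the stored transform reproduces fit-transform
  again <- scaleCenter(x, transform = st)
  expect_identical(again$scaled, st$scaled)
  expect_error(scaleCenter(matrix(numeric(0), 0, 0)), "empty")
})

test_that("random forest recovers a perfect predictor and fails a permutation null", {
  set.seed(1)
  n <- 300L
  x <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  y <- x[, 3L]
  # every split may consider all features: the forest can isolate the copy
  rep1 <- fitRandomForest(x, y, nFolds = 5L, nTrees = 300L, seed = 1L,
                          mtry = ncol(x), minNodeSize = 1L)
  expect_s4_class(rep1, "ModelReport")
  expect_equal(rep1@mode, "regression")
  expect_gte(rep1@scoreCV, 0.99)
  expect_equal(names(which.max(rep1@importance)), "f3")

  # pure-noise target: out-of-fold R2 near zero
  yPerm <- sample(rep(c(50, 100, 200, 400), length.out = n))
  rep0 <- fitRandomForest(x, yPerm, nFolds = 5L, nTrees = 300L, seed = 1L)
  expect_lte(rep0@scoreCV, 0.1)

  # importances normalized; CV predictions are strictly out-of-fold
  expect_equal(sum(rep1@importance), 100, tolerance = 1e-6)
  expect_true(all(rep1@importance >= 0))
  expect_equal(sort(unique(rep1@folds)), 1:5)

  # errors on degenerate inputs
  expect_error(fitRandomForest(x, rep(1, n), seed = 1L), "single distinct")
  expect_error(fitRandomForest(x[1:10, ], y[1:10], seed = 1L), "fewer rows")
})

test_that("model fits are reproducible given a seed", {
  set.seed(2)
  x <- matrix(rnorm(600), 100, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- x[, 1L] + rnorm(100, 0, 0.3)
  a <- fitRandomForest(x, y, seed = 7L)
  b <- fitRandomForest(x, y, seed = 7L)
  expect_identical(a@scoreCV, b@scoreCV)
  expect_identical(a@importance, b@importance)
  expect_identical(a@folds, b@folds)
})

test_that("wild-type vs knockout genotype classification is near-perfect", {
  cfg <- simulationConfig(fieldShapePx = c(448L, 448L),
                          nOrganoidsPerField = c(7L, 7L), fusionProb = 0,
                          fieldsPerWell = 4L)
  design <- list(A01 = wellCondition(genotype = "WT"),
                 A02 = wellCondition(genotype = "KO"))
  plate <- simulatePlate(cfg, design, seed = 33)
  res <- runAnalyze(plate$fields, plate$plateMap,
                    families = c("shape", "radial", "engineered"))
  ret <- res$retained
  expect_gte(nrow(ret), 30L)
  fm <- buildFeatureMatrix(ret, "genotype")
  rep <- fitRandomForest(fm, nFolds = 5L, nTrees = 300L, seed = 33)
  expect_equal(rep@mode, "classification")
  expect_gte(rep@scoreCV, 0.9)
})

test_that("rankImportance orders features and rolls up families", {
  imp <- setNames(c(50, 50), c("a_rad_cs_frac_r1", "b"))
  rp <- new("ModelReport", mode = "regression", scoreTrain = 1, scoreCV = 1,
            importance = imp, nTrees = 10L, seed = 1L, folds = c(1L, 2L),
            predictions = data.frame())
  out <- rankImportance(rp)
  expect_equal(out$features$importance_pct, c(50, 50))
  # family roll-up is additive
  imp2 <- setNames(c(10, 20, 70), c("x_rad_cs_frac_r1", "x_rad_cs_frac_r2",
                                    "org_shape_area_um2"))
  rp2 <- initialize(rp, importance = imp2)
  fam <- rankImportance(rp2)$families
  expect_equal(fam$importance_pct[fam$family == "radial"], 30)
  expect_equal(fam$importance_pct[fam$family == "shape"], 70)
})

test_that("linearFit returns exact results on collinear points", {
  fit <- linearFit(c(0, 1, 2), c(0, 2, 4))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  anti <- linearFit(c(0, 1, 2, 3), c(9, 6, 3, 0))
  expect_equal(anti$r2, 1, tolerance = 1e-12)
  expect_lt(anti$slope, 0)

  set.seed(6)
  x <- 1:6; y <- x + rnorm(6, 0, 0.01)
  expect_gte(linearFit(x, y)$r2, 0.99)

  expect_error(linearFit(1:2, 1:2), "3")
  expect_error(linearFit(rep(1, 5), 1:5), "variance")
})

test_that("groupCompare adjusts pairwise p-values under each scheme", {
  set.seed(8)
  same <- data.frame(v = rep(rnorm(50), 2),
                     g = rep(c("a", "b"), each = 50))
  for (meth in c("anova_fdr", "kruskal_dunn", "mannwhitney")) {
    out <- groupCompare(same, "v", "g", meth)
    expect_gte(out$pairs$p_adjusted, 0.5)
    expect_equal(out$pairs$method, meth)
  }

  shift <- data.frame(v = c(rnorm(50), rnorm(50) + 10),
                      g = rep(c("a", "b"), each = 50))
  for (meth in c("anova_fdr", "kruskal_dunn", "mannwhitney")) {
    expect_lt(groupCompare(shift, "v", "g", meth)$pairs$p_adjusted, 1e-6)
  }

  # three groups: all pairs reported, omnibus recorded
  three <- data.frame(v = c(rnorm(30), rnorm(30) + 1, rnorm(30) + 2),
                      g = rep(c("a", "b", "c"), each = 30))
  out <- groupCompare(three, "v", "g", "kruskal_dunn")
  expect_equal(nrow(out$pairs), 3L)
  expect_equal(out$omnibus$method, "kruskal_wallis")
  expect_lt(out$omnibus$p_value, 1e-6)

  expect_error(groupCompare(data.frame(v = 1:3, g = c("a", "a", "a")),
                            "v", "g"), "two groups")
  expect_error(groupCompare(data.frame(v = 1:3, g = c("a", "a", "b")),
                            "v", "g"), "2 observations")
})
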