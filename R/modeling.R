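# Statistical layer: scaling, cross-validated random forests with
# normalized variable importance, linear regression utilities and
# group-comparison summaries.

#' Scale and center a feature matrix
#'
#' Centers every numeric column to mean 0 and scales it to unit standard
#' deviation; zero-variance columns are dropped (and reported). The fitted
#' transform is stored so it can be re-applied to new data.
#'
#' @param x numeric matrix or data.frame of features.
#' @param transform a previous `scaleTransform` to re-apply instead of
#'   fitting.
#' @return a list of class `scaleTransform`: `scaled` (matrix), `center`,
#'   `scale` (named vectors) and `dropped` (names of zero-variance
#'   columns).
#' @examples
#' scaleCenter(cbind(a = 1:3, b = c(5, 5, 5)))$dropped
#' @export
scaleCenter <- function(x, transform = NULL) {
  x <- as.matrix(x)
  stopIfNot(nrow(x) > 0L && ncol(x) > 0L, "empty matrix")
  if (is.null(transform)) {
    ctr <- colMeans(x)
    scl <- apply(x, 2L, sd)
    dropped <- colnames(x)[!is.finite(scl) | scl == 0]
    if (length(dropped))
      msg(sprintf("dropping %d zero-variance column(s): %s",
                  length(dropped), paste(head(dropped, 5L), collapse = ", ")))
    keep <- setdiff(colnames(x), dropped)
    ctr <- ctr[keep]; scl <- scl[keep]
  } else {
    ctr <- transform$center; scl <- transform$scale
    dropped <- transform$dropped
    keep <- names(ctr)
  }
  scaled <- sweep(sweep(x[, keep, drop = FALSE], 2L, ctr), 2L, scl, "/")
  structure(list(scaled = scaled, center = ctr, scale = scl,
                 dropped = dropped), class = "scaleTransform")
}

#' Build a modeling matrix from QC-retained records
#'
#' Selects the numeric feature columns ([featureColumns()]), resolves
#' sentinel values by dropping rows with missing features (records that
#' passed the single-lumen QC have none), and extracts the prediction
#' target.
#'
#' @param records data.frame of retained, metadata-joined records.
#' @param target name of the target column (`"concentration_um"`,
#'   `"ko_fraction"`, `"genotype"`, ...).
#' @return list with `x` (numeric matrix), `y` (target vector) and `rows`
#'   (indices of `records` used).
#' @export
buildFeatureMatrix <- function(records, target) {
  stopIfNot(target %in% names(records), "target column not found: ", target)
  cols <- featureColumns(records)
  x <- as.matrix(records[, cols, drop = FALSE])
  complete <- stats::complete.cases(x) & !is.na(records[[target]])
  list(x = x[complete, , drop = FALSE], y = records[[target]][complete],
       rows = which(complete))
}

#' Fit a bootstrap random forest with k-fold cross-validation
#'
#' Features are scaled and centered, then a random forest (bootstrap
#' resampling per tree) is fit. The cross-validated score uses out-of-fold
#' predictions only: rows are partitioned into `nFolds` folds, a forest is
#' fit on each training split and scored on the held-out fold. Variable
#' importance is permutation importance from a forest on the full data
#' (assessed on out-of-bag samples), truncated at zero and normalized to
#' sum to 100. Regression reports R-squared (1 - SSE/SST); classification
#' reports accuracy. Fully reproducible given the seed.
#'
#' @param x numeric feature matrix (or the list from
#'   [buildFeatureMatrix()]).
#' @param y target vector (ignored when `x` is a `buildFeatureMatrix`
#'   list); numeric targets give regression, others classification.
#' @param mode `"auto"`, `"regression"` or `"classification"`.
#' @param nFolds number of cross-validation folds (default 5).
#' @param nTrees trees per forest (default 500).
#' @param seed integer seed (mandatory for reproducibility).
#' @param mtry candidate features per split (default: ranger's default,
#'   sqrt of the feature count).
#' @param minNodeSize minimum terminal node size (default: ranger's
#'   default, 5 for regression and 1 for classification).
#' @return a [ModelReport-class].
#' @export
fitRandomForest <- function(x, y = NULL, mode = c("auto", "regression",
                                                  "classification"),
                            nFolds = 5L, nTrees = 500L, seed = 1L,
                            mtry = NULL, minNodeSize = NULL) {
  mode <- match.arg(mode)
  if (is.list(x) && !is.data.frame(x) && all(c("x", "y") %in% names(x))) {
    y <- x$y; x <- x$x
  }
  x <- as.matrix(x)
  stopIfNot(nrow(x) == length(y), "x and y dimensions differ")
  stopIfNot(length(unique(y)) >= 2L, "target has a single distinct value")
  stopIfNot(nrow(x) >= 5L * nFolds, "fewer rows than 5 per fold")
  if (mode == "auto")
    mode <- if (is.numeric(y)) "regression" else "classification"
  if (mode == "classification") y <- factor(y)

  st <- scaleCenter(x)
  xs <- st$scaled
  df <- data.frame(xs, check.names = FALSE)
  set.seed(seed)
  folds <- sample(rep(seq_len(nFolds), length.out = nrow(xs)))
  predCV <- if (mode == "regression") numeric(nrow(xs)) else
    character(nrow(xs))
  for (f in seq_len(nFolds)) {
    tr <- folds != f
    fit <- ranger::ranger(
      x = df[tr, , drop = FALSE], y = y[tr], num.trees = nTrees,
      replace = TRUE, mtry = mtry, min.node.size = minNodeSize,
      seed = subSeed(seed, f), num.threads = 1L)
    p <- predict(fit, data = df[!tr, , drop = FALSE],
                 num.threads = 1L)$predictions
    predCV[!tr] <- if (mode == "regression") p else as.character(p)
  }
  full <- ranger::ranger(
    x = df, y = y, num.trees = nTrees, replace = TRUE,
    mtry = mtry, min.node.size = minNodeSize,
    importance = "permutation", seed = subSeed(seed, 0L), num.threads = 1L)
  predTrain <- predict(full, data = df, num.threads = 1L)$predictions

  score <- function(obs, pred) {
    if (mode == "regression") {
      1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
    } else mean(as.character(obs) == as.character(pred))
  }
  imp <- pmax(full$variable.importance, 0)
  imp <- if (sum(imp) > 0) 100 * imp / sum(imp) else
    rep(100 / length(imp), length(imp))
  # renormalize exactly against accumulated float error
  imp <- 100 * imp / sum(imp)
  predDf <- data.frame(observed = y, predicted_cv = if (mode == "regression")
    as.numeric(predCV) else predCV, fold = folds)
  new("ModelReport", mode = mode,
      scoreTrain = score(y, predTrain),
      scoreCV = score(y, if (mode == "regression") as.numeric(predCV) else predCV),
      importance = imp, nTrees = as.integer(nTrees),
      seed = as.integer(seed), folds = as.integer(folds),
      predictions = predDf)
}

#' Rank variable importances (with family roll-ups)
#'
#' @param report a [ModelReport-class].
#' @return list with `features` (data.frame of feature, family, importance
#'   in percent, descending) and `families` (summed percentage per feature
#'   family).
#' @examples
#' \dontrun{rankImportance(fitRandomForest(x, y, seed = 1))}
#' @export
rankImportance <- function(report) {
  imp <- report@importance
  o <- order(imp, decreasing = TRUE)
  feats <- data.frame(feature = names(imp)[o],
                      family = featureFamily(names(imp)[o]),
                      importance_pct = as.numeric(imp[o]))
  famTot <- tapply(feats$importance_pct, feats$family, sum)
  fams <- data.frame(family = names(famTot),
                     importance_pct = as.numeric(famTot))
  fams <- fams[order(fams$importance_pct, decreasing = TRUE), ]
  rownames(fams) <- NULL
  list(features = feats, families = fams)
}

#' Ordinary least-squares fit of condition means
#'
#' @param x,y numeric vectors of condition means (>= 3 points; `x` must
#'   vary).
#' @return list with `slope`, `intercept`, `r2` (squared Pearson
#'   correlation).
#' @examples
#' linearFit(0:2, c(0, 2, 4))
#' @export
linearFit <- function(x, y) {
  stopIfNot(length(x) >= 3L && length(y) == length(x),
            "need at least 3 paired points")
  stopIfNot(var(x) > 0, "x has zero variance")
  fit <- lm(y ~ x)
  r2 <- if (var(y) > 0) cor(x, y)^2 else 1   # squared Pearson correlation
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r2 = r2)
}

# Dunn's post hoc z tests after Kruskal-Wallis, with tie correction
#' @noRd
dunnTest <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  gl <- split(r, groups)
  rbar <- vapply(gl, mean, 0)
  ns <- vapply(gl, length, 0L)
  gs <- names(gl)
  out <- list()
  for (i in seq_along(gs)[-length(gs)]) for (j in (i + 1L):length(gs)) {
    se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / ns[i] + 1 / ns[j]))
    z <- (rbar[i] - rbar[j]) / se
    out[[length(out) + 1L]] <- data.frame(
      group1 = gs[i], group2 = gs[j], statistic = z,
      p_value = 2 * pnorm(-abs(z)))
  }
  do.call(rbind, out)
}

#' Pairwise group comparisons with multiplicity adjustment
#'
#' Per-pair statistics under the selected scheme: `anova_fdr` = one-way
#' ANOVA omnibus plus all-pairs Welch t tests with Benjamini-Hochberg
#' adjustment; `kruskal_dunn` = Kruskal-Wallis omnibus plus Dunn's z tests
#' with Bonferroni adjustment; `mannwhitney` = all-pairs Wilcoxon rank-sum
#' tests with Benjamini-Hochberg adjustment.
#'
#' @param records data.frame.
#' @param valueColumn name of the numeric value column.
#' @param groupColumn name of the grouping column.
#' @param method `"anova_fdr"`, `"kruskal_dunn"` or `"mannwhitney"`.
#' @return list with `omnibus` (data.frame: method, statistic, p) and
#'   `pairs` (data.frame with raw and adjusted p-values; the method and
#'   adjustment are recorded in columns).
#' @export
groupCompare <- function(records, valueColumn, groupColumn,
                         method = c("anova_fdr", "kruskal_dunn",
                                    "mannwhitney")) {
  method <- match.arg(method)
  v <- records[[valueColumn]]
  g <- factor(records[[groupColumn]])
  stopIfNot(!is.null(v), "value column not found: ", valueColumn)
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  ns <- table(g)
  stopIfNot(nlevels(g) >= 2L, "need at least two groups")
  stopIfNot(all(ns >= 2L), "each group needs at least 2 observations")
  lv <- levels(g)

  if (method == "kruskal_dunn") {
    kw <- kruskal.test(v, g)
    omnibus <- data.frame(method = "kruskal_wallis",
                          statistic = unname(kw$statistic),
                          p_value = kw$p.value)
    pairs <- dunnTest(v, g)
    pairs$p_adjusted <- pmin(p.adjust(pairs$p_value, "bonferroni"), 1)
    pairs$adjustment <- "bonferroni"
  } else {
    if (method == "anova_fdr") {
      av <- summary(aov(v ~ g))[[1L]]
      omnibus <- data.frame(method = "anova",
                            statistic = av[1L, "F value"],
                            p_value = av[1L, "Pr(>F)"])
    } else {
      omnibus <- data.frame(method = "none", statistic = NA_real_,
                            p_value = NA_real_)
    }
    out <- list()
    for (i in seq_along(lv)[-length(lv)]) for (j in (i + 1L):length(lv)) {
      vi <- v[g == lv[i]]; vj <- v[g == lv[j]]
      tst <- if (method == "anova_fdr") {
        if (sd(vi) == 0 && sd(vj) == 0 && mean(vi) == mean(vj))
          list(statistic = 0, p.value = 1)     # identical degenerate groups
        else t.test(vi, vj)
      } else wilcox.test(vi, vj, exact = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        group1 = lv[i], group2 = lv[j],
        statistic = unname(tst$statistic), p_value = tst$p.value)
    }
    pairs <- do.call(rbind, out)
    pairs$p_adjusted <- p.adjust(pairs$p_value, "BH")
    pairs$adjustment <- "BH"
  }
  pairs$method <- method
  list(omnibus = omnibus, pairs = pairs)
}
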