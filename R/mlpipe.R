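#' Classifier / pipeline configuration
#'
#' The protocol: SMOTE class balancing and z-score scaling fitted inside
#' every training fold, greedy sequential forward selection (SFS) scored by
#' mean stratified 5-fold F1, outer leave-one-out cross-validation for the
#' reported metrics. Positive class defaults to PR (the majority class;
#' reported precision/sensitivity refer to PR).
#'
#' @param classifier `"svm"` or `"knn"`.
#' @param svm_kernel `"linear"` (default) or `"rbf"`.
#' @param svm_cost squared-hinge penalty weight (default 1).
#' @param rbf_gamma RBF width; default `1/n_features` at fit time.
#' @param knn_k neighbours for k-NN (default 5).
#' @param smote_neighbors SMOTE nearest-neighbour pool (default 5).
#' @param max_features SFS model sizes 1..max_features (default 7).
#' @param inner_folds inner CV folds for SFS scoring (default 5).
#' @param positive_class `"PR"` (default) or `"CR"`.
#' @param seed integer seed controlling folding and SMOTE draws.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(classifier = c("svm", "knn"),
                            svm_kernel = c("linear", "rbf"), svm_cost = 1,
                            rbf_gamma = NULL, knn_k = 5L,
                            smote_neighbors = 5L, max_features = 7L,
                            inner_folds = 5L,
                            positive_class = c("PR", "CR"), seed = 1L) {
  structure(list(classifier = match.arg(classifier),
                 svm_kernel = match.arg(svm_kernel), svm_cost = svm_cost,
                 rbf_gamma = rbf_gamma, knn_k = as.integer(knn_k),
                 smote_neighbors = as.integer(smote_neighbors),
                 max_features = as.integer(max_features),
                 inner_folds = as.integer(inner_folds),
                 positive_class = match.arg(positive_class),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' SMOTE: synthetic minority oversampling
#'
#' Synthetic minority samples are convex interpolations between a minority
#' sample and one of its `k` nearest minority neighbours (Euclidean),
#' generated until the classes are equal-sized. Applied only to training
#' folds by the cross-validation drivers. Already-balanced input is
#' returned unchanged.
#'
#' @param x numeric matrix (samples x features).
#' @param y class labels (two classes).
#' @param k neighbour pool size; must be < minority class size.
#' @param seed RNG seed for reproducible draws.
#' @return list with balanced `x`, `y` and `n_synthetic`.
#' @export
smote_balance <- function(x, y, k = 5L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.character(y)
  tab <- table(y)
  if (length(tab) != 2) stop("smote_balance: need exactly two classes")
  if (tab[1] == tab[2])
    return(list(x = x, y = y, n_synthetic = 0L))
  minority <- names(tab)[which.min(tab)]
  idx <- which(y == minority)
  n_min <- length(idx)
  if (n_min < 2) stop("minority class of 1: cannot interpolate")
  k <- min(k, n_min - 1L)
  need <- as.integer(max(tab) - n_min)
  xm <- x[idx, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nbrs <- apply(d, 1, function(r) order(r)[seq_len(k)])
  nbrs <- matrix(nbrs, nrow = k)
  set.seed(as.integer(seed))
  base_i <- rep_len(seq_len(n_min), need)
  pick <- nbrs[cbind(sample.int(k, need, replace = TRUE), base_i)]
  lam <- runif(need)
  synth <- xm[base_i, , drop = FALSE] +
    lam * (xm[pick, , drop = FALSE] - xm[base_i, , drop = FALSE])
  list(x = rbind(x, synth), y = c(y, rep(minority, need)),
       n_synthetic = need)
}

#' Fit z-score scaling on a training set
#'
#' Per-feature `(x - mean) / sd`, statistics from the training set only.
#' Zero-variance features are dropped with a warning (error if all are).
#'
#' @param train numeric matrix.
#' @return list of class `zscore_scaler`: `center`, `scale`, `keep`.
#' @export
zscore_fit <- function(train) {
  train <- as.matrix(train)
  ctr <- colMeans(train)
  scl <- apply(train, 2, sd)
  keep <- scl > 0
  if (!any(keep)) stop("all features have zero training variance")
  if (!all(keep))
    warning("dropping zero-variance features: ",
            paste(colnames(train)[!keep], collapse = ", "))
  structure(list(center = ctr[keep], scale = scl[keep], keep = keep),
            class = "zscore_scaler")
}

#' Apply a fitted z-score scaler
#' @param scaler from [zscore_fit()]; `x` a matrix on the same columns.
#' @param x numeric matrix to scale.
#' @return scaled matrix (zero-variance training columns removed).
#' @export
zscore_apply <- function(scaler, x) {
  x <- as.matrix(x)[, scaler$keep, drop = FALSE]
  sweep(sweep(x, 2, scaler$center), 2, scaler$scale, "/")
}

# ---- classifiers ---------------------------------------------------------
# Linear SVM: primal squared-hinge (L2-SVM), convex and smooth, solved with
# BFGS; deterministic. RBF: same loss over a kernel expansion.

.svm_fit_linear <- function(x, yy, cost) {
  n <- nrow(x); d <- ncol(x)
  obj <- function(w) {
    f <- drop(x %*% w[1:d]) + w[d + 1]
    m <- pmax(0, 1 - yy * f)
    0.5 * sum(w[1:d]^2) + cost * sum(m^2)
  }
  grad <- function(w) {
    f <- drop(x %*% w[1:d]) + w[d + 1]
    m <- pmax(0, 1 - yy * f)
    gw <- w[1:d] - 2 * cost * drop(crossprod(x, yy * m))
    gb <- -2 * cost * sum(yy * m)
    c(gw, gb)
  }
  w <- optim(numeric(d + 1), obj, grad, method = "BFGS",
             control = list(maxit = 200, reltol = 1e-10))$par
  list(w = w[1:d], b = w[d + 1])
}

.rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

.svm_fit_rbf <- function(x, yy, cost, gamma) {
  n <- nrow(x)
  K <- .rbf_kernel(x, x, gamma)
  obj <- function(w) {
    f <- drop(K %*% w[1:n]) + w[n + 1]
    m <- pmax(0, 1 - yy * f)
    0.5 * drop(crossprod(w[1:n], K %*% w[1:n])) + cost * sum(m^2)
  }
  grad <- function(w) {
    f <- drop(K %*% w[1:n]) + w[n + 1]
    m <- pmax(0, 1 - yy * f)
    gb <- -2 * cost * sum(yy * m)
    c(drop(K %*% (w[1:n] - 2 * cost * yy * m)), gb)
  }
  w <- optim(numeric(n + 1), obj, grad, method = "BFGS",
             control = list(maxit = 200, reltol = 1e-10))$par
  list(beta = w[1:n], b = w[n + 1], xtrain = x, gamma = gamma)
}

.fit_classifier <- function(x, y, cfg) {
  pos <- cfg$positive_class
  if (cfg$classifier == "svm") {
    yy <- ifelse(y == pos, 1, -1)
    if (cfg$svm_kernel == "linear") {
      mod <- .svm_fit_linear(x, yy, cfg$svm_cost)
      mod$kind <- "svm_linear"
    } else {
      gamma <- cfg$rbf_gamma %||% (1 / ncol(x))
      mod <- .svm_fit_rbf(x, yy, cfg$svm_cost, gamma)
      mod$kind <- "svm_rbf"
    }
  } else {
    mod <- list(kind = "knn", xtrain = x, ypos = (y == pos), k = cfg$knn_k)
  }
  mod$positive_class <- pos
  mod
}

# decision score: > threshold means positive class.
# svm: signed distance (threshold 0); knn: positive vote fraction (0.5).
.predict_score <- function(mod, x) {
  x <- as.matrix(x)
  switch(mod$kind,
         svm_linear = drop(x %*% mod$w) + mod$b,
         svm_rbf = drop(.rbf_kernel(x, mod$xtrain, mod$gamma) %*% mod$beta) +
           mod$b,
         knn = {
           an <- rowSums(x^2); bn <- rowSums(mod$xtrain^2)
           d2 <- outer(an, bn, "+") - 2 * tcrossprod(x, mod$xtrain)
           apply(d2, 1, function(r) {
             mean(mod$ypos[order(r)[seq_len(min(mod$k, length(r)))]])
           })
         })
}

.score_threshold <- function(mod) if (mod$kind == "knn") 0.5 else 0

#' Metrics from a confusion-count set
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), Acc = (TP+TN)/total, Precision =
#' TP/(TP+FP), F1 = 2 Precision Sn / (Precision + Sn), balanced accuracy =
#' (Sn+Sp)/2. Percent metrics are on the 0--100 scale. Undefined ratios
#' (zero denominator) are reported as 0 and flagged.
#'
#' @param tp,fp,tn,fn confusion counts (positive class per config).
#' @return list of class `metric_set`.
#' @export
metrics_from_confusion <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  safe <- function(num, den) if (den > 0) num / den else 0
  flags <- c(sensitivity = tp + fn == 0, specificity = tn + fp == 0,
             precision = tp + fp == 0)
  sn <- safe(tp, tp + fn); sp <- safe(tn, tn + fp)
  prec <- safe(tp, tp + fp)
  f1 <- if (prec + sn > 0) 2 * prec * sn / (prec + sn) else 0
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 sensitivity_pct = 100 * sn, specificity_pct = 100 * sp,
                 accuracy_pct = 100 * (tp + tn) / (tp + fp + tn + fn),
                 precision_pct = 100 * prec, F1 = f1,
                 balanced_accuracy_pct = 100 * (sn + sp) / 2,
                 undefined_flags = flags[flags]),
            class = "metric_set")
}

# pooled-score ROC and AUC (Mann-Whitney with tie correction)
.roc_auc <- function(scores, is_pos) {
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) return(list(auc = NA_real_, roc = NULL))
  r <- rank(scores)
  auc <- (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  roc <- t(vapply(c(Inf, thr, -Inf), function(t) {
    c(fpr = sum(!is_pos & scores >= t) / n0,
      tpr = sum(is_pos & scores >= t) / n1)
  }, numeric(2)))
  list(auc = auc, roc = as.data.frame(roc))
}

# deterministic stratified k-fold assignment
.stratified_folds <- function(y, k, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Inner cross-validated F1 of a feature subset
#'
#' Stratified k-fold on the given data; SMOTE and z-scoring are fitted
#' inside every training fold. This is the SFS scoring function; it is
#' exported so selection can be audited by exhaustive candidate scans.
#'
#' @param x feature matrix; `y` labels.
#' @param y class labels (two classes).
#' @param cfg a [pipeline_config()].
#' @param seed seed for the fold assignment and SMOTE.
#' @return mean F1 over folds.
#' @export
inner_cv_f1 <- function(x, y, cfg, seed = cfg$seed) {
  x <- as.matrix(x)
  k <- cfg$inner_folds
  if (min(table(y)) < k)
    k <- max(2L, min(table(y)))
  fold <- .stratified_folds(y, k, seed)
  f1s <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2) stop("degenerate inner fold")
    bal <- smote_balance(x[tr, , drop = FALSE], y[tr],
                         cfg$smote_neighbors, seed = seed + 7919L * f)
    sc <- zscore_fit(bal$x)
    xtr <- zscore_apply(sc, bal$x)
    mod <- .fit_classifier(xtr, bal$y, cfg)
    xte <- zscore_apply(sc, x[!tr, , drop = FALSE])
    pred <- .predict_score(mod, xte) > .score_threshold(mod)
    truth <- y[!tr] == cfg$positive_class
    tp <- sum(pred & truth); fp <- sum(pred & !truth)
    fn <- sum(!pred & truth)
    if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1s)
}

#' Sequential forward selection by inner-CV F1
#'
#' Greedy wrapper selection: at each step the candidate feature whose
#' addition maximises the mean inner-fold F1 of the configured classifier
#' joins the set; ties are broken by ascending column index. All candidates
#' within one step share the same fold assignment and per-fold SMOTE seeds,
#' so the selection is auditable by re-scoring any candidate with
#' [inner_cv_f1()] at seed `cfg$seed + 131 * step`.
#'
#' @param x feature matrix with column names; `y` labels.
#' @param y class labels (two classes).
#' @param cfg a [pipeline_config()].
#' @return list of class `sfs_result`: `features` (ordered selected names),
#'   `scores` (inner F1 of the selected set at each step), and
#'   `step_scores` (per-step named candidate score vectors).
#' @export
sfs_select <- function(x, y, cfg) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 1, length(unique(y)) == 2)
  nmax <- min(cfg$max_features, ncol(x))
  selected <- character(0)
  sel_scores <- numeric(0)
  step_scores <- list()
  for (step in seq_len(nmax)) {
    cand <- setdiff(colnames(x), selected)
    sseed <- cfg$seed + 131L * step
    scores <- vapply(cand, function(cn) {
      inner_cv_f1(x[, c(selected, cn), drop = FALSE], y, cfg, seed = sseed)
    }, numeric(1))
    best <- cand[which.max(scores)]   # first max = lowest column index
    selected <- c(selected, best)
    sel_scores <- c(sel_scores, max(scores))
    step_scores[[step]] <- scores
  }
  structure(list(features = selected, scores = sel_scores,
                 step_scores = step_scores),
            class = "sfs_result")
}

#' Leave-one-out cross-validated evaluation of a feature subset
#'
#' Every patient is held out once; SMOTE and z-scoring are refit on the
#' remaining patients, the classifier is trained, and the held-out decision
#' score recorded. Confusion counts are aggregated over all folds; ROC and
#' AUC come from the pooled decision scores.
#'
#' @param x feature matrix; `y` labels; `features` subset of column names.
#' @param y class labels (two classes).
#' @param features character vector of feature columns to use.
#' @param cfg a [pipeline_config()].
#' @return list of class `loocv_report`: `metrics` ([metrics_from_confusion()]
#'   output), `auc`, `roc`, `scores`, `features`.
#' @export
evaluate_loocv <- function(x, y, features, cfg) {
  stopifnot(length(features) >= 1)
  x <- as.matrix(x)[, features, drop = FALSE]
  n <- nrow(x)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    bal <- smote_balance(x[-i, , drop = FALSE], y[-i],
                         cfg$smote_neighbors, seed = cfg$seed + i)
    sc <- zscore_fit(bal$x)
    mod <- .fit_classifier(zscore_apply(sc, bal$x), bal$y, cfg)
    scores[i] <- .predict_score(mod, zscore_apply(sc, x[i, , drop = FALSE]))
  }
  thr <- if (cfg$classifier == "knn") 0.5 else 0
  pred <- scores > thr
  truth <- y == cfg$positive_class
  met <- metrics_from_confusion(tp = sum(pred & truth),
                                fp = sum(pred & !truth),
                                tn = sum(!pred & !truth),
                                fn = sum(!pred & truth))
  ra <- .roc_auc(scores, truth)
  structure(list(metrics = met, auc = ra$auc, roc = ra$roc,
                 scores = scores, features = features, n = n),
            class = "loocv_report")
}

#' Run the full classification protocol on one dataset
#'
#' SFS up to `cfg$max_features`, then LOOCV evaluation of each nested model
#' size: one report row per size with the selected features and all metrics.
#'
#' @param dataset a `cohort_dataset`.
#' @param cfg a [pipeline_config()].
#' @return list of class `model_report`: `table` (data.frame, one row per
#'   model size), `selected` (feature list), `roc` (per size), `config`.
#' @export
run_pipeline <- function(dataset, cfg) {
  x <- as.matrix(dataset[, feature_columns(dataset), drop = FALSE])
  y <- dataset$label
  sel <- sfs_select(x, y, cfg)
  rows <- list(); rocs <- list()
  for (sz in seq_along(sel$features)) {
    rep <- evaluate_loocv(x, y, sel$features[seq_len(sz)], cfg)
    m <- rep$metrics
    rows[[sz]] <- data.frame(
      features_used = sz,
      sensitivity_pct = round(m$sensitivity_pct, 1),
      specificity_pct = round(m$specificity_pct, 1),
      accuracy_pct = round(m$accuracy_pct, 1),
      precision_pct = round(m$precision_pct, 1),
      F1 = round(m$F1, 3),
      balanced_accuracy_pct = round(m$balanced_accuracy_pct, 1),
      AUC = round(rep$auc, 2))
    rocs[[sz]] <- rep$roc
  }
  structure(list(table = do.call(rbind, rows),
                 selected = sel$features, roc = rocs, config = cfg),
            class = "model_report")
}

#' Run the end-to-end protocol: synthesis to comparison tables
#'
#' Generates (or accepts) a synthetic cohort, assembles the stage-1 QUS
#' texture dataset (7 maps x 68 features), builds the stage-2 enhanced
#' dataset (preset base-5 features + TOT features), and runs the SFS + LOOCV
#' protocol for both classifiers on both datasets.
#'
#' @param cohort a `synthetic_cohort` or a [cohort_spec()].
#' @param classifiers character subset of `c("svm", "knn")`.
#' @param ng gray levels; `max_features` SFS depth.
#' @param max_features largest model size evaluated.
#' @param seed pipeline seed.
#' @return list of class `qus_run`: `stage1`, `stage2` (datasets) and
#'   `reports[[dataset]][[classifier]]` model reports.
#' @export
qus_run_all <- function(cohort, classifiers = c("svm", "knn"), ng = 16L,
                        max_features = 7L, seed = 1L) {
  if (inherits(cohort, "cohort_spec")) cohort <-
      generate_synthetic_cohort(cohort)
  stage1 <- assemble_dataset(cohort, ng)
  reports <- list(stage1 = list(), stage2 = list())
  stage2 <- list()
  for (cl in classifiers) {
    cfg <- pipeline_config(classifier = cl, max_features = max_features,
                           seed = seed)
    reports$stage1[[cl]] <- run_pipeline(stage1, cfg)
    base5 <- preset_base5(cl)
    stage2[[cl]] <- assemble_tot_dataset(stage1, cohort, base5, ng)
    reports$stage2[[cl]] <- run_pipeline(stage2[[cl]], cfg)
  }
  structure(list(stage1 = stage1, stage2 = stage2, reports = reports),
            class = "qus_run")
}
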