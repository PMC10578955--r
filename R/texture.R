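#' Discretize a parametric map into gray levels
#'
#' Equal-width binning between the minimum and maximum of the valid pixels
#' into `ng` levels. A constant map maps every valid pixel to level 1. Binning
#' is min--max based, so multiplying the underlying map by a positive constant
#' (or adding any constant) leaves the gray image unchanged.
#'
#' @param map a `parametric_map` (see [parametric_map()]) or a plain numeric
#'   matrix, in which case non-finite entries are treated as invalid.
#' @param ng number of gray levels (>= 2).
#' @return an object of class `gray_image`: list with `levels` (integer matrix,
#'   `NA` outside validity), `ng`, and `provenance`.
#' @export
discretize <- function(map, ng = 16L) {
  ng <- as.integer(ng)
  if (ng < 2L) stop("ng must be >= 2")
  if (inherits(map, "parametric_map")) {
    vals <- map$values
    valid <- map$validity & is.finite(vals)
    pid <- map$parameter_id
  } else {
    vals <- as.matrix(map)
    valid <- is.finite(vals)
    pid <- "matrix"
  }
  if (!any(valid)) stop("discretize: no valid pixels")
  v <- vals[valid]
  lo <- min(v); hi <- max(v)
  lev <- matrix(NA_integer_, nrow(vals), ncol(vals))
  if (hi > lo) {
    l <- floor((vals[valid] - lo) / (hi - lo) * ng) + 1L
    lev[valid] <- pmin(as.integer(l), ng)
  } else {
    lev[valid] <- 1L
  }
  structure(list(levels = lev, ng = ng,
                 provenance = list(parameter_id = pid, rule = "equal-width",
                                   min = lo, max = hi)),
            class = "gray_image")
}

#' Compute the four gray-level texture matrices
#'
#' GLCM (distance 1, four directions, symmetrised, direction-summed), GLRLM
#' (runs per direction, direction-summed), GLSZM (8-connected zones) and GLDM
#' (8-neighbourhood, zero tolerance; the dependence column is the number of
#' equal-valued neighbours plus one, so an isolated pixel has dependence 1).
#' Invalid pixels never pair with valid ones.
#'
#' @param g a `gray_image` from [discretize()].
#' @return list of class `texture_matrices` with elements `glcm`, `glrlm`,
#'   `glszm`, `gldm` (count matrices, rows = gray level) and `n_valid`.
#' @export
compute_matrices <- function(g) {
  stopifnot(inherits(g, "gray_image"))
  lv <- g$levels
  structure(list(glcm = .cpp_glcm(lv, g$ng),
                 glrlm = .cpp_glrlm(lv, g$ng),
                 glszm = .cpp_glszm(lv, g$ng),
                 gldm = .cpp_gldm(lv, g$ng),
                 ng = g$ng,
                 n_valid = sum(!is.na(lv))),
            class = "texture_matrices")
}

#' The frozen texture-feature catalog
#'
#' 22 GLCM + 14 GLDM + 16 GLRLM + 16 GLSZM = 68 features per map. The GLCM
#' list is the classical 24-feature set minus Sum Average (a duplicate of
#' twice Joint Average for symmetric matrices) and MCC.
#'
#' @param family optional: one of `"glcm"`, `"glrlm"`, `"glszm"`, `"gldm"`,
#'   `"firstorder"`; default returns the four matrix families.
#' @return named list of character vectors (feature names per family), or a
#'   single character vector when `family` is given.
#' @export
texture_feature_catalog <- function(family = NULL) {
  cat <- list(
    glcm = c("Autocorrelation", "ClusterProminence", "ClusterShade",
             "ClusterTendency", "Contrast", "Correlation",
             "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
             "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2", "InverseVariance",
             "JointAverage", "JointEnergy", "JointEntropy",
             "MaximumProbability", "SumEntropy", "SumSquares"),
    gldm = c("DependenceEntropy", "DependenceNonUniformity",
             "DependenceNonUniformityNormalized", "DependenceVariance",
             "GrayLevelNonUniformity", "GrayLevelVariance",
             "HighGrayLevelEmphasis", "LargeDependenceEmphasis",
             "LargeDependenceHighGrayLevelEmphasis",
             "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
             "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
             "SmallDependenceLowGrayLevelEmphasis"),
    glrlm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "GrayLevelVariance", "HighGrayLevelRunEmphasis",
              "LongRunEmphasis", "LongRunHighGrayLevelEmphasis",
              "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
              "RunEntropy", "RunLengthNonUniformity",
              "RunLengthNonUniformityNormalized", "RunPercentage",
              "RunVariance", "ShortRunEmphasis",
              "ShortRunHighGrayLevelEmphasis", "ShortRunLowGrayLevelEmphasis"),
    glszm = c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
              "GrayLevelVariance", "HighGrayLevelZoneEmphasis",
              "LargeAreaEmphasis", "LargeAreaHighGrayLevelEmphasis",
              "LargeAreaLowGrayLevelEmphasis", "LowGrayLevelZoneEmphasis",
              "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
              "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
              "SmallAreaLowGrayLevelEmphasis", "ZoneEntropy", "ZonePercentage",
              "ZoneVariance"),
    firstorder = c("Energy", "Entropy", "Minimum", "Percentile10",
                   "Percentile90", "Maximum", "Mean", "Median",
                   "InterquartileRange", "Range", "MeanAbsoluteDeviation",
                   "RobustMeanAbsoluteDeviation", "RootMeanSquared",
                   "Skewness", "Kurtosis", "Variance", "Uniformity"))
  if (is.null(family)) return(cat[c("glcm", "gldm", "glrlm", "glszm")])
  cat[[match.arg(family, names(cat))]]
}

# --- vectorised multi-image feature kernels -------------------------------
# `counts` is P x (ng*maxj), each row the column-major flattening of one
# ng x maxj count matrix; returns P x nfeat with catalog column names.
# Zero-safe conventions: an empty matrix yields all-zero features (entropy of
# the empty distribution is 0, emphasis ratios with empty mass are 0);
# GLCM Correlation of a degenerate (zero-variance) nonempty matrix is 1.

.xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

.glcm_features_multi <- function(counts, ng) {
  P <- nrow(counts)
  iv <- rep.int(seq_len(ng), ng)
  jv <- rep(seq_len(ng), each = ng)
  N <- rowSums(counts)
  Ns <- ifelse(N > 0, N, 1)
  p <- counts / Ns
  # marginals
  Mrow <- outer(iv, seq_len(ng), "==") * 1
  px <- p %*% Mrow                       # P x ng (symmetric: py = px)
  gl <- seq_len(ng)
  mux <- drop(px %*% gl)
  sigx2 <- drop(px %*% gl^2) - mux^2
  sigx <- sqrt(pmax(sigx2, 0))
  # sum / difference distributions
  sums <- iv + jv
  Msum <- outer(sums, 2:(2 * ng), "==") * 1
  psum <- p %*% Msum
  ks <- 2:(2 * ng)
  diffs <- abs(iv - jv)
  Mdiff <- outer(diffs, 0:(ng - 1), "==") * 1
  pdiff <- p %*% Mdiff
  kd <- 0:(ng - 1)
  # raw sums of (i+j)^k for cluster moments
  s1 <- drop(p %*% sums); s2 <- drop(p %*% sums^2)
  s3 <- drop(p %*% sums^3); s4 <- drop(p %*% sums^4)
  m <- 2 * mux
  autoc <- drop(p %*% (iv * jv))
  contrast <- drop(p %*% (iv - jv)^2)
  corr <- ifelse(sigx2 > 0, (autoc - mux^2) / pmax(sigx^2, .Machine$double.eps),
                 ifelse(N > 0, 1, 0))
  da <- drop(pdiff %*% kd)
  dentropy <- rowSums(-.xlog2(pdiff))
  dvar <- drop(pdiff %*% kd^2) - da^2
  jentropy <- rowSums(-.xlog2(p))
  hx <- rowSums(-.xlog2(px))
  # joint independent surface px_i * py_j
  pxi <- px[, iv, drop = FALSE]
  pyj <- px[, jv, drop = FALSE]
  pind <- pxi * pyj
  lind <- matrix(0, P, length(iv))
  pos <- pind > 0
  lind[pos] <- log2(pind[pos])
  hxy1 <- rowSums(-p * lind)
  hxy2 <- rowSums(-pind * lind)
  imc1 <- ifelse(hx > 0, (jentropy - hxy1) / hx, 0)
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - jentropy))))
  w_id   <- 1 / (1 + abs(iv - jv))
  w_idm  <- 1 / (1 + (iv - jv)^2)
  w_idmn <- 1 / (1 + (iv - jv)^2 / ng^2)
  w_idn  <- 1 / (1 + abs(iv - jv) / ng)
  w_iv   <- ifelse(iv != jv, 1 / (iv - jv)^2, 0)
  out <- cbind(
    Autocorrelation = autoc,
    ClusterProminence = s4 - 4 * m * s3 + 6 * m^2 * s2 - 4 * m^3 * s1 +
      m^4 * (N > 0),
    ClusterShade = s3 - 3 * m * s2 + 3 * m^2 * s1 - m^3 * (N > 0),
    ClusterTendency = s2 - 2 * m * s1 + m^2 * (N > 0),
    Contrast = contrast,
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = dentropy,
    DifferenceVariance = dvar,
    Id = drop(p %*% w_id),
    Idm = drop(p %*% w_idm),
    Idmn = drop(p %*% w_idmn),
    Idn = drop(p %*% w_idn),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = drop(p %*% w_iv),
    JointAverage = mux,
    JointEnergy = rowSums(p^2),
    JointEntropy = jentropy,
    MaximumProbability = apply(p, 1, max),
    SumEntropy = rowSums(-.xlog2(psum)),
    SumSquares = drop(p %*% iv^2) - mux^2)
  out
}

# shared kernel for the three level x size families (GLRLM / GLSZM / GLDM)
.lvsize_core <- function(counts, ng, maxj, np) {
  iv <- rep.int(seq_len(ng), maxj)
  jv <- rep(seq_len(maxj), each = ng)
  N <- rowSums(counts)
  Ns <- ifelse(N > 0, N, 1)
  p <- counts / Ns
  Mrow <- outer(iv, seq_len(ng), "==") * 1
  Mcol <- outer(jv, seq_len(maxj), "==") * 1
  rowmass <- counts %*% Mrow    # P x ng
  colmass <- counts %*% Mcol    # P x maxj
  pg <- rowmass / Ns
  pj <- colmass / Ns
  gl <- seq_len(ng); sz <- seq_len(maxj)
  mug <- drop(pg %*% gl)
  muj <- drop(pj %*% sz)
  list(iv = iv, jv = jv, N = N, Ns = Ns, p = p,
       rowmass = rowmass, colmass = colmass,
       glv = drop(pg %*% gl^2) - mug^2,
       jvar = drop(pj %*% sz^2) - muj^2,
       entropy = rowSums(-.xlog2(p)),
       gln = rowSums(rowmass^2) / Ns,
       glnn = rowSums(rowmass^2) / Ns^2,
       jn = rowSums(colmass^2) / Ns,
       jnn = rowSums(colmass^2) / Ns^2,
       pct = ifelse(np > 0, N / np, 0),
       e = function(w) drop(p %*% w))
}

.glrlm_features_multi <- function(counts, ng, maxj, np) {
  k <- .lvsize_core(counts, ng, maxj, np)
  iv <- k$iv; jv <- k$jv; e <- k$e
  cbind(GrayLevelNonUniformity = k$gln,
        GrayLevelNonUniformityNormalized = k$glnn,
        GrayLevelVariance = k$glv,
        HighGrayLevelRunEmphasis = e(iv^2),
        LongRunEmphasis = e(jv^2),
        LongRunHighGrayLevelEmphasis = e(iv^2 * jv^2),
        LongRunLowGrayLevelEmphasis = e(jv^2 / iv^2),
        LowGrayLevelRunEmphasis = e(1 / iv^2),
        RunEntropy = k$entropy,
        RunLengthNonUniformity = k$jn,
        RunLengthNonUniformityNormalized = k$jnn,
        RunPercentage = k$pct,
        RunVariance = k$jvar,
        ShortRunEmphasis = e(1 / jv^2),
        ShortRunHighGrayLevelEmphasis = e(iv^2 / jv^2),
        ShortRunLowGrayLevelEmphasis = e(1 / (iv^2 * jv^2)))
}

.glszm_features_multi <- function(counts, ng, maxj, np) {
  k <- .lvsize_core(counts, ng, maxj, np)
  iv <- k$iv; jv <- k$jv; e <- k$e
  cbind(GrayLevelNonUniformity = k$gln,
        GrayLevelNonUniformityNormalized = k$glnn,
        GrayLevelVariance = k$glv,
        HighGrayLevelZoneEmphasis = e(iv^2),
        LargeAreaEmphasis = e(jv^2),
        LargeAreaHighGrayLevelEmphasis = e(iv^2 * jv^2),
        LargeAreaLowGrayLevelEmphasis = e(jv^2 / iv^2),
        LowGrayLevelZoneEmphasis = e(1 / iv^2),
        SizeZoneNonUniformity = k$jn,
        SizeZoneNonUniformityNormalized = k$jnn,
        SmallAreaEmphasis = e(1 / jv^2),
        SmallAreaHighGrayLevelEmphasis = e(iv^2 / jv^2),
        SmallAreaLowGrayLevelEmphasis = e(1 / (iv^2 * jv^2)),
        ZoneEntropy = k$entropy,
        ZonePercentage = k$pct,
        ZoneVariance = k$jvar)
}

.gldm_features_multi <- function(counts, ng, maxj, np) {
  k <- .lvsize_core(counts, ng, maxj, np)
  iv <- k$iv; jv <- k$jv; e <- k$e
  cbind(DependenceEntropy = k$entropy,
        DependenceNonUniformity = k$jn,
        DependenceNonUniformityNormalized = k$jnn,
        DependenceVariance = k$jvar,
        GrayLevelNonUniformity = k$gln,
        GrayLevelVariance = k$glv,
        HighGrayLevelEmphasis = e(iv^2),
        LargeDependenceEmphasis = e(jv^2),
        LargeDependenceHighGrayLevelEmphasis = e(iv^2 * jv^2),
        LargeDependenceLowGrayLevelEmphasis = e(jv^2 / iv^2),
        LowGrayLevelEmphasis = e(1 / iv^2),
        SmallDependenceEmphasis = e(1 / jv^2),
        SmallDependenceHighGrayLevelEmphasis = e(iv^2 / jv^2),
        SmallDependenceLowGrayLevelEmphasis = e(1 / (iv^2 * jv^2)))
}

.family_features_multi <- function(family, counts, ng, maxj, np) {
  switch(family,
         glcm = .glcm_features_multi(counts, ng),
         glrlm = .glrlm_features_multi(counts, ng, maxj, np),
         glszm = .glszm_features_multi(counts, ng, maxj, np),
         gldm = .gldm_features_multi(counts, ng, maxj, np),
         stop("unknown family: ", family))
}

#' Compute the 68 texture features from a set of texture matrices
#'
#' @param m a `texture_matrices` object from [compute_matrices()].
#' @return named numeric vector of 68 features, keys `<family>_<Feature>`.
#' @export
compute_texture_features <- function(m) {
  stopifnot(inherits(m, "texture_matrices"))
  np <- m$n_valid
  res <- c()
  for (fam in c("glcm", "gldm", "glrlm", "glszm")) {
    cm <- m[[fam]]
    maxj <- ncol(cm)
    counts <- matrix(as.vector(cm), nrow = 1)
    f <- .family_features_multi(fam, counts, m$ng, maxj, np)[1, ]
    # freeze catalog order
    f <- f[texture_feature_catalog(fam)]
    names(f) <- paste0(fam, "_", names(f))
    res <- c(res, f)
  }
  res
}

#' First-order (intensity histogram) features of ROI pixel values
#'
#' Percentiles use linear interpolation (R type 7). Entropy and Uniformity
#' use a 16-bin min--max histogram of the values. Skewness and kurtosis of a
#' constant input are 0 by convention (kurtosis is otherwise the
#' non-excess moment ratio m4/m2^2).
#'
#' @param x numeric vector (or `parametric_map`, in which case valid pixels
#'   are used).
#' @param nbins histogram bins for Entropy/Uniformity.
#' @return named numeric vector of 17 features, keys `firstorder_<Feature>`.
#' @export
first_order_features <- function(x, nbins = 16L) {
  if (inherits(x, "parametric_map")) x <- x$values[x$validity]
  x <- x[is.finite(x)]
  if (length(x) < 1) stop("first_order_features: no valid values")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  qs <- quantile(x, c(.1, .25, .5, .75, .9), names = FALSE, type = 7)
  lo <- min(x); hi <- max(x)
  if (hi > lo) {
    lev <- pmin(floor((x - lo) / (hi - lo) * nbins) + 1L, nbins)
  } else lev <- rep(1L, n)
  pb <- tabulate(lev, nbins) / n
  sub <- x[x >= qs[1] & x <= qs[5]]
  out <- c(
    Energy = sum(x^2),
    Entropy = sum(-.xlog2(pb)),
    Minimum = lo,
    Percentile10 = qs[1],
    Percentile90 = qs[5],
    Maximum = hi,
    Mean = mu,
    Median = qs[3],
    InterquartileRange = qs[4] - qs[2],
    Range = hi - lo,
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(sub)) mean(abs(sub - mean(sub))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) mean((x - mu)^4) / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(pb^2))
  names(out) <- paste0("firstorder_", names(out))
  out
}

#' Texture features of one frame's seven QUS parametric maps
#'
#' @param maps named list of 7 `parametric_map`s (one frame).
#' @param ng gray levels for discretization.
#' @param include_first_order also include the 17 first-order features per map.
#' @return named numeric vector (7 x 68 = 476 by default), keys
#'   `<map>_<family>_<Feature>`.
#' @export
frame_features <- function(maps, ng = 16L, include_first_order = FALSE) {
  out <- lapply(names(maps), function(id) {
    g <- discretize(maps[[id]], ng)
    f <- compute_texture_features(compute_matrices(g))
    if (include_first_order) f <- c(f, first_order_features(maps[[id]]))
    names(f) <- paste0(id, "_", names(f))
    f
  })
  unlist(out)
}

#' Assemble the per-patient feature dataset from a synthetic cohort
#'
#' Per-feature mean across each patient's frames; one row per patient, 476
#' columns (7 maps x 68 features) under the default catalog, plus a `label`
#' column. Patients with no valid frame are dropped with a warning.
#'
#' @param cohort a cohort from [generate_synthetic_cohort()].
#' @param ng gray levels.
#' @param include_first_order add first-order features per map.
#' @return data.frame of class `cohort_dataset`: `patient_id`, `label`, then
#'   feature columns.
#' @export
assemble_dataset <- function(cohort, ng = 16L, include_first_order = FALSE) {
  pids <- unique(cohort$manifest$patient_id)
  rows <- list()
  for (pid in pids) {
    fr <- cohort$frames[cohort$manifest$patient_id == pid]
    feats <- lapply(fr, function(f) {
      tryCatch(frame_features(f$maps, ng, include_first_order),
               error = function(e) NULL)
    })
    feats <- feats[!vapply(feats, is.null, logical(1))]
    if (!length(feats)) {
      warning("patient ", pid, " has no valid frames; excluded")
      next
    }
    rows[[as.character(pid)]] <- colMeans(do.call(rbind, feats))
  }
  mat <- do.call(rbind, rows)
  labels <- cohort$labels[match(names(rows), names(cohort$labels))]
  df <- data.frame(patient_id = names(rows), label = unname(labels),
                   mat, check.names = FALSE, row.names = NULL)
  stopifnot(!anyNA(df))
  class(df) <- c("cohort_dataset", class(df))
  df
}

#' Feature columns of a cohort dataset
#' @param dataset a `cohort_dataset`.
#' @return character vector of feature column names.
#' @export
feature_columns <- function(dataset) {
  setdiff(colnames(dataset), c("patient_id", "label"))
}
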