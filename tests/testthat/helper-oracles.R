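# Independent brute-force oracles for texture matrices and features.
# Deliberately naive (explicit loops, direct formula transcription); these
# stand in for an external reference radiomics implementation and must stay
# independent of the package's vectorised/C++ code paths.

bf_glcm <- function(lv, ng) {
  out <- matrix(0, ng, ng)
  nr <- nrow(lv); nc <- ncol(lv)
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  for (r in 1:nr) for (c in 1:nc) {
    if (is.na(lv[r, c])) next
    for (o in offs) {
      r2 <- r + o[1]; c2 <- c + o[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (is.na(lv[r2, c2])) next
      a <- lv[r, c]; b <- lv[r2, c2]
      out[a, b] <- out[a, b] + 1
      out[b, a] <- out[b, a] + 1
    }
  }
  out
}

bf_glrlm <- function(lv, ng) {
  nr <- nrow(lv); nc <- ncol(lv)
  maxlen <- max(nr, nc)
  out <- matrix(0, ng, maxlen)
  add_line <- function(vals) {
    n <- length(vals)
    i <- 1
    while (i <= n) {
      if (is.na(vals[i])) { i <- i + 1; next }
      j <- i
      while (j < n && !is.na(vals[j + 1]) && vals[j + 1] == vals[i]) j <- j + 1
      out[vals[i], j - i + 1] <<- out[vals[i], j - i + 1] + 1
      i <- j + 1
    }
  }
  for (r in 1:nr) add_line(lv[r, ])                       # 0 degrees
  for (c in 1:nc) add_line(lv[, c])                       # 90 degrees
  for (s in (-(nr - 1)):(nc - 1)) {                       # 45 / 135 via diagonals
    idx <- which(col(lv) - row(lv) == s)
    add_line(lv[idx[order(row(lv)[idx])]])                # down-right
  }
  for (s in 2:(nr + nc)) {
    idx <- which(col(lv) + row(lv) == s)
    add_line(lv[idx[order(row(lv)[idx])]])                # down-left
  }
  out
}

bf_glszm <- function(lv, ng) {
  nr <- nrow(lv); nc <- ncol(lv)
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  for (r in 1:nr) for (c in 1:nc) {
    if (seen[r, c] || is.na(lv[r, c])) next
    g <- lv[r, c]
    queue <- list(c(r, c)); seen[r, c] <- TRUE; size <- 0
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- cur[1] + dr; c2 <- cur[2] + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (seen[r2, c2] || is.na(lv[r2, c2]) || lv[r2, c2] != g) next
        seen[r2, c2] <- TRUE
        queue[[length(queue) + 1]] <- c(r2, c2)
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  maxsize <- max(1, vapply(zones, `[`, numeric(1), 2))
  out <- matrix(0, ng, maxsize)
  for (z in zones) out[z[1], z[2]] <- out[z[1], z[2]] + 1
  out
}

bf_gldm <- function(lv, ng) {
  nr <- nrow(lv); nc <- ncol(lv)
  out <- matrix(0, ng, 9)
  for (r in 1:nr) for (c in 1:nc) {
    if (is.na(lv[r, c])) next
    dep <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!is.na(lv[r2, c2]) && lv[r2, c2] == lv[r, c]) dep <- dep + 1
    }
    out[lv[r, c], dep + 1] <- out[lv[r, c], dep + 1] + 1
  }
  out
}

# naive GLCM features by direct double loops over the normalised matrix
naive_glcm_features <- function(P, ng) {
  N <- sum(P)
  if (N == 0) {
    out <- rep(0, 22)
    names(out) <- qusradiomics::texture_feature_catalog("glcm")
    return(out)
  }
  p <- P / N
  px <- rowSums(p); py <- colSums(p)
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sigx <- sqrt(sum((1:ng - mux)^2 * px)); sigy <- sqrt(sum((1:ng - muy)^2 * py))
  psum <- numeric(2 * ng); pdiff <- numeric(ng)
  ac <- 0; contrast <- 0; id <- 0; idm <- 0; idmn <- 0; idn <- 0; iv <- 0
  je <- 0; jent <- 0; cp <- 0; cs <- 0; ct <- 0; ss <- 0
  hxy1 <- 0; hxy2terms <- 0
  for (i in 1:ng) for (j in 1:ng) {
    pij <- p[i, j]
    psum[i + j] <- psum[i + j] + pij
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + pij
    ac <- ac + pij * i * j
    contrast <- contrast + pij * (i - j)^2
    id <- id + pij / (1 + abs(i - j))
    idm <- idm + pij / (1 + (i - j)^2)
    idmn <- idmn + pij / (1 + (i - j)^2 / ng^2)
    idn <- idn + pij / (1 + abs(i - j) / ng)
    if (i != j) iv <- iv + pij / (i - j)^2
    je <- je + pij^2
    if (pij > 0) jent <- jent - pij * log2(pij)
    cp <- cp + pij * (i + j - mux - muy)^4
    cs <- cs + pij * (i + j - mux - muy)^3
    ct <- ct + pij * (i + j - mux - muy)^2
    ss <- ss + pij * (i - mux)^2
    if (px[i] * py[j] > 0) {
      if (pij > 0) hxy1 <- hxy1 - pij * log2(px[i] * py[j])
      hxy2terms <- hxy2terms - px[i] * py[j] * log2(px[i] * py[j])
    }
  }
  da <- sum((0:(ng - 1)) * pdiff)
  dent <- -sum(pdiff[pdiff > 0] * log2(pdiff[pdiff > 0]))
  dvar <- sum(((0:(ng - 1)) - da)^2 * pdiff)
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  sent <- -sum(psum[psum > 0] * log2(psum[psum > 0]))
  corr <- if (sigx * sigy > 0) (ac - mux * muy) / (sigx * sigy) else 1
  imc1 <- if (max(hx, hy) > 0) (jent - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2terms - jent))))
  c(Autocorrelation = ac, ClusterProminence = cp, ClusterShade = cs,
    ClusterTendency = ct, Contrast = contrast, Correlation = corr,
    DifferenceAverage = da, DifferenceEntropy = dent,
    DifferenceVariance = dvar, Id = id, Idm = idm, Idmn = idmn, Idn = idn,
    Imc1 = imc1, Imc2 = imc2, InverseVariance = iv, JointAverage = mux,
    JointEnergy = je, JointEntropy = jent,
    MaximumProbability = max(p), SumEntropy = sent, SumSquares = ss)
}

# naive level x size family features (GLRLM / GLSZM / GLDM share structure)
naive_lvsize_features <- function(P, ng, np, family) {
  maxj <- ncol(P)
  N <- sum(P)
  e <- function(w_fun) {
    if (N == 0) return(0)
    s <- 0
    for (i in 1:ng) for (j in 1:maxj) s <- s + P[i, j] * w_fun(i, j)
    s / N
  }
  rm_ <- rowSums(P); cm_ <- colSums(P)
  gln <- if (N > 0) sum(rm_^2) / N else 0
  glnn <- if (N > 0) sum(rm_^2) / N^2 else 0
  jn <- if (N > 0) sum(cm_^2) / N else 0
  jnn <- if (N > 0) sum(cm_^2) / N^2 else 0
  pg <- if (N > 0) rm_ / N else rm_
  pj <- if (N > 0) cm_ / N else cm_
  mug <- sum((1:ng) * pg); muj <- sum((1:maxj) * pj)
  glv <- sum(((1:ng) - mug)^2 * pg)
  jvar <- sum(((1:maxj) - muj)^2 * pj)
  p <- if (N > 0) P / N else P
  ent <- -sum(p[p > 0] * log2(p[p > 0]))
  pct <- if (np > 0) N / np else 0
  if (family == "glrlm")
    c(GrayLevelNonUniformity = gln, GrayLevelNonUniformityNormalized = glnn,
      GrayLevelVariance = glv,
      HighGrayLevelRunEmphasis = e(function(i, j) i^2),
      LongRunEmphasis = e(function(i, j) j^2),
      LongRunHighGrayLevelEmphasis = e(function(i, j) i^2 * j^2),
      LongRunLowGrayLevelEmphasis = e(function(i, j) j^2 / i^2),
      LowGrayLevelRunEmphasis = e(function(i, j) 1 / i^2),
      RunEntropy = ent, RunLengthNonUniformity = jn,
      RunLengthNonUniformityNormalized = jnn, RunPercentage = pct,
      RunVariance = jvar, ShortRunEmphasis = e(function(i, j) 1 / j^2),
      ShortRunHighGrayLevelEmphasis = e(function(i, j) i^2 / j^2),
      ShortRunLowGrayLevelEmphasis = e(function(i, j) 1 / (i^2 * j^2)))
  else if (family == "glszm")
    c(GrayLevelNonUniformity = gln, GrayLevelNonUniformityNormalized = glnn,
      GrayLevelVariance = glv,
      HighGrayLevelZoneEmphasis = e(function(i, j) i^2),
      LargeAreaEmphasis = e(function(i, j) j^2),
      LargeAreaHighGrayLevelEmphasis = e(function(i, j) i^2 * j^2),
      LargeAreaLowGrayLevelEmphasis = e(function(i, j) j^2 / i^2),
      LowGrayLevelZoneEmphasis = e(function(i, j) 1 / i^2),
      SizeZoneNonUniformity = jn, SizeZoneNonUniformityNormalized = jnn,
      SmallAreaEmphasis = e(function(i, j) 1 / j^2),
      SmallAreaHighGrayLevelEmphasis = e(function(i, j) i^2 / j^2),
      SmallAreaLowGrayLevelEmphasis = e(function(i, j) 1 / (i^2 * j^2)),
      ZoneEntropy = ent, ZonePercentage = pct, ZoneVariance = jvar)
  else
    c(DependenceEntropy = ent, DependenceNonUniformity = jn,
      DependenceNonUniformityNormalized = jnn, DependenceVariance = jvar,
      GrayLevelNonUniformity = gln, GrayLevelVariance = glv,
      HighGrayLevelEmphasis = e(function(i, j) i^2),
      LargeDependenceEmphasis = e(function(i, j) j^2),
      LargeDependenceHighGrayLevelEmphasis = e(function(i, j) i^2 * j^2),
      LargeDependenceLowGrayLevelEmphasis = e(function(i, j) j^2 / i^2),
      LowGrayLevelEmphasis = e(function(i, j) 1 / i^2),
      SmallDependenceEmphasis = e(function(i, j) 1 / j^2),
      SmallDependenceHighGrayLevelEmphasis = e(function(i, j) i^2 / j^2),
      SmallDependenceLowGrayLevelEmphasis = e(function(i, j) 1 / (i^2 * j^2)))
}

# full 68-feature naive vector matching compute_texture_features() keys
naive_texture_features <- function(lv, ng) {
  np <- sum(!is.na(lv))
  f <- c()
  g <- naive_glcm_features(bf_glcm(lv, ng), ng)
  names(g) <- paste0("glcm_", names(g))
  d <- naive_lvsize_features(bf_gldm(lv, ng), ng, np, "gldm")
  names(d) <- paste0("gldm_", names(d))
  r <- naive_lvsize_features(bf_glrlm(lv, ng), ng, np, "glrlm")
  names(r) <- paste0("glrlm_", names(r))
  s <- naive_lvsize_features(bf_glszm(lv, ng), ng, np, "glszm")
  names(s) <- paste0("glszm_", names(s))
  c(g, d, r, s)
}

# random gray image with optional invalid pixels
random_gray_image <- function(nr, nc, ng, p_na = 0) {
  lv <- matrix(sample.int(ng, nr * nc, replace = TRUE), nr, nc)
  if (p_na > 0) lv[runif(nr * nc) < p_na] <- NA_integer_
  lv
}

# wrap a plain level matrix as the package's gray_image class
as_gray_image <- function(lv, ng) {
  structure(list(levels = lv, ng = as.integer(ng),
                 provenance = list(parameter_id = "test", rule = "direct")),
            class = "gray_image")
}

# small helper: parametric map from a matrix
pm_from_matrix <- function(m, id = "MBF") {
  qusradiomics::parametric_map(id, m, is.finite(m))
}
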