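#' Specification of one texture-of-texture (TOT) map
#'
#' @param source_parameter one of the 7 QUS map ids.
#' @param feature_id a catalog feature, `"<family>_<Feature>"`, e.g.
#'   `"glszm_SmallAreaLowGrayLevelEmphasis"`.
#' @param window odd window size in pixels (default 3).
#' @param ng gray levels for the (global) discretization of the source map.
#' @return list of class `tot_map_spec`.
#' @export
tot_map_spec <- function(source_parameter, feature_id, window = 3L,
                         ng = 16L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be odd and >= 3")
  fam <- sub("_.*$", "", feature_id)
  feat <- sub("^[a-z]+_", "", feature_id)
  if (!fam %in% c("glcm", "glrlm", "glszm", "gldm") ||
      !feat %in% texture_feature_catalog(fam))
    stop("unknown feature id: ", feature_id)
  structure(list(source_parameter = source_parameter,
                 feature_id = feature_id, family = fam, feature = feat,
                 window = window, ng = as.integer(ng)),
            class = "tot_map_spec")
}

.family_code <- c(glcm = 1L, glrlm = 2L, glszm = 3L, gldm = 4L)

#' Build a texture-of-texture parametric map
#'
#' The source map is discretized once globally (so all patches share one
#' gray scale); for every pixel whose full `window x window` neighbourhood
#' is valid, the single named texture feature is evaluated on that patch's
#' matrix and assigned to the centre pixel. With `window` covering the whole
#' ROI the operator degenerates to the ordinary scalar feature (single-pixel
#' map).
#'
#' @param qus_map a `parametric_map`.
#' @param spec a [tot_map_spec()].
#' @return a `parametric_map` whose `parameter_id` is
#'   `"<source>_<feature_id>"`.
#' @export
build_tot_map <- function(qus_map, spec) {
  stopifnot(inherits(spec, "tot_map_spec"))
  g <- discretize(qus_map, spec$ng)
  pm <- .cpp_patch_matrices(g$levels, spec$ng,
                            .family_code[[spec$family]], spec$window)
  if (length(pm$center_row) == 0)
    stop("ROI too small for TOT: no full ", spec$window, "x", spec$window,
         " valid neighbourhood")
  feats <- .family_features_multi(spec$family, pm$counts, pm$ng, pm$maxj,
                                  pm$n_valid)
  fv <- feats[, spec$feature]
  vals <- matrix(NA_real_, nrow(g$levels), ncol(g$levels))
  vals[cbind(pm$center_row, pm$center_col)] <- fv
  parametric_map(paste0(spec$source_parameter, "_", spec$feature_id),
                 vals, is.finite(vals), qus_map$pixel_spacing_mm,
                 units = "a.u.")
}

#' Extract the TOT feature set of one TOT map
#'
#' First-order features plus the full four-family texture catalog computed
#' on the TOT map itself (with its own fresh min--max discretization):
#' 17 + 68 = 85 features per map by default.
#'
#' @param tot_map a `parametric_map` from [build_tot_map()].
#' @param ng gray levels for the TOT map's discretization.
#' @param include_first_order include the 17 first-order features.
#' @param include_texture include the 68 texture features.
#' @return named numeric vector; names are prefixed with the TOT map's
#'   `parameter_id`.
#' @export
extract_tot_features <- function(tot_map, ng = 16L,
                                 include_first_order = TRUE,
                                 include_texture = TRUE) {
  out <- numeric(0)
  if (include_first_order) out <- c(out, first_order_features(tot_map))
  if (include_texture) {
    g <- discretize(tot_map, ng)
    out <- c(out, compute_texture_features(compute_matrices(g)))
  }
  if (length(out)) names(out) <- paste0(tot_map$parameter_id, "_", names(out))
  out
}

#' Preset base-5 feature lists for TOT map construction
#'
#' The five texture features that generate the TOT maps, as identified by
#' 5-feature multivariable models for each classifier.
#'
#' @param which `"svm"` or `"knn"`.
#' @return character vector of 5 feature column names.
#' @export
preset_base5 <- function(which = c("svm", "knn")) {
  which <- match.arg(which)
  if (which == "svm")
    c("ASD_anderson_glszm_ZoneEntropy",
      "SI_gldm_SmallDependenceLowGrayLevelEmphasis",
      "SS_gldm_SmallDependenceHighGrayLevelEmphasis",
      "AAC_gaussian_gldm_DependenceVariance",
      "AAC_anderson_gldm_SmallDependenceEmphasis")
  else
    c("ASD_anderson_glszm_ZoneEntropy",
      "ASD_anderson_glrlm_LongRunLowGrayLevelEmphasis",
      "ASD_anderson_glszm_LargeAreaLowGrayLevelEmphasis",
      "ASD_gaussian_gldm_LowGrayLevelEmphasis",
      "SS_glszm_SmallAreaLowGrayLevelEmphasis")
}

# split "MAP_family_Feature" into source map id and feature id
.parse_feature_column <- function(col) {
  m <- regmatches(col, regexec(
    "^(.*)_(glcm|glrlm|glszm|gldm)_([A-Za-z0-9]+)$", col))[[1]]
  if (length(m) != 4) stop("cannot parse feature column: ", col)
  list(map = m[2], feature_id = paste0(m[3], "_", m[4]))
}

#' Assemble the enhanced (base-5 + TOT) dataset
#'
#' For every frame in the cohort, builds the five TOT maps named by `base5`,
#' extracts the per-map TOT feature set, averages across each patient's
#' frames, and concatenates with the (pass-through) base-5 columns of the
#' stage-1 dataset. Frames whose TOT construction fails are dropped from
#' that patient's average with a message.
#'
#' @param stage1 the stage-1 `cohort_dataset` from [assemble_dataset()].
#' @param cohort the `synthetic_cohort` the stage-1 dataset came from.
#' @param base5 character vector of 5 stage-1 feature columns (see
#'   [preset_base5()]).
#' @param ng gray levels; `window` TOT window size.
#' @param window TOT sliding-window size (odd, >= 3).
#' @param include_first_order,include_texture per-map TOT catalog switches;
#'   both `FALSE` empties the TOT catalog and reduces the dataset to the
#'   base-5 columns exactly.
#' @return a `cohort_dataset` with `5 + 5 * catalog_size` feature columns.
#' @export
assemble_tot_dataset <- function(stage1, cohort, base5 = preset_base5("svm"),
                                 ng = 16L, window = 3L,
                                 include_first_order = TRUE,
                                 include_texture = TRUE) {
  stopifnot(all(base5 %in% colnames(stage1)))
  specs <- lapply(base5, function(col) {
    pf <- .parse_feature_column(col)
    tot_map_spec(pf$map, pf$feature_id, window, ng)
  })
  pids <- stage1$patient_id
  tot_rows <- list()
  if (include_first_order || include_texture) {
    for (pid in pids) {
      fr <- cohort$frames[cohort$manifest$patient_id == pid]
      feats <- lapply(fr, function(f) {
        tryCatch({
          unlist(lapply(specs, function(sp) {
            tm <- build_tot_map(f$maps[[sp$source_parameter]], sp)
            extract_tot_features(tm, ng, include_first_order,
                                 include_texture)
          }))
        }, error = function(e) {
          message("TOT failed for ", pid, " frame: ", conditionMessage(e))
          NULL
        })
      })
      feats <- feats[!vapply(feats, is.null, logical(1))]
      if (!length(feats)) stop("patient ", pid, " has no valid TOT frames")
      tot_rows[[pid]] <- colMeans(do.call(rbind, feats))
    }
    tot_mat <- do.call(rbind, tot_rows[as.character(pids)])
  } else tot_mat <- NULL
  base_mat <- as.matrix(stage1[, base5, drop = FALSE])
  all_names <- c(colnames(base_mat), colnames(tot_mat))
  if (anyDuplicated(all_names))
    stop("duplicate feature names in enhanced dataset: ",
         paste(unique(all_names[duplicated(all_names)]), collapse = ", "))
  df <- data.frame(patient_id = stage1$patient_id, label = stage1$label,
                   base_mat, check.names = FALSE, row.names = NULL)
  if (!is.null(tot_mat)) df <- cbind(df, as.data.frame(tot_mat,
                                                       check.names = FALSE))
  stopifnot(!anyNA(df))
  class(df) <- c("cohort_dataset", class(df))
  df
}
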