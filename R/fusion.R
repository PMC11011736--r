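#' Specify one crater-spectrum fusion model
#'
#' A fusion spec names which crater parameters and which emission lines enter
#' the feature matrix, which spectral correction is applied before line
#' extraction, and which regression model is fitted.
#'
#' @param lines List of [emission_line]s (named) whose peak intensities are
#'   used. Default: the three Cd lines.
#' @param crater_vars Character vector of crater parameter names, the
#'   sentinel `"stepwise"` (resolve by backward stepwise MLR on the
#'   calibration data, the default), or `NULL` for no crater features.
#' @param correction Spectral pretreatment before extraction: `"none"`,
#'   `"baseline"` (AsLS), `"normalization"` (total area) or `"cprc"`.
#' @param model_kind `"curve"`, `"mlr"`, `"plsr"`, `"lssvm"` or `"rf"`.
#'   A curve model requires exactly one line and no crater variables.
#' @param label Optional human-readable label for reports.
#' @return Object of class `fusion_spec`.
#' @export
fusion_spec <- function(lines = cd_lines(),
                        crater_vars = "stepwise",
                        correction = c("none", "baseline", "normalization",
                                       "cprc"),
                        model_kind = c("curve", "mlr", "plsr", "lssvm", "rf"),
                        label = NULL) {
  correction <- match.arg(correction)
  model_kind <- match.arg(model_kind)
  if (inherits(lines, "emission_line")) lines <- list(lines)
  if (is.null(names(lines)))
    names(lines) <- vapply(lines, function(l)
      sprintf("%s_%s_%.2f", l$element, l$stage, l$wavelength), "")
  if (!is.null(crater_vars) && !identical(crater_vars, "stepwise")) {
    bad <- setdiff(crater_vars, crater_parameters())
    if (length(bad))
      stop("unknown crater parameter(s): ", paste(bad, collapse = ", "))
  }
  if (model_kind == "curve" &&
      (length(lines) != 1L || !is.null(crater_vars)))
    stop("a calibration curve takes exactly one line and no crater variables")
  if (is.null(label))
    label <- paste0(model_kind, " / ", correction, " / ",
                    paste(names(lines), collapse = "+"),
                    if (!is.null(crater_vars)) " + craters" else "")
  structure(list(lines = lines, crater_vars = crater_vars,
                 correction = correction, model_kind = model_kind,
                 label = label),
            class = "fusion_spec")
}

#' Resolve the stepwise-retained crater parameters on a calibration set
#'
#' Runs backward stepwise MLR on the nine crater parameters plus the raw
#' intensities of the given emission lines (the raw signal is not
#' preprocessed at this stage) and returns the crater parameters that
#' survive.
#'
#' @param ds Calibration [calibration_dataset] (must carry craters).
#' @param lines Emission lines whose raw intensities join the regression.
#' @param alpha Stepwise significance level. Default 0.05.
#' @return List with `crater_vars` (character) and the full
#'   `stepwise_result`.
#' @export
resolve_crater_vars <- function(ds, lines = cd_lines(), alpha = 0.05) {
  if (is.null(ds$craters)) stop("dataset carries no crater table")
  feats <- cbind(as.matrix(ds$craters[, crater_parameters()]),
                 extract_lines(ds$spectra, lines))
  sw <- stepwise_backward(feats, ds$references, alpha = alpha)
  list(crater_vars = intersect(sw$retained, crater_parameters()),
       stepwise = sw)
}

#' Build the fused feature matrix for a dataset
#'
#' Columns are the chosen crater parameters followed by one peak intensity
#' per emission line, extracted after the spec's correction. With
#' `correction = "cprc"` a fitted per-line `cprc_model` map must be supplied
#' (fit it on calibration data only). The sentinel `crater_vars =
#' "stepwise"` is resolved on `ds` itself — only do that on calibration
#' data; [run_grid()] handles the split correctly.
#'
#' @param ds A [calibration_dataset].
#' @param spec A [fusion_spec].
#' @param cprc_models Named list of `cprc_model`s keyed like `spec$lines`
#'   (required when `spec$correction == "cprc"`).
#' @return n x k named feature matrix.
#' @export
build_features <- function(ds, spec, cprc_models = NULL) {
  stopifnot(inherits(ds, "calibration_dataset"), inherits(spec, "fusion_spec"))
  crater_vars <- spec$crater_vars
  if (identical(crater_vars, "stepwise"))
    crater_vars <- resolve_crater_vars(ds, spec$lines)$crater_vars
  craterM <- NULL
  if (!is.null(crater_vars) && length(crater_vars)) {
    if (is.null(ds$craters)) stop("spec requests crater variables but the ",
                                  "dataset carries no crater table")
    craterM <- as.matrix(ds$craters[, crater_vars, drop = FALSE])
    rownames(craterM) <- ds$spectra$sample_ids
  }
  ss <- switch(spec$correction,
    none = ds$spectra,
    baseline = baseline_correct_set(ds$spectra),
    normalization = area_normalize_set(ds$spectra),
    cprc = ds$spectra)   # per-line correction handled below
  if (spec$correction == "cprc") {
    if (is.null(cprc_models))
      stop("correction = 'cprc' requires fitted cprc_models")
    miss <- setdiff(names(spec$lines), names(cprc_models))
    if (length(miss))
      stop("missing CPRC model(s) for line(s): ", paste(miss, collapse = ", "))
    cols <- lapply(names(spec$lines), function(nm)
      corrected_peak(cprc_models[[nm]], ds$spectra)$intensity)
    lineM <- do.call(cbind, cols)
    dimnames(lineM) <- list(ds$spectra$sample_ids, names(spec$lines))
  } else {
    lineM <- extract_lines(ss, spec$lines)
  }
  cbind(craterM, lineM)
}

#' Run a grid of fusion specs over a calibration/prediction split
#'
#' Splits the dataset by group, fits every requested spec on the calibration
#' subset and evaluates on the prediction subset. All data-dependent fitting
#' — CPRC matrix-variable selection, stepwise crater retention,
#' hyperparameter cross-validation — sees calibration samples only.
#'
#' @param ds A [calibration_dataset].
#' @param specs List of [fusion_spec]s.
#' @param calibration_groups,prediction_groups Group labels for the split.
#' @param seed Seed fanned out to CPRC CV, model CV and RF.
#' @param alpha Stepwise significance level for `"stepwise"` crater vars.
#' @param cprc_max_m,cprc_folds Passed to [fit_cprc()].
#' @return List with `report` (one data.frame row per spec: Model,
#'   Variables, Rc2, RMSEC, Rp2, RMSEP, LOD, LOQ), `models`, `cprc_models`,
#'   `stepwise`, and the `split`.
#' @export
run_grid <- function(ds, specs,
                     calibration_groups = c("Group1", "Group2", "Group3"),
                     prediction_groups = "Group4",
                     seed = 1L, alpha = 0.05,
                     cprc_max_m = 10L, cprc_folds = 10L) {
  if (!length(specs)) {
    return(list(report = data.frame(), models = list(),
                cprc_models = list(), stepwise = NULL, split = NULL))
  }
  split <- split_by_group(ds, calibration_groups, prediction_groups)
  cal <- split$calibration; pred <- split$prediction
  y_cal <- cal$references$values
  y_pred <- pred$references$values

  # fit shared calibration-only artifacts once
  need_cprc <- unique(unlist(lapply(specs, function(s)
    if (s$correction == "cprc") names(s$lines) else character())))
  all_lines <- list()
  for (s in specs) all_lines[names(s$lines)] <- s$lines
  cprc_models <- list()
  for (nm in need_cprc)
    cprc_models[[nm]] <- fit_cprc(cal$spectra, cal$references,
                                  all_lines[[nm]], max_m = cprc_max_m,
                                  folds = cprc_folds, seed = seed)
  needs_sw <- any(vapply(specs, function(s)
    identical(s$crater_vars, "stepwise"), TRUE))
  sw <- if (needs_sw) resolve_crater_vars(cal, cd_lines(), alpha) else NULL

  rows <- list(); models <- list()
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    if (identical(s$crater_vars, "stepwise")) s$crater_vars <- sw$crater_vars
    Fc <- build_features(cal, s, cprc_models)
    Fp <- build_features(pred, s, cprc_models)
    model <- switch(s$model_kind,
      curve = fit_curve(Fc[, 1L], y_cal),
      mlr   = fit_mlr(Fc, y_cal),
      plsr  = fit_plsr(Fc, y_cal, seed = seed),
      lssvm = fit_lssvm(Fc, y_cal, seed = seed),
      rf    = fit_rf(Fc, y_cal, seed = seed))
    rep_i <- evaluate(model,
                      cal = list(features = Fc, y = y_cal),
                      pred = list(features = Fp, y = y_pred))
    rows[[i]] <- data.frame(Model = s$model_kind,
                            Variables = s$label,
                            Rc2 = rep_i$Rc2, RMSEC = rep_i$RMSEC,
                            Rp2 = rep_i$Rp2, RMSEP = rep_i$RMSEP,
                            LOD = rep_i$LOD, LOQ = rep_i$LOQ,
                            stringsAsFactors = FALSE)
    models[[s$label]] <- model
  }
  list(report = do.call(rbind, rows), models = models,
       cprc_models = cprc_models, stepwise = sw, split = split)
}
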