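#' Emission line descriptor
#'
#' A single atomic emission line, identified by element, ionization stage and
#' nominal wavelength. Wavelengths follow the NIST atomic spectra database
#' convention (nm, air).
#'
#' @param element Element symbol, e.g. `"Cd"`.
#' @param stage Ionization stage, `"I"` (neutral) or `"II"` (singly ionized).
#' @param wavelength Nominal wavelength in nm.
#' @return An object of class `emission_line`.
#' @examples
#' emission_line("Cd", "I", 228.80)
#' @export
emission_line <- function(element, stage = c("I", "II"), wavelength) {
  stage <- match.arg(stage)
  stopifnot(is.character(element), length(element) == 1L,
            is.numeric(wavelength), length(wavelength) == 1L,
            is.finite(wavelength), wavelength > 0)
  structure(list(element = element, stage = stage, wavelength = wavelength),
            class = "emission_line")
}

#' @export
format.emission_line <- function(x, ...) {
  sprintf("%s %s %.2f nm", x$element, x$stage, x$wavelength)
}

#' @export
print.emission_line <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' The three cadmium analytical lines
#'
#' Cd II 214.44 nm, Cd II 226.50 nm and Cd I 228.80 nm, the emission lines
#' conventionally used for Cd quantification in the 210-231 nm window.
#' Note that Cd II 226.50 nm suffers spectral interference from Fe II
#' 226.48 nm / Fe I 226.50 nm in plant matrices.
#'
#' @return A named list of three [emission_line] objects
#'   (`"Cd_II_214.44"`, `"Cd_II_226.50"`, `"Cd_I_228.80"`).
#' @export
cd_lines <- function() {
  list(
    "Cd_II_214.44" = emission_line("Cd", "II", 214.44),
    "Cd_II_226.50" = emission_line("Cd", "II", 226.50),
    "Cd_I_228.80"  = emission_line("Cd", "I", 228.80)
  )
}

#' Canonical crater morphology parameter names
#'
#' The nine parameters reported by shape-measurement laser microscopy of
#' ablation craters: volume (um^3), cross-sectional area and surface
#' area (um^2), average and maximum depth (um), perimeter, horizontal and
#' vertical Feret's diameters and circle-equivalent diameter (um).
#'
#' @return Character vector of the nine column names.
#' @export
crater_parameters <- function() {
  c("volume", "cross_sectional_area", "surface_area",
    "average_depth", "maximum_depth", "perimeter",
    "horizontal_feret", "vertical_feret", "circle_equivalent_diameter")
}

#' Construct a set of LIBS spectra on a shared wavelength axis
#'
#' @param X n x p numeric intensity matrix (arbitrary counts), one row per
#'   sample.
#' @param wavelengths Length-p strictly ascending wavelength axis in nm.
#' @param sample_ids Length-n character vector of unique sample identifiers.
#' @return An object of class `spectrum_set` with fields `X`, `wavelengths`,
#'   `sample_ids`.
#' @export
spectrum_set <- function(X, wavelengths, sample_ids = rownames(X)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(X)))
  sample_ids <- as.character(sample_ids)
  if (nrow(X) < 1L || ncol(X) < 2L)
    stop("spectrum_set requires n >= 1 samples and p >= 2 wavelengths")
  if (length(wavelengths) != ncol(X))
    stop("wavelength axis length (", length(wavelengths),
         ") does not match ncol(X) (", ncol(X), ")")
  if (any(!is.finite(wavelengths)) || any(diff(wavelengths) <= 0))
    stop("wavelengths must be finite and strictly ascending")
  if (any(!is.finite(X)))
    stop("all intensities must be finite")
  if (length(sample_ids) != nrow(X) || anyDuplicated(sample_ids))
    stop("sample_ids must be unique and match nrow(X)")
  dimnames(X) <- list(sample_ids, NULL)
  structure(list(X = X, wavelengths = as.numeric(wavelengths),
                 sample_ids = sample_ids),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("spectrum_set: %d spectra x %d wavelengths (%.2f-%.2f nm)\n",
              nrow(x$X), ncol(x$X), min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.spectrum_set <- function(x) dim(x$X)

#' Subset a spectrum_set by sample
#'
#' @param x A [spectrum_set].
#' @param i Row (sample) index or sample_id vector.
#' @param ... Unused.
#' @return A `spectrum_set` with the selected samples.
#' @export
`[.spectrum_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$sample_ids)
  if (anyNA(i)) stop("unknown sample_id in spectrum_set subset")
  spectrum_set(x$X[i, , drop = FALSE], x$wavelengths, x$sample_ids[i])
}

#' Reference concentrations aligned to a spectrum set
#'
#' @param values Length-n non-negative Cd concentrations in ug/g (e.g. from
#'   ICP-MS digestion of the same tablets).
#' @param sample_ids Length-n sample identifiers, aligned to the paired
#'   [spectrum_set].
#' @return Object of class `reference_values`.
#' @export
reference_values <- function(values, sample_ids) {
  values <- as.numeric(values)
  sample_ids <- as.character(sample_ids)
  if (length(values) != length(sample_ids))
    stop("values and sample_ids must have equal length")
  if (any(!is.finite(values)) || any(values < 0))
    stop("reference values must be finite and >= 0")
  if (anyDuplicated(sample_ids)) stop("duplicate sample_ids in references")
  structure(list(values = values, sample_ids = sample_ids),
            class = "reference_values")
}

#' @export
print.reference_values <- function(x, ...) {
  cat(sprintf("reference_values: n=%d, range %.2f-%.2f ug/g\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Validate a crater morphology table
#'
#' One row per ablation site; columns `sample_id` plus the nine parameters of
#' [crater_parameters()]. All values must be positive and
#' `maximum_depth >= average_depth`.
#'
#' @param craters data.frame of crater measurements.
#' @return The validated data.frame (invisibly unchanged).
#' @export
validate_craters <- function(craters) {
  need <- c("sample_id", crater_parameters())
  miss <- setdiff(need, names(craters))
  if (length(miss))
    stop("crater table is missing columns: ", paste(miss, collapse = ", "))
  vals <- as.matrix(craters[, crater_parameters()])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all nine crater parameters must be finite and > 0")
  bad <- craters$maximum_depth < craters$average_depth
  if (any(bad))
    stop("maximum_depth < average_depth for sample(s): ",
         paste(craters$sample_id[bad], collapse = ", "))
  craters
}

#' Assemble an aligned calibration dataset
#'
#' Binds spectra, crater morphology, reference concentrations and design
#' labels (brand, replicate group) into one object. Alignment is by explicit
#' `sample_id`: components whose ids disagree in content or order are
#' rejected rather than silently reordered.
#'
#' @param spectra A [spectrum_set].
#' @param craters Crater table (see [validate_craters()]), or `NULL`.
#' @param references A [reference_values].
#' @param brand Length-n character brand labels.
#' @param group Length-n labels assigning each sample to a replicate group
#'   (e.g. `"Group1"`..`"Group4"`), used for calibration/prediction splits.
#' @param level Optional length-n nominal spike levels in ug/g.
#' @return Object of class `calibration_dataset`.
#' @export
calibration_dataset <- function(spectra, craters, references, brand, group,
                                level = NULL) {
  stopifnot(inherits(spectra, "spectrum_set"),
            inherits(references, "reference_values"))
  ids <- spectra$sample_ids
  if (!identical(ids, references$sample_ids))
    stop("sample_id mismatch between spectra and references")
  if (!is.null(craters)) {
    craters <- validate_craters(craters)
    if (!identical(as.character(craters$sample_id), ids))
      stop("sample_id mismatch between spectra and craters")
  }
  brand <- as.character(brand); group <- as.character(group)
  if (length(brand) != length(ids) || length(group) != length(ids))
    stop("brand and group labels must have one entry per sample")
  if (!is.null(level) && length(level) != length(ids))
    stop("level must have one entry per sample")
  structure(list(spectra = spectra, craters = craters,
                 references = references, brand = brand, group = group,
                 level = level),
            class = "calibration_dataset")
}

#' @export
print.calibration_dataset <- function(x, ...) {
  cat(sprintf(
    "calibration_dataset: %d samples, %d brands, groups {%s}%s\n",
    length(x$spectra$sample_ids), length(unique(x$brand)),
    paste(sort(unique(x$group)), collapse = ","),
    if (is.null(x$craters)) ", no craters" else ""))
  invisible(x)
}

#' Number of samples in a calibration dataset
#' @param ds A [calibration_dataset].
#' @return Integer sample count.
#' @export
n_samples <- function(ds) length(ds$spectra$sample_ids)

#' Subset a calibration dataset by sample index
#'
#' @param ds A [calibration_dataset].
#' @param idx Integer or logical sample index.
#' @return A `calibration_dataset` restricted to the selected samples.
#' @export
subset_dataset <- function(ds, idx) {
  if (is.logical(idx)) idx <- which(idx)
  out <- calibration_dataset(
    spectra = ds$spectra[idx],
    craters = if (is.null(ds$craters)) NULL else ds$craters[idx, , drop = FALSE],
    references = reference_values(ds$references$values[idx],
                                  ds$references$sample_ids[idx]),
    brand = ds$brand[idx], group = ds$group[idx],
    level = if (is.null(ds$level)) NULL else ds$level[idx])
  # generator-side extras, when present
  if (!is.null(ds$truth)) out$truth <- ds$truth[idx]
  if (!is.null(ds$ablation_factor))
    out$ablation_factor <- ds$ablation_factor[idx]
  out
}

#' Split a dataset into calibration and prediction subsets by group label
#'
#' The replicate groups partition the samples; typical usage assigns three
#' groups to calibration and holds the fourth out for prediction, so that
#' within every brand each concentration level appears in both subsets.
#'
#' @param ds A [calibration_dataset].
#' @param calibration_groups Character vector of group labels for the
#'   calibration set.
#' @param prediction_groups Character vector of group labels for the
#'   prediction set.
#' @return A list with elements `calibration` and `prediction`, both
#'   `calibration_dataset`s, disjoint and jointly covering the requested
#'   groups.
#' @export
split_by_group <- function(ds, calibration_groups, prediction_groups) {
  all_groups <- unique(ds$group)
  req <- c(calibration_groups, prediction_groups)
  unknown <- setdiff(req, all_groups)
  if (length(unknown))
    stop("unknown group label(s): ", paste(unknown, collapse = ", "))
  if (length(intersect(calibration_groups, prediction_groups)))
    stop("calibration and prediction groups overlap")
  if (length(calibration_groups) == 0L || length(prediction_groups) == 0L)
    stop("both splits must receive at least one group")
  cal_idx <- ds$group %in% calibration_groups
  pred_idx <- ds$group %in% prediction_groups
  if (!any(cal_idx) || !any(pred_idx))
    stop("degenerate split: one side is empty")
  list(calibration = subset_dataset(ds, cal_idx),
       prediction = subset_dataset(ds, pred_idx))
}

#' Read LIBS spectra from CSV
#'
#' Two dialects are supported. `wide`: first column is the wavelength in nm,
#' every further column is one sample (header = sample_id). `long`: columns
#' `sample_id`, `wavelength_nm`, `intensity`; every sample must carry the
#' identical wavelength set.
#'
#' @param path CSV file path.
#' @param layout `"wide"` or `"long"`.
#' @return A [spectrum_set]; wavelengths sorted ascending.
#' @export
read_spectra <- function(path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("spectra file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (layout == "wide") {
    wl <- suppressWarnings(as.numeric(df[[1L]]))
    if (anyNA(wl)) stop("non-numeric wavelength cell in ", path)
    if (ncol(df) < 2L) stop("wide spectra CSV needs at least one sample column")
    M <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(M) <- "double"
    if (anyNA(M)) stop("non-numeric or missing intensity cell in ", path)
    if (anyDuplicated(wl)) stop("duplicate wavelengths in ", path)
    o <- order(wl)
    spectrum_set(t(M[o, , drop = FALSE]), wl[o], colnames(df)[-1L])
  } else {
    need <- c("sample_id", "wavelength_nm", "intensity")
    if (!all(need %in% names(df)))
      stop("long spectra CSV needs columns: ", paste(need, collapse = ", "))
    wl_num <- suppressWarnings(as.numeric(df$wavelength_nm))
    int_num <- suppressWarnings(as.numeric(df$intensity))
    if (anyNA(wl_num) || anyNA(int_num))
      stop("non-numeric cell in ", path)
    ids <- unique(as.character(df$sample_id))
    wl <- sort(unique(wl_num))
    X <- matrix(NA_real_, length(ids), length(wl),
                dimnames = list(ids, NULL))
    pos <- cbind(match(as.character(df$sample_id), ids), match(wl_num, wl))
    if (anyDuplicated(pos))
      stop("duplicate (sample_id, wavelength) rows in ", path)
    X[pos] <- int_num
    if (anyNA(X))
      stop("ragged wavelength axes across samples in ", path,
           ": every sample must cover the same wavelengths")
    spectrum_set(X, wl, ids)
  }
}

#' Write LIBS spectra to CSV
#'
#' @param ss A [spectrum_set].
#' @param path Output CSV path.
#' @param layout `"wide"` or `"long"` (see [read_spectra()]).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(ss, path, layout = c("wide", "long")) {
  layout <- match.arg(layout)
  stopifnot(inherits(ss, "spectrum_set"))
  fmt <- function(x) sprintf("%.17g", x)        # lossless float round trip
  if (layout == "wide") {
    df <- data.frame(wavelength_nm = fmt(ss$wavelengths),
                     apply(t(ss$X), 2L, fmt),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("wavelength_nm", ss$sample_ids)
  } else {
    df <- data.frame(
      sample_id = rep(ss$sample_ids, each = length(ss$wavelengths)),
      wavelength_nm = fmt(rep(ss$wavelengths,
                              times = length(ss$sample_ids))),
      intensity = fmt(as.vector(t(ss$X))), stringsAsFactors = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read crater morphology table from CSV
#' @param path CSV with columns `sample_id` + the nine crater parameters.
#' @return Validated data.frame.
#' @export
read_craters <- function(path) {
  if (!file.exists(path)) stop("crater file not found: ", path)
  validate_craters(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read reference concentrations from CSV
#' @param path CSV with columns `sample_id`, `cd_ug_g`.
#' @return A [reference_values].
#' @export
read_references <- function(path) {
  if (!file.exists(path)) stop("reference file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "cd_ug_g") %in% names(df)))
    stop("reference CSV needs columns sample_id, cd_ug_g")
  reference_values(df$cd_ug_g, df$sample_id)
}
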