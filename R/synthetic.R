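#' Configuration for the synthetic LIBS benchmark generator
#'
#' Encodes the study design the generator emulates: six commercial brands of
#' botanical powder spiked at ten Cd levels (0-70 ug/g) with four replicate
#' tablets per level, measured on a 210-231 nm axis. Each brand carries a
#' multiplicative ablation-efficiency factor (the matrix effect), interfering
#' Fe/Al/Si/Ca emission lines with brand-dependent composition, a smooth
#' baseline plus an instrumental ramp, multiplicative log-normal noise, and
#' crater morphology correlated with the per-sample ablation factor.
#'
#' @param n_brands Number of brands. Default 6.
#' @param brand_factors Length-`n_brands` multiplicative ablation factors;
#'   `NULL` (default) draws them uniformly from [0.5, 1.5] under `seed`.
#' @param levels Spike concentrations in ug/g. Default
#'   c(0, 0.5, 1, 10, 20, 30, 40, 50, 60, 70) — ten processing levels.
#' @param replicates Tablets per (brand, level). Default 4; replicate k is
#'   assigned to group "Group k", so a 3+1 group split holds every level of
#'   every brand in both subsets.
#' @param wl_start,wl_stop,wl_step Wavelength grid in nm. Default
#'   210.00-231.00 in 0.02 nm steps (p = 1051).
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   noise, applied once per sample (shot-to-shot) and once per bin
#'   (detector). Default 0.02.
#' @param ref_noise_cv CV of the multiplicative error on the ICP-MS-like
#'   reference values. Default 0.01.
#' @param baseline_amplitude Continuum level in counts. Default 200.
#' @param background_exponent Power of the per-sample ablation factor that
#'   scales the continuum (line emission scales with the factor itself).
#'   Values below 1 reproduce the partial nature of ratio correction on real
#'   plasmas — the background does not track the analyte lines exactly, so a
#'   residual matrix effect survives the correction and crater morphology
#'   retains independent compensating information. Default 0.85.
#' @param baseline_drift Relative amplitude of the per-sample instrumental
#'   background drift: an additive ramp of height `baseline_drift *
#'   baseline_amplitude * U[0,1]` (drawn per sample) that decays linearly to
#'   zero at `drift_stop_nm`. Bins beyond the ramp — in particular the
#'   229.5-231 nm tail — are the cleanest carriers of the multiplicative
#'   matrix information, which is why the ratio correction gravitates there.
#'   Default 0.3.
#' @param drift_stop_nm Wavelength at which the drift ramp reaches zero.
#'   Default 228 (below the Cd I 228.80 nm analytical window).
#' @param native_offset_range Per-brand native Cd content drawn uniformly
#'   from this range (ug/g), so even unspiked tablets emit Cd. Default
#'   c(0.4, 1.6).
#' @param line_sigma_nm Gaussian instrumental line width (sd). Default 0.05.
#' @param cd_responses Named counts-nm-per-(ug/g) response of the three Cd
#'   analytical lines.
#' @param interferent_area Named base peak areas (counts nm) for the
#'   interfering elements Fe, Al, Si, Ca.
#' @param composition_sdlog Log-sd of the per-brand composition multiplier of
#'   each interfering element. Default 0.4.
#' @param crater_noise_cv Named per-parameter log-normal CVs of the crater
#'   measurements.
#' @param additive_noise_sd Optional additive Gaussian noise sd in counts
#'   (0 = purely multiplicative noise, the default).
#' @param seed Integer RNG seed, recorded in the dataset manifest.
#' @return Object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_brands = 6L,
                             brand_factors = NULL,
                             levels = c(0, 0.5, 1, 10, 20, 30, 40, 50, 60, 70),
                             replicates = 4L,
                             wl_start = 210, wl_stop = 231, wl_step = 0.02,
                             noise_cv = 0.02,
                             ref_noise_cv = 0.01,
                             baseline_amplitude = 200,
                             background_exponent = 0.85,
                             baseline_drift = 0.3,
                             drift_stop_nm = 228,
                             native_offset_range = c(0.4, 1.6),
                             line_sigma_nm = 0.05,
                             cd_responses = c("Cd_II_214.44" = 12,
                                              "Cd_II_226.50" = 8,
                                              "Cd_I_228.80" = 15),
                             interferent_area = c(Fe = 150, Al = 100,
                                                  Si = 80, Ca = 120),
                             composition_sdlog = 0.4,
                             crater_noise_cv = c(
                               volume = 0.25, cross_sectional_area = 0.15,
                               surface_area = 0.15, average_depth = 0.10,
                               maximum_depth = 0.10, perimeter = 0.20,
                               horizontal_feret = 0.10, vertical_feret = 0.10,
                               circle_equivalent_diameter = 0.10),
                             additive_noise_sd = 0,
                             seed = 1L) {
  stopifnot(n_brands >= 1L, replicates >= 1L, length(levels) >= 2L,
            wl_step > 0, wl_stop > wl_start,
            noise_cv >= 0, ref_noise_cv >= 0, additive_noise_sd >= 0,
            baseline_amplitude > 0, line_sigma_nm > 0,
            length(native_offset_range) == 2L)
  if (!is.null(brand_factors)) {
    stopifnot(length(brand_factors) == n_brands, all(brand_factors > 0))
  }
  wl <- seq(wl_start, wl_stop, by = wl_step)
  lines <- cd_lines()
  for (nm in names(lines)) {
    l <- lines[[nm]]
    if (l$wavelength <= wl_start + 0.2 || l$wavelength >= wl_stop - 0.2)
      stop("Cd line ", format(l), " too close to the grid edge")
  }
  structure(list(
    n_brands = as.integer(n_brands), brand_factors = brand_factors,
    levels = levels, replicates = as.integer(replicates),
    wl_start = wl_start, wl_stop = wl_stop, wl_step = wl_step,
    noise_cv = noise_cv, ref_noise_cv = ref_noise_cv,
    baseline_amplitude = baseline_amplitude,
    background_exponent = background_exponent,
    baseline_drift = baseline_drift,
    drift_stop_nm = drift_stop_nm,
    native_offset_range = native_offset_range,
    line_sigma_nm = line_sigma_nm,
    cd_responses = cd_responses,
    interferent_area = interferent_area,
    composition_sdlog = composition_sdlog,
    crater_noise_cv = crater_noise_cv,
    additive_noise_sd = additive_noise_sd,
    seed = as.integer(seed)),
    class = "synthetic_config")
}

# interfering emission lines inside 210-231 nm (element, wavelength nm)
.interferent_lines <- function() {
  data.frame(
    element = c(rep("Al", 3L), rep("Si", 6L), rep("Ca", 4L), rep("Fe", 9L)),
    wavelength = c(221.00, 226.35, 226.91,
                   212.41, 220.80, 221.09, 221.17, 221.67, 221.81,
                   211.28, 212.30, 215.08, 227.55,
                   213.65, 213.70, 215.24, 215.59, 221.10, 221.71,
                   226.48, 226.50, 227.71),
    stringsAsFactors = FALSE)
}

# crater parameter scale model: pooled means anchored to typical laser-
# microscope measurements, with power-law coupling to the per-sample
# ablation factor (volume ~ a^3, areas ~ a^2, depths/perimeter ~ a,
# diameters ~ a^0.7)
.crater_base <- function() {
  data.frame(
    parameter = crater_parameters(),
    base = c(6.0e7, 6.3e5, 9.1e5, 88, 278, 5555, 1018, 1049, 873),
    exponent = c(3, 2, 2, 1, 1, 1, 0.7, 0.7, 0.7),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic calibration dataset
#'
#' Draws a full benchmark dataset under the design in the
#' [synthetic_config()]: per sample, true concentration = spike level +
#' brand-native offset; every Cd line contributes a Gaussian whose area is
#' (ablation factor) x (line response) x (concentration); interfering
#' Fe/Al/Si/Ca lines contribute areas proportional to the brand's
#' composition; a smooth continuum plus a fixed instrumental ramp (decaying
#' toward the 229.5-231 nm tail) complete the expectation, which is then
#' perturbed by per-sample and per-bin multiplicative log-normal noise.
#' Crater parameters are drawn log-normally around power laws of the same
#' per-sample ablation factor, so looser-textured (higher-factor) brands
#' produce larger craters. Reference values carry ICP-MS-like multiplicative
#' error. Deterministic given the config (same seed, bit-identical output).
#'
#' @param config A [synthetic_config()].
#' @return A [calibration_dataset] with an extra element `truth` (the true
#'   concentrations, ug/g) and attribute `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  wl <- seq(cfg$wl_start, cfg$wl_stop, by = cfg$wl_step)
  p <- length(wl)
  nb <- cfg$n_brands; nl <- length(cfg$levels); nr <- cfg$replicates
  n <- nb * nl * nr
  lines <- cd_lines()
  intf <- .interferent_lines()
  sdlog_of_cv <- function(cv) if (cv > 0) sqrt(log(1 + cv^2)) else 0
  lnorm_mult <- function(k, cv) {
    if (cv <= 0) return(rep(1, k))
    s <- sdlog_of_cv(cv)
    exp(stats::rnorm(k, -s^2 / 2, s))      # mean-1 log-normal
  }
  .with_seed(cfg$seed, {
    factors <- if (is.null(cfg$brand_factors))
      stats::runif(nb, 0.5, 1.5) else cfg$brand_factors
    native <- stats::runif(nb, cfg$native_offset_range[1L],
                           cfg$native_offset_range[2L])
    # per-brand composition multipliers of the interfering elements
    comp <- matrix(exp(stats::rnorm(nb * 4L, 0, cfg$composition_sdlog)),
                   nb, 4L, dimnames = list(NULL, c("Fe", "Al", "Si", "Ca")))

    design <- expand.grid(rep = seq_len(nr), level_i = seq_len(nl),
                          brand_i = seq_len(nb))
    design <- design[order(design$brand_i, design$level_i, design$rep), ]
    brand_i <- design$brand_i
    spike <- cfg$levels[design$level_i]
    truth <- spike + native[brand_i]
    ids <- sprintf("B%d_L%02d_R%d", brand_i, design$level_i, design$rep)
    brand <- sprintf("Brand-%d", brand_i)
    group <- sprintf("Group%d", design$rep)

    # per-sample total multiplicative (ablation) factor
    a <- factors[brand_i] * lnorm_mult(n, cfg$noise_cv)

    # flat continuum; per-sample additive drift ramp vanishing beyond
    # drift_stop_nm (instrument background, uncorrelated with the matrix)
    continuum <- rep(cfg$baseline_amplitude, p)
    ramp <- pmax(0, (cfg$drift_stop_nm - wl) /
                      (cfg$drift_stop_nm - cfg$wl_start))
    drift_amp <- cfg$baseline_drift * cfg$baseline_amplitude *
      stats::runif(n)
    gauss <- function(center) stats::dnorm(wl, center, cfg$line_sigma_nm)

    # fixed per-line profiles (p-vectors); sample scaling applied below
    cd_prof <- lapply(names(lines),
                      function(nm) gauss(lines[[nm]]$wavelength))
    names(cd_prof) <- names(lines)
    intf_prof <- lapply(seq_len(nrow(intf)),
                        function(i) gauss(intf$wavelength[i]))

    X <- matrix(0, n, p)
    for (i in seq_len(n)) {
      emis <- rep(0, p)
      for (nm in names(lines))
        emis <- emis + cfg$cd_responses[[nm]] * truth[i] * cd_prof[[nm]]
      for (j in seq_len(nrow(intf))) {
        el <- intf$element[j]
        emis <- emis +
          cfg$interferent_area[[el]] * comp[brand_i[i], el] * intf_prof[[j]]
      }
      # line emission tracks the ablation factor; the continuum tracks it
      # sublinearly, so ratio correction by background bins is only partial
      X[i, ] <- a[i] * emis + a[i]^cfg$background_exponent * continuum +
        drift_amp[i] * ramp
    }
    if (cfg$noise_cv > 0) {
      s <- sdlog_of_cv(cfg$noise_cv)
      X <- X * matrix(exp(stats::rnorm(n * p, -s^2 / 2, s)), n, p)
    }
    if (cfg$additive_noise_sd > 0) {
      X <- X + matrix(stats::rnorm(n * p, 0, cfg$additive_noise_sd), n, p)
      X[X <= 0] <- .Machine$double.eps
    }

    cb <- .crater_base()
    craters <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(cb))) {
      pstr <- cb$parameter[r]
      craters[[pstr]] <- cb$base[r] * a^cb$exponent[r] *
        lnorm_mult(n, cfg$crater_noise_cv[[pstr]])
    }
    # enforce maximum depth >= average depth while keeping the ratio noisy
    ratio <- pmax(1.05, 3.16 * lnorm_mult(n, 0.05))
    craters$maximum_depth <- craters$average_depth * ratio

    refs_val <- truth * lnorm_mult(n, cfg$ref_noise_cv)

    ds <- calibration_dataset(
      spectra = spectrum_set(X, wl, ids),
      craters = craters,
      references = reference_values(refs_val, ids),
      brand = brand, group = group, level = spike)
    ds$truth <- truth
    ds$ablation_factor <- a
    attr(ds, "config") <- cfg
    ds
  })
}

#' Write a dataset to a directory of plain-text files
#'
#' Emits `spectra.csv` (wide), `craters.csv`, `refs.csv`, `labels.csv` and
#' `manifest.json` (configuration echo including the seed, when the dataset
#' was generated synthetically).
#'
#' @param ds A [calibration_dataset].
#' @param dir Output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "calibration_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_spectra(ds$spectra, file.path(dir, "spectra.csv"), "wide")
  if (!is.null(ds$craters))
    utils::write.csv(ds$craters, file.path(dir, "craters.csv"),
                     row.names = FALSE)
  utils::write.csv(data.frame(sample_id = ds$references$sample_ids,
                              cd_ug_g = ds$references$values),
                   file.path(dir, "refs.csv"), row.names = FALSE)
  labels <- data.frame(sample_id = ds$spectra$sample_ids,
                       brand = ds$brand, group = ds$group)
  if (!is.null(ds$level)) labels$level_ug_g <- ds$level
  utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  cfg <- attr(ds, "config")
  manifest <- list(files = c("spectra.csv", "craters.csv", "refs.csv",
                             "labels.csv"),
                   n_samples = n_samples(ds))
  if (!is.null(cfg)) {
    cfgl <- unclass(cfg)
    # named vectors must serialize as JSON objects, not bare arrays
    for (f in c("cd_responses", "interferent_area", "crater_noise_cv"))
      cfgl[[f]] <- as.list(cfgl[[f]])
    manifest$config <- cfgl
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return A [calibration_dataset].
#' @export
read_dataset <- function(dir) {
  ss <- read_spectra(file.path(dir, "spectra.csv"), "wide")
  refs <- read_references(file.path(dir, "refs.csv"))
  labels <- utils::read.csv(file.path(dir, "labels.csv"),
                            stringsAsFactors = FALSE)
  if (!identical(as.character(labels$sample_id), ss$sample_ids))
    stop("labels.csv misaligned with spectra.csv")
  craters_path <- file.path(dir, "craters.csv")
  craters <- if (file.exists(craters_path)) read_craters(craters_path)
             else NULL
  calibration_dataset(ss, craters, refs, labels$brand, labels$group,
                      level = labels$level_ug_g)
}

#' Rebuild a synthetic configuration from a manifest
#'
#' @param path `manifest.json` written by [write_dataset()] for a generated
#'   dataset.
#' @return A [synthetic_config()].
#' @export
read_manifest_config <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(m$config)) stop("manifest carries no generator config")
  cfg <- m$config
  bf <- cfg$brand_factors
  if (!length(bf)) bf <- NULL                 # JSON null round-trip
  synthetic_config(
    n_brands = cfg$n_brands, brand_factors = bf,
    levels = cfg$levels, replicates = cfg$replicates,
    wl_start = cfg$wl_start, wl_stop = cfg$wl_stop, wl_step = cfg$wl_step,
    noise_cv = cfg$noise_cv, ref_noise_cv = cfg$ref_noise_cv,
    baseline_amplitude = cfg$baseline_amplitude,
    background_exponent = cfg$background_exponent,
    baseline_drift = cfg$baseline_drift,
    drift_stop_nm = cfg$drift_stop_nm,
    native_offset_range = cfg$native_offset_range,
    line_sigma_nm = cfg$line_sigma_nm,
    cd_responses = unlist(cfg$cd_responses),
    interferent_area = unlist(cfg$interferent_area),
    composition_sdlog = cfg$composition_sdlog,
    crater_noise_cv = unlist(cfg$crater_noise_cv),
    additive_noise_sd = cfg$additive_noise_sd,
    seed = cfg$seed)
}
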