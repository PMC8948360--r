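.CONFIG_KEYS <- c("method", "L", "N", "SBR", "c", "wavelength",
                  "numerical_aperture", "m", "map_grid", "seed",
                  "output_dir")
.REQUIRED_KEYS <- c("method", "L", "N", "SBR", "c", "wavelength")

.checkConfigValue <- function(key, ok) {
  if (!ok) stop("config validation error for key \"", key, "\"", call. = FALSE)
}

#' Build a run configuration in code
#'
#' Same validation as [loadConfig()] but from arguments. `SBR = Inf` (or the
#' string `"inf"` in a file) is mapped to the internal no-background
#' convention 1e6, which keeps the Fisher information finite at the
#' pattern-center exposure.
#'
#' @param method `"minflux"` or `"rastmin"`.
#' @param L pattern size (nm).
#' @param N photon budget per localization.
#' @param SBR signal-to-background ratio.
#' @param order excitation order c.
#' @param wavelength excitation wavelength (nm).
#' @param numericalAperture objective NA (default 1.4).
#' @param m rastmin grid side (default 4).
#' @param mapGrid precision-map grid side (default 41).
#' @param seed master seed (default 1).
#' @param outputDir output directory (default `"."`).
#' @return a [RunConfig-class].
#' @export
makeRunConfig <- function(method, L, N, SBR, order, wavelength,
                          numericalAperture = 1.4, m = 4, mapGrid = 41,
                          seed = 1, outputDir = ".") {
  .checkConfigValue("method", is.character(method) && length(method) == 1L &&
                      method %in% c("minflux", "rastmin"))
  .checkConfigValue("L", is.numeric(L) && length(L) == 1L && is.finite(L) &&
                      L > 0)
  .checkConfigValue("N", is.numeric(N) && length(N) == 1L && is.finite(N) &&
                      N >= 1 && N == round(N))
  if (is.character(SBR) && length(SBR) == 1L &&
      tolower(SBR) %in% c("inf", "infinite")) SBR <- Inf
  .checkConfigValue("SBR", is.numeric(SBR) && length(SBR) == 1L &&
                      !is.na(SBR) && SBR > 0)
  if (is.infinite(SBR)) SBR <- 1e6
  .checkConfigValue("c", is.numeric(order) && length(order) == 1L &&
                      is.finite(order) && order >= 1)
  .checkConfigValue("wavelength", is.numeric(wavelength) &&
                      length(wavelength) == 1L && is.finite(wavelength) &&
                      wavelength > 0)
  .checkConfigValue("numerical_aperture", is.numeric(numericalAperture) &&
                      length(numericalAperture) == 1L &&
                      numericalAperture > 0 && numericalAperture <= 1.7)
  .checkConfigValue("m", is.numeric(m) && length(m) == 1L && m >= 2 &&
                      m == round(m))
  .checkConfigValue("map_grid", is.numeric(mapGrid) && length(mapGrid) == 1L &&
                      mapGrid >= 3 && mapGrid == round(mapGrid))
  .checkConfigValue("seed", is.numeric(seed) && length(seed) == 1L &&
                      is.finite(seed) && seed == round(seed))
  .checkConfigValue("output_dir", is.character(outputDir) &&
                      length(outputDir) == 1L)
  new("RunConfig", method = method, L = L, m = m, wavelength = wavelength,
      numericalAperture = numericalAperture, order = order, N = N, SBR = SBR,
      mapGrid = mapGrid, seed = seed, outputDir = outputDir, configHash = "")
}

#' Load and validate a run configuration file
#'
#' Reads a YAML `key: value` file, rejects unknown keys, validates every
#' field against the preconditions of the module it feeds, fills defaults
#' (numerical_aperture 1.4, m 4, map_grid 41, seed 1, output_dir "."), and
#' records the file's md5 hash for provenance. `SBR: inf` selects the
#' internal no-background convention (1e6).
#'
#' @param path path to the configuration file.
#' @return a [RunConfig-class].
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  # YAML 1.1 reads the bare key "N" as a boolean; restore its name
  names(raw)[names(raw) == "FALSE"] <- "N"
  unknown <- setdiff(names(raw), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(.REQUIRED_KEYS, names(raw))
  if (length(missing))
    stop("missing required config key(s): ", paste(missing, collapse = ", "))
  pick <- function(key, default) {
    v <- raw[[key, exact = TRUE]]
    if (is.null(v)) default else v
  }
  cfg <- makeRunConfig(
    method = raw[["method"]], L = raw[["L"]], N = raw[["N"]],
    SBR = raw[["SBR"]], order = raw[["c"]], wavelength = raw[["wavelength"]],
    numericalAperture = pick("numerical_aperture", 1.4),
    m = pick("m", 4),
    mapGrid = pick("map_grid", 41),
    seed = pick("seed", 1),
    outputDir = pick("output_dir", "."))
  cfg@configHash <- unname(tools::md5sum(path))
  cfg
}

#' Scenario from a run configuration
#'
#' @param config a [RunConfig-class].
#' @param emitterPosition emitter position in nm (default the origin).
#' @return a [Scenario-class].
#' @export
scenarioFromConfig <- function(config, emitterPosition = c(0, 0)) {
  stopifnot(is(config, "RunConfig"))
  seqn <- if (config@method == "minflux") minfluxSequence(config@L)
          else rastminSequence(config@L, config@m)
  makeScenario(makeBeamProfile(config@wavelength, config@numericalAperture),
               seqn, order = config@order, N = config@N, SBR = config@SBR,
               emitterPosition = emitterPosition)
}

setMethod("show", "RunConfig", function(object) {
  cat(sprintf(
    "RunConfig: %s L = %g nm, c = %g, N = %g, SBR = %g, lambda = %g nm, NA = %g\n",
    object@method, object@L, object@order, object@N, object@SBR,
    object@wavelength, object@numericalAperture))
})

.writeRunLog <- function(dir, tag, config, elapsed) {
  lines <- c(
    sprintf("run: %s", tag),
    sprintf("config_hash: %s", config@configHash),
    sprintf("seed: %d", as.integer(config@seed)),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("smlssi"))),
    sprintf("r_version: %s", R.version.string),
    sprintf("wall_time_s: %.3f", elapsed),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  writeLines(lines, file.path(dir, paste0(tag, "_run.log")))
}

#' Write precision-map artifacts
#'
#' Writes the sigma matrix as a comma-separated table (header row of the x
#' coordinates in nm, no index column), a YAML metadata sidecar with the
#' full generating configuration and units, an optional single-plane 32-bit
#' float TIFF in nm, and a JSON summary. Outputs are byte-identical across
#' reruns of the same configuration.
#'
#' @param map a [PrecisionMap-class].
#' @param dir output directory (created if absent).
#' @param basename stem for the output files.
#' @param tiff also write `<basename>.tif`.
#' @return invisibly, the named vector of written paths.
#' @export
writePrecisionMap <- function(map, dir = ".", basename = "precision_map",
                              tiff = FALSE) {
  stopifnot(is(map, "PrecisionMap"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create output directory ", dir)
  paths <- c(csv = file.path(dir, paste0(basename, ".csv")),
             meta = file.path(dir, paste0(basename, "_meta.yaml")),
             summary = file.path(dir, paste0(basename, "_summary.json")))
  sig <- map@sigma
  colnames(sig) <- sprintf("x_%g_nm", map@coordinates)
  utils::write.csv(sig, paths[["csv"]], row.names = FALSE)
  meta <- c(map@fingerprint,
            list(units = "nm", value = "sigma_CRB",
                 layout = "rows = y from -L/2 to L/2, columns = x",
                 coordinates_nm = map@coordinates))
  yaml::write_yaml(meta, paths[["meta"]])
  jsonlite::write_json(mapSummary(map), paths[["summary"]],
                       auto_unbox = TRUE, digits = NA)
  if (tiff) {
    paths <- c(paths, tif = file.path(dir, paste0(basename, ".tif")))
    tiff::writeTIFF(map@sigma / max(map@sigma), paths[["tif"]],
                    bits.per.sample = 32L, reduce = FALSE)
    # writeTIFF stores [0,1] floats; keep the nm scale in the sidecar
    meta$tiff_scale_nm <- max(map@sigma)
    yaml::write_yaml(meta, paths[["meta"]])
  }
  invisible(paths)
}

#' Run a precision-map computation from a configuration
#'
#' Computes the \eqn{\sigma_{CRB}} map for the configured scenario and
#' writes CSV + metadata sidecar (+ optional TIFF) + JSON summary into the
#' config's output directory, plus a run log.
#'
#' @param config a [RunConfig-class].
#' @param tiff also write a 32-bit float TIFF.
#' @return invisibly, a list with the [PrecisionMap-class], its summary and
#'   the written paths.
#' @export
runMap <- function(config, tiff = FALSE) {
  stopifnot(is(config, "RunConfig"))
  t0 <- proc.time()[["elapsed"]]
  map <- precisionMap(scenarioFromConfig(config), config@mapGrid)
  base <- sprintf("map_%s_c%g", config@method, config@order)
  paths <- writePrecisionMap(map, config@outputDir, base, tiff = tiff)
  .writeRunLog(config@outputDir, base, config, proc.time()[["elapsed"]] - t0)
  invisible(list(map = map, summary = mapSummary(map), paths = paths))
}

#' Run a Monte-Carlo validation of the estimator against the bound
#'
#' Draws `repeats` seeded count records at the pattern center, localizes
#' them, and writes a JSON report comparing the empirical sigma to
#' \eqn{\sigma_{CRB}}. Completion does not depend on the ratio: judging
#' efficiency belongs to tests, not to the run.
#'
#' @param config a [RunConfig-class].
#' @param repeats number of records (>= 100).
#' @param truePosition emitter position (nm), default the origin.
#' @return invisibly, a list with the [PrecisionSummary-class], the report
#'   list and the report path.
#' @export
runValidate <- function(config, repeats = 1000, truePosition = c(0, 0)) {
  stopifnot(is(config, "RunConfig"))
  if (!is.numeric(repeats) || length(repeats) != 1L || repeats < 100)
    stop("invalid parameter: repeats must be >= 100 (got ", repeats, ")")
  t0 <- proc.time()[["elapsed"]]
  sc <- scenarioFromConfig(config)
  ps <- monteCarloPrecision(truePosition, sc, repeats = repeats,
                            seed = config@seed)
  report <- list(
    method = config@method, order = config@order, N = config@N,
    SBR = config@SBR, L_nm = config@L,
    true_position_nm = as.numeric(truePosition),
    repeats = ps@repeats, excluded = ps@nExcluded,
    sigma_x_nm = ps@sigmaAxis[1], sigma_y_nm = ps@sigmaAxis[2],
    sigma_pooled_nm = ps@sigmaPooled, sigma_crb_nm = ps@sigmaCRB,
    ratio = ps@sigmaPooled / ps@sigmaCRB,
    bias_x_nm = ps@bias[1], bias_y_nm = ps@bias[2],
    identifiable = ps@identifiable, seed = config@seed)
  if (!dir.exists(config@outputDir))
    dir.create(config@outputDir, recursive = TRUE, showWarnings = FALSE)
  base <- sprintf("validate_%s_c%g", config@method, config@order)
  path <- file.path(config@outputDir, paste0(base, ".json"))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  .writeRunLog(config@outputDir, base, config,
               proc.time()[["elapsed"]] - t0)
  invisible(list(summary = ps, report = report, path = path))
}
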