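#' Default food-web configuration
#'
#' A complete configuration for the zero-dimensional lake food web:
#' seven pools (dissolved nutrient, phytoplankton, zooplankton, zoobenthos,
#' sediment detritus, omnivorous fish, predator fish) in a single biomass
#' currency (g m^-3), with an omnivorous fish feeding in pelagic (on
#' zooplankton) and benthic (on zoobenthos and sediment detritus) modes and
#' a predator fish feeding on the omnivore. Parameter values are owned by
#' this package (chosen as order-of-magnitude plausible for a temperate
#' eutrophic lake); they are a toy calibration, not a fit to any lake.
#'
#' @return A nested named list; see [validate_config()] for the schema.
#' @export
default_config <- function() {
  list(
    run = list(years = 100, dt = 1, analysis_fraction = 0.5),
    forcing = list(
      temperature = list(mean = 10, amplitude = 9, phase = 112),
      light = list(mean = 0.55, amplitude = 0.45, phase = 81),
      load = list(base = 0.002, amplitude = 0.001, phase = 300),
      load_scale = 1
    ),
    physics = list(
      flushing = 0.004,        # d^-1, outflow of dissolved nutrient + phytoplankton
      burial = 0.0008,         # d^-1, permanent burial of sediment detritus
      mineralization = 0.01    # d^-1 at 20 C, detritus -> nutrient
    ),
    chl_conversion = 1,        # chlorophyll proxy per unit phytoplankton biomass
    phytoplankton = list(mu_max = 1.2, K_N = 0.01, resp = 0.06, mort = 0.03,
                         q10 = 2),
    zooplankton = list(c = 2, I_max = 0.8, f_gut = 1, a = 0.7, u = 0.04,
                       m_nat = 0.01, q10 = 2),
    zoobenthos = list(c = 0.08, I_max = 0.12, f_gut = 2, a = 0.6, u = 0.004,
                      m_nat = 0.003, q10 = 2),
    omnivore = list(
      obm = TRUE,
      tradeoff = list(f_PM = 0.9, f_FC = 0.675, f_RF = 0.3),
      I_max = 0.05, u = 0.005, m_nat = 5e-4, q10 = 2, f_veg = 1,
      prey = list(
        list(id = "zooplankton", mode = "pelagic", c = 1.2, f_gut = 1, a = 0.7),
        list(id = "zoobenthos", mode = "benthic", c = 0.25, f_gut = 1.5, a = 0.6),
        list(id = "detritus", mode = "benthic", c = 0.05, f_gut = 4, a = 0.2)
      )
    ),
    predator = list(
      obm = TRUE,
      tradeoff = list(f_PM = 1, f_FC = 1, f_RF = 0.3),
      I_max = 0.05, u = 0.008, m_nat = 0.002, q10 = 2, f_veg = 1,
      c = 0.8, f_gut = 1, a = 0.8
    ),
    init = list(nutrient = 0.05, phytoplankton = 0.2, zooplankton = 0.1,
                zoobenthos = 0.5, detritus = 2, omnivore = 0.3,
                predator = 0.1)
  )
}

.POOLS <- c("nutrient", "phytoplankton", "zooplankton", "zoobenthos",
            "detritus", "omnivore", "predator")

#' Validate a food-web configuration
#'
#' Checks structure, ranges and cross-field constraints of a configuration
#' list (e.g. `m_nat > 0` for fish groups running the behavioral
#' optimization, trade-off fractions in \[0, 1\], non-negative rates,
#' prey ids referring to model pools). Called by [foodweb_run()] and the
#' command-line tool; a violation is an error.
#'
#' @param cfg Configuration list as produced by [default_config()] or
#'   [read_config()].
#' @return `cfg`, invisibly, possibly with defaults filled in.
#' @export
validate_config <- function(cfg) {
  if (!is.list(cfg)) stop("configuration must be a list", call. = FALSE)
  user <- cfg
  cfg <- modifyList(default_config(), cfg)
  # prey menus are unnamed lists, which modifyList cannot merge element-wise:
  # a user-supplied menu replaces the default wholesale
  if (!is.null(user$omnivore$prey)) cfg$omnivore$prey <- user$omnivore$prey
  bad <- function(msg) stop("invalid configuration: ", msg, call. = FALSE)

  r <- cfg$run
  if (!is.numeric(r$years) || r$years < 2) bad("run$years must be >= 2")
  if (!is.numeric(r$dt) || r$dt <= 0) bad("run$dt must be > 0")
  if (r$analysis_fraction <= 0 || r$analysis_fraction > 1)
    bad("run$analysis_fraction must be in (0, 1]")
  if (cfg$forcing$load_scale <= 0) bad("forcing$load_scale must be > 0")
  p <- cfg$physics
  if (any(unlist(p) < 0)) bad("physics rates must be >= 0")

  for (g in c("zooplankton", "zoobenthos")) {
    gc <- cfg[[g]]
    if (any(unlist(gc[c("c", "I_max", "f_gut", "u", "m_nat")]) < 0))
      bad(paste(g, "rates must be >= 0"))
    if (gc$a < 0 || gc$a > 1) bad(paste(g, "assimilation must be in [0, 1]"))
  }
  for (g in c("omnivore", "predator")) {
    gc <- cfg[[g]]
    if (!is.logical(gc$obm)) bad(paste(g, "$obm must be TRUE/FALSE"))
    tp <- gc$tradeoff
    if (tp$f_PM < 0 || tp$f_PM > 1 || tp$f_FC < 0 || tp$f_FC > 1 || tp$f_RF < 0)
      bad(paste(g, "trade-off parameters out of range"))
    if (gc$I_max < 0 || gc$u < 0 || gc$q10 <= 0) bad(paste(g, "rates out of range"))
    if (isTRUE(gc$obm) && gc$m_nat <= 0)
      bad(paste(g, "$m_nat must be > 0 when the behavioral model is on"))
    if (gc$m_nat < 0) bad(paste(g, "$m_nat must be >= 0"))
    if (gc$f_veg < 0 || gc$f_veg > 1) bad(paste(g, "$f_veg must be in [0, 1]"))
  }
  ids <- vapply(cfg$omnivore$prey, `[[`, character(1), "id")
  if (anyDuplicated(ids)) bad("omnivore prey ids must be unique")
  for (pr in cfg$omnivore$prey) {
    if (!pr$id %in% c("zooplankton", "zoobenthos", "detritus"))
      bad(paste("unknown omnivore prey id:", pr$id))
    if (!pr$mode %in% c("pelagic", "benthic")) bad("invalid omnivore prey mode")
    if (pr$c < 0 || pr$f_gut < 0 || pr$a < 0 || pr$a > 1)
      bad(paste("omnivore prey", pr$id, "parameters out of range"))
  }
  if (!all(.POOLS %in% names(cfg$init))) bad("init must name all seven pools")
  if (any(unlist(cfg$init[.POOLS]) < 0)) bad("initial pools must be >= 0")
  invisible(cfg)
}

#' Read / write a configuration file
#'
#' Configurations are stored as YAML. Reading merges the file over the
#' package defaults and validates.
#'
#' @param path File path.
#' @return `read_config()` returns a validated configuration list;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg Configuration list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# canonicalize: recursively sort names so the hash ignores key order
.canonical <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(nzchar(nm))) x <- x[order(nm)]
    lapply(x, .canonical)
  } else x
}

#' Stable configuration hash
#'
#' MD5 hash of the canonicalized (recursively name-sorted) configuration;
#' invariant under reordering of keys.
#'
#' @param cfg Configuration list.
#' @return A 32-character hexadecimal string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(.canonical(cfg), auto_unbox = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Run manifest
#'
#' Structured metadata for one simulation run: configuration hash, seed,
#' package version, timestamps and output paths. Written as a JSON sidecar
#' by the command-line tool.
#'
#' @param cfg Configuration list.
#' @param seed Integer seed recorded with the run.
#' @param outputs Character vector of output paths.
#' @return A list of class `"run_manifest"`.
#' @export
run_manifest <- function(cfg, seed = NA_integer_, outputs = character()) {
  structure(list(
    config_hash = config_hash(cfg),
    seed = seed,
    package_version = as.character(utils::packageVersion("lakeOBM")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs
  ), class = "run_manifest")
}
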