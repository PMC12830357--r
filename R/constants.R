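#' Gas conversion constants
#'
#' Bundles the two physical constants that convert an administered volume of
#' nitrous oxide into a carbon footprint: the density of N2O gas at the
#' conditions assumed for cylinder discharge, and the global warming potential
#' (GWP) used to express a mass of N2O as the mass of CO2 with the same
#' warming effect over a 100-year horizon.
#'
#' The defaults (density 0.001984467 kg/L, GWP 265) reproduce the figures an
#' AR5-era audit prints. The latest IPCC assessment revised the 100-year GWP
#' of N2O to 273; pass `gwp = 273` to use it — every CO2e figure then scales
#' by exactly 273/265.
#'
#' @param density_kg_per_l Mass of one litre of N2O gas, in kg. Must be
#'   positive.
#' @param gwp Dimensionless global-warming-potential multiplier. Must be
#'   positive.
#' @return An object of class `gas_constants`: a list with elements
#'   `density_kg_per_l` and `gwp`.
#' @examples
#' gas_constants()
#' gas_constants(gwp = 273)
#' @export
gas_constants <- function(density_kg_per_l = 0.001984467, gwp = 265) {
  if (!is.numeric(density_kg_per_l) || length(density_kg_per_l) != 1L ||
      !is.finite(density_kg_per_l) || density_kg_per_l <= 0) {
    stop("`density_kg_per_l` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(gwp) || length(gwp) != 1L || !is.finite(gwp) || gwp <= 0) {
    stop("`gwp` must be a single positive number", call. = FALSE)
  }
  structure(
    list(density_kg_per_l = density_kg_per_l, gwp = gwp),
    class = "gas_constants"
  )
}

#' @export
print.gas_constants <- function(x, ...) {
  cat("N2O gas constants\n")
  cat(sprintf("  density: %.9f kg/L\n", x$density_kg_per_l))
  cat(sprintf("  GWP    : %g\n", x$gwp))
  invisible(x)
}

#' Cylinder capacity registry
#'
#' Maps cylinder size codes to the nominal volume of N2O gas (litres) released
#' by one full cylinder. Defaults cover the two sizes commonly found in UK
#' dental services: size E (machine-mounted, 1,800 L) and size G
#' (manifold bank, 9,000 L). These capacities are the unique round-number
#' values consistent with the standard procurement conversions of
#' 10 E-cylinders/year = 346 L/week and 6 G-cylinders/year = 1,038 L/week.
#'
#' @param ... Named positive numbers, one per size code, e.g.
#'   `cylinder_registry(E = 1800, G = 9000, J = 18000)`. Codes must be unique.
#' @return An object of class `cylinder_registry`: a named numeric vector of
#'   litres per full cylinder.
#' @examples
#' reg <- cylinder_registry()
#' reg[["E"]]
#' @export
cylinder_registry <- function(...) {
  vols <- c(...)
  if (length(vols) == 0L) vols <- c(E = 1800, G = 9000)
  if (is.null(names(vols)) || any(!nzchar(names(vols)))) {
    stop("every cylinder capacity must be named by its size code", call. = FALSE)
  }
  if (anyDuplicated(names(vols))) {
    stop("cylinder size codes must be unique", call. = FALSE)
  }
  if (!is.numeric(vols) || any(!is.finite(vols)) || any(vols <= 0)) {
    stop("cylinder capacities must be positive numbers (litres)", call. = FALSE)
  }
  structure(stats::setNames(as.numeric(vols), names(vols)),
            class = "cylinder_registry")
}

#' Look up a cylinder capacity
#'
#' @param registry A [cylinder_registry()].
#' @param size_code Character vector of size codes.
#' @return Numeric vector of nominal volumes (L). Unknown codes are an error
#'   naming the offending code.
#' @export
cylinder_volume <- function(registry, size_code) {
  stopifnot(inherits(registry, "cylinder_registry"))
  unknown <- setdiff(unique(as.character(size_code)), names(registry))
  if (length(unknown) > 0L) {
    stop("unknown cylinder size code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unname(unclass(registry)[as.character(size_code)])
}

#' Audit configuration
#'
#' Collects every tunable the audit pipeline uses: gas constants, the cylinder
#' registry, the wastage investigation threshold, report rounding, and
#' anonymisation. The default threshold of 0.20 follows the forward-looking
#' recommendation to investigate wastage over 20%; the stricter in-study
#' trigger of 25% is available as `wastage_threshold = 0.25`.
#'
#' @param constants A [gas_constants()] object.
#' @param registry A [cylinder_registry()] object.
#' @param wastage_threshold Wastage fraction above which a site is flagged for
#'   investigation; in \[0, 1\].
#' @param report_decimal_places Decimal places used when formatting report
#'   numbers (raw values are always kept at full precision).
#' @param anonymise Replace service identifiers with stable pseudonyms in
#'   rendered outputs.
#' @param collection_period_days Length of the episode data-collection window
#'   in days; used to express administered volumes per week. Services with a
#'   low-volume sedation list typically extend the window to 14 or ~30 days.
#' @return An object of class `audit_config`.
#' @export
audit_config <- function(constants = gas_constants(),
                         registry = cylinder_registry(),
                         wastage_threshold = 0.20,
                         report_decimal_places = 2L,
                         anonymise = TRUE,
                         collection_period_days = 7L) {
  stopifnot(inherits(constants, "gas_constants"),
            inherits(registry, "cylinder_registry"))
  if (!is.numeric(wastage_threshold) || length(wastage_threshold) != 1L ||
      is.na(wastage_threshold) || wastage_threshold < 0 || wastage_threshold > 1) {
    stop("`wastage_threshold` must be in [0, 1]", call. = FALSE)
  }
  report_decimal_places <- as.integer(report_decimal_places)
  if (is.na(report_decimal_places) || report_decimal_places < 0) {
    stop("`report_decimal_places` must be a non-negative integer", call. = FALSE)
  }
  if (!is.logical(anonymise) || length(anonymise) != 1L || is.na(anonymise)) {
    stop("`anonymise` must be TRUE or FALSE", call. = FALSE)
  }
  collection_period_days <- as.numeric(collection_period_days)
  if (is.na(collection_period_days) || collection_period_days <= 0) {
    stop("`collection_period_days` must be positive", call. = FALSE)
  }
  structure(
    list(constants = constants,
         registry = registry,
         wastage_threshold = wastage_threshold,
         report_decimal_places = report_decimal_places,
         anonymise = anonymise,
         collection_period_days = collection_period_days),
    class = "audit_config"
  )
}

#' Read an audit configuration from a JSON file
#'
#' Recognised keys: `density_kg_per_l`, `gwp`, `registry` (object mapping size
#' code to litres), `wastage_threshold`, `report_decimal_places`, `anonymise`,
#' `collection_period_days`. Absent keys fall back to the [audit_config()]
#' defaults.
#'
#' @param path Path to a JSON file.
#' @return An `audit_config` object.
#' @export
read_audit_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  dflt <- audit_config()
  constants <- gas_constants(
    density_kg_per_l = raw$density_kg_per_l %||% dflt$constants$density_kg_per_l,
    gwp = raw$gwp %||% dflt$constants$gwp
  )
  registry <- if (!is.null(raw$registry)) {
    do.call(cylinder_registry, as.list(unlist(raw$registry)))
  } else {
    dflt$registry
  }
  audit_config(
    constants = constants,
    registry = registry,
    wastage_threshold = raw$wastage_threshold %||% dflt$wastage_threshold,
    report_decimal_places = raw$report_decimal_places %||% dflt$report_decimal_places,
    anonymise = raw$anonymise %||% dflt$anonymise,
    collection_period_days = raw$collection_period_days %||% dflt$collection_period_days
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
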