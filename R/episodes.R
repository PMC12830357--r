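# Episode / site / procurement data model and delimited-text ingest.
#
# Internal canonical representation is a plain data.frame, one row per record,
# with titration stored as a fraction in (0, 1] (files carry percent), ASA
# grades as integers 1..6 (files may carry Roman numerals), and logical
# success / acclimatisation flags.

EPISODE_FILE_COLUMNS <- c(
  "episode_id", "service_id", "site_id", "age_years", "sex", "asa_grade",
  "flow_lpm", "max_n2o_pct", "duration_min", "procedure", "success",
  "acclimatisation_only"
)

EPISODE_COLUMNS <- c(
  "episode_id", "service_id", "site_id", "age_years", "sex", "asa_grade",
  "flow_lpm", "max_n2o_fraction", "duration_min", "procedure", "success",
  "acclimatisation_only"
)

SITE_FILE_COLUMNS <- c("site_id", "service_id", "supply_type", "scavenging",
                       "shared_supply")

PROCUREMENT_FILE_COLUMNS <- c("site_id", "cylinder_size", "quantity",
                              "period_days")

SEX_LEVELS <- c("female", "male", "other")
PROCEDURE_LEVELS <- c("extraction", "restoration", "acclimatisation", "other")
SCAVENGING_LEVELS <- c("central", "mobile", "high_speed_suction")

.roman_asa <- c(I = 1L, II = 2L, III = 3L, IV = 4L, V = 5L, VI = 6L)

.parse_asa <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- suppressWarnings(as.integer(x))
  roman <- is.na(out) & x %in% names(.roman_asa)
  out[roman] <- .roman_asa[x[roman]]
  out
}

.parse_logical <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[x %in% c("false", "f", "no", "n", "0")] <- FALSE
  as.logical(out)
}

.parse_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("other", length(x))
  out[x %in% c("female", "f")] <- "female"
  out[x %in% c("male", "m")] <- "male"
  out
}

.parse_procedure <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- ifelse(x %in% PROCEDURE_LEVELS, x, "other")
  out
}

.read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    stop("input error: ", what, " file not found: ", path, call. = FALSE)
  }
  if (file.size(path) == 0L) {
    stop("input error: ", what, " file is empty: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("schema error: ", what, " file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    stop("input error: ", what, " file has a header but no rows: ", path,
         call. = FALSE)
  }
  df
}

#' Read sedation episodes from a CSV data-collection template
#'
#' Parses the per-episode audit template, normalises units and encodings, and
#' validates every row against the episode invariants. Titration is accepted
#' as a percent in (0, 100\] and stored as a fraction; ASA grades may be Roman
#' numerals; sex and procedure strings are normalised to lower-case category
#' sets. Rows failing any check are excluded and enumerated in the validation
#' report, so every input row is accounted for: `n_valid + n_excluded` always
#' equals the row count.
#'
#' @param path Path to a CSV file with header columns
#'   `episode_id,service_id,site_id,age_years,sex,asa_grade,flow_lpm,max_n2o_pct,duration_min,procedure,success,acclimatisation_only`.
#' @param strict If `TRUE`, any invalid row raises an error (listing the
#'   failures) instead of being excluded.
#' @return A list with elements:
#'   \describe{
#'     \item{episodes}{data.frame of validated episodes, titration as a
#'       fraction in column `max_n2o_fraction`.}
#'     \item{report}{list with `n_rows`, `n_valid`, `n_excluded` and an
#'       `exclusions` data.frame (`row`, `episode_id`, `reason`).}
#'   }
#' @export
read_episodes <- function(path, strict = FALSE) {
  raw <- .read_csv_checked(path, EPISODE_FILE_COLUMNS, "episodes")
  n <- nrow(raw)

  age <- suppressWarnings(as.numeric(raw$age_years))
  asa <- .parse_asa(raw$asa_grade)
  flow <- suppressWarnings(as.numeric(raw$flow_lpm))
  pct <- suppressWarnings(as.numeric(raw$max_n2o_pct))
  dur <- suppressWarnings(as.numeric(raw$duration_min))
  success <- .parse_logical(raw$success)
  acc_only <- .parse_logical(raw$acclimatisation_only)
  procedure <- .parse_procedure(raw$procedure)

  reason <- character(n)
  add_reason <- function(bad, msg) {
    bad <- which(bad)
    reason[bad] <<- ifelse(nzchar(reason[bad]),
                           paste(reason[bad], msg, sep = "; "), msg)
  }
  add_reason(is.na(flow), "non-numeric or missing flow_lpm")
  add_reason(!is.na(flow) & flow <= 0, "flow_lpm must be > 0")
  add_reason(is.na(pct), "non-numeric or missing max_n2o_pct")
  add_reason(!is.na(pct) & (pct <= 0 | pct > 100),
             "max_n2o_pct must be in (0, 100]")
  add_reason(is.na(dur), "non-numeric or missing duration_min")
  add_reason(!is.na(dur) & dur <= 0, "duration_min must be > 0")
  add_reason(is.na(age) | age < 0 | age != floor(age),
             "age_years must be a non-negative integer")
  add_reason(is.na(asa) | asa < 1L | asa > 6L, "asa_grade must be 1-6 (I-VI)")
  add_reason(is.na(success), "success must be a true/false value")
  add_reason(is.na(acc_only), "acclimatisation_only must be a true/false value")
  add_reason(!is.na(acc_only) & acc_only & procedure != "acclimatisation",
             "acclimatisation_only=TRUE requires procedure=acclimatisation")

  bad <- nzchar(reason)
  exclusions <- data.frame(
    row = which(bad),
    episode_id = raw$episode_id[bad],
    reason = reason[bad],
    stringsAsFactors = FALSE
  )
  if (strict && any(bad)) {
    stop("validation failure in ", sum(bad), " row(s):\n",
         paste(sprintf("  row %d (%s): %s", exclusions$row,
                       exclusions$episode_id, exclusions$reason),
               collapse = "\n"),
         call. = FALSE)
  }
  keep <- !bad
  episodes <- data.frame(
    episode_id = raw$episode_id[keep],
    service_id = raw$service_id[keep],
    site_id = raw$site_id[keep],
    age_years = as.integer(age[keep]),
    sex = .parse_sex(raw$sex[keep]),
    asa_grade = asa[keep],
    flow_lpm = flow[keep],
    max_n2o_fraction = pct[keep] / 100,
    duration_min = dur[keep],
    procedure = procedure[keep],
    success = success[keep],
    acclimatisation_only = acc_only[keep],
    stringsAsFactors = FALSE
  )
  if (sum(bad) > 0L) {
    warning(sum(bad), " row(s) excluded by validation; see report$exclusions",
            call. = FALSE)
  }
  list(
    episodes = episodes,
    report = list(n_rows = n, n_valid = sum(keep), n_excluded = sum(bad),
                  exclusions = exclusions)
  )
}

#' Write sedation episodes back to the CSV template
#'
#' Inverse of [read_episodes()]: titration fractions are written as percent.
#' Reading the written file back yields identical field values.
#'
#' @param episodes data.frame in the internal episode layout.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_episodes <- function(episodes, path) {
  stopifnot(all(EPISODE_COLUMNS %in% names(episodes)))
  out <- episodes[EPISODE_COLUMNS]
  out$max_n2o_pct <- out$max_n2o_fraction * 100
  out$max_n2o_fraction <- NULL
  out <- out[EPISODE_FILE_COLUMNS]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read site configurations
#'
#' Sites describe how N2O is supplied (per-machine cylinders or a central
#' piped manifold) and scavenged, and whether a manifold is shared with
#' non-dental specialties — sharing makes a wastage estimate impossible.
#'
#' @param path CSV with columns
#'   `site_id,service_id,supply_type,scavenging,shared_supply`.
#' @return data.frame of validated sites.
#' @export
read_sites <- function(path) {
  raw <- .read_csv_checked(path, SITE_FILE_COLUMNS, "sites")
  supply <- tolower(trimws(raw$supply_type))
  scav <- tolower(trimws(raw$scavenging))
  shared <- .parse_logical(raw$shared_supply)
  bad_supply <- !supply %in% c("cylinder", "manifold")
  if (any(bad_supply)) {
    stop("validation failure: supply_type must be 'cylinder' or 'manifold' (rows ",
         paste(which(bad_supply), collapse = ", "), ")", call. = FALSE)
  }
  if (any(is.na(shared))) {
    stop("validation failure: shared_supply must be true/false (rows ",
         paste(which(is.na(shared)), collapse = ", "), ")", call. = FALSE)
  }
  bad_shared <- shared & supply != "manifold"
  if (any(bad_shared)) {
    stop("validation failure: shared_supply=TRUE is only valid for manifold sites (rows ",
         paste(which(bad_shared), collapse = ", "), ")", call. = FALSE)
  }
  scav[!scav %in% SCAVENGING_LEVELS] <- "central"
  data.frame(
    site_id = raw$site_id,
    service_id = raw$service_id,
    supply_type = supply,
    scavenging = scav,
    shared_supply = shared,
    stringsAsFactors = FALSE
  )
}

#' Read cylinder procurement records
#'
#' One row per (site, cylinder size) procurement figure: how many cylinders of
#' a given size were bought over a period of days.
#'
#' @param path CSV with columns `site_id,cylinder_size,quantity,period_days`.
#' @param registry Optional [cylinder_registry()]; if supplied, size codes are
#'   checked against it and unknown codes raise a lookup error naming the code.
#' @return data.frame of validated procurement records.
#' @export
read_procurement <- function(path, registry = NULL) {
  raw <- .read_csv_checked(path, PROCUREMENT_FILE_COLUMNS, "procurement")
  qty <- suppressWarnings(as.numeric(raw$quantity))
  per <- suppressWarnings(as.numeric(raw$period_days))
  size <- trimws(raw$cylinder_size)
  bad <- is.na(qty) | qty < 1 | qty != floor(qty) |
    is.na(per) | per < 1
  if (any(bad)) {
    stop("validation failure: quantity must be a positive integer and ",
         "period_days >= 1 (rows ", paste(which(bad), collapse = ", "), ")",
         call. = FALSE)
  }
  if (!is.null(registry)) cylinder_volume(registry, size)  # lookup check
  data.frame(
    site_id = raw$site_id,
    cylinder_size = size,
    quantity = as.integer(qty),
    period_days = as.integer(per),
    stringsAsFactors = FALSE
  )
}
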