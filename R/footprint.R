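# Footprint engine: machine settings + time -> volume -> mass -> kg CO2e.
#
# The audit convention is deliberately simple: the maximum titration is
# applied over the whole administration, and the initial titration increments
# are ignored (they have minimal impact on the overall volume). Everything is
# linear, so full precision is carried internally and rounding happens only
# at report formatting.

#' Administered N2O volume for one episode
#'
#' Volume (L) = total flow rate (L/min) x maximum N2O fraction x duration
#' (min). Example: a 5 LPM flow at a 30% maximum titration for 20 minutes
#' delivers 5 x 0.3 x 20 = 30 L of N2O.
#'
#' @param flow_rate_lpm Total gas-mix flow in litres per minute; > 0.
#' @param max_n2o_fraction Maximum N2O fraction of the mix, in (0, 1\].
#' @param duration_min Minutes of N2O administration; > 0.
#' @return Litres of N2O administered. Vectorised over all arguments.
#' @examples
#' episode_volume(5, 0.30, 20)  # 30 L
#' @export
episode_volume <- function(flow_rate_lpm, max_n2o_fraction, duration_min) {
  if (any(!is.finite(flow_rate_lpm)) || any(flow_rate_lpm <= 0)) {
    stop("`flow_rate_lpm` must be > 0", call. = FALSE)
  }
  if (any(!is.finite(max_n2o_fraction)) || any(max_n2o_fraction <= 0) ||
      any(max_n2o_fraction > 1)) {
    stop("`max_n2o_fraction` must be in (0, 1]", call. = FALSE)
  }
  if (any(!is.finite(duration_min)) || any(duration_min <= 0)) {
    stop("`duration_min` must be > 0", call. = FALSE)
  }
  flow_rate_lpm * max_n2o_fraction * duration_min
}

#' Convert an N2O volume to a carbon footprint
#'
#' Mass (kg) = volume (L) x density (kg/L); CO2e (kg) = mass x GWP. With the
#' default constants, 30 L of N2O is equivalent to 15.78 kg CO2e (15.7765...
#' at full precision).
#'
#' @param volume_l Litres of N2O; >= 0. Vectorised.
#' @param constants A [gas_constants()] object.
#' @return A data.frame of class `footprint_result` with columns `volume_l`,
#'   `mass_kg`, `co2e_kg`.
#' @examples
#' volume_to_co2e(30)
#' @export
volume_to_co2e <- function(volume_l, constants = gas_constants()) {
  stopifnot(inherits(constants, "gas_constants"))
  if (any(!is.finite(volume_l)) || any(volume_l < 0)) {
    stop("`volume_l` must be >= 0", call. = FALSE)
  }
  mass <- volume_l * constants$density_kg_per_l
  structure(
    data.frame(volume_l = volume_l, mass_kg = mass,
               co2e_kg = mass * constants$gwp),
    class = c("footprint_result", "data.frame")
  )
}

#' Carbon footprint of sedation episodes
#'
#' Composes [episode_volume()] and [volume_to_co2e()] over the rows of an
#' episode data.frame (as returned by [read_episodes()] or
#' [generate_cohort()]).
#'
#' @param episodes data.frame with columns `flow_lpm`, `max_n2o_fraction`,
#'   `duration_min`.
#' @param constants A [gas_constants()] object.
#' @return A `footprint_result` data.frame, one row per episode, carrying
#'   `episode_id` when present in the input.
#' @examples
#' ep <- data.frame(flow_lpm = 5, max_n2o_fraction = 0.3, duration_min = 20)
#' episode_footprint(ep)
#' @export
episode_footprint <- function(episodes, constants = gas_constants()) {
  need <- c("flow_lpm", "max_n2o_fraction", "duration_min")
  miss <- setdiff(need, names(episodes))
  if (length(miss) > 0L) {
    stop("episodes are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  vol <- episode_volume(episodes$flow_lpm, episodes$max_n2o_fraction,
                        episodes$duration_min)
  out <- volume_to_co2e(vol, constants)
  if ("episode_id" %in% names(episodes)) {
    out <- cbind(data.frame(episode_id = episodes$episode_id,
                            stringsAsFactors = FALSE), out)
    class(out) <- c("footprint_result", "data.frame")
  }
  out
}
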