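# Supply wastage: procurement -> weekly availability -> shortfall fraction.

#' Convert a period in days to weeks
#'
#' Procurement figures quoted "per year" are conventionally spread over 52
#' weeks (the convention under which 10 size-E cylinders/year is 346 L/week);
#' 364-366 day periods therefore map to exactly 52 weeks, and any other
#' period uses `period_days / 7`.
#'
#' @param period_days Positive number of days. Vectorised.
#' @return Number of weeks.
#' @export
period_weeks <- function(period_days) {
  if (any(!is.finite(period_days)) || any(period_days <= 0)) {
    stop("`period_days` must be > 0", call. = FALSE)
  }
  ifelse(period_days >= 364 & period_days <= 366, 52, period_days / 7)
}

#' Weekly procured N2O volume for one site
#'
#' Resolves each procurement record against the cylinder registry and returns
#' total litres procured per week:
#' sum(quantity x nominal volume) / weeks covered. Full precision is
#' returned; reports round to the nearest litre (10 size-E cylinders over a
#' year is printed as 346 L/week, 6 size-G as 1,038 L/week).
#'
#' @param records data.frame of procurement records for a single site
#'   (columns `cylinder_size`, `quantity`, `period_days`).
#' @param registry A [cylinder_registry()].
#' @return Litres of N2O procured per week (full precision).
#' @examples
#' recs <- data.frame(site_id = "A", cylinder_size = "E",
#'                    quantity = 10, period_days = 365)
#' round(weekly_procured_volume(recs, cylinder_registry()))  # 346
#' @export
weekly_procured_volume <- function(records, registry = cylinder_registry()) {
  stopifnot(is.data.frame(records),
            all(c("cylinder_size", "quantity", "period_days") %in% names(records)))
  if (nrow(records) == 0L) stop("no procurement records supplied", call. = FALSE)
  vols <- cylinder_volume(registry, records$cylinder_size)
  sum(records$quantity * vols / period_weeks(records$period_days))
}

#' Estimate wastage as the procured-vs-administered shortfall
#'
#' `wastage_fraction = 1 - administered / procured`. A site procuring
#' 346 L/week and administering 300 L in the audit week wastes 13%; one
#' procuring 1,038 L/week and administering 519 L wastes 50%. Negative values
#' arise when the audit week was unusually busy (more gas administered than
#' the pro-rata procured volume); they are reported verbatim, never clipped,
#' and flagged `negative_anomaly`. Fractions above `threshold` are flagged
#' `investigate`.
#'
#' @param procured_l_per_week Litres procured per week; > 0.
#' @param administered_l_per_week Litres administered per week; >= 0.
#' @param threshold Investigation threshold on the wastage fraction, in
#'   \[0, 1\]; default 0.20 ("investigate wastage over 20%").
#' @param site_id Optional identifier carried into the result.
#' @return One-row data.frame of class `wastage_estimate`: `site_id`,
#'   `procured_l_per_week`, `administered_l_per_week`, `wastage_fraction`,
#'   `wastage_pct` (nearest integer percent), `flag`.
#' @examples
#' estimate_wastage(346, 300)   # 13%, ok
#' estimate_wastage(1038, 519)  # 50%, investigate
#' @export
estimate_wastage <- function(procured_l_per_week, administered_l_per_week,
                             threshold = 0.20, site_id = NA_character_) {
  if (any(!is.finite(procured_l_per_week)) || any(procured_l_per_week <= 0)) {
    stop("`procured_l_per_week` must be > 0", call. = FALSE)
  }
  if (any(!is.finite(administered_l_per_week)) ||
      any(administered_l_per_week < 0)) {
    stop("`administered_l_per_week` must be >= 0", call. = FALSE)
  }
  if (length(threshold) != 1L || threshold < 0 || threshold > 1) {
    stop("`threshold` must be in [0, 1]", call. = FALSE)
  }
  w <- 1 - administered_l_per_week / procured_l_per_week
  flag <- ifelse(w < 0, "negative_anomaly",
                 ifelse(w > threshold, "investigate", "ok"))
  structure(
    data.frame(
      site_id = site_id,
      procured_l_per_week = procured_l_per_week,
      administered_l_per_week = administered_l_per_week,
      wastage_fraction = w,
      wastage_pct = round(w * 100),
      flag = flag,
      stringsAsFactors = FALSE
    ),
    class = c("wastage_estimate", "data.frame")
  )
}

#' Is a site eligible for a wastage estimate?
#'
#' Wastage can only be estimated when the procured gas is attributable to
#' dental sedation: always true for per-machine cylinder supplies, and true
#' for piped manifolds only when the manifold is not shared with other
#' medical or surgical specialties (e.g. theatres).
#'
#' @param sites data.frame with columns `supply_type` and `shared_supply`
#'   (as from [read_sites()]).
#' @return Logical vector, one element per site.
#' @export
eligible_for_wastage <- function(sites) {
  stopifnot(all(c("supply_type", "shared_supply") %in% names(sites)))
  !(sites$supply_type == "manifold" & sites$shared_supply)
}

#' Episodes of sedation one cylinder supports
#'
#' Nominal cylinder volume divided by the mean administered volume per
#' episode. At the national mean footprint of 28.62 kg CO2e per episode
#' (54.4 L of N2O under the default constants), one 1,800 L size-E cylinder
#' lasts about 33 episodes if there is minimal wastage.
#'
#' @param mean_episode_volume_l Mean administered volume per episode (L); > 0.
#' @param size_code Cylinder size code to look up.
#' @param registry A [cylinder_registry()].
#' @return Real-valued episode count.
#' @export
episodes_per_cylinder <- function(mean_episode_volume_l, size_code = "E",
                                  registry = cylinder_registry()) {
  if (any(!is.finite(mean_episode_volume_l)) ||
      any(mean_episode_volume_l <= 0)) {
    stop("`mean_episode_volume_l` must be > 0", call. = FALSE)
  }
  cylinder_volume(registry, size_code) / mean_episode_volume_l
}
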