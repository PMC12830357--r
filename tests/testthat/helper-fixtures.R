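# Fixture builders: everything is constructed in code at test time.

# A small data.frame of valid episodes in the internal layout.
make_episodes <- function(n = 4L,
                          service_id = "svcA",
                          site_id = "site001",
                          flow = 5, frac = 0.30, dur = 20,
                          age = 10L, asa = 1L,
                          success = TRUE,
                          procedure = "extraction") {
  data.frame(
    episode_id = sprintf("ep%03d", seq_len(n)),
    service_id = rep_len(service_id, n),
    site_id = rep_len(site_id, n),
    age_years = as.integer(rep_len(age, n)),
    sex = rep_len(c("female", "male"), n),
    asa_grade = as.integer(rep_len(asa, n)),
    flow_lpm = rep_len(flow, n),
    max_n2o_fraction = rep_len(frac, n),
    duration_min = rep_len(dur, n),
    procedure = rep_len(procedure, n),
    success = rep_len(success, n),
    acclimatisation_only = rep_len(procedure, n) == "acclimatisation",
    stringsAsFactors = FALSE
  )
}

# Episodes engineered so each has an exact target footprint in kg CO2e
# (flow = volume, fraction 1, duration 1).
make_episodes_with_co2e <- function(co2e_kg, service_id = "svcA",
                                    constants = gas_constants(), ...) {
  vol <- co2e_kg / (constants$density_kg_per_l * constants$gwp)
  ep <- make_episodes(n = length(co2e_kg), service_id = service_id, ...)
  ep$flow_lpm <- vol
  ep$max_n2o_fraction <- 1
  ep$duration_min <- 1
  ep
}

# Raw episodes CSV text, allowing malformed rows to be injected verbatim.
write_raw_episode_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- paste(c("episode_id", "service_id", "site_id", "age_years", "sex",
                    "asa_grade", "flow_lpm", "max_n2o_pct", "duration_min",
                    "procedure", "success", "acclimatisation_only"),
                  collapse = ",")
  writeLines(c(header, rows), path)
  path
}

valid_row <- function(id = "e1", flow = 5, pct = 30, dur = 20,
                      age = 10, sex = "F", asa = "I",
                      procedure = "extraction", success = "TRUE",
                      acc = "FALSE", service = "svcA", site = "s1") {
  paste(id, service, site, age, sex, asa, flow, pct, dur, procedure, success,
        acc, sep = ",")
}

make_sites <- function(n = 3L, supply = "cylinder", shared = FALSE,
                       service_id = "svcA") {
  data.frame(
    site_id = sprintf("site%03d", seq_len(n)),
    service_id = rep_len(service_id, n),
    supply_type = rep_len(supply, n),
    scavenging = rep_len("central", n),
    shared_supply = rep_len(shared, n),
    stringsAsFactors = FALSE
  )
}

write_sites_csv <- function(sites, path = tempfile(fileext = ".csv")) {
  utils::write.csv(sites, path, row.names = FALSE, quote = FALSE)
  path
}

write_procurement_csv <- function(records, path = tempfile(fileext = ".csv")) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  path
}
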