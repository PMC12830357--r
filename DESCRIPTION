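Package: n2oaudit
Title: Carbon Footprint and Wastage Auditing for Nitrous Oxide Dental Sedation
Version: 0.1.0
Authors@R: person("QIP", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for auditing the environmental impact of nitrous oxide used
    for inhalation sedation in dental services. Computes per-episode carbon
    footprints (administered gas volume, mass, and CO2-equivalent via a
    global-warming-potential factor), estimates supply wastage from cylinder
    procurement records, screens cohorts for intravenous-sedation eligibility,
    aggregates service-level and national summaries, and generates calibrated
    synthetic sedation-episode cohorts for pipeline testing when audit data
    cannot be shared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
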