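# Small in-code fixtures shared across test files.

# a 2-location, 1-year world small enough for Monte-Carlo replication
small_config <- function(pop_scale = 2e4, ...) {
  sim_config(n_locations = 2, n_years = 1, n_causes = 6,
             pop_scale = pop_scale, ...)
}

# records for one stratum with explicit counts per code
stratum_records <- function(codes, deaths, location = "loc_01", year = 2010L,
                            age = 10L, sex = "male", source_type = "VR") {
  tibble::tibble(location = location, year = year, age = age, sex = sex,
                 source_type = source_type, code = codes, deaths = deaths)
}

# total deaths per location-year-age-sex stratum
stratum_totals <- function(records) {
  dplyr::summarise(dplyr::group_by(records, location, year, age, sex),
                   deaths = sum(deaths), .groups = "drop")
}

# a proportional-only garbage map covering the toy hierarchy's two codes
proportional_map <- function(hierarchy) {
  targets <- paste(leaf_causes(hierarchy), collapse = ";")
  garbage_map(data.frame(code = c("gc_major", "gc_minor"), level = c(1L, 3L),
                         method = "proportional", targets = targets,
                         props = ""), hierarchy)
}
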