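# Shared fixtures: the study conditions and a sphere-consistent variant.

study_medium <- function() medium_properties(24, 35)

# working volume 2.8 mm3 as reported alongside ESD 1.7 mm
study_geometry <- function() aggregate_geometry(1.7, volume_mm3 = 2.8)

# sphere-consistent geometry (volume implied by the ESD)
sphere_geometry <- function() aggregate_geometry(1.7)

study_scenario <- function(noise_sd = 0, seed = 1) {
  berry_scenario(noise_sd = noise_sd, seed = seed)
}

# scenario whose local rates equal the nominal volumetric rates exactly
# (no working-volume rescaling), for point-rate round-trips
sphere_scenario <- function(noise_sd = 0, seed = 1) {
  scenario_spec(sphere_geometry(), study_medium(), model_params(),
                dark_resp_umol_cm3_h = 6.8,
                net_umol_cm3_h = c("170" = 4.8, "320" = 11),
                noise_sd = noise_sd, seed = seed)
}
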