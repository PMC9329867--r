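# shared fixtures, built in code

carot_components <- c("beta_carotene", "lutein", "zeaxanthin")

# default study conditions with all stochastic terms switched off
noise_free_config <- function(...) {
  synth_config(noise_mult = 0, noise_add_frac = 0, gain_jitter_sd = 0, ...)
}

# absorption models from the generator's ground-truth (scatter-free) extinction
truth_models <- function(cfg, d1 = cfg$d1, d2 = cfg$d2) {
  lapply(stats::setNames(carot_components, carot_components), function(comp)
    absorption_model(simulate_absorbance(comp, 1, cfg, scatter = FALSE),
                     laser_nm = cfg$laser_nm, c_ref = 1, d1 = d1, d2 = d2))
}

# attenuation-free pure-component spectra at 1 mg/mL on the intensity scale
# of the generator (contract-clean references for unmixing)
truth_unmix_refs <- function(cfg) {
  lapply(stats::setNames(carot_components, carot_components), function(comp) {
    r <- make_reference_spectrum(comp, cfg)
    r$intensity <- cfg$carot_amp * r$intensity
    r
  })
}

# attenuated, interferent-free mixture spectrum straight from ground truth
truth_mixture <- function(weights, cfg) {
  refs <- truth_unmix_refs(cfg)
  S <- Reduce(`+`, Map(function(w, r) w * r$intensity, weights, refs))
  Tu <- if (cfg$attenuation)
    carotRaman:::attenuation_profile(stats::setNames(as.list(weights),
                                                     carot_components), cfg)
  else 1
  spectrum(cfg$grid, Tu * S,
           meta = list(source_wavelength_nm = cfg$laser_nm))
}

default_interferents <- function(cfg) {
  list(water = make_reference_spectrum("water", cfg),
       bsa = make_reference_spectrum("bsa", cfg))
}

sum_reference <- function(cfg) {
  refs <- lapply(carot_components, make_reference_spectrum, cfg = cfg)
  out <- refs[[1]]
  out$intensity <- refs[[1]]$intensity + refs[[2]]$intensity + refs[[3]]$intensity
  out$meta$analyte <- "carotenoid_sum"
  out
}
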