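# Shared small fixtures. Forest settings are deliberately modest (few trees,
# short EM) so the suite stays fast; recovery checks that need power use
# larger, purpose-built configurations inline.

small_mixrf_cfg <- function(seed = 1L, n_trees = 50, max_em_iter = 3) {
  mixrf_config(n_trees = n_trees, max_em_iter = max_em_iter, seed = seed)
}

# A compact planted-signal survey: 3 countries, strong effects on the first
# two measures, no interactions, no zero inflation.
small_signal_config <- function(seed = 1L, n_features = 8,
                                farms_per_country = 20, sigma_noise = 0.2,
                                sigma_country = 1.0) {
  synthetic_config(
    n_countries = 3, farms_per_country = farms_per_country,
    n_features = n_features, feature_prevalences = 0.5,
    true_effects = c(q_001 = -0.8, q_002 = 0.8),
    interaction_terms = list(),
    sigma_country = sigma_country, sigma_noise = sigma_noise,
    zero_inflation = 0, seed = seed)
}

# Encoded design + transformed outcome for a config.
encoded_data <- function(cfg) {
  farms <- generate_farms(cfg)
  filt <- filter_features(farms)
  list(farms = farms,
       X = encode_features(farms, filt$retained),
       y = transform_amu(farms$tiddd),
       groups = farms$country,
       retained = filt$retained)
}
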