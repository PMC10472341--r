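# Shared fixture builders. Everything is generated in code under fixed seeds.

# A compact paired-survey scenario: 2 regions (20 areas), modest samples.
small_cfg <- function(seed = 7L, ...) {
  sim_config(n_regions = 2, national_sample_per_area = 80,
             regional_sample_per_area = 250, seed = seed, ...)
}

# Microdata for a single area built directly from vectors.
one_area_micro <- function(status, weight = rep(1, length(status)), area_id = 1L) {
  m <- data.frame(respondent_id = seq_along(status), area_id = area_id,
                  weight = weight, status = status, stringsAsFactors = FALSE)
  class(m) <- c("survey_microdata", "data.frame")
  m
}

# Independent one-way ANOVA ICC oracle: mean squares from aov(), then the
# two-method variance-components form (MSB - MSW) / (MSB + MSW).
icc_oracle_aov <- function(x, y) {
  long <- data.frame(v = c(x, y), id = factor(rep(seq_along(x), 2)))
  ms <- summary(stats::aov(v ~ id, data = long))[[1]][["Mean Sq"]]
  (ms[1] - ms[2]) / (ms[1] + ms[2])
}
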