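# Shared fixtures, built in code.

# tiny hand-built cohort: 3 subjects, 2 visits each, one volume region
tiny_table <- function() {
  d <- data.frame(
    subject_id = rep(c("C1", "P1", "Q1"), each = 2L),
    group = rep(c("CTRL", "PDN", "PDCI"), each = 2L),
    sex = rep(c("M", "F", "M"), each = 2L),
    education = rep(c(16, 12, 13), each = 2L),
    baseline_age = rep(c(65, 70, 72), each = 2L),
    icv = rep(c(1500, 1400, 1450), each = 2L),
    visit_index = rep(0:1, 3L),
    time_from_baseline = rep(c(0, 1.1), 3L),
    cognitive_status = c("NORMAL", "NORMAL", "NORMAL", "MCI", "MCI", "MCI"),
    mean_thickness = rep(2.5, 6L),
    brain_volume = c(1200, 1195, 1150, 1140, 1100, 1095),
    stringsAsFactors = FALSE)
  long_table(d, region_dictionary("brain_volume", "volume"))
}

# single-region config for fast simulation-based tests
roi_config <- function(n = c(CTRL = 20, PDN = 20, PDCI = 20),
                       beta = c(100, -0.5, -0.8, -0.01, -1.2, -0.005,
                                -0.3, 0.05),
                       sd0 = 5, sd1 = 0.4, corr = -0.2, residual_sd = 1.5,
                       retention = NULL, ...) {
  synthetic_config(
    n_per_group = n,
    retention = retention,
    regions = list(roi = region_spec("volume", beta,
                                     rand_cov(sd0, sd1, corr), residual_sd)),
    ...)
}

full_retention <- function(k = 5L) {
  list(CTRL = rep(1, k), PDN = rep(1, k), PDCI = rep(1, k))
}
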