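# Shared fixtures built in code at test time.

# Tiny measured spine + segment tables for aggregation tests.
tiny_tables <- function() {
  spines <- data.table::data.table(
    case_id = c(1L, 1L, 1L, 1L, 2L),
    region = "BA37",
    neuron_id = c(1L, 1L, 2L, 2L, 1L),
    segment_id = 1L,
    spine_id = c(1L, 2L, 1L, 2L, 1L),
    spine_class = c("thin", "mushroom", "thin", "stubby", "mushroom"),
    length_um = c(1.5, 1.0, 2.0, 0.8, 1.2),
    head_diameter_um = c(0.25, 0.50, 0.22, 0.45, 0.55),
    neck_diameter_um = c(0.24, 0.35, 0.21, 0.44, 0.36),
    volume_um3 = c(0.02, 0.10, 0.03, 0.08, 0.12))
  segments <- data.table::data.table(
    case_id = c(1L, 1L, 2L),
    region = "BA37",
    neuron_id = c(1L, 2L, 1L),
    segment_id = 1L,
    length_um = c(20, 25, 30))
  list(spines = spines, segments = segments)
}

# Small analysis-style table with a known linear signal.
toy_regression_table <- function(n = 24, noise = 0.2, seed = 42) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  data.table::data.table(
    case_id = seq_len(n), x1 = x1, x2 = x2, x3 = x3,
    episodic_memory = 1 + 0.8 * x1 - 0.5 * x2 + noise * rnorm(n))
}

# Small default-condition cohort used by several suites (cached per session).
small_ba37_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(cohort_params(seed = 20, regions = "BA37",
                                              beta_hd = c(BA37 = 8)))
    cache
  }
})
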