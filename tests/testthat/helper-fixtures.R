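# shared fixtures, built once per test run

# noiseless glucose-tracer simulation at default (infusion) parameters
default_glucose_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      net <- build_tca_network(network_config())
      cache <<- simulate_timecourse(
        net, tracer_spec("glucose_U13C6"),
        times = c(0, 5, 10, 15, 20, 25, 30, 60, 150))
    }
    cache
  }
})

# synthetic expression cohort with strongly planted genes (n = 200)
planted_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_expression_cohort(
        cohort_spec(n_genes = 200L, n_samples = 200L, target_r = 0.8,
                    seed = 42L))
    }
    cache
  }
})

# a long-format time course encoding prescribed enrichment values:
# citrate MID (1 - x, 0, ..., 0, x) has atom-fraction enrichment x
enrichment_tc <- function(times, values, metabolite = "citrate",
                          condition = "cond", replicate = 1L,
                          tracer = "glucose_U13C6") {
  n <- carbon_count_of(metabolite)
  rows <- mapply(function(t, x, r) {
    frac <- numeric(n + 1L)
    frac[1L] <- 1 - x
    frac[n + 1L] <- x
    data.frame(sample_id = paste0(condition, "_r", r), condition = condition,
               tracer = tracer, metabolite = metabolite, time_min = t,
               replicate = r, mass_shift = 0:n, fraction = frac,
               stringsAsFactors = FALSE)
  }, times, values, replicate, SIMPLIFY = FALSE)
  label_timecourse(do.call(rbind, rows))
}

carbon_count_of <- function(metabolite) {
  reg <- metabolite_registry()
  reg$n_carbons[match(metabolite, reg$metabolite)]
}

random_mid <- function(n_carbons) {
  f <- stats::runif(n_carbons + 1L)
  mid_vector(f / sum(f), n_carbons = n_carbons)
}
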