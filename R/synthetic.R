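#' Measurement-noise model
#'
#' Parameters of the measurement layer applied on top of noiseless
#' simulator output: per-carbon natural 13C abundance (convolved into
#' every MID) and additive truncated-Gaussian noise on isotopologue
#' fractions. Noise is modeled on fractions rather than raw ion
#' intensities because the pipeline consumes fractional distributions.
#'
#' @param p13 natural 13C abundance per carbon, in \[0, 0.5); default
#'   0.0107.
#' @param sd_mid additive noise standard deviation per isotopologue
#'   fraction (>= 0).
#' @param seed integer seed making the noise reproducible.
#' @return an object of class `"noise_model"`.
#' @export
noise_model <- function(p13 = 0.0107, sd_mid = 0.01, seed = 1L) {
  check_p13(p13)
  if (!is.numeric(sd_mid) || sd_mid < 0)
    stop_config("sd_mid must be >= 0")
  structure(list(p13 = p13, sd_mid = sd_mid, seed = as.integer(seed)),
            class = "noise_model")
}

#' Add natural abundance and measurement noise to a time course
#'
#' Convolves every measurement with natural 13C abundance (optional,
#' `convolve = TRUE`), adds zero-mean Gaussian noise of standard deviation
#' `noise$sd_mid` to each isotopologue fraction, clamps at zero, and
#' renormalizes each MID to sum 1. Deterministic given `noise$seed`.
#'
#' @param tc a [label_timecourse()].
#' @param noise a [noise_model()].
#' @param convolve logical; also apply the natural-abundance convolution
#'   (default `TRUE`).
#' @return a [label_timecourse()] of the same shape.
#' @export
add_measurement_noise <- function(tc, noise, convolve = TRUE) {
  stopifnot(inherits(tc, "label_timecourse"), inherits(noise, "noise_model"))
  df <- as.data.frame(tc)
  key <- interaction(df$sample_id, df$condition, df$tracer, df$metabolite,
                     df$time_min, df$replicate, drop = TRUE)
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(noise$seed)
  for (i in split(seq_len(nrow(df)), key)) {
    ord <- i[order(df$mass_shift[i])]
    f <- df$fraction[ord]
    if (convolve && noise$p13 > 0) {
      m <- mid_vector(f, n_carbons = length(f) - 1L)
      f <- convolve_natural_abundance(m, noise$p13)$fractions
    }
    if (noise$sd_mid > 0) {
      f <- pmax(f + stats::rnorm(length(f), 0, noise$sd_mid), 0)
      f <- f / sum(f)
    }
    df$fraction[ord] <- f
  }
  label_timecourse(df)
}

#' Simulate a measured tracer dataset
#'
#' Convenience wrapper tying the noiseless simulator to the measurement
#' layer: one noiseless simulation per condition, expanded into
#' `n_replicates` independently noised replicates.
#'
#' @param network a `"tca_network"`.
#' @param tracer a [tracer_spec()].
#' @param times sampling times, minutes.
#' @param n_replicates replicates per condition (default 5).
#' @param noise a [noise_model()].
#' @param condition condition label.
#' @param ... further arguments passed to [simulate_timecourse()].
#' @return a [label_timecourse()].
#' @export
synth_tracer_dataset <- function(network, tracer, times, n_replicates = 5L,
                                 noise = noise_model(), condition = tracer$name,
                                 ...) {
  base <- simulate_timecourse(network, tracer, times,
                              condition = condition, ...)
  reps <- lapply(seq_len(n_replicates), function(r) {
    df <- as.data.frame(base)
    df$replicate <- as.integer(r)
    df$sample_id <- paste0(condition, "_r", r)
    rep_noise <- noise_model(p13 = noise$p13, sd_mid = noise$sd_mid,
                             seed = noise$seed + 1000L * r)
    add_measurement_noise(label_timecourse(df), rep_noise)
  })
  label_timecourse(do.call(rbind, lapply(reps, as.data.frame)))
}

#' Cohort specification for synthetic expression data
#'
#' Describes a synthetic tumor expression cohort with a leukocyte-fraction
#' covariate and planted, recoverable structure: gene lists with target
#' correlation magnitudes against the covariate, and differentially
#' expressed genes with true log2 fold changes. Default planted lists are
#' the amino-acid transporter/enzyme symbols reported to correlate with
#' leukocyte infiltration in melanoma.
#'
#' @param n_genes number of genes (planted genes included).
#' @param n_samples number of samples (>= 3); default 369, the size of
#'   the TCGA melanoma leukocyte-fraction cohort this generator emulates.
#' @param planted_positive,planted_negative character vectors of gene
#'   symbols planted to correlate positively/negatively with the
#'   covariate.
#' @param target_r target correlation magnitude for planted genes, in
#'   (0, 1).
#' @param de_genes data.frame (`gene`, `log2fc`) of planted
#'   differentially expressed genes, or `NULL`.
#' @param seed integer seed.
#' @return an object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_genes = 500L, n_samples = 369L,
                        planted_positive = c("SLC7A7", "IL4I1", "SLC43A2",
                                             "SLC38A5", "ACY3", "SLC6A12",
                                             "SLC38A1", "DDO", "GLUL",
                                             "ASS1", "ABAT", "GFPT2",
                                             "SLC6A6", "SLC36A1", "SLC38A4"),
                        planted_negative = c("SLC7A5", "SLC16A10", "SLC3A1",
                                             "GLUD2", "GAD2", "SLC3A2",
                                             "SLC43A1", "PPAT", "ADSL",
                                             "CAD", "SLC6A15", "SLC7A1"),
                        target_r = 0.5, de_genes = NULL, seed = 1L) {
  planted_positive <- toupper(planted_positive)
  planted_negative <- toupper(planted_negative)
  if (length(intersect(planted_positive, planted_negative)))
    stop_config("planted gene lists must be disjoint")
  if (n_samples < 3L) stop_config("n_samples must be >= 3")
  if (!is.numeric(target_r) || abs(target_r) >= 1)
    stop_config("target |correlation| must be < 1")
  structure(
    list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
         planted_positive = planted_positive,
         planted_negative = planted_negative,
         target_r = target_r, de_genes = de_genes, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic expression cohort
#'
#' Draws a leukocyte-fraction covariate in \[0, 1\] (Beta(2, 5) quantile
#' transform of a latent standard normal), log-normal expression for all
#' genes, planted genes whose latent component has the target correlation
#' with the covariate's latent, and `GZMA`/`PRF1` columns sharing that
#' latent so that cytolytic activity (their geometric mean) correlates
#' positively with the covariate. Seeded and reproducible.
#'
#' @param spec a [cohort_spec()].
#' @return a list with `expr` (genes x samples matrix, gene symbols as
#'   rownames) and `covariate` (data.frame `sample_id`,
#'   `leukocyte_fraction`).
#' @export
generate_expression_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)
  n <- spec$n_samples
  z <- stats::rnorm(n)                         # latent infiltration axis
  leuk <- stats::qbeta(stats::pnorm(z), 2, 5)  # fraction in [0, 1]

  planted <- c(spec$planted_positive, spec$planted_negative)
  cyt_genes <- setdiff(c("GZMA", "PRF1"), planted)
  n_null <- max(spec$n_genes - length(planted) - length(cyt_genes), 0L)
  null_names <- sprintf("GENE%04d", seq_len(n_null))
  genes <- c(planted, cyt_genes, null_names)

  sigma <- 0.4  # log-scale dispersion; mild, keeps exp() near-linear
  latent_for <- function(r) r * z + sqrt(1 - r^2) * stats::rnorm(n)
  expr <- matrix(NA_real_, length(genes), n,
                 dimnames = list(genes, sprintf("S%03d", seq_len(n))))
  for (g in spec$planted_positive)
    expr[g, ] <- exp(3 + sigma * latent_for(spec$target_r))
  for (g in spec$planted_negative)
    expr[g, ] <- exp(3 + sigma * latent_for(-spec$target_r))
  for (g in intersect(c("GZMA", "PRF1"), rownames(expr)))
    if (all(is.na(expr[g, ]))) expr[g, ] <- exp(3 + sigma * latent_for(0.6))
  for (g in null_names)
    expr[g, ] <- exp(3 + sigma * stats::rnorm(n))

  # planted differential expression: shift half the samples (unused by the
  # covariate screen; consumed by the DE-table generator)
  if (!is.null(spec$de_genes)) {
    for (i in seq_len(nrow(spec$de_genes))) {
      g <- toupper(spec$de_genes$gene[i])
      if (!g %in% rownames(expr)) next
      grp <- seq_len(n) > n / 2
      expr[g, grp] <- expr[g, grp] * 2^spec$de_genes$log2fc[i]
    }
  }
  list(expr = expr,
       covariate = data.frame(sample_id = colnames(expr),
                              leukocyte_fraction = leuk,
                              stringsAsFactors = FALSE))
}

#' Generate a synthetic differential-expression table
#'
#' Null genes receive small log2 fold changes and uniform p-values;
#' planted genes receive their true log2 fold change and a small p-value.
#' The output mimics the result table of a count-model differential
#' expression analysis and is consumed by [classify_de()].
#'
#' @param genes character vector of gene symbols.
#' @param de_genes data.frame (`gene`, `log2fc`) of planted genes.
#' @param seed integer seed.
#' @return data.frame with columns `gene`, `log2fc`, `pvalue`.
#' @export
generate_de_table <- function(genes, de_genes = NULL, seed = 1L) {
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  genes <- toupper(genes)
  out <- data.frame(gene = genes,
                    log2fc = stats::rnorm(length(genes), 0, 0.4),
                    pvalue = stats::runif(length(genes)),
                    stringsAsFactors = FALSE)
  if (!is.null(de_genes)) {
    i <- match(toupper(de_genes$gene), out$gene)
    keep <- !is.na(i)
    out$log2fc[i[keep]] <- de_genes$log2fc[keep]
    out$pvalue[i[keep]] <- 10^-stats::runif(sum(keep), 6, 12)
  }
  out
}

#' Generate a synthetic prognostic Z-score table
#'
#' Null genes draw survival Z scores from the standard normal; planted
#' detrimental/beneficial genes draw from +/- U(3.5, 6).
#'
#' @param genes character vector of gene symbols.
#' @param detrimental,beneficial character vectors of planted genes.
#' @param seed integer seed.
#' @return data.frame with columns `gene`, `zscore`.
#' @export
generate_z_table <- function(genes, detrimental = character(),
                             beneficial = character(), seed = 1L) {
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  genes <- toupper(genes)
  z <- stats::rnorm(length(genes))
  z[genes %in% toupper(detrimental)] <-
    stats::runif(sum(genes %in% toupper(detrimental)), 3.5, 6)
  z[genes %in% toupper(beneficial)] <-
    -stats::runif(sum(genes %in% toupper(beneficial)), 3.5, 6)
  data.frame(gene = genes, zscore = z, stringsAsFactors = FALSE)
}

#' Generate a synthetic substrate-deprivation growth dataset
#'
#' Logistic growth counted at 24, 48 and 72 h after plating, three
#' replicate wells with three counting measurements each per condition,
#' with multiplicative log-normal noise — emulating Trypan-blue counts
#' under full versus substrate-deprived media. Counts approach a plateau
#' (horizontal asymptote) by 72 h.
#'
#' @param conditions data.frame with columns `condition`, `media`,
#'   `rate` (per hour), `plateau` (carrying capacity, cells) and
#'   optionally `n0` (seeding count, default 1e4).
#' @param seed integer seed.
#' @param cv multiplicative noise coefficient of variation (default
#'   0.05; 0 = noiseless).
#' @param times_h counting times in hours.
#' @return data.frame with columns `condition`, `media`, `time_h`,
#'   `replicate`, `measurement`, `cell_count`.
#' @export
generate_growth_dataset <- function(conditions, seed = 1L, cv = 0.05,
                                    times_h = c(24, 48, 72)) {
  req <- c("condition", "media", "rate", "plateau")
  miss <- setdiff(req, names(conditions))
  if (length(miss))
    stop_schema(paste("missing column(s):", paste(miss, collapse = ", ")))
  if (any(conditions$plateau <= 0))
    stop_config("plateau must be > 0")
  old_seed <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  n0 <- conditions$n0 %||% rep(1e4, nrow(conditions))
  rows <- list()
  for (i in seq_len(nrow(conditions))) {
    K <- conditions$plateau[i]; r <- conditions$rate[i]; N0 <- n0[i]
    for (t in times_h) {
      mu <- K / (1 + (K / N0 - 1) * exp(-r * t))
      for (rep_ in 1:3) for (meas in 1:3) {
        count <- mu * if (cv > 0) exp(stats::rnorm(1, 0, cv)) else 1
        rows[[length(rows) + 1L]] <- data.frame(
          condition = conditions$condition[i], media = conditions$media[i],
          time_h = t, replicate = rep_, measurement = meas,
          cell_count = count, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' End-to-end citrate-synthase flux recovery benchmark
#'
#' Simulates two conditions whose true citrate-synthase fluxes differ by
#' `true_ratio`, pushes both through the measurement layer
#' (natural-abundance convolution plus additive MID noise), corrects the
#' natural abundance back out, and estimates the relative V_CS.
#'
#' The scenario is constructed in the estimator's validity regime: the
#' slow-turnover `"linear_range"` network preset (the 0-30 min window
#' must be pre-steady-state for both conditions), glucose as the sole
#' acetyl-CoA source, and a fully labeled medium. The slope is fitted
#' unconstrained on the \[13C2\]citrate isotopologue channel — the
#' canonical readout of glucose's contribution to the cycle — because a
#' single channel carries far less measurement noise than a pool-average
#' enrichment, and because clamped-at-zero noise plus natural abundance
#' leave a small positive apparent baseline that the measured t = 0
#' samples expose and an intercept absorbs.
#'
#' @param true_ratio true V_CS ratio between the two conditions
#'   (default 2).
#' @param seed integer seed for the measurement noise.
#' @param sd_mid additive MID noise standard deviation (default 0.01).
#' @param n_replicates replicates per condition (default 5).
#' @param times sampling times, minutes.
#' @return a list with `estimate` (recovered ratio), `true_ratio`, and
#'   the underlying `"vcs_fit"`.
#' @export
vcs_recovery_benchmark <- function(true_ratio = 2, seed = 1L,
                                   sd_mid = 0.01, n_replicates = 5L,
                                   times = seq(0, 30, 2.5)) {
  tr <- tracer_spec("glucose_U13C6", plateau_enrichment = 1)
  mk <- function(vcs, cond, sub_seed) {
    net <- build_tca_network(
      network_config("linear_range", vcs = vcs, acetyl_from_pdh = 1))
    synth_tracer_dataset(net, tr, times, n_replicates,
                         noise_model(sd_mid = sd_mid, seed = sub_seed),
                         condition = cond, metabolites = "citrate")
  }
  tc <- label_timecourse(rbind(
    as.data.frame(mk(1, "reference", seed)),
    as.data.frame(mk(true_ratio, "test", seed + 7919L))))
  s_ref <- fit_label_slope(tc, condition = "reference",
                           through_origin = FALSE,
                           isotopologue = 2L)$slope
  s_test <- fit_label_slope(tc, condition = "test",
                            through_origin = FALSE,
                            isotopologue = 2L)$slope
  list(estimate = relative_vcs(s_test, s_ref), true_ratio = true_ratio,
       slopes = c(reference = s_ref, test = s_test))
}
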