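#' Fit the 13C label-accumulation slope
#'
#' Least-squares slope of enrichment versus time, constrained through the
#' origin (label is zero at infusion start). With measurements at a single
#' positive time point the slope is the origin ratio `mean(E(t*)) / t*`,
#' the in vivo convention for a single steady-state-window sample. The
#' standard error comes from the fit residuals (single-point mode: from
#' the replicate spread of `E/t`).
#'
#' @param tc a [label_timecourse()].
#' @param metabolite metabolite whose enrichment is fitted (default
#'   citrate).
#' @param window numeric `(t_start, t_end)` in minutes.
#' @param condition restrict to one condition (default: all rows; supply
#'   when the table holds several).
#' @param mode enrichment mode, see [enrichment()].
#' @param through_origin logical; `FALSE` fits an unconstrained line.
#' @param isotopologue optional integer mass shift; when supplied the
#'   response is that isotopologue's fraction (e.g. 2 for the
#'   \[13C2\]citrate readout under uniformly labeled glucose) instead of
#'   a pool-average enrichment.
#' @return a list with `slope` (enrichment/min), `se`, `n`, `window`,
#'   `metabolite`, `condition`.
#' @export
fit_label_slope <- function(tc, metabolite = "citrate", window = c(0, 30),
                            condition = NULL,
                            mode = c("atom_fraction", "labeled_fraction"),
                            through_origin = TRUE, isotopologue = NULL) {
  mode <- match.arg(mode)
  if (is.null(isotopologue)) {
    et <- enrichment_table(tc, mode = mode)
  } else {
    sel <- tc$mass_shift == as.integer(isotopologue)
    et <- as.data.frame(tc)[sel, , drop = FALSE]
    names(et)[names(et) == "fraction"] <- "enrichment"
  }
  et <- et[et$metabolite == metabolite, , drop = FALSE]
  if (!is.null(condition)) et <- et[et$condition == condition, , drop = FALSE]
  et <- et[et$time_min >= window[1L] & et$time_min <= window[2L], ,
           drop = FALSE]
  if (!nrow(et))
    stop_data(sprintf("no %s measurements in window [%g, %g]",
                      metabolite, window[1L], window[2L]))
  tt <- et$time_min; ee <- et$enrichment
  distinct <- unique(tt)
  if (length(distinct) == 1L) {
    if (distinct == 0)
      tcaflux_error("fit", "only t = 0 measurements; slope undefined")
    ratios <- ee / tt
    slope <- mean(ratios)
    se <- if (length(ratios) > 1L)
      stats::sd(ratios) / sqrt(length(ratios)) else NA_real_
  } else if (through_origin) {
    slope <- sum(tt * ee) / sum(tt^2)
    r <- ee - slope * tt
    dfree <- length(ee) - 1L
    se <- if (dfree > 0) sqrt(sum(r^2) / dfree / sum(tt^2)) else NA_real_
  } else {
    sxx <- sum((tt - mean(tt))^2)
    slope <- sum((tt - mean(tt)) * (ee - mean(ee))) / sxx
    r <- ee - mean(ee) - slope * (tt - mean(tt))
    dfree <- length(ee) - 2L
    se <- if (dfree > 0) sqrt(sum(r^2) / dfree / sxx) else NA_real_
  }
  list(slope = slope, se = se, n = length(ee), window = window,
       metabolite = metabolite,
       condition = condition %||% paste(unique(et$condition), collapse = "+"))
}

#' Relative citrate-synthase flux from two slopes
#'
#' Relative V_CS is the label-accumulation slope normalized to a
#' reference condition's slope; the reference against itself is 1.
#'
#' @param slope enrichment slope of the condition of interest.
#' @param reference_slope enrichment slope of the reference condition
#'   (> 0).
#' @return dimensionless relative flux.
#' @export
relative_vcs <- function(slope, reference_slope) {
  if (!is.finite(reference_slope) || reference_slope <= 0)
    stop_domain("reference slope must be > 0")
  slope / reference_slope
}

#' Fit relative citrate-synthase fluxes across conditions
#'
#' The modelling interface of the flux module: fits the citrate (or other
#' metabolite) label-accumulation slope for every condition in a time
#' course and normalizes each to a reference condition, giving relative
#' V_CS per condition.
#'
#' Two measurement conventions are supported: `mode = "window"` fits the
#' origin-constrained least-squares slope over `window` (the in vitro
#' 0-30 min convention), and `mode = "single_point"` uses the origin
#' ratio `E(t*)/t*` at `single_time` (the in vivo 60 min convention).
#'
#' @param tc a [label_timecourse()] holding one or more conditions.
#' @param reference condition used as denominator (default: first
#'   condition in the table).
#' @param metabolite metabolite fitted (default citrate).
#' @param mode `"window"` or `"single_point"`.
#' @param window fitting window, minutes (window mode).
#' @param single_time sampling time, minutes (single-point mode).
#' @param enrichment_mode see [enrichment()].
#' @return an object of class `"vcs_fit"` with per-condition slopes,
#'   standard errors and relative V_CS; supports `print()`, `summary()`,
#'   `coef()` (relative V_CS), `predict()`, `residuals()` and `plot()`.
#' @examples
#' net1 <- build_tca_network(network_config("linear_range"))
#' net2 <- build_tca_network(network_config("linear_range", vcs = 2))
#' tr <- tracer_spec("glucose_U13C6")
#' tc <- rbind(
#'   simulate_timecourse(net1, tr, seq(0, 30, 10), condition = "A"),
#'   simulate_timecourse(net2, tr, seq(0, 30, 10), condition = "B"))
#' fit <- vcs_fit(label_timecourse(tc), reference = "A")
#' coef(fit)
#' @export
vcs_fit <- function(tc, reference = NULL, metabolite = "citrate",
                    mode = c("window", "single_point"), window = c(0, 30),
                    single_time = 60,
                    enrichment_mode = c("atom_fraction", "labeled_fraction")) {
  mode <- match.arg(mode)
  enrichment_mode <- match.arg(enrichment_mode)
  conds <- unique(tc$condition)
  reference <- reference %||% conds[1L]
  if (!reference %in% conds)
    stop_lookup(sprintf("reference condition '%s' not in time course",
                        reference))
  if (mode == "single_point") window <- c(single_time, single_time)
  fits <- lapply(conds, function(cn)
    fit_label_slope(tc, metabolite = metabolite, window = window,
                    condition = cn, mode = enrichment_mode))
  slopes <- data.frame(
    condition = conds,
    tracer = vapply(conds, function(cn)
      tc$tracer[tc$condition == cn][1L], ""),
    slope = vapply(fits, `[[`, 0, "slope"),
    se = vapply(fits, `[[`, 0, "se"),
    n = vapply(fits, `[[`, 0L, "n"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  ref_slope <- slopes$slope[slopes$condition == reference]
  slopes$relative_vcs <- vapply(slopes$slope, relative_vcs,
                                0, reference_slope = ref_slope)
  et <- enrichment_table(tc, mode = enrichment_mode)
  et <- et[et$metabolite == metabolite &
             et$time_min >= window[1L] & et$time_min <= window[2L], ,
           drop = FALSE]
  structure(
    list(slopes = slopes, reference = reference, metabolite = metabolite,
         mode = mode, window = window,
         enrichment_mode = enrichment_mode, data = et),
    class = "vcs_fit"
  )
}

#' @export
print.vcs_fit <- function(x, ...) {
  cat(sprintf(
    "Relative citrate-synthase flux (%s %s, %s slope over [%g, %g] min)\n",
    x$metabolite, x$enrichment_mode, x$mode, x$window[1L], x$window[2L]))
  cat(sprintf("Reference condition: %s\n", x$reference))
  print(x$slopes, digits = 4)
  invisible(x)
}

#' @export
summary.vcs_fit <- function(object, ...) {
  s <- object$slopes
  s$rel_se <- s$se / s$slope
  structure(list(fit = object, table = s), class = "summary.vcs_fit")
}

#' @export
print.summary.vcs_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("n = %d enrichment measurements\n", nrow(x$fit$data)))
  invisible(x)
}

#' @export
coef.vcs_fit <- function(object, ...) {
  stats::setNames(object$slopes$relative_vcs, object$slopes$condition)
}

#' @export
predict.vcs_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data[c("condition", "time_min")]
  s <- object$slopes
  slope <- s$slope[match(newdata$condition, s$condition)]
  slope * newdata$time_min
}

#' @export
residuals.vcs_fit <- function(object, ...) {
  object$data$enrichment - predict(object, object$data)
}

#' @export
plot.vcs_fit <- function(x, ...) {
  d <- x$data
  conds <- unique(d$condition)
  graphics::plot(d$time_min, d$enrichment,
                 col = match(d$condition, conds), pch = 16,
                 xlab = "time (min)",
                 ylab = paste0("13C ", x$metabolite, " enrichment"), ...)
  for (i in seq_along(conds)) {
    sl <- x$slopes$slope[x$slopes$condition == conds[i]]
    graphics::abline(0, sl, col = i)
  }
  graphics::legend("topleft", legend = conds, col = seq_along(conds),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Test attainment of isotopic steady state
#'
#' Two-tailed unpaired Student's t test comparing replicate enrichments at
#' two infusion durations (default 60 vs 150 min); steady state is
#' declared when equality is *not* rejected at `alpha`. This mirrors the
#' usual 60/150-min infusion comparison and is a non-equivalence test:
#' failing to reject is weaker evidence than demonstrating equivalence.
#'
#' @param tc a [label_timecourse()] with replicates at both times.
#' @param metabolite metabolite tested (default citrate).
#' @param t1,t2 the two infusion durations, minutes.
#' @param alpha significance level (default 0.05).
#' @param condition restrict to one condition.
#' @param mode enrichment mode.
#' @return a list with `steady` (logical), `p`, `mean_t1`, `mean_t2`,
#'   `t1`, `t2`, `alpha`.
#' @export
steady_state_check <- function(tc, metabolite = "citrate", t1 = 60,
                               t2 = 150, alpha = 0.05, condition = NULL,
                               mode = c("atom_fraction", "labeled_fraction")) {
  mode <- match.arg(mode)
  et <- enrichment_table(tc, mode = mode)
  et <- et[et$metabolite == metabolite, , drop = FALSE]
  if (!is.null(condition)) et <- et[et$condition == condition, , drop = FALSE]
  e1 <- et$enrichment[et$time_min == t1]
  e2 <- et$enrichment[et$time_min == t2]
  if (length(e1) < 2L || length(e2) < 2L)
    stop_data(sprintf("need >= 2 replicates at both t=%g and t=%g", t1, t2))
  ht <- students_t_test(e1, e2)
  list(steady = ht$p >= alpha, p = ht$p, mean_t1 = mean(e1),
       mean_t2 = mean(e2), t1 = t1, t2 = t2, alpha = alpha)
}

#' Glycolysis readout
#'
#' Ratio of fully labeled pyruvate to fully labeled glucose
#' (\[13C3\]pyruvate / \[13C6\]glucose), used as a relative readout of
#' glycolysis under the uniformly labeled glucose tracer.
#'
#' @param pyruvate_m3 \[13C3\]pyruvate fraction.
#' @param glucose_m6 \[13C6\]glucose fraction (> 0).
#' @return dimensionless ratio.
#' @export
glycolysis_index <- function(pyruvate_m3, glucose_m6) {
  if (!is.finite(glucose_m6) || glucose_m6 <= 0)
    stop_domain("glucose M+6 fraction must be > 0")
  pyruvate_m3 / glucose_m6
}

#' Anaplerotic label-dilution profile
#'
#' Per-metabolite steady-state enrichment and a dilution index
#' `1 - E_metabolite / E_reference` quantifying how much unlabeled
#' (anaplerotic) carbon has diluted the label downstream of the
#' reference. The reference defaults to citrate, the first labeled
#' TCA-proximal metabolite for the acetyl-CoA-entry tracers; use
#' glutamate for the glutamine tracer. Indices are clamped to \[0, 1\]
#' with clamping flagged. The dilution index is one reasonable
#' operationalization of "label dilution through the cycle"; it is
#' labeled as such in outputs.
#'
#' @param tc a [label_timecourse()] at (or near) isotopic steady state.
#' @param reference_metabolite reference for the dilution index.
#' @param time time point used (default: latest in the table).
#' @param condition restrict to one condition.
#' @param mode enrichment mode.
#' @param steady result of [steady_state_check()], or `NULL`; when `NULL`
#'   the output is flagged `steady_checked = FALSE` (user override).
#' @return a data.frame of class `"dilution_profile"` with columns
#'   `metabolite`, `enrichment`, `dilution_index`, `clamped`, plus
#'   attributes `reference`, `time`, `steady_checked`.
#' @export
dilution_profile <- function(tc, reference_metabolite = "citrate",
                             time = NULL, condition = NULL,
                             mode = c("atom_fraction", "labeled_fraction"),
                             steady = NULL) {
  mode <- match.arg(mode)
  et <- enrichment_table(tc, mode = mode)
  if (!is.null(condition)) et <- et[et$condition == condition, , drop = FALSE]
  time <- time %||% max(et$time_min)
  et <- et[et$time_min == time, , drop = FALSE]
  if (!nrow(et)) stop_data(sprintf("no measurements at t=%g", time))
  mets <- unique(et$metabolite)
  if (!reference_metabolite %in% mets)
    stop_lookup(sprintf("reference metabolite '%s' not measured",
                        reference_metabolite))
  e_mean <- vapply(mets, function(m)
    mean(et$enrichment[et$metabolite == m]), 0)
  e_ref <- e_mean[[reference_metabolite]]
  if (e_ref <= 0)
    tcaflux_error("degenerate_reference", "reference enrichment is 0")
  raw <- 1 - e_mean / e_ref
  idx <- pmin(pmax(raw, 0), 1)
  out <- data.frame(metabolite = mets, enrichment = unname(e_mean),
                    dilution_index = unname(idx),
                    clamped = unname(abs(idx - raw) > 1e-12),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, class = c("dilution_profile", "data.frame"),
            reference = reference_metabolite, time = time,
            steady_checked = !is.null(steady) && isTRUE(steady$steady))
}

#' Lactate production rate
#'
#' Rate of lactate accumulation in the medium, assumed linear over the
#' incubation, normalized to total protein.
#'
#' @param conc_start,conc_end medium lactate concentration at the start
#'   and end of the incubation.
#' @param hours incubation length, hours (default 6).
#' @param protein_mg total protein, mg (> 0).
#' @return rate in concentration units per hour per mg protein.
#' @export
lactate_production_rate <- function(conc_start, conc_end, hours = 6,
                                    protein_mg) {
  if (!is.finite(hours) || hours <= 0)
    stop_domain("hours must be > 0")
  if (!is.finite(protein_mg) || protein_mg <= 0)
    stop_domain("protein_mg must be > 0")
  (conc_end - conc_start) / hours / protein_mg
}
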