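#' @name tca_simulator
#' @title Positional-isotopomer simulation of 13C label propagation
#' @description
#' The simulator tracks, for every pool, a probability vector over
#' positional labeling states (length `2^c` for a `c`-carbon pool) and
#' integrates the isotopomer balance equations with a fixed-step 4th-order
#' Runge-Kutta scheme. Positional (bit-vector) resolution is required
#' because the two oxidative decarboxylations remove *specific* carbons:
#' mass-only bookkeeping cannot reproduce the first-turn carbon fates of
#' the tracer schemes (citrate M+2 from glucose/palmitate via acetyl-CoA,
#' M+4 from glutamine via alpha-ketoglutarate).
#'
#' Carbon conventions: citrate positions 1-4 derive from oxaloacetate and
#' 5-6 from the acetyl unit; the isocitrate- and alpha-ketoglutarate-
#' dehydrogenase steps each release an oxaloacetate-derived carbon, so
#' acetyl carbons survive the first turn. Succinate (and the fumarate step
#' into malate) is a symmetric intermediate: every formed state is
#' averaged with its carbon-reversed twin.
NULL

# ---- bit-level machinery ------------------------------------------------

bit_of <- function(s, b) bitwAnd(bitwShiftR(s, b - 1L), 1L)

popcounts <- function(n_bits) {
  s <- 0:(2^n_bits - 1L)
  out <- integer(length(s))
  for (b in seq_len(n_bits)) out <- out + bit_of(s, b)
  out
}

# projection matrix keeping source bits `keep` (in order) as target bits
proj_matrix <- function(n_src_bits, keep) {
  s <- 0:(2^n_src_bits - 1L)
  t <- integer(length(s))
  for (i in seq_along(keep)) {
    t <- t + bit_of(s, keep[i]) * 2L^(i - 1L)
  }
  P <- matrix(0, 2^length(keep), 2^n_src_bits)
  P[cbind(t + 1L, s + 1L)] <- 1
  P
}

# symmetrization: average each state with its bit-reversed twin
sym_matrix <- function(n_bits) {
  s <- 0:(2^n_bits - 1L)
  r <- integer(length(s))
  for (b in seq_len(n_bits)) {
    r <- r + bit_of(s, b) * 2L^(n_bits - b)
  }
  R <- matrix(0, 2^n_bits, 2^n_bits)
  R[cbind(r + 1L, s + 1L)] <- 1
  (diag(2^n_bits) + R) / 2
}

# mass-isotopologue marginalization matrix: (c+1) x 2^c
mid_matrix <- function(n_bits) {
  pc <- popcounts(n_bits)
  B <- matrix(0, n_bits + 1L, 2^n_bits)
  B[cbind(pc + 1L, seq_along(pc))] <- 1
  B
}

# reaction carbon maps, resolved once per simulation
reaction_maps <- function() {
  sym4 <- sym_matrix(4L)
  list(
    pdh = proj_matrix(3L, c(2L, 3L)),          # pyruvate C1 lost as CO2
    idh = proj_matrix(6L, 2:6),                # citrate C1 (OAA) lost
    akgdh_sym = sym4 %*% proj_matrix(5L, 2:5), # aKG C1 (OAA) lost, then sym
    identity_sym = sym4                        # fumarate symmetry
  )
}

# ---- simulator ----------------------------------------------------------

#' Simulate a 13C label time course
#'
#' Integrates positional-isotopomer balance equations for a balanced
#' [build_tca_network()] model under a [tracer_spec()], starting from
#' all-unlabeled pools, and reports mass-isotopologue distributions of
#' the requested metabolites at the requested times.
#'
#' With `first_turn_only = TRUE` the recycling edge downstream of the
#' tracer's entry point is severed (malate-to-oxaloacetate for tracers
#' entering at acetyl-CoA; citrate-to-alpha-ketoglutarate for the
#' glutamine tracer), so the partner pool of each condensation stays
#' unlabeled and the output reproduces the first-turn labeling schemes
#' (citrate M+2 for glucose/palmitate, M+4 for glutamine).
#'
#' @param network a `"tca_network"` from [build_tca_network()].
#' @param tracer a [tracer_spec()].
#' @param times sorted nonnegative sampling times, minutes.
#' @param metabolites metabolites to report (default: citrate, glutamate,
#'   succinate, malate, pyruvate).
#' @param step fixed Runge-Kutta step in minutes (`<= 0.1`; default 0.05).
#' @param first_turn_only logical; sever label recycling (see Details).
#' @param condition condition label written into the output.
#' @param replicate replicate index written into the output.
#' @return a `"label_timecourse"`: a long data.frame with columns
#'   `sample_id`, `condition`, `tracer`, `metabolite`, `time_min`,
#'   `replicate`, `mass_shift`, `fraction`.
#' @examples
#' net <- build_tca_network(network_config())
#' tc <- simulate_timecourse(net, tracer_spec("glucose_U13C6"),
#'                           times = c(0, 10, 20, 30))
#' head(as.data.frame(tc))
#' @export
simulate_timecourse <- function(network, tracer, times,
                                metabolites = c("citrate", "glutamate",
                                                "succinate", "malate",
                                                "pyruvate"),
                                step = 0.05, first_turn_only = FALSE,
                                condition = tracer$name, replicate = 1L) {
  stopifnot(inherits(network, "tca_network"), inherits(tracer, "tracer_spec"))
  if (length(times) < 1L || any(!is.finite(times)) || any(times < 0) ||
      is.unsorted(times))
    stop_data("times must be sorted, finite and >= 0")
  if (!is.finite(step) || step <= 0 || step > 0.1)
    stop_config("step must be in (0, 0.1] minutes")
  unknown <- setdiff(metabolites, names(network$carbons))
  if (length(unknown))
    stop_config(paste("unknown metabolite(s):", paste(unknown, collapse = ", ")))

  maps <- reaction_maps()
  carbons <- network$carbons
  pool_names <- names(carbons)
  # initial condition: all pools unlabeled (state 0)
  state <- lapply(pool_names, function(p) {
    x <- numeric(2^carbons[[p]]); x[1L] <- 1; x
  })
  names(state) <- pool_names

  inflows <- network$inflows
  if (first_turn_only) {
    cut_from <- if (tracer$entry_node == "acetyl_coa") {
      c(pool = "oxaloacetate", from = "malate")
    } else {
      c(pool = "alpha_ketoglutarate", from = "citrate")
    }
    inflows <- lapply(inflows, function(i) {
      if (i$type == "transfer" && i$pool == cut_from[["pool"]] &&
          i$from == cut_from[["from"]]) {
        list(pool = i$pool, rate = i$rate, type = "unlabeled")
      } else i
    })
  }

  # resolve each inflow into a closure ingredient list
  chan_of_tracer <- c(glucose_U13C6 = "glycolysis",
                      palmitate_U13C16 = "fatty_acid",
                      glutamine_U13C5 = "glutamine")
  resolved <- lapply(inflows, function(i) {
    if (i$rate == 0) return(NULL)
    r <- i
    if (i$type == "transfer" && i$map != "identity")
      r$M <- maps[[i$map]]
    if (i$type == "source") {
      nc <- carbons[[i$pool]]
      lab <- numeric(2^nc); lab[2^nc] <- 1      # fully labeled unit
      unl <- numeric(2^nc); unl[1L] <- 1
      r$labeled_state <- lab
      r$unlabeled_state <- unl
      r$active <- identical(chan_of_tracer[[tracer$name]], i$channel)
    }
    r
  })
  resolved <- Filter(Negate(is.null), resolved)

  sizes <- network$pools
  pm <- tracer$plasma_model
  f_prime <- min(pm$prime_multiplier * pm$rate_constant, 1)
  enr_at <- function(t)
    pm$plateau_enrichment * (1 - (1 - f_prime) * exp(-pm$rate_constant * t))

  deriv <- function(t, x) {
    e <- enr_at(t)
    d <- lapply(x, function(v) numeric(length(v)))
    for (i in resolved) {
      s_in <- switch(i$type,
        transfer = if (is.null(i$M)) x[[i$from]] else
          as.numeric(i$M %*% x[[i$from]]),
        condense = as.numeric(outer(x[[i$from[1L]]], x[[i$from[2L]]])),
        unlabeled = { u <- numeric(length(x[[i$pool]])); u[1L] <- 1; u },
        source = if (i$active)
          e * i$labeled_state + (1 - e) * i$unlabeled_state
        else i$unlabeled_state
      )
      d[[i$pool]] <- d[[i$pool]] + (i$rate / sizes[[i$pool]]) * (s_in - x[[i$pool]])
    }
    d
  }

  add_scaled <- function(x, d, h)
    mapply(function(v, dv) v + h * dv, x, d, SIMPLIFY = FALSE)

  t_end <- max(times)
  n_steps <- ceiling(t_end / step - 1e-9)
  record_steps <- as.integer(round(times / step))
  mids <- mid_mats_for(metabolites, carbons)
  out <- vector("list", length(times))
  rec_i <- 1L

  record <- function(t_now, x) {
    rows <- lapply(metabolites, function(m) {
      frac <- as.numeric(mids[[m]] %*% x[[m]])
      data.frame(metabolite = m, time_min = t_now,
                 mass_shift = seq_along(frac) - 1L, fraction = frac,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }

  x <- state
  while (rec_i <= length(times) && record_steps[rec_i] == 0L) {
    out[[rec_i]] <- record(times[rec_i], x)
    rec_i <- rec_i + 1L
  }
  if (n_steps > 0) {
    for (k in seq_len(n_steps)) {
      t0 <- (k - 1L) * step
      k1 <- deriv(t0, x)
      k2 <- deriv(t0 + step / 2, add_scaled(x, k1, step / 2))
      k3 <- deriv(t0 + step / 2, add_scaled(x, k2, step / 2))
      k4 <- deriv(t0 + step, add_scaled(x, k3, step))
      x <- mapply(function(v, a, b, c2, d2)
        v + step / 6 * (a + 2 * b + 2 * c2 + d2),
        x, k1, k2, k3, k4, SIMPLIFY = FALSE)
      if (any(vapply(x, min, 0) < -1e-6))
        stop_integration(
          "state component fell below -1e-6; use a smaller step")
      while (rec_i <= length(times) && record_steps[rec_i] == k) {
        out[[rec_i]] <- record(times[rec_i], x)
        rec_i <- rec_i + 1L
      }
    }
  }

  df <- do.call(rbind, out)
  df <- data.frame(
    sample_id = paste0(condition, "_r", replicate),
    condition = condition, tracer = tracer$name,
    metabolite = df$metabolite, time_min = df$time_min,
    replicate = as.integer(replicate), mass_shift = df$mass_shift,
    fraction = df$fraction, stringsAsFactors = FALSE
  )
  label_timecourse(df)
}

mid_mats_for <- function(metabolites, carbons) {
  out <- lapply(metabolites, function(m) mid_matrix(carbons[[m]]))
  names(out) <- metabolites
  out
}

#' Long-format label time course
#'
#' Validates and classes a long-format table of mass-isotopologue
#' fractions (columns `sample_id`, `condition`, `tracer`, `metabolite`,
#' `time_min`, `replicate`, `mass_shift`, `fraction`).
#'
#' @param df a data.frame with the columns above.
#' @param renormalize_tol measurements whose fractions sum within this
#'   distance of 1 are renormalized; larger deviations are rejected.
#' @return an object of classes `"label_timecourse"` and `"data.frame"`.
#' @export
label_timecourse <- function(df, renormalize_tol = 1e-3) {
  req <- c("sample_id", "condition", "tracer", "metabolite", "time_min",
           "replicate", "mass_shift", "fraction")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_schema(paste("missing column(s):", paste(miss, collapse = ", ")))
  if (any(df$fraction < -1e-9)) {
    row <- which(df$fraction < -1e-9)[1L]
    stop_validation(sprintf("negative fraction at row %d", row))
  }
  key <- interaction(df$sample_id, df$condition, df$tracer, df$metabolite,
                     df$time_min, df$replicate, drop = TRUE)
  sums <- tapply(df$fraction, key, sum)
  off <- abs(sums - 1) > renormalize_tol
  if (any(off)) {
    bad_key <- names(sums)[off][1L]
    row <- which(as.character(key) == bad_key)[1L]
    stop_validation(sprintf(
      "MID fractions sum to %.4f (row %d); tolerance %.0e",
      sums[off][1L], row, renormalize_tol))
  }
  df$fraction <- df$fraction / as.numeric(sums[key])
  class(df) <- c("label_timecourse", "data.frame")
  df
}

#' @export
print.label_timecourse <- function(x, ...) {
  cat(sprintf(
    "label_timecourse: %d measurements (%s), %d time point(s), tracer(s): %s\n",
    nrow(x), paste(unique(x$metabolite), collapse = ", "),
    length(unique(x$time_min)), paste(unique(x$tracer), collapse = ", ")))
  invisible(x)
}

#' Extract one MID from a time course
#'
#' @param tc a [label_timecourse()].
#' @param metabolite metabolite name.
#' @param time time point, minutes.
#' @param condition condition label (default: first in the table).
#' @param replicate replicate index (default: first matching).
#' @return a [mid_vector()].
#' @export
tc_mid <- function(tc, metabolite, time, condition = NULL, replicate = NULL) {
  sel <- tc$metabolite == metabolite & tc$time_min == time
  if (!is.null(condition)) sel <- sel & tc$condition == condition
  if (!is.null(replicate)) sel <- sel & tc$replicate == replicate
  sub <- tc[sel, , drop = FALSE]
  if (!nrow(sub))
    stop_data(sprintf("no rows for %s at t=%g", metabolite, time))
  sub <- sub[sub$replicate == sub$replicate[1L] &
               sub$condition == sub$condition[1L], , drop = FALSE]
  sub <- sub[order(sub$mass_shift), , drop = FALSE]
  mid_vector(sub$fraction, metabolite = metabolite)
}

#' Per-measurement enrichment table
#'
#' Collapses a long time course into one enrichment value per measurement.
#'
#' @param tc a [label_timecourse()].
#' @param mode passed to [enrichment()].
#' @return a data.frame with columns `condition`, `tracer`, `metabolite`,
#'   `time_min`, `replicate`, `enrichment`.
#' @export
enrichment_table <- function(tc, mode = c("atom_fraction", "labeled_fraction")) {
  mode <- match.arg(mode)
  key <- interaction(tc$condition, tc$tracer, tc$metabolite, tc$time_min,
                     tc$replicate, drop = TRUE)
  idx <- split(seq_len(nrow(tc)), key)
  rows <- lapply(idx, function(i) {
    sub <- tc[i, , drop = FALSE]
    sub <- sub[order(sub$mass_shift), , drop = FALSE]
    m <- mid_vector(sub$fraction, metabolite = sub$metabolite[1L])
    data.frame(condition = sub$condition[1L], tracer = sub$tracer[1L],
               metabolite = sub$metabolite[1L], time_min = sub$time_min[1L],
               replicate = sub$replicate[1L],
               enrichment = enrichment(m, mode = mode),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$condition, out$metabolite, out$time_min, out$replicate), ,
      drop = FALSE]
}

#' @export
plot.label_timecourse <- function(x, metabolite = "citrate",
                                  mode = "atom_fraction", ...) {
  et <- enrichment_table(x, mode = mode)
  et <- et[et$metabolite == metabolite, , drop = FALSE]
  conds <- unique(et$condition)
  graphics::plot(et$time_min, et$enrichment, type = "n",
                 xlab = "time (min)", ylab = paste0("13C enrichment (", mode, ")"),
                 main = metabolite, ...)
  for (i in seq_along(conds)) {
    sub <- et[et$condition == conds[i], ]
    agg <- stats::aggregate(enrichment ~ time_min, sub, mean)
    graphics::lines(agg$time_min, agg$enrichment, col = i)
    graphics::points(sub$time_min, sub$enrichment, col = i, pch = 16, cex = 0.6)
  }
  graphics::legend("bottomright", legend = conds, col = seq_along(conds),
                   lty = 1, bty = "n")
  invisible(x)
}
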