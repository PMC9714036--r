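#' Natural-abundance convolution and correction
#'
#' About 1.07% of carbon is naturally 13C. An instrument therefore observes
#' a MID in which every carbon that is *not* tracer-labeled is independently
#' heavy with probability `p13`; the observed distribution is the true MID
#' convolved with a binomial over the unlabeled carbons:
#' \deqn{O_j = \sum_{k \le j} M_k \, \mathrm{Binom}(j-k;\, n-k,\, p_{13}).}
#' `convolve_natural_abundance()` applies this forward map (used by the
#' synthetic-data generator); `correct_natural_abundance()` inverts it by
#' solving the triangular linear system, clamping any small negative
#' components to zero and renormalizing. Only skeleton carbons are
#' convolved (no derivatization-atom correction).
#'
#' @param mid a true (tracer-only) MID of class `"mid"`.
#' @param p13 per-carbon natural 13C abundance, in \[0, 0.5); default
#'   0.0107.
#' @return a `"mid"` of the same metabolite.
#' @examples
#' m <- mid_vector(c(1, 0, 0), metabolite = "acetyl_coa")
#' obs <- convolve_natural_abundance(m)
#' correct_natural_abundance(obs)
#' @export
convolve_natural_abundance <- function(mid, p13 = 0.0107) {
  validate_mid(mid)
  check_p13(p13)
  A <- na_matrix(mid$n_carbons, p13)
  out <- as.numeric(A %*% mid$fractions)
  mid_vector(out / sum(out), metabolite = mid$metabolite,
             n_carbons = mid$n_carbons)
}

#' @param observed the measured MID of class `"mid"`.
#' @rdname convolve_natural_abundance
#' @export
correct_natural_abundance <- function(observed, p13 = 0.0107) {
  validate_mid(observed)
  check_p13(p13)
  A <- na_matrix(observed$n_carbons, p13)
  # lower-triangular with positive diagonal: exact forward solve
  x <- solve(A, observed$fractions)
  x <- pmax(x, 0)
  s <- sum(x)
  if (s <= 0) stop_validation("correction produced an all-zero MID")
  mid_vector(x / s, metabolite = observed$metabolite,
             n_carbons = observed$n_carbons)
}

#' Natural-abundance correction of a whole time course
#'
#' Applies [correct_natural_abundance()] to every measurement of a long
#' time course.
#'
#' @param tc a [label_timecourse()].
#' @param p13 per-carbon natural 13C abundance.
#' @return a corrected [label_timecourse()].
#' @export
correct_timecourse <- function(tc, p13 = 0.0107) {
  stopifnot(inherits(tc, "label_timecourse"))
  df <- as.data.frame(tc)
  key <- interaction(df$sample_id, df$condition, df$tracer, df$metabolite,
                     df$time_min, df$replicate, drop = TRUE)
  for (i in split(seq_len(nrow(df)), key)) {
    ord <- i[order(df$mass_shift[i])]
    m <- mid_vector(df$fraction[ord], n_carbons = length(ord) - 1L)
    df$fraction[ord] <- correct_natural_abundance(m, p13)$fractions
  }
  label_timecourse(df)
}

check_p13 <- function(p13) {
  if (!is.numeric(p13) || length(p13) != 1L || is.na(p13) ||
      p13 < 0 || p13 >= 0.5)
    stop_domain("p13 must be a single value in [0, 0.5)")
  invisible(p13)
}

# (n+1) x (n+1) lower-triangular convolution matrix:
# A[j+1, k+1] = P(Binom(n - k, p13) = j - k)
na_matrix <- function(n_carbons, p13) {
  n <- n_carbons
  A <- matrix(0, n + 1L, n + 1L)
  for (k in 0:n) {
    j <- k:n
    A[j + 1L, k + 1L] <- stats::dbinom(j - k, size = n - k, prob = p13)
  }
  A
}
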