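#' Hamming distance between two haplotypes
#'
#' Counts differing positions. Positions where either vector is `NA`
#' (uncalled, e.g. interpolation gaps) are excluded from the distance and
#' reported via the `uncalled` attribute.
#'
#' @param x,y binary vectors of equal length.
#' @return integer distance with attribute `uncalled`.
#' @export
hamming <- function(x, y) {
  if (length(x) != length(y)) stop("haplotype length mismatch")
  ok <- !is.na(x) & !is.na(y)
  structure(sum(x[ok] != y[ok]), uncalled = sum(!ok))
}

perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms(n - 1L)) {
    for (i in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
    }
  }
  out
}

#' Optimal truth-estimate pairing and its Hamming distances
#'
#' For K = 2 this is the smaller of `d(A,a) + d(B,b)` and
#' `d(A,b) + d(B,a)`; for K up to 5 the minimum summed Hamming distance
#' over all permutations is found by exhaustive search. Contributor flags
#' follow the true proportions: row 1 of `truth` is the major.
#'
#' @param truth K x M binary matrix of true haplotypes, major first.
#' @param est K x M binary matrix of estimated haplotypes (`NA` = uncalled).
#' @return list of class `accuracy_record`: `total` distance, `per_contrib`
#'   distances under the optimal matching, `major_correct`, `minor_correct`
#'   (K = 2), `perm` (the matching), `uncalled`.
#' @export
paired_distance <- function(truth, est) {
  truth <- rbind(truth)
  est <- rbind(est)
  K <- nrow(truth)
  stopifnot(nrow(est) == K, ncol(est) == ncol(truth), K <= 5L)
  best <- NULL
  for (p in perms(K)) {
    d <- vapply(seq_len(K), function(k) {
      as.integer(hamming(truth[k, ], est[p[k], ]))
    }, integer(1))
    if (is.null(best) || sum(d) < sum(best$d)) best <- list(d = d, p = p)
  }
  unc <- vapply(seq_len(K), function(k) {
    attr(hamming(truth[k, ], est[best$p[k], ]), "uncalled")
  }, integer(1))
  structure(list(total = sum(best$d), per_contrib = best$d,
                 major_correct = best$d[1] == 0L,
                 minor_correct = if (K >= 2L) best$d[K] == 0L else NA,
                 perm = best$p, uncalled = unc),
            class = "accuracy_record")
}

#' Deconvolution accuracy with binomial confidence interval
#'
#' The percentage of mixtures in which every contributor was recovered at
#' zero Hamming distance, with an exact binomial 95% CI for plotting.
#'
#' @param records list of `accuracy_record`s, or an integer vector of total
#'   paired distances.
#' @return list with `accuracy` (percent), `n`, `n_perfect`, `ci` (percent
#'   scale).
#' @export
deconvolution_accuracy <- function(records) {
  totals <- if (is.list(records) && !is.numeric(records)) {
    vapply(records, function(r) as.integer(r$total), integer(1))
  } else {
    as.integer(records)
  }
  if (length(totals) == 0L) stop("no records")
  k <- sum(totals == 0L)
  n <- length(totals)
  ci <- as.numeric(binom.test(k, n)$conf.int) * 100
  list(accuracy = 100 * k / n, n = n, n_perfect = k, ci = ci)
}

#' Fit of observed to expected mixture proportions
#'
#' Ordinary least-squares R-squared of the observed minor proportions on
#' the expected ones, plus per-ratio variance and SD of the observed
#' values when a ratio label is supplied.
#'
#' @param expected,observed numeric vectors of equal length (>= 2).
#' @param ratio optional grouping labels (e.g. "50:1") for the per-ratio
#'   spread summary.
#' @return list with `r_squared`, `fit` (the `lm` object) and `by_ratio`
#'   (data.frame of per-ratio variance and SD, or `NULL`).
#' @export
proportion_fit <- function(expected, observed, ratio = NULL) {
  stopifnot(length(expected) == length(observed), length(expected) >= 2L)
  if (var(expected) == 0) stop("expected proportions are constant")
  fit <- lm(observed ~ expected)
  by_ratio <- NULL
  if (!is.null(ratio)) {
    sp <- split(observed, ratio)
    by_ratio <- data.frame(
      ratio = names(sp),
      n = vapply(sp, length, integer(1)),
      variance = vapply(sp, function(v) {
        if (length(v) > 1L) var(v) else NA_real_
      }, numeric(1)),
      sd = vapply(sp, function(v) {
        if (length(v) > 1L) sd(v) else NA_real_
      }, numeric(1)),
      row.names = NULL)
  }
  list(r_squared = summary(fit)$r.squared, fit = fit, by_ratio = by_ratio)
}
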