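#' Configuration for the phasing engine
#'
#' @param K number of strains (contributor haplotypes) to model, 1..5.
#' @param n_steps MCMC sweeps; 3000 is the working default (800-step runs
#'   do not reliably reach stationarity on full mitogenome site sets).
#' @param burn_in_fraction fraction of sweeps discarded as burn-in.
#' @param read_error per-read miscall probability `e` folded into the
#'   binomial success probability as `pi = q(1-e) + (1-q)e`.
#' @param miscopy_rate probability `mu` that a copied allele differs from
#'   its panel donor; this is what lets estimated mitotypes deviate from
#'   the panel.
#' @param recombination_rate fixed at 0 for mtDNA: each strain copies a
#'   single panel donor per sweep, with no switching along the genome.
#' @param titre_sd prior SD of the Gaussian titres whose softmax gives the
#'   proportions.
#' @param proposal_sd random-walk SD of the titre proposals.
#' @param proportion_floor detection threshold for counting effective
#'   contributors.
#' @param align_tol proportion gap under which K = 2 labels are aligned to
#'   the running modal haplotypes instead of by proportion rank (the 1:1
#'   label-switching guard).
#' @param seed RNG seed; `NULL` leaves the global RNG state untouched.
#' @return list of class `engine_config`.
#' @export
engine_config <- function(K = 2L, n_steps = 3000L, burn_in_fraction = 0.5,
                          read_error = 0.01, miscopy_rate = 0.01,
                          recombination_rate = 0, titre_sd = 3,
                          proposal_sd = 0.1, proportion_floor = 0.01,
                          align_tol = 0.05, seed = NULL) {
  stopifnot(K >= 1L, K <= 5L, read_error > 0, read_error < 0.5,
            miscopy_rate > 0, miscopy_rate < 0.5,
            recombination_rate == 0, n_steps >= 2L,
            burn_in_fraction >= 0, burn_in_fraction < 1)
  structure(list(K = as.integer(K), n_steps = as.integer(n_steps),
                 burn_in_fraction = burn_in_fraction,
                 read_error = read_error, miscopy_rate = miscopy_rate,
                 recombination_rate = recombination_rate,
                 titre_sd = titre_sd, proposal_sd = proposal_sd,
                 proportion_floor = proportion_floor,
                 align_tol = align_tol, seed = seed),
            class = "engine_config")
}

counts_alt_n <- function(counts) {
  list(alt = as.integer(counts$alt_count),
       n = as.integer(counts$ref_count + counts$alt_count))
}

#' Mixture log-likelihood under the binomial read-count model
#'
#' `sum_j log Binomial(a_j | n_j, pi_j)` with within-sample alternative
#' allele fraction `q_j = sum_k w_k h_kj` and `pi_j = q_j(1-e) + (1-q_j)e`.
#' Zero-depth sites contribute 0; each site term is floored at -745 so a
#' zero error rate on inconsistent counts stays finite.
#'
#' @param w proportion vector (sums to 1).
#' @param h K x M binary haplotype matrix.
#' @param counts a `site_counts` table with M rows.
#' @param e per-read error rate.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(w, h, counts, e = 0.01) {
  h <- matrix(as.integer(h), nrow = length(w))
  stopifnot(ncol(h) == nrow(counts), abs(sum(w) - 1) < 1e-8)
  cn <- counts_alt_n(counts)
  loglik_cpp(as.numeric(w), h, cn$alt, cn$n, e)
}

new_state <- function(t, h, log_lik = NA_real_) {
  w <- exp(t - max(t))
  list(t = t, w = w / sum(w), h = h, log_lik = log_lik)
}

#' One Metropolis-Hastings update of the contributor proportions
#'
#' Proposes `t'_k = t_k + N(0, proposal_sd)` for all titres jointly and
#' accepts with the usual ratio under the `N(0, titre_sd^2)` titre prior.
#' Uses (and advances) the global R RNG stream.
#'
#' @param state list with elements `t` (titres) and `h` (K x M matrix), as
#'   produced by this function or built by hand.
#' @param counts a `site_counts` table.
#' @param cfg an [engine_config()].
#' @return updated state (elements `t`, `w`, `h`, `log_lik`, `accepted`).
#' @export
update_proportions <- function(state, counts, cfg = engine_config()) {
  cn <- counts_alt_n(counts)
  h <- matrix(as.integer(state$h), nrow = length(state$t))
  res <- titre_step_cpp(as.numeric(state$t), h, cn$alt, cn$n,
                        cfg$read_error, cfg$titre_sd, cfg$proposal_sd)
  out <- new_state(res$t, state$h, res$log_lik)
  out$w <- res$w
  out$accepted <- res$accepted
  out
}

#' One block-Gibbs update of a strain's haplotype
#'
#' Exact draw of the donor index and the full haplotype of strain `k`
#' conditional on everything else: donor weights are products over sites of
#' the emission-weighted site likelihoods (uniform donor prior), then each
#' site allele is drawn independently given the donor. All products are
#' accumulated in log space.
#'
#' @param state list with `w`, `h`.
#' @param k strain index (1-based).
#' @param counts a `site_counts` table.
#' @param panel a `mito_panel`.
#' @param cfg an [engine_config()].
#' @return updated state with element `z` recording the sampled donor row.
#' @export
update_haplotype <- function(state, k, counts, panel,
                             cfg = engine_config()) {
  if (nrow(panel$H) == 0L) stop("empty reference panel")
  cn <- counts_alt_n(counts)
  h <- matrix(as.integer(state$h), nrow = length(state$w))
  res <- hap_step_cpp(as.integer(k), as.numeric(state$w), h, cn$alt, cn$n,
                      panel$H, cfg$miscopy_rate, cfg$read_error)
  state$h <- res$h
  state$z <- res$z
  state$log_lik <- loglik_cpp(as.numeric(state$w), res$h, cn$alt, cn$n,
                              cfg$read_error)
  state
}

#' Run the full MCMC mixture deconvolution
#'
#' Initializes titres at zero (uniform proportions) and each strain at a
#' random panel row, then iterates sweeps of one proportion update plus one
#' block-Gibbs haplotype update per strain in random order. After burn-in,
#' strains are label-aligned by proportion rank (with a Hamming-based
#' orientation guard for near-equal K = 2 proportions) and summarized.
#'
#' @param counts a `site_counts` table (restricted to the panel's site
#'   universe).
#' @param panel a `mito_panel`.
#' @param cfg an [engine_config()].
#' @param keep_draws record per-sweep haplotype draws (chain order, M <= 40
#'   only); used by the enumeration-oracle tests.
#' @return object of class `mito_deconv`: posterior-mean `proportions`
#'   (sorted decreasing), modal `haplotypes` (K x M), `allele_prob`
#'   (per-site posterior P(allele = 1)), `trace` (per-sweep log posterior),
#'   `accept_rate`, `prop_samples`, diagnostics via [diagnostics()].
#' @export
run_mcmc <- function(counts, panel, cfg = engine_config(),
                     keep_draws = FALSE) {
  if (nrow(panel$H) == 0L) stop("empty reference panel")
  if (ncol(panel$H) != nrow(counts)) {
    stop("counts and panel are on different site sets")
  }
  n_burn <- floor(cfg$n_steps * cfg$burn_in_fraction)
  if (cfg$n_steps - n_burn < 2L) {
    stop("fewer than 2 retained samples; increase n_steps")
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  cn <- counts_alt_n(counts)
  raw <- mcmc_deconvolve_cpp(cn$alt, cn$n, panel$H, cfg$K, cfg$n_steps,
                             cfg$burn_in_fraction, cfg$read_error,
                             cfg$miscopy_rate, cfg$titre_sd,
                             cfg$proposal_sd, cfg$align_tol, keep_draws)
  allele_prob <- raw$allele_sum / raw$n_keep
  haplotypes <- matrix(as.integer(allele_prob > 0.5), nrow = cfg$K)
  colnames(haplotypes) <- colnames(allele_prob) <- colnames(panel$H)
  res <- structure(list(
    proportions = colMeans(raw$prop_samples),
    haplotypes = haplotypes,
    allele_prob = allele_prob,
    trace = raw$trace,
    accept_rate = raw$accept_rate,
    prop_samples = raw$prop_samples,
    hap_codes = raw$hap_codes,
    n_keep = raw$n_keep,
    burn_in = n_burn,
    config = cfg,
    loci = panel$loci), class = "mito_deconv")
  res$diagnostics <- diagnostics(res)
  res
}

#' @export
print.mito_deconv <- function(x, ...) {
  cat(sprintf("mito_deconv: K = %d strains, %d sites, %d kept sweeps\n",
              nrow(x$haplotypes), ncol(x$haplotypes), x$n_keep))
  cat("  proportions:", paste(sprintf("%.3f", x$proportions),
                              collapse = ", "), "\n")
  cat(sprintf("  MH acceptance %.2f; Geweke z = %.2f (%s)\n",
              x$accept_rate, x$diagnostics$geweke_z,
              if (x$diagnostics$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Convergence diagnostics for a deconvolution run
#'
#' Geweke-style z score comparing the mean log posterior of the first 10%
#' and the last 50% of the post-burn-in trace, with batch-means standard
#' errors (the trace is strongly autocorrelated, so naive variances would
#' flag converged but slowly wiggling chains). A run is flagged when
#' |z| > 2; a constant trace gives z = 0.
#'
#' @param result a `mito_deconv`, or a numeric trace vector.
#' @return list with `geweke_z` and logical `converged`.
#' @export
diagnostics <- function(result) {
  trace <- if (inherits(result, "mito_deconv")) {
    result$trace[(result$burn_in + 1L):length(result$trace)]
  } else {
    as.numeric(result)
  }
  if (length(trace) < 20L) stop("trace too short for diagnostics")
  bm_se2 <- function(x) {
    # batches of >= 20 draws so batch means are near-independent
    nb <- min(10L, max(2L, floor(length(x) / 20L)))
    m <- floor(length(x) / nb)
    bm <- colMeans(matrix(x[seq_len(nb * m)], nrow = m))
    var(bm) / nb
  }
  n <- length(trace)
  a <- trace[seq_len(max(2L, floor(0.1 * n)))]
  b <- trace[(n - floor(0.5 * n) + 1L):n]
  se2 <- bm_se2(a) + bm_se2(b)
  z <- if (se2 == 0) 0 else (mean(a) - mean(b)) / sqrt(se2)
  list(geweke_z = z, converged = abs(z) <= 2)
}

#' Count contributors above the detection floor
#'
#' Strains whose posterior-mean proportion reaches the detection threshold
#' are counted. For a full deconvolution result, strains with identical
#' modal haplotypes are merged first (their proportions summed): when two
#' strains converge on the same mitotype they represent one contributor,
#' and the split of proportion mass between them is not identifiable.
#'
#' @param result a `mito_deconv` (or a plain numeric proportion vector, in
#'   which case only the threshold is applied).
#' @param tau detection threshold on the posterior-mean proportion.
#' @return integer number of effective contributors.
#' @export
effective_contributors <- function(result, tau = 0.01) {
  if (inherits(result, "mito_deconv")) {
    key <- apply(result$haplotypes, 1L, paste, collapse = "")
    w <- vapply(split(result$proportions, key), sum, numeric(1))
  } else {
    w <- result
  }
  sum(w >= tau)
}
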