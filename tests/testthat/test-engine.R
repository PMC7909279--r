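test_that("log-likelihood matches the closed-form binomial", {
  # single all-reference strain against all-HoR counts: pi = e everywhere
  M <- 6
  counts <- site_counts(1:M, rep("A", M), rep("G", M), rep(100L, M),
                        rep(0L, M))
  h <- matrix(0L, 1, M)
  expect_equal(log_likelihood(1, h, counts, e = 0.01),
               M * dbinom(0, 100, 0.01, log = TRUE))

  # w = (0.8, 0.2), h1 = 1, h2 = 0 -> pi = 0.8*0.99 + 0.2*0.01 = 0.794
  c1 <- site_counts(1, "A", "G", 20L, 80L)
  expect_equal(log_likelihood(c(0.8, 0.2), rbind(1L, 0L), c1, e = 0.01),
               dbinom(80, 100, 0.794, log = TRUE))

  # zero-depth sites contribute exactly 0
  c2 <- site_counts(1:2, rep("A", 2), rep("G", 2), c(20L, 0L), c(80L, 0L))
  expect_equal(log_likelihood(c(0.8, 0.2), rbind(c(1L, 1L), c(0L, 0L)),
                              c2, e = 0.01),
               dbinom(80, 100, 0.794, log = TRUE))

  # e = 0 with inconsistent counts is floored, not -Inf
  c3 <- site_counts(1, "A", "G", 50L, 50L)
  ll <- log_likelihood(1, matrix(0L, 1, 1), c3, e = 1e-300)
  expect_true(is.finite(ll))
})

test_that("proportion update respects its degenerate cases", {
  counts <- toy_counts_4to1()
  st <- list(t = c(0.3, -0.3), h = toy_truth())

  # zero proposal SD: always accepted, proportions unchanged
  cfg0 <- engine_config(proposal_sd = 0)
  set.seed(1)
  out <- update_proportions(st, counts, cfg0)
  expect_true(out$accepted)
  expect_equal(out$t, st$t)

  # K = 1: proportions pinned at 1 whatever the titre does
  st1 <- list(t = 0, h = matrix(1L, 1, 10))
  set.seed(2)
  out1 <- update_proportions(st1, counts, engine_config(K = 1))
  expect_equal(out1$w, 1)
})

test_that("MH acceptance rate is in a healthy band on a 2:1 mixture", {
  fx <- the_fixture()
  rates <- vapply(1:5, function(sd) {
    counts <- make_mixture(fx$haps, mixture_spec(fx$sources[sd],
                                                 fx$sources[sd + 1],
                                                 c(2L, 1L)))
    panel <- build_edit_distance_panel(fx$haps, counts, d = Inf)
    run_mcmc(counts, panel, engine_config(seed = sd))$accept_rate
  }, numeric(1))
  expect_true(all(rates > 0.1 & rates < 0.9))
})

test_that("single-strain Gibbs draw matches the enumerated conditional", {
  counts <- site_counts(1:4, rep("A", 4), rep("G", 4),
                        c(7L, 3L, 5L, 10L), c(3L, 7L, 5L, 0L))
  P <- rbind(c(1L, 0L, 1L, 0L), c(0L, 1L, 0L, 1L))
  panel <- toy_panel(P)
  e <- 0.05
  mu <- 0.2
  w <- c(0.8, 0.2)
  h_fixed <- rbind(c(1L, 0L, 1L, 0L), c(0L, 0L, 0L, 0L))
  alt <- counts$alt_count
  n <- counts$ref_count + counts$alt_count

  # exact conditional P(h_2) marginal over donors
  codes <- 0:15
  lp <- matrix(NA_real_, 2, 16)
  for (z in 1:2) {
    for (cd in codes) {
      h2 <- as.integer(intToBits(cd)[1:4])
      q <- w[1] * h_fixed[1, ] + w[2] * h2
      pi <- q * (1 - e) + (1 - q) * e
      lp[z, cd + 1] <- sum(ifelse(h2 == P[z, ], log(1 - mu), log(mu))) +
        sum(dbinom(alt, n, pi, log = TRUE))
    }
  }
  pj <- exp(lp - max(lp))
  p_h <- colSums(pj) / sum(pj)

  cfg <- engine_config(read_error = e, miscopy_rate = mu)
  set.seed(5)
  ndr <- 20000
  draws <- vapply(seq_len(ndr), function(i) {
    st <- update_haplotype(list(w = w, h = h_fixed), 2, counts, panel, cfg)
    sum(st$h[2, ] * 2^(0:3))
  }, numeric(1))
  emp <- tabulate(draws + 1, nbins = 16) / ndr
  keep <- which(p_h > 0.001)
  se <- sqrt(p_h[keep] * (1 - p_h[keep]) / ndr)
  expect_true(all(abs(emp[keep] - p_h[keep]) < 4 * se + 1e-12))

  # degenerate emission: mu -> 0 with the true haplotype as sole donor
  counts_hom <- site_counts(1:4, rep("A", 4), rep("G", 4),
                            c(0L, 100L, 0L, 100L), c(100L, 0L, 100L, 0L))
  sole <- toy_panel(matrix(c(1L, 0L, 1L, 0L), 1))
  cfg0 <- engine_config(K = 1, miscopy_rate = 1e-6)
  set.seed(6)
  st <- update_haplotype(list(w = 1, h = matrix(0L, 1, 4)), 1, counts_hom,
                         sole, cfg0)
  expect_equal(unname(st$h[1, ]), c(1L, 0L, 1L, 0L))
  expect_error(update_haplotype(list(w = 1, h = matrix(0L, 1, 4)), 1,
                                counts_hom, toy_panel(matrix(0L, 0, 4)),
                                cfg0),
               "empty")
})

test_that("chain posterior matches exhaustive enumeration on a small instance", {
  counts <- site_counts(1:4, rep("A", 4), rep("G", 4),
                        c(7L, 3L, 5L, 10L), c(3L, 7L, 5L, 0L))
  P <- rbind(c(1L, 0L, 1L, 0L), c(0L, 1L, 0L, 1L))
  panel <- toy_panel(P)
  e <- 0.05
  mu <- 0.2
  post <- enumerate_posterior(counts, P, c(0.5, 0.5), e, mu)
  res <- run_mcmc(counts, panel,
                  engine_config(seed = 99, n_steps = 200000L,
                                read_error = e, miscopy_rate = mu,
                                proposal_sd = 0),
                  keep_draws = TRUE)
  emp <- table(factor(res$hap_codes[, 1], levels = 0:15),
               factor(res$hap_codes[, 2], levels = 0:15))
  emp <- emp / sum(emp)
  tv <- 0.5 * sum(abs(emp - post))
  expect_lt(tv, 0.05)
})

test_that("proportions stay on the simplex and runs are seed-deterministic", {
  fx <- the_fixture()
  counts <- make_mixture(fx$haps, mixture_spec(fx$sources[1],
                                               fx$sources[3], c(4L, 1L)))
  panel <- build_edit_distance_panel(fx$haps, counts, d = Inf)
  cfg <- engine_config(seed = 17, n_steps = 400L)
  r1 <- run_mcmc(counts, panel, cfg)
  r2 <- run_mcmc(counts, panel, cfg)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$haplotypes, r2$haplotypes)
  expect_true(all(abs(rowSums(r1$prop_samples) - 1) < 1e-12))
  expect_true(all(r1$prop_samples > 0))
  expect_error(run_mcmc(counts, panel, engine_config(n_steps = 2L)),
               "retained")
})

test_that("posterior-mean minor proportion recovers truth within 0.03", {
  fx <- the_fixture()
  ratios <- list(c(2L, 1L), c(4L, 1L), c(9L, 1L))
  for (i in seq_along(ratios)) {
    r <- ratios[[i]]
    counts <- make_mixture(fx$haps, mixture_spec(fx$sources[i],
                                                 fx$sources[i + 3], r))
    panel <- build_edit_distance_panel(fx$haps, counts, d = Inf)
    res <- run_mcmc(counts, panel, engine_config(seed = 20 + i))
    expect_lt(abs(min(res$proportions) - r[2] / sum(r)), 0.03)
  }
})

test_that("deconvolution accuracy improves as the panel approaches the truth", {
  # panels at increasing Hamming distance from the contributors: accuracy
  # (measured as negative paired distance) must not increase with distance
  fx <- the_fixture()
  counts <- make_mixture(fx$haps, mixture_spec(fx$sources[1],
                                               fx$sources[4], c(4L, 1L)))
  tr <- attr(counts, "truth")
  truth <- rbind(tr$major, tr$minor)
  set.seed(31)
  dists <- c(0L, 8L, 30L)
  err <- vapply(dists, function(d) {
    Hp <- truth
    for (k in 1:2) {
      flip <- sample(ncol(Hp), d)
      Hp[k, flip] <- 1L - Hp[k, flip]
    }
    rownames(Hp) <- c("P1", "P2")
    res <- run_mcmc(counts, toy_panel(Hp), engine_config(seed = 40 + d))
    paired_distance(truth, res$haplotypes)$total
  }, integer(1))
  expect_true(all(diff(err) >= 0))
  expect_equal(err[1], 0L)
})

test_that("diagnostics flag trends but pass stationary chains", {
  expect_equal(diagnostics(rep(5, 200))$geweke_z, 0)
  expect_false(diagnostics(seq(0, 10, length.out = 200))$converged)
  expect_error(diagnostics(1:10), "too short")

  fx <- the_fixture()
  conv <- vapply(1:20, function(sd) {
    i <- ((sd - 1) %% 9) + 1
    counts <- make_mixture(fx$haps, mixture_spec(fx$sources[i],
                                                 fx$sources[i + 1],
                                                 c(2L, 1L)))
    panel <- build_edit_distance_panel(fx$haps, counts, d = Inf)
    run_mcmc(counts, panel, engine_config(seed = sd))$diagnostics$converged
  }, logical(1))
  expect_gte(mean(conv), 0.8)
})

test_that("effective contributor count applies the detection floor", {
  expect_equal(effective_contributors(c(0.8, 0.2), tau = 0.01), 2L)
  expect_equal(effective_contributors(c(0.995, 0.005), tau = 0.01), 1L)
  # K = 2 on single-source data collapses to one effective contributor
  fx <- the_fixture()
  id <- fx$sources[1]
  M <- ncol(fx$haps$H)
  h <- fx$haps$H[id, ]
  counts <- site_counts(fx$haps$loci$pos, fx$haps$loci$ref,
                        fx$haps$loci$alt, 1000L * (1L - h), 1000L * h)
  panel <- build_edit_distance_panel(fx$haps, counts, d = Inf)
  res <- run_mcmc(counts, panel, engine_config(seed = 77))
  expect_equal(effective_contributors(res), 1L)
  expect_equal(unname(res$haplotypes[1, ]), unname(h))
})
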