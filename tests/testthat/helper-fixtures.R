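# Shared fixtures, generated in code. The default synthetic database is
# built once per test session.

the_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_fixture_suite(seed = 42)
    cache
  }
})

# a toy mixture: 5 major-only + 5 minor-only He sites at 4:1, depth 100
toy_counts_4to1 <- function() {
  site_counts(1:10, rep("A", 10), rep("G", 10),
              c(rep(20, 5), rep(80, 5)), c(rep(80, 5), rep(20, 5)))
}

toy_truth <- function() {
  rbind(major = c(rep(1L, 5), rep(0L, 5)),
        minor = c(rep(0L, 5), rep(1L, 5)))
}

toy_panel <- function(H = toy_truth()) {
  structure(list(H = H, loci = NULL, provenance = "toy"),
            class = "mito_panel")
}

# enumeration oracle: exact joint posterior over (h1, h2) for K = 2 with
# fixed proportions w, marginalized over panel donors
enumerate_posterior <- function(counts, panel_H, w, e, mu) {
  M <- nrow(counts)
  alt <- counts$alt_count
  n <- counts$ref_count + counts$alt_count
  codes <- 0:(2^M - 1)
  hap <- function(code) as.integer(intToBits(code)[1:M])
  em <- function(h, z) {
    sum(ifelse(h == panel_H[z, ], log(1 - mu), log(mu)))
  }
  post <- matrix(0, 2^M, 2^M)
  for (c1 in codes) {
    h1 <- hap(c1)
    for (c2 in codes) {
      h2 <- hap(c2)
      q <- w[1] * h1 + w[2] * h2
      pi <- q * (1 - e) + (1 - q) * e
      ll <- sum(dbinom(alt, n, pi, log = TRUE))
      lp <- outer(seq_len(nrow(panel_H)), seq_len(nrow(panel_H)),
                  Vectorize(function(z1, z2) em(h1, z1) + em(h2, z2) + ll))
      post[c1 + 1, c2 + 1] <- sum(exp(lp))
    }
  }
  post / sum(post)
}
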