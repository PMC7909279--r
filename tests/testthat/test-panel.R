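test_that("edit distance counts alleles unsupported by the mixture", {
  counts <- toy_counts_4to1()  # 10 He sites
  truth <- toy_truth()
  # a contributor is fully compatible with the mixture it is part of
  expect_equal(mixture_edit_distance(truth["major", ], counts), 0L)
  # He sites accept either allele: differing at two He sites costs nothing
  cand <- truth["major", ]
  cand[c(1, 6)] <- 1L - cand[c(1, 6)]
  expect_equal(mixture_edit_distance(cand, counts), 0L)
  # an extra alt at an HoR site costs 1
  counts2 <- site_counts(1:3, rep("A", 3), rep("G", 3),
                         c(20, 100, 0), c(80, 0, 100))
  expect_equal(mixture_edit_distance(c(1L, 1L, 1L), counts2), 1L)
  # zero-depth sites contribute 0
  counts3 <- site_counts(1:2, rep("A", 2), rep("G", 2), c(0, 100), c(0, 0))
  expect_equal(mixture_edit_distance(c(1L, 0L), counts3), 0L)
})

test_that("compatibility with any generated mixture is free (property)", {
  fx <- the_fixture()
  set.seed(13)
  for (rep in 1:10) {
    pr <- sample(fx$sources, 2)
    counts <- make_mixture(fx$haps, mixture_spec(pr[1], pr[2],
                                                 c(sample(1:50, 1), 1L)))
    expect_equal(mixture_edit_distance(fx$haps$H[pr[1], ], counts), 0L)
    expect_equal(mixture_edit_distance(fx$haps$H[pr[2], ], counts), 0L)
  }
})

test_that("edit-distance panel filters, caps deterministically and falls back", {
  fx <- the_fixture()
  counts <- make_mixture(fx$haps,
                         mixture_spec(fx$sources[1], fx$sources[2],
                                      c(4L, 1L)))
  p1 <- build_edit_distance_panel(fx$haps, counts, d = 1)
  p2 <- build_edit_distance_panel(fx$haps, counts, d = 2)
  p4 <- build_edit_distance_panel(fx$haps, counts, d = 4)
  # monotone nesting before capping
  expect_true(all(rownames(p1$H) %in% rownames(p2$H)))
  expect_true(all(rownames(p2$H) %in% rownames(p4$H)))
  expect_lte(nrow(p4$H), 25L)

  # cap with all-equal distances is resolved lexicographically
  H <- matrix(0L, 40, 2,
              dimnames = list(sprintf("X%02d", 40:1), c("1", "2")))
  haps <- structure(list(
    loci = data.frame(pos = 1:2, ref = "A", alt = "G"), H = H),
    class = "mito_haps")
  cc <- site_counts(1:2, rep("A", 2), rep("G", 2), c(100, 100), c(0, 0))
  pc <- build_edit_distance_panel(haps, cc, d = 0, max_panel = 25)
  expect_equal(rownames(pc$H), sprintf("X%02d", 1:25))

  # impossible filter falls back to the single nearest, with a warning
  far <- site_counts(1:2, rep("A", 2), rep("G", 2), c(0, 0), c(100, 100))
  expect_warning(pf <- build_edit_distance_panel(haps, far, d = 0),
                 "falling back")
  expect_equal(nrow(pf$H), 1L)
})

test_that("experimental panel designs modify exactly what they claim", {
  fx <- the_fixture()
  a <- fx$sources[1]
  b <- fx$sources[2]
  H <- fx$haps$H

  e1 <- build_experimental_panel(fx$haps, a, b, type = 1, seed = 1)
  expect_true(all(c(a, b) %in% rownames(e1$panel$H)))
  expect_identical(e1$H_mix, H[c(a, b), ])

  e2 <- build_experimental_panel(fx$haps, a, b, type = 2, seed = 1)
  expect_equal(nrow(e2$panel$H), nrow(H) - 2L)
  expect_false(any(c(a, b) %in% rownames(e2$panel$H)))

  for (type in 3:4) {
    e <- build_experimental_panel(fx$haps, a, b, type = type, seed = 3)
    # exactly one contributor kept in the panel, one excluded
    expect_equal(sum(c(a, b) %in% rownames(e$panel$H)), 1L)
    kept <- intersect(c(a, b), rownames(e$panel$H))
    d_mix <- sum(e$H_mix[kept, ] != H[kept, ])
    d_panel <- sum(e$panel$H[kept, ] != H[kept, ])
    if (type == 3) {  # flip lives in the mixture copy
      expect_equal(c(d_mix, d_panel), c(1L, 0L))
    } else {          # flip lives in the panel copy
      expect_equal(c(d_mix, d_panel), c(0L, 1L))
    }
  }
  expect_error(build_experimental_panel(fx$haps, "nope", b, 1), "not found")
})

test_that("private-site error accounting follows the panel's allele content", {
  panel <- toy_panel(rbind(c(1L, 0L, 0L), c(1L, 1L, 0L)))
  # site 1: true allele 0 absent from panel -> private
  # site 2: true allele 0 present in panel member 1 -> not private
  rep <- private_site_report(c(1L, 2L), c(0L, 0L), panel)
  expect_equal(rep, c(private = 1L, total = 2L))
  expect_equal(private_site_report(integer(0), integer(0), panel),
               c(private = 0L, total = 0L))
})
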