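test_that("EMPOP token grammar classifies substitutions, insertions and deletions", {
  db <- parse_empop(text = c("S1\t263G 315.1C 523DEL", "S2\t", "S3\t16519c 249-"))
  v <- db$S1
  expect_equal(v$kind, c("substitution", "insertion", "deletion"))
  expect_equal(v$position, c(263L, 315L, 523L))
  expect_equal(v$base, c("G", "C", NA))
  expect_equal(v$insertion_index, c(NA, 1L, NA))
  expect_equal(nrow(db$S2), 0L)        # rCRS-identical sample
  expect_equal(db$S3$kind, c("substitution", "deletion"))
  expect_equal(db$S3$base[1], "C")     # case-normalized
})

test_that("malformed tokens raise parse errors naming the token", {
  expect_error(parse_empop(text = "S3\t99999A"), "99999A")
  expect_error(parse_empop(text = "S3\t0G"), "out of range")
  expect_error(parse_empop(text = "S3\t263X"), "malformed")
  expect_error(parse_empop(text = c("S1\t263G", "S1\t73G")), "duplicate")
})

test_that("parse / serialize round-trips well-formed records", {
  lines <- c("S1\t263G 315.1C 523DEL", "S2\t", "S3\t73G 152C")
  db <- parse_empop(text = lines)
  expect_identical(parse_empop(text = serialize_empop(db)), db)
})

test_that("site universe drops indels and multi-allelic positions", {
  # 152 is tri-allelic across the pool (rCRS base + C + T): excluded
  db <- parse_empop(text = c("S1\t152C 263G 315.1C", "S2\t152T 263G"))
  u <- build_site_universe(db)
  expect_equal(u$loci$pos, 263L)
  expect_equal(unname(u$H[, "263"]), c(1L, 1L))
  expect_false(any(u$loci$ref == u$loci$alt))

  empty <- build_site_universe(parse_empop(text = character(0)))
  expect_equal(nrow(empty$loci), 0L)
})

test_that("site universe never contains indel or multi-allelic loci (property)", {
  set.seed(101)
  for (rep in 1:20) {
    n_samp <- sample(2:6, 1)
    lines <- vapply(seq_len(n_samp), function(i) {
      n_tok <- sample(0:8, 1)
      toks <- vapply(seq_len(n_tok), function(j) {
        pos <- sample(16569, 1)
        switch(sample(3, 1),
               paste0(pos, sample(c("A", "C", "G", "T"), 1)),
               paste0(pos, ".1", sample(c("A", "C", "G", "T"), 1)),
               paste0(pos, "DEL"))
      }, character(1))
      paste0("R", i, "\t", paste(toks, collapse = " "))
    }, character(1))
    db <- parse_empop(text = lines)
    u <- build_site_universe(db)
    subs <- do.call(rbind, lapply(db, function(v) {
      v[v$kind == "substitution", c("position", "base")]
    }))
    for (p in u$loci$pos) {
      expect_length(unique(subs$base[subs$position == p]), 1L)
    }
    expect_true(all(u$H %in% 0:1))
    expect_equal(ncol(u$H), nrow(u$loci))
  }
})

test_that("genotype classes partition sites", {
  counts <- site_counts(1:4, rep("A", 4), rep("G", 4),
                        c(90, 100, 0, 0), c(10, 0, 100, 0))
  cls <- classify_sites(counts)
  expect_equal(as.character(cls), c("He", "HoR", "HoA", "missing"))
  expect_false(any(is.na(cls)))  # exactly one class per site
})

test_that("count table TSV round-trips bit-exactly and validates", {
  f <- tempfile(fileext = ".tsv")
  x <- site_counts(c(73L, 263L), c("A", "A"), c("G", "G"),
                   c(90L, 0L), c(10L, 100L))
  write_counts(x, f)
  expect_identical(read_counts(f), x)

  # empty table round-trips
  e <- site_counts(integer(0), character(0), character(0),
                   integer(0), integer(0))
  write_counts(e, f)
  expect_equal(nrow(read_counts(f)), 0L)

  # negative count and missing column are format errors
  writeLines(c("POS\tREF\tALT\tREF_COUNT\tALT_COUNT",
               "73\tA\tG\t-1\t10"), f)
  expect_error(read_counts(f), "non-negative")
  writeLines(c("POS\tREF\tALT\tREF_COUNT", "73\tA\tG\t5"), f)
  expect_error(suppressWarnings(read_counts(f)), "column")
})
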