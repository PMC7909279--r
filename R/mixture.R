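#' Specify a two-person (or K-person) mixture
#'
#' A mixture specification names the contributing haplotypes (major first),
#' the integer mixing ratio and the total per-site read depth.
#'
#' @param major,minor sample IDs of the contributors.
#' @param ratio length-2 positive integer vector `c(p, q)` meaning p:q
#'   major:minor; proportions are `p/(p+q)` and `q/(p+q)`.
#' @param depth total reads per site (default 100, the depth at which the
#'   engine's copying prior and the binomial likelihood are balanced).
#' @return list of class `mixture_spec`.
#' @export
mixture_spec <- function(major, minor, ratio = c(1L, 1L), depth = 100L) {
  stopifnot(length(ratio) == 2L, all(ratio > 0), depth >= 1L)
  structure(list(major = major, minor = minor,
                 ratio = as.integer(ratio), depth = as.integer(depth)),
            class = "mixture_spec")
}

#' Generate exact in silico mixture read counts
#'
#' Normalizes the idealized mixing ratio into integer read counts at every
#' site: `alt_count = round(D * sum_k w_k h_kj)` with round-half-away-from-
#' zero, and `ref_count = D - alt_count`, so the total depth is conserved
#' exactly. A 1:9 mixture at depth 100 therefore produces 10:90 counts at a
#' site where only the 9-part contributor carries the alternative allele.
#' No sequencing noise is injected: the counts are the exact expectation of
#' the mixture, which isolates the phasing model from genotyping error.
#'
#' @param haps a `mito_haps` object containing the contributors, or a
#'   binary matrix whose rows are haplotypes.
#' @param spec a [mixture_spec()].
#' @return a `site_counts` table with attribute `truth` (list with the true
#'   contributor haplotypes and proportions).
#' @export
make_mixture <- function(haps, spec) {
  H <- if (inherits(haps, "mito_haps")) haps$H else haps
  loci <- if (inherits(haps, "mito_haps")) haps$loci else NULL
  if (!all(c(spec$major, spec$minor) %in% rownames(H))) {
    stop("contributors not found in the haplotype set")
  }
  hA <- H[spec$major, ]
  hB <- H[spec$minor, ]
  if (length(hA) != length(hB)) stop("mismatched site universes")
  w <- spec$ratio / sum(spec$ratio)
  q <- w[1] * hA + w[2] * hB
  alt_count <- as.integer(floor(spec$depth * q + 0.5))
  ref_count <- spec$depth - alt_count
  M <- length(hA)
  if (is.null(loci)) {
    loci <- data.frame(pos = seq_len(M),
                       ref = synthetic_ref_base(seq_len(M)),
                       alt = rep("G", M), stringsAsFactors = FALSE)
    loci$alt[loci$ref == "G"] <- "A"
  }
  counts <- site_counts(loci$pos, loci$ref, loci$alt, ref_count, alt_count)
  attr(counts, "truth") <- list(
    major = hA, minor = hB, major_id = spec$major, minor_id = spec$minor,
    proportions = w, depth = spec$depth, ratio = spec$ratio)
  counts
}

#' Enumerate all pairwise mixtures of a haplotype set
#'
#' Takes every unordered pair of sample IDs and crosses it with every
#' ratio. Within a pair, the lexicographically smaller ID takes the major
#' role (1:1 mixtures keep the same tie-break so the major/minor labels are
#' well-defined approximations).
#'
#' @param ids character vector of sample IDs (>= 2).
#' @param ratios list of length-2 integer vectors, e.g.
#'   `list(c(50,1), c(19,1), c(9,1), c(4,1), c(2,1), c(1,1))`.
#' @param depth per-site total depth for every spec.
#' @return list of [mixture_spec()] objects of length `choose(n,2) *
#'   length(ratios)`.
#' @examples
#' length(enumerate_pairs(paste0("S", 1:10), default_ratios()))  # 270
#' @export
enumerate_pairs <- function(ids, ratios, depth = 100L) {
  stopifnot(length(ids) >= 2L)
  prs <- combn(sort(ids), 2L, simplify = FALSE)
  out <- list()
  for (pr in prs) {
    for (r in ratios) {
      out[[length(out) + 1L]] <- mixture_spec(pr[1], pr[2], r, depth)
    }
  }
  out
}

#' The study's six mixture ratios
#' @return list of length-2 integer vectors 50:1 ... 1:1.
#' @export
default_ratios <- function() {
  list(c(50L, 1L), c(19L, 1L), c(9L, 1L), c(4L, 1L), c(2L, 1L), c(1L, 1L))
}

#' Drop sites without mixture signal
#'
#' Optionally removes sites that carry no alternative-allele evidence in
#' either the mixture counts or the supplied haplotype set (they are HoR
#' everywhere and carry no information for phasing). A site map back to the
#' full universe is attached so full-genome mitotypes can be reconstituted.
#'
#' @param counts a `site_counts` table.
#' @param haps optional `mito_haps` whose alternative alleles also count as
#'   evidence.
#' @param drop_invariant when `FALSE` the table is returned unchanged.
#' @return the (possibly) restricted table with attribute `site_map`, the
#'   indices of retained sites in the input table.
#' @export
restrict_to_mixture_sites <- function(counts, haps = NULL,
                                      drop_invariant = TRUE) {
  if (!drop_invariant) {
    attr(counts, "site_map") <- seq_len(nrow(counts))
    return(counts)
  }
  evid <- counts$alt_count > 0L
  if (!is.null(haps)) {
    H <- if (inherits(haps, "mito_haps")) haps$H else haps
    j <- match(counts$pos, as.integer(colnames(H)))
    evid <- evid | (!is.na(j) & colSums(H)[j] > 0L)
  }
  keep <- which(evid)
  out <- counts[keep, , drop = FALSE]
  class(out) <- class(counts)
  tr <- attr(counts, "truth")
  if (!is.null(tr)) {
    tr$major <- tr$major[keep]
    tr$minor <- tr$minor[keep]
  }
  attr(out, "truth") <- tr
  attr(out, "site_map") <- keep
  out
}
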