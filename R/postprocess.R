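#' Interpolate the minor contributor from an accurately phased major
#'
#' In a two-person mixture, once the major mitotype is fixed the remaining
#' observed alleles necessarily belong to the minor contributor: at He
#' sites the minor takes the complement of the major allele, at homozygous
#' sites it copies the single observed allele, and zero-depth sites are
#' left uncalled rather than defaulted to the reference.
#'
#' @param major binary vector: the asserted major haplotype.
#' @param counts a `site_counts` table aligned to `major`.
#' @param strict when `TRUE` (default), a covered site whose asserted major
#'   allele has zero supporting reads raises an inconsistency error (the
#'   major cannot be correct there); when `FALSE` such sites are tagged
#'   `"inconsistent"` and the minor copies the observed allele.
#' @return list of class `minor_interpolation`: `minor` (integer vector,
#'   `NA` at uncalled sites) and `source` (per-site tag: `He-complement`,
#'   `Ho-copy`, `missing`, or `inconsistent`).
#' @export
interpolate_minor <- function(major, counts, strict = TRUE) {
  if (length(major) != nrow(counts)) {
    stop("major haplotype and counts are on different site sets")
  }
  cls <- classify_sites(counts)
  major_reads <- ifelse(major == 1L, counts$alt_count, counts$ref_count)
  bad <- cls != "missing" & major_reads == 0L
  if (any(bad) && strict) {
    stop("major haplotype inconsistent with counts at site(s) ",
         paste(counts$pos[bad], collapse = ", "),
         ": its allele has zero supporting reads")
  }
  minor <- rep(NA_integer_, length(major))
  src <- rep("missing", length(major))
  he <- cls == "He" & !bad
  minor[he] <- 1L - major[he]
  src[he] <- "He-complement"
  ho <- cls %in% c("HoR", "HoA") & !bad
  minor[ho] <- as.integer(counts$alt_count[ho] > 0L)
  src[ho] <- "Ho-copy"
  minor[bad] <- as.integer(counts$alt_count[bad] > 0L)
  src[bad] <- "inconsistent"
  structure(list(minor = minor, source = src),
            class = "minor_interpolation")
}

#' Classify phasing errors by mechanism
#'
#' Labels every site where the (already optimally matched) estimated pair
#' disagrees with the true pair:
#' \describe{
#'   \item{He->Ho coercion}{contributors truly differ but were estimated
#'     equal (the minor was forced onto its major homologue).}
#'   \item{Ho->He coercion}{contributors truly agree but were estimated to
#'     differ.}
#'   \item{point-switch}{both estimates wrong in complementary fashion at a
#'     truly He site (alleles swapped between haplotypes).}
#'   \item{allele-flip}{both estimates wrong identically at a truly Ho
#'     site.}
#' }
#'
#' @param truth 2 x M binary matrix of true haplotypes (major, minor).
#' @param est 2 x M binary matrix of matched estimates.
#' @return data.frame with columns `site` (column index) and `label`;
#'   zero rows when the estimate is exact.
#' @export
error_taxonomy <- function(truth, est) {
  stopifnot(nrow(truth) == 2L, nrow(est) == 2L,
            ncol(truth) == ncol(est))
  bad <- which(colSums(truth != est, na.rm = FALSE) > 0)
  bad <- bad[!is.na(colSums(truth[, bad, drop = FALSE]) +
                    colSums(est[, bad, drop = FALSE]))]
  if (length(bad) == 0L) {
    return(data.frame(site = integer(0), label = character(0)))
  }
  label <- vapply(bad, function(j) {
    t_he <- truth[1L, j] != truth[2L, j]
    e_he <- est[1L, j] != est[2L, j]
    if (t_he && !e_he) {
      "He->Ho coercion"
    } else if (!t_he && e_he) {
      "Ho->He coercion"
    } else if (t_he && e_he) {
      "point-switch"
    } else {
      "allele-flip"
    }
  }, character(1))
  data.frame(site = bad, label = label, stringsAsFactors = FALSE)
}
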