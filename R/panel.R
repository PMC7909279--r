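#' Graph edit distance between a candidate haplotype and a mixture
#'
#' The number of allele changes a database haplotype needs to be compatible
#' with the observed mixture genotypes: a site contributes 1 when the
#' candidate's allele received zero reads there (He sites, with reads on
#' both alleles, accept either allele; zero-depth sites contribute 0).
#'
#' @param candidate binary haplotype vector aligned to `counts`.
#' @param counts a `site_counts` table.
#' @return non-negative integer distance.
#' @export
mixture_edit_distance <- function(candidate, counts) {
  if (length(candidate) != nrow(counts)) {
    stop("candidate and counts are on different site sets")
  }
  supported <- ifelse(candidate == 1L, counts$alt_count, counts$ref_count)
  covered <- counts$ref_count + counts$alt_count > 0L
  sum(covered & supported == 0L)
}

new_panel <- function(H, loci, provenance, distances = NULL) {
  structure(list(H = H, loci = loci, provenance = provenance,
                 distances = distances), class = "mito_panel")
}

#' @export
print.mito_panel <- function(x, ...) {
  cat(sprintf("mito_panel [%s]: %d haplotypes x %d sites\n",
              x$provenance, nrow(x$H), ncol(x$H)))
  invisible(x)
}

#' Build a reference panel by graph edit distance to the mixture
#'
#' Keeps database haplotypes whose [mixture_edit_distance()] to the mixture
#' is at most `d`, then caps the panel at the `max_panel` nearest (ties
#' broken lexicographically by sample ID for reproducibility). If no
#' candidate passes the filter the single globally nearest haplotype is
#' returned with a warning, since the copying model needs at least one
#' donor.
#'
#' @param haps a `mito_haps` database aligned to `counts`.
#' @param counts a `site_counts` table for the mixture.
#' @param d maximum edit distance (use `Inf` for a pure nearest-k panel).
#' @param max_panel panel size cap (default 25, the size at which copying
#'   accuracy and quadratic runtime balance).
#' @param exclude sample IDs never to include (e.g. known contributors for
#'   hold-out validation).
#' @return a `mito_panel`.
#' @export
build_edit_distance_panel <- function(haps, counts, d, max_panel = 25L,
                                      exclude = character(0)) {
  H <- haps$H
  H <- H[setdiff(rownames(H), exclude), , drop = FALSE]
  if (nrow(H) == 0L) stop("empty candidate database")
  dist <- apply(H, 1L, mixture_edit_distance, counts = counts)
  ord <- order(dist, rownames(H))
  pass <- ord[dist[ord] <= d]
  if (length(pass) == 0L) {
    warning("no haplotype within edit distance ", d,
            "; falling back to the single nearest")
    pass <- ord[1L]
  }
  if (length(pass) > max_panel) pass <- pass[seq_len(max_panel)]
  new_panel(H[pass, , drop = FALSE], haps$loci,
            sprintf("edit_distance(%s)", format(d)),
            distances = dist[pass])
}

#' Build one of the four experimental panel designs
#'
#' The designs probe how panel composition bounds phasing accuracy:
#' \describe{
#'   \item{type 1}{idealized: the full database, both contributors
#'     included.}
#'   \item{type 2}{hold-two-out cross-validation: both contributors
#'     removed.}
#'   \item{type 3}{a one-SNP "derived" haplotype enters the \emph{mixture}:
#'     one randomly chosen contributor gets a single random allele flip in
#'     its mixture copy while the panel keeps the original ("ancestral")
#'     sequence; the other contributor is removed from the panel.}
#'   \item{type 4}{the flip goes into the \emph{panel} copy instead; the
#'     mixture keeps the original; the other contributor is removed from
#'     the panel.}
#' }
#'
#' @param haps a `mito_haps` database containing both contributors.
#' @param major,minor contributor sample IDs.
#' @param type integer 1..4.
#' @param seed RNG seed selecting the flipped contributor and site.
#' @return list with `panel` (a `mito_panel`) and `H_mix` (2 x M matrix of
#'   the haplotypes to mix, rows named by contributor ID; equal to the
#'   database copies except under type 3).
#' @export
build_experimental_panel <- function(haps, major, minor, type, seed = NULL) {
  stopifnot(type %in% 1:4)
  H <- haps$H
  if (!all(c(major, minor) %in% rownames(H))) {
    stop("contributors not found in the database")
  }
  if (!is.null(seed)) set.seed(seed)
  H_mix <- H[c(major, minor), , drop = FALSE]
  tag <- paste0("panel", type)
  if (type == 1L) {
    panel_H <- H
  } else if (type == 2L) {
    panel_H <- H[setdiff(rownames(H), c(major, minor)), , drop = FALSE]
  } else {
    pick <- sample(c(major, minor), 1L)
    other <- setdiff(c(major, minor), pick)
    site <- sample(ncol(H), 1L)
    panel_H <- H[setdiff(rownames(H), other), , drop = FALSE]
    if (type == 3L) {
      H_mix[pick, site] <- 1L - H_mix[pick, site]
    } else {
      panel_H[pick, site] <- 1L - panel_H[pick, site]
    }
  }
  if (nrow(panel_H) == 0L) stop("experimental panel is empty")
  list(panel = new_panel(panel_H, haps$loci, tag), H_mix = H_mix)
}

#' Align an EMPOP database to a count table's site universe
#'
#' Codes every sample of `db` as a binary haplotype over the sites of
#' `counts` (1 where the sample carries a substitution at the site's
#' position); variants at positions outside the count table are ignored,
#' as are indel tokens. This is how a panel file is brought onto the
#' engine's site coding.
#'
#' @param db an `empop_db`.
#' @param counts a `site_counts` table defining the site universe.
#' @param provenance provenance tag for the panel.
#' @return a `mito_panel`.
#' @export
panel_from_empop <- function(db, counts, provenance = "file") {
  H <- matrix(0L, length(db), nrow(counts),
              dimnames = list(names(db), as.character(counts$pos)))
  for (id in names(db)) {
    v <- db[[id]]
    sub <- v[v$kind == "substitution", , drop = FALSE]
    j <- match(sub$position, counts$pos)
    H[id, j[!is.na(j)]] <- 1L
  }
  new_panel(H, data.frame(pos = counts$pos, ref = counts$ref,
                          alt = counts$alt, stringsAsFactors = FALSE),
            provenance)
}

#' Convert binary haplotypes back to EMPOP variant lists
#'
#' @param H binary matrix (samples x sites) with sample IDs as rownames.
#' @param loci site list (`pos`, `ref`, `alt`) aligned to the columns.
#' @return an `empop_db` whose samples carry a substitution token at every
#'   site where they hold the alternative allele.
#' @export
haps_to_empop <- function(H, loci) {
  H <- rbind(H)
  stopifnot(ncol(H) == nrow(loci))
  out <- lapply(seq_len(nrow(H)), function(i) {
    j <- which(H[i, ] == 1L)
    data.frame(position = loci$pos[j], kind = rep("substitution",
                                                  length(j)),
               base = loci$alt[j],
               insertion_index = rep(NA_integer_, length(j)),
               stringsAsFactors = FALSE)
  })
  names(out) <- rownames(H)
  structure(out, class = "empop_db")
}

#' Count phasing errors attributable to private sites
#'
#' A mismatched site is "private" when the true allele there is carried by
#' no haplotype in the reference panel, so the copying prior could never
#' have supplied it.
#'
#' @param mismatch_sites integer site indices (columns) where an estimated
#'   haplotype disagreed with truth.
#' @param true_alleles the true alleles (0/1) at those sites.
#' @param panel a `mito_panel`.
#' @return named integer vector `c(private = ..., total = ...)`.
#' @export
private_site_report <- function(mismatch_sites, true_alleles, panel) {
  stopifnot(length(mismatch_sites) == length(true_alleles))
  if (length(mismatch_sites) == 0L) {
    return(c(private = 0L, total = 0L))
  }
  private <- vapply(seq_along(mismatch_sites), function(i) {
    !any(panel$H[, mismatch_sites[i]] == true_alleles[i])
  }, logical(1))
  c(private = sum(private), total = length(mismatch_sites))
}
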