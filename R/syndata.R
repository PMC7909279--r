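#' Configuration for the synthetic haplotype database generator
#'
#' The generator emulates an HmtDB-like population database with haplogroup
#' structure: a star phylogeny in which each haplogroup carries a Poisson
#' number of defining ("branch") substitutions and every sample adds its
#' own Poisson number of private substitutions. With the defaults
#' (8 haplogroups, branch mean 15, private mean 4) pairwise Hamming
#' distances span roughly 1-56 with a mean near 38, the regime observed in
#' forensic full-mitogenome population samples.
#'
#' @param n_haplogroups number of haplogroups (default 8).
#' @param samples_per_group samples per haplogroup (default 4, so the
#'   default database holds 32 mitotypes).
#' @param lambda_branch Poisson mean of haplogroup-defining substitutions.
#' @param lambda_private Poisson mean of per-sample private substitutions.
#' @param site_pool number of rCRS positions available (default 16569).
#' @param seed RNG seed (`NULL` = use current RNG state).
#' @return list of class `syn_db_config`.
#' @export
syn_db_config <- function(n_haplogroups = 8L, samples_per_group = 4L,
                          lambda_branch = 15, lambda_private = 4,
                          site_pool = MT_GENOME_LENGTH, seed = NULL) {
  stopifnot(n_haplogroups >= 1L, samples_per_group >= 1L,
            lambda_branch > 0, lambda_private > 0, site_pool >= 1L)
  structure(list(n_haplogroups = as.integer(n_haplogroups),
                 samples_per_group = as.integer(samples_per_group),
                 lambda_branch = lambda_branch,
                 lambda_private = lambda_private,
                 site_pool = as.integer(site_pool), seed = seed),
            class = "syn_db_config")
}

rand_alt_base <- function(ref) {
  vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
         character(1))
}

#' Generate a synthetic haplogroup-structured haplotype database
#'
#' Draws a star tree of haplogroups from an rCRS-like root: each group
#' receives `Poisson(lambda_branch)` defining substitutions at fresh
#' positions, and each sample carries its group's variants plus
#' `Poisson(lambda_private)` private substitutions. Within a lineage no
#' position mutates twice; alternative bases are drawn uniformly from the
#' three non-reference bases. Deterministic for a fixed seed.
#'
#' @param cfg a [syn_db_config()].
#' @return an `empop_db` with samples named `HG<g>_S<i>`; the haplogroup
#'   assignment is attached as attribute `groups`.
#' @export
generate_db <- function(cfg = syn_db_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  db <- list()
  groups <- character(0)
  for (g in seq_len(cfg$n_haplogroups)) {
    n_branch <- rpois(1L, cfg$lambda_branch)
    branch_pos <- sample.int(cfg$site_pool, n_branch)
    branch_base <- rand_alt_base(synthetic_ref_base(branch_pos))
    for (s in seq_len(cfg$samples_per_group)) {
      n_priv <- rpois(1L, cfg$lambda_private)
      avail <- setdiff(seq_len(cfg$site_pool), branch_pos)
      if (length(avail) < n_priv) stop("site pool exhausted")
      priv_pos <- sample(avail, n_priv)
      priv_base <- rand_alt_base(synthetic_ref_base(priv_pos))
      pos <- c(branch_pos, priv_pos)
      base <- c(branch_base, priv_base)
      o <- order(pos)
      id <- sprintf("HG%d_S%02d", g, s)
      db[[id]] <- data.frame(position = pos[o], kind = "substitution",
                             base = base[o],
                             insertion_index = NA_integer_,
                             stringsAsFactors = FALSE)
      groups <- c(groups, sprintf("HG%d", g))
    }
  }
  structure(db, class = "empop_db",
            groups = setNames(groups, names(db)))
}

#' Build the standard validation fixture suite
#'
#' Emits the full in silico study design from one synthetic database:
#' 10 mixture-source mitotypes spread across the haplogroups plus the
#' remaining samples as panel background (32 mitotypes in the default
#' configuration), and every pairwise mixture specification for the given
#' ratios (45 pairs x 6 ratios = 270 with the defaults).
#'
#' @param cfg a [syn_db_config()].
#' @param ratios list of mixture ratios (default [default_ratios()]).
#' @param depth per-site read depth for the mixture specs.
#' @param n_sources number of mixture-source mitotypes (default 10).
#' @param seed RNG seed for the database draw.
#' @return list with `db` (the `empop_db`), `haps` (`mito_haps` universe),
#'   `sources`, `background` (ID vectors) and `specs` (list of
#'   [mixture_spec()]).
#' @export
make_fixture_suite <- function(cfg = syn_db_config(),
                               ratios = default_ratios(), depth = 100L,
                               n_sources = 10L, seed = NULL) {
  if (!is.null(seed)) cfg$seed <- seed
  db <- generate_db(cfg)
  haps <- build_site_universe(db)
  groups <- attr(db, "groups")
  # one source per haplogroup first, then cycle back for the remainder
  ids_by_group <- split(names(db), groups)
  sources <- character(0)
  rank <- 1L
  while (length(sources) < n_sources) {
    for (g in names(ids_by_group)) {
      if (length(sources) >= n_sources) break
      if (length(ids_by_group[[g]]) >= rank) {
        sources <- c(sources, ids_by_group[[g]][rank])
      }
    }
    rank <- rank + 1L
  }
  sources <- sort(sources[seq_len(n_sources)])
  list(db = db, haps = haps, sources = sources,
       background = setdiff(names(db), sources),
       specs = enumerate_pairs(sources, ratios, depth))
}
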