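#' @useDynLib mitophase, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rpois pnorm pchisq pf qf var sd lm coef
#'   binom.test setNames rbinom prop.test
#' @importFrom utils read.delim write.table combn head
NULL

MT_GENOME_LENGTH <- 16569L

#' Parse an EMPOP-style haplotype table
#'
#' Reads the forensic EMPOP convention: one sample per line, a sample ID
#' followed by whitespace-separated variant tokens giving the differences
#' from the rCRS. Substitutions are written `263G`, insertions `315.1C`,
#' and deletions `249DEL` (case-insensitive) or `249-`. A line with only a
#' sample ID is an rCRS-identical mitotype.
#'
#' @param path path to the file, or a character vector of lines via `text`.
#' @param text optional character vector of record lines (used instead of
#'   `path`).
#' @return an object of class `empop_db`: a named list, one element per
#'   sample, each a data.frame with columns `position`, `kind`
#'   (substitution/insertion/deletion), `base` and `insertion_index`.
#' @examples
#' db <- parse_empop(text = c("S1\t263G 315.1C 249DEL", "S2\t"))
#' db$S1
#' @export
parse_empop <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\\s+")[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) == 0L) next
    id <- fields[[1]]
    if (id %in% names(out)) {
      stop(sprintf("line %d: duplicate sample ID '%s'", i, id))
    }
    toks <- fields[-1]
    out[[id]] <- parse_variant_tokens(toks, line = i)
  }
  structure(out, class = "empop_db")
}

parse_variant_tokens <- function(tokens, line = NA_integer_) {
  n <- length(tokens)
  position <- integer(n)
  kind <- character(n)
  base <- rep(NA_character_, n)
  ins_index <- rep(NA_integer_, n)
  for (i in seq_along(tokens)) {
    tok <- tokens[[i]]
    fail <- function(why) {
      stop(sprintf("line %s, token '%s': %s",
                   ifelse(is.na(line), "?", line), tok, why))
    }
    if (grepl("^[0-9]+\\.[0-9]+[ACGTacgt]$", tok)) {
      parts <- regmatches(tok, regexec("^([0-9]+)\\.([0-9]+)([ACGTacgt])$",
                                       tok))[[1]]
      position[i] <- as.integer(parts[2])
      kind[i] <- "insertion"
      ins_index[i] <- as.integer(parts[3])
      base[i] <- toupper(parts[4])
      if (ins_index[i] < 1L) fail("insertion index must be >= 1")
    } else if (grepl("^[0-9]+([Dd][Ee][Ll]|-)$", tok)) {
      position[i] <- as.integer(sub("([0-9]+).*", "\\1", tok))
      kind[i] <- "deletion"
    } else if (grepl("^[0-9]+[ACGTacgt]$", tok)) {
      position[i] <- as.integer(sub("([0-9]+).*", "\\1", tok))
      kind[i] <- "substitution"
      base[i] <- toupper(sub("^[0-9]+", "", tok))
    } else {
      fail("malformed variant token")
    }
    if (position[i] < 1L || position[i] > MT_GENOME_LENGTH) {
      fail(sprintf("position out of range 1..%d", MT_GENOME_LENGTH))
    }
  }
  data.frame(position = position, kind = kind, base = base,
             insertion_index = ins_index, stringsAsFactors = FALSE)
}

#' Serialize an `empop_db` back to EMPOP-style lines
#'
#' Inverse of [parse_empop()]: `parse_empop(text = serialize_empop(db))`
#' reproduces `db` for well-formed records.
#'
#' @param db an `empop_db`.
#' @param path optional output file; when `NULL` the lines are returned.
#' @return character vector of lines (invisibly when written to `path`).
#' @export
serialize_empop <- function(db, path = NULL) {
  lines <- vapply(names(db), function(id) {
    v <- db[[id]]
    if (nrow(v) == 0L) return(paste0(id, "\t"))
    toks <- character(nrow(v))
    for (i in seq_len(nrow(v))) {
      toks[i] <- switch(v$kind[i],
        substitution = paste0(v$position[i], v$base[i]),
        insertion = paste0(v$position[i], ".", v$insertion_index[i],
                           v$base[i]),
        deletion = paste0(v$position[i], "DEL"))
    }
    paste0(id, "\t", paste(toks, collapse = " "))
  }, character(1))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Synthetic stand-in reference base for a position
#'
#' When no rCRS FASTA is supplied, the reference base at a position is a
#' deterministic function of the coordinate. It exists only so that every
#' locus has a reference allele distinct from its alternative; the engine
#' operates on binary allele codes and never inspects the base itself.
#' @param pos integer vector of rCRS positions.
#' @return character vector of bases.
#' @keywords internal
synthetic_ref_base <- function(pos) {
  c("A", "C", "G", "T")[(pos %% 4L) + 1L]
}

#' Build the bi-allelic SNP site universe from haplotype databases
#'
#' Applies the engine's input filter: all insertion and deletion tokens are
#' dropped, and any position at which more than one distinct alternative
#' base occurs across the supplied databases (a multi-allelic locus, given
#' the reference base) is excluded. The remaining positions form an ordered
#' bi-allelic site list and every sample becomes a binary haplotype over it
#' (1 = carries the site's alternative allele).
#'
#' @param db an `empop_db` (or a list of them, whose samples are pooled for
#'   the multi-allelic filter so all components share one site coding).
#' @param rcrs optional named character vector of reference bases indexed by
#'   position; when absent a synthetic stand-in base is used.
#' @return a list of class `mito_haps` with elements `loci` (data.frame
#'   `pos`, `ref`, `alt`) and `H` (samples x sites binary integer matrix with
#'   sample IDs as rownames).
#' @examples
#' db <- parse_empop(text = c("S1\t263G 315.1C", "S2\t263G"))
#' u <- build_site_universe(db)
#' u$loci  # the insertion is gone; 263 A>G remains
#' @export
build_site_universe <- function(db, rcrs = NULL) {
  dbs <- if (inherits(db, "empop_db")) list(db) else db
  all <- do.call(rbind, lapply(dbs, function(d) {
    if (length(d) == 0L) return(NULL)
    do.call(rbind, lapply(names(d), function(id) {
      v <- d[[id]]
      if (nrow(v) == 0L) return(NULL)
      cbind(v, sample_id = id, stringsAsFactors = FALSE)
    }))
  }))
  ids <- unlist(lapply(dbs, names), use.names = FALSE)
  if (is.null(all) || nrow(all) == 0L) {
    loci <- data.frame(pos = integer(0), ref = character(0),
                       alt = character(0), stringsAsFactors = FALSE)
    H <- matrix(0L, nrow = length(ids), ncol = 0L,
                dimnames = list(ids, NULL))
    return(structure(list(loci = loci, H = H), class = "mito_haps"))
  }
  subs <- all[all$kind == "substitution", , drop = FALSE]
  # multi-allelic: >1 distinct alt base at a position across the pool
  n_alt <- tapply(subs$base, subs$position, function(b) length(unique(b)))
  keep_pos <- sort(as.integer(names(n_alt)[n_alt == 1L]))
  alt <- vapply(keep_pos, function(p) {
    unique(subs$base[subs$position == p])
  }, character(1))
  ref <- if (is.null(rcrs)) {
    synthetic_ref_base(keep_pos)
  } else {
    unname(rcrs[as.character(keep_pos)])
  }
  bad <- which(!is.na(ref) & ref == alt)
  if (length(bad) > 0L) {  # alt equal to reference base: not a variant site
    keep_pos <- keep_pos[-bad]
    alt <- alt[-bad]
    ref <- ref[-bad]
  }
  loci <- data.frame(pos = keep_pos, ref = ref, alt = alt,
                     stringsAsFactors = FALSE)
  H <- matrix(0L, nrow = length(ids), ncol = nrow(loci),
              dimnames = list(ids, as.character(keep_pos)))
  for (i in seq_len(nrow(subs))) {
    j <- match(subs$position[i], keep_pos)
    if (!is.na(j)) H[subs$sample_id[i], j] <- 1L
  }
  structure(list(loci = loci, H = H), class = "mito_haps")
}

#' @export
print.mito_haps <- function(x, ...) {
  cat(sprintf("mito_haps: %d haplotypes x %d bi-allelic sites\n",
              nrow(x$H), ncol(x$H)))
  invisible(x)
}

#' Per-site mixture genotype classes
#'
#' Classifies each site of a count table as `He` (reads supporting both
#' alleles), `HoR` (reference reads only), `HoA` (alternative reads only)
#' or `missing` (zero depth).
#'
#' @param counts a `site_counts` table (see [read_counts()]).
#' @return factor with levels `He`, `HoR`, `HoA`, `missing`.
#' @export
classify_sites <- function(counts) {
  r <- counts$ref_count
  a <- counts$alt_count
  cls <- ifelse(r + a == 0L, "missing",
         ifelse(r > 0L & a > 0L, "He",
         ifelse(a == 0L, "HoR", "HoA")))
  factor(cls, levels = c("He", "HoR", "HoA", "missing"))
}

#' Construct a site count table
#'
#' @param pos integer rCRS positions.
#' @param ref,alt reference / alternative bases.
#' @param ref_count,alt_count non-negative integer read counts.
#' @return a data.frame of class `site_counts`.
#' @export
site_counts <- function(pos, ref, alt, ref_count, alt_count) {
  stopifnot(length(pos) == length(ref_count),
            length(pos) == length(alt_count))
  if (any(ref_count < 0) || any(alt_count < 0)) {
    stop("read counts must be non-negative")
  }
  structure(
    data.frame(pos = as.integer(pos), ref = ref, alt = alt,
               ref_count = as.integer(ref_count),
               alt_count = as.integer(alt_count),
               stringsAsFactors = FALSE),
    class = c("site_counts", "data.frame"))
}

#' Write / read a site count table as TSV
#'
#' Plain TSV with header `POS REF ALT REF_COUNT ALT_COUNT`; the round trip
#' `read_counts(write_counts(x, f))` is exact.
#'
#' @param counts a `site_counts` table.
#' @param path file path.
#' @return `write_counts` returns `path` invisibly; `read_counts` returns a
#'   `site_counts` table.
#' @export
write_counts <- function(counts, path) {
  out <- data.frame(POS = counts$pos, REF = counts$ref, ALT = counts$alt,
                    REF_COUNT = counts$ref_count,
                    ALT_COUNT = counts$alt_count)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(NA, "character", "character", NA, NA))
  need <- c("POS", "REF", "ALT", "REF_COUNT", "ALT_COUNT")
  if (!all(need %in% names(x))) {
    stop("count table must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(x) == 0L) {
    return(site_counts(integer(0), character(0), character(0),
                       integer(0), integer(0)))
  }
  for (col in c("POS", "REF_COUNT", "ALT_COUNT")) {
    if (!is.numeric(x[[col]]) || any(x[[col]] != as.integer(x[[col]]))) {
      stop("column ", col, " must be integer")
    }
  }
  site_counts(x$POS, x$REF, x$ALT, x$REF_COUNT, x$ALT_COUNT)
}
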