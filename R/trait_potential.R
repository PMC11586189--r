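# Genus-level hydrocarbon-degradation potential: genome-fraction coefficients
# and coefficient-weighted community scores.

norm_genus <- function(x) tolower(trimws(x))

#' Derive per-genus marker coefficients from genome traits
#'
#' For each genus with at least one classified genome, the coefficient for a
#' marker set is the fraction of that genus's genomes satisfying the set's
#' combine rule — an estimate of the fraction of the genus harboring the
#' marker genes. Coefficients therefore lie in \[0, 1\] by construction.
#' Genomes labelled `"unclassified"` are excluded.
#'
#' @param g a [genome_trait_table()].
#' @param marker_sets list of [marker_set()] objects; each may group several
#'   HMM columns of `g` (subunits, homologs) under one functional marker.
#' @return object of class `trait_coefficients`: list with `coeff`
#'   (genus x marker matrix) and `n_genomes` (named integer vector).
#' @export
build_coefficients <- function(g, marker_sets) {
  stopifnot(inherits(g, "genome_trait_table"))
  if (inherits(marker_sets, "marker_set")) marker_sets <- list(marker_sets)
  for (ms in marker_sets) {
    missing <- setdiff(ms$hmm_ids, g$markers)
    if (length(missing) > 0L)
      stop("marker set '", ms$name, "' references unknown column(s): ",
           paste(missing, collapse = ", "))
  }
  keep <- g$genus_of != "unclassified"
  if (!any(keep)) stop("no classified genomes in trait table")
  pres <- g$presence[keep, , drop = FALSE]
  genus <- g$genus_of[keep]
  genera <- sort(unique(genus))
  n_genomes <- vapply(genera, function(gn) sum(genus == gn), integer(1L))
  marker_names <- vapply(marker_sets, `[[`, character(1L), "name")
  coeff <- matrix(NA_real_, nrow = length(genera), ncol = length(marker_names),
                  dimnames = list(genera, marker_names))
  for (ms in marker_sets) {
    sub <- pres[, ms$hmm_ids, drop = FALSE]
    sat <- if (ms$combine_rule == "any") rowSums(sub) > 0
           else rowSums(sub) == length(ms$hmm_ids)
    coeff[, ms$name] <- vapply(genera,
                               function(gn) mean(sat[genus == gn]),
                               numeric(1L))
  }
  structure(list(coeff = coeff, n_genomes = n_genomes),
            class = "trait_coefficients")
}

#' @export
print.trait_coefficients <- function(x, ...) {
  cat(sprintf("trait_coefficients: %d genera x %d markers\n",
              nrow(x$coeff), ncol(x$coeff)))
  invisible(x)
}

#' Write / read trait coefficients as TSV
#'
#' Columns: genus, n_genomes, then one column per marker set.
#' @param c a `trait_coefficients` object.
#' @param path file path.
#' @export
write_coefficients <- function(c, path) {
  stopifnot(inherits(c, "trait_coefficients"))
  df <- data.frame(genus = rownames(c$coeff),
                   n_genomes = unname(c$n_genomes[rownames(c$coeff)]),
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(c$coeff, check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# microdeg genus x marker coefficients (genome fractions)", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coefficients
#' @export
read_coefficients <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  stopifnot(all(c("genus", "n_genomes") %in% names(df)))
  markers <- setdiff(names(df), c("genus", "n_genomes"))
  coeff <- as.matrix(df[, markers, drop = FALSE])
  rownames(coeff) <- df$genus
  if (any(coeff < 0 | coeff > 1)) stop("coefficients must lie in [0, 1]")
  structure(list(coeff = coeff,
                 n_genomes = stats::setNames(as.integer(df$n_genomes),
                                             df$genus)),
            class = "trait_coefficients")
}

#' Score a community's hydrocarbon-degradation potential
#'
#' Multiplies each genus's relative abundance by its marker coefficient and
#' sums over genera:
#' `potential(s, m) = 100 * sum_g rel(s, g) * coeff(g, m)` (percent of the
#' community). Genera absent from the coefficient table — including
#' unclassified bins — contribute zero and are tallied per sample in
#' `unscored_fraction`; the community is never renormalized to scored taxa
#' only, so potentials remain fractions of the whole community.
#'
#' Genus names are matched exactly after whitespace trimming and case
#' folding; no fuzzy synonym resolution is attempted.
#'
#' @param t an [abundance_table()] in relative mode, collapsed to genus
#'   (taxon ids are genus names, e.g. from [collapse_to_rank()]).
#' @param c a `trait_coefficients` table covering any subset of `t`'s genera.
#' @return object of class `potential_profile`: `potential` (sample x marker
#'   matrix, percent), `unscored_fraction` (named vector, percent), and the
#'   table's `sample_meta`.
#' @export
estimate_potential <- function(t, c) {
  stopifnot(inherits(t, "abundance_table"), inherits(c, "trait_coefficients"))
  if (t$mode != "relative")
    stop("abundance table is in counts mode; apply to_relative() first")
  rel <- t$values
  key_t <- norm_genus(colnames(rel))
  key_c <- norm_genus(rownames(c$coeff))
  if (anyDuplicated(key_c))
    stop("coefficient table has genera identical after case folding")
  idx <- match(key_t, key_c)
  scored <- !is.na(idx)
  pot <- matrix(0, nrow = nrow(rel), ncol = ncol(c$coeff),
                dimnames = list(rownames(rel), colnames(c$coeff)))
  if (any(scored))
    pot <- 100 * rel[, scored, drop = FALSE] %*%
      c$coeff[idx[scored], , drop = FALSE]
  unscored <- 100 * rowSums(rel[, !scored, drop = FALSE])
  structure(list(sample_ids = rownames(rel),
                 markers = colnames(c$coeff),
                 potential = pot,
                 unscored_fraction = unscored,
                 sample_meta = t$sample_meta),
            class = "potential_profile")
}

#' @export
print.potential_profile <- function(x, ...) {
  cat(sprintf("potential_profile: %d samples x %d markers (percent)\n",
              nrow(x$potential), ncol(x$potential)))
  invisible(x)
}

#' Summarize potentials per sample group
#'
#' Reports minimum, maximum and mean potential per marker within groups
#' defined by a sample-metadata key — the form results are typically quoted
#' in (ranges across samples of a season or host).
#'
#' @param p a `potential_profile` carrying sample metadata.
#' @param group_by metadata column name; `NULL` pools all samples into one
#'   group `"all"`.
#' @return data.frame with columns group, marker, min, max, mean, n.
#' @export
potential_report <- function(p, group_by = NULL) {
  stopifnot(inherits(p, "potential_profile"))
  if (nrow(p$potential) == 0L) stop("empty potential profile")
  if (is.null(group_by)) {
    grp <- rep("all", nrow(p$potential))
  } else {
    if (is.null(p$sample_meta) || !group_by %in% colnames(p$sample_meta))
      stop("unknown sample metadata key: '", group_by, "'")
    grp <- as.character(p$sample_meta[rownames(p$potential), group_by])
  }
  out <- do.call(rbind, lapply(unique(grp), function(gv) {
    sub <- p$potential[grp == gv, , drop = FALSE]
    data.frame(group = gv, marker = colnames(sub),
               min = apply(sub, 2L, min), max = apply(sub, 2L, max),
               mean = colMeans(sub), n = nrow(sub), row.names = NULL)
  }))
  out
}
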