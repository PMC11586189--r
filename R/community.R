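# Community-table operations: ASV filtering, rank collapse, minor-taxon
# aggregation, Hellinger transform, PCA ordination.

#' Filter ASVs to one domain, discarding organelles
#'
#' Retains taxa classified to `domain_keep`, discarding taxa from other
#' domains, taxa unclassified at domain level, and any lineage containing
#' "Chloroplast" or "Mitochondria" at any rank (case-insensitive) — the
#' standard clean-up of plant-associated 16S libraries, where organelle
#' reads can dominate.
#'
#' Counts tables are subset as-is; relative tables are renormalized to the
#' retained taxa so downstream potentials are fractions of the retained
#' community. An audit of removals is attached as attribute `audit`.
#'
#' @param t an [abundance_table()] with lineages.
#' @param domain_keep domain to retain, default `"Bacteria"`.
#' @return filtered `abundance_table` with attribute `audit` (counts of
#'   input, retained, and removal reasons).
#' @export
filter_asvs <- function(t, domain_keep = "Bacteria") {
  stopifnot(inherits(t, "abundance_table"))
  if (is.null(t$lineages)) stop("table has no lineages; cannot filter")
  lin <- t$lineages[colnames(t$values)]
  domains <- vapply(lin, `[[`, character(1L), "domain")
  organelle <- vapply(lin, function(l)
    any(tolower(l) %in% c("chloroplast", "mitochondria"), na.rm = TRUE),
    logical(1L))
  unclassified <- is.na(domains)
  wrong_domain <- !unclassified & domains != domain_keep
  keep <- !unclassified & !wrong_domain & !organelle
  audit <- list(n_input = ncol(t$values),
                n_retained = sum(keep),
                n_removed_domain = sum(wrong_domain & !organelle),
                n_removed_unclassified = sum(unclassified & !organelle),
                n_removed_organelle = sum(organelle),
                empty_result = !any(keep))
  vals <- t$values[, keep, drop = FALSE]
  if (t$mode == "relative") {
    rs <- rowSums(vals)
    if (any(rs <= 0))
      stop("sample '", rownames(vals)[which(rs <= 0)[1L]],
           "' has no retained abundance after filtering")
    vals <- vals / rs
  }
  out <- abundance_table(vals, mode = t$mode, lineages = lin[keep],
                         sample_meta = t$sample_meta)
  attr(out, "audit") <- audit
  out
}

#' Collapse taxa to a taxonomic rank
#'
#' Sums abundances of taxa sharing the full lineage prefix down to `rank`
#' (e.g. all ASVs of the same genus). Taxa unclassified at `rank` are binned
#' by their deepest classified name as `unclassified_<name>` — e.g. ASVs
#' classified only to family Bacillaceae become `unclassified_Bacillaceae`.
#' Per-sample totals are conserved exactly.
#'
#' @param t an [abundance_table()] with lineages.
#' @param rank target rank, one of [RANKS].
#' @return collapsed `abundance_table`; taxon ids are the rank names and
#'   bin labels.
#' @export
collapse_to_rank <- function(t, rank = "genus") {
  stopifnot(inherits(t, "abundance_table"))
  if (is.null(t$lineages)) stop("table has no lineages; cannot collapse")
  if (!rank %in% RANKS) stop("unknown rank name: '", rank, "'")
  depth <- match(rank, RANKS)
  lin <- t$lineages[colnames(t$values)]
  info <- lapply(lin, function(l) {
    pre <- l[seq_len(depth)]
    if (!is.na(pre[depth])) {
      list(key = paste(pre, collapse = ";"), label = pre[depth], lineage = {
        full <- stats::setNames(rep(NA_character_, length(RANKS)), RANKS)
        full[seq_len(depth)] <- pre
        full
      })
    } else {
      deepest <- classified_depth(l)
      nm <- if (is.na(deepest)) "unclassified" else l[[deepest]]
      trunc <- stats::setNames(rep(NA_character_, length(RANKS)), RANKS)
      if (!is.na(deepest)) {
        d <- match(deepest, RANKS)
        trunc[seq_len(d)] <- l[seq_len(d)]
      }
      list(key = paste0("unclassified|", paste(l[!is.na(l)], collapse = ";")),
           label = paste0("unclassified_", nm), lineage = trunc)
    }
  })
  keys <- vapply(info, `[[`, character(1L), "key")
  groups <- split(seq_along(keys), keys)
  vals <- vapply(groups, function(ix)
    rowSums(t$values[, ix, drop = FALSE]), numeric(nrow(t$values)))
  if (nrow(t$values) == 1L) vals <- matrix(vals, nrow = 1L,
                                           dimnames = list(rownames(t$values),
                                                           names(groups)))
  labels <- vapply(groups, function(ix) info[[ix[1L]]]$label, character(1L))
  labels <- make.unique(unname(labels), sep = "_")
  colnames(vals) <- labels
  new_lin <- stats::setNames(lapply(groups, function(ix) info[[ix[1L]]]$lineage),
                             labels)
  abundance_table(vals, mode = t$mode, lineages = new_lin,
                  sample_meta = t$sample_meta)
}

#' Group minor taxa under "Other genera"
#'
#' A taxon is retained iff its relative abundance reaches `threshold_pct`
#' (>=, boundary retained) in at least one sample; all taxa strictly below
#' the threshold in every sample are merged into a single `"Other genera"`
#' row. Per-sample sums are conserved. The operation is idempotent at a
#' fixed threshold.
#'
#' @param t an [abundance_table()] in relative mode.
#' @param threshold_pct threshold in percent, strictly between 0 and 100;
#'   2 and 5 are common barplot choices.
#' @param other_label label of the merged row.
#' @return aggregated `abundance_table`.
#' @export
aggregate_minor <- function(t, threshold_pct = 2, other_label = "Other genera") {
  stopifnot(inherits(t, "abundance_table"))
  if (t$mode != "relative")
    stop("aggregate_minor needs a relative table; apply to_relative() first")
  if (!is.numeric(threshold_pct) || threshold_pct <= 0 || threshold_pct >= 100)
    stop("threshold_pct must lie strictly between 0 and 100")
  peak <- apply(t$values, 2L, max) * 100
  keep <- peak >= threshold_pct | colnames(t$values) == other_label
  if (all(keep)) return(t)
  other <- rowSums(t$values[, !keep, drop = FALSE])
  vals <- t$values[, keep, drop = FALSE]
  if (other_label %in% colnames(vals)) {
    vals[, other_label] <- vals[, other_label] + other
  } else {
    vals <- cbind(vals, other)
    colnames(vals)[ncol(vals)] <- other_label
  }
  lineages <- NULL
  if (!is.null(t$lineages)) {
    lineages <- t$lineages[colnames(t$values)[keep]]
    lineages[[other_label]] <- stats::setNames(
      rep(NA_character_, length(RANKS)), RANKS)
  }
  abundance_table(vals, mode = "relative", lineages = lineages,
                  sample_meta = t$sample_meta)
}

#' Hellinger transform
#'
#' Square root of relative abundances. Euclidean distance between
#' transformed rows equals the Hellinger distance between compositions, so
#' PCA of the transformed matrix is a Hellinger-distance ordination; each
#' transformed sample row has unit Euclidean norm.
#'
#' @param t an [abundance_table()]; counts are converted to relative
#'   internally.
#' @return numeric samples x taxa matrix of square-rooted proportions.
#' @export
hellinger <- function(t) {
  stopifnot(inherits(t, "abundance_table"))
  t <- to_relative(t, allow_relative = TRUE)
  sqrt(t$values)
}

#' Principal component analysis with a deterministic sign convention
#'
#' Column-centered, unscaled PCA (Hellinger-transformed inputs already share
#' a common row geometry, so no column scaling is applied). Per-axis
#' variance fractions are relative to the total variance over all
#' `min(n - 1, p)` axes, and each axis's sign is fixed so that its
#' largest-magnitude loading is positive, making score tables reproducible
#' across platforms.
#'
#' @param m numeric samples x variables matrix (e.g. from [hellinger()]).
#' @param n_axes number of axes to return.
#' @return object of class `ordination_result`: `sample_scores`,
#'   `axis_variance_fraction`, `n_axes`, `taxon_loadings`, `audit`.
#' @export
pca_ordination <- function(m, n_axes = 2L) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("PCA needs at least 2 samples")
  max_axes <- min(nrow(m) - 1L, ncol(m))
  if (n_axes > max_axes)
    stop("n_axes must not exceed min(samples - 1, variables) = ", max_axes)
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  eig <- pc$sdev^2
  total <- sum(eig)
  degenerate <- total <= .Machine$double.eps * max(1, max(abs(m)))^2
  frac <- if (degenerate) rep(0, length(eig)) else eig / total
  scores <- pc$x[, seq_len(n_axes), drop = FALSE]
  loadings <- pc$rotation[, seq_len(n_axes), drop = FALSE]
  for (a in seq_len(n_axes)) {
    j <- which.max(abs(loadings[, a]))
    if (loadings[j, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(n_axes))
  structure(list(sample_scores = scores,
                 axis_variance_fraction = frac[seq_len(n_axes)],
                 all_variance_fractions = frac,
                 n_axes = n_axes,
                 taxon_loadings = loadings,
                 audit = list(degenerate = degenerate,
                              max_axes = max_axes)),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("ordination_result: %d samples, %d axes (%s%% variance)\n",
              nrow(x$sample_scores), x$n_axes,
              paste(sprintf("%.1f", 100 * x$axis_variance_fraction),
                    collapse = " + ")))
  invisible(x)
}
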