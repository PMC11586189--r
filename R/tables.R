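# Data model and I/O: abundance tables, lineages, genome-trait tables,
# hmmsearch tblout hit files.

#' Taxonomic ranks used throughout the package
#'
#' Ordered from domain to genus; lineages are stored as named character
#' vectors over exactly these ranks, with `NA` below the deepest classified
#' rank.
#' @export
RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Parse a semicolon-delimited lineage string
#'
#' Accepts the lineage dialects emitted by common amplicon classifiers:
#' semicolon-separated ranked names, optionally carrying rank prefixes such
#' as `g__` (stripped). Assignments are truncated at the first empty rank so
#' that names are present contiguously from domain down to the deepest
#' classified rank and absent below it.
#'
#' @param x a single lineage string, e.g.
#'   `"Bacteria;Pseudomonadota;Alphaproteobacteria;Sphingomonadales;Sphingomonadaceae;Sphingomonas"`.
#' @return named character vector over [RANKS]; unassigned ranks are `NA`.
#' @examples
#' parse_lineage("Bacteria;Bacillota;Bacilli;Bacillales;Bacillaceae")
#' @export
parse_lineage <- function(x) {
  out <- stats::setNames(rep(NA_character_, length(RANKS)), RANKS)
  if (is.null(x) || length(x) != 1L || is.na(x)) return(out)
  parts <- trimws(strsplit(as.character(x), ";", fixed = TRUE)[[1L]])
  parts <- sub("^[a-zA-Z]__", "", parts)
  n <- min(length(parts), length(RANKS))
  if (n == 0L) return(out)
  parts <- parts[seq_len(n)]
  # truncate at first empty assignment: no gaps allowed
  empty <- which(parts == "" | is.na(parts) | tolower(parts) %in%
                   c("na", "unclassified", "unknown"))
  if (length(empty) > 0L) n <- empty[1L] - 1L
  if (n > 0L) out[seq_len(n)] <- parts[seq_len(n)]
  out
}

#' Deepest classified rank of a lineage
#'
#' @param lineage named character vector as returned by [parse_lineage()].
#' @return rank name (one of [RANKS]) or `NA` if unclassified at domain.
#' @export
classified_depth <- function(lineage) {
  ok <- which(!is.na(lineage[RANKS]))
  if (length(ok) == 0L) return(NA_character_)
  RANKS[max(ok)]
}

deparse_lineage <- function(lineage) {
  paste(lineage[!is.na(lineage)], collapse = ";")
}

#' Construct an abundance table
#'
#' The central container: a samples x taxa non-negative matrix in `counts`
#' or `relative` mode, with optional per-taxon lineages and per-sample
#' metadata. In relative mode every sample row must sum to 1 (within 1e-9).
#'
#' @param values numeric matrix, samples in rows, taxa in columns; both
#'   dimensions named with unique identifiers.
#' @param mode `"counts"` or `"relative"`.
#' @param lineages optional named list mapping taxon id to a lineage vector
#'   (see [parse_lineage()]), or a character vector of lineage strings.
#' @param sample_meta optional data.frame of per-sample labels, rows matching
#'   `rownames(values)`.
#' @return object of class `abundance_table`.
#' @export
abundance_table <- function(values, mode = c("counts", "relative"),
                            lineages = NULL, sample_meta = NULL) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have sample row names and taxon column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample id: ",
         rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop("duplicate taxon id: ",
         colnames(values)[duplicated(colnames(values))][1L])
  if (any(!is.finite(values)) || any(values < 0))
    stop("abundance values must be finite and non-negative")
  if (mode == "relative") {
    rs <- rowSums(values)
    bad <- which(abs(rs - 1) > 1e-9)
    if (length(bad) > 0L)
      stop("relative-mode row does not sum to 1: sample '",
           rownames(values)[bad[1L]], "' (sum = ", rs[bad[1L]], ")")
  }
  if (is.character(lineages)) {
    if (length(lineages) != ncol(values))
      stop("lineage strings must match the number of taxa")
    lineages <- stats::setNames(lapply(lineages, parse_lineage),
                                colnames(values))
  }
  if (!is.null(lineages)) {
    if (!all(colnames(values) %in% names(lineages)))
      stop("lineages missing for some taxa")
    lineages <- lineages[colnames(values)]
  }
  if (!is.null(sample_meta)) {
    sample_meta <- as.data.frame(sample_meta)
    if (!all(rownames(values) %in% rownames(sample_meta)))
      stop("sample_meta missing rows for some samples")
    sample_meta <- sample_meta[rownames(values), , drop = FALSE]
  }
  structure(list(values = values, mode = mode, lineages = lineages,
                 sample_meta = sample_meta),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d taxa (%s mode)%s\n",
              nrow(x$values), ncol(x$values), x$mode,
              if (is.null(x$lineages)) "" else ", with lineages"))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Sample identifiers of an abundance table
#' @param t an `abundance_table`.
#' @export
sample_ids <- function(t) rownames(t$values)

#' Taxon identifiers of an abundance table
#' @param t an `abundance_table`.
#' @export
taxon_ids <- function(t) colnames(t$values)

# -- TSV reading -------------------------------------------------------------

split_tsv_lines <- function(path) {
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  if (length(lines) < 2L)
    stop("file '", path, "' has no data rows")
  list(fields = strsplit(lines, "\t", fixed = TRUE),
       line_no = which(keep))
}

#' Read an abundance table from TSV
#'
#' Reads a tab-separated table with one header line. The orientation must be
#' declared: `taxa_rows` (taxa in rows, samples in columns; the layout QIIME
#' and DADA2 exports commonly use, optionally with a trailing lineage column)
#' or `samples_rows` (samples in rows). There is no orientation auto-detect:
#' silently transposed tables are a classic source of wrong results.
#'
#' Mode is `counts` unless every sample row sums to 1 (within 1e-6), in which
#' case the table is flagged `relative`. Lines starting with `#` are skipped.
#'
#' @param path file path.
#' @param dialect `"taxa_rows"` or `"samples_rows"`.
#' @param lineage_col name of the lineage column (taxa_rows dialect only).
#' @return an [abundance_table()].
#' @export
read_abundance_table <- function(path, dialect = c("taxa_rows", "samples_rows"),
                                 lineage_col = "lineage") {
  dialect <- match.arg(dialect)
  parsed <- split_tsv_lines(path)
  fields <- parsed$fields
  line_no <- parsed$line_no
  header <- fields[[1L]]
  ncol_expect <- length(header)
  body <- fields[-1L]
  body_lines <- line_no[-1L]
  widths <- lengths(body)
  if (any(widths != ncol_expect))
    stop("ragged row at line ", body_lines[which(widths != ncol_expect)[1L]],
         ": expected ", ncol_expect, " fields, found ",
         widths[which(widths != ncol_expect)[1L]])

  row_ids <- vapply(body, `[`, character(1L), 1L)
  col_ids <- header[-1L]
  lin_idx <- NULL
  if (dialect == "taxa_rows" && lineage_col %in% col_ids) {
    lin_idx <- which(col_ids == lineage_col) + 1L  # position within fields
    lineage_strings <- vapply(body, `[`, character(1L), lin_idx)
    col_ids <- col_ids[col_ids != lineage_col]
  }
  if (anyDuplicated(row_ids))
    stop("duplicate identifier '", row_ids[duplicated(row_ids)][1L],
         "' in first column")
  if (anyDuplicated(col_ids))
    stop("duplicate identifier '", col_ids[duplicated(col_ids)][1L],
         "' in header")

  val_pos <- setdiff(seq_len(ncol_expect)[-1L], lin_idx)
  m <- matrix(NA_real_, nrow = length(body), ncol = length(val_pos),
              dimnames = list(row_ids, col_ids))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][val_pos]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop("non-numeric value '", body[[i]][val_pos[j]], "' at line ",
           body_lines[i], ", column '", col_ids[j], "'")
    }
    m[i, ] <- v
  }
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop("negative value at row '", rownames(m)[neg[1L, 1L]],
         "', column '", colnames(m)[neg[1L, 2L]], "'")

  lineages <- NULL
  if (dialect == "taxa_rows") {
    if (!is.null(lin_idx))
      lineages <- stats::setNames(lapply(lineage_strings, parse_lineage),
                                  row_ids)
    m <- t(m)
  }
  mode <- if (all(abs(rowSums(m) - 1) < 1e-6)) "relative" else "counts"
  if (mode == "relative") m <- m / rowSums(m)  # exact renormalization
  abundance_table(m, mode = mode, lineages = lineages)
}

#' Write an abundance table to TSV
#'
#' Emits a taxa-in-rows TSV with a `#`-comment provenance header; lineages,
#' when present, go into a final `lineage` column. Counts are written
#' exactly; relative abundances at full double precision.
#'
#' @param t an `abundance_table`.
#' @param path output file path.
#' @export
write_abundance_table <- function(t, path) {
  stopifnot(inherits(t, "abundance_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# microdeg %s abundance table", t$mode),
               sprintf("# written %s", format(Sys.time(), "%Y-%m-%d"))), con)
  has_lin <- !is.null(t$lineages)
  header <- c("taxon_id", rownames(t$values), if (has_lin) "lineage")
  writeLines(paste(header, collapse = "\t"), con)
  vals <- t(t$values)  # taxa x samples
  for (i in seq_len(nrow(vals))) {
    num <- format(vals[i, ], digits = 17, trim = TRUE, scientific = FALSE)
    row <- c(rownames(vals)[i], num,
             if (has_lin) deparse_lineage(t$lineages[[rownames(vals)[i]]]))
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}

#' Convert a counts table to relative abundances
#'
#' Divides each sample row by its total. Zero counts map to zero; a sample
#' with no counts at all is an error (its composition is undefined).
#'
#' @param t an `abundance_table` in counts mode.
#' @param allow_relative if `TRUE`, a relative-mode input is returned
#'   unchanged instead of raising an error.
#' @return the table in relative mode.
#' @export
to_relative <- function(t, allow_relative = FALSE) {
  stopifnot(inherits(t, "abundance_table"))
  if (t$mode == "relative") {
    if (allow_relative) return(t)
    stop("table is already in relative mode (use allow_relative = TRUE ",
         "to accept)")
  }
  rs <- rowSums(t$values)
  if (any(rs <= 0))
    stop("all-zero sample row: '", rownames(t$values)[which(rs <= 0)[1L]], "'")
  abundance_table(t$values / rs, mode = "relative", lineages = t$lineages,
                  sample_meta = t$sample_meta)
}

# -- genome-trait tables -----------------------------------------------------

#' Construct a genome-trait table
#'
#' Per-genome boolean presence of hydrocarbon-degradation marker genes, with
#' a genus label per genome. Genomes lacking a genus assignment carry the
#' sentinel `"unclassified"` and are excluded from coefficient estimation.
#'
#' @param presence logical (or 0/1) matrix, genomes in rows (named), markers
#'   in columns (named).
#' @param genus_of named character vector mapping genome id to genus.
#' @return object of class `genome_trait_table`.
#' @export
genome_trait_table <- function(presence, genus_of) {
  presence <- as.matrix(presence)
  if (is.null(rownames(presence)) || is.null(colnames(presence)))
    stop("presence must have genome row names and marker column names")
  if (anyDuplicated(rownames(presence)))
    stop("duplicate genome_id: ",
         rownames(presence)[duplicated(rownames(presence))][1L])
  if (is.numeric(presence)) {
    if (!all(presence %in% c(0, 1)))
      stop("presence values must be strictly 0/1")
    presence <- presence == 1
  }
  if (!is.logical(presence)) stop("presence must be boolean")
  genus_of <- genus_of[rownames(presence)]
  genus_of[is.na(genus_of) | genus_of == ""] <- "unclassified"
  names(genus_of) <- rownames(presence)
  structure(list(genome_ids = rownames(presence),
                 genus_of = genus_of,
                 markers = colnames(presence),
                 presence = presence),
            class = "genome_trait_table")
}

#' @export
print.genome_trait_table <- function(x, ...) {
  cat(sprintf("genome_trait_table: %d genomes, %d genera, %d markers\n",
              length(x$genome_ids), length(unique(x$genus_of)),
              length(x$markers)))
  invisible(x)
}

#' Read a genome-trait table from TSV
#'
#' Expects columns `genome_id`, `genus`, then one 0/1 column per marker.
#' An empty genus cell becomes the sentinel `"unclassified"`.
#'
#' @param path file path.
#' @return a [genome_trait_table()].
#' @export
read_genome_traits <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          colClasses = "character")
  if (!all(c("genome_id", "genus") %in% names(df)))
    stop("genome-trait TSV needs 'genome_id' and 'genus' columns")
  if (anyDuplicated(df$genome_id))
    stop("duplicate genome_id: ", df$genome_id[duplicated(df$genome_id)][1L])
  marker_cols <- setdiff(names(df), c("genome_id", "genus"))
  if (length(marker_cols) == 0L) stop("no marker columns found")
  m <- as.matrix(df[, marker_cols, drop = FALSE])
  if (!all(m %in% c("0", "1")))
    stop("non-binary presence value '",
         m[which(!(m %in% c("0", "1")))[1L]], "'")
  pres <- matrix(m == "1", nrow = nrow(df),
                 dimnames = list(df$genome_id, marker_cols))
  genus <- df$genus
  genus[is.na(genus) | trimws(genus) == ""] <- "unclassified"
  genome_trait_table(pres, stats::setNames(genus, df$genome_id))
}

#' Write a genome-trait table to TSV
#' @param g a `genome_trait_table`.
#' @param path output file path.
#' @export
write_genome_traits <- function(g, path) {
  stopifnot(inherits(g, "genome_trait_table"))
  df <- data.frame(genome_id = g$genome_ids, genus = unname(g$genus_of),
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(g$presence * 1L, check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# microdeg genome-trait table (0/1 marker presence)", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- hmmsearch tblout --------------------------------------------------------

#' Read hmmsearch tblout hits into a per-genome presence matrix
#'
#' Parses the whitespace-delimited `--tblout` format of hmmsearch (target
#' name in column 1, query/HMM name in column 3, full-sequence E-value in
#' column 5; `#` lines are comments), retains hits with E-value at or below
#' `evalue_max`, and maps hit targets (typically protein or contig ids) to
#' genomes. Any retained hit makes the genome positive for that HMM.
#'
#' Targets missing from `genome_map` are skipped with a warning; the skip
#' count is attached as attribute `n_skipped`.
#'
#' @param path tblout file path.
#' @param evalue_max maximum full-sequence E-value; default 1e-5, a common
#'   conservative cut-off for marker-gene presence calls.
#' @param genome_map named character vector: target name -> genome id.
#' @return logical genome x HMM matrix with attribute `n_skipped`.
#' @export
read_hmm_hits <- function(path, evalue_max = 1e-5, genome_map) {
  stopifnot(is.numeric(evalue_max), evalue_max > 0)
  raw <- readLines(path, warn = FALSE)
  data_idx <- which(!grepl("^#", raw) & nzchar(trimws(raw)))
  genomes <- sort(unique(unname(genome_map)))
  hmms <- character(0)
  recs <- list()
  n_skipped <- 0L
  for (i in data_idx) {
    f <- strsplit(trimws(raw[i]), "\\s+")[[1L]]
    if (length(f) < 5L)
      stop("malformed tblout row at line ", i, ": fewer than 5 fields")
    ev <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(ev))
      stop("malformed E-value '", f[5L], "' at line ", i)
    if (ev > evalue_max) next
    target <- f[1L]
    if (!target %in% names(genome_map)) {
      n_skipped <- n_skipped + 1L
      next
    }
    recs[[length(recs) + 1L]] <- c(genome_map[[target]], f[3L])
  }
  if (n_skipped > 0L)
    warning(n_skipped, " hit(s) with unmappable target skipped")
  hmms <- sort(unique(vapply(recs, `[`, character(1L), 2L)))
  out <- matrix(FALSE, nrow = length(genomes), ncol = length(hmms),
                dimnames = list(genomes, hmms))
  for (r in recs) out[r[1L], r[2L]] <- TRUE
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Build a genome-trait table from an hmm hit presence matrix
#'
#' @param hits logical genome x HMM matrix as returned by [read_hmm_hits()].
#' @param genus_of named character vector mapping genome id to genus; genomes
#'   absent from the map get the sentinel `"unclassified"`.
#' @return a [genome_trait_table()].
#' @export
traits_from_hits <- function(hits, genus_of) {
  g <- stats::setNames(genus_of[rownames(hits)], rownames(hits))
  genome_trait_table(hits, g)
}

#' Define a marker set
#'
#' A named group of profile HMMs whose hits count toward one functional
#' marker (e.g. the subunits and homologs grouped as "naphthalene
#' dioxygenase"). With `combine_rule = "any"` a genome is positive if any
#' member HMM hits; `"all"` demands every member (multi-subunit strictness).
#'
#' @param name marker-set label.
#' @param hmm_ids character vector of member HMM identifiers (non-empty).
#' @param combine_rule `"any"` (default) or `"all"`.
#' @return object of class `marker_set`.
#' @export
marker_set <- function(name, hmm_ids, combine_rule = c("any", "all")) {
  combine_rule <- match.arg(combine_rule)
  if (length(hmm_ids) == 0L) stop("hmm_ids must be non-empty")
  structure(list(name = name, hmm_ids = as.character(hmm_ids),
                 combine_rule = combine_rule),
            class = "marker_set")
}

#' Read marker-set definitions from TSV
#'
#' Columns: `name`, `hmm_ids` (comma-separated member HMM identifiers),
#' optional `combine_rule` (`any`/`all`, default `any`).
#'
#' @param path file path.
#' @return list of [marker_set()] objects.
#' @export
read_marker_sets <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          colClasses = "character")
  if (!all(c("name", "hmm_ids") %in% names(df)))
    stop("marker-set TSV needs 'name' and 'hmm_ids' columns")
  lapply(seq_len(nrow(df)), function(i) {
    rule <- if ("combine_rule" %in% names(df) &&
                nzchar(df$combine_rule[i])) df$combine_rule[i] else "any"
    marker_set(df$name[i],
               trimws(strsplit(df$hmm_ids[i], ",", fixed = TRUE)[[1L]]),
               combine_rule = rule)
  })
}
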