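#' Read an OTU time-series table from disk
#'
#' Two dialects are supported. `"tsv"`: tab-delimited, taxa as rows, first
#' column the taxon id, header row the sample ids; collection days come from
#' a `#day` metadata row (first cell literally `#day`, remaining cells the
#' day of each sample) or from a sidecar metadata CSV passed as `metadata`
#' with columns `sample_id, day`. An optional trailing `taxonomy` column
#' carries lineage strings. `"biom-json"`: a BIOM v1 (JSON) table read with
#' the biomformat package; days must then come from `metadata`.
#'
#' @param path Path to the table file.
#' @param dialect `"tsv"` or `"biom-json"`.
#' @param metadata Optional path to a CSV with columns `sample_id, day`.
#' @param units Units tag of the stored values (`"counts"` default).
#' @return A validated [otu_table()] with samples sorted by day.
#' @export
read_otu_table <- function(path, dialect = c("tsv", "biom-json"),
                           metadata = NULL, units = "counts") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "biom-json") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM tables requires the biomformat package")
    }
    b <- biomformat::read_biom(path)
    values <- as.matrix(biomformat::biom_data(b))
    taxon_ids <- rownames(values)
    sample_ids <- colnames(values)
    if (is.null(metadata)) stop("biom-json input requires a `metadata` CSV with sample days")
    days <- lookup_days(sample_ids, metadata)
    return(otu_table(values, taxon_ids, days, sample_ids, units = units))
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("TSV table needs a taxon-id column plus >= 1 sample column")
  ids <- as.character(raw[[1]])
  taxonomy <- NULL
  if (tolower(names(raw)[ncol(raw)]) == "taxonomy") {
    taxonomy <- as.character(raw[[ncol(raw)]])
    raw <- raw[, -ncol(raw), drop = FALSE]
  }
  sample_ids <- names(raw)[-1]
  day_row <- which(ids == "#day")
  body <- raw[setdiff(seq_along(ids), day_row), -1, drop = FALSE]
  taxon_ids <- ids[setdiff(seq_along(ids), day_row)]
  if (!is.null(taxonomy)) taxonomy <- taxonomy[setdiff(seq_along(ids), day_row)]
  for (j in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[[1]]
      stop(sprintf("non-numeric cell at taxon '%s', sample '%s'",
                   taxon_ids[bad], sample_ids[j]))
    }
    body[[j]] <- v
  }
  values <- as.matrix(body)
  if (length(day_row) == 1) {
    days <- suppressWarnings(as.numeric(unlist(raw[day_row, -1])))
    if (anyNA(days)) stop("unparseable #day metadata row")
  } else if (!is.null(metadata)) {
    days <- lookup_days(sample_ids, metadata)
  } else {
    stop("no sample days: provide a #day row or a `metadata` CSV")
  }
  otu_table(values, taxon_ids, days, sample_ids, units = units,
            taxonomy = taxonomy)
}

lookup_days <- function(sample_ids, metadata_path) {
  if (!file.exists(metadata_path)) stop("no such metadata file: ", metadata_path)
  md <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "day")
  if (!all(need %in% names(md))) stop("metadata CSV must have columns sample_id, day")
  idx <- match(sample_ids, md$sample_id)
  if (anyNA(idx)) {
    stop("metadata CSV missing day for sample: ", sample_ids[is.na(idx)][[1]])
  }
  days <- suppressWarnings(as.numeric(md$day[idx]))
  if (anyNA(days)) stop("unparseable day in metadata CSV")
  days
}

#' Write an OTU table as TSV
#'
#' Inverse of [read_otu_table()]'s TSV dialect: taxa as rows, a `#day`
#' metadata row, optional trailing taxonomy column.
#'
#' @param table An `otu_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  con <- file(path, "w")
  on.exit(close(con))
  has_tax <- !is.null(table$taxonomy)
  header <- c("taxon_id", table$sample_ids, if (has_tax) "taxonomy")
  writeLines(paste(header, collapse = "\t"), con)
  day_line <- c("#day", format(table$sample_days, trim = TRUE, scientific = FALSE),
                if (has_tax) "")
  writeLines(paste(day_line, collapse = "\t"), con)
  vals <- format(table$values, trim = TRUE, scientific = FALSE, digits = 12)
  for (i in seq_len(n_taxa(table))) {
    line <- c(table$taxon_ids[i], vals[i, ], if (has_tax) table$taxonomy[i])
    writeLines(paste(line, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' Plain "square" dialect: first line the number of taxa, then one row per
#' taxon with its name followed by the full row of distances.
#'
#' @param path Path to the matrix file.
#' @return A symmetric matrix with taxon ids as dimnames.
#' @export
read_phylip_distances <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[[1]]))
  if (is.na(n) || length(lines) < n + 1) stop("malformed PHYLIP matrix")
  ids <- character(n)
  vals <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[[i + 1]]), "\\s+")[[1]]
    ids[i] <- parts[[1]]
    row <- suppressWarnings(as.numeric(parts[-1]))
    if (length(row) != n || anyNA(row)) stop("malformed row for taxon ", parts[[1]])
    vals[i, ] <- row
  }
  if (max(abs(vals - t(vals))) > 1e-8) stop("distance matrix is not symmetric")
  dimnames(vals) <- list(ids, ids)
  vals
}
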