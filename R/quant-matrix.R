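#' Construct a quantitative feature-by-sample matrix
#'
#' The central data container of the pipeline: a numeric matrix with
#' features in rows and samples in columns, values on the log2 scale unless
#' stated otherwise, and \code{NA} for missing quantifications. The layer
#' tag records which molecular layer the matrix holds.
#'
#' @param values Numeric matrix with unique rownames (feature ids) and
#'   unique colnames (sample ids). \code{NA} allowed; infinities are not.
#' @param layer One of \code{"protein"}, \code{"phosphopeptide"},
#'   \code{"rna"}, \code{"score"}.
#' @return The validated matrix with a \code{"layer"} attribute.
#' @export
quant_matrix <- function(values, layer = c("protein", "phosphopeptide",
                                           "rna", "score")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop2("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop2("'values' must have feature rownames and sample colnames")
  dup_r <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_r))
    stop2("duplicate feature ids: ", paste(dup_r, collapse = ", "))
  dup_c <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_c))
    stop2("duplicate sample ids: ", paste(dup_c, collapse = ", "))
  if (any(is.infinite(values)))
    stop2("infinite values are not permitted in a quant matrix")
  attr(values, "layer") <- layer
  values
}

#' @rdname quant_matrix
#' @param x A matrix.
#' @export
quant_layer <- function(x) attr(x, "layer") %||% "protein"

#' Read a quantitative matrix from a tab-separated file
#'
#' Expects a header row of sample ids and a first column of feature ids.
#' Empty cells denote missing values; any other non-numeric cell is an
#' error that names its position.
#'
#' @param path Path to a tab-separated text file.
#' @param layer Layer tag passed to [quant_matrix()].
#' @return A quant matrix preserving the file's feature and sample order.
#' @export
read_quant_table <- function(path, layer = "protein") {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2L) stop2("expected a feature-id column plus sample columns")
  ids <- raw[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop2("duplicate feature ids in ", path, ": ", paste(dup, collapse = ", "))
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(vals) & !(cells == "" | is.na(cells) | cells == "NA"))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(cells)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(cells)) + 1L
    stop2("non-numeric value '", cells[i, j], "' at feature ", ids[i],
          ", sample ", colnames(cells)[j])
  }
  rownames(vals) <- ids
  colnames(vals) <- colnames(cells)
  quant_matrix(vals, layer)
}

#' Write a quantitative matrix to a tab-separated file
#'
#' Missing values are written as empty cells so they survive a round trip
#' unambiguously (log2 data can legitimately be zero or negative).
#'
#' @param x Quant matrix.
#' @param path Output path.
#' @param id_col Name of the feature-id column in the header.
#' @export
write_quant_table <- function(x, path, id_col = "feature_id") {
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT layout: one set per line, fields are set name, description,
#' then member genes. Duplicate genes within a set are removed, keeping the
#' first occurrence.
#'
#' @param path Path to a GMT file.
#' @param source_tag Free-text provenance label stored on the result.
#' @return A named list of character vectors of gene symbols, with
#'   attribute \code{source_tag}.
#' @export
read_gmt <- function(path, source_tag = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop2("GMT line ", i, " has fewer than 3 fields")
    nm[[i]] <- f[[1L]]
    genes <- f[-c(1L, 2L)]
    sets[[i]] <- genes[!duplicated(genes) & nzchar(genes)]
  }
  if (anyDuplicated(nm))
    stop2("duplicate gene-set names: ",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(sets) <- nm
  attr(sets, "source_tag") <- source_tag
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(n) {
    paste(c(n, "na", sets[[n]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical sample table
#'
#' Tab-separated, one row per sample. Logical subgroup flags are parsed
#' from TRUE/FALSE or 0/1; empty cells are missing.
#'
#' @param path Path to a tab-separated clinical table.
#' @return A data.frame with one row per sample.
#' @export
read_clinical_table <- function(path) {
  cl <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"))
  if (!"sample_id" %in% names(cl)) stop2("clinical table needs 'sample_id'")
  if (anyDuplicated(cl$sample_id)) stop2("duplicate sample ids in clinical table")
  flag_cols <- intersect(names(cl),
                         c("t_11_14", "t_4_14", "t_14_16", "hrd", "del_13q",
                           "del_17p", "del_1p", "macs_sorted",
                           "pfs_event", "os_event"))
  for (f in flag_cols) cl[[f]] <- as.integer(as.logical(cl[[f]]) |
                                               cl[[f]] %in% c(1, "1"))
  cl
}

#' Write a clinical sample table
#' @param clinical Data frame as produced by [generate_cohort()].
#' @param path Output path.
#' @export
write_clinical_table <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}
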