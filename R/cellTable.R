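#' Validate a cell table
#'
#' A cell table is a data.frame with one row per segmented cell and
#' columns \code{cell_id}, \code{x}, \code{y}, \code{sample_id},
#' \code{condition} and (optionally filled) \code{cell_type}.
#' Coordinates are centroid positions in pixel units with x = column
#' index and y = row index, 0-based at pixel centers.
#'
#' Checks performed: required columns present; \code{cell_id} unique
#' within \code{sample_id}; coordinates finite; \code{condition}
#' constant within each sample.  Violations raise an error naming the
#' offending column (and file, when supplied).
#'
#' @param cells data.frame to validate.
#' @param file optional path the table was read from, used in messages.
#' @return the validated data.frame, invisibly, with \code{cell_type}
#'   missing values replaced by \code{"unknown"} only when
#'   \code{fillUnknown = TRUE}.
#' @param fillUnknown replace missing cell types by \code{"unknown"}.
#' @export
validateCellTable <- function(cells, file = NULL, fillUnknown = FALSE) {
  where <- if (is.null(file)) "cell table" else sprintf("cell table '%s'", file)
  required <- c("cell_id", "x", "y", "sample_id", "condition")
  missing <- setdiff(required, names(cells))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", where,
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (!is.numeric(cells$x) || !is.numeric(cells$y))
    stop(sprintf("%s: columns 'x' and 'y' must be numeric", where), call. = FALSE)
  if (any(!is.finite(cells$x)) || any(!is.finite(cells$y)))
    stop(sprintf("%s: non-finite values in column 'x' or 'y'", where), call. = FALSE)
  dup <- duplicated(paste(cells$sample_id, cells$cell_id, sep = "\r"))
  if (any(dup))
    stop(sprintf("%s: column 'cell_id' not unique within sample_id (e.g. %s)",
                 where, paste(utils::head(cells$cell_id[dup], 3), collapse = ", ")),
         call. = FALSE)
  byCond <- tapply(as.character(cells$condition), cells$sample_id,
                   function(v) length(unique(v)))
  if (any(byCond > 1))
    stop(sprintf("%s: column 'condition' not constant within sample(s): %s",
                 where, paste(names(byCond)[byCond > 1], collapse = ", ")),
         call. = FALSE)
  if (!"cell_type" %in% names(cells)) cells$cell_type <- NA_character_
  if (fillUnknown) {
    ct <- as.character(cells$cell_type)
    ct[is.na(ct) | ct == ""] <- "unknown"
    cells$cell_type <- ct
  }
  invisible(cells)
}

#' Read or write a cell table CSV
#'
#' The CSV dialect has header
#' \code{cell_id,x,y,sample_id,condition,cell_type} (\code{cell_type}
#' may be empty).
#'
#' @param path file path.
#' @return `readCellTable` returns the validated data.frame.
#' @export
readCellTable <- function(path) {
  cells <- read.csv(path, stringsAsFactors = FALSE)
  validateCellTable(cells, file = path)
}

#' @rdname readCellTable
#' @param cells a cell table data.frame.
#' @export
writeCellTable <- function(cells, path) {
  validateCellTable(cells)
  write.csv(cells, path, row.names = FALSE)
  invisible(path)
}
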