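#' Construct and validate a cell table
#'
#' A cell table is the package's primary input: one row per detected cell
#' nucleus, with the specimen (larva) it came from, its genotype group, the
#' body side, its 3D centre coordinates in micrometres, and a marker status.
#' Coordinates follow the convention that the midline lies at `x_um = 0`
#' (mediolateral position increases laterally; the sign encodes the side)
#' and that `z_um` increases dorsally from a ventral origin.
#'
#' The `marker` column distinguishes reference cells (`"positive"`), which
#' define the per-larva dorsoventral and mediolateral extents used for
#' occupancy binning, from target cells (`"negative"`), which are the cells
#' that get binned. Tables where all cells share one marker status are
#' treated as self-referencing.
#'
#' @param larva_id Specimen identifiers (coerced to character).
#' @param genotype Genotype/group labels.
#' @param side `"left"` or `"right"` for each cell.
#' @param x_um,y_um,z_um Cell centre coordinates in micrometres.
#' @param marker `"positive"` or `"negative"` marker status.
#' @param label Optional subnucleus label.
#' @return A `data.frame` of class `cell_table`.
#' @seealso [read_cell_table()], [assign_bins()], [per_larva_summary()]
#' @export
cell_table <- function(larva_id, genotype, side, x_um, y_um, z_um,
                       marker = "negative", label = NA_character_) {
  df <- data.frame(
    larva_id = as.character(larva_id),
    genotype = as.character(genotype),
    side = as.character(side),
    x_um = as.numeric(x_um),
    y_um = as.numeric(y_um),
    z_um = as.numeric(z_um),
    marker = as.character(marker),
    label = as.character(label),
    stringsAsFactors = FALSE
  )
  validate_cell_table(df)
}

#' Validate a cell table
#'
#' Checks the schema and invariants of a cell table: required columns, finite
#' coordinates, non-empty larva/genotype identifiers and a valid `side`
#' factor. Returns the table (with class `cell_table` attached) or fails with
#' a message naming the offending column.
#'
#' @param df A data frame with the cell-table columns.
#' @return The validated table.
#' @export
validate_cell_table <- function(df) {
  required <- c("larva_id", "genotype", "side", "x_um", "y_um", "z_um", "marker")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("cell table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"label" %in% names(df)) df$label <- NA_character_
  for (col in c("x_um", "y_um", "z_um")) {
    if (!all(is.finite(df[[col]]))) {
      stop("non-finite values in column ", col, call. = FALSE)
    }
  }
  if (any(!nzchar(df$larva_id)) || any(is.na(df$larva_id))) {
    stop("empty larva_id", call. = FALSE)
  }
  if (any(!nzchar(df$genotype)) || any(is.na(df$genotype))) {
    stop("empty genotype", call. = FALSE)
  }
  bad <- setdiff(unique(df$side), c("left", "right"))
  if (length(bad) > 0) {
    stop("side must be 'left' or 'right'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(df$marker), c("positive", "negative"))
  if (length(bad) > 0) {
    stop("marker must be 'positive' or 'negative'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  class(df) <- unique(c("cell_table", class(df)))
  df
}

#' Read / write cell tables as tab-delimited text
#'
#' @param path File path.
#' @return `read_cell_table` returns a validated [cell_table()];
#'   `write_cell_table` returns `path` invisibly.
#' @export
read_cell_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(larva_id = "character"))
  validate_cell_table(df)
}

#' @rdname read_cell_table
#' @param cells A [cell_table()].
#' @export
write_cell_table <- function(cells, path) {
  cells <- validate_cell_table(cells)
  write.table(cells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select the dorsal half of each larva's cells
#'
#' Dorsal cells are defined per larva as those with `z_um` at or above the
#' midpoint of that larva's dorsoventral extent (`[min(z), max(z)]`), the
#' extent being anchored at the first and last cell along the axis.
#'
#' @param cells A [cell_table()].
#' @return The subset of rows in the dorsal half, still a `cell_table`.
#' @export
dorsal_half <- function(cells) {
  cells <- validate_cell_table(cells)
  keep <- unlist(lapply(split(seq_len(nrow(cells)), cells$larva_id), function(idx) {
    z <- cells$z_um[idx]
    idx[z >= (min(z) + max(z)) / 2]
  }), use.names = FALSE)
  out <- cells[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
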