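#' Node and edge type tables
#'
#' A type table maps a `node_type_id` (or `edge_type_id`) to a set of
#' attributes shared by every node (edge) instance referencing that id.
#' Because models typically contain far fewer types than instances, type
#' tables live in space-separated plain-text CSV files that are easy to edit
#' by hand, while per-instance attributes live in HDF5 (see
#' [write_nodes()]).
#'
#' The reserved token `NONE` (case-sensitive) denotes an absent value: it is
#' dropped on read and never appears in a resolved attribute map. Node type
#' tables must carry a `model_type` column restricted to the reserved values
#' `"biophysical"`, `"point_neuron"`, `"single compartment"` and
#' `"virtual"` (enforced by [validate_circuit()], not the constructor, so
#' that partially built tables can be inspected).
#'
#' @param role `"node"` or `"edge"`.
#' @param ids integer vector of unique, non-negative type ids.
#' @param rows list, parallel to `ids`, of named lists of attribute values
#'   (integer, double, or character scalars). Absent values are simply
#'   omitted from the row.
#' @param columns character vector fixing the attribute column order. If
#'   `NULL`, the union of row names in first-appearance order.
#'
#' @return An object of class `sonata_type_table` with fields `role`,
#'   `id_col`, `ids`, `columns` and `rows`.
#' @seealso [read_type_table()], [write_type_table()], [resolve_node()]
#' @examples
#' tt <- type_table("node", ids = c(0L, 3L), rows = list(
#'   list(model_type = "biophysical", morphology = "cell.swc"),
#'   list(model_type = "point_neuron")))
#' type_row(tt, 3L)
#' @export
type_table <- function(role, ids = integer(), rows = list(), columns = NULL) {
  role <- match.arg(role, c("node", "edge"))
  ids <- as.integer(ids)
  if (length(ids) != length(rows)) {
    abort("bad_table", "ids and rows must have equal length")
  }
  if (anyNA(ids) || any(ids < 0)) abort("bad_table", "type ids must be non-negative integers")
  if (anyDuplicated(ids)) {
    abort("duplicate_type_id", "duplicate type id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  rows <- lapply(rows, function(r) {
    if (length(r) && is.null(names(r))) abort("bad_table", "rows must be named lists")
    r[!vapply(r, is.null, logical(1))]
  })
  if (is.null(columns)) {
    columns <- unique(unlist(lapply(rows, names), use.names = FALSE)) %||% character()
  }
  structure(
    list(role = role,
         id_col = paste0(role, "_type_id"),
         ids = ids,
         columns = as.character(columns),
         rows = rows),
    class = "sonata_type_table")
}

#' @export
print.sonata_type_table <- function(x, ...) {
  cat(sprintf("SONATA %s type table: %d type(s), columns: %s\n",
              x$role, length(x$ids),
              if (length(x$columns)) paste(x$columns, collapse = ", ") else "<none>"))
  invisible(x)
}

#' @export
format.sonata_type_table <- function(x, ...) {
  sprintf("<sonata_type_table role=%s n=%d>", x$role, length(x$ids))
}

#' Look up one type row
#'
#' @param table a [type_table()].
#' @param type_id integer type id.
#' @return Named list of attribute values (absent/NONE entries omitted).
#' @export
type_row <- function(table, type_id) {
  stopifnot(inherits(table, "sonata_type_table"))
  k <- match(as.integer(type_id), table$ids)
  if (is.na(k)) {
    abort("dangling_type_id", "%s %d not present in %s type table",
          table$id_col, type_id, table$role)
  }
  table$rows[[k]]
}

#' @rdname type_table
#' @param x object to convert.
#' @param ... unused.
#' @export
as.data.frame.sonata_type_table <- function(x, ...) {
  cols <- c(x$id_col, x$columns)
  out <- lapply(x$columns, function(cn) {
    vals <- lapply(x$rows, function(r) r[[cn]])
    if (all(vapply(vals, function(v) is.null(v) || is.numeric(v), logical(1))) &&
        any(!vapply(vals, is.null, logical(1)))) {
      vapply(vals, function(v) if (is.null(v)) NA_real_ else as.numeric(v), numeric(1))
    } else {
      vapply(vals, function(v) if (is.null(v)) NA_character_ else as.character(v), character(1))
    }
  })
  names(out) <- x$columns
  df <- data.frame(id = x$ids, stringsAsFactors = FALSE)
  names(df) <- x$id_col
  for (cn in x$columns) df[[cn]] <- out[[cn]]
  df
}

# tokenize one space-separated CSV line honouring double-quoted fields
tokenize_line <- function(line) {
  scan(text = line, what = character(), quote = "\"", quiet = TRUE,
       strip.white = TRUE)
}

#' Read a type table from space-separated CSV
#'
#' The dialect is the one used throughout the format: fields separated by
#' spaces, values containing spaces wrapped in double quotes, `#` carrying no
#' comment meaning, and the literal token `NONE` marking an absent value.
#' Fields that look like numbers are parsed as integers or doubles; all
#' others are kept as text.
#'
#' @param path file to read.
#' @param role `"node"` or `"edge"`; the header must contain the matching
#'   `<role>_type_id` column.
#' @return A [type_table()].
#' @export
read_type_table <- function(path, role) {
  role <- match.arg(role, c("node", "edge"))
  if (!file.exists(path)) abort("io", "no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) abort("bad_table", "empty type table file: %s", path)
  header <- tokenize_line(lines[[1]])
  id_col <- paste0(role, "_type_id")
  id_pos <- match(id_col, header)
  if (is.na(id_pos)) {
    abort("missing_id_column", "header of %s lacks required column %s", path, id_col)
  }
  if (anyDuplicated(header)) abort("bad_table", "duplicate column names in %s", path)
  columns <- header[-id_pos]
  ids <- integer(0)
  rows <- vector("list", length(lines) - 1L)
  for (i in seq_along(rows)) {
    toks <- tokenize_line(lines[[i + 1L]])
    if (length(toks) != length(header)) {
      abort("ragged_row", "row %d of %s has %d fields, expected %d",
            i, path, length(toks), length(header))
    }
    idv <- parse_value(toks[[id_pos]])
    if (!is.integer(idv)) abort("bad_table", "non-integer %s in row %d of %s", id_col, i, path)
    ids[i] <- idv
    vals <- toks[-id_pos]
    keep <- vals != "NONE"
    row <- lapply(vals[keep], parse_value)
    names(row) <- columns[keep]
    rows[[i]] <- row
  }
  type_table(role, ids = ids, rows = rows, columns = columns)
}

#' Write a type table to space-separated CSV
#'
#' Inverse of [read_type_table()]: absent values are rendered as `NONE`,
#' values containing whitespace are double-quoted, and numbers are printed
#' with enough digits that reading the file back reproduces the table
#' exactly (including the integer/double distinction). Output is written
#' atomically (temp file + rename).
#'
#' @param table a [type_table()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_type_table <- function(table, path) {
  stopifnot(inherits(table, "sonata_type_table"))
  render <- function(v) {
    s <- format_value(v)
    if (grepl("\"", s)) abort("bad_value", "double quotes not representable in CSV value: %s", s)
    if (grepl("[[:space:]]", s)) s <- paste0("\"", s, "\"")
    s
  }
  header <- paste(c(table$id_col, table$columns), collapse = " ")
  body <- vapply(seq_along(table$ids), function(i) {
    row <- table$rows[[i]]
    fields <- vapply(table$columns, function(cn) {
      v <- row[[cn]]
      if (is.null(v)) "NONE" else render(v)
    }, character(1))
    paste(c(format(table$ids[i], scientific = FALSE), fields), collapse = " ")
  }, character(1))
  write_atomically(path, function(tmp) writeLines(c(header, body), tmp))
}
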