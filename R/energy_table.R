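#' Orientation-specific residue-pair energy tables
#'
#' An energy table holds the 400 pairwise energies `e(a, b)` used to score a
#' beta-pairing between two sequence stretches: the row residue `a` belongs to
#' the first (lower-start) stretch and the column residue `b` to its partner.
#' Lower energies are more stabilising. Tables are orientation-specific
#' (parallel vs antiparallel) and are *not* symmetrised by default, since a
#' statistical potential for parallel pairings need not be symmetric.
#'
#' @param mat numeric 20x20 matrix with row/column names covering the 20
#'   standard amino-acid one-letter codes (any order; reordered internally).
#' @param orientation `"parallel"` or `"antiparallel"`.
#' @return An object of class `energy_table`: a 20x20 numeric matrix in
#'   canonical alphabet order with an `orientation` attribute.
#' @examples
#' tab <- energy_table(matrix(0, 20, 20, dimnames = list(
#'   c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y"),
#'   c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y"))),
#'   "parallel")
#' @export
energy_table <- function(mat, orientation = c("parallel", "antiparallel")) {
  orientation <- match.arg(orientation)
  if (!is.matrix(mat) || !is.numeric(mat) || any(dim(mat) != 20L))
    stop("energy table must be a numeric 20x20 matrix")
  rn <- rownames(mat); cn <- colnames(mat)
  if (is.null(rn) || is.null(cn)) stop("energy table must have residue row and column names")
  miss_r <- setdiff(AA20, rn)
  if (length(miss_r)) stop("missing residue row(s): ", paste(miss_r, collapse = ", "))
  miss_c <- setdiff(AA20, cn)
  if (length(miss_c)) stop("missing residue column(s): ", paste(miss_c, collapse = ", "))
  if (anyDuplicated(rn)) stop("duplicate residue row: ", rn[duplicated(rn)][1L])
  if (anyDuplicated(cn)) stop("duplicate residue column: ", cn[duplicated(cn)][1L])
  if (any(!is.finite(mat))) stop("energy table contains non-finite entries")
  out <- mat[AA20, AA20, drop = FALSE]
  attr(out, "orientation") <- orientation
  class(out) <- c("energy_table", class(out))
  out
}

#' Read a residue-pair energy table from a plain-text matrix file
#'
#' The format is a 21-line whitespace-delimited matrix: a header row with the
#' 20 residue letters (any order, must be a permutation of the standard
#' alphabet), then 20 rows of the form `letter v1 ... v20`. Lines starting
#' with `#` and blank lines are ignored. The row residue indexes the first
#' stretch's residue; the column indexes the partner residue.
#'
#' @param path file path.
#' @inheritParams energy_table
#' @return An [energy_table()].
#' @seealso [write_energy_table()]
#' @export
load_energy_table <- function(path, orientation = c("parallel", "antiparallel")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("energy table file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("format error: expected a header plus 20 residue rows")
  tok <- strsplit(lines, "[ \t]+")
  header <- toupper(tok[[1L]])
  dup_c <- header[duplicated(header)]
  if (length(dup_c)) stop("format error: duplicate residue column: ", dup_c[1L])
  miss_c <- setdiff(AA20, header)
  if (length(miss_c))
    stop("format error: missing residue column(s): ", paste(miss_c, collapse = ", "))
  if (length(header) != 20L)
    stop("format error: header must contain exactly the 20 residue letters")
  rows <- tok[-1L]
  row_letters <- toupper(vapply(rows, `[`, "", 1L))
  dup_r <- row_letters[duplicated(row_letters)]
  if (length(dup_r)) stop("format error: duplicate residue row: ", dup_r[1L])
  odd_r <- setdiff(row_letters, AA20)
  if (length(odd_r))
    stop("format error: unexpected residue row: ", odd_r[1L])
  miss_r <- setdiff(AA20, row_letters)
  if (length(miss_r))
    stop("format error: missing residue row(s): ", paste(miss_r, collapse = ", "))
  mat <- matrix(NA_real_, 20L, 20L, dimnames = list(row_letters, header))
  for (i in seq_along(rows)) {
    vals <- rows[[i]][-1L]
    if (length(vals) != 20L)
      stop("format error: row ", row_letters[i], " has ", length(vals),
           " values, expected 20")
    num <- suppressWarnings(as.numeric(vals))
    if (anyNA(num)) {
      j <- which(is.na(num))[1L]
      stop(sprintf("parse error: non-numeric energy for row %s, column %s (value '%s')",
                   row_letters[i], header[j], vals[j]))
    }
    mat[i, ] <- num
  }
  energy_table(mat, orientation)
}

#' Write a residue-pair energy table to a plain-text matrix file
#'
#' Writes the canonical-order header plus 20 labelled rows, readable by
#' [load_energy_table()]. Values are written with enough precision to
#' round-trip exactly through the text format.
#'
#' @param table an [energy_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(table, path) {
  stopifnot(inherits(table, "energy_table"))
  lines <- c(paste(AA20, collapse = " "),
             vapply(AA20, function(a) {
               paste(a, paste(sprintf("%.17g", table[a, AA20]), collapse = " "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Symmetrise an energy table
#'
#' Replaces the table by `(e + t(e)) / 2`. Off by default in all scoring code;
#' provided for users whose parameter sets are defined up to symmetrisation.
#'
#' @param table an [energy_table()].
#' @return The symmetrised [energy_table()].
#' @export
symmetrize_energy_table <- function(table) {
  stopifnot(inherits(table, "energy_table"))
  orientation <- attr(table, "orientation")
  m <- unclass(table)
  attr(m, "orientation") <- NULL
  energy_table((m + t(m)) / 2, orientation)
}

#' @export
print.energy_table <- function(x, ...) {
  cat(sprintf("energy_table (%s), 20 x 20; range [%.4g, %.4g]\n",
              attr(x, "orientation"), min(x), max(x)))
  invisible(x)
}

# validate and normalise a `tables` argument: a named list with at least one
# of $parallel / $antiparallel, or a single energy_table (its own orientation)
as_table_pair <- function(tables) {
  if (inherits(tables, "energy_table"))
    tables <- stats::setNames(list(tables), attr(tables, "orientation"))
  if (!is.list(tables) || !length(tables))
    stop("tables must be an energy_table or a list(parallel=, antiparallel=)")
  nm <- names(tables)
  if (is.null(nm) || !all(nm %in% c("parallel", "antiparallel")))
    stop("tables list must be named 'parallel' and/or 'antiparallel'")
  for (o in nm) {
    if (!inherits(tables[[o]], "energy_table"))
      stop("tables$", o, " is not an energy_table")
    if (!identical(attr(tables[[o]], "orientation"), o))
      stop("tables$", o, " has orientation attribute '",
           attr(tables[[o]], "orientation"), "'")
  }
  tables
}
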