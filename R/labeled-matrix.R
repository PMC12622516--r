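#' Construct a labeled expression matrix
#'
#' Expression data are carried as plain base matrices with genes in rows and
#' cells in columns; `rownames` are gene identifiers and `colnames` are cell
#' identifiers. This constructor validates the container contract: all
#' entries non-negative and finite, identifiers present and unique within
#' their axis.
#'
#' @param values numeric matrix (genes x cells) of non-negative finite
#'   values.
#' @param gene_ids character vector of row identifiers; defaults to existing
#'   rownames.
#' @param cell_ids character vector of column identifiers; defaults to
#'   existing colnames.
#' @return The validated matrix with dimnames set.
#' @examples
#' m <- labeled_matrix(matrix(0:5, 3, 2), paste0("g", 1:3), c("c1", "c2"))
#' @export
labeled_matrix <- function(values, gene_ids = rownames(values),
                           cell_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene and cell identifiers are required", call. = FALSE)
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values))
    stop(sprintf("%d gene ids for %d rows", length(gene_ids), nrow(values)),
         call. = FALSE)
  if (length(cell_ids) != ncol(values))
    stop(sprintf("%d cell ids for %d columns", length(cell_ids),
                 ncol(values)), call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicated gene identifiers", call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("duplicated cell identifiers", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("matrix entries must be finite", call. = FALSE)
  if (any(values < 0))
    stop("matrix entries must be non-negative", call. = FALSE)
  dimnames(values) <- list(gene_ids, cell_ids)
  values
}

#' Read an expression matrix from disk
#'
#' Two on-disk layouts are accepted: Matrix Market sparse triplets
#' (`format = "mtx"`) with sidecar `genes.tsv` / `barcodes.tsv` files (one
#' identifier per line, in matrix order), and dense delimited text
#' (`format = "delimited"`: first row cell ids, first column gene ids, tab
#' or comma separated). `format = "auto"` picks by file extension.
#'
#' @param path path to the matrix file.
#' @param format one of `"auto"`, `"mtx"`, `"delimited"`.
#' @param genes_path,cells_path sidecar identifier files for `mtx` input;
#'   default to `genes.tsv` and `barcodes.tsv` next to `path`.
#' @return A validated labeled matrix (see [labeled_matrix()]).
#' @seealso [write_labeled_matrix()]
#' @export
read_labeled_matrix <- function(path, format = c("auto", "mtx", "delimited"),
                                genes_path = NULL, cells_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx"
              else "delimited"
  if (format == "mtx") {
    genes_path <- genes_path %||% file.path(dirname(path), "genes.tsv")
    cells_path <- cells_path %||% file.path(dirname(path), "barcodes.tsv")
    for (p in c(genes_path, cells_path))
      if (!file.exists(p))
        stop(sprintf("sidecar file not found: %s", p), call. = FALSE)
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genes_path)
    cells <- readLines(cells_path)
    if (length(genes) != nrow(m))
      stop(sprintf("%d gene ids for %d matrix rows", length(genes), nrow(m)),
           call. = FALSE)
    if (length(cells) != ncol(m))
      stop(sprintf("%d cell ids for %d matrix columns", length(cells),
                   ncol(m)), call. = FALSE)
    labeled_matrix(m, genes, cells)
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                            check.names = FALSE, quote = "",
                            comment.char = "", colClasses = "character")
    m <- suppressWarnings(
      matrix(as.numeric(as.matrix(df)), nrow(df), ncol(df),
             dimnames = list(rownames(df), colnames(df))))
    if (anyNA(m))
      stop("non-numeric entries in delimited matrix", call. = FALSE)
    labeled_matrix(m)
  }
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_labeled_matrix()]: `mtx` writes a Matrix Market file
#' plus `genes.tsv` / `barcodes.tsv` sidecars, `delimited` a dense table
#' (TSV, or CSV if `path` ends in `.csv`).
#'
#' @param m labeled matrix.
#' @param path destination file.
#' @param format `"mtx"` or `"delimited"`.
#' @return `path`, invisibly.
#' @export
write_labeled_matrix <- function(m, path, format = c("delimited", "mtx")) {
  format <- match.arg(format)
  m <- labeled_matrix(m)
  if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(rownames(m), file.path(dirname(path), "genes.tsv"))
    writeLines(colnames(m), file.path(dirname(path), "barcodes.tsv"))
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    # %.17g keeps doubles bit-exact through the text round trip
    chr <- matrix(sprintf("%.17g", m), nrow(m), dimnames = dimnames(m))
    df <- data.frame(gene_id = rownames(m), chr, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read per-cell spatial coordinates
#'
#' Coordinates travel as a three-column table `cell_id, x, y` (TSV, or CSV
#' by extension). Cell order must afterwards be aligned to the ST matrix
#' column order; [align_coords()] does that.
#'
#' @param path coordinate table file.
#' @return data frame with columns `cell_id` (character), `x`, `y`
#'   (finite numerics).
#' @export
read_coords <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  need <- c("cell_id", "x", "y")
  if (!all(need %in% names(df)))
    stop("coordinate table must have columns cell_id, x, y", call. = FALSE)
  df <- df[need]
  df$cell_id <- as.character(df$cell_id)
  validate_coords(df)
}

#' @rdname read_coords
#' @param coords coordinate data frame.
#' @export
write_coords <- function(coords, path) {
  coords <- validate_coords(coords)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(coords, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_coords <- function(coords) {
  if (!is.data.frame(coords) ||
      !all(c("cell_id", "x", "y") %in% names(coords)))
    stop("'coords' must be a data frame with columns cell_id, x, y",
         call. = FALSE)
  coords <- coords[c("cell_id", "x", "y")]
  coords$cell_id <- as.character(coords$cell_id)
  if (anyDuplicated(coords$cell_id))
    stop("duplicated cell ids in coordinates", call. = FALSE)
  if (!all(is.finite(coords$x)) || !all(is.finite(coords$y)))
    stop("coordinates must be finite", call. = FALSE)
  rownames(coords) <- NULL
  coords
}

#' Align coordinates to a matrix's cell order
#'
#' Reorders (and subsets) a coordinate table so its rows match the column
#' order of an ST matrix, e.g. after QC removed cells.
#'
#' @param coords coordinate data frame (`cell_id, x, y`).
#' @param m labeled ST matrix whose column order to match.
#' @return Coordinates reordered to `colnames(m)`.
#' @export
align_coords <- function(coords, m) {
  coords <- validate_coords(coords)
  idx <- match(colnames(m), coords$cell_id)
  if (anyNA(idx))
    stop(sprintf("coordinates missing for %d cells", sum(is.na(idx))),
         call. = FALSE)
  out <- coords[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
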