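#' Remove low-quality cells
#'
#' Drops every cell (column) in which fewer than `min_features` genes are
#' detected (value > 0), the usual `min.feature` quality-control step for
#' both ST and scRNA-seq input.
#'
#' @param m labeled genes x cells matrix.
#' @param min_features minimum number of detected genes per retained cell
#'   (default 200).
#' @return The matrix restricted to passing cells; the gene axis is
#'   untouched. Errors if no cell passes.
#' @export
qc_filter_cells <- function(m, min_features = 200) {
  m <- labeled_matrix(m)
  check_scalar(min_features, "min_features", lower = 0, integer = TRUE)
  keep <- colSums(m > 0) >= min_features
  if (!any(keep))
    stop("quality control removed every cell", call. = FALSE)
  m[, keep, drop = FALSE]
}

#' Normalize ST counts
#'
#' Applies the depth normalization
#' \deqn{D_{ij} = \log\!\left(\bar N \, C_{ij} / \sum_j C_{ij} + 1\right)}
#' where \eqn{\bar N} is the mean number of detected transcripts per cell
#' (mean of column sums). As printed, the denominator is gene i's total
#' across cells (`st_norm = "as_printed"`, the default); the conventional
#' per-cell depth reading, dividing by cell j's total instead, is available
#' as `st_norm = "per_cell"`. Natural logarithm; gene rows (or, per cell,
#' columns) summing to zero map to zeros rather than NaN.
#'
#' @param counts labeled matrix of raw ST counts.
#' @param st_norm denominator convention, see Details.
#' @return Labeled matrix of normalized values (non-negative).
#' @export
normalize_st <- function(counts, st_norm = c("as_printed", "per_cell")) {
  counts <- labeled_matrix(counts)
  st_norm <- match.arg(st_norm)
  nbar <- mean(colSums(counts))
  if (st_norm == "as_printed") {
    tot <- rowSums(counts)
    scl <- ifelse(tot > 0, nbar / tot, 0)
    out <- log1p(counts * scl)
  } else {
    tot <- colSums(counts)
    scl <- ifelse(tot > 0, nbar / tot, 0)
    out <- log1p(sweep(counts, 2L, scl, `*`))
  }
  labeled_matrix(out, rownames(counts), colnames(counts))
}

#' Log-normalize scRNA-seq counts
#'
#' Per-cell library-size normalization followed by `log1p`, the
#' "LogNormalize" convention:
#' \eqn{D_{ij} = \log(1 + s \, C_{ij} / \sum_i C_{ij})} with scale factor
#' \eqn{s} (default 1e4). Cells with zero total map to zero columns.
#'
#' @param counts labeled matrix of raw scRNA-seq counts.
#' @param scale_factor positive scale factor, default `1e4`.
#' @return Labeled matrix of log-normalized values.
#' @export
lognormalize_sc <- function(counts, scale_factor = 1e4) {
  counts <- labeled_matrix(counts)
  check_scalar(scale_factor, "scale_factor", lower = 0, strict = TRUE)
  tot <- colSums(counts)
  scl <- ifelse(tot > 0, scale_factor / tot, 0)
  out <- log1p(sweep(counts, 2L, scl, `*`))
  labeled_matrix(out, rownames(counts), colnames(counts))
}

#' Select highly expressed reference genes
#'
#' Ranks the scRNA-seq genes *outside* the shared panel by mean normalized
#' expression across cells and returns the top `n_top` (default 2000); these
#' populate the "unique" gene set whose spatial expression the model
#' predicts. Ties are broken by lexical gene id so the selection is
#' deterministic.
#'
#' @param msc labeled (log-normalized) scRNA-seq matrix.
#' @param shared character vector of shared gene ids to exclude.
#' @param n_top how many genes to return; clamped to the candidate count.
#' @return Character vector of selected gene ids, best first.
#' @export
select_top_genes <- function(msc, shared, n_top = 2000) {
  msc <- labeled_matrix(msc)
  check_scalar(n_top, "n_top", lower = 1, integer = TRUE)
  cand <- setdiff(rownames(msc), shared)
  if (length(cand) == 0L)
    stop("no candidate genes outside the shared set", call. = FALSE)
  means <- rowMeans(msc[cand, , drop = FALSE])
  ord <- order(-means, cand)
  cand[ord][seq_len(min(n_top, length(cand)))]
}

#' Partition ST and scRNA-seq matrices into the coupled-input triple
#'
#' Splits the inputs by gene sharing: `X1` is the ST matrix restricted to
#' the genes present in both assays, `X2` the scRNA-seq rows for those same
#' genes (identical row order), and `X3` the scRNA-seq rows for
#' `unique_genes` (genes absent from the ST panel). `X2` bridges the two
#' modalities: it shares its gene axis with `X1` and its cell axis with
#' `X3`.
#'
#' @param mst labeled ST matrix.
#' @param msc labeled scRNA-seq matrix.
#' @param unique_genes scRNA-only genes to predict (e.g. from
#'   [select_top_genes()]).
#' @return An object of class `"edges_input"`: list with elements `X1`
#'   (S x c1), `X2` (S x c2), `X3` (U x c2), `shared_genes`, `unique_genes`.
#' @export
partition_input <- function(mst, msc, unique_genes) {
  mst <- labeled_matrix(mst)
  msc <- labeled_matrix(msc)
  shared <- intersect(rownames(mst), rownames(msc))
  if (length(shared) == 0L)
    stop("no genes shared between ST and scRNA-seq input", call. = FALSE)
  unique_genes <- as.character(unique_genes)
  if (anyDuplicated(unique_genes))
    stop("duplicated entries in 'unique_genes'", call. = FALSE)
  if (length(bad <- intersect(unique_genes, shared)))
    stop(sprintf("unique_genes overlap the shared set: %s",
                 paste(utils::head(bad, 3L), collapse = ", ")),
         call. = FALSE)
  if (length(miss <- setdiff(unique_genes, rownames(msc))))
    stop(sprintf("unique_genes absent from scRNA-seq matrix: %s",
                 paste(utils::head(miss, 3L), collapse = ", ")),
         call. = FALSE)
  out <- structure(list(
    X1 = mst[shared, , drop = FALSE],
    X2 = msc[shared, , drop = FALSE],
    X3 = msc[unique_genes, , drop = FALSE],
    shared_genes = shared,
    unique_genes = unique_genes), class = "edges_input")
  validate_edges_input(out)
}

validate_edges_input <- function(p) {
  stopifnot(inherits(p, "edges_input"))
  for (nm in c("X1", "X2", "X3")) p[[nm]] <- labeled_matrix(p[[nm]])
  if (!identical(rownames(p$X1), p$shared_genes) ||
      !identical(rownames(p$X2), p$shared_genes))
    stop("X1/X2 gene order must equal shared_genes", call. = FALSE)
  if (!identical(rownames(p$X3), p$unique_genes))
    stop("X3 gene order must equal unique_genes", call. = FALSE)
  if (!identical(colnames(p$X2), colnames(p$X3)))
    stop("X2 and X3 must share cell order", call. = FALSE)
  if (length(intersect(p$shared_genes, p$unique_genes)))
    stop("shared and unique gene sets overlap", call. = FALSE)
  p
}

#' @export
print.edges_input <- function(x, ...) {
  cat(sprintf(paste0(
    "Coupled ST/scRNA-seq input\n",
    "  shared genes  S = %d\n  unique genes  U = %d\n",
    "  ST cells     c1 = %d\n  scRNA cells  c2 = %d\n"),
    length(x$shared_genes), length(x$unique_genes),
    ncol(x$X1), ncol(x$X2)))
  invisible(x)
}

#' Drop all-zero genes and cells
#'
#' Genes or cells that are entirely zero make multiplicative factor updates
#' degenerate (their rows/columns can never leave zero), so they are removed
#' before fitting. Coordinates, if supplied, are subset alongside the cells.
#'
#' @param m labeled matrix.
#' @param coords optional coordinate data frame to keep aligned.
#' @return The pruned matrix, or `list(m, coords)` when coords are given.
#' @export
drop_zero_axes <- function(m, coords = NULL) {
  m <- labeled_matrix(m)
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) == 0L || ncol(m) == 0L)
    stop("matrix empty after dropping zero rows/columns", call. = FALSE)
  if (is.null(coords)) return(m)
  list(m = m, coords = align_coords(coords, m))
}
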