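#' Mutual k-nearest-neighbor adjacency from spatial coordinates
#'
#' Builds the cell-cell proximity graph used by the spatial penalty: an
#' undirected edge joins cells i and j iff each is among the other's k
#' nearest neighbors by Euclidean distance. Self-neighborhood is excluded;
#' distance ties are broken by ascending cell index, so the graph is
#' deterministic. Duplicate coordinates are allowed (distance zero ranks
#' first).
#'
#' @param coords coordinate data frame (`cell_id, x, y`).
#' @param k neighborhood size (default 5); needs at least `k + 1` cells.
#' @return Sparse symmetric binary adjacency (`dgCMatrix`) with zero
#'   diagonal, dimnames = cell ids.
#' @export
mutual_knn <- function(coords, k = 5) {
  coords <- validate_coords(coords)
  check_scalar(k, "k", lower = 1, integer = TRUE)
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 cells", call. = FALSE)
  if (n < k + 1L)
    stop(sprintf("k = %d needs at least %d cells, got %d", k, k + 1L, n),
         call. = FALSE)
  d2 <- as.matrix(stats::dist(cbind(coords$x, coords$y)))
  # directed kNN relation; order() breaks distance ties by ascending index
  nbr <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(d2[i, ], seq_len(n))
    ord <- ord[ord != i]
    nbr[i, ord[seq_len(k)]] <- TRUE
  }
  a <- nbr & t(nbr)
  adj <- Matrix::Matrix(a * 1, sparse = TRUE)
  dimnames(adj) <- list(coords$cell_id, coords$cell_id)
  methods::as(adj, "generalMatrix")
}

#' Normalized graph Laplacian of a cell-cell adjacency
#'
#' Computes \eqn{\hat A = D^{-1/2} A D^{-1/2}} and the normalized Laplacian
#' \eqn{L = I - \hat A}, where D is the diagonal degree matrix. For
#' isolated nodes (degree 0) the corresponding \eqn{\hat A} rows/columns
#' are zero and \eqn{L_{ii} = 1}, which keeps L symmetric positive
#' semi-definite with spectrum in \[0, 2\].
#'
#' @param adj symmetric binary adjacency with zero diagonal (dense or
#'   sparse).
#' @return Object of class `"spatial_graph"`: list with sparse `A`, `Ahat`,
#'   `L`, integer `degrees`, and `cell_ids`.
#' @export
normalized_laplacian <- function(adj) {
  a <- Matrix::Matrix(adj, sparse = TRUE)
  n <- nrow(a)
  if (n != ncol(a)) stop("adjacency must be square", call. = FALSE)
  if (!Matrix::isSymmetric(a))
    stop("adjacency must be symmetric", call. = FALSE)
  a <- methods::as(a, "generalMatrix")
  if (any(Matrix::diag(a) != 0))
    stop("adjacency must have zero diagonal", call. = FALSE)
  if (!all(a@x %in% c(0, 1)))
    stop("adjacency must be binary", call. = FALSE)
  deg <- Matrix::rowSums(a)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)  # isolated nodes: row stays 0
  ahat <- Matrix::Diagonal(x = dinv) %*% a %*% Matrix::Diagonal(x = dinv)
  lap <- Matrix::Diagonal(n) - ahat
  structure(list(
    A = a,
    Ahat = methods::as(ahat, "generalMatrix"),
    L = methods::as(lap, "generalMatrix"),
    degrees = as.integer(deg),
    cell_ids = rownames(a) %||% as.character(seq_len(n))),
    class = "spatial_graph")
}

#' Build the spatial graph in one step
#'
#' Convenience wrapper: [mutual_knn()] then [normalized_laplacian()].
#'
#' @inheritParams mutual_knn
#' @return A `"spatial_graph"` object.
#' @export
spatial_graph <- function(coords, k = 5) {
  normalized_laplacian(mutual_knn(coords, k = k))
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat(sprintf(paste0(
    "Mutual-kNN spatial graph: %d cells, %d edges, ",
    "%d isolated, max degree %d\n"),
    length(x$cell_ids), sum(x$degrees) / 2L, sum(x$degrees == 0L),
    max(x$degrees)))
  invisible(x)
}

#' Laplacian quadratic form of a loading matrix
#'
#' Evaluates the spatial smoothness penalty \eqn{\mathrm{tr}(H L H^T)} for a
#' d x c loading matrix H whose columns index graph nodes. Non-negative for
#' any H because L is positive semi-definite; zero when the degree-scaled
#' loadings are constant within each connected component.
#'
#' @param h numeric matrix, columns aligned to graph nodes.
#' @param graph `"spatial_graph"` object.
#' @return Scalar penalty value.
#' @export
laplacian_quadratic <- function(h, graph) {
  stopifnot(inherits(graph, "spatial_graph"))
  h <- as.matrix(h)
  if (ncol(h) != length(graph$cell_ids))
    stop(sprintf("H has %d columns for %d graph nodes", ncol(h),
                 length(graph$cell_ids)), call. = FALSE)
  sum(h * as.matrix(h %*% graph$L))
}

#' Export the spatial graph as an edge list
#'
#' Writes one row per undirected edge (`cell_id_i`, `cell_id_j`,
#' i before j in node order) as TSV.
#'
#' @param graph `"spatial_graph"` object.
#' @param path destination file.
#' @export
write_graph_edges <- function(graph, path) {
  stopifnot(inherits(graph, "spatial_graph"))
  idx <- Matrix::which(graph$A != 0, arr.ind = TRUE)
  idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
  utils::write.table(
    data.frame(cell_id_i = graph$cell_ids[idx[, 1L]],
               cell_id_j = graph$cell_ids[idx[, 2L]]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
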