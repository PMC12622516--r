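#' Write a fitted model to a plain-text checkpoint
#'
#' Serializes the four factor matrices, identifiers, hyperparameters and
#' objective trace into one self-describing text file made of `#@ name`
#' sections (matrices as TSV with row/column labels, scalars as
#' `key: value` lines). [read_edges_checkpoint()] restores an
#' `"edges_fit"` object (without the graph, which is rebuildable from the
#' coordinates).
#'
#' @param fit an `"edges_fit"` object.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_edges_checkpoint <- function(fit, path) {
  fit <- check_fitted(fit)
  con <- file(path, "w")
  on.exit(close(con))
  put <- function(name) cat(sprintf("#@ %s\n", name), file = con)
  put_mat <- function(name, m, rn, cn) {
    put(name)
    df <- data.frame(id = rn, m, check.names = FALSE)
    colnames(df) <- c("id", cn)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  dn <- function(n) sprintf("f%02d", seq_len(n))
  put("params")
  ctl <- fit$control
  for (nm in c("theta1", "theta2", "lambda1", "lambda2", "tau", "eps"))
    cat(sprintf("%s: %.17g\n", nm, ctl[[nm]]), file = con)
  cat(sprintf("max_iter: %d\n", ctl$max_iter), file = con)
  cat(sprintf("update_rule: %s\n", ctl$update_rule), file = con)
  cat(sprintf("d: %d\nseed: %d\nn_iter: %d\nconverged: %s\n",
              fit$d, as.integer(fit$seed), fit$n_iter, fit$converged),
      file = con)
  put("objective_trace")
  cat(sprintf("%.17g", fit$objective_trace), sep = "\n", file = con)
  put_mat("W1", fit$W1, fit$shared_genes, dn(fit$d))
  put_mat("W2", fit$W2, fit$unique_genes, dn(fit$d))
  put_mat("H1", t(fit$H1), fit$st_cells, dn(fit$d))
  put_mat("H2", t(fit$H2), fit$sc_cells, dn(fit$d))
  invisible(path)
}

#' @rdname write_edges_checkpoint
#' @param path checkpoint file written by [write_edges_checkpoint()].
#' @return For the reader: the restored `"edges_fit"` object (its `graph`
#'   element is `NULL`).
#' @export
read_edges_checkpoint <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  heads <- grep("^#@ ", lines)
  names(heads) <- sub("^#@ ", "", lines[heads])
  section <- function(nm) {
    i <- heads[[nm]]
    nxt <- heads[heads > i]
    lines[(i + 1L):(if (length(nxt)) min(nxt) - 1L else length(lines))]
  }
  kv <- strsplit(section("params"), ": ", fixed = TRUE)
  params <- stats::setNames(vapply(kv, `[`, "", 2L),
                            vapply(kv, `[`, "", 1L))
  num <- function(nm) as.numeric(params[[nm]])
  get_mat <- function(nm) {
    df <- utils::read.table(text = section(nm), header = TRUE, sep = "\t",
                            check.names = FALSE)
    m <- as.matrix(df[-1L])
    rownames(m) <- df$id
    m
  }
  w1 <- get_mat("W1"); w2 <- get_mat("W2")
  h1 <- t(get_mat("H1")); h2 <- t(get_mat("H2"))
  ctl <- edges_control(theta1 = num("theta1"), theta2 = num("theta2"),
                       lambda1 = num("lambda1"), lambda2 = num("lambda2"),
                       tau = num("tau"), max_iter = num("max_iter"),
                       eps = num("eps"),
                       update_rule = params[["update_rule"]])
  structure(list(
    W1 = unname(w1) * 1, W2 = unname(w2) * 1,
    H1 = unname(h1) * 1, H2 = unname(h2) * 1,
    objective_trace = as.numeric(section("objective_trace")),
    n_iter = as.integer(num("n_iter")),
    converged = identical(params[["converged"]], "TRUE"),
    shared_genes = rownames(w1), unique_genes = rownames(w2),
    st_cells = colnames(h1), sc_cells = colnames(h2),
    d = as.integer(num("d")), seed = as.integer(num("seed")),
    control = ctl, graph = NULL), class = "edges_fit")
}
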