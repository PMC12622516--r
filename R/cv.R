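#' Build a gene-fold assignment for cross-validation
#'
#' A seeded uniform permutation of the shared genes is cut into K blocks
#' whose sizes differ by at most one; no stratification is applied.
#'
#' @param genes character vector of shared gene ids.
#' @param K fold count, e.g. from [choose_K()].
#' @param seed RNG seed for the permutation.
#' @return List of class `"cv_plan"`: `K`, `seed`, and `fold_of_gene`, a
#'   named integer vector mapping every gene to a fold in `1..K`.
#' @export
make_cv_plan <- function(genes, K, seed = 1L) {
  genes <- as.character(genes)
  check_scalar(K, "K", lower = 2, integer = TRUE)
  if (anyDuplicated(genes)) stop("duplicated gene ids", call. = FALSE)
  if (length(genes) < K)
    stop("fewer genes than folds", call. = FALSE)
  perm <- with_seed(seed, sample(genes))
  fold <- stats::setNames(sort(rep(seq_len(K), length.out = length(perm))),
                          perm)
  structure(list(K = as.integer(K), seed = seed,
                 fold_of_gene = fold[genes]), class = "cv_plan")
}

#' Gene-level cross-validation of spatial prediction
#'
#' For each fold, the validation genes are removed from the shared panel
#' (their ST rows discarded, never seen by the model) and their scRNA-seq
#' rows are appended to the unique set; the model is refitted from scratch
#' and their spatial expression is read off [predict_undetected()]. After
#' all K fits every shared gene has a predicted profile, which is scored
#' against its measured ST profile with the four expression metrics.
#'
#' @param input `"edges_input"` with the full shared panel.
#' @param graph `"spatial_graph"` over the ST cells.
#' @param plan `"cv_plan"` covering exactly the shared genes.
#' @param d latent dimension for the fold fits.
#' @param control `"edges_control"` hyperparameters.
#' @param seed seed for the fold-fit initializations.
#' @return List of class `"cv_report"`: `per_gene` data frame (gene, fold,
#'   pcc, ssim, rmse, js), `per_cell` data frame (cell, similarity),
#'   `predicted` labeled matrix of cross-validated predictions, `plan`.
#' @export
run_gene_cv <- function(input, graph, plan, d = 20,
                        control = edges_control(), seed = 1L) {
  input <- validate_edges_input(input)
  stopifnot(inherits(plan, "cv_plan"))
  if (!setequal(names(plan$fold_of_gene), input$shared_genes))
    stop("plan must cover exactly the shared genes", call. = FALSE)
  if (min(table(factor(plan$fold_of_gene, levels = seq_len(plan$K)))) == 0)
    stop("a fold has zero genes", call. = FALSE)
  pred <- matrix(NA_real_, length(input$shared_genes), ncol(input$X1),
                 dimnames = list(input$shared_genes, colnames(input$X1)))
  pred_by_fold <- vector("list", plan$K)
  for (f in seq_len(plan$K)) {
    held <- names(plan$fold_of_gene)[plan$fold_of_gene == f]
    keep <- setdiff(input$shared_genes, held)
    fold_input <- structure(list(
      X1 = input$X1[keep, , drop = FALSE],
      X2 = input$X2[keep, , drop = FALSE],
      X3 = rbind(input$X3, input$X2[held, , drop = FALSE]),
      shared_genes = keep,
      unique_genes = c(input$unique_genes, held)),
      class = "edges_input")
    fit <- edges_fit(fold_input, graph, d = d, control = control,
                     seed = seed)
    ph <- predict_undetected(fit)[held, , drop = FALSE]
    pred[held, ] <- ph
    pred_by_fold[[f]] <- ph
  }
  per_gene <- data.frame(
    gene = input$shared_genes,
    fold = as.integer(plan$fold_of_gene[input$shared_genes]),
    t(vapply(input$shared_genes,
             function(g) expression_metrics(pred[g, ], input$X1[g, ]),
             numeric(4L))),
    row.names = NULL)
  per_cell <- cell_level_scores(pred_by_fold, input$X1)
  structure(list(per_gene = per_gene, per_cell = per_cell,
                 predicted = pred, plan = plan), class = "cv_report")
}

#' Cell-level similarity from fold-wise predictions
#'
#' For each fold and each cell, a mixed expression vector is built by
#' substituting that fold's predictions into the measured profile (all
#' other genes keep their measured values); its Pearson correlation with
#' the fully measured profile is taken and a cell's score is the mean over
#' folds. Mixing per fold avoids scale differences between folds dominating
#' the comparison. Constant vectors give an undefined correlation, reported
#' as `NA`.
#'
#' @param pred_by_fold list of labeled matrices, one per fold, rows = that
#'   fold's validation genes, columns = ST cells.
#' @param measured labeled measured ST matrix covering all genes and cells.
#' @return Data frame with columns `cell` and `similarity`.
#' @export
cell_level_scores <- function(pred_by_fold, measured) {
  measured <- labeled_matrix(measured)
  all_genes <- unlist(lapply(pred_by_fold, rownames))
  if (anyDuplicated(all_genes) || !setequal(all_genes, rownames(measured)))
    stop("fold predictions must cover every measured gene exactly once",
         call. = FALSE)
  scores <- matrix(NA_real_, length(pred_by_fold), ncol(measured))
  for (f in seq_along(pred_by_fold)) {
    pf <- pred_by_fold[[f]]
    mixed <- measured
    mixed[rownames(pf), ] <- pf
    for (j in seq_len(ncol(measured))) {
      scores[f, j] <- tryCatch(metric_pcc(mixed[, j], measured[, j]),
                               error = function(e) NA_real_)
    }
  }
  data.frame(cell = colnames(measured),
             similarity = apply(scores, 2L,
                                function(s) if (all(is.na(s))) NA_real_
                                            else mean(s, na.rm = TRUE)),
             row.names = NULL)
}
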