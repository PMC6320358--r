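#' Prediction accuracy as plain Pearson correlation
#'
#' The Pearson correlation between observed line values (BLUEs) and
#' predictions, with no division by the square root of heritability.
#' Vectors are aligned by line ID.
#'
#' @param observed named numeric vector of observed values.
#' @param predicted named numeric vector, or a `prediction_result`
#'   data.frame with columns `line_id` and `predicted`.
#' @return Pearson r.
#' @export
pearson_accuracy <- function(observed, predicted) {
  if (is.data.frame(predicted))
    predicted <- stats::setNames(predicted$predicted, predicted$line_id)
  ids <- intersect(names(observed), names(predicted))
  o <- observed[ids]; p <- predicted[ids]
  ok <- !is.na(o) & !is.na(p)
  if (sum(ok) < 3) stop("need at least 3 overlapping non-missing pairs")
  if (stats::sd(o[ok]) == 0 || stats::sd(p[ok]) == 0)
    stop("accuracy undefined: zero variance")
  stats::cor(o[ok], p[ok])
}

#' Phenotypic and genetic correlation matrices for a set of traits
#'
#' Phenotypic correlations are pairwise-complete Pearson correlations of
#' the trait values (BLUEs); genetic correlations come from pairwise
#' bivariate [reml_multivariate()] fits against the relationship matrix.
#'
#' @param Y lines x traits matrix of BLUEs (rownames = line IDs).
#' @param K relationship matrix covering the lines.
#' @return list with elements `phenotypic` and `genetic` (t x t matrices).
#' @export
correlation_table <- function(Y, K) {
  Y <- as.matrix(Y)
  t <- ncol(Y)
  if (t < 2) stop("need at least two traits")
  phen <- stats::cor(Y, use = "pairwise.complete.obs")
  gen <- diag(1, t)
  dimnames(gen) <- dimnames(phen)
  for (i in seq_len(t - 1)) for (j in (i + 1):t) {
    fit <- reml_multivariate(Y[, c(i, j)], K)
    gen[i, j] <- gen[j, i] <- fit$genetic_cor[1, 2]
  }
  list(phenotypic = phen, genetic = gen)
}

#' Aggregate a grid of accuracy reports
#'
#' Computes the mean and standard deviation of per-fold accuracies per
#' reporting group (e.g. environment x model x design), the granularity at
#' which "average +/- sd" accuracies are quoted.
#'
#' @param reports data.frame with a numeric column `r` and any grouping
#'   columns.
#' @param group_by character vector of column names to group on.
#' @return data.frame with the grouping columns plus `mean_r`, `sd_r`,
#'   `n`.
#' @export
aggregate_grid <- function(reports, group_by) {
  if (!nrow(reports)) stop("no reports to aggregate")
  if (!all(group_by %in% names(reports)))
    stop("unknown grouping column(s)")
  key <- interaction(reports[group_by], drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(split(reports, key), function(g) {
    cbind(g[1, group_by, drop = FALSE],
          data.frame(mean_r = mean(g$r), sd_r = stats::sd(g$r), n = nrow(g)))
  }))
  out$sd_r[is.na(out$sd_r)] <- 0
  rownames(out) <- NULL
  out
}

#' Run a k-fold cross-validation of kernel predictions
#'
#' Convenience driver: for each fold of a [kfold_partition()] (or each
#' train/val split of a `fullsib_split`), fits the requested kernel model
#' and records the validation accuracy.
#'
#' @param y named numeric vector of line values (BLUEs).
#' @param kernels named list of relationship matrices; a model is fitted
#'   for each element, and for `length(kernels) == 2` an additional
#'   combined two-kernel model.
#' @param part a `partition`.
#' @param combined fit the combined model when two kernels are given
#'   (default TRUE).
#' @return data.frame with columns `model`, `fold`, `r`.
#' @export
cv_kernel_models <- function(y, kernels, part, combined = length(kernels) == 2) {
  folds <- if (part$design == "kfold")
    sort(unique(part$assignments$fold)) else 1L
  rows <- list()
  for (f in folds) {
    fs <- if (part$design == "kfold") fold_sets(part, f)
    else list(train = part$assignments$line_id[part$assignments$set == "train"],
              val = part$assignments$line_id[part$assignments$set == "val"])
    tr <- intersect(fs$train, names(y)[!is.na(y)])
    vl <- intersect(fs$val, names(y)[!is.na(y)])
    for (m in names(kernels)) {
      pred <- predict_gblup(y, kernels[[m]], tr, vl, model = m)
      rows[[length(rows) + 1]] <- data.frame(
        model = m, fold = f, r = pearson_accuracy(y, pred))
    }
    if (combined) {
      K1 <- kernels[[1]]; K2 <- kernels[[2]]
      fit <- reml_two_kernel(y[tr], K1, K2)
      Kb <- fit$alpha * K1 + (1 - fit$alpha) * K2[rownames(K1), colnames(K1)]
      pred <- predict_gblup(y, Kb, tr, vl,
                            model = paste(names(kernels), collapse = "+"))
      rows[[length(rows) + 1]] <- data.frame(
        model = paste(names(kernels), collapse = "+"), fold = f,
        r = pearson_accuracy(y, pred))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
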