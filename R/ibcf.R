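#' Cosine similarity between two vectors
#'
#' cos(theta) = sum(x y) / (sqrt(sum(x^2)) sqrt(sum(y^2))), computed over
#' the pairwise-complete entries.
#'
#' @param x,y numeric vectors of equal length.
#' @return similarity in [-1, 1].
#' @export
cosine_similarity <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop("cosine similarity undefined for a zero-norm vector")
  sum(x * y) / (nx * ny)
}

#' Ratings matrix for item-based collaborative filtering
#'
#' Wraps a lines x items trait table (lines are the "users", trait-date
#' combinations the "items") and stores per-item standardization
#' parameters. Ratings are z-scored per item so that items on different
#' scales (yield in t/ha, GNDVI unitless) can be averaged; the stored mean
#' and sd also back-transform predictions.
#'
#' @param mat numeric matrix, rownames = line IDs, colnames = item IDs;
#'   `NA` for unrated cells.
#' @param center,scale optional named vectors of per-item mean/sd to use
#'   instead of the matrix's own statistics (e.g. training-set parameters).
#' @return list of class `ratings_matrix`: `raw`, `z`, `center`, `scale`.
#' @export
ratings_matrix <- function(mat, center = NULL, scale = NULL) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least two items")
  if (is.null(center)) center <- colMeans(mat, na.rm = TRUE)
  if (is.null(scale)) scale <- apply(mat, 2, stats::sd, na.rm = TRUE)
  center <- center[colnames(mat)]; scale <- scale[colnames(mat)]
  if (any(!is.finite(scale) | scale == 0))
    stop("every item needs a finite, nonzero sd")
  z <- sweep(sweep(mat, 2, center), 2, scale, `/`)
  structure(list(raw = mat, z = z, center = center, scale = scale),
            class = "ratings_matrix")
}

#' Item-to-item cosine similarity matrix
#'
#' All pairwise cosine similarities between the standardized item columns
#' of a training ratings matrix. Pairs sharing fewer than `min_co`
#' co-observed lines are flagged unusable (`NA`).
#'
#' @param train a [ratings_matrix()].
#' @param min_co minimum co-observed lines per pair (default 3).
#' @return symmetric item x item matrix, diagonal 1, class
#'   `item_similarity`.
#' @export
build_item_similarity <- function(train, min_co = 3) {
  Z <- train$z
  k <- ncol(Z)
  W <- diag(1, k)
  dimnames(W) <- list(colnames(Z), colnames(Z))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- !is.na(Z[, i]) & !is.na(Z[, j])
    if (sum(ok) < min_co) {
      W[i, j] <- W[j, i] <- NA_real_
    } else {
      W[i, j] <- W[j, i] <- cosine_similarity(Z[ok, i], Z[ok, j])
    }
  }
  class(W) <- c("item_similarity", class(W))
  W
}

#' Predict a target item by weighted collaborative filtering
#'
#' For every line missing the target item, predicts the standardized
#' rating as sum_j y_ij w_jj' / sum_j |w_jj'| over the line's rated items
#' j (all other items are neighbors; weights may be negative, and the
#' denominator takes absolute values exactly as the recommender rule
#' states). Predictions are back-transformed with the target item's
#' stored center and scale.
#'
#' @param ratings a [ratings_matrix()] containing the target column (`NA`
#'   where it is to be predicted).
#' @param sim an [build_item_similarity()] matrix over the same items.
#' @param target_item item (column) to predict.
#' @param target_center,target_scale back-transform parameters for the
#'   target; default to the ones stored in `ratings` (pass the training
#'   set's when predicting across sets).
#' @return named vector of predictions (raw scale) for the lines missing
#'   the target; lines with no usable neighbor are `NA` (with a warning).
#' @export
predict_ibcf <- function(ratings, sim, target_item,
                         target_center = NULL, target_scale = NULL) {
  Z <- ratings$z
  if (!target_item %in% colnames(Z)) stop("target item not in ratings")
  if (is.null(target_center)) target_center <- ratings$center[[target_item]]
  if (is.null(target_scale)) target_scale <- ratings$scale[[target_item]]
  others <- setdiff(colnames(Z), target_item)
  w <- sim[others, target_item]
  need <- which(is.na(Z[, target_item]))
  pred <- rep(NA_real_, length(need))
  names(pred) <- rownames(Z)[need]
  for (ii in seq_along(need)) {
    i <- need[ii]
    yi <- Z[i, others]
    use <- !is.na(yi) & !is.na(w)
    denom <- sum(abs(w[use]))
    if (!any(use) || denom == 0) next
    pred[ii] <- sum(yi[use] * w[use]) / denom
  }
  if (anyNA(pred))
    warning(sum(is.na(pred)), " line(s) had no usable neighbor item")
  pred * target_scale + target_center
}

#' IBCF grain-yield prediction from GNDVI items
#'
#' Learns the item-to-item similarity (target trait + secondary items) on
#' the training set, standardizes the validation lines' secondary items by
#' the validation set's own statistics, and predicts the target by
#' [predict_ibcf()], back-transforming with the training set's target mean
#' and sd. Items are matched across sets by name; pass `item_map` (named
#' character vector, `names` = validation items, values = training items,
#' e.g. growth-stage labels) when the sets name their items differently.
#'
#' @param train_mat lines x items matrix for the training nursery,
#'   including the target column.
#' @param val_mat lines x items matrix for the validation lines (secondary
#'   items only, or with the target column all-`NA`).
#' @param target target item name in `train_mat` (default "GY").
#' @param item_map optional validation-to-training item name mapping.
#' @param min_co minimum co-observation for a similarity weight.
#' @return `prediction_result` data.frame (`line_id`, `predicted`).
#' @export
ibcf_predict_gy <- function(train_mat, val_mat, target = "GY",
                            item_map = NULL, min_co = 3) {
  train_mat <- as.matrix(train_mat); val_mat <- as.matrix(val_mat)
  if (!is.null(item_map)) {
    keep <- colnames(val_mat) %in% names(item_map)
    val_mat <- val_mat[, keep, drop = FALSE]
    colnames(val_mat) <- unname(item_map[colnames(val_mat)])
  }
  sec <- intersect(setdiff(colnames(train_mat), target), colnames(val_mat))
  if (!length(sec)) stop("no common items between training and validation sets")
  train_rm <- ratings_matrix(train_mat[, c(target, sec), drop = FALSE])
  sim <- build_item_similarity(train_rm, min_co = min_co)

  vm <- val_mat[, sec, drop = FALSE]
  vm <- cbind(vm, matrix(NA_real_, nrow(vm), 1,
                         dimnames = list(rownames(vm), target)))
  # validation items standardized by the validation set itself; the target
  # column carries the training parameters for the back-transform
  centers <- c(colMeans(vm[, sec, drop = FALSE], na.rm = TRUE),
               stats::setNames(train_rm$center[[target]], target))
  scales <- c(apply(vm[, sec, drop = FALSE], 2, stats::sd, na.rm = TRUE),
              stats::setNames(train_rm$scale[[target]], target))
  val_rm <- ratings_matrix(vm, center = centers, scale = scales)
  pred <- predict_ibcf(val_rm, sim, target)
  out <- data.frame(line_id = names(pred), predicted = unname(pred),
                    stringsAsFactors = FALSE)
  attr(out, "model") <- "IBCF"
  attr(out, "similarity") <- sim
  class(out) <- c("prediction_result", "data.frame")
  out
}
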