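#' k-fold cross-validation partition
#'
#' Shuffles the lines uniformly at random under `seed` and deals them into
#' `k` folds of size floor(n/k) or ceiling(n/k).
#'
#' @param line_ids character vector of lines to partition.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return list of class `partition`: `design = "kfold"`, `seed`,
#'   `assignments` (data.frame `line_id`, `fold`).
#' @export
kfold_partition <- function(line_ids, k = 5, seed = 1L) {
  n <- length(line_ids)
  if (n < k) stop("fewer lines than folds")
  set.seed(as.integer(seed))
  fold <- sample(rep(seq_len(k), length.out = n))
  structure(list(
    design = "kfold", seed = as.integer(seed),
    assignments = data.frame(line_id = line_ids, fold = fold,
                             stringsAsFactors = FALSE)
  ), class = "partition")
}

# train/validation line sets for one fold of a partition
fold_sets <- function(part, fold) {
  a <- part$assignments
  list(train = a$line_id[a$fold != fold], val = a$line_id[a$fold == fold])
}

#' One-progeny-per-cross line subset
#'
#' Retains exactly one line per cross, chosen uniformly at random under
#' `seed`: the design that removes all full-sib relationships from the
#' population.
#'
#' @param ped a [pedigree()].
#' @param seed integer seed.
#' @return character vector of retained line IDs.
#' @export
one_progeny_subset <- function(ped, seed = 1L) {
  set.seed(as.integer(seed))
  idx <- unlist(lapply(split(seq_len(nrow(ped)), ped$cross_id), function(i)
    if (length(i) == 1) i else sample(i, 1)), use.names = FALSE)
  ped$line_id[sort(idx)]
}

#' Full-sib split partition
#'
#' Restricts to families of at least `min_family_size` full sibs and splits
#' every family so that about `train_fraction` of its members train the
#' model that predicts the rest. With the default 50/50 split the odd
#' member of odd-sized families alternates between train and validation
#' across families, so the overall split stays balanced. Every validation
#' line is guaranteed at least one full sib in training.
#'
#' @param ped a [pedigree()].
#' @param min_family_size minimum family size for inclusion (default 3:
#'   lines with at least two other full sibs).
#' @param train_fraction fraction of each family used for training
#'   (default 0.5).
#' @param seed integer seed.
#' @return `partition` with `assignments` (`line_id`, `set` in
#'   \{"train", "val"\}).
#' @export
fullsib_split <- function(ped, min_family_size = 3, train_fraction = 0.5,
                          seed = 1L) {
  fams <- split(ped$line_id, ped$cross_id)
  fams <- fams[lengths(fams) >= min_family_size]
  if (!length(fams)) stop("no family of size >= ", min_family_size)
  set.seed(as.integer(seed))
  fams <- fams[sample(length(fams))]
  rows <- list()
  extra_to_train <- TRUE
  for (f in fams) {
    f <- sample(f)
    n_tr <- train_fraction * length(f)
    if (n_tr != floor(n_tr)) {
      n_tr <- if (extra_to_train) ceiling(n_tr) else floor(n_tr)
      extra_to_train <- !extra_to_train
    }
    n_tr <- max(1, min(length(f) - 1, n_tr))
    rows[[length(rows) + 1]] <- data.frame(
      line_id = f, set = rep(c("train", "val"), c(n_tr, length(f) - n_tr)),
      stringsAsFactors = FALSE)
  }
  a <- do.call(rbind, rows)
  structure(list(design = "fullsib_split", seed = as.integer(seed),
                 assignments = a[order(a$line_id), ]),
            class = "partition")
}

#' Heading-date line subset
#'
#' Excludes lines at the tails of the days-to-heading distribution:
#' `sd_window` mode keeps lines within one standard deviation of the mean;
#' `explicit_range` keeps lines inside a closed interval of days.
#'
#' @param dthd named numeric vector of days to heading per line.
#' @param mode `"sd_window"` or `"explicit_range"`.
#' @param range length-2 numeric (closed interval) for `explicit_range`.
#' @return character vector of retained line IDs.
#' @export
dthd_subset <- function(dthd, mode = c("sd_window", "explicit_range"),
                        range = NULL) {
  mode <- match.arg(mode)
  if (anyNA(dthd)) stop("DTHD must be available for every line")
  if (mode == "sd_window") {
    s <- stats::sd(dthd)
    keep <- if (s == 0) rep(TRUE, length(dthd)) else
      abs(dthd - mean(dthd)) <= s
  } else {
    if (is.null(range) || length(range) != 2) stop("explicit_range needs `range`")
    keep <- dthd >= range[1] & dthd <= range[2]
  }
  if (!any(keep)) stop("DTHD subset is empty")
  names(dthd)[keep]
}

#' Across-nursery prediction plans
#'
#' All ordered train -> validation nursery pairs (forward and backward
#' predictions), plus, for every nursery, the plan that pools all the
#' remaining nurseries as training.
#'
#' @param nurseries character vector of nursery IDs (>= 2).
#' @return list of plans, each a list with `train_set` and `val_set`
#'   (character vectors of nursery IDs) and a `label`.
#' @export
across_nursery_plan <- function(nurseries) {
  if (length(nurseries) < 2) stop("need at least two nurseries")
  plans <- list()
  for (v in nurseries) for (tr in setdiff(nurseries, v)) {
    plans[[length(plans) + 1]] <- list(
      train_set = tr, val_set = v,
      label = sprintf("%s from %s", v, tr))
  }
  for (v in nurseries) {
    rest <- setdiff(nurseries, v)
    plans[[length(plans) + 1]] <- list(
      train_set = rest, val_set = v,
      label = sprintf("%s from all others", v))
  }
  plans
}

#' Serialize / deserialize a partition
#'
#' Partitions round-trip losslessly through JSON so that a fold layout can
#' be archived next to the predictions it produced.
#'
#' @param part a `partition`.
#' @param path file path.
#' @return `read_partition` returns the reconstructed `partition`.
#' @export
write_partition <- function(part, path) {
  jsonlite::write_json(
    list(design = part$design, seed = part$seed,
         assignments = part$assignments),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(design = x$design, seed = as.integer(x$seed),
                 assignments = as.data.frame(x$assignments)),
            class = "partition")
}
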