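#' Marker quality-control filter
#'
#' Removes markers with more than `max_missing` missing calls, minor allele
#' frequency below `min_maf`, or heterozygosity (fraction of dosage-1 calls
#' among observed calls) above `max_het`. Marker order is preserved.
#'
#' @param geno a [geno_matrix()].
#' @param max_missing maximum missing fraction per marker (default 0.5).
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @param max_het maximum heterozygous fraction (default 0.05).
#' @return filtered `geno_matrix`.
#' @export
filter_markers <- function(geno, max_missing = 0.5, min_maf = 0.05,
                           max_het = 0.05) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 1,
            max_het >= 0, max_het <= 1)
  X <- geno$dosage
  n_obs <- colSums(!is.na(X))
  miss <- 1 - n_obs / nrow(X)
  p <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  het <- colSums(X == 1, na.rm = TRUE) / pmax(n_obs, 1)
  keep <- miss <= max_missing & !is.na(maf) & maf >= min_maf & het <= max_het
  keep[n_obs == 0] <- FALSE
  if (!any(keep)) stop("all markers removed by QC filters")
  subset_geno(geno, markers = which(keep))
}

#' Line quality-control filter
#'
#' Removes lines with more than `max_missing` missing marker calls.
#'
#' @inheritParams filter_markers
#' @return filtered `geno_matrix`.
#' @export
filter_lines <- function(geno, max_missing = 0.5) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  miss <- rowMeans(is.na(geno$dosage))
  keep <- miss <= max_missing
  if (!any(keep)) stop("all lines removed by QC filter")
  subset_geno(geno, lines = which(keep))
}

#' Marker-mean imputation of missing dosages
#'
#' Replaces each missing call by the marker's observed mean dosage.
#' Observed calls are untouched. Downstream VanRaden centering makes this
#' imputation neutral on average.
#'
#' @param geno a [geno_matrix()].
#' @return `geno_matrix` without missing values.
#' @export
impute_mean <- function(geno) {
  X <- geno$dosage
  n_obs <- colSums(!is.na(X))
  if (any(n_obs == 0)) stop("marker(s) with no observed calls; filter first")
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  out <- geno
  out$dosage <- X
  out
}

#' VanRaden genomic relationship matrix
#'
#' G = Z Z' / (2 * sum(p (1 - p))), where Z is the dosage matrix centered
#' at twice the observed allele frequencies (VanRaden method 1; frequencies
#' computed from the analyzed lines themselves). A small jitter is added to
#' the diagonal so G is safely positive definite for mixed-model solvers.
#'
#' @param geno a [geno_matrix()] without missing values (see
#'   [impute_mean()]).
#' @param jitter value added to the diagonal (default 1e-6).
#' @return symmetric n x n matrix with line IDs as dimnames, attribute
#'   `kind = "G"`.
#' @export
vanraden_g <- function(geno, jitter = 1e-6) {
  X <- geno$dosage
  if (anyNA(X)) stop("missing dosages: impute first")
  p <- colMeans(X) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: G is degenerate")
  Z <- sweep(X, 2, 2 * p)
  G <- tcrossprod(Z) / denom
  diag(G) <- diag(G) + jitter
  attr(G, "kind") <- "G"
  G
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Builds the additive (numerator) relationship matrix A by the recursive
#' tabular rules: A[i,i] = 1 + F_i with inbreeding F_i = A[sire, dam] / 2,
#' and A[i,j] = (A[j, sire(i)] + A[j, dam(i)]) / 2 for j processed before
#' i. Unknown parents are treated as unrelated, non-inbred founders. Lines
#' are sorted topologically (parents before offspring); a cycle is an
#' error.
#'
#' @param ped a [pedigree()]; parents not listed as lines are added as
#'   founders.
#' @return symmetric matrix over all pedigree members (founders included),
#'   attribute `kind = "A"`. Subset to the genotyped lines as needed.
#' @export
pedigree_a <- function(ped) {
  ids <- ped$line_id
  parents <- setdiff(unique(c(ped$female_parent, ped$male_parent)), c(ids, NA))
  all_ids <- c(parents, ids)
  fem <- stats::setNames(rep(NA_character_, length(all_ids)), all_ids)
  mal <- fem
  fem[ped$line_id] <- ped$female_parent
  mal[ped$line_id] <- ped$male_parent

  # topological sort: repeatedly emit members whose parents are placed
  placed <- character(0)
  todo <- all_ids
  while (length(todo)) {
    ready <- todo[vapply(todo, function(id) {
      pr <- c(fem[[id]], mal[[id]])
      all(is.na(pr) | pr %in% placed)
    }, TRUE)]
    if (!length(ready)) stop("pedigree cycle detected")
    placed <- c(placed, ready)
    todo <- setdiff(todo, ready)
  }

  n <- length(placed)
  A <- matrix(0, n, n, dimnames = list(placed, placed))
  pos <- stats::setNames(seq_len(n), placed)
  for (i in seq_len(n)) {
    id <- placed[i]
    s <- fem[[id]]; d <- mal[[id]]
    si <- if (is.na(s)) 0L else pos[[s]]
    di <- if (is.na(d)) 0L else pos[[d]]
    if (i > 1) {
      js <- seq_len(i - 1)
      as_ <- if (si) A[js, si] else rep(0, i - 1)
      ad_ <- if (di) A[js, di] else rep(0, i - 1)
      A[js, i] <- A[i, js] <- (as_ + ad_) / 2
    }
    Fi <- if (si && di) A[si, di] / 2 else 0
    A[i, i] <- 1 + Fi
  }
  A <- A[all_ids, all_ids]
  attr(A, "kind") <- "A"
  A
}

#' Rescale a relationship matrix to the unit interval
#'
#' Affine rescaling so the smallest entry becomes 0 and the largest 1
#' (as done before visualizing relationship heat maps).
#'
#' @param kin numeric matrix.
#' @return rescaled matrix.
#' @export
rescale_unit <- function(kin) {
  r <- range(kin)
  if (r[1] == r[2]) stop("constant matrix cannot be rescaled")
  out <- (kin - r[1]) / (r[2] - r[1])
  attr(out, "kind") <- attr(kin, "kind")
  out
}
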