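#' Univariate REML fit of the kernel mixed model (GBLUP/ABLUP)
#'
#' Fits y = mu + u + e with u ~ N(0, K sigma_g2) and e ~ N(0, I sigma_e2)
#' by restricted maximum likelihood, using the spectral decomposition of K
#' to profile the likelihood down to the single ratio
#' lambda = sigma_g2 / sigma_e2 (EMMA-style eigen-rotation). lambda is
#' found by 1-D bounded search on log(lambda) in [-10, 10]. BLUPs
#' E[u | y] are returned for every line in K, including unphenotyped ones.
#'
#' @param y named numeric vector of line-level values (e.g. BLUEs); names
#'   must appear among the rows of `K`.
#' @param K relationship matrix (PSD, dimnames = line IDs).
#' @param log_lambda_bounds search interval for log(lambda).
#' @param tol convergence tolerance of the 1-D search.
#' @param lambda optional fixed variance ratio; skips the REML search (the
#'   K = I case then reduces to ridge regression toward the mean with
#'   penalty 1/lambda).
#' @return list of class `kernel_fit`: `sigma_g2`, `sigma_e2`, `lambda`,
#'   `mu`, `loglik` (restricted), `u` (named BLUPs for all lines in K),
#'   `train_ids`.
#' @export
reml_univariate <- function(y, K, log_lambda_bounds = c(-10, 10), tol = 1e-8,
                            lambda = NULL) {
  if (is.null(names(y))) stop("y must be named by line ID")
  y <- y[!is.na(y)]
  ids <- intersect(names(y), rownames(K))
  if (length(ids) < 10) stop("need at least 10 phenotyped lines in K")
  yt <- y[ids]
  Kt <- K[ids, ids]
  eg <- eigen(Kt, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values)))
    stop("K is not positive semidefinite")
  D <- pmax(eg$values, 0)
  U <- eg$vectors
  n <- length(yt)
  ys <- drop(crossprod(U, yt))
  xs <- drop(crossprod(U, rep(1, n)))

  neg_restricted_ll <- function(loglam) {
    lam <- exp(loglam)
    h <- lam * D + 1
    w <- 1 / h
    xwx <- sum(w * xs^2)
    mu <- sum(w * xs * ys) / xwx
    r <- ys - xs * mu
    rss <- sum(w * r^2)
    s2 <- rss / (n - 1)
    0.5 * ((n - 1) * log(s2) + sum(log(h)) + log(xwx) + (n - 1))
  }
  if (is.null(lambda)) {
    opt <- stats::optimize(neg_restricted_ll, log_lambda_bounds, tol = tol)
    lam <- exp(opt$minimum)
    ll <- -opt$objective
  } else {
    lam <- lambda
    ll <- -neg_restricted_ll(log(lam))
  }
  h <- lam * D + 1
  w <- 1 / h
  xwx <- sum(w * xs^2)
  mu <- sum(w * xs * ys) / xwx
  r <- ys - xs * mu
  sigma_e2 <- sum(w * r^2) / (n - 1)
  sigma_g2 <- lam * sigma_e2
  # u_hat = sigma_g2 K[.,train] V^{-1} (y - mu) = lambda K[.,train] U w r
  v_inv_res <- U %*% (w * r)
  u_all <- lam * (K[, ids, drop = FALSE] %*% v_inv_res)
  u <- stats::setNames(drop(u_all), rownames(K))
  structure(list(
    sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, lambda = lam, mu = mu,
    loglik = ll, u = u, train_ids = ids
  ), class = "kernel_fit")
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat(sprintf("kernel_fit: n=%d, sigma_g2=%.4g, sigma_e2=%.4g, restricted loglik=%.3f\n",
              length(x$train_ids), x$sigma_g2, x$sigma_e2, x$loglik))
  invisible(x)
}

#' Kernel-based prediction of unphenotyped lines
#'
#' Trains [reml_univariate()] on the training lines only and returns
#' mu + BLUP for the validation lines.
#'
#' @param blues named numeric vector of line values (or a `blue_set`).
#' @param K relationship matrix covering train and validation lines.
#' @param train_ids,val_ids disjoint line-ID sets, both present in `K`.
#' @param model label stored with the result (e.g. "G", "A", "G+A").
#' @return data.frame of class `prediction_result` with columns `line_id`,
#'   `predicted`; the fit is in attribute `fit`, the label in `model`.
#' @export
predict_gblup <- function(blues, K, train_ids, val_ids, model = "G") {
  y <- if (inherits(blues, "blue_set")) blues$blues else blues
  if (length(intersect(train_ids, val_ids)))
    stop("training and validation sets overlap")
  missing_k <- setdiff(c(train_ids, val_ids), rownames(K))
  if (length(missing_k))
    stop("lines absent from K: ", paste(utils::head(missing_k, 5), collapse = ", "))
  fit <- reml_univariate(y[intersect(train_ids, names(y))], K)
  pred <- fit$mu + fit$u[val_ids]
  out <- data.frame(line_id = val_ids, predicted = unname(pred),
                    stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  attr(out, "model") <- model
  class(out) <- c("prediction_result", "data.frame")
  out
}

#' Two-kernel REML fit (combined G + A model)
#'
#' Profiles the mixing weight alpha over a grid, fitting
#' [reml_univariate()] with the blended kernel
#' K(alpha) = alpha K1 + (1 - alpha) K2 at each grid point and keeping the
#' restricted-likelihood maximizer. The per-kernel genetic variances are
#' alpha * sigma_K2 and (1 - alpha) * sigma_K2.
#'
#' @param y named numeric vector of line values.
#' @param K1,K2 relationship matrices with identical dimnames.
#' @param alpha_grid grid of mixing weights (default 0, 0.02, ..., 1).
#' @return a `kernel_fit` with extra elements `alpha`, `sigma_k1_2`,
#'   `sigma_k2_2`.
#' @export
reml_two_kernel <- function(y, K1, K2, alpha_grid = seq(0, 1, by = 0.02)) {
  if (!identical(dim(K1), dim(K2)))
    stop("K1 and K2 must be conformable")
  K2 <- K2[rownames(K1), colnames(K1)]
  best <- NULL
  for (a in alpha_grid) {
    fit <- reml_univariate(y, a * K1 + (1 - a) * K2)
    if (is.null(best) || fit$loglik > best$loglik) {
      best <- fit
      best$alpha <- a
    }
  }
  best$sigma_k1_2 <- best$alpha * best$sigma_g2
  best$sigma_k2_2 <- (1 - best$alpha) * best$sigma_g2
  best
}

clip_psd <- function(M, floor = 1e-10) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% diag(pmax(e$values, floor), nrow(M)) %*% t(e$vectors)
}

#' Multivariate kernel mixed model by expectation-maximization
#'
#' Fits Y = 1 beta' + A + E for t traits with vec(A) ~ N(0, V_G x K)
#' (Kronecker) and vec(E) ~ N(0, V_E x I), estimating the t x t genetic
#' and residual (co)variance matrices by an EM algorithm in the
#' eigen-rotated basis of K, where rows decouple and every iteration is
#' closed-form. Genetic correlations are read off V_G. Lines with any
#' missing trait are excluded from (V_G, V_E) estimation (prediction for
#' them is done by [predict_trait_assisted()], which conditions on all
#' observed cells).
#'
#' @param Y lines x traits matrix (rownames = line IDs, >= 2 columns);
#'   rows with missing entries are dropped from estimation.
#' @param K relationship matrix covering the rows of Y.
#' @param max_iter,tol EM control: stop when the observed-data
#'   log-likelihood improves by less than `tol` (default 1e-6) or after
#'   `max_iter` iterations (with a warning).
#' @return list of class `multitrait_fit`: `V_G`, `V_E`, `beta` (trait
#'   intercepts), `genetic_cor`, `loglik` (trace), `converged`, `blups`
#'   (genetic-effect matrix for the lines used), `ids`.
#' @export
reml_multivariate <- function(Y, K, max_iter = 1000, tol = 1e-6) {
  Y <- as.matrix(Y)
  if (ncol(Y) < 2) stop("need at least two traits")
  cc <- stats::complete.cases(Y)
  ids <- rownames(Y)[cc]
  ids <- intersect(ids, rownames(K))
  if (length(ids) < 20) stop("need >= 20 lines with complete traits in K")
  Yc <- Y[ids, , drop = FALSE]
  t <- ncol(Yc)
  Kt <- K[ids, ids]
  eg <- eigen(Kt, symmetric = TRUE)
  D <- pmax(eg$values, 0)
  U <- eg$vectors
  n <- length(ids)
  Ys <- crossprod(U, Yc)
  Xs <- drop(crossprod(U, rep(1, n)))

  S0 <- stats::cov(Yc)
  V_G <- clip_psd(S0 / 2, 1e-8)
  V_E <- clip_psd(S0 / 2, 1e-8)
  beta <- colMeans(Yc)
  ll_trace <- numeric(0)
  converged <- FALSE

  # Every iteration simultaneously diagonalizes (V_G, V_E): with
  # V_E = L L', L^-1 V_G L^-T = Q Lam Q' and T = Q' L^-1, the per-row
  # covariances become T^-T (D_i Lam + I) T^-1, so all row operations are
  # elementwise over an n x t array.
  for (it in seq_len(max_iter)) {
    L <- t(chol(V_E))
    Minner <- forwardsolve(L, t(forwardsolve(L, V_G)))
    eig <- eigen((Minner + t(Minner)) / 2, symmetric = TRUE)
    lam <- pmax(eig$values, 0)
    Tm <- t(eig$vectors) %*% forwardsolve(L, diag(t))
    Tinv <- L %*% eig$vectors

    Yt <- Ys %*% t(Tm)                     # n x t, transformed responses
    H <- outer(D, lam) + 1                 # n x t, per-cell variances

    # GLS intercepts in the transformed basis
    a <- colSums(Xs^2 / H)
    cvec <- colSums(Xs * Yt / H)
    beta_t <- cvec / a
    beta <- drop(Tinv %*% beta_t)

    Rt <- Yt - outer(Xs, beta_t)           # transformed residuals
    Ew <- Rt / H                           # e_i = r_i / H_i
    Sw <- sweep(Ew, 2, lam, `*`)           # s_i = lam * r_i / H_i

    # REML: the intercept is integrated out, which adds the GLS
    # uncertainty of beta (diagonal in this basis, covariance 1/a_q) to
    # the conditional second moments
    S1 <- crossprod(Sw, D * Sw)            # sum_i D_i s_i s_i'
    gcorr <- lam^2 * colSums(D * Xs^2 / H^2) / a
    ecorr <- colSums(Xs^2 / H^2) / a
    VG_core <- S1 + diag(n * lam, t) - diag(colSums(D / H) * lam^2, t) +
      diag(gcorr, t)
    VE_core <- crossprod(Ew) + diag(n, t) - diag(colSums(1 / H), t) +
      diag(ecorr, t)
    V_G <- clip_psd(Tinv %*% VG_core %*% t(Tinv) / n)
    V_E <- clip_psd(Tinv %*% VE_core %*% t(Tinv) / n, 1e-8)

    ldetVE <- 2 * sum(log(diag(L)))
    # restricted log-likelihood (constants independent of the parameters
    # dropped): profile loglik minus half the log-determinant of X'V^-1X
    ll <- -0.5 * (n * t * log(2 * pi) + (n - 1) * ldetVE + sum(log(H)) +
                    sum(Rt^2 / H) + sum(log(a)))
    ll_trace <- c(ll_trace, ll)
    if (it > 1 && abs(ll - ll_trace[it - 1]) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations; returning last iterate")

  # genetic-effect BLUPs at the final estimates, back-rotated:
  # a*_i = D_i V_G W_i r_i = Tinv (D_i * s_i)
  L <- t(chol(V_E))
  Minner <- forwardsolve(L, t(forwardsolve(L, V_G)))
  eig <- eigen((Minner + t(Minner)) / 2, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  Tm <- t(eig$vectors) %*% forwardsolve(L, diag(t))
  Tinv <- L %*% eig$vectors
  Yt <- Ys %*% t(Tm)
  H <- outer(D, lam) + 1
  beta_t <- drop(Tm %*% beta)
  Rt <- Yt - outer(Xs, beta_t)
  Sw <- sweep(Rt / H, 2, lam, `*`)
  Astar <- (D * Sw) %*% t(Tinv)
  blups <- U %*% Astar
  dimnames(blups) <- list(ids, colnames(Yc))
  sg <- sqrt(pmax(diag(V_G), 1e-12))
  gc_mat <- V_G / outer(sg, sg)
  dimnames(V_G) <- dimnames(V_E) <- dimnames(gc_mat) <-
    list(colnames(Yc), colnames(Yc))
  names(beta) <- colnames(Yc)
  structure(list(
    V_G = V_G, V_E = V_E, beta = beta, genetic_cor = gc_mat,
    loglik = ll_trace, converged = converged, blups = blups, ids = ids
  ), class = "multitrait_fit")
}

#' @export
print.multitrait_fit <- function(x, ...) {
  cat(sprintf("multitrait_fit: %d lines, %d traits, loglik %.3f (%s)\n",
              length(x$ids), ncol(x$V_G), utils::tail(x$loglik, 1),
              if (x$converged) "converged" else "NOT converged"))
  cat("genetic correlations:\n")
  print(round(x$genetic_cor, 3))
  invisible(x)
}

#' Trait-assisted prediction of a target trait from correlated traits
#'
#' Predicts a target trait (grain yield) for lines on which only the
#' correlated secondary traits (GNDVI dates) were observed. (V_G, V_E) are
#' estimated by [reml_multivariate()] on the lines with complete records;
#' the prediction for each incomplete line is then the exact joint
#' multivariate-normal conditional expectation of its missing target given
#' every observed cell of Y and the relationship matrix.
#'
#' Lines with no observed secondary trait at all are still predicted
#' (through relationships alone) and are listed in attribute
#' `relationship_only`.
#'
#' @param Y lines x traits matrix with the target trait `NA` for
#'   validation lines; other traits may be missing too.
#' @param K relationship matrix covering the rows of Y.
#' @param target column name of the trait to predict (default "GY").
#' @param fit optionally, a ready `multitrait_fit` (skips re-estimation).
#' @return `prediction_result` data.frame (`line_id`, `predicted`) for the
#'   lines missing the target; fit in attribute `fit`.
#' @export
predict_trait_assisted <- function(Y, K, target = "GY", fit = NULL) {
  Y <- as.matrix(Y)
  if (!target %in% colnames(Y)) stop("target trait not in Y")
  if (is.null(fit)) fit <- reml_multivariate(Y, K)
  t <- ncol(Y)
  ids <- intersect(rownames(Y), rownames(K))
  Y <- Y[ids, , drop = FALSE]
  Kyy <- K[ids, ids]
  n <- length(ids)

  mu <- matrix(fit$beta[colnames(Y)], n, t, byrow = TRUE)
  v <- as.vector(Y)            # column-major: trait blocks of n lines
  vm <- as.vector(mu)
  obs <- !is.na(v)
  tgt_col <- which(colnames(Y) == target)
  miss_target <- which(is.na(Y[, tgt_col]))
  if (!length(miss_target)) stop("no line is missing the target trait")
  M <- (tgt_col - 1) * n + miss_target   # cells to predict
  O <- which(obs)

  # Sigma = V_G (x) K + V_E (x) I over the vectorized trait blocks
  VG <- fit$V_G[colnames(Y), colnames(Y)]
  VE <- fit$V_E[colnames(Y), colnames(Y)]
  Sigma_OO <- kron_block(VG, Kyy, O, O) + kron_block(VE, diag(n), O, O)
  Sigma_MO <- kron_block(VG, Kyy, M, O) + kron_block(VE, diag(n), M, O)
  ch <- chol(Sigma_OO + diag(1e-8, length(O)))
  w <- backsolve(ch, backsolve(ch, v[O] - vm[O], transpose = TRUE))
  pred <- vm[M] + drop(Sigma_MO %*% w)

  sec_obs <- rowSums(!is.na(Y[miss_target, -tgt_col, drop = FALSE])) > 0
  out <- data.frame(line_id = ids[miss_target], predicted = pred,
                    stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  attr(out, "model") <- paste0("K+", target, "-assisted")
  attr(out, "relationship_only") <- ids[miss_target][!sec_obs]
  class(out) <- c("prediction_result", "data.frame")
  out
}

# rows/cols of the Kronecker product A (x) B indexed without forming it:
# index k corresponds to trait q = (k-1) %/% n + 1, line i = (k-1) %% n + 1
kron_block <- function(A, B, rows, cols) {
  n <- nrow(B)
  qr_ <- (rows - 1L) %/% n + 1L; ir <- (rows - 1L) %% n + 1L
  qc <- (cols - 1L) %/% n + 1L; ic <- (cols - 1L) %% n + 1L
  A[qr_, qc, drop = FALSE] * B[ir, ic, drop = FALSE]
}
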