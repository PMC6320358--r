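identity_k <- function(ids) {
  K <- diag(length(ids))
  dimnames(K) <- list(ids, ids)
  K
}

test_that("fixed-ratio BLUPs with an identity kernel equal closed-form ridge", {
  set.seed(1)
  n <- 40
  ids <- sprintf("L%02d", 1:n)
  y <- setNames(rnorm(n, 5), ids)
  K <- identity_k(ids)
  for (lam in c(0.3, 1, 4)) {
    fit <- reml_univariate(y, K, lambda = lam)
    # ridge toward the GLS mean with penalty 1/lambda:
    # u = lambda/(1 + lambda) * (y - mu)
    expect_equal(fit$mu, mean(y), tolerance = 1e-10)
    expect_equal(fit$u, lam / (1 + lam) * (y - mean(y)), tolerance = 1e-8)
  }
})

test_that("pure-noise data drives the genetic variance to the boundary", {
  nur <- small_nursery()
  G <- vanraden_g(nur$genotypes)
  set.seed(2)
  y <- setNames(rnorm(length(nur$line_ids), 10), nur$line_ids)
  fit <- reml_univariate(y[1:100], G)
  expect_lt(fit$sigma_g2 / fit$sigma_e2, 0.05)
  # unphenotyped lines are shrunk essentially to the mean
  val <- nur$line_ids[101:120]
  expect_equal(unname(fit$mu + fit$u[val]), rep(fit$mu, 20), tolerance = 0.05)
})

test_that("the 1-D restricted-likelihood search beats a 100-point grid", {
  nur <- small_nursery()
  G <- vanraden_g(nur$genotypes)
  ids <- nur$line_ids[1:30]
  y <- line_means(nur$plot_table, "GY")[ids]
  fit <- reml_univariate(y, G[ids, ids])
  grid <- exp(seq(-10, 10, length.out = 100))
  grid_ll <- vapply(grid, function(l)
    reml_univariate(y, G[ids, ids], lambda = l)$loglik, 0)
  expect_gte(fit$loglik + 1e-6, max(grid_ll))
})

test_that("estimates are invariant to permuting line order in y and K", {
  nur <- small_nursery()
  G <- vanraden_g(nur$genotypes)
  y <- line_means(nur$plot_table, "GY")[nur$line_ids]
  f1 <- reml_univariate(y, G)
  set.seed(3)
  perm <- sample(names(y))
  f2 <- reml_univariate(y[perm], G[perm, perm])
  expect_equal(f1$sigma_g2, f2$sigma_g2, tolerance = 1e-6)
  expect_equal(f1$u[names(f1$u)], f2$u[names(f1$u)], tolerance = 1e-6)
})

test_that("kernel prediction requires disjoint sets and full kernel coverage", {
  nur <- small_nursery()
  G <- vanraden_g(nur$genotypes)
  y <- line_means(nur$plot_table, "GY")[nur$line_ids]
  ids <- nur$line_ids
  expect_error(predict_gblup(y, G, ids[1:50], ids[45:60]), "overlap")
  expect_error(predict_gblup(y, G, ids[1:50], c(ids[60], "GHOST")),
               "absent from K")
  pred <- predict_gblup(y, G, ids[1:100], ids[101:120])
  expect_identical(pred$line_id, ids[101:120])
  expect_true(all(is.finite(pred$predicted)))
})

test_that("a duplicated genotype is predicted like its twin, better than an unrelated control", {
  nur <- small_nursery()
  geno <- nur$genotypes
  y <- line_means(nur$plot_table, "GY")[nur$line_ids]
  # clone line 1 into a pseudo-validation line
  d2 <- rbind(geno$dosage, clone = geno$dosage[1, ])
  rownames(d2)[nrow(d2)] <- "clone"
  G <- vanraden_g(geno_matrix(d2))
  fit <- reml_univariate(y[setdiff(names(y), "clone")], G)
  expect_equal(unname(fit$u["clone"]), unname(fit$u[nur$line_ids[1]]),
               tolerance = 1e-5)
})

test_that("the two-kernel profile degenerates correctly and recovers a pure-K1 truth", {
  nur <- small_nursery()
  G <- vanraden_g(nur$genotypes)
  y <- line_means(nur$plot_table, "GY")[nur$line_ids]

  # K2 = K1: any mixing weight gives the same fit
  f_single <- reml_univariate(y, G)
  f_two <- reml_two_kernel(y, G, G, alpha_grid = c(0, 0.5, 1))
  expect_equal(f_two$sigma_g2, f_single$sigma_g2, tolerance = 1e-6)
  expect_equal(f_two$loglik, f_single$loglik, tolerance = 1e-6)

  # fixed alpha = 0.5 equals the direct fit on the averaged matrix
  A <- pedigree_a(nur$pedigree)[nur$line_ids, nur$line_ids]
  f_half <- reml_two_kernel(y, G, A, alpha_grid = 0.5)
  f_avg <- reml_univariate(y, 0.5 * G + 0.5 * A)
  expect_equal(f_half$sigma_g2, f_avg$sigma_g2, tolerance = 1e-10)
  expect_equal(f_half$sigma_k1_2, 0.5 * f_avg$sigma_g2)
})

test_that("data simulated from one kernel pulls the mixing weight toward it", {
  set.seed(44)
  n <- 400
  ids <- sprintf("L%03d", 1:n)
  # K1: factor structure; K2: unrelated identity
  B <- matrix(rnorm(n * 8), n, 8)
  K1 <- tcrossprod(B) / 8 + diag(1e-3, n)
  dimnames(K1) <- list(ids, ids)
  K2 <- identity_k(ids)
  u <- drop(crossprod(chol(K1), rnorm(n)))
  y <- setNames(u + rnorm(n, 0, 0.5), ids)
  fit <- reml_two_kernel(y, K1, K2, alpha_grid = seq(0, 1, 0.1))
  expect_gte(fit$alpha, 0.8)
})

test_that("multivariate EM tracks a monotone restricted likelihood and matches univariate fits on a diagonal truth", {
  set.seed(55)
  n <- 400
  ids <- sprintf("L%03d", 1:n)
  B <- matrix(rnorm(n * 10), n, 10)
  K <- tcrossprod(B) / 10 + diag(1e-3, n)
  dimnames(K) <- list(ids, ids)
  Lk <- t(chol(K))
  a1 <- drop(Lk %*% rnorm(n)); a2 <- drop(Lk %*% rnorm(n)) * 0.8
  Y <- cbind(t1 = 1 + a1 + rnorm(n, 0, 0.7),
             t2 = 2 + a2 + rnorm(n, 0, 0.5))
  rownames(Y) <- ids
  fit <- reml_multivariate(Y, K)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik) > -1e-8))
  expect_lt(abs(fit$genetic_cor[1, 2]), 3 / sqrt(n) * 1.5)
  u1 <- reml_univariate(setNames(Y[, 1], ids), K)
  u2 <- reml_univariate(setNames(Y[, 2], ids), K)
  expect_equal(fit$V_G[1, 1], u1$sigma_g2, tolerance = 0.02)
  expect_equal(fit$V_G[2, 2], u2$sigma_g2, tolerance = 0.02)
  expect_equal(fit$V_E[1, 1], u1$sigma_e2, tolerance = 0.02)
})

test_that("a duplicated trait is estimated as perfectly genetically correlated", {
  nur <- small_nursery()
  G <- vanraden_g(nur$genotypes)
  y <- line_means(nur$plot_table, "GY")[nur$line_ids]
  Y <- cbind(GY = y, GY2 = y)
  fit <- suppressWarnings(reml_multivariate(Y, G))
  expect_gt(fit$genetic_cor[1, 2], 0.99)
})

test_that("a perfect surrogate with an identity kernel predicts the target almost exactly", {
  set.seed(66)
  n <- 60
  ids <- sprintf("L%02d", 1:n)
  gy <- rnorm(n, 4)
  Y <- cbind(GY = gy, GNDVI = gy)
  rownames(Y) <- ids
  Y[41:60, "GY"] <- NA
  pred <- suppressWarnings(
    predict_trait_assisted(Y, identity_k(ids), target = "GY"))
  expect_identical(pred$line_id, ids[41:60])
  expect_gt(cor(pred$predicted, gy[41:60]), 0.99)
})

test_that("a genetically correlated secondary trait raises prediction accuracy over plain GBLUP", {
  wins <- 0; n_seeds <- 6
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(
      n_nurseries = 1, n_families = 40, progeny_range = c(2, 5),
      n_founders = 30, n_markers = 300, n_chromosomes = 10,
      trait_names = c("GY", "GNDVI_1"),
      trait_means = c(GY = 3.1, GNDVI_1 = 0.6),
      trait_dates = c(GNDVI_1 = "2016-05-02"),
      lines_per_trial = 28, seed = 100 + s)
    nur <- simulate_population(cfg)$nurseries[[1]]
    G <- vanraden_g(nur$genotypes)
    gy <- line_means(nur$plot_table, "GY")[nur$line_ids]
    gn <- line_means(nur$plot_table, "GNDVI_1")[nur$line_ids]
    set.seed(s)
    val <- sample(nur$line_ids, 40)
    tr <- setdiff(nur$line_ids, val)
    Y <- cbind(GY = gy, GNDVI_1 = gn)
    Y[val, "GY"] <- NA
    p_mv <- suppressWarnings(predict_trait_assisted(Y, G, target = "GY"))
    p_uv <- predict_gblup(gy, G, tr, val)
    if (pearson_accuracy(gy, p_mv) >= pearson_accuracy(gy, p_uv))
      wins <- wins + 1
  }
  expect_gte(wins, ceiling(0.7 * n_seeds))
})
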