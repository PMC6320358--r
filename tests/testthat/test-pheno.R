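test_that("GNDVI matches an independently coded evaluation of the index", {
  expect_equal(compute_gndvi(0.4, 0.4), 0)
  expect_equal(compute_gndvi(0.6, 0.2), 0.5)
  set.seed(14)
  r780 <- runif(100, 0, 1)
  r550 <- runif(100, 0.01, 1)
  oracle <- mapply(function(a, b) (a - b) / (a + b), r780, r550)
  expect_equal(compute_gndvi(r780, r550), oracle)
  expect_true(all(abs(compute_gndvi(r780, r550)) <= 1))
  expect_error(compute_gndvi(0, 0), "undefined")
  expect_error(compute_gndvi(-0.1, 0.5), "non-negative")
})

test_that("the spread-based outlier rule matches a brute-force Huber fit", {
  expect_true(all(huber_outlier_filter(rep(5, 5))))
  expect_true(all(huber_outlier_filter(c(0, 0.1, -0.1, 0.05, 100),
                                       k_spreads = Inf)))

  # independent fixed-point iteration for Huber's Proposal 2 (k = 1.345):
  # winsorize at mu +/- k s, take the winsorized mean, and rescale the
  # winsorized variance by its expected value under normality
  oracle_hubers <- function(y, k = 1.345, iters = 500) {
    n <- length(y)
    mu <- median(y); s <- mad(y)
    beta <- 2 * pnorm(k) - 1 - 2 * k * dnorm(k) + 2 * k^2 * (1 - pnorm(k))
    for (i in seq_len(iters)) {
      yy <- pmin(pmax(y, mu - k * s), mu + k * s)
      mu <- mean(yy)
      s <- sqrt(sum((yy - mu)^2) / ((n - 1) * beta))
    }
    list(mu = mu, s = s)
  }
  y <- c(0, 0.1, -0.1, 0.05, 100)
  or <- oracle_hubers(y)
  # the fitted fixed point is approached within its iteration cap, so
  # agreement is to ~1e-2 relative, enough to pin the estimator family
  cs <- stressgp:::huber_center_spread(y)
  expect_equal(cs$center, or$mu, tolerance = 1e-2)
  expect_equal(cs$spread, or$s, tolerance = 1e-2)
  keep <- huber_outlier_filter(y, k_spreads = 4)
  expect_identical(keep, c(TRUE, TRUE, TRUE, TRUE, FALSE))

  set.seed(2)
  y2 <- c(rnorm(40), 25)
  or2 <- oracle_hubers(y2)
  keep2 <- huber_outlier_filter(y2, 4)
  expect_identical(keep2, abs(y2 - or2$mu) <= 4 * or2$s)
})

test_that("group-wise outlier filtering removes only planted outliers", {
  nur <- small_nursery()
  pt <- nur$plot_table
  idx <- which(pt$trait == "GY")[c(3, 50)]
  pt$value[idx] <- pt$value[idx] + 50
  filtered <- filter_plot_outliers(pt)
  expect_true(all(is.na(filtered$value[idx])))
  expect_gte(attr(filtered, "n_outliers"), 2)
  expect_lte(attr(filtered, "n_outliers"), 6)
})

test_that("the plot model collapses to line means in a degenerate design", {
  d <- data.frame(line_id = rep(c("a", "b", "c"), each = 2),
                  nursery = "N", environment = "heat", trial = 1, rep = 1,
                  block = 1, trait = "GY",
                  date = NA_character_,
                  value = c(1, 3, 4, 6, 10, 12))
  b <- fit_plot_model(d)
  expect_equal(b$blues, c(a = 2, b = 5, c = 11))
})

test_that("BLUEs equal a generalized-least-squares solve at the fitted variance components", {
  # balanced 6 lines x 2 trials x 2 reps (<= 50 plots)
  set.seed(60)
  d <- expand.grid(line_id = sprintf("L%d", 1:6), trial = 1:2, rep = 1:2,
                   stringsAsFactors = FALSE)
  d$block <- ifelse(match(d$line_id, sprintf("L%d", 1:6)) <= 3, 1, 2)
  d$nursery <- "N"; d$environment <- "heat"; d$trait <- "GY"
  d$date <- NA_character_
  tbv <- rnorm(6); names(tbv) <- sprintf("L%d", 1:6)
  d$value <- 5 + tbv[d$line_id] + rnorm(2)[d$trial] +
    0.5 * rnorm(4)[(d$trial - 1) * 2 + d$rep] + rnorm(nrow(d), 0, 0.6)
  fit <- fit_plot_model(d)
  oracle <- gls_blues_oracle(d, fit$sigma)
  expect_equal(fit$blues, oracle, tolerance = 1e-8)

  # duplicating every record leaves the GLS/REML agreement intact
  d2 <- rbind(d, d)
  fit2 <- fit_plot_model(d2)
  expect_equal(fit2$blues, gls_blues_oracle(d2, fit2$sigma), tolerance = 1e-8)
})

test_that("BLUEs are invariant to record order", {
  nur <- small_nursery()
  gy <- nur$plot_table[nur$plot_table$trait == "GY", ]
  b1 <- fit_plot_model(gy)
  set.seed(4)
  b2 <- fit_plot_model(gy[sample(nrow(gy)), ])
  expect_equal(b1$blues, b2$blues[names(b1$blues)], tolerance = 1e-6)
})

test_that("heritability follows the line-mean formula and its limits", {
  expect_equal(heritability(1, 0, 3), 1)
  expect_equal(heritability(0, 5, 3), 0)
  expect_equal(heritability(1, 3, 3), sqrt(0.5))
  expect_error(heritability(0, 0, 3), "undefined")
  expect_error(heritability(-1, 1, 3), ">= 0")
  # inverse helper round-trips
  ve <- heritability_to_ve(0.75, 0.25, 3)
  expect_equal(heritability(0.25, ve, 3), 0.75)
})

test_that("correlation of BLUEs with true breeding values increases with replication", {
  cors <- sapply(1:8, function(s) {
    cfg <- sim_config(n_nurseries = 1, n_families = 30, progeny_range = c(2, 3),
                      n_founders = 20, n_markers = 120, n_chromosomes = 5,
                      trait_names = "GY", trait_means = c(GY = 3),
                      V_G = matrix(0.25), V_E = matrix(1.2),
                      lines_per_trial = 25, n_reps = 1, n_blocks = 5, seed = s)
    cfg3 <- cfg; cfg3$n_reps <- 3
    n1 <- simulate_population(cfg)$nurseries[[1]]
    n3 <- simulate_population(cfg3)$nurseries[[1]]
    c(r1 = cor(line_means(n1$plot_table, "GY")[n1$line_ids],
               n1$true_breeding_values[, "GY"]),
      r3 = cor(line_means(n3$plot_table, "GY")[n3$line_ids],
               n3$true_breeding_values[, "GY"]))
  })
  expect_gt(mean(cors["r3", ]), mean(cors["r1", ]))
})

test_that("date screening drops low-heritability dates and labels stages", {
  mk_blue <- function(date, vg, ve) {
    structure(list(blues = NULL,
                   sigma = c(genotype = vg, env = NA, trial = 0, rep = 0,
                             block = 0, residual = ve),
                   nreps = 3, trait = "GNDVI", date = date, n_obs = 100,
                   loglik = 0), class = "blue_set")
  }
  sets <- list(mk_blue("2016-04-10", 1, 0.5), mk_blue("2016-05-02", 0.1, 9))
  out <- screen_dates(sets, min_H = 0.5)
  expect_identical(out$retained, c(TRUE, FALSE))
  expect_identical(out$stage, c("grain-filling 1", NA_character_))

  out2 <- screen_dates(sets, min_H = 0)
  expect_true(all(out2$retained))

  # stage labels from heading/maturity dates
  sets3 <- list(mk_blue("2016-03-20", 1, 0.5), mk_blue("2016-04-02", 1, 0.5),
                mk_blue("2016-04-20", 1, 0.5), mk_blue("2016-05-20", 1, 0.5))
  out3 <- screen_dates(sets3, min_H = 0.5, heading_date = "2016-04-01",
                       maturity_date = "2016-05-15")
  expect_identical(out3$stage,
                   c("vegetative", "heading", "grain-filling 1", "maturity"))
  expect_error(screen_dates(sets, min_H = 0.99), "all dates dropped")
})

test_that("simulated GNDVI dates all clear the default heritability screen", {
  nur <- small_nursery()
  sets <- lapply(c("2016-05-02", "2016-05-09"), function(dt) {
    tr <- sub("@.*", "", c("GNDVI_1", "GNDVI_2")[c("2016-05-02", "2016-05-09") == dt])
    fit_plot_model(nur$plot_table, trait = tr, date = dt,
                   genotype_random = TRUE)
  })
  out <- screen_dates(sets, min_H = 0.5)
  expect_true(all(out$retained))
  expect_true(all(out$H > 0.75 & out$H < 1))
})
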