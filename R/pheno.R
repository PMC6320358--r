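#' Green normalized difference vegetation index
#'
#' GNDVI = (R780 - R550) / (R780 + R550), a canopy greenness proxy computed
#' from near-infrared (780 nm) and green (550 nm) reflectance.
#'
#' @param r780,r550 non-negative reflectance values (vectorized).
#' @return GNDVI values in [-1, 1].
#' @export
compute_gndvi <- function(r780, r550) {
  if (any(r780 < 0 | r550 < 0, na.rm = TRUE))
    stop("reflectances must be non-negative")
  if (any(r780 + r550 == 0, na.rm = TRUE))
    stop("GNDVI undefined when both reflectances are zero")
  (r780 - r550) / (r780 + r550)
}

# Huber "Proposal 2" joint location/scale (k = 1.345); zero-MAD inputs get
# spread 0, which the outlier rule treats as "flag nothing"
huber_center_spread <- function(values, k = 1.345) {
  v <- values[is.finite(values)]
  if (length(v) < 3) stop("need at least 3 finite values")
  if (stats::mad(v) == 0) return(list(center = stats::median(v), spread = 0))
  h <- MASS::hubers(v, k = k)
  list(center = h$mu, spread = h$s)
}

#' Robust outlier mask for plot-level trait values
#'
#' Flags values more than `k_spreads` robust spreads from a robust center
#' as outliers (to be set missing). Center and spread are the joint Huber
#' M-estimates of location and scale (tuning constant 1.345). When the
#' spread is zero (all values identical), nothing is flagged.
#'
#' @param values numeric vector (NAs pass through as NA in the mask).
#' @param k_spreads number of spreads beyond which a value is an outlier
#'   (default 4; `Inf` keeps everything).
#' @return logical mask, `TRUE` = keep; same length as `values`.
#' @export
huber_outlier_filter <- function(values, k_spreads = 4) {
  keep <- rep(NA, length(values))
  fin <- is.finite(values)
  if (sum(fin) < 3) stop("need at least 3 finite values")
  if (is.infinite(k_spreads)) {
    keep[fin] <- TRUE
    return(keep)
  }
  cs <- huber_center_spread(values[fin])
  if (cs$spread == 0) {
    keep[fin] <- TRUE
  } else {
    keep[fin] <- abs(values[fin] - cs$center) <= k_spreads * cs$spread
  }
  keep
}

#' Apply the outlier rule per trait within a plot table
#'
#' Runs [huber_outlier_filter()] separately for every
#' nursery x environment x trait x date group and sets flagged values to
#' `NA`.
#'
#' @param plots plot-record data.frame (see [read_phenotypes()]).
#' @param k_spreads spread multiplier passed on.
#' @return `plots` with outliers set missing; the number removed is
#'   recorded in attribute `n_outliers`.
#' @export
filter_plot_outliers <- function(plots, k_spreads = 4) {
  grp <- interaction(plots$nursery, plots$environment, plots$trait,
                     ifelse(is.na(plots$date), "", plots$date), drop = TRUE)
  removed <- 0L
  for (g in levels(grp)) {
    idx <- which(grp == g)
    if (sum(is.finite(plots$value[idx])) < 3) next
    keep <- huber_outlier_filter(plots$value[idx], k_spreads)
    bad <- idx[!is.na(keep) & !keep]
    plots$value[bad] <- NA_real_
    removed <- removed + length(bad)
  }
  attr(plots, "n_outliers") <- removed
  plots
}

#' Fit the plot-level mixed model and extract BLUEs or variance components
#'
#' Fits `value = mu + genotype + trial + rep(trial) + block(trial, rep) +
#' error` by REML (via \pkg{lme4}), with trial, replicate-within-trial and
#' block-within-replicate random. With `genotype_random = FALSE` the
#' genotype is fixed and its estimates are the line BLUEs; with
#' `genotype_random = TRUE` the genotype is random and the genetic and
#' residual variance components feed the line-mean heritability. With
#' `pool_environments = TRUE` a random environment effect is added and
#' trials are nested in environments.
#'
#' Grouping factors with fewer than two levels are dropped (a single-trial,
#' single-replicate dataset collapses to per-line means).
#'
#' @param plots plot-record data.frame with columns `line_id`, `trial`,
#'   `rep`, `block`, `trait`, `value` (and `nursery`, `environment`,
#'   `date`).
#' @param trait which trait to fit (required if several present).
#' @param date which date to fit (for dated traits such as GNDVI).
#' @param pool_environments pool environments with a random environment
#'   effect.
#' @param genotype_random fit genotype as random (for heritability) rather
#'   than fixed (for BLUEs).
#' @return an object of class `blue_set`: list with `blues` (named vector;
#'   `NULL` when genotype is random), `sigma` (named vector of variance
#'   components: `genotype`, `env`, `trial`, `rep`, `block`, `residual`),
#'   `nreps`, `trait`, `date`, `n_obs`, `loglik`.
#' @export
fit_plot_model <- function(plots, trait = NULL, date = NULL,
                           pool_environments = FALSE,
                           genotype_random = FALSE) {
  d <- plots
  if (!is.null(trait)) d <- d[d$trait == trait, , drop = FALSE]
  if (is.null(trait)) {
    tr <- unique(d$trait)
    if (length(tr) > 1) stop("several traits present; pass `trait`")
    trait <- tr
  }
  if (!is.null(date)) d <- d[!is.na(d$date) & d$date == date, , drop = FALSE]
  d <- d[!is.na(d$value), , drop = FALSE]
  if (!nrow(d)) stop("no observations to fit")
  if (!pool_environments && length(unique(d$environment)) > 1)
    stop("multiple environments present; subset or set pool_environments = TRUE")

  d$line_id <- factor(d$line_id)
  envp <- if (pool_environments) as.character(d$environment) else ""
  d$.trial <- factor(paste(envp, d$trial, sep = ":"))
  d$.rep <- factor(paste(d$.trial, d$rep, sep = ":"))
  d$.block <- factor(paste(d$.rep, d$block, sep = ":"))
  d$.env <- factor(envp)

  terms <- c()
  if (pool_environments && nlevels(d$.env) > 1) terms <- c(terms, "(1 | .env)")
  for (v in c(".trial", ".rep", ".block"))
    if (nlevels(d[[v]]) > 1) terms <- c(terms, sprintf("(1 | %s)", v))
  if (genotype_random) terms <- c("(1 | line_id)", terms)

  sigma <- c(genotype = NA_real_, env = NA_real_, trial = NA_real_,
             rep = NA_real_, block = NA_real_, residual = NA_real_)
  blues <- NULL

  if (length(terms) == 0) {
    # no usable grouping factors: ordinary least squares (per-line means)
    fit <- stats::lm(value ~ 0 + line_id, data = d)
    if (anyNA(stats::coef(fit))) stop("singular fixed design: unestimable line")
    blues <- stats::coef(fit)
    names(blues) <- levels(d$line_id)
    sigma["residual"] <- summary(fit)$sigma^2
    ll <- as.numeric(stats::logLik(fit))
  } else {
    lhs <- if (genotype_random) "value ~ 1 + " else "value ~ 0 + line_id + "
    form <- stats::as.formula(paste0(lhs, paste(terms, collapse = " + ")))
    fit <- lme4::lmer(form, data = d, REML = TRUE,
                      control = lme4::lmerControl(
                        check.nobs.vs.nlev = "ignore",
                        check.nobs.vs.nRE = "ignore",
                        calc.derivs = FALSE))
    vc <- as.data.frame(lme4::VarCorr(fit))
    for (i in seq_len(nrow(vc))) {
      nm <- switch(vc$grp[i], "line_id" = "genotype", ".env" = "env",
                   ".trial" = "trial", ".rep" = "rep", ".block" = "block",
                   "Residual" = "residual", NA_character_)
      if (!is.na(nm)) sigma[nm] <- vc$vcov[i]
    }
    if (!genotype_random) {
      fe <- lme4::fixef(fit)
      if (anyNA(fe)) stop("singular fixed design: unestimable line")
      names(fe) <- sub("^line_id", "", names(fe))
      blues <- fe
    }
    ll <- as.numeric(stats::logLik(fit))
  }

  nreps <- stats::median(table(d$line_id))
  out <- list(
    blues = blues, sigma = sigma, nreps = as.numeric(nreps),
    trait = trait, date = if (is.null(date)) NA_character_ else date,
    n_obs = nrow(d), loglik = ll
  )
  class(out) <- "blue_set"
  out
}

#' @export
print.blue_set <- function(x, ...) {
  cat(sprintf("blue_set: trait %s%s, %d obs, %s\n", x$trait,
              if (is.na(x$date)) "" else paste0(" @", x$date), x$n_obs,
              if (is.null(x$blues)) "genotype random" else
                sprintf("%d line BLUEs", length(x$blues))))
  sg <- x$sigma[!is.na(x$sigma)]
  cat("  variance components:",
      paste(sprintf("%s=%.4g", names(sg), sg), collapse = ", "), "\n")
  invisible(x)
}

#' Line-mean heritability (square-root scale)
#'
#' H = sqrt(vg / (vg + ve / nreps)): the square root of line-mean
#' broad-sense heritability, the form in which heritabilities are reported
#' for these trials.
#'
#' @param sigma_g2 genetic variance.
#' @param sigma_e2 residual (plot error) variance.
#' @param nreps number of replicates.
#' @return H in [0, 1].
#' @export
heritability <- function(sigma_g2, sigma_e2, nreps) {
  if (sigma_g2 < 0 || sigma_e2 < 0 || nreps < 1)
    stop("variances must be >= 0 and nreps >= 1")
  if (sigma_g2 == 0 && sigma_e2 == 0)
    stop("heritability undefined when both variances are zero")
  sqrt(sigma_g2 / (sigma_g2 + sigma_e2 / nreps))
}

#' Heritability of a trait straight from plot records
#'
#' Convenience wrapper: fits [fit_plot_model()] with genotype random and
#' applies [heritability()].
#'
#' @inheritParams fit_plot_model
#' @return H (square-root scale).
#' @export
line_heritability <- function(plots, trait = NULL, date = NULL,
                              pool_environments = FALSE) {
  fit <- fit_plot_model(plots, trait = trait, date = date,
                        pool_environments = pool_environments,
                        genotype_random = TRUE)
  heritability(fit$sigma[["genotype"]], fit$sigma[["residual"]], fit$nreps)
}

#' Screen dated trait measurements by heritability and label growth stages
#'
#' Drops measurement dates whose line-mean heritability falls below
#' `min_H` and labels the survivors with growth stages. When the nursery's
#' mean heading and maturity dates are supplied, dates before heading are
#' `vegetative`, dates within a week after heading are `heading`, dates up
#' to maturity are `grain-filling 1..n` (in date order), and later dates
#' are `maturity`. Without them, survivors are labeled
#' `grain-filling 1..n` in date order.
#'
#' @param blue_sets list of `blue_set` objects fitted with
#'   `genotype_random = TRUE`, one per date.
#' @param min_H heritability threshold (square-root scale, default 0.5).
#' @param heading_date,maturity_date optional ISO-8601 dates (nursery
#'   means) used for stage labels.
#' @return data.frame with columns `date`, `H`, `retained`, `stage`
#'   (`NA` stage for dropped dates), ordered by date.
#' @export
screen_dates <- function(blue_sets, min_H = 0.5, heading_date = NULL,
                         maturity_date = NULL) {
  if (!length(blue_sets)) stop("need at least one date")
  H <- vapply(blue_sets, function(b)
    heritability(b$sigma[["genotype"]], b$sigma[["residual"]], b$nreps), 0)
  dates <- vapply(blue_sets, function(b) b$date, "")
  ord <- order(dates)
  dates <- dates[ord]; H <- H[ord]
  retained <- H >= min_H
  if (!any(retained)) stop("all dates dropped at min_H = ", min_H)
  stage <- rep(NA_character_, length(dates))
  kept <- which(retained)
  if (!is.null(heading_date)) {
    hd <- as.Date(heading_date)
    md <- if (is.null(maturity_date)) as.Date(Inf) else as.Date(maturity_date)
    gf <- 0L
    for (i in kept) {
      d <- as.Date(dates[i])
      if (d < hd) stage[i] <- "vegetative"
      else if (d < hd + 7) stage[i] <- "heading"
      else if (d < md) { gf <- gf + 1L; stage[i] <- paste("grain-filling", gf) }
      else stage[i] <- "maturity"
    }
  } else {
    stage[kept] <- paste("grain-filling", seq_along(kept))
  }
  data.frame(date = dates, H = H, retained = retained, stage = stage,
             stringsAsFactors = FALSE)
}

#' BLUEs for every trait (and date) in a plot table
#'
#' Maps [fit_plot_model()] over all trait x date combinations present and
#' assembles a lines x items matrix of BLUEs. Item names are the trait name,
#' or `trait@date` for dated traits.
#'
#' @inheritParams fit_plot_model
#' @param traits traits to include (default: all in the table).
#' @param exclude_checks drop check entries (line IDs containing `_CHK`)
#'   from the returned matrix (they still contribute to model fitting).
#' @return numeric matrix, rownames = line IDs, colnames = items.
#' @export
blues_matrix <- function(plots, traits = NULL, pool_environments = FALSE,
                         exclude_checks = TRUE) {
  if (is.null(traits)) traits <- unique(plots$trait)
  cols <- list()
  for (tr in traits) {
    sub <- plots[plots$trait == tr, , drop = FALSE]
    dts <- unique(sub$date[!is.na(sub$date)])
    if (length(dts) == 0) {
      b <- fit_plot_model(sub, trait = tr, pool_environments = pool_environments)
      cols[[tr]] <- b$blues
    } else {
      for (dt in sort(dts)) {
        b <- fit_plot_model(sub, trait = tr, date = dt,
                            pool_environments = pool_environments)
        cols[[paste0(tr, "@", dt)]] <- b$blues
      }
    }
  }
  ids <- sort(unique(unlist(lapply(cols, names))))
  M <- matrix(NA_real_, length(ids), length(cols),
              dimnames = list(ids, names(cols)))
  for (nm in names(cols)) M[names(cols[[nm]]), nm] <- cols[[nm]]
  if (exclude_checks) {
    chk <- grepl("_CHK", rownames(M), fixed = TRUE)
    if ("is_check" %in% names(plots)) {
      chk_ids <- unique(plots$line_id[plots$is_check])
      chk <- chk | rownames(M) %in% chk_ids
    }
    M <- M[!chk, , drop = FALSE]
  }
  M
}
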