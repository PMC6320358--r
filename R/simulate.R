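#' Simulation configuration for a synthetic breeding population
#'
#' Bundles every knob of the synthetic elite-yield-trial generator: the
#' family structure (founders, crosses, progeny per cross, selfing
#' generations), the genome (markers, chromosomes, one Morgan each), the
#' multi-trait genetic architecture (`V_G`, `V_E`), and the field design
#' (trials of `lines_per_trial` entries plus two checks, `n_reps`
#' replicates, `n_blocks` incomplete blocks per replicate).
#'
#' The defaults emulate an elite spring-wheat yield trial nursery evaluated
#' under late-sown heat stress: ~1092 F6:F7 lines per nursery in small
#' full-sib families (1-6 progeny per cross), 39 trials of 28 lines + 2
#' checks in 3 replicates x 6 blocks, 9285 SNP markers on 21 chromosomes,
#' grain yield (GY, t/ha), days to heading (DTHD), plant height (HT, cm)
#' and GNDVI at two dates, with line-mean heritabilities (square-root
#' scale) of 0.75 for GY and ~0.9 for GNDVI and a GY-GNDVI genetic
#' correlation of 0.7.
#'
#' @param n_nurseries number of nurseries (years) to simulate.
#' @param n_families full-sib families (crosses) per nursery.
#' @param progeny_range integer length-2 vector: min and max progeny per
#'   cross (sizes drawn uniformly).
#' @param n_founders inbred founder (parent) lines the crosses are drawn
#'   from.
#' @param n_grandfounders size of the older, unrecorded breeding pool the
#'   founders themselves descend from (default 30). Founders derived from
#'   a finite pool are related to one another, but the delivered pedigree
#'   records them as unknown-parent lines -- as recorded pedigrees of
#'   elite material do -- so marker data sees relatedness the A matrix
#'   cannot.
#' @param rg_across genetic correlation of marker effects between
#'   nurseries (default 0.75): successive years share most but not all of
#'   the trait architecture (genotype-by-year interaction), which caps
#'   across-nursery prediction accuracy below the within-nursery level.
#' @param n_markers,n_chromosomes genome size; markers are spread evenly
#'   over chromosomes of one Morgan each.
#' @param n_selfing_generations selfing generations after the cross
#'   (default 5, giving F6-like lines).
#' @param within_family_selection fraction of the within-family genetic
#'   deviation retained after the earlier-stage selection the lines went
#'   through before reaching the elite trial (default 0.5). Selected-bulk
#'   material enters these trials with full sibs clustered near their
#'   family mean; 1 means no prior selection.
#' @param trait_names character vector of trait names.
#' @param trait_means named numeric vector of trait intercepts.
#' @param trait_dates optional named character vector mapping a trait to a
#'   measurement date (ISO-8601), used for GNDVI items.
#' @param V_G,V_E t x t genetic and residual (co)variance matrices
#'   (symmetric positive semidefinite, dimnames = traits).
#' @param lines_per_trial,n_reps,n_blocks,variance_trial,variance_rep,variance_block
#'   field design: entries per trial (checks excluded), replicates, blocks
#'   per replicate, and the trial / replicate / block variance components
#'   (shared across traits, on each trait's own scale via scaling by
#'   `diag(V_E)`; see Details).
#' @param prop_scored fraction of the simulated markers delivered in each
#'   nursery's genotype output (default 0.6). All markers are causal; the
#'   unscored remainder emulates the part of the genome a genotyping-by-
#'   sequencing panel does not tag, so marker-based relationships are a
#'   (realistically) noisy estimate of the realized ones.
#' @param environment label attached to every plot record.
#' @param seed integer seed; the whole simulation is reproducible from it.
#'
#' @details Trial, replicate and block variances are specified as
#'   proportions of each trait's residual variance so that one number is
#'   meaningful for traits on different scales: the realized variance for
#'   trait q is `variance_trial * V_E[q,q]`, etc.
#'
#' `heritability_to_ve()` is the companion helper that converts a target
#' line-mean heritability (square-root scale, as reported for these trials)
#' into the residual variance implied by Eq.-2-style line means.
#'
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_nurseries = 4,
                       n_families = 312,
                       progeny_range = c(1L, 6L),
                       n_founders = 60,
                       n_grandfounders = 30,
                       rg_across = 0.75,
                       n_markers = 9285,
                       n_chromosomes = 21,
                       n_selfing_generations = 5,
                       within_family_selection = 0.5,
                       trait_names = c("GY", "DTHD", "HT", "GNDVI_1", "GNDVI_2"),
                       trait_means = c(GY = 3.1, DTHD = 60, HT = 75,
                                       GNDVI_1 = 0.65, GNDVI_2 = 0.55),
                       trait_dates = c(GNDVI_1 = "2016-05-02",
                                       GNDVI_2 = "2016-05-09"),
                       V_G = NULL,
                       V_E = NULL,
                       lines_per_trial = 28,
                       n_reps = 3,
                       n_blocks = 6,
                       variance_trial = 0.5,
                       variance_rep = 0.25,
                       variance_block = 0.25,
                       prop_scored = 0.6,
                       environment = "heat",
                       seed = 1L) {
  if (n_families < 1 || n_founders < 2 || n_markers < 1 || n_chromosomes < 1)
    stop("counts must be positive (and n_founders >= 2)")
  if (progeny_range[1] < 1 || progeny_range[2] < progeny_range[1])
    stop("progeny_range must satisfy 1 <= min <= max")
  t <- length(trait_names)
  if (is.null(V_G) || is.null(V_E)) {
    arch <- default_architecture(trait_names, n_reps)
    if (is.null(V_G)) V_G <- arch$V_G
    if (is.null(V_E)) V_E <- arch$V_E
  }
  V_G <- as.matrix(V_G); V_E <- as.matrix(V_E)
  if (!all(dim(V_G) == t) || !all(dim(V_E) == t))
    stop("V_G and V_E must be t x t with t = length(trait_names)")
  check_psd(V_G, "V_G"); check_psd(V_E, "V_E")
  dimnames(V_G) <- dimnames(V_E) <- list(trait_names, trait_names)
  if (rg_across < -1 || rg_across > 1) stop("rg_across must be in [-1, 1]")
  cfg <- list(
    n_nurseries = n_nurseries, n_families = n_families,
    progeny_range = as.integer(progeny_range), n_founders = n_founders,
    n_grandfounders = n_grandfounders, rg_across = rg_across,
    n_markers = n_markers, n_chromosomes = n_chromosomes,
    n_selfing_generations = n_selfing_generations,
    within_family_selection = within_family_selection,
    trait_names = trait_names, trait_means = trait_means,
    trait_dates = trait_dates, V_G = V_G, V_E = V_E,
    lines_per_trial = lines_per_trial, n_reps = n_reps, n_blocks = n_blocks,
    variance_trial = variance_trial, variance_rep = variance_rep,
    variance_block = variance_block, prop_scored = prop_scored,
    environment = environment, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

check_psd <- function(M, name) {
  if (!isSymmetric(unname(M), tol = 1e-8))
    stop(name, " must be symmetric")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop(name, " must be positive semidefinite")
  invisible(TRUE)
}

#' Residual variance implied by a target line-mean heritability
#'
#' Inverts the line-mean heritability definition
#' H = sqrt(vg / (vg + ve / nreps)) (H on the square-root scale, as
#' reported for these trials) to give the residual variance that produces a
#' target H for a given genetic variance and replicate count.
#'
#' @param H target heritability (square-root scale), in (0, 1].
#' @param vg genetic variance.
#' @param nreps number of replicates.
#' @return residual (plot error) variance.
#' @export
heritability_to_ve <- function(H, vg, nreps) {
  stopifnot(H > 0, H <= 1, vg >= 0, nreps >= 1)
  nreps * vg * (1 / H^2 - 1)
}

# default multi-trait architecture: genetic SDs and heritabilities chosen
# to mirror a heat-stressed elite yield trial (GY H ~0.75, GNDVI H ~0.9,
# GY-GNDVI genetic correlation 0.7, GNDVI dates correlated 0.9)
default_architecture <- function(traits, n_reps) {
  known_sd <- c(GY = 0.5, DTHD = 3, HT = 5, GNDVI = 0.03)
  known_H <- c(GY = 0.75, DTHD = 0.95, HT = 0.9, GNDVI = 0.9)
  base <- sub("_[0-9]+$", "", traits)
  sdv <- ifelse(base %in% names(known_sd), known_sd[base], 1)
  Hv <- ifelse(base %in% names(known_H), known_H[base], 0.8)
  t <- length(traits)
  R <- diag(t)
  for (i in seq_len(t)) for (j in seq_len(t)) {
    if (i == j) next
    bi <- base[i]; bj <- base[j]
    r <- 0
    if (bi == "GNDVI" && bj == "GNDVI") r <- 0.9
    else if (sort(c(bi, bj))[1] == "GNDVI" || sort(c(bi, bj))[2] == "GNDVI") {
      other <- setdiff(c(bi, bj), "GNDVI")
      r <- switch(other, GY = 0.7, DTHD = 0.3, HT = 0.2, 0)
    } else if (all(c(bi, bj) %in% c("GY", "HT"))) r <- 0.3
    else if (all(c(bi, bj) %in% c("GY", "DTHD"))) r <- -0.2
    R[i, j] <- r
  }
  # nearest-PSD guard for hand-entered correlation patterns
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    R <- ev$vectors %*% diag(pmax(ev$values, 1e-6)) %*% t(ev$vectors)
    d <- sqrt(diag(R)); R <- R / outer(d, d)
  }
  V_G <- R * outer(sdv, sdv)
  ve <- mapply(heritability_to_ve, H = Hv, vg = sdv^2,
               MoreArgs = list(nreps = n_reps))
  V_E <- diag(ve, nrow = t)
  # residual correlations: repeated GNDVI dates share sensor and canopy
  # state; GNDVI and yield share the plot and its stress microenvironment
  # (phenotypic correlations in these trials attenuate less than the
  # heritabilities alone would allow)
  gn <- which(base == "GNDVI")
  if (length(gn) > 1) {
    for (i in gn) for (j in gn) if (i != j)
      V_E[i, j] <- 0.3 * sqrt(ve[i] * ve[j])
  }
  gy <- which(base == "GY")
  if (length(gy) == 1 && length(gn)) {
    for (j in gn)
      V_E[gy, j] <- V_E[j, gy] <- 0.3 * sqrt(ve[gy] * ve[j])
  }
  dimnames(V_G) <- dimnames(V_E) <- list(traits, traits)
  list(V_G = V_G, V_E = V_E)
}

#' Simulate fully inbred founder lines
#'
#' Draws an allele frequency per marker (uniform on 0.05-0.95) and then,
#' independently per founder and marker, a homozygous dosage in \{0, 2\}
#' with P(dosage = 2) equal to that frequency. Markers are spread evenly
#' over `n_chromosomes` chromosomes of one Morgan each.
#'
#' @param n_founders,n_markers,n_chromosomes positive counts.
#' @param seed integer seed.
#' @return a `geno_matrix` with no missing values and the drawn allele
#'   frequencies in `$allele_freq`; founder haplotypes are attached for use
#'   by [simulate_progeny()].
#' @export
simulate_founders <- function(n_founders, n_markers, n_chromosomes = 1, seed = 1L) {
  if (n_founders < 1 || n_markers < 1 || n_chromosomes < 1)
    stop("counts must be positive")
  rng <- local_rng(seed)
  p <- stats::runif(n_markers, 0.05, 0.95)
  haplo <- matrix(
    stats::rbinom(n_founders * n_markers, 1L, rep(p, each = n_founders)),
    nrow = n_founders
  )
  ids <- sprintf("F%03d", seq_len(n_founders))
  chrom <- rep(seq_len(n_chromosomes), length.out = n_markers)
  chrom <- sort(chrom)
  pos <- stats::ave(rep(0, n_markers), chrom,
                    FUN = function(v) (seq_along(v) - 0.5) / length(v))
  dn <- list(ids, sprintf("M%05d", seq_len(n_markers)))
  dosage <- 2 * haplo
  dimnames(dosage) <- dn
  g <- geno_matrix(dosage, chrom = chrom, pos = pos, allele_freq = p)
  dimnames(haplo) <- dn
  g$haplo <- list(h1 = haplo, h2 = haplo)
  g
}

# all simulator entry points are reproducible from an explicit seed
local_rng <- function(seed) {
  set.seed(as.integer(seed))
  invisible(NULL)
}

# one meiosis: recombine two haplotypes (0/1 vectors over all markers)
# using Poisson(1) crossovers per chromosome at uniform positions
meiosis <- function(h1, h2, chrom, pos) {
  out <- h1
  for (c_id in unique(chrom)) {
    idx <- which(chrom == c_id)
    nx <- stats::rpois(1, 1)
    start <- stats::rbinom(1, 1, 0.5)
    if (nx == 0) {
      strand <- rep(start, length(idx))
    } else {
      bp <- sort(stats::runif(nx))
      strand <- (start + findInterval(pos[idx], bp)) %% 2
    }
    out[idx] <- ifelse(strand == 0, h1[idx], h2[idx])
  }
  out
}

#' Simulate progeny lines by gamete dropping and selfing
#'
#' For each line in the crossing plan, draws one gamete from each parent
#' (Poisson(1) crossovers per one-Morgan chromosome, uniform positions) to
#' form an F1, then self-fertilizes for `n_selfing_generations` generations
#' (each generation replaces the line's two haplotypes by two independent
#' gametes from itself). Residual heterozygosity halves per selfing
#' generation in expectation, so the default 5 generations emulates
#' F6-like lines.
#'
#' @param founders a `geno_matrix` carrying haplotypes (from
#'   [simulate_founders()] or a previous [simulate_progeny()] call).
#' @param crossing_plan a [pedigree()] whose parents all exist in
#'   `founders`.
#' @param n_selfing_generations selfing generations after the cross.
#' @param seed integer seed.
#' @return a `geno_matrix` for the progeny (haplotypes attached, pedigree
#'   attached as attribute `pedigree`).
#' @export
simulate_progeny <- function(founders, crossing_plan, n_selfing_generations = 5,
                             seed = 1L) {
  if (is.null(founders$haplo))
    stop("founders must carry haplotypes (simulate_founders output)")
  par_ids <- unique(c(crossing_plan$female_parent, crossing_plan$male_parent))
  unknown <- setdiff(par_ids[!is.na(par_ids)], line_ids(founders))
  if (length(unknown))
    stop("missing parent(s) in founders: ", paste(unknown, collapse = ", "))
  if (any(is.na(crossing_plan$female_parent) | is.na(crossing_plan$male_parent)))
    stop("crossing plan must name both parents for every line")
  local_rng(seed)
  chrom <- founders$chrom; pos <- founders$pos
  H1 <- founders$haplo$h1; H2 <- founders$haplo$h2
  n <- nrow(crossing_plan)
  m <- ncol(founders$dosage)
  out1 <- matrix(0L, n, m); out2 <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    f <- crossing_plan$female_parent[i]; mn <- crossing_plan$male_parent[i]
    h1 <- meiosis(H1[f, ], H2[f, ], chrom, pos)
    h2 <- meiosis(H1[mn, ], H2[mn, ], chrom, pos)
    for (g in seq_len(n_selfing_generations)) {
      n1 <- meiosis(h1, h2, chrom, pos)
      n2 <- meiosis(h1, h2, chrom, pos)
      h1 <- n1; h2 <- n2
    }
    out1[i, ] <- h1; out2[i, ] <- h2
  }
  dn <- list(crossing_plan$line_id, marker_ids(founders))
  dimnames(out1) <- dimnames(out2) <- dn
  dosage <- out1 + out2
  g <- geno_matrix(dosage, chrom = chrom, pos = pos,
                   allele_freq = founders$allele_freq)
  g$haplo <- list(h1 = out1, h2 = out2)
  attr(g, "pedigree") <- crossing_plan
  g
}

# build a random crossing plan: n_families crosses among the founders,
# family sizes uniform on progeny_range
make_crossing_plan <- function(founder_ids, n_families, progeny_range,
                               prefix = "L") {
  sizes <- sample(seq(progeny_range[1], progeny_range[2]), n_families,
                  replace = TRUE)
  fem <- character(0); mal <- character(0); cross <- character(0)
  for (f in seq_len(n_families)) {
    pr <- sample(founder_ids, 2)
    fem <- c(fem, rep(pr[1], sizes[f]))
    mal <- c(mal, rep(pr[2], sizes[f]))
    cross <- c(cross, rep(sprintf("%s_X%04d", prefix, f), sizes[f]))
  }
  n <- length(fem)
  pedigree(sprintf("%s%04d", prefix, seq_len(n)), fem, mal, cross)
}

#' Simulate traits and a field trial layout for a set of genotyped lines
#'
#' Marker effects are drawn standard-normal and then linearly transformed
#' so that the realized true breeding values across lines have exactly the
#' genetic covariance `config$V_G`. Lines are randomized into trials of
#' `lines_per_trial` entries plus two checks; every trial is laid out in
#' `n_reps` replicates of `n_blocks` incomplete blocks, and plot values add
#' trial, replicate-within-trial and block-within-replicate random effects
#' plus a residual that is multivariate normal over traits with covariance
#' `V_E` within a plot.
#'
#' @param genotypes a `geno_matrix` (typically from [simulate_progeny()]).
#' @param config a [sim_config()].
#' @param nursery_id label for the nursery.
#' @param ped pedigree for the lines; defaults to the one attached by
#'   [simulate_progeny()].
#' @param check_tbv optional t-vector of check true breeding values (shared
#'   across nurseries when supplied).
#' @param marker_effects optional markers x traits matrix of raw marker
#'   effects (still rescaled to hit `V_G` on the realized genotypes);
#'   drawn standard-normal when `NULL`. [simulate_population()] passes
#'   correlated effects across nurseries through this argument.
#' @param seed integer seed (defaults to `config$seed`).
#' @return a list of class `sim_nursery` with elements `genotypes`,
#'   `pedigree`, `true_breeding_values` (lines x traits), `plot_table`
#'   (long data.frame of plot records), `line_ids`, `check_ids`, `config`.
#' @export
simulate_traits <- function(genotypes, config, nursery_id = "EYT1",
                            ped = attr(genotypes, "pedigree"),
                            check_tbv = NULL, marker_effects = NULL,
                            seed = config$seed) {
  V_G <- config$V_G; V_E <- config$V_E
  t <- length(config$trait_names)
  if (!all(dim(V_G) == t) || !all(dim(V_E) == t))
    stop("V_G / V_E dimensions must match trait count")
  check_psd(V_G, "V_G"); check_psd(V_E, "V_E")
  local_rng(seed)
  X <- genotypes$dosage
  n <- nrow(X)
  # standard-normal marker effects, rescaled to hit V_G on the realized
  # genotypes: the empirical covariance of the TBVs equals V_G exactly
  B <- if (is.null(marker_effects))
    matrix(stats::rnorm(ncol(X) * t), ncol(X), t)
  else as.matrix(marker_effects)
  if (!all(dim(B) == c(ncol(X), t)))
    stop("marker_effects must be markers x traits")
  tbv0 <- scale(X, center = TRUE, scale = FALSE) %*% B
  # earlier-stage selection pulls full sibs toward their family mean
  wfs <- config$within_family_selection
  if (!is.null(wfs) && wfs < 1 && !is.null(ped)) {
    fam <- ped$cross_id[match(rownames(X), ped$line_id)]
    fam[is.na(fam)] <- paste0("solo_", which(is.na(fam)))
    fam_mean <- apply(tbv0, 2, function(v) stats::ave(v, fam))
    tbv0 <- fam_mean + wfs * (tbv0 - fam_mean)
  }
  tbv0 <- scale(tbv0, center = TRUE, scale = FALSE)
  C <- stats::cov(tbv0)
  L <- tryCatch(chol(C), error = function(e)
    stop("degenerate genotypes: cannot scale marker effects"))
  tbv <- tbv0 %*% solve(L) %*% psd_sqrt(V_G)
  dimnames(tbv) <- list(rownames(X), config$trait_names)

  ids <- rownames(X)
  n_trials <- ceiling(n / config$lines_per_trial)
  trial_of <- sample(rep(seq_len(n_trials), length.out = n))
  check_ids <- paste0(nursery_id, "_CHK", 1:2)
  if (is.null(check_tbv))
    check_tbv <- matrix(stats::rnorm(2 * t), 2, t) %*% psd_sqrt(V_G)
  check_tbv <- matrix(check_tbv, 2, t)
  dimnames(check_tbv) <- list(check_ids, config$trait_names)

  plots <- vector("list", n_trials)
  for (j in seq_len(n_trials)) {
    entries <- c(ids[trial_of == j], check_ids)
    ne <- length(entries)
    reps <- lapply(seq_len(config$n_reps), function(k) {
      ord <- sample(entries)
      block <- sort(rep(seq_len(config$n_blocks), length.out = ne))
      data.frame(line_id = ord, trial = j, rep = k, block = block,
                 stringsAsFactors = FALSE)
    })
    plots[[j]] <- do.call(rbind, reps)
  }
  layout <- do.call(rbind, plots)
  layout$is_check <- layout$line_id %in% check_ids

  tbv_all <- rbind(tbv, check_tbv)
  ve <- diag(V_E)
  # per-trait design effects, scaled to each trait's residual variance
  n_tr <- n_trials; n_rp <- n_trials * config$n_reps
  n_bl <- n_rp * config$n_blocks
  recs <- vector("list", t)
  Eps <- mvrnorm_chol(nrow(layout), V_E)
  for (q in seq_len(t)) {
    trait <- config$trait_names[q]
    sd_t <- sqrt(config$variance_trial * ve[q])
    sd_r <- sqrt(config$variance_rep * ve[q])
    sd_b <- sqrt(config$variance_block * ve[q])
    te <- stats::rnorm(n_tr, 0, sd_t)
    re <- stats::rnorm(n_rp, 0, sd_r)
    be <- stats::rnorm(n_bl, 0, sd_b)
    rid <- (layout$trial - 1) * config$n_reps + layout$rep
    bid <- (rid - 1) * config$n_blocks + layout$block
    val <- config$trait_means[[trait]] + tbv_all[layout$line_id, q] +
      te[layout$trial] + re[rid] + be[bid] + Eps[, q]
    date <- if (trait %in% names(config$trait_dates))
      config$trait_dates[[trait]] else NA_character_
    recs[[q]] <- data.frame(
      line_id = layout$line_id, nursery = nursery_id,
      environment = config$environment, trial = layout$trial,
      rep = layout$rep, block = layout$block, trait = trait,
      date = date, value = val, is_check = layout$is_check,
      stringsAsFactors = FALSE
    )
  }
  plot_table <- do.call(rbind, recs)
  rownames(plot_table) <- NULL
  if (is.null(ped))
    ped <- pedigree(ids, rep(NA_character_, n), rep(NA_character_, n))
  out <- list(
    genotypes = genotypes, pedigree = ped, true_breeding_values = tbv,
    plot_table = plot_table, line_ids = ids, check_ids = check_ids,
    config = config, nursery_id = nursery_id
  )
  class(out) <- "sim_nursery"
  out
}

#' @export
print.sim_nursery <- function(x, ...) {
  cat(sprintf("sim_nursery '%s': %d lines, %d plot records, traits: %s\n",
              x$nursery_id, length(x$line_ids), nrow(x$plot_table),
              paste(colnames(x$true_breeding_values), collapse = ", ")))
  invisible(x)
}

psd_sqrt <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(M)) %*% t(e$vectors)
}

mvrnorm_chol <- function(n, Sigma) {
  t <- nrow(Sigma)
  Z <- matrix(stats::rnorm(n * t), n, t)
  Z %*% psd_sqrt(Sigma)
}

#' Simulate a multi-nursery elite-yield-trial population
#'
#' Builds an older, unrecorded breeding pool of `n_grandfounders` inbred
#' lines, derives the `n_founders` parent lines from it by crossing and
#' selfing (so founders are related through cycles the delivered pedigree
#' does not reach), then for each nursery draws an independent set of
#' crosses among the founders, gamete-drops and selfs the progeny, and
#' simulates traits and field trials. Marker effects are shared across
#' nurseries with correlation `rg_across`, emulating genotype-by-year
#' interaction, and check lines share true breeding values across
#' nurseries. Each nursery's delivered genotype panel is the same
#' `prop_scored` subset of the simulated genome.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_population`: `nurseries` (list of
#'   `sim_nursery`), `founders` (the parent pool), `config`.
#' @export
simulate_population <- function(config) {
  local_rng(config$seed)
  seeds <- sample.int(.Machine$integer.max, 4 + 3 * config$n_nurseries)
  grand <- simulate_founders(config$n_grandfounders, config$n_markers,
                             config$n_chromosomes, seed = seeds[1])
  # parent lines: crosses within the old pool, selfed back to homozygosity;
  # their mutual relatedness is real but unrecorded downstream
  set.seed(seeds[2])
  gids <- line_ids(grand)
  fem <- sample(gids, config$n_founders, replace = TRUE)
  mal <- sample(gids, config$n_founders, replace = TRUE)
  same <- which(fem == mal)
  if (length(same))
    mal[same] <- vapply(fem[same], function(p) sample(setdiff(gids, p), 1), "")
  fplan <- pedigree(sprintf("P%03d", seq_len(config$n_founders)), fem, mal)
  founders <- simulate_progeny(grand, fplan, n_selfing_generations = 6,
                               seed = seeds[3])
  attr(founders, "pedigree") <- NULL

  scored <- sort(sample(config$n_markers,
                        max(2, round(config$prop_scored * config$n_markers))))
  t <- length(config$trait_names)
  set.seed(seeds[4])
  check_tbv <- matrix(stats::rnorm(2 * t), 2, t) %*% psd_sqrt(config$V_G)
  B_shared <- matrix(stats::rnorm(config$n_markers * t), config$n_markers, t)
  rho <- config$rg_across

  nurseries <- vector("list", config$n_nurseries)
  for (k in seq_len(config$n_nurseries)) {
    nid <- sprintf("EYT%d", k)
    set.seed(seeds[4 + 3 * k - 2])
    plan <- make_crossing_plan(line_ids(founders), config$n_families,
                               config$progeny_range,
                               prefix = sprintf("N%d_", k))
    B_k <- rho * B_shared +
      sqrt(1 - rho^2) * matrix(stats::rnorm(config$n_markers * t),
                               config$n_markers, t)
    prog <- simulate_progeny(founders, plan, config$n_selfing_generations,
                             seed = seeds[4 + 3 * k - 1])
    nur <- simulate_traits(prog, config, nursery_id = nid,
                           check_tbv = check_tbv, marker_effects = B_k,
                           seed = seeds[4 + 3 * k])
    # traits come from the full genome; the delivered genotypes carry the
    # scored marker panel only
    nur$genotypes <- subset_geno(prog, markers = scored)
    attr(nur$genotypes, "pedigree") <- attr(prog, "pedigree")
    nurseries[[k]] <- nur
  }
  names(nurseries) <- vapply(nurseries, `[[`, "", "nursery_id")
  structure(list(nurseries = nurseries, founders = founders, config = config),
            class = "sim_population")
}
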