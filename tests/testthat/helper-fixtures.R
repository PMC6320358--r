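# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a small single nursery with full family structure, used across modules
small_nursery <- function() {
  cached("small_nursery", function() {
    cfg <- sim_config(n_nurseries = 1, n_families = 40,
                      progeny_range = c(1, 6), n_founders = 30,
                      n_markers = 300, n_chromosomes = 10,
                      lines_per_trial = 28, seed = 42)
    simulate_population(cfg)$nurseries[[1]]
  })
}

# two related nurseries sharing a founder pool, GY only (fast)
twin_nurseries <- function() {
  cached("twin_nurseries", function() {
    cfg <- sim_config(
      n_nurseries = 2, n_families = 48, progeny_range = c(2, 6),
      n_founders = 40, n_markers = 400, n_chromosomes = 10,
      trait_names = c("GY", "GNDVI_1"), trait_means = c(GY = 3.1, GNDVI_1 = 0.6),
      trait_dates = c(GNDVI_1 = "2016-05-02"),
      lines_per_trial = 28, seed = 99)
    simulate_population(cfg)
  })
}

# outbred (heterozygous) parents: one round of random crossing between
# distinct inbred founders, no selfing
outbred_lines <- function(n_lines, n_markers = 300, n_chrom = 10, seed = 5) {
  founders <- simulate_founders(2 * n_lines, n_markers, n_chrom, seed = seed)
  ids <- line_ids(founders)
  plan <- pedigree(sprintf("OB%03d", seq_len(n_lines)),
                   ids[seq(1, 2 * n_lines, 2)], ids[seq(2, 2 * n_lines, 2)])
  simulate_progeny(founders, plan, n_selfing_generations = 0, seed = seed + 1)
}

# line means per trait from a plot table (balanced designs only; used as a
# cheap stand-in for BLUEs where the mixed-model fit is not under test)
line_means <- function(plot_table, trait, exclude_checks = TRUE) {
  d <- plot_table[plot_table$trait == trait, ]
  if (exclude_checks && "is_check" %in% names(d)) d <- d[!d$is_check, ]
  tapply(d$value, d$line_id, mean, na.rm = TRUE)
}

# independent GLS solve for the plot model at given variance components:
# the oracle for Eq.-1 BLUEs
gls_blues_oracle <- function(d, sigma) {
  d$line_id <- factor(d$line_id)
  trialf <- factor(d$trial)
  repf <- factor(paste(d$trial, d$rep))
  blockf <- factor(paste(d$trial, d$rep, d$block))
  n <- nrow(d)
  V <- diag(sigma[["residual"]], n)
  add_term <- function(V, f, s2) {
    if (is.na(s2) || s2 == 0) return(V)
    Z <- stats::model.matrix(~ 0 + f)
    V + s2 * tcrossprod(Z)
  }
  V <- add_term(V, trialf, sigma[["trial"]])
  V <- add_term(V, repf, sigma[["rep"]])
  V <- add_term(V, blockf, sigma[["block"]])
  X <- stats::model.matrix(~ 0 + line_id, data = d)
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% d$value)
  stats::setNames(drop(b), levels(d$line_id))
}

# gene-dropping estimate of the numerator relationship matrix: founders get
# unique allele pairs, alleles drop through the pedigree; A_ij is twice the
# coancestry, A_ii is 1 + P(the two alleles of i are IBD)
gene_drop_a_oracle <- function(ped, n_drops = 50000, seed = 1) {
  set.seed(seed)
  ids <- ped$line_id
  parents <- setdiff(unique(c(ped$female_parent, ped$male_parent)),
                     c(ids, NA))
  all_ids <- c(parents, ids)
  fem <- stats::setNames(rep(NA_character_, length(all_ids)), all_ids)
  mal <- fem
  fem[ped$line_id] <- ped$female_parent
  mal[ped$line_id] <- ped$male_parent
  h1 <- list(); h2 <- list()
  placed <- character(0)
  todo <- all_ids
  next_allele <- 1L
  while (length(todo)) {
    ready <- todo[vapply(todo, function(id) {
      pr <- c(fem[[id]], mal[[id]])
      all(is.na(pr) | pr %in% placed)
    }, TRUE)]
    for (id in ready) {
      gamete <- function(p) {
        if (is.na(p)) {
          a <- rep(next_allele, n_drops)
          next_allele <<- next_allele + 1L
          a
        } else {
          pick <- stats::runif(n_drops) < 0.5
          ifelse(pick, h1[[p]], h2[[p]])
        }
      }
      h1[[id]] <- gamete(fem[[id]])
      h2[[id]] <- gamete(mal[[id]])
    }
    placed <- c(placed, ready)
    todo <- setdiff(todo, ready)
  }
  n <- length(all_ids)
  A <- matrix(0, n, n, dimnames = list(all_ids, all_ids))
  for (i in seq_len(n)) for (j in i:n) {
    ai1 <- h1[[all_ids[i]]]; ai2 <- h2[[all_ids[i]]]
    aj1 <- h1[[all_ids[j]]]; aj2 <- h2[[all_ids[j]]]
    if (i == j) {
      A[i, i] <- 1 + mean(ai1 == ai2)
    } else {
      f <- (mean(ai1 == aj1) + mean(ai1 == aj2) +
              mean(ai2 == aj1) + mean(ai2 == aj2)) / 4
      A[i, j] <- A[j, i] <- 2 * f
    }
  }
  A[ped$line_id, ped$line_id]
}

# random multi-generation pedigree for the gene-dropping comparison
random_pedigree <- function(n_founders = 8, n_gen = 3, per_gen = 10, seed = 1) {
  set.seed(seed)
  ids <- sprintf("P%02d", seq_len(n_founders))
  ped_rows <- data.frame(line_id = ids, female_parent = NA_character_,
                         male_parent = NA_character_,
                         stringsAsFactors = FALSE)
  pool <- ids
  counter <- n_founders
  for (g in seq_len(n_gen)) {
    for (k in seq_len(per_gen)) {
      pr <- sample(pool, 2)
      counter <- counter + 1
      ped_rows <- rbind(ped_rows, data.frame(
        line_id = sprintf("P%02d", counter), female_parent = pr[1],
        male_parent = pr[2], stringsAsFactors = FALSE))
    }
    pool <- utils::tail(ped_rows$line_id, per_gen + n_founders %/% 2)
  }
  pedigree(ped_rows$line_id, ped_rows$female_parent, ped_rows$male_parent)
}
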