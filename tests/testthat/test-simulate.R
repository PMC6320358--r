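test_that("founders are fully homozygous, deterministic, and match their drawn frequencies", {
  g <- simulate_founders(2, 4, 1, seed = 3)
  expect_true(all(g$dosage %in% c(0, 2)))
  expect_identical(dim(g$dosage), c(2L, 4L))

  g2 <- simulate_founders(2, 4, 1, seed = 3)
  expect_identical(g$dosage, g2$dosage)
  g3 <- simulate_founders(2, 4, 1, seed = 4)
  expect_false(identical(g$dosage, g3$dosage))

  # empirical allele frequencies track the generator's drawn frequencies
  # within binomial error (one Bernoulli draw per founder)
  big <- simulate_founders(200, 1000, 5, seed = 11)
  phat <- colMeans(big$dosage) / 2
  se <- sqrt(big$allele_freq * (1 - big$allele_freq) / 200)
  z <- (phat - big$allele_freq) / se
  expect_gt(mean(abs(z) < 3), 0.99)
  expect_lt(max(abs(z)), 5)

  expect_error(simulate_founders(0, 10), "positive")
})

test_that("progeny of identical homozygous parents are identical to them", {
  f <- simulate_founders(2, 50, 2, seed = 1)
  f$dosage[2, ] <- f$dosage[1, ]
  f$haplo$h1[2, ] <- f$haplo$h1[1, ]
  f$haplo$h2[2, ] <- f$haplo$h2[1, ]
  plan <- pedigree("kid", "F001", "F002")
  kid <- simulate_progeny(f, plan, n_selfing_generations = 0, seed = 9)
  expect_equal(unname(kid$dosage[1, ]), unname(f$dosage[1, ]))
})

test_that("unknown parents in a crossing plan are rejected", {
  f <- simulate_founders(3, 20, 1, seed = 1)
  plan <- pedigree("kid", "F001", "NOPE")
  expect_error(simulate_progeny(f, plan), "missing parent")
})

test_that("selfing reduces heterozygosity by half per generation", {
  parents <- outbred_lines(20, n_markers = 400, seed = 21)
  ids <- line_ids(parents)
  plan <- pedigree(sprintf("S%02d", 1:40),
                   rep(ids[1:10], each = 4), rep(ids[11:20], each = 4))
  f1 <- simulate_progeny(parents, plan, n_selfing_generations = 0, seed = 22)
  f6 <- simulate_progeny(parents, plan, n_selfing_generations = 5, seed = 23)
  het <- function(g) mean(g$dosage == 1)
  # F1 heterozygosity is ~0.5 at these frequencies; after 5 selfing
  # generations the expectation is 2^-5 of that
  expect_gt(het(f1), 0.2)
  ratio <- het(f6) / het(f1)
  expect_lt(ratio, 2^-5 + 3 * sqrt(het(f1) / (40 * 400)))
})

test_that("F1 full sibs of outbred, unrelated parents have VanRaden relationship near 0.5", {
  n_fam <- 100
  founders <- simulate_founders(4 * n_fam, 300, 10, seed = 31)
  fids <- line_ids(founders)
  # each family uses its own founder quadruple, so parent pairs are
  # unrelated across and within families
  par_plan <- pedigree(sprintf("PAR%03d", seq_len(2 * n_fam)),
                       fids[seq(1, 4 * n_fam, 2)], fids[seq(2, 4 * n_fam, 2)])
  parents <- simulate_progeny(founders, par_plan, 0, seed = 32)
  pids <- line_ids(parents)
  sib_plan <- pedigree(sprintf("SIB%03d", seq_len(2 * n_fam)),
                       rep(pids[seq(1, 2 * n_fam, 2)], each = 2),
                       rep(pids[seq(2, 2 * n_fam, 2)], each = 2))
  sibs <- simulate_progeny(parents, sib_plan, 0, seed = 33)
  G <- vanraden_g(sibs)
  rel <- vapply(seq_len(n_fam), function(f) G[2 * f - 1, 2 * f], 0)
  expect_lt(abs(mean(rel) - 0.5), 0.05)
  # outbred lines: mean diagonal near 1
  expect_lt(abs(mean(diag(G)) - 1), 0.05)
})

test_that("noise-free simulation returns plot values equal to mean + breeding value", {
  traits <- c("GY", "GNDVI_1")
  V_G <- matrix(c(0.25, 0.05, 0.05, 0.01), 2, dimnames = list(traits, traits))
  cfg <- sim_config(n_nurseries = 1, n_families = 10, progeny_range = c(2, 3),
                    n_founders = 10, n_markers = 100, n_chromosomes = 5,
                    trait_names = traits, trait_means = c(GY = 4, GNDVI_1 = 0.6),
                    trait_dates = c(GNDVI_1 = "2016-05-02"),
                    V_G = V_G, V_E = diag(1e-12, 2),
                    variance_trial = 0, variance_rep = 0, variance_block = 0,
                    lines_per_trial = 10, seed = 8)
  founders <- simulate_founders(10, 100, 5, seed = 1)
  plan <- make_plan <- pedigree(sprintf("L%02d", 1:20),
                                rep(line_ids(founders)[1:5], each = 4),
                                rep(line_ids(founders)[6:10], each = 4))
  prog <- simulate_progeny(founders, plan, 5, seed = 2)
  nur <- simulate_traits(prog, cfg, seed = 3)
  gy <- nur$plot_table[nur$plot_table$trait == "GY" & !nur$plot_table$is_check, ]
  expect_equal(gy$value,
               4 + nur$true_breeding_values[gy$line_id, "GY"],
               tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(heritability(0.25, 0, 3), 1)
})

test_that("realized breeding values hit the configured genetic covariance exactly", {
  nur <- small_nursery()
  expect_equal(unname(cov(nur$true_breeding_values)),
               unname(nur$config$V_G), tolerance = 1e-8)
})

test_that("plot tables are balanced: lines appear n_reps times, checks once per trial and rep", {
  nur <- small_nursery()
  gy <- nur$plot_table[nur$plot_table$trait == "GY", ]
  counts <- table(gy$line_id[!gy$is_check])
  expect_true(all(counts == nur$config$n_reps))
  chk <- gy[gy$is_check, ]
  per_cell <- table(chk$line_id, chk$trial, chk$rep)
  expect_true(all(per_cell == 1))
  # blocks nested in reps nested in trials
  expect_true(all(gy$block >= 1 & gy$block <= nur$config$n_blocks))
})

test_that("the population simulator is deterministic and nurseries share founders", {
  cfg <- sim_config(n_nurseries = 2, n_families = 6, progeny_range = c(1, 3),
                    n_founders = 12, n_markers = 60, n_chromosomes = 3,
                    lines_per_trial = 6, seed = 77)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$nurseries[[1]]$plot_table, p2$nurseries[[1]]$plot_table)
  expect_identical(p1$nurseries[[2]]$genotypes$dosage,
                   p2$nurseries[[2]]$genotypes$dosage)
  par1 <- unique(p1$nurseries[[1]]$pedigree$female_parent)
  expect_true(all(par1 %in% line_ids(p1$founders)))
})

test_that("full sibs share both parents and every plotted line is genotyped", {
  nur <- small_nursery()
  ped <- nur$pedigree
  for (cr in unique(ped$cross_id)) {
    fam <- ped[ped$cross_id == cr, ]
    expect_length(unique(fam$female_parent), 1)
    expect_length(unique(fam$male_parent), 1)
  }
  plotted <- unique(nur$plot_table$line_id[!nur$plot_table$is_check])
  expect_true(all(plotted %in% line_ids(nur$genotypes)))
  expect_true(all(plotted %in% ped$line_id))
})

test_that("invalid covariance matrices are rejected", {
  expect_error(
    sim_config(trait_names = c("a", "b"), trait_means = c(a = 0, b = 0),
               V_G = matrix(c(1, 2, 2, 1), 2), V_E = diag(2)),
    "positive semidefinite")
  expect_error(
    sim_config(trait_names = c("a", "b"), trait_means = c(a = 0, b = 0),
               V_G = matrix(c(1, 0, 0.5, 1), 2), V_E = diag(2)),
    "symmetric")
})
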