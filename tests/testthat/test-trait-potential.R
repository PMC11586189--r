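toy_traits <- function() {
  # Sphingomonas: 4 genomes, alkB in 1, nahAc in none (the zero-coefficient
  # naphthalene-dioxygenase scenario); Massilia: 2 genomes, both alkB+.
  pres <- rbind(
    g1 = c(alkB = 1, nahAc = 0), g2 = c(alkB = 0, nahAc = 0),
    g3 = c(alkB = 0, nahAc = 0), g4 = c(alkB = 0, nahAc = 0),
    g5 = c(alkB = 1, nahAc = 1), g6 = c(alkB = 1, nahAc = 0),
    g7 = c(alkB = 1, nahAc = 1))
  genus <- c(g1 = "Sphingomonas", g2 = "Sphingomonas", g3 = "Sphingomonas",
             g4 = "Sphingomonas", g5 = "Massilia", g6 = "Massilia",
             g7 = "unclassified")
  genome_trait_table(pres, genus)
}

test_that("coefficients are genome fractions per genus", {
  ct <- build_coefficients(toy_traits(),
                           list(marker_set("alkB", "alkB"),
                                marker_set("naphthalene_dioxygenase", "nahAc")))
  expect_equal(ct$coeff["Sphingomonas", "alkB"], 0.25)
  expect_equal(ct$coeff["Massilia", "alkB"], 1.0)
  # a genus with no genome carrying a naphthalene dioxygenase scores 0
  expect_equal(ct$coeff["Sphingomonas", "naphthalene_dioxygenase"], 0)
  expect_equal(unname(ct$n_genomes[c("Massilia", "Sphingomonas")]), c(2L, 4L))
  # unclassified genomes are excluded entirely
  expect_false("unclassified" %in% rownames(ct$coeff))
})

test_that("combine rules any/all act over multi-HMM marker sets", {
  pres <- rbind(a = c(h1 = 1, h2 = 0), b = c(h1 = 1, h2 = 1),
                c = c(h1 = 0, h2 = 0))
  g <- genome_trait_table(pres, c(a = "X", b = "X", c = "X"))
  any_ct <- build_coefficients(g, list(marker_set("m", c("h1", "h2"), "any")))
  all_ct <- build_coefficients(g, list(marker_set("m", c("h1", "h2"), "all")))
  expect_equal(any_ct$coeff["X", "m"], 2 / 3)
  expect_equal(all_ct$coeff["X", "m"], 1 / 3)
  expect_error(build_coefficients(g, list(marker_set("m", "absent"))),
               "unknown column")
})

test_that("potential is the coefficient-weighted relative abundance", {
  ct <- structure(list(coeff = matrix(c(0.2, 0.6), 2, 1,
                                      dimnames = list(c("A", "B"), "m")),
                       n_genomes = c(A = 5L, B = 5L)),
                  class = "trait_coefficients")
  t <- abundance_table(matrix(c(0.5, 0.5), 1, 2,
                              dimnames = list("s1", c("A", "B"))),
                       mode = "relative")
  p <- estimate_potential(t, ct)
  expect_equal(unname(p$potential["s1", "m"]), 40)
  expect_equal(unname(p$unscored_fraction["s1"]), 0)

  # all coefficients one, all taxa scored: potential 100%
  ct1 <- ct; ct1$coeff[] <- 1
  expect_equal(unname(estimate_potential(t, ct1)$potential[1, 1]), 100)

  # unknown genus contributes zero and is tallied as unscored
  t2 <- abundance_table(matrix(c(0.9, 0.1), 1, 2,
                               dimnames = list("s1", c("A", "Mystery"))),
                        mode = "relative")
  ct2 <- ct; ct2$coeff["A", "m"] <- 0.1
  p2 <- estimate_potential(t2, ct2)
  expect_equal(unname(p2$potential[1, 1]), 9)
  expect_equal(unname(p2$unscored_fraction["s1"]), 10)

  # counts-mode input is rejected with a pointer to to_relative
  tc <- abundance_table(matrix(c(5, 5), 1, 2,
                               dimnames = list("s1", c("A", "B"))),
                        mode = "counts")
  expect_error(estimate_potential(tc, ct), "to_relative")
})

test_that("potential matches the dot-product oracle on random tables", {
  genera <- sprintf("Genus%02d", 1:50)
  for (rep in 1:5) {
    t <- random_rel_table(20, genera, seed = 100 + rep)
    set.seed(200 + rep)
    known <- sample(genera, 35)
    coeff <- matrix(stats::runif(35 * 3), 35, 3,
                    dimnames = list(known, c("m1", "m2", "m3")))
    ct <- structure(list(coeff = coeff,
                         n_genomes = stats::setNames(rep(4L, 35), known)),
                    class = "trait_coefficients")
    p <- estimate_potential(t, ct)
    expect_equal(p$potential, oracle_potential(t$values, coeff),
                 tolerance = 1e-12)
  }
})

test_that("potential is scale-invariant and monotone in coefficients", {
  m <- matrix(c(3, 7, 10, 1, 5, 4), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  ct <- structure(list(coeff = matrix(c(0.3, 0.5, 0.9), 3, 1,
                                      dimnames = list(c("A", "B", "C"), "m")),
                       n_genomes = c(A = 1L, B = 1L, C = 1L)),
                  class = "trait_coefficients")
  base <- estimate_potential(to_relative(abundance_table(m, "counts")), ct)
  scaled <- estimate_potential(
    to_relative(abundance_table(m * 17, "counts")), ct)
  expect_equal(base$potential, scaled$potential, tolerance = 1e-12)

  ct_up <- ct; ct_up$coeff["B", "m"] <- 0.8
  up <- estimate_potential(to_relative(abundance_table(m, "counts")), ct_up)
  expect_true(all(up$potential >= base$potential))
})

test_that("potential never exceeds the scored fraction of the community", {
  genera <- sprintf("G%02d", 1:30)
  for (rep in 1:10) {
    t <- random_rel_table(8, genera, seed = 300 + rep)
    set.seed(400 + rep)
    known <- sample(genera, 18)
    ct <- structure(list(coeff = matrix(stats::runif(18), 18, 1,
                                        dimnames = list(known, "m")),
                         n_genomes = stats::setNames(rep(2L, 18), known)),
                    class = "trait_coefficients")
    p <- estimate_potential(t, ct)
    expect_true(all(p$potential <= 100 - p$unscored_fraction + 1e-9))
    expect_true(all(p$potential >= 0 & p$potential <= 100))
    expect_true(all(p$unscored_fraction >= 0 & p$unscored_fraction <= 100))
  }
})

test_that("genus matching trims whitespace and folds case", {
  t <- abundance_table(matrix(c(0.6, 0.4), 1, 2,
                              dimnames = list("s1", c("sphingomonas", "B"))),
                       mode = "relative")
  ct <- structure(list(coeff = matrix(c(0.5, 1), 2, 1,
                                      dimnames = list(c(" Sphingomonas ", "b"),
                                                      "m")),
                       n_genomes = c(2L, 2L)),
                  class = "trait_coefficients")
  p <- estimate_potential(t, ct)
  expect_equal(unname(p$potential[1, 1]), 100 * (0.6 * 0.5 + 0.4 * 1))
})

test_that("grouped potential reports match per-group recomputation", {
  pot <- matrix(c(2, 6, 4, 10), 4, 1,
                dimnames = list(sprintf("s%d", 1:4), "m"))
  meta <- data.frame(season = c("spring", "spring", "autumn", "autumn"),
                     row.names = sprintf("s%d", 1:4))
  p <- structure(list(sample_ids = rownames(pot), markers = "m",
                      potential = pot,
                      unscored_fraction = stats::setNames(rep(0, 4),
                                                          rownames(pot)),
                      sample_meta = meta),
                 class = "potential_profile")
  rep_all <- potential_report(p)
  expect_equal(rep_all$min, 2); expect_equal(rep_all$max, 10)
  expect_equal(rep_all$mean, 5.5)

  by_season <- potential_report(p, "season")
  spring <- by_season[by_season$group == "spring", ]
  expect_equal(c(spring$min, spring$max, spring$mean), c(2, 6, 4))
  autumn <- by_season[by_season$group == "autumn", ]
  expect_equal(c(autumn$min, autumn$max, autumn$mean), c(4, 10, 7))

  # single sample: min = max = mean
  p1 <- p; p1$potential <- pot[1, , drop = FALSE]
  p1$unscored_fraction <- p$unscored_fraction[1]
  r1 <- potential_report(p1)
  expect_equal(r1$min, r1$max)
  expect_equal(r1$min, r1$mean)

  expect_error(potential_report(p, "no_such_key"), "unknown")
})

test_that("coefficient tables round-trip through TSV", {
  ct <- build_coefficients(toy_traits(),
                           list(marker_set("alkB", "alkB"),
                                marker_set("nd", "nahAc")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_coefficients(ct, f)
  ct2 <- read_coefficients(f)
  expect_equal(ct2$coeff, ct$coeff, tolerance = 1e-12)
  expect_equal(ct2$n_genomes, ct$n_genomes)
})
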