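demo_asv_table <- function() {
  lins <- c(
    asv1 = "Bacteria;Pseudomonadota;Alpha;Sphingomonadales;Sphingomonadaceae;Sphingomonas",
    asv2 = "Bacteria;Bacillota;Bacilli;Bacillales;Bacillaceae;Massilia",
    asv3 = "Bacteria;Bacillota;Bacilli;Bacillales;Bacillaceae;Massilia",
    asv4 = "Bacteria;Bacillota;Bacilli;Bacillales;Bacillaceae",
    asv5 = "Eukarya;Ascomycota",
    asv6 = "Bacteria;Cyanobacteria;Oxyphotobacteria;Chloroplast",
    asv7 = "Archaea;Euryarchaeota",
    asv8 = "")
  m <- matrix(c(10, 20, 30, 5, 7, 100, 3, 2,
                40, 10, 10, 15, 1, 50, 2, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("sA", "sB"), names(lins)))
  abundance_table(m, mode = "counts",
                  lineages = stats::setNames(lapply(lins, parse_lineage),
                                             names(lins)))
}

test_that("ASV filtering removes foreign domains, organelles and unclassified", {
  t <- demo_asv_table()
  f <- filter_asvs(t, "Bacteria")
  expect_setequal(taxon_ids(f), c("asv1", "asv2", "asv3", "asv4"))
  audit <- attr(f, "audit")
  expect_equal(audit$n_input, 8L)
  expect_equal(audit$n_retained, 4L)
  expect_equal(audit$n_removed_organelle, 1L)   # Chloroplast lineage
  expect_equal(audit$n_removed_domain, 2L)      # Eukarya, Archaea
  expect_equal(audit$n_removed_unclassified, 1L)
  # removal accounting is exact
  expect_equal(audit$n_retained + audit$n_removed_domain +
                 audit$n_removed_unclassified + audit$n_removed_organelle,
               audit$n_input)
})

test_that("relative tables are renormalized to retained taxa after filtering", {
  t <- to_relative(demo_asv_table())
  f <- filter_asvs(t, "Bacteria")
  expect_equal(unname(rowSums(f$values)), c(1, 1), tolerance = 1e-12)
})

test_that("genus collapse merges lineage prefixes and conserves totals", {
  t <- filter_asvs(demo_asv_table(), "Bacteria")
  g <- collapse_to_rank(t, "genus")
  expect_setequal(taxon_ids(g),
                  c("Sphingomonas", "Massilia", "unclassified_Bacillaceae"))
  # two Massilia ASVs merged by sum
  expect_equal(unname(g$values[, "Massilia"]),
               unname(t$values[, "asv2"] + t$values[, "asv3"]))
  # family-only ASV binned by its deepest classified name
  expect_equal(unname(g$values[, "unclassified_Bacillaceae"]),
               unname(t$values[, "asv4"]))
  expect_identical(rowSums(g$values), rowSums(t$values))

  expect_error(collapse_to_rank(t, "kingdom"), "unknown rank")
})

test_that("relative genus rows merge exactly (0.2 + 0.3 = 0.5)", {
  lins <- c(a1 = "Bacteria;P;C;O;F;Massilia",
            a2 = "Bacteria;P;C;O;F;Massilia",
            a3 = "Bacteria;P;C;O;F;Other")
  t <- abundance_table(matrix(c(0.2, 0.3, 0.5), 1, 3,
                              dimnames = list("s1", names(lins))),
                       mode = "relative", lineages = unname(lins))
  g <- collapse_to_rank(t, "genus")
  expect_equal(unname(g$values[1, "Massilia"]), 0.5)
})

test_that("minor-taxon aggregation respects the reaching-X% boundary", {
  m <- rbind(s1 = c(peak19 = 0.019, boundary = 0.020, big = 0.961),
             s2 = c(peak19 = 0.010, boundary = 0.005, big = 0.985))
  t <- abundance_table(m, mode = "relative")
  agg <- aggregate_minor(t, 2)
  # "not reaching 2%": a 1.9% peak is merged, an exact 2.0% peak retained
  expect_true("boundary" %in% taxon_ids(agg))
  expect_false("peak19" %in% taxon_ids(agg))
  expect_true("Other genera" %in% taxon_ids(agg))
  expect_equal(unname(agg$values[, "Other genera"]), unname(m[, "peak19"]))
  expect_equal(rowSums(agg$values), rowSums(m), tolerance = 1e-12)

  # idempotence at the same threshold
  agg2 <- aggregate_minor(agg, 2)
  expect_identical(agg2$values, agg$values)

  expect_error(aggregate_minor(t, 0), "between 0 and 100")
  expect_error(aggregate_minor(t, 100), "between 0 and 100")
  tc <- abundance_table(matrix(c(5, 5), 1, 2,
                               dimnames = list("s", c("a", "b"))), "counts")
  expect_error(aggregate_minor(tc, 2), "relative")
})

test_that("Hellinger transform takes square roots and normalizes rows", {
  t <- abundance_table(matrix(c(0.25, 0.25, 0.5), 1, 3,
                              dimnames = list("s1", c("a", "b", "c"))),
                       mode = "relative")
  h <- hellinger(t)
  expect_equal(unname(h[1, ]), c(0.5, 0.5, sqrt(0.5)), tolerance = 1e-12)

  # zero abundances stay zero; counts are converted internally
  tc <- abundance_table(matrix(c(1, 0, 3, 2, 2, 0), 2, 3, byrow = TRUE,
                               dimnames = list(c("s1", "s2"),
                                               c("a", "b", "c"))), "counts")
  hc <- hellinger(tc)
  expect_equal(hc[1, "b"][[1]], 0)
  # every transformed row has unit Euclidean norm
  expect_equal(unname(sqrt(rowSums(hc^2))), c(1, 1), tolerance = 1e-12)
})

test_that("PCA matches the eigendecomposition oracle with fixed signs", {
  set.seed(31)
  for (rep in 1:5) {
    m <- matrix(stats::rnorm(4 * 3), 4, 3,
                dimnames = list(paste0("s", 1:4), paste0("v", 1:3)))
    ord <- pca_ordination(m, n_axes = 3)
    orc <- oracle_pca(m)
    for (a in 1:3) {
      # agreement up to the per-axis sign choice
      same <- max(abs(ord$sample_scores[, a] - orc$scores[, a]))
      flip <- max(abs(ord$sample_scores[, a] + orc$scores[, a]))
      expect_lt(min(same, flip), 1e-10)
    }
    expect_equal(ord$all_variance_fractions,
                 orc$values / sum(orc$values), tolerance = 1e-10)
    # full-rank input: fractions over all axes sum to one, non-increasing
    expect_equal(sum(ord$all_variance_fractions), 1, tolerance = 1e-9)
    expect_true(all(diff(ord$axis_variance_fraction) <= 1e-12))
    # sign convention: the dominant loading of each axis is positive
    for (a in 1:3)
      expect_gte(ord$taxon_loadings[which.max(abs(ord$taxon_loadings[, a])), a], 0)
  }
})

test_that("degenerate PCA input yields zero variance fractions and a flag", {
  m <- matrix(1, 4, 3, dimnames = list(paste0("s", 1:4), paste0("v", 1:3)))
  ord <- pca_ordination(m, n_axes = 2)
  expect_equal(ord$axis_variance_fraction, c(0, 0))
  expect_true(ord$audit$degenerate)
  expect_error(pca_ordination(m[1, , drop = FALSE]), "at least 2 samples")
  expect_error(pca_ordination(m, n_axes = 5), "must not exceed")
})

test_that("Hellinger PCA agrees with classical MDS on Hellinger distances", {
  set.seed(41)
  m <- matrix(stats::rexp(6 * 8), 6, 8,
              dimnames = list(paste0("s", 1:6), paste0("t", 1:8)))
  t <- to_relative(abundance_table(m, "counts"))
  h <- hellinger(t)
  ord <- pca_ordination(h, n_axes = 2)
  mds <- stats::cmdscale(stats::dist(h), k = 2)
  for (a in 1:2) {
    same <- max(abs(ord$sample_scores[, a] - mds[, a]))
    flip <- max(abs(ord$sample_scores[, a] + mds[, a]))
    expect_lt(min(same, flip), 1e-8)
  }
})

test_that("PCA axis variances agree with vegan's rda on Hellinger data", {
  skip_if_not_installed("vegan")
  set.seed(51)
  m <- matrix(stats::rexp(8 * 10), 8, 10,
              dimnames = list(paste0("s", 1:8), paste0("t", 1:10)))
  h <- hellinger(to_relative(abundance_table(m, "counts")))
  ord <- pca_ordination(h, n_axes = 2)
  rd <- vegan::rda(h)
  expect_equal(ord$axis_variance_fraction,
               unname(rd$CA$eig[1:2] / sum(rd$CA$eig)), tolerance = 1e-10)
})

test_that("filter -> collapse -> aggregate conserves totals on random tables", {
  set.seed(61)
  for (rep in 1:10) {
    n_taxa <- 30
    fams <- sprintf("Fam%02d", sample.int(5, n_taxa, replace = TRUE))
    gens <- sprintf("Gen%02d", sample.int(12, n_taxa, replace = TRUE))
    unclass <- stats::runif(n_taxa) < 0.2
    lins <- ifelse(unclass,
                   sprintf("Bacteria;P;C;O;%s", fams),
                   sprintf("Bacteria;P;C;O;%s;%s", fams, gens))
    m <- matrix(stats::rpois(5 * n_taxa, 40), 5, n_taxa,
                dimnames = list(sprintf("s%d", 1:5),
                                sprintf("asv%02d", 1:n_taxa)))
    t <- abundance_table(m, "counts", lineages = lins)
    f <- filter_asvs(t, "Bacteria")
    g <- collapse_to_rank(f, "genus")
    expect_identical(rowSums(g$values), rowSums(f$values))
    r <- to_relative(g)
    agg <- aggregate_minor(r, 5)
    expect_equal(rowSums(agg$values), rowSums(r$values), tolerance = 1e-12)
  }
})
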