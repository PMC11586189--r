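# Seeded synthetic-data generators. Each returns its output paired with a
# SyntheticTruth record (seed, kind, full parameterization, realized values)
# so recovery tests can compare estimates against known truth. One global
# seed fans out to per-generator substreams by fixed offsets, so adding a
# generator never perturbs existing streams.

SUBSTREAM_OFFSETS <- c(community = 101L, traits = 211L, decay = 307L,
                       flask = 401L)

substream_seed <- function(seed, component) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  (as.integer(seed) + SUBSTREAM_OFFSETS[[component]]) %% 2147483647L
}

synthetic_truth <- function(seed, kind, params) {
  structure(list(seed = seed, kind = kind, params = params),
            class = "synthetic_truth")
}

# Dirichlet sampling via normalized gamma draws.
rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1  # degenerate guard at tiny alpha
  x / sum(x)
}

softmax <- function(eta) {
  e <- exp(eta - max(eta))
  e / sum(e)
}

#' Generate a synthetic compositional genus table
#'
#' Emulates heterogeneous genus-level amplicon communities with categorical
#' sample structure (e.g. season, host tree species). Each sample's
#' composition is Dirichlet-distributed: a shared log-scale base profile is
#' shifted by per-level effect vectors for each design factor, passed
#' through a softmax, and scaled by the Dirichlet `concentration` (small
#' values give the strong sample-to-sample heterogeneity typical of
#' tree-associated substrates). A configurable fraction of taxa is left
#' unclassified at genus (binned as `unclassified_<family>`).
#'
#' @param n_samples number of samples (>= 2).
#' @param n_genera number of taxa (>= 2).
#' @param concentration Dirichlet concentration (sum of alphas), > 0;
#'   default 5.
#' @param meta_design named list of factor levels, e.g.
#'   `list(season = c("spring", "autumn"))`; levels are assigned to samples
#'   in a balanced full-factorial cycle.
#' @param effect_size sd of the per-level log-abundance shifts; 0 means no
#'   group structure.
#' @param unclassified_fraction fraction of taxa unclassified at genus.
#' @param seed integer seed.
#' @return list with `table` (relative-mode [abundance_table()] with
#'   lineages and sample metadata) and `truth` (`synthetic_truth` recording
#'   base profile, shifts, per-sample alphas and assignments).
#' @export
gen_community <- function(n_samples, n_genera, concentration = 5,
                          meta_design = list(season = c("spring", "autumn")),
                          effect_size = 1, unclassified_fraction = 0.1,
                          seed = 1) {
  stopifnot(n_samples >= 2L, n_genera >= 2L)
  if (!is.numeric(concentration) || concentration <= 0)
    stop("concentration must be positive")
  stopifnot(unclassified_fraction >= 0, unclassified_fraction <= 1)
  set.seed(substream_seed(seed, "community"))

  design <- expand.grid(meta_design, stringsAsFactors = FALSE)
  assign <- design[((seq_len(n_samples) - 1L) %% nrow(design)) + 1L, ,
                   drop = FALSE]
  rownames(assign) <- sprintf("S%03d", seq_len(n_samples))

  eta0 <- stats::rnorm(n_genera, 0, 1.5)
  shifts <- lapply(meta_design, function(levels) {
    s <- lapply(levels, function(l) stats::rnorm(n_genera, 0, effect_size))
    names(s) <- levels
    s
  })

  alpha <- matrix(NA_real_, n_samples, n_genera)
  vals <- matrix(NA_real_, n_samples, n_genera)
  for (i in seq_len(n_samples)) {
    eta <- eta0
    for (f in names(meta_design))
      eta <- eta + shifts[[f]][[assign[i, f]]]
    alpha[i, ] <- concentration * softmax(eta)
    vals[i, ] <- rdirichlet1(alpha[i, ])
  }

  families <- sprintf("Family%02d", ((seq_len(n_genera) - 1L) %% 8L) + 1L)
  n_unclass <- round(unclassified_fraction * n_genera)
  unclass <- seq_len(n_genera) %in% sample.int(n_genera, n_unclass)
  genus_names <- sprintf("Genus%03d", seq_len(n_genera))
  taxon_ids <- ifelse(unclass, paste0("unclassified_", families), genus_names)
  taxon_ids <- make.unique(taxon_ids, sep = "_")
  lineages <- lapply(seq_len(n_genera), function(j) {
    l <- stats::setNames(c("Bacteria", "PhylumA", "ClassA", "OrderA",
                           families[j],
                           if (unclass[j]) NA_character_ else genus_names[j]),
                         RANKS)
    l
  })
  names(lineages) <- taxon_ids
  rownames(vals) <- rownames(assign)
  colnames(vals) <- taxon_ids
  vals <- vals / rowSums(vals)

  table <- abundance_table(vals, mode = "relative", lineages = lineages,
                           sample_meta = assign)
  truth <- synthetic_truth(seed, "community",
                           list(n_samples = n_samples, n_genera = n_genera,
                                concentration = concentration,
                                effect_size = effect_size,
                                unclassified_fraction = unclassified_fraction,
                                base_log_profile = eta0, shifts = shifts,
                                alpha = alpha, assignment = assign,
                                unclassified = stats::setNames(unclass,
                                                               taxon_ids)))
  list(table = table, truth = truth)
}

#' Generate a synthetic genome-trait table
#'
#' Emulates the result of searching marker-gene HMMs against a genome
#' database: for each genus, each genome's marker presence is an independent
#' Bernoulli draw at that genus's target prevalence. The truth record keeps
#' both target prevalences and the exactly realized per-genus fractions, so
#' coefficient estimation can be checked by equality.
#'
#' @param genus_prevalences named list: genus -> named numeric vector of
#'   marker prevalences in \[0, 1\].
#' @param genomes_per_genus genomes drawn per genus (>= 1); scalar or named
#'   vector.
#' @param seed integer seed.
#' @return list with `traits` (a [genome_trait_table()]) and `truth`
#'   (records target and realized prevalences).
#' @export
gen_genome_traits <- function(genus_prevalences, genomes_per_genus, seed = 1) {
  stopifnot(is.list(genus_prevalences), length(genus_prevalences) >= 1L)
  markers <- unique(unlist(lapply(genus_prevalences, names)))
  if (is.null(markers)) stop("prevalences must be named by marker")
  prev <- lapply(genus_prevalences, function(p) {
    if (any(p < 0 | p > 1)) stop("prevalences must lie in [0, 1]")
    full <- stats::setNames(rep(0, length(markers)), markers)
    full[names(p)] <- p
    full
  })
  genera <- names(genus_prevalences)
  npg <- if (length(genomes_per_genus) == 1L)
    stats::setNames(rep(genomes_per_genus, length(genera)), genera)
  else genomes_per_genus[genera]
  if (any(npg < 1L)) stop("genomes_per_genus must be >= 1")

  set.seed(substream_seed(seed, "traits"))
  rows <- list(); ids <- character(0); genus_of <- character(0)
  realized <- matrix(NA_real_, length(genera), length(markers),
                     dimnames = list(genera, markers))
  for (gn in genera) {
    pres <- vapply(markers, function(m)
      stats::rbinom(npg[[gn]], 1L, prev[[gn]][[m]]) == 1L,
      logical(npg[[gn]]))
    pres <- matrix(pres, nrow = npg[[gn]],
                   dimnames = list(NULL, markers))
    realized[gn, ] <- colMeans(pres)
    gid <- sprintf("G_%s_%03d", gn, seq_len(npg[[gn]]))
    rownames(pres) <- gid
    rows[[gn]] <- pres
    ids <- c(ids, gid)
    genus_of <- c(genus_of, stats::setNames(rep(gn, npg[[gn]]), gid))
  }
  presence <- do.call(rbind, rows)
  traits <- genome_trait_table(presence, genus_of)
  truth <- synthetic_truth(seed, "genome_traits",
                           list(target_prevalences = prev,
                                realized_prevalences = realized,
                                genomes_per_genus = npg))
  list(traits = traits, truth = truth)
}

#' Generate a synthetic first-order decay experiment
#'
#' Residual percentages follow `100 * 2^(-t / half_life) * exp(eps)` with
#' `eps ~ Normal(0, noise_sd_log^2)` — multiplicative log-normal noise, which
#' keeps concentrations positive and matches the log-scale model fitted
#' downstream. Defaults mirror a greenhouse leaf-degradation regime:
#' an inoculated condition with a 6-day half-life and an untreated one with
#' 24 days, sampling at 0, 2, 4, 8 and 16 days, two replicate plants, and
#' log-scale noise sd 0.05.
#'
#' @param conditions named list: condition -> list(half_life, noise_sd_log).
#' @param times sampling times (must include 0).
#' @param replicates replicates per condition and time.
#' @param noise_at_t0 if `FALSE`, t = 0 records are exactly 100%.
#' @param time_unit declared time unit.
#' @param seed integer seed.
#' @return list with `experiment` (a [decay_experiment()] in percent units)
#'   and `truth` (half-lives and the implied rates `k = log(2) / half_life`).
#' @export
gen_decay <- function(conditions = list(
                        inoculated = list(half_life = 6, noise_sd_log = 0.05),
                        untreated = list(half_life = 24, noise_sd_log = 0.05)),
                      times = c(0, 2, 4, 8, 16), replicates = 2L,
                      noise_at_t0 = TRUE, time_unit = "days", seed = 1) {
  stopifnot(0 %in% times, replicates >= 1L)
  for (cc in conditions)
    if (cc$half_life <= 0) stop("half_life must be positive")
  set.seed(substream_seed(seed, "decay"))
  recs <- list()
  for (cond in names(conditions)) {
    hl <- conditions[[cond]]$half_life
    sd <- conditions[[cond]]$noise_sd_log
    for (tt in times) {
      eps <- stats::rnorm(replicates, 0, sd)
      if (tt == 0 && !noise_at_t0) eps <- rep(0, replicates)
      recs[[length(recs) + 1L]] <- data.frame(
        time = tt, condition = cond,
        replicate = sprintf("%s_r%d", cond, seq_len(replicates)),
        concentration = 100 * 2^(-tt / hl) * exp(eps))
    }
  }
  recs <- do.call(rbind, recs)
  experiment <- decay_experiment(recs$time, recs$condition, recs$replicate,
                                 recs$concentration, time_unit = time_unit,
                                 conc_unit = "percent")
  truth <- synthetic_truth(seed, "decay",
                           list(conditions = conditions,
                                rates = vapply(conditions, function(cc)
                                  log(2) / cc$half_life, numeric(1L)),
                                times = times, replicates = replicates,
                                noise_at_t0 = noise_at_t0))
  list(experiment = experiment, truth = truth)
}

#' Generate a synthetic flask removal experiment
#'
#' Emulates PAH-degradation flask assays with heat-killed controls: control
#' concentrations are the nominal amount reduced by the abiotic loss with
#' multiplicative log-normal noise; each strain's sample concentrations are
#' the (noise-free) control level reduced by the strain's true removal, with
#' the same noise model. Defaults reflect a volatile-compound regime:
#' 35% abiotic control loss and triplicate flasks.
#'
#' @param removal_true named numeric vector: strain -> true removal percent
#'   in \[0, 100\].
#' @param control_loss_pct abiotic loss in the heat-killed controls, percent.
#' @param replicates flasks per strain and for the controls (>= 1).
#' @param noise_sd log-scale noise sd.
#' @param nominal nominal spiked concentration (arbitrary unit).
#' @param seed integer seed.
#' @return list with `samples` (named list of concentration vectors per
#'   strain), `controls` (concentration vector) and `truth`.
#' @export
gen_flask <- function(removal_true, control_loss_pct = 35, replicates = 3L,
                      noise_sd = 0.05, nominal = 10, seed = 1) {
  stopifnot(all(removal_true >= 0), all(removal_true <= 100),
            replicates >= 1L, !is.null(names(removal_true)))
  set.seed(substream_seed(seed, "flask"))
  control_level <- nominal * (1 - control_loss_pct / 100)
  controls <- control_level * exp(stats::rnorm(replicates, 0, noise_sd))
  samples <- lapply(removal_true, function(rm)
    control_level * (1 - rm / 100) * exp(stats::rnorm(replicates, 0, noise_sd)))
  truth <- synthetic_truth(seed, "flask",
                           list(removal_true = removal_true,
                                control_loss_pct = control_loss_pct,
                                replicates = replicates, noise_sd = noise_sd,
                                nominal = nominal,
                                control_level = control_level))
  list(samples = samples, controls = controls, truth = truth)
}
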