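#' Configuration for the synthetic IL-population generator
#'
#' Builds the parameter set describing a simulated introgression-line (IL)
#' field experiment: a control line plus `n_lines` ILs, each grown in
#' `n_plots` replicate field plots under two maternal irrigation regimes
#' (fresh water `SDF`, saline water `SDS`). Seed metabolite levels are drawn
#' on the log scale from a two-set correlation structure: metabolites belong
#' to one of two latent sets (S1/S2) with correlation `rho_within` inside a
#' set and `rho_between` across sets. Germination is driven by the balance
#' score of each plot (mean S2 latent minus mean S1 latent), so that plots
#' whose profile tilts towards S1 germinate late and poorly.
#'
#' A fraction `failure_frac` of plots additionally receives a strong
#' metabolic failure shift (+`failure_shift` log units on S1 metabolites,
#' -`failure_shift` on S2), emulating the non-germinating seed batches seen
#' in field material (e.g. after post-harvest stress): their balance score
#' collapses and their final germination percent is at or near zero.
#'
#' @param n_lines number of ILs (the control line is added on top).
#' @param control_line name of the recurrent control genotype.
#' @param n_plots replicate field plots per line and treatment.
#' @param n_metabolites number of annotated metabolites.
#' @param set_sizes integer pair partitioning metabolites into sets S1/S2.
#' @param rho_within,rho_between target latent correlations (within > 0 >
#'   between).
#' @param n_blocks number of GC-MS run blocks; plots are assigned to blocks
#'   round-robin within a season.
#' @param block_sigma log-scale SD of the per-metabolite, per-block
#'   multiplicative run effect.
#' @param noise_sigma residual log-scale SD of a metabolite within a plot.
#' @param qtl_lines_frac fraction of ILs carrying metabolite QTLs.
#' @param qtl_metabolites_per_line number of affected metabolites per QTL
#'   line.
#' @param qtl_effect absolute log-scale additive QTL effect (sign is drawn
#'   per QTL).
#' @param treatment_effect log-scale shift applied under SDS to
#'   `n_treatment_metabolites` metabolites in `n_treatment_lines` lines
#'   (sparse, line-specific salinity responses).
#' @param n_treatment_metabolites,n_treatment_lines see `treatment_effect`.
#' @param n_weight_qtl_lines number of ILs with seed-weight QTLs.
#' @param weight_qtl_effect absolute seed-weight QTL effect (mg).
#' @param base_seed_weight population mean single-seed weight (mg).
#' @param weight_line_sd,weight_noise_sd between-line and residual SD of
#'   seed weight (mg).
#' @param abortion_base baseline per-seed abortion probability.
#' @param abortion_salinity_effect additive increase of the abortion
#'   probability under SDS.
#' @param seeds_per_fruit mean total (mature + aborted) seeds per fruit.
#' @param failure_frac fraction of plots with the metabolic failure shift.
#' @param failure_shift size of the failure shift (log units).
#' @param germ_beta0 intercept of the germination logit.
#' @param germ_beta slope of the germination log-odds on the balance score.
#' @param t50_mu0 baseline mean germination day.
#' @param t50_gamma decrease of the mean germination day per unit balance
#'   score.
#' @param t50_size negative-binomial size (dispersion) of the day
#'   distribution.
#' @param max_day last scored germination day.
#' @param seeds_per_plate,n_plates germination assay design.
#' @param seed_mass_mean,seed_mass_sd seed mass extracted per sample (mg).
#' @param load_sigma log-scale SD of the per-sample injection load factor.
#' @param missing_frac fraction of peak entries missing completely at
#'   random.
#' @param season season label attached to all samples.
#' @param rng_seed master seed; every component derives a named substream
#'   from it.
#' @return an object of class `synth_config`.
#' @seealso [simulate_population()]
#' @export
synth_config <- function(n_lines = 72,
                         control_line = "CTRL",
                         n_plots = 5,
                         n_metabolites = 65,
                         set_sizes = c(40, 25),
                         rho_within = 0.6,
                         rho_between = -0.4,
                         n_blocks = 4,
                         block_sigma = 0.3,
                         noise_sigma = 0.15,
                         qtl_lines_frac = 0.2,
                         qtl_metabolites_per_line = 3,
                         qtl_effect = 0.5,
                         treatment_effect = 0.25,
                         n_treatment_metabolites = 5,
                         n_treatment_lines = 3,
                         n_weight_qtl_lines = 6,
                         weight_qtl_effect = 0.5,
                         base_seed_weight = 2.8,
                         weight_line_sd = 0.15,
                         weight_noise_sd = 0.1,
                         abortion_base = 0.15,
                         abortion_salinity_effect = 0.2,
                         seeds_per_fruit = 70,
                         failure_frac = 0.1,
                         failure_shift = 1.5,
                         germ_beta0 = 3.3,
                         germ_beta = 4,
                         t50_mu0 = 3,
                         t50_gamma = 1.5,
                         t50_size = 8,
                         max_day = 14,
                         seeds_per_plate = 50,
                         n_plates = 3,
                         seed_mass_mean = 50,
                         seed_mass_sd = 5,
                         load_sigma = 0.2,
                         missing_frac = 0.02,
                         season = "S1",
                         rng_seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  with(cfg, {
    if (length(set_sizes) != 2 || sum(set_sizes) != n_metabolites)
      stop("set_sizes must be a pair summing to n_metabolites")
    if (!(rho_within > 0 && rho_between < 0))
      stop("rho_within must be > 0 and rho_between < 0")
    if (any(c(block_sigma, noise_sigma, load_sigma) < 0))
      stop("all SDs must be >= 0")
    probs <- c(abortion_base, abortion_base + abortion_salinity_effect,
               failure_frac, missing_frac, qtl_lines_frac)
    if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
    if (n_plots < 1 || n_lines < 1 || n_plates < 1) stop("counts must be >= 1")
  })
  # the two-set correlation matrix must be positive semi-definite
  R <- two_set_correlation(cfg$set_sizes, cfg$rho_within, cfg$rho_between)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("infeasible correlation structure: ",
         "rho_within/rho_between yield a non-positive-definite matrix")
  invisible(cfg)
}

# matrix square root via eigen decomposition; tolerates semi-definite R
# (e.g. perfectly correlated degenerate configurations)
correlation_sqrt <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# block correlation matrix: rho_within inside each set, rho_between across
two_set_correlation <- function(set_sizes, rho_within, rho_between) {
  n <- sum(set_sizes)
  grp <- rep(1:2, set_sizes)
  R <- ifelse(outer(grp, grp, "=="), rho_within, rho_between)
  diag(R) <- 1
  R
}

metabolite_names <- function(cfg) sprintf("met%02d", seq_len(cfg$n_metabolites))
line_names <- function(cfg) c(cfg$control_line,
                              sprintf("IL%02d", seq_len(cfg$n_lines)))

# sample sheet: one row per (line, treatment, plot); run blocks round-robin
sample_sheet <- function(cfg) {
  lines <- line_names(cfg)
  df <- expand.grid(plot = seq_len(cfg$n_plots),
                    treatment = c("SDF", "SDS"),
                    line = lines,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[, c("line", "treatment", "plot")]
  df$season <- cfg$season
  df$sample_id <- sprintf("%s_%s_%s_p%d", df$season, df$line, df$treatment,
                          df$plot)
  df$run_block <- sprintf("B%d", ((seq_len(nrow(df)) - 1L) %% cfg$n_blocks) + 1L)
  df
}

#' Draw the latent (log-scale) metabolite matrix
#'
#' Latent values are multivariate normal with the two-set correlation
#' structure scaled to `noise_sigma`, plus line-specific metabolite QTL
#' shifts, sparse line-specific salinity shifts under SDS, and the failure
#' shift for a random fraction of plots. The ground truth (set assignment,
#' QTL map, treatment map, failure flags and per-plot balance score) is
#' returned alongside.
#'
#' @param config a [synth_config()].
#' @return list with `latents` (plots x metabolites matrix), `samples`
#'   (sample sheet) and `truth` (ground-truth list).
#' @export
generate_metabolite_latents <- function(config) {
  validate_synth_config(config)
  set.seed(substream_seed(config$rng_seed, "latents"))
  samples <- sample_sheet(config)
  mets <- metabolite_names(config)
  n <- nrow(samples)
  m <- config$n_metabolites
  set_assignment <- stats::setNames(rep(c("S1", "S2"), config$set_sizes), mets)

  R <- two_set_correlation(config$set_sizes, config$rho_within,
                           config$rho_between)
  Z <- matrix(stats::rnorm(n * m), n, m) %*% correlation_sqrt(R) *
    config$noise_sigma
  colnames(Z) <- mets
  rownames(Z) <- samples$sample_id

  ils <- setdiff(line_names(config), config$control_line)

  # metabolite QTLs: a fraction of ILs, a few metabolites each, signed
  n_qtl_lines <- round(config$qtl_lines_frac * length(ils))
  qtl_map <- NULL
  if (n_qtl_lines > 0 && config$qtl_effect != 0) {
    qtl_lines <- sample(ils, n_qtl_lines)
    qtl_map <- do.call(rbind, lapply(qtl_lines, function(ln) {
      tr <- sample(mets, min(config$qtl_metabolites_per_line, m))
      data.frame(line = ln, trait = tr,
                 effect = config$qtl_effect * sample(c(-1, 1), length(tr),
                                                     replace = TRUE))
    }))
  }
  if (is.null(qtl_map))
    qtl_map <- data.frame(line = character(), trait = character(),
                          effect = numeric())

  # sparse salinity responses: a few lines x a few metabolites, SDS only
  treatment_map <- data.frame(line = character(), trait = character(),
                              effect = numeric())
  if (config$treatment_effect != 0 && config$n_treatment_lines > 0) {
    t_lines <- sample(line_names(config),
                      min(config$n_treatment_lines, length(line_names(config))))
    treatment_map <- do.call(rbind, lapply(t_lines, function(ln) {
      tr <- sample(mets, min(config$n_treatment_metabolites, m))
      data.frame(line = ln, trait = tr,
                 effect = config$treatment_effect * sample(c(-1, 1), length(tr),
                                                           replace = TRUE))
    }))
  }

  lat <- Z
  if (nrow(qtl_map) > 0) {
    for (i in seq_len(nrow(qtl_map))) {
      rows <- samples$line == qtl_map$line[i]
      lat[rows, qtl_map$trait[i]] <- lat[rows, qtl_map$trait[i]] +
        qtl_map$effect[i]
    }
  }
  if (nrow(treatment_map) > 0) {
    for (i in seq_len(nrow(treatment_map))) {
      rows <- samples$line == treatment_map$line[i] &
        samples$treatment == "SDS"
      lat[rows, treatment_map$trait[i]] <- lat[rows, treatment_map$trait[i]] +
        treatment_map$effect[i]
    }
  }

  # metabolic failure shift: S1 up, S2 down
  failed <- stats::runif(n) < config$failure_frac
  if (any(failed) && config$failure_shift != 0) {
    s1 <- names(set_assignment)[set_assignment == "S1"]
    s2 <- names(set_assignment)[set_assignment == "S2"]
    lat[failed, s1] <- lat[failed, s1] + config$failure_shift
    lat[failed, s2] <- lat[failed, s2] - config$failure_shift
  }

  s1 <- names(set_assignment)[set_assignment == "S1"]
  s2 <- names(set_assignment)[set_assignment == "S2"]
  balance <- rowMeans(lat[, s2, drop = FALSE]) -
    rowMeans(lat[, s1, drop = FALSE])

  truth <- list(set_assignment = set_assignment,
                qtl_map = qtl_map,
                treatment_map = treatment_map,
                failed = stats::setNames(failed, samples$sample_id),
                balance = stats::setNames(balance, samples$sample_id))
  list(latents = lat, samples = samples, truth = truth)
}

#' Turn latent metabolite values into a raw peak-height table
#'
#' Peak height = exp(latent) x seed mass extracted x per-(metabolite, block)
#' run factor x per-sample load factor; a fraction of entries is then set
#' missing completely at random. The per-sample seed mass and run block are
#' recorded so that [normalize_peaks()] can undo these nuisance factors.
#'
#' @param latents result of [generate_metabolite_latents()].
#' @param config the same [synth_config()].
#' @return a `peak_table` (see [peak_table()]).
#' @export
latents_to_peaks <- function(latents, config) {
  set.seed(substream_seed(config$rng_seed, "peaks"))
  samples <- latents$samples
  lat <- latents$latents
  n <- nrow(lat); m <- ncol(lat)
  mets <- colnames(lat)

  seed_mass <- pmax(stats::rnorm(n, config$seed_mass_mean, config$seed_mass_sd),
                    config$seed_mass_mean / 5)
  load <- exp(stats::rnorm(n, 0, config$load_sigma))
  blocks <- sort(unique(samples$run_block))
  block_fac <- matrix(exp(stats::rnorm(length(blocks) * m, 0,
                                       config$block_sigma)),
                      length(blocks), m, dimnames = list(blocks, mets))

  peaks <- exp(lat) * seed_mass * load * block_fac[samples$run_block, ,
                                                   drop = FALSE]
  if (config$missing_frac > 0) {
    miss <- matrix(stats::runif(n * m) < config$missing_frac, n, m)
    peaks[miss] <- NA_real_
  }
  df <- cbind(samples[, c("sample_id", "line", "treatment", "season", "plot",
                          "run_block")],
              seed_mass_extracted = seed_mass,
              as.data.frame(peaks, optional = TRUE))
  rownames(df) <- NULL
  peak_table(df, metabolites = mets)
}

#' Simulate germination plate records from balance scores
#'
#' Every sown seed germinates independently with probability
#' `plogis(germ_beta0 + germ_beta * score)`; the day of germination of a
#' germinating seed is `1 + NB(size, mu - 1)` truncated at `max_day`, where
#' `mu = max(1.5, t50_mu0 - t50_gamma * score)`, giving integer-day counts
#' with T50 in the observed 2-8 day range and later, more spread-out
#' germination for low balance scores.
#'
#' @param balance_scores named numeric vector, one score per plot
#'   (names = sample ids).
#' @param samples sample sheet rows matching `balance_scores`.
#' @param config a [synth_config()].
#' @return long data frame: one row per plate and day with cumulative
#'   germinated counts.
#' @export
generate_germination <- function(balance_scores, samples, config) {
  set.seed(substream_seed(config$rng_seed, "germination"))
  stopifnot(nrow(samples) == length(balance_scores))
  out <- vector("list", nrow(samples) * config$n_plates)
  k <- 0
  for (i in seq_len(nrow(samples))) {
    score <- balance_scores[i]
    p <- stats::plogis(config$germ_beta0 + config$germ_beta * score)
    mu <- max(1.5, config$t50_mu0 - config$t50_gamma * score)
    for (pl in seq_len(config$n_plates)) {
      n_germ <- stats::rbinom(1, config$seeds_per_plate, p)
      days <- integer(0)
      if (n_germ > 0) {
        days <- 1L + stats::rnbinom(n_germ, size = config$t50_size,
                                    mu = mu - 1)
        days <- pmin(days, config$max_day)
      }
      cum <- cumsum(tabulate(days, nbins = config$max_day))
      k <- k + 1
      out[[k]] <- data.frame(
        plate_id = sprintf("%s_pl%d", samples$sample_id[i], pl),
        line = samples$line[i], treatment = samples$treatment[i],
        season = samples$season[i], plot = samples$plot[i],
        seeds_sown = config$seeds_per_plate,
        day = seq_len(config$max_day), cumulative = cum)
    }
  }
  do.call(rbind, out)
}

#' Simulate per-plot seed morphology
#'
#' Seed weight is a line-level trait (base + optional weight QTL + residual)
#' unaffected by treatment; the per-seed abortion probability increases by
#' `abortion_salinity_effect` under SDS, so the maturation percent drops
#' under salinity by construction.
#'
#' @param samples sample sheet (one row per plot).
#' @param config a [synth_config()].
#' @return list with `morphology` (data frame: plot keys, avg_seed_weight,
#'   mature, aborted) and `weight_qtl_map` ground truth.
#' @export
generate_morphology <- function(samples, config) {
  set.seed(substream_seed(config$rng_seed, "morphology"))
  lines <- line_names(config)
  ils <- setdiff(lines, config$control_line)
  base <- stats::setNames(
    config$base_seed_weight + stats::rnorm(length(lines), 0,
                                           config$weight_line_sd), lines)
  base[config$control_line] <- config$base_seed_weight

  weight_qtl_map <- data.frame(line = character(), trait = character(),
                               effect = numeric())
  if (config$n_weight_qtl_lines > 0 && config$weight_qtl_effect != 0) {
    w_lines <- sample(ils, min(config$n_weight_qtl_lines, length(ils)))
    eff <- config$weight_qtl_effect * sample(c(-1, 1), length(w_lines),
                                             replace = TRUE)
    weight_qtl_map <- data.frame(line = w_lines, trait = "seed_weight",
                                 effect = eff)
    base[w_lines] <- base[w_lines] + eff
  }

  n <- nrow(samples)
  weight <- pmax(base[samples$line] + stats::rnorm(n, 0, config$weight_noise_sd),
                 0.2)
  total <- stats::rpois(n, config$seeds_per_fruit)
  p_ab <- pmin(pmax(config$abortion_base +
                      config$abortion_salinity_effect *
                        (samples$treatment == "SDS"), 0), 1)
  aborted <- stats::rbinom(n, total, p_ab)
  morph <- data.frame(samples[, c("sample_id", "line", "treatment", "season",
                                  "plot")],
                      avg_seed_weight = as.numeric(weight),
                      mature = total - aborted, aborted = aborted)
  rownames(morph) <- NULL
  list(morphology = morph, weight_qtl_map = weight_qtl_map)
}

#' Simulate a complete synthetic IL-population dataset
#'
#' Runs the full generator: latent metabolites, raw peaks, germination
#' plates and seed morphology, with the complete ground truth attached.
#' Regeneration with the same `rng_seed` is bit-identical.
#'
#' @param config a [synth_config()].
#' @return object of class `seedmet_sim`: list with `peaks`, `germination`,
#'   `morphology`, `truth` and `config`.
#' @export
simulate_population <- function(config = synth_config()) {
  lat <- generate_metabolite_latents(config)
  peaks <- latents_to_peaks(lat, config)
  germ <- generate_germination(lat$truth$balance, lat$samples, config)
  morph <- generate_morphology(lat$samples, config)
  truth <- lat$truth
  truth$weight_qtl_map <- morph$weight_qtl_map
  structure(list(peaks = peaks, germination = germ,
                 morphology = morph$morphology, latents = lat$latents,
                 truth = truth, config = config),
            class = "seedmet_sim")
}

#' Write a synthetic dataset (and its ground truth) to disk
#'
#' Writes the standard pipeline input files `peaks.tsv`, `morphology.tsv`
#' and `germination.tsv`, plus `ground_truth.tsv` (set assignment, QTL /
#' treatment / weight-QTL effects, per-plot balance score and failure flag)
#' and the generating configuration as `config.yaml`.
#'
#' @param sim result of [simulate_population()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "seedmet_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_file(sim$peaks, file.path(dir, "peaks.tsv"))
  write_tsv_file(sim$morphology, file.path(dir, "morphology.tsv"))
  write_tsv_file(sim$germination, file.path(dir, "germination.tsv"))

  tr <- sim$truth
  gt <- rbind(
    data.frame(record = "set_assignment", key = names(tr$set_assignment),
               value = unname(tr$set_assignment)),
    data.frame(record = "qtl_effect",
               key = paste(tr$qtl_map$line, tr$qtl_map$trait, sep = ":"),
               value = as.character(tr$qtl_map$effect)),
    data.frame(record = "treatment_effect",
               key = paste(tr$treatment_map$line, tr$treatment_map$trait,
                           sep = ":"),
               value = as.character(tr$treatment_map$effect)),
    data.frame(record = "weight_qtl_effect",
               key = tr$weight_qtl_map$line,
               value = as.character(tr$weight_qtl_map$effect)),
    data.frame(record = "balance_score", key = names(tr$balance),
               value = as.character(unname(tr$balance))),
    data.frame(record = "failed", key = names(tr$failed),
               value = as.character(unname(tr$failed))))
  write_tsv_file(gt, file.path(dir, "ground_truth.tsv"))
  yaml::write_yaml(unclass(sim$config), file.path(dir, "config.yaml"))
  invisible(dir)
}
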