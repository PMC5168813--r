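test_that("degenerate correlation targets give perfectly signed pairs", {
  cfg <- synth_config(n_lines = 2, n_metabolites = 4, set_sizes = c(2, 2),
                      rho_within = 0.999999, rho_between = -0.999999,
                      qtl_effect = 0, treatment_effect = 0, failure_frac = 0,
                      rng_seed = 1)
  lat <- generate_metabolite_latents(cfg)
  cr <- cor(lat$latents)
  expect_true(all(abs(abs(cr) - 1) < 1e-3))
  grp <- lat$truth$set_assignment
  same <- outer(grp, grp, "==")
  expect_true(all(cr[same] > 0.99))
  expect_true(all(cr[!same] < -0.99))
})

test_that("infeasible correlation structures are rejected", {
  expect_error(
    synth_config(n_metabolites = 30, set_sizes = c(20, 10),
                 rho_within = 0.1, rho_between = -0.9),
    "infeasible correlation structure")
})

test_that("empirical correlations match the targets at large n", {
  # 500 plots: 4 lines x 2 treatments x ~63 plots, no systematic effects
  cfg <- synth_config(n_lines = 4, n_plots = 50, n_metabolites = 12,
                      set_sizes = c(7, 5), qtl_effect = 0,
                      treatment_effect = 0, failure_frac = 0, rng_seed = 5)
  lat <- generate_metabolite_latents(cfg)
  grp <- lat$truth$set_assignment
  cr <- cor(lat$latents)
  same <- outer(grp, grp, "==") & upper.tri(cr)
  diff <- outer(grp, grp, "!=") & upper.tri(cr)
  expect_lt(abs(mean(cr[same]) - 0.6), 0.1)
  expect_lt(abs(mean(cr[diff]) - (-0.4)), 0.1)
})

test_that("with no planted effects line-vs-control rejections occur at ~alpha", {
  cfg <- null_config(n_lines = 20, rng_seed = 11)
  lat <- generate_metabolite_latents(cfg)
  df <- data.frame(lat$samples, lat$latents, check.names = FALSE)
  mets <- colnames(lat$latents)
  q <- detect_trait_qtls(df, mets, cfg$control_line, "SDF", rule = "raw_05")
  rate <- mean(q$significant)
  # 20 lines x 12 metabolites = 240 (correlated) tests; generous band
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.12)
})

test_that("latents map to peaks exactly when nuisance factors are off", {
  cfg <- small_config(block_sigma = 0, load_sigma = 0, seed_mass_mean = 1,
                      seed_mass_sd = 0, missing_frac = 0)
  lat <- generate_metabolite_latents(cfg)
  peaks <- latents_to_peaks(lat, cfg)
  expect_equal(unname(rmc_matrix(peaks)), unname(exp(lat$latents)),
               tolerance = 1e-12)
})

test_that("requested missingness fraction is realized up to binomial noise", {
  cfg <- small_config(missing_frac = 0.05, rng_seed = 3)
  peaks <- latents_to_peaks(generate_metabolite_latents(cfg), cfg)
  mat <- rmc_matrix(peaks)
  n <- length(mat)
  p_hat <- mean(is.na(mat))
  expect_lt(abs(p_hat - 0.05), 4 * sqrt(0.05 * 0.95 / n))
})

test_that("null germination link produces no score correlation", {
  cfg <- synth_config(n_lines = 15, n_plots = 10, n_metabolites = 12,
                      set_sizes = c(7, 5), germ_beta = 0, t50_gamma = 0,
                      failure_frac = 0, qtl_effect = 0, treatment_effect = 0,
                      rng_seed = 21)
  lat <- generate_metabolite_latents(cfg)
  germ <- generate_germination(lat$truth$balance, lat$samples, cfg)
  tr <- germination_traits(germ)
  score <- lat$truth$balance[tr$sample_id]
  expect_lt(abs(cor(score, tr$percent)), 0.1)
})

test_that("positive germination link yields a positive significant correlation", {
  cfg <- small_config(failure_frac = 0, rng_seed = 22)
  lat <- generate_metabolite_latents(cfg)
  germ <- generate_germination(lat$truth$balance, lat$samples, cfg)
  tr <- germination_traits(germ)
  score <- lat$truth$balance[tr$sample_id]
  ct <- suppressWarnings(cor.test(score, tr$percent, method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.001)
})

test_that("zero germination probability gives empty plates with undefined T50", {
  cfg <- small_config(n_lines = 1, n_plots = 2, germ_beta0 = -50,
                      germ_beta = 0)
  lat <- generate_metabolite_latents(cfg)
  germ <- generate_germination(lat$truth$balance, lat$samples, cfg)
  tr <- germination_traits(germ)
  expect_true(all(tr$percent == 0))
  expect_true(all(is.na(tr$t50)))
})

test_that("salinity raises abortion so bulked maturation percent drops", {
  cfg <- small_config(abortion_salinity_effect = 0.2)
  lat <- generate_metabolite_latents(cfg)
  morph <- generate_morphology(lat$samples, cfg)$morphology
  mp <- maturation_percent(morph$mature, morph$aborted)
  expect_lt(mean(mp[morph$treatment == "SDS"]),
            mean(mp[morph$treatment == "SDF"]))
})

test_that("without a salinity abortion effect maturation is balanced", {
  cfg <- null_config(rng_seed = 31)
  lat <- generate_metabolite_latents(cfg)
  morph <- generate_morphology(lat$samples, cfg)$morphology
  mp <- maturation_percent(morph$mature, morph$aborted)
  tt <- welch_t_test(mp[morph$treatment == "SDS"],
                     mp[morph$treatment == "SDF"])
  expect_gt(tt$p, 0.01)
})

test_that("a planted seed-weight QTL is recovered at five replicates", {
  cfg <- small_config(n_weight_qtl_lines = 2, weight_qtl_effect = 0.5,
                      rng_seed = 41)
  lat <- generate_metabolite_latents(cfg)
  morph <- generate_morphology(lat$samples, cfg)
  expect_gt(nrow(morph$weight_qtl_map), 0)
  q <- detect_trait_qtls(morph$morphology, "avg_seed_weight",
                         cfg$control_line, "SDF", rule = "Bcp_05")
  for (i in seq_len(nrow(morph$weight_qtl_map))) {
    rec <- q[q$line == morph$weight_qtl_map$line[i], ]
    expect_true(rec$significant)
    expect_equal(rec$direction,
                 ifelse(morph$weight_qtl_map$effect[i] > 0, "+", "-"))
  }
})

test_that("simulation is bit-identical under the same seed", {
  cfg <- small_config(rng_seed = 77)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$peaks, s2$peaks)
  expect_identical(s1$germination, s2$germination)
  expect_identical(s1$morphology, s2$morphology)
  expect_identical(s1$truth, s2$truth)

  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  write_dataset(s1, d1); write_dataset(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("ground truth is complete and excludes the control line", {
  sim <- simulate_population(small_config(rng_seed = 9))
  tr <- sim$truth
  expect_setequal(names(tr$set_assignment), attr(sim$peaks, "metabolites"))
  expect_true(all(tr$set_assignment %in% c("S1", "S2")))
  expect_false(sim$config$control_line %in% tr$qtl_map$line)
  expect_false(sim$config$control_line %in% tr$weight_qtl_map$line)
  expect_setequal(names(tr$balance), sim$peaks$sample_id)
})
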