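#' Build or read a pipeline configuration
#'
#' A configuration either names the three input files (`peaks`,
#' `morphology`, `germination`) or carries a `simulate` block of
#' [synth_config()] overrides — exactly one of the two. Remaining entries
#' tune the stages and all have defaults.
#'
#' @param x path to a YAML file, or a named list.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(x = list()) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  stopifnot(is.list(cfg))
  has_input <- !is.null(cfg$input)
  has_sim <- !is.null(cfg$simulate)
  if (has_input && has_sim)
    stop("config must contain exactly one of 'input' and 'simulate'")
  if (!has_input && !has_sim) cfg$simulate <- list()
  defaults <- list(
    seed = 1,
    control_line = NULL,           # taken from simulate config if absent
    output = "seedmet_out",
    normalization = list(n_components = 5, max_iter = 1000, tol = 1e-6),
    qtl = list(metabolite_rule = "Bc_05", treatment_rule = "raw_01",
               fc_rule = "Bc_05", trait_rule = "Bcp_05"),
    network = list(q = 0.05, r_min = 0.4, steps = 4),
    integration = list(k = 3, n_restarts = 50))
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) {
      cfg[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]])) {
      cfg[[nm]] <- utils::modifyList(defaults[[nm]], cfg[[nm]])
    }
  }
  num_checks <- c(q = cfg$network$q, r_min = cfg$network$r_min,
                  k = cfg$integration$k)
  if (cfg$network$q < 0 || cfg$network$q > 1) stop("network q outside [0, 1]")
  if (cfg$network$r_min < 0 || cfg$network$r_min > 1)
    stop("network r_min outside [0, 1]")
  if (cfg$integration$k < 1) stop("integration k must be >= 1")
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg[sort(names(unclass(cfg)))], tmp)
  unname(tools::md5sum(tmp))
}

stage_log <- function(verbose, ...) if (verbose) message("seedmet: ", ...)

#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (simulation or reading),
#' normalization + log transform + imputation, germination and morphology
#' traits, QTL scans, per-condition signed networks with community/set
#' partition, and the PCA / k-means / group-contrast integration. All stage
#' artifacts are written as TSV into the output directory along with
#' `manifest.json` (package version, config hash, seed, file checksums).
#' Reruns with the same configuration are bit-identical.
#'
#' @param config a [pipeline_config()] (or list/path coercible to one).
#' @param out_dir output directory (overrides `config$output`).
#' @param verbose log stage progress.
#' @return (invisibly) list of in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    pipeline_config(config)
  out <- out_dir %||% cfg$output
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  # --- stage: data ---------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    stage_log(verbose, "simulating population")
    sc_args <- cfg$simulate
    sc_args$rng_seed <- sc_args$rng_seed %||% cfg$seed
    sc <- do.call(synth_config, sc_args)
    sim <- simulate_population(sc)
    write_dataset(sim, file.path(out, "data"))
    peaks <- sim$peaks
    germ <- sim$germination
    morph <- sim$morphology
    control <- cfg$control_line %||% sc$control_line
  } else {
    stage_log(verbose, "reading inputs")
    if (is.null(cfg$control_line))
      stop_stage("data", "control_line is required with file inputs")
    control <- cfg$control_line
    peaks <- tryCatch(read_peak_table(cfg$input$peaks),
                      error = function(e) stop_stage("data", conditionMessage(e)))
    germ <- read_germination_table(cfg$input$germination)
    morph <- morphology_traits(read_tsv_file(cfg$input$morphology))
  }

  # --- stage: normalize ----------------------------------------------------
  stage_log(verbose, "normalizing peaks")
  norm <- tryCatch({
    rmc <- normalize_peaks(peaks)
    lrmc <- log_transform(rmc)
    imp <- impute_missing(lrmc,
                          n_components = cfg$normalization$n_components,
                          max_iter = cfg$normalization$max_iter,
                          tol = cfg$normalization$tol)
    list(rmc = rmc, lrmc = lrmc, imputed = imp)
  }, error = function(e) stop_stage("normalize", conditionMessage(e)))
  write_tsv_file(as.data.frame(norm$rmc), file.path(out, "rmc.tsv"))
  write_tsv_file(as.data.frame(norm$imputed),
                 file.path(out, "rmc_imputed.tsv"))
  write_tsv_file(attr(norm$imputed, "imputation_report"),
                 file.path(out, "imputation_report.tsv"))

  # --- stage: germination & morphology traits ------------------------------
  stage_log(verbose, "germination traits")
  traits <- tryCatch(germination_traits(germ),
                     error = function(e) stop_stage("germination",
                                                    conditionMessage(e)))
  morph <- morphology_traits(morph)
  fc <- salinity_fold_change(traits)
  write_tsv_file(traits, file.path(out, "germ_traits.tsv"))
  write_tsv_file(morph, file.path(out, "morph_traits.tsv"))
  write_tsv_file(fc, file.path(out, "salinity_fc.tsv"))

  # --- stage: QTL scans ----------------------------------------------------
  stage_log(verbose, "QTL scans")
  mets <- attr(norm$imputed, "metabolites")
  lrmc_df <- as.data.frame(norm$lrmc)   # t-tests on non-imputed values
  qtls <- tryCatch({
    rbind(
      detect_trait_qtls(lrmc_df, mets, control, "SDF",
                        cfg$qtl$metabolite_rule),
      detect_trait_qtls(lrmc_df, mets, control, "SDS",
                        cfg$qtl$metabolite_rule),
      detect_treatment_effects(lrmc_df, mets, cfg$qtl$treatment_rule),
      detect_fc_qtls(lrmc_df, mets, control, cfg$qtl$fc_rule),
      detect_trait_qtls(morph, c("avg_seed_weight", "maturation_percent"),
                        control, "SDF", cfg$qtl$trait_rule),
      detect_trait_qtls(morph, c("avg_seed_weight", "maturation_percent"),
                        control, "SDS", cfg$qtl$trait_rule),
      detect_trait_qtls(traits, c("percent", "t50", "sd_plate"), control,
                        "SDF", cfg$qtl$trait_rule),
      detect_trait_qtls(traits, c("percent", "t50", "sd_plate"), control,
                        "SDS", cfg$qtl$trait_rule))
  }, error = function(e) stop_stage("qtl", conditionMessage(e)))
  write_tsv_file(qtls, file.path(out, "qtl_records.tsv"))

  # --- stage: networks per condition ---------------------------------------
  stage_log(verbose, "correlation networks")
  networks <- list()
  imp_df <- as.data.frame(norm$imputed)
  attrs <- list(); all_edges <- list(); all_sets <- list()
  for (cond in c("SDF", "SDS")) {
    sub <- imp_df[imp_df$treatment == cond, , drop = FALSE]
    m <- as.matrix(sub[, mets, drop = FALSE])
    rownames(m) <- sub$sample_id
    gt <- traits[match(sub$sample_id, traits$sample_id),
                 c("percent", "t50", "sd_plate")]
    m <- cbind(m, as.matrix(gt))
    sp <- spearman_matrix(m)
    g <- build_network(sp, r_min = cfg$network$r_min, q = cfg$network$q)
    if (igraph::vcount(g) == 0) {
      warning("empty network for condition ", cond)
      next
    }
    memb <- walktrap_communities(g, steps = cfg$network$steps)
    sets <- assemble_metabolite_sets(g, memb)
    rep <- germination_edge_report(g, sets)
    networks[[cond]] <- list(graph = g, membership = memb, sets = sets,
                             germination_edges = rep)
    ed <- igraph::as_data_frame(g, what = "edges")
    all_edges[[cond]] <- cbind(condition = cond, ed)
    all_sets[[cond]] <- cbind(condition = cond, sets$sets)
    attrs[[cond]] <- cbind(condition = cond, network_attributes(g))
  }
  if (length(all_edges) > 0) {
    write_tsv_file(do.call(rbind, all_edges), file.path(out, "edges.tsv"))
    write_tsv_file(do.call(rbind, all_sets), file.path(out, "sets.tsv"))
    write_tsv_file(do.call(rbind, attrs), file.path(out, "attributes.tsv"))
  }

  # --- stage: integration --------------------------------------------------
  stage_log(verbose, "integration (PCA, k-means, contrasts)")
  integ <- tryCatch({
    m_all <- as.matrix(imp_df[, mets, drop = FALSE])
    rownames(m_all) <- imp_df$sample_id
    keep <- imp_df$sample_id %in% traits$sample_id
    m_g <- m_all[keep, , drop = FALSE]
    groups <- classify_germination_group(
      traits$percent[match(rownames(m_g), traits$sample_id)])
    pca <- run_pca(m_g)
    km <- kmeans_plots(m_g, k = cfg$integration$k,
                       n_restarts = cfg$integration$n_restarts,
                       rng_seed = cfg$seed)
    enr <- cluster_germination_enrichment(km, groups)
    ctr <- if (sum(groups == "non", na.rm = TRUE) >= 2 &&
                 sum(groups == "well", na.rm = TRUE) >= 2)
      germination_group_contrasts(m_g, groups) else NULL
    list(pca = pca, kmeans = km, groups = groups, enrichment = enr,
         contrasts = ctr)
  }, error = function(e) stop_stage("integrate", conditionMessage(e)))
  write_tsv_file(data.frame(sample_id = rownames(integ$pca$scores),
                            integ$pca$scores[, 1:min(5, ncol(integ$pca$scores))]),
                 file.path(out, "pca_scores.tsv"))
  write_tsv_file(data.frame(metabolite = rownames(integ$pca$loadings),
                            integ$pca$loadings[, 1:min(5,
                                                       ncol(integ$pca$loadings))]),
                 file.path(out, "pca_loadings.tsv"))
  write_tsv_file(data.frame(sample_id = names(integ$kmeans),
                            cluster = as.integer(integ$kmeans),
                            group = as.character(integ$groups)),
                 file.path(out, "clusters.tsv"))
  enr_df <- as.data.frame(integ$enrichment$composition)
  names(enr_df) <- c("cluster", "group", "percent_within_cluster")
  enr_df$chi_square <- integ$enrichment$statistic
  enr_df$df <- integ$enrichment$df
  enr_df$p_value <- integ$enrichment$p_value
  write_tsv_file(enr_df, file.path(out, "enrichment.tsv"))
  if (!is.null(integ$contrasts))
    write_tsv_file(integ$contrasts, file.path(out, "group_contrasts.tsv"))

  # --- manifest ------------------------------------------------------------
  files <- setdiff(list.files(out, recursive = TRUE), "manifest.json")
  manifest <- list(
    package = "seedmet",
    version = as.character(utils::packageVersion("seedmet")),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    checksums = as.list(tools::md5sum(file.path(out, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(config = cfg, normalized = norm, traits = traits,
                 morphology = morph, fold_changes = fc, qtls = qtls,
                 networks = networks, integration = integ,
                 output = out))
}

#' Command-line entry point
#'
#' Thin argv-level wrapper around the stage functions. Subcommands:
#' `simulate`, `run-all` (full pipeline), plus `normalize`, `germ`, `qtl`,
#' `network` and `integrate`, which run the pipeline and are retained for
#' scripting symmetry. Flags: `--config <yaml>`, `--out <dir>`,
#' `--seed <int>`, `--verbose`.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit code (0 success, 2 usage error, 1 failure).
#' @export
cli <- function(argv = character()) {
  usage <- paste(
    "usage: seedmet <simulate|normalize|germ|qtl|network|integrate|run-all>",
    "[--config FILE] [--out DIR] [--seed INT] [--verbose]")
  known <- c("simulate", "normalize", "germ", "qtl", "network", "integrate",
             "run-all")
  if (length(argv) == 0 || !(argv[1] %in% known)) {
    message(usage)
    return(2L)
  }
  sub <- argv[1]; argv <- argv[-1]
  opt <- list(config = NULL, out = NULL, seed = NULL, verbose = FALSE)
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (a == "--verbose") { opt$verbose <- TRUE; i <- i + 1; next }
    if (!(a %in% c("--config", "--out", "--seed")) || i == length(argv)) {
      message(usage)
      return(2L)
    }
    opt[[sub("^--", "", a)]] <- argv[i + 1]
    i <- i + 2
  }
  if (!is.null(opt$config) && !file.exists(opt$config)) {
    message("config file not found: ", opt$config)
    return(2L)
  }
  res <- tryCatch({
    cfg <- pipeline_config(opt$config %||% list())
    if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
    if (!is.null(opt$out)) cfg$output <- opt$out
    if (sub == "simulate") {
      sc_args <- cfg$simulate %||% list()
      sc_args$rng_seed <- sc_args$rng_seed %||% cfg$seed
      sim <- simulate_population(do.call(synth_config, sc_args))
      write_dataset(sim, cfg$output)
    } else {
      run_pipeline(cfg, verbose = opt$verbose)
    }
    0L
  }, error = function(e) {
    message("seedmet error: ", conditionMessage(e))
    1L
  })
  res
}
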