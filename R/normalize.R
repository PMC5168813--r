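#' Construct a peak table
#'
#' A peak table holds raw GC-MS peak heights (one column per annotated
#' metabolite) together with the sample metadata needed by the
#' normalization: line, treatment (`SDF`/`SDS`), season, replicate plot,
#' GC-MS run block, and the seed mass extracted for the sample.
#'
#' @param df data frame with mandatory columns `sample_id`, `line`,
#'   `treatment`, `season`, `plot`, `run_block`, `seed_mass_extracted`
#'   followed by metabolite columns.
#' @param metabolites character vector naming the metabolite columns; by
#'   default every non-metadata column.
#' @return `df` with class `peak_table` and a `metabolites` attribute.
#' @export
peak_table <- function(df, metabolites = NULL) {
  meta_cols <- c("sample_id", "line", "treatment", "season", "plot",
                 "run_block", "seed_mass_extracted")
  missing_cols <- setdiff(meta_cols, names(df))
  if (length(missing_cols) > 0)
    stop("peak table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  metabolites <- metabolites %||% setdiff(names(df), meta_cols)
  if (length(metabolites) == 0) stop("peak table has no metabolite columns")
  for (m in metabolites) {
    if (!is.numeric(df[[m]]))
      stop("non-numeric peak values in column '", m, "'")
    bad <- which(!is.na(df[[m]]) & df[[m]] < 0)
    if (length(bad) > 0)
      stop("negative peak height in column '", m, "', row ", bad[1])
  }
  if (any(is.na(df$seed_mass_extracted) | df$seed_mass_extracted <= 0))
    stop("seed_mass_extracted must be positive for every sample")
  if (any(!nzchar(df$line)) || any(!nzchar(df$treatment)))
    stop("line and treatment must be non-empty")
  key <- interaction(df$line, df$treatment, df$season, df$plot, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicated (line, treatment, season, plot) sample key")
  structure(df, metabolites = metabolites,
            class = c("peak_table", "data.frame"))
}

#' Read a raw peak-height table from TSV
#'
#' Expects one header row, tab separation, missing values encoded `NA`.
#' Non-numeric entries in a metabolite column raise a parse error naming
#' the column.
#'
#' @param path path to `peaks.tsv`.
#' @return a [peak_table()].
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read_tsv_file(path)
  meta_cols <- c("sample_id", "line", "treatment", "season", "plot",
                 "run_block", "seed_mass_extracted")
  mets <- setdiff(names(df), meta_cols)
  for (m in mets) {
    if (is.character(df[[m]])) {
      conv <- suppressWarnings(as.numeric(df[[m]]))
      bad <- which(is.na(conv) & !is.na(df[[m]]))
      if (length(bad) > 0)
        stop("non-numeric peak value in column '", m, "', row ", bad[1])
      df[[m]] <- conv
    }
  }
  message(sprintf("read_peak_table: %d samples, %d metabolite columns",
                  nrow(df), length(mets)))
  peak_table(df, metabolites = mets)
}

meta_columns <- function(x) {
  setdiff(names(x), attr(x, "metabolites"))
}

#' Extract the numeric metabolite matrix of a peak or RMC table
#'
#' @param x a `peak_table` or `rmc_table`.
#' @return numeric matrix, samples in rows (named by `sample_id`).
#' @export
rmc_matrix <- function(x) {
  mets <- attr(x, "metabolites")
  mat <- as.matrix(as.data.frame(x)[, mets, drop = FALSE])
  rownames(mat) <- x$sample_id
  mat
}

new_rmc_table <- function(df, metabolites, log_transformed = FALSE,
                          imputed_mask = NULL) {
  structure(df, metabolites = metabolites, log_transformed = log_transformed,
            imputed_mask = imputed_mask,
            class = c("rmc_table", "data.frame"))
}

#' Normalize raw peaks to relative metabolite content (RMC)
#'
#' Applies, in order: (1) division of each peak by its sample's seed mass
#' extracted; (2) division by the sum of the sample's weight-normalized,
#' non-missing peaks; (3) division of each metabolite by its median over the
#' non-missing samples of the same run block. Missing values stay missing
#' throughout. After step 3 the per-block, per-metabolite median equals 1
#' exactly, which makes RMC values comparable across run blocks.
#'
#' @param peaks a [peak_table()].
#' @return an `rmc_table` (same keys, metabolite columns now dimensionless
#'   RMC).
#' @export
normalize_peaks <- function(peaks) {
  stopifnot(inherits(peaks, "peak_table"))
  mets <- attr(peaks, "metabolites")
  mat <- rmc_matrix(peaks)

  mat <- mat / peaks$seed_mass_extracted            # (1) seed weight
  sums <- rowSums(mat, na.rm = TRUE)
  if (any(sums == 0))
    stop("zero peak sum for sample(s): ",
         paste(peaks$sample_id[sums == 0], collapse = ", "))
  mat <- mat / sums                                 # (2) total sum

  for (b in unique(peaks$run_block)) {              # (3) block median
    rows <- peaks$run_block == b
    med <- apply(mat[rows, , drop = FALSE], 2, stats::median, na.rm = TRUE)
    empty <- is.na(med)
    if (any(empty)) {
      warning("metabolite(s) entirely missing in block ", b, ": ",
              paste(mets[empty], collapse = ", "))
      med[empty] <- 1  # values are all NA anyway; keep them missing
    }
    mat[rows, ] <- sweep(mat[rows, , drop = FALSE], 2, med, "/")
  }

  df <- as.data.frame(peaks)[, meta_columns(peaks), drop = FALSE]
  df[mets] <- as.data.frame(mat, optional = TRUE)
  rownames(df) <- NULL
  new_rmc_table(df, mets)
}

#' Natural-log transform an RMC table
#'
#' Variance of metabolite abundances grows with the mean; working on the log
#' scale stabilizes it before t-tests and correlations.
#'
#' @param rmc an `rmc_table` that has not been log-transformed yet.
#' @return the table with `log()` applied elementwise and the
#'   `log_transformed` flag set.
#' @export
log_transform <- function(rmc) {
  stopifnot(inherits(rmc, "rmc_table"))
  if (isTRUE(attr(rmc, "log_transformed")))
    stop("table is already log-transformed")
  mets <- attr(rmc, "metabolites")
  mat <- rmc_matrix(rmc)
  bad <- which(!is.na(mat) & mat <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cells <- apply(bad[seq_len(min(5, nrow(bad))), , drop = FALSE], 1,
                   function(z) paste0(rownames(mat)[z[1]], "/",
                                      colnames(mat)[z[2]]))
    stop("non-positive RMC value(s), e.g.: ", paste(cells, collapse = ", "))
  }
  df <- as.data.frame(rmc)
  df[mets] <- as.data.frame(log(mat), optional = TRUE)
  new_rmc_table(df, mets, log_transformed = TRUE,
                imputed_mask = attr(rmc, "imputed_mask"))
}

#' Complete missing RMC values by iterative low-rank imputation
#'
#' EM-style probabilistic-PCA completion: missing cells are initialized with
#' column means, then the matrix is repeatedly approximated by its leading
#' `n_components` principal components (on column-centered data) and missing
#' cells replaced by the reconstruction, until the largest absolute change
#' is below `tol` or `max_iter` is reached. Observed cells are never
#' altered. Metabolites with more than `max_missing` missing fraction are
#' excluded from the model (their missing cells stay missing) and listed in
#' the attached imputation report.
#'
#' @param rmc a log-transformed `rmc_table`.
#' @param n_components rank of the PCA model.
#' @param max_iter,tol convergence controls.
#' @param max_missing maximal tolerated per-metabolite missing fraction.
#' @return the completed `rmc_table`; attributes `imputed_mask` (logical
#'   matrix over the originally missing cells) and `imputation_report`
#'   (data frame of excluded metabolites) are set.
#' @export
impute_missing <- function(rmc, n_components = 5, max_iter = 1000,
                           tol = 1e-6, max_missing = 0.5) {
  stopifnot(inherits(rmc, "rmc_table"))
  if (!isTRUE(attr(rmc, "log_transformed")))
    stop("impute_missing expects a log-transformed table")
  mets <- attr(rmc, "metabolites")
  mat <- rmc_matrix(rmc)
  miss <- is.na(mat)

  frac <- colMeans(miss)
  excluded <- mets[frac > max_missing]
  report <- data.frame(metabolite = excluded,
                       missing_fraction = frac[frac > max_missing],
                       row.names = NULL)
  usable <- setdiff(mets, excluded)

  if (any(miss[, usable])) {
    sub <- mat[, usable, drop = FALSE]
    sub_miss <- is.na(sub)
    mu <- colMeans(sub, na.rm = TRUE)
    filled <- sub
    filled[sub_miss] <- mu[col(sub)[sub_miss]]
    k <- min(n_components, ncol(sub) - 1L, nrow(sub) - 1L)
    for (it in seq_len(max_iter)) {
      ctr <- colMeans(filled)
      X <- sweep(filled, 2, ctr)
      sv <- svd(X, nu = k, nv = k)
      recon <- sweep(sv$u %*% (diag(sv$d[seq_len(k)], k, k) %*% t(sv$v)),
                     2, ctr, "+")
      delta <- max(abs(recon[sub_miss] - filled[sub_miss]))
      filled[sub_miss] <- recon[sub_miss]
      if (delta < tol) break
    }
    mat[, usable] <- filled
  }

  df <- as.data.frame(rmc)
  df[mets] <- as.data.frame(mat, optional = TRUE)
  prev_mask <- attr(rmc, "imputed_mask")
  imputed_now <- miss & !is.na(mat)
  mask <- if (is.null(prev_mask)) imputed_now else (prev_mask | imputed_now)
  out <- new_rmc_table(df, mets, log_transformed = TRUE, imputed_mask = mask)
  attr(out, "imputation_report") <- report
  out
}

#' Read an already-normalized RMC table
#'
#' Entry point for externally normalized datasets (e.g. a published
#' normalized metabolite table): the file must carry the same sample key
#' columns as `peaks.tsv` minus `seed_mass_extracted`/`run_block`, plus one
#' column per metabolite.
#'
#' @param path TSV path.
#' @param log_transformed whether values are already on the log scale.
#' @return an `rmc_table`.
#' @export
read_rmc_table <- function(path, log_transformed = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read_tsv_file(path)
  meta <- c("sample_id", "line", "treatment", "season", "plot")
  missing_cols <- setdiff(meta, names(df))
  if (length(missing_cols) > 0)
    stop("RMC table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  mets <- setdiff(names(df), c(meta, "run_block", "seed_mass_extracted"))
  for (m in mets) df[[m]] <- as.numeric(df[[m]])
  new_rmc_table(df, mets, log_transformed = log_transformed)
}
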