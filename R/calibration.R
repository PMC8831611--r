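#' Calibration dataset container
#'
#' Beta values (fractional methylation, in [0,1] or NA) for probes by
#' arrays, where each array is an engineered standard with a known
#' methylation proportion: the benchmark variable takes the ordinal values
#' 0, 0.25, 0.5, 0.75, 1.
#'
#' @param beta numeric matrix, probes x arrays, rownames = probe ids.
#' @param levels numeric vector of per-array benchmark proportions, one
#'   per column, each in {0, 0.25, 0.5, 0.75, 1}.
#' @param species free-text species label.
#' @param platform free-text platform label.
#' @return list of class `calibration_dataset`.
#' @export
calibration_dataset <- function(beta, levels, species = "",
                                platform = "") {
  stopifnot(is.matrix(beta), ncol(beta) == length(levels))
  if (!all(levels %in% c(0, 0.25, 0.5, 0.75, 1)))
    stop("levels must be drawn from {0, 0.25, 0.5, 0.75, 1}")
  rng <- range(beta, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 1) stop("beta values must lie in [0,1]")
  structure(list(beta = beta, levels = levels, species = species,
                 platform = platform), class = "calibration_dataset")
}

#' @export
print.calibration_dataset <- function(x, ...) {
  cat("calibration_dataset:", nrow(x$beta), "probes x", ncol(x$beta),
      "arrays (", x$species, "/", x$platform, "), levels:",
      paste(sort(unique(x$levels)), collapse = " "), "\n")
  invisible(x)
}

#' Simulator configuration for calibration standards
#'
#' @param n_probes number of probes.
#' @param replicates_per_level arrays per benchmark level (the study used
#'   2 for human, 4 for mouse, 3 for rat).
#' @param depth effective read depth d driving binomial noise.
#' @param bias_sd standard deviation of per-probe additive bias on the
#'   methylation proportion.
#' @param f_fail fraction of probes that fail in the target species.
#' @param seed mandatory integer seed.
#' @return list of class `simulator_config`.
#' @export
simulator_config <- function(n_probes = 2000L, replicates_per_level = 4L,
                             depth = 100L, bias_sd = 0, f_fail = 0.1,
                             seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(depth >= 1, f_fail >= 0, f_fail <= 1)
  structure(list(n_probes = as.integer(n_probes),
                 replicates_per_level = as.integer(replicates_per_level),
                 depth = as.integer(depth), bias_sd = bias_sd,
                 f_fail = f_fail, seed = as.integer(seed)),
            class = "simulator_config")
}

#' Simulate calibration-standard arrays
#'
#' Emulates premixed methylation standards measured on an array: for a
#' working probe on an array with benchmark proportion p, the beta value
#' is Binomial(d, clamp(p + bias)) / d, the binomial read-out of an
#' effective depth d with an optional probe-specific bias. A planted
#' fraction `f_fail` of probes fail in the species — their betas are
#' drawn uniformly on [0,1], independent of the benchmark. Fully
#' reproducible from the seed.
#'
#' @param config a [simulator_config()].
#' @param species,platform labels stored in the dataset.
#' @return a [calibration_dataset()] with attributes `failing` (logical
#'   vector over probes) and `config`.
#' @export
simulate_calibration <- function(config, species = "sim",
                                 platform = "simArray") {
  stopifnot(inherits(config, "simulator_config"))
  set.seed(config$seed)
  levels <- rep(c(0, 0.25, 0.5, 0.75, 1),
                each = config$replicates_per_level)
  n <- config$n_probes
  failing <- stats::runif(n) < config$f_fail
  bias <- if (config$bias_sd > 0)
    stats::rnorm(n, 0, config$bias_sd) else numeric(n)
  beta <- matrix(NA_real_, n, length(levels),
                 dimnames = list(sprintf("probe%05d", seq_len(n)),
                                 sprintf("array%02d",
                                         seq_along(levels))))
  for (j in seq_along(levels)) {
    p <- pmin(1, pmax(0, levels[j] + bias))
    draw <- stats::rbinom(n, config$depth, p) / config$depth
    u <- stats::runif(n)
    beta[, j] <- ifelse(failing, u, draw)
  }
  out <- calibration_dataset(beta, levels, species, platform)
  attr(out, "failing") <- failing
  attr(out, "config") <- config
  out
}

#' Per-probe correlation with the benchmark proportion
#'
#' Pearson correlation of each probe's beta values against the per-array
#' benchmark proportions. Probes with zero variance (or all-missing
#' values) get NA, flagged for downstream exclusion.
#'
#' @param dataset a [calibration_dataset()].
#' @return named numeric vector of correlations (NA where undefined).
#' @export
correlate_with_benchmark <- function(dataset) {
  stopifnot(inherits(dataset, "calibration_dataset"))
  if (length(unique(dataset$levels)) < 2L)
    stop("at least two distinct benchmark levels are required")
  apply(dataset$beta, 1L, function(b) {
    ok <- !is.na(b)
    if (sum(ok) < 3L || stats::sd(b[ok]) == 0) return(NA_real_)
    stats::cor(b[ok], dataset$levels[ok])
  })
}

#' Count probes exceeding correlation thresholds
#'
#' Strictly-greater-than comparison per threshold; undefined correlations
#' are excluded.
#'
#' @param r per-probe correlations from [correlate_with_benchmark()].
#' @param thresholds correlation thresholds (default 0.85, 0.90, 0.95).
#' @return named integer vector of counts.
#' @export
threshold_counts <- function(r, thresholds = c(0.85, 0.90, 0.95)) {
  r <- r[!is.na(r)]
  stats::setNames(vapply(thresholds, function(t) sum(r > t), integer(1L)),
                  format(thresholds))
}

#' Remove probes poorly correlated with the benchmark
#'
#' Discards probes whose benchmark correlation is below the cutoff
#' (strictly), or undefined. The removed probe ids are attached as
#' attribute `"removed"`.
#'
#' @param dataset a [calibration_dataset()].
#' @param r per-probe correlations.
#' @param cutoff correlation cutoff (default 0.8).
#' @return filtered [calibration_dataset()].
#' @export
filter_outliers <- function(dataset, r, cutoff = 0.8) {
  stopifnot(inherits(dataset, "calibration_dataset"))
  drop <- is.na(r) | r < cutoff
  out <- calibration_dataset(dataset$beta[!drop, , drop = FALSE],
                             dataset$levels, dataset$species,
                             dataset$platform)
  attr(out, "removed") <- rownames(dataset$beta)[drop]
  out
}

#' Mean-variance relation of beta values
#'
#' Beta values from a binomial read-out of depth d satisfy
#' variance = mean(1-mean)/d, making the data heteroscedastic: spread is
#' largest at intermediate methylation. For each probe and each benchmark
#' level, the mean and variance of the betas across the replicate arrays
#' of that level are computed (levels with a single array carry no
#' variance information and are skipped); the constant is fitted by least
#' squares through the origin over all probe-level points, and the
#' Pearson correlation between variance and mean(1-mean) is reported.
#'
#' @param dataset a [calibration_dataset()].
#' @return list: `c` (fitted constant; 1/d for pure binomial data),
#'   `r` (correlation between the per-level pooled variance and pooled
#'   mean(1-mean); NA when variance is constant), `r_points` (the same
#'   correlation over the raw probe-level scatter — attenuated by the
#'   few-replicate noise of each variance estimate), `mean`, `variance`
#'   (per probe-level point), `level_table` (per-level pooled summary).
#' @export
mean_variance_check <- function(dataset) {
  stopifnot(inherits(dataset, "calibration_dataset"))
  if (nrow(dataset$beta) < 3L) stop("at least 3 probes are required")
  m <- numeric(0)
  v <- numeric(0)
  lev_m <- numeric(0)
  lev_v <- numeric(0)
  lev_id <- numeric(0)
  for (lev in sort(unique(dataset$levels))) {
    cols <- which(dataset$levels == lev)
    if (length(cols) < 2L) next
    b <- dataset$beta[, cols, drop = FALSE]
    mi <- rowMeans(b, na.rm = TRUE)
    vi <- apply(b, 1L, stats::var, na.rm = TRUE)
    m <- c(m, mi)
    v <- c(v, vi)
    lev_m <- c(lev_m, mean(mi * (1 - mi), na.rm = TRUE))
    lev_v <- c(lev_v, mean(vi, na.rm = TRUE))
    lev_id <- c(lev_id, lev)
  }
  if (length(m) == 0L)
    stop("no benchmark level has replicate arrays")
  x <- m * (1 - m)
  # unbiased through-origin fit: E[sample variance | x] = c * x
  c_hat <- if (sum(x^2) == 0) 0 else sum(x * v) / sum(x^2)
  r_points <- if (stats::sd(v) == 0 || stats::sd(x) == 0) NA_real_
              else stats::cor(v, x)
  r <- if (length(lev_v) < 2L || stats::sd(lev_v) == 0 ||
           stats::sd(lev_m) == 0) NA_real_
       else stats::cor(lev_v, lev_m)
  list(c = c_hat, r = r, r_points = r_points, mean = m, variance = v,
       level_table = data.frame(level = lev_id, mean_x = lev_m,
                                mean_variance = lev_v))
}

#' Cross-platform / cross-species mean-methylation correlation
#'
#' Computes per-probe mean methylation within each of two data sets and
#' correlates the means over shared probe ids. For sequencing-derived
#' input given as methylated/total counts, sites below a minimum read
#' depth are dropped before averaging.
#'
#' @param matrix_a,matrix_b numeric matrices (probes x samples) with
#'   probe ids as rownames; or for `matrix_b` a data frame with columns
#'   `id`, `meth`, `total` (sequencing counts).
#' @param shared_ids probe ids to compare; defaults to the intersection.
#' @param min_depth minimum total read count for count-based input
#'   (default NULL = no filter).
#' @return list: `r` (Pearson), `n` (probes compared), `mean_a`, `mean_b`.
#' @export
cross_platform_mean_correlation <- function(matrix_a, matrix_b,
                                            shared_ids = NULL,
                                            min_depth = NULL) {
  mean_a <- rowMeans(matrix_a, na.rm = TRUE)
  if (is.data.frame(matrix_b)) {
    if (!is.null(min_depth))
      matrix_b <- matrix_b[matrix_b$total >= min_depth, , drop = FALSE]
    mean_b <- stats::setNames(matrix_b$meth / matrix_b$total, matrix_b$id)
  } else {
    mean_b <- rowMeans(matrix_b, na.rm = TRUE)
  }
  if (is.null(shared_ids))
    shared_ids <- intersect(names(mean_a), names(mean_b))
  if (length(shared_ids) < 3L)
    stop("need at least 3 shared probes, got ", length(shared_ids))
  a <- mean_a[shared_ids]
  b <- mean_b[shared_ids]
  list(r = stats::cor(a, b), n = length(shared_ids),
       mean_a = a, mean_b = b)
}

#' Read / write a beta matrix with its sample sheet
#'
#' The beta matrix travels as CSV (probes x samples, first column probe
#' id) with a sidecar sample sheet CSV (sample_id, level, species,
#' platform).
#'
#' @param beta_path beta matrix CSV.
#' @param sheet_path sample sheet CSV.
#' @return a [calibration_dataset()].
#' @export
read_calibration_csv <- function(beta_path, sheet_path) {
  b <- utils::read.csv(beta_path, check.names = FALSE)
  beta <- as.matrix(b[, -1L, drop = FALSE])
  rownames(beta) <- b[[1L]]
  sheet <- utils::read.csv(sheet_path)
  lev <- sheet$level[match(colnames(beta), sheet$sample_id)]
  if (anyNA(lev)) stop("sample sheet is missing levels for some arrays")
  calibration_dataset(beta, lev,
                      species = sheet$species[1L] %||% "",
                      platform = sheet$platform[1L] %||% "")
}

#' @rdname read_calibration_csv
#' @param dataset a [calibration_dataset()].
#' @export
write_calibration_csv <- function(dataset, beta_path, sheet_path) {
  df <- data.frame(probe_id = rownames(dataset$beta), dataset$beta,
                   check.names = FALSE)
  utils::write.csv(df, beta_path, row.names = FALSE, quote = FALSE)
  sheet <- data.frame(sample_id = colnames(dataset$beta),
                      level = dataset$levels,
                      species = dataset$species,
                      platform = dataset$platform)
  utils::write.csv(sheet, sheet_path, row.names = FALSE, quote = FALSE)
  invisible(beta_path)
}
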