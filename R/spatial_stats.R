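#' Append normalized center distances to a particle table
#'
#' For every record, the Euclidean distance from the particle to its
#' tomogram's fitted nucleolar center, divided by that tomogram's fitted
#' radius (1.0 = the nucleolar surface). Records from tomograms without a
#' fit are dropped with a message.
#'
#' @param table A [particle_table()].
#' @param fits Result of [fit_spheres_per_tomogram()] (or a named list of
#'   `sphere_fit`s).
#' @return The table with a `normalized_distance` column.
#' @export
normalized_distances <- function(table, fits) {
  fit_list <- if (!is.null(fits$fits)) fits$fits else fits
  have <- table$tomogram_id %in% names(fit_list)
  if (any(!have))
    message(sprintf("dropping %d particle(s) from %d unfitted tomogram(s)",
                    sum(!have), length(unique(table$tomogram_id[!have]))))
  out <- table[have, , drop = FALSE]
  nd <- numeric(nrow(out))
  for (id in unique(out$tomogram_id)) {
    f <- fit_list[[id]]
    sel <- out$tomogram_id == id
    nd[sel] <- sqrt((out$x[sel] - f$center[1])^2 +
                    (out$y[sel] - f$center[2])^2 +
                    (out$z[sel] - f$center[3])^2) / f$radius
  }
  out$normalized_distance <- nd
  out
}

#' Gaussian-kernel radial probability density
#'
#' Kernel density estimate of normalized distances with a normal kernel on
#' an even grid covering the data plus/minus 4 bandwidths. The automatic
#' bandwidth is Silverman's rule, h = 0.9 min(SD, IQR/1.34) n^(-1/5).
#'
#' @param distances Numeric vector (>= 2 values).
#' @param bandwidth Kernel SD in normalized-distance units, or `"auto"`.
#' @param n_grid Number of evaluation points.
#' @return A list of class `radial_pdf`: `grid`, `density`, `bandwidth`.
#' @export
radial_pdf <- function(distances, bandwidth = "auto", n_grid = 512L) {
  distances <- distances[is.finite(distances)]
  if (length(distances) < 2)
    ng_error("kernel density needs at least 2 points", "ng_too_few_points")
  h <- if (identical(bandwidth, "auto")) {
    s <- min(stats::sd(distances), stats::IQR(distances) / 1.34)
    if (s == 0) s <- stats::sd(distances)
    if (s == 0)
      ng_error("all distances identical: bandwidth undefined",
               "ng_degenerate_input")
    0.9 * s * length(distances)^(-1 / 5)
  } else bandwidth
  ng_stopifnot(is.numeric(h) && h > 0, "bandwidth must be positive")
  dens <- stats::density(distances, bw = h, kernel = "gaussian",
                         from = min(distances) - 4 * h,
                         to = max(distances) + 4 * h, n = n_grid)
  structure(list(grid = dens$x, density = dens$y, bandwidth = h,
                 n = length(distances)),
            class = "radial_pdf")
}

#' Mode of a radial PDF
#' @param pdf A `radial_pdf`.
#' @return The grid point of maximum density.
#' @export
pdf_mode <- function(pdf) pdf$grid[which.max(pdf$density)]

.perm_statistics <- list(
  mean_diff = function(x, y) mean(x) - mean(y),
  var_diff = function(x, y) stats::var(x) - stats::var(y),
  var_ratio = function(x, y) stats::var(x) / stats::var(y)
)

#' Fisher-Pitman permutation test
#'
#' Tests a two-sample contrast (difference of means, difference of
#' variances, or variance ratio) by permuting group labels over the pooled
#' observations. In exhaustive mode every distinct relabeling is
#' enumerated and the p-value is the exact fraction of relabelings at
#' least as extreme as the observed one. In Monte-Carlo mode `n_perm`
#' random relabelings are drawn and p = (b + 1) / (m + 1), where b counts
#' permuted statistics at least as extreme. Two-sided extremity compares
#' absolute statistics (absolute log-ratio for `var_ratio`).
#'
#' @param x,y Numeric samples.
#' @param statistic `"mean_diff"`, `"var_diff"` or `"var_ratio"`.
#' @param alternative `"two_sided"`, `"greater"` or `"less"`.
#' @param n_perm Number of Monte-Carlo permutations, or `"exhaustive"`
#'   (allowed up to 1e6 distinct relabelings).
#' @param seed Seed for Monte-Carlo mode.
#' @return A `permutation_test_result`: `statistic_name`, `observed`,
#'   `p_value`, `n_permutations` (or `"exhaustive"`), `alternative`,
#'   `seed`.
#' @export
permutation_test <- function(x, y, statistic = "mean_diff",
                             alternative = "two_sided", n_perm = 1e5,
                             seed = 1L) {
  statistic <- match.arg(statistic, names(.perm_statistics))
  alternative <- match.arg(alternative, c("two_sided", "greater", "less"))
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y))
    ng_error("both samples must be non-empty", "ng_too_few_points")
  stat_fn <- .perm_statistics[[statistic]]
  pooled <- c(x, y)
  nx <- length(x); n <- length(pooled)
  observed <- stat_fn(x, y)
  extremity <- function(s) {
    if (alternative == "greater") return(s)
    if (alternative == "less") return(-s)
    if (statistic == "var_ratio") abs(log(s)) else abs(s)
  }
  obs_e <- extremity(observed)
  tol <- 1e-12 * (1 + abs(obs_e))
  exhaustive <- identical(n_perm, "exhaustive")
  if (exhaustive) {
    n_comb <- choose(n, nx)
    if (n_comb > 1e6)
      ng_error(sprintf(
        "exhaustive enumeration of %.3g relabelings exceeds the 1e6 cap",
        n_comb), "ng_enumeration_cap")
    combs <- utils::combn(n, nx)
    perm_e <- apply(combs, 2, function(ix)
      extremity(stat_fn(pooled[ix], pooled[-ix])))
    p <- mean(perm_e >= obs_e - tol)
    m <- "exhaustive"
  } else {
    m <- as.integer(n_perm)
    perm_e <- with_rng_seed(seed, vapply(seq_len(m), function(i) {
      ix <- sample.int(n, nx)
      extremity(stat_fn(pooled[ix], pooled[-ix]))
    }, 0))
    b <- sum(perm_e >= obs_e - tol)
    p <- (b + 1) / (m + 1)
  }
  structure(list(statistic_name = statistic, observed = observed,
                 p_value = p, n_permutations = m,
                 alternative = alternative, seed = seed),
            class = "permutation_test_result")
}

#' @export
print.permutation_test_result <- function(x, ...) {
  cat(sprintf("Fisher-Pitman permutation test (%s, %s)\n",
              x$statistic_name, x$alternative))
  cat(sprintf("  observed = %.6g, p = %.3g (%s permutations) %s\n",
              x$observed, x$p_value,
              if (identical(x$n_permutations, "exhaustive")) "exhaustive"
              else format(x$n_permutations, big.mark = ","),
              significance_stars(x$p_value)))
  invisible(x)
}

#' Per-condition class abundance table
#'
#' Counts particles per (condition, class) and reports each class as a
#' percentage of its condition's total; percentages within a condition sum
#' to 100. Conditions with no labeled particles are omitted with a
#' warning.
#'
#' @param table A [particle_table()] with `class_label` and `condition`
#'   set on all records.
#' @return A data.frame: condition, class_label, count, percent.
#' @export
class_abundance <- function(table) {
  if (any(is.na(table$class_label)) || any(is.na(table$condition)))
    ng_error("class_label and condition must be present on all records",
             "ng_invalid_argument")
  conditions <- unique(table$condition)
  classes <- sort(unique(table$class_label))
  rows <- list()
  for (cond in conditions) {
    sub <- table[table$condition == cond, ]
    if (!nrow(sub)) {
      warning(sprintf("condition '%s' has no particles; omitted", cond))
      next
    }
    cnt <- vapply(classes, function(k) sum(sub$class_label == k), 0L)
    rows[[cond]] <- data.frame(condition = cond, class_label = classes,
                               count = cnt,
                               percent = 100 * cnt / nrow(sub),
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Boxplot summary statistics
#'
#' Quartiles by linear interpolation; by convention the whiskers span the
#' minimum and maximum (so there are no outliers); the alternative Tukey
#' convention (1.5 IQR whiskers plus outlier list) is available.
#'
#' @param values Numeric vector (>= 1 value).
#' @param convention `"minmax"` (default) or `"tukey"`.
#' @return A list: mean, median, q1, q3, whisker_low, whisker_high,
#'   outliers.
#' @export
boxplot_summary <- function(values, convention = c("minmax", "tukey")) {
  convention <- match.arg(convention)
  values <- values[is.finite(values)]
  if (!length(values))
    ng_error("no finite values", "ng_too_few_points")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  if (convention == "minmax") {
    wl <- min(values); wh <- max(values); outl <- numeric()
  } else {
    iqr <- q[3] - q[1]
    wl <- min(values[values >= q[1] - 1.5 * iqr])
    wh <- max(values[values <= q[3] + 1.5 * iqr])
    outl <- values[values < wl | values > wh]
  }
  list(mean = mean(values), median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = wl, whisker_high = wh, outliers = outl)
}

#' Significance stars
#'
#' Maps a p-value to the reporting convention P >= 0.05: NS; P <= 0.05: *;
#' P <= 0.01: **; P <= 0.0001: ***.
#'
#' @param p A p-value in (0, 1].
#' @return `"NS"`, `"*"`, `"**"` or `"***"`.
#' @export
significance_stars <- function(p) {
  if (!is.numeric(p) || length(p) != 1 || !is.finite(p) || p <= 0 || p > 1)
    ng_error("p must be a single value in (0, 1]", "ng_invalid_argument")
  if (p <= 1e-4) "***"
  else if (p <= 0.01) "**"
  else if (p <= 0.05) "*"
  else "NS"
}
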