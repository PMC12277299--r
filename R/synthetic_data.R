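#' Specification for a synthetic country-level dataset
#'
#' Describes a mixture of `k` well-separated clusters of country
#' percentages in \[0, 100\], per-country sampling error, and a paired
#' low-to-high-activity shift. The defaults emulate the structure of the
#' bundled low-activity table: five clusters with means 41/52/60/67/78 and
#' sizes 8/7/16/16/9, within-cluster spread of about 2 percentage points,
#' an average paired shift of -3 points (the OECD-average change) with a
#' 3-point spread, and per-country standard errors between 0.5 and 4.5.
#'
#' @param k Number of true clusters.
#' @param cluster_means,cluster_sds,sizes Numeric vectors of length `k`:
#'   component means (in \[0, 100\]), standard deviations (>= 0) and sizes
#'   (positive integers).
#' @param paired_shift_mean,paired_shift_sd Mean and sd of the per-country
#'   low-to-high change, percentage points.
#' @param se_range Length-2 positive range for the uniform per-country
#'   standard errors.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return An `anx_synth_spec` list.
#' @export
synthetic_spec <- function(k = 5,
                           cluster_means = c(41, 52, 60, 67, 78),
                           cluster_sds = rep(2, k),
                           sizes = c(8, 7, 16, 16, 9),
                           paired_shift_mean = -3,
                           paired_shift_sd = 3,
                           se_range = c(0.5, 4.5),
                           seed = 2018L) {
  ok <- is.numeric(k) && length(k) == 1 && k >= 1 && k == round(k) &&
    length(cluster_means) == k && length(cluster_sds) == k &&
    length(sizes) == k &&
    all(cluster_means >= 0 & cluster_means <= 100) &&
    all(cluster_sds >= 0) &&
    all(sizes >= 1 & sizes == round(sizes)) &&
    is.numeric(paired_shift_mean) && length(paired_shift_mean) == 1 &&
    paired_shift_sd >= 0 &&
    length(se_range) == 2 && all(se_range > 0) && se_range[1] <= se_range[2] &&
    is.numeric(seed) && length(seed) == 1
  if (!ok) abort("invalid synthetic specification", class = "anx_validation_error")
  structure(
    list(
      k = as.integer(k), cluster_means = cluster_means,
      cluster_sds = cluster_sds, sizes = as.integer(sizes),
      paired_shift_mean = paired_shift_mean,
      paired_shift_sd = paired_shift_sd,
      se_range = se_range, seed = as.integer(seed)
    ),
    class = "anx_synth_spec"
  )
}

#' Generate a synthetic paired country dataset with known clusters
#'
#' Low-activity values are drawn per cluster from
#' `Normal(cluster_mean, cluster_sd)` and clipped to \[0, 100\];
#' high-activity values add a `Normal(paired_shift_mean, paired_shift_sd)`
#' per-country shift (clipped likewise); per-country standard errors are
#' uniform on `se_range`. The true generating component of every country is
#' returned so downstream stages can be scored against ground truth.
#'
#' @param spec An [synthetic_spec()] object.
#' @return A list with tibbles `low` and `high` (in [read_anxiety_csv()]
#'   layout) and `truth` (`country`, `cluster`).
#' @export
#' @examples
#' sim <- generate_anxiety(synthetic_spec(
#'   k = 2, cluster_means = c(40, 78),
#'   cluster_sds = c(2, 2), sizes = c(10, 10), seed = 1
#' ))
#' sim$low
generate_anxiety <- function(spec) {
  if (!inherits(spec, "anx_synth_spec")) spec <- do.call(synthetic_spec, spec)
  n <- sum(spec$sizes)
  comp <- rep(seq_len(spec$k), spec$sizes)
  withr_seed <- spec$seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(withr_seed)
  clip <- function(x) pmin(100, pmax(0, x))
  low <- clip(stats::rnorm(n, spec$cluster_means[comp], spec$cluster_sds[comp]))
  shift <- stats::rnorm(n, spec$paired_shift_mean, spec$paired_shift_sd)
  high <- clip(low + shift)
  se_low <- stats::runif(n, spec$se_range[1], spec$se_range[2])
  se_high <- stats::runif(n, spec$se_range[1], spec$se_range[2])
  country <- sprintf("Country %02d", seq_len(n))
  list(
    low = tibble::tibble(
      country = country, group = "low", anxiety_pct = low, se = se_low
    ),
    high = tibble::tibble(
      country = country, group = "high", anxiety_pct = high, se = se_high
    ),
    truth = tibble::tibble(country = country, cluster = comp)
  )
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between a reference partition and an
#' estimate, computed from the contingency table of the two labelings. It
#' is 1 exactly when the partitions are identical up to label permutation,
#' and close to 0 for independent random labelings.
#'
#' @param truth,estimate Partition tibbles (`country`, `cluster`) over the
#'   same country set.
#' @return A number in \[-1, 1\].
#' @export
recovery_score <- function(truth, estimate) {
  if (!setequal(truth$country, estimate$country) ||
    nrow(truth) != nrow(estimate)) {
    abort("partitions cover different country sets", class = "anx_validation_error")
  }
  a <- as.character(truth$cluster)
  b <- as.character(estimate$cluster[match(truth$country, estimate$country)])
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  denom <- (sum_a + sum_b) / 2 - expected
  # both partitions trivial (all-singleton or single-cluster): agreement is
  # total iff the pair-count sums coincide
  if (denom == 0) {
    return(if (sum_ij == (sum_a + sum_b) / 2) 1 else 0)
  }
  (sum_ij - expected) / denom
}
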