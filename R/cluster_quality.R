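# Align a partition tibble (country, cluster) with a set of country labels;
# returns integer cluster codes in label order.
align_partition <- function(partition, countries) {
  if (!all(c("country", "cluster") %in% names(partition))) {
    abort("a partition needs columns `country` and `cluster`", class = "anx_schema_error")
  }
  if (!setequal(partition$country, countries) ||
    length(partition$country) != length(countries)) {
    abort("partition and data cover different country sets", class = "anx_validation_error")
  }
  cl <- partition$cluster[match(countries, partition$country)]
  if (any(is.na(cl))) abort("unassigned country", class = "anx_validation_error")
  as.integer(factor(cl, levels = unique(cl)))
}

#' Per-country silhouette widths
#'
#' For each country `i`, `a(i)` is the mean distance to the other members
#' of its own cluster, `b(i)` the smallest mean distance to the members of
#' any other cluster, and the silhouette width is
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))`. Countries in singleton
#' clusters get `s(i) = 0` (the usual convention, keeping the mean defined
#' for any partition with at least two clusters). The mean silhouette is
#' the unweighted average of the returned widths.
#'
#' @param dist An [anx_distances()] matrix.
#' @param partition A partition tibble (`country`, `cluster`) covering the
#'   same countries.
#' @return A tibble with columns `country`, `cluster`, `a`, `b`,
#'   `sil_width`.
#' @export
#' @examples
#' d <- anx_distances(anx_fixture("table1_low"))
#' sw <- silhouette_widths(d, anx_fixture("table1_low")[c("country", "cluster")])
#' mean(sw$sil_width)
silhouette_widths <- function(dist, partition) {
  m <- unclass(as.matrix(dist))
  countries <- rownames(m)
  cl <- align_partition(partition, countries)
  k <- length(unique(cl))
  n <- length(cl)
  if (k < 2) {
    abort("silhouette needs at least 2 clusters (b(i) is undefined for k = 1)",
      class = "anx_validation_error"
    )
  }
  sizes <- tabulate(cl, nbins = k)
  # column c of `sums`: total distance from each point to cluster c members
  sums <- sapply(seq_len(k), function(c) rowSums(m[, cl == c, drop = FALSE]))
  a <- ifelse(sizes[cl] > 1, sums[cbind(seq_len(n), cl)] / (sizes[cl] - 1), 0)
  b <- vapply(seq_len(n), function(i) {
    min((sums[i, -cl[i]] / sizes[-cl[i]]))
  }, numeric(1))
  denom <- pmax(a, b)
  s <- ifelse(sizes[cl] == 1 | denom == 0, 0, (b - a) / denom)
  tibble::tibble(
    country = countries,
    cluster = partition$cluster[match(countries, partition$country)],
    a = a, b = b, sil_width = s
  )
}

#' Within-cluster sum of squares and its interpretability transforms
#'
#' `wcss` is the sum over clusters of squared Euclidean deviations of each
#' member from its cluster centroid. Two transforms put it on an
#' interpretable scale: the average square distance `wcss / n` and the
#' "percentual" WCSS `sqrt(wcss / n)`, a root-mean-square deviation in
#' percentage points.
#'
#' @param data A country dataset.
#' @param partition A partition tibble (`country`, `cluster`).
#' @param cols Feature column(s); default `"anxiety_pct"`.
#' @return A one-row tibble: `n`, `k`, `wcss`, `avg_square_distance`,
#'   `percentual_wcss`.
#' @export
wcss_suite <- function(data, partition, cols = "anxiety_pct") {
  data <- validate_anxiety(data)
  x <- as.matrix(data[cols])
  cl <- align_partition(partition, data$country)
  wcss <- sum(vapply(split(seq_len(nrow(x)), cl), function(idx) {
    centroid <- colMeans(x[idx, , drop = FALSE])
    sum(sweep(x[idx, , drop = FALSE], 2, centroid)^2)
  }, numeric(1)))
  n <- nrow(x)
  tibble::tibble(
    n = n, k = length(unique(cl)), wcss = wcss,
    avg_square_distance = wcss / n,
    percentual_wcss = sqrt(wcss / n)
  )
}

#' Between-cluster sum of squares, explained variation and BCSS/WCSS ratio
#'
#' `bcss_total` is the size-weighted sum of squared deviations of cluster
#' centroids from the global centroid. Together with [wcss_suite()] it
#' decomposes the total sum of squares (`tss = wcss + bcss_total`, the law
#' of total variance), giving the explained variation `bcss_total / tss`.
#' The per-cluster average `bcss_total / k` and the `bcss_total / wcss`
#' ratio are the two interpretability transforms reported alongside. The
#' ratio is `NA` for an all-singleton partition (`wcss = 0`).
#'
#' @inheritParams wcss_suite
#' @return A one-row tibble: `k`, `bcss_total`, `avg_bcss_per_cluster`,
#'   `tss`, `explained_variation`, `bcss_wcss_ratio`.
#' @export
bcss_suite <- function(data, partition, cols = "anxiety_pct") {
  data <- validate_anxiety(data)
  x <- as.matrix(data[cols])
  cl <- align_partition(partition, data$country)
  mu <- colMeans(x)
  bcss <- sum(vapply(split(seq_len(nrow(x)), cl), function(idx) {
    length(idx) * sum((colMeans(x[idx, , drop = FALSE]) - mu)^2)
  }, numeric(1)))
  wcss <- wcss_suite(data, partition, cols)$wcss
  tss <- sum(sweep(x, 2, mu)^2)
  k <- length(unique(cl))
  tibble::tibble(
    k = k, bcss_total = bcss, avg_bcss_per_cluster = bcss / k,
    tss = tss,
    explained_variation = if (tss > 0) bcss / tss else 0,
    bcss_wcss_ratio = if (wcss > 0) bcss / wcss else NA_real_
  )
}

#' Full cluster-quality report
#'
#' Bundles the silhouette widths with the within- and between-cluster
#' dispersion metrics for one partition, checking the `wcss + bcss = tss`
#' decomposition.
#'
#' @inheritParams wcss_suite
#' @param dist Optional precomputed [anx_distances()] matrix; computed from
#'   `data` when omitted.
#' @return An `anx_quality` object. `glance()` gives the one-row metric
#'   summary, `tidy()` the per-country silhouette tibble.
#' @export
#' @examples
#' tb <- anx_fixture("table2_high")
#' q <- quality_report(tb, tb[c("country", "cluster")])
#' glance(q)
quality_report <- function(data, partition, cols = "anxiety_pct", dist = NULL) {
  data <- validate_anxiety(data)
  if (is.null(dist)) dist <- anx_distances(data, cols)
  sil <- silhouette_widths(dist, partition)
  w <- wcss_suite(data, partition, cols)
  b <- bcss_suite(data, partition, cols)
  if (abs(w$wcss + b$bcss_total - b$tss) > 1e-6 * (1 + b$tss)) {
    abort("internal error: WCSS + BCSS != TSS", class = "anx_internal_error")
  }
  structure(
    list(
      k = b$k, n = w$n,
      silhouette = sil,
      silhouette_mean = mean(sil$sil_width),
      wcss = w, bcss = b
    ),
    class = "anx_quality"
  )
}

#' @export
print.anx_quality <- function(x, ...) {
  cat("<anx_quality> k = ", x$k, ", n = ", x$n, "\n", sep = "")
  cat(sprintf("  mean silhouette     %8.3f\n", x$silhouette_mean))
  cat(sprintf("  WCSS                %8.2f  (avg sq dist %.2f, percentual %.2f)\n",
    x$wcss$wcss, x$wcss$avg_square_distance, x$wcss$percentual_wcss))
  cat(sprintf("  BCSS                %8.2f  (avg per cluster %.2f)\n",
    x$bcss$bcss_total, x$bcss$avg_bcss_per_cluster))
  cat(sprintf("  explained variation %7.0f%%   BCSS/WCSS ratio %.2f\n",
    100 * round(x$bcss$explained_variation, 2), x$bcss$bcss_wcss_ratio))
  invisible(x)
}

#' @method glance anx_quality
#' @export
glance.anx_quality <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(k = x$k, n = x$n, silhouette_mean = x$silhouette_mean),
    x$wcss[c("wcss", "avg_square_distance", "percentual_wcss")],
    x$bcss[c(
      "bcss_total", "avg_bcss_per_cluster", "tss",
      "explained_variation", "bcss_wcss_ratio"
    )]
  )
}

#' @method tidy anx_quality
#' @export
tidy.anx_quality <- function(x, ...) x$silhouette

#' Three-step choice of the number of clusters
#'
#' Implements the sequential procedure used throughout the package:
#' 1. cut the dendrogram at a fraction of its maximum height (default 20%)
#'    to obtain a candidate k from the tree itself;
#' 2. compute the mean silhouette for every k in `k_range` and record the
#'    maximizer (smallest k on ties);
#' 3. report the full dispersion metrics for the chosen k.
#'
#' The chosen k is the silhouette maximizer; the dendrogram-cut candidate
#' is reported alongside and a warning is raised when the two disagree.
#'
#' @inheritParams wcss_suite
#' @param linkage Linkage passed to [anx_agglomerate()].
#' @param k_range Integer vector of candidate cluster counts, within
#'   `[2, n - 1]`.
#' @param fraction Height fraction for the dendrogram-cut candidate.
#' @return An `anx_kselect` object with elements `chosen_k`,
#'   `candidate_k`, `profile` (tibble of k and mean silhouette),
#'   `partition` (at `chosen_k`), `quality`, and `dendrogram`.
#' @export
select_k <- function(data, linkage = "ward", k_range = 2:10, fraction = 0.20,
                     cols = "anxiety_pct") {
  data <- validate_anxiety(data)
  n <- nrow(data)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0 || min(k_range) < 2 || max(k_range) > n - 1) {
    abort(paste0("k_range must lie within [2, ", n - 1, "]"), class = "anx_validation_error")
  }
  d <- anx_distances(data, cols)
  dendro <- anx_agglomerate(d, linkage)
  cand <- cut_at_fraction(dendro, fraction)
  profile <- tibble::tibble(
    k = k_range,
    silhouette_mean = vapply(k_range, function(k) {
      mean(silhouette_widths(d, cut_to_k(dendro, k))$sil_width)
    }, numeric(1))
  )
  chosen_k <- profile$k[which.max(profile$silhouette_mean)]
  if (chosen_k != attr(cand, "k")) {
    warn(paste0(
      "dendrogram cut at fraction ", fraction, " suggests k = ",
      attr(cand, "k"), " but the silhouette maximizer is k = ", chosen_k
    ), class = "anx_kselect_disagreement")
  }
  partition <- cut_to_k(dendro, chosen_k)
  structure(
    list(
      chosen_k = chosen_k, candidate_k = attr(cand, "k"),
      fraction = fraction, profile = profile,
      partition = partition,
      quality = quality_report(data, partition, cols, dist = d),
      dendrogram = dendro
    ),
    class = "anx_kselect"
  )
}

#' @export
print.anx_kselect <- function(x, ...) {
  cat("<anx_kselect> chosen k = ", x$chosen_k,
    " (silhouette maximizer); dendrogram cut at ", x$fraction,
    " suggests k = ", x$candidate_k, "\n",
    sep = ""
  )
  print(x$profile)
  invisible(x)
}

#' @method tidy anx_kselect
#' @export
tidy.anx_kselect <- function(x, ...) x$profile

#' @method glance anx_kselect
#' @export
glance.anx_kselect <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      chosen_k = x$chosen_k, candidate_k = x$candidate_k,
      fraction = x$fraction
    ),
    glance(x$quality)[-1]
  )
}
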