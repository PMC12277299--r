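test_that("duplicated points in two clusters give silhouette 1 everywhere", {
  data <- make_dataset(c(0, 0, 10, 10))
  part <- tibble::tibble(country = data$country, cluster = c(1, 1, 2, 2))
  sw <- silhouette_widths(anx_distances(data), part)
  expect_equal(sw$sil_width, rep(1, 4))
  expect_equal(mean(sw$sil_width), 1.0)
})

test_that("silhouette needs k >= 2 and zeroes singletons", {
  data <- make_dataset(c(1, 2, 9))
  d <- anx_distances(data)
  expect_error(
    silhouette_widths(d, tibble::tibble(country = data$country, cluster = c(1, 1, 1))),
    class = "anx_validation_error"
  )
  sw <- silhouette_widths(d, tibble::tibble(country = data$country, cluster = c(1, 1, 2)))
  expect_equal(sw$sil_width[3], 0)
})

test_that("silhouette matches the brute-force oracle on random partitions", {
  set.seed(23)
  for (rep in 1:15) {
    n <- sample(6:12, 1)
    data <- make_dataset(sample(0:100, n, replace = TRUE))
    cl <- sample(1:3, n, replace = TRUE)
    while (length(unique(cl)) < 2) cl <- sample(1:3, n, replace = TRUE)
    part <- tibble::tibble(country = data$country, cluster = cl)
    d <- anx_distances(data)
    expect_equal(
      silhouette_widths(d, part)$sil_width,
      oracle_silhouette(unclass(as.matrix(d)), cl),
      tolerance = 1e-9
    )
  }
})

test_that("wcss has the documented closed forms on tiny inputs", {
  data <- make_dataset(c(1, 2, 3))
  one <- tibble::tibble(country = data$country, cluster = rep(1, 3))
  w <- wcss_suite(data, one)
  expect_equal(w$wcss, 2)
  expect_equal(w$avg_square_distance, 2 / 3)
  expect_equal(w$percentual_wcss, sqrt(2 / 3))

  singletons <- tibble::tibble(country = data$country, cluster = 1:3)
  expect_equal(wcss_suite(data, singletons)$wcss, 0)
  expect_equal(wcss_suite(data, singletons)$percentual_wcss, 0)
})

test_that("bcss behaves correctly at both degenerate extremes", {
  data <- make_dataset(c(10, 20, 40, 80))
  one <- tibble::tibble(country = data$country, cluster = rep(1, 4))
  b1 <- bcss_suite(data, one)
  expect_equal(b1$bcss_total, 0)
  expect_equal(b1$explained_variation, 0)

  singles <- tibble::tibble(country = data$country, cluster = 1:4)
  bs <- bcss_suite(data, singles)
  expect_equal(bs$bcss_total, bs$tss)
  expect_equal(bs$explained_variation, 1)
  expect_true(is.na(bs$bcss_wcss_ratio))
})

test_that("wcss and bcss match brute-force oracles and decompose the tss", {
  set.seed(29)
  for (rep in 1:15) {
    n <- sample(6:12, 1)
    data <- make_dataset(runif(n, 0, 100))
    cl <- sample(1:4, n, replace = TRUE)
    part <- tibble::tibble(country = data$country, cluster = cl)
    x <- as.matrix(data["anxiety_pct"])
    w <- wcss_suite(data, part)
    b <- bcss_suite(data, part)
    expect_equal(w$wcss, oracle_wcss(x, cl), tolerance = 1e-9)
    expect_equal(b$bcss_total, oracle_bcss(x, cl), tolerance = 1e-9)
    tss <- sum((x - mean(x))^2)
    expect_equal(w$wcss + b$bcss_total, tss, tolerance = 1e-9 * (1 + tss))
    expect_equal(w$percentual_wcss^2 * w$n, w$wcss, tolerance = 1e-9)
  }
})

test_that("splitting a cluster never increases the wcss", {
  set.seed(37)
  data <- make_dataset(runif(14, 0, 100))
  cl <- sample(1:3, 14, replace = TRUE)
  part <- tibble::tibble(country = data$country, cluster = cl)
  w0 <- wcss_suite(data, part)$wcss
  for (target in unique(cl)) {
    idx <- which(cl == target)
    if (length(idx) < 2) next
    cl2 <- cl
    cl2[idx[seq_len(ceiling(length(idx) / 2))]] <- max(cl) + 1
    w1 <- wcss_suite(data, tibble::tibble(country = data$country, cluster = cl2))$wcss
    expect_lte(w1, w0 + 1e-9)
  }
})

test_that("quality_report bundles consistent metrics and zero-noise data explain everything", {
  sim <- generate_anxiety(synthetic_spec(
    k = 2, cluster_means = c(40, 78), cluster_sds = c(0, 0),
    sizes = c(3, 3), paired_shift_mean = 0, paired_shift_sd = 0, seed = 2
  ))
  part <- dplyr::rename(sim$truth, cluster = cluster)
  q <- quality_report(sim$low, part)
  expect_s3_class(q, "anx_quality")
  expect_equal(q$bcss$explained_variation, 1.0)
  expect_equal(q$silhouette_mean, 1.0)
  g <- glance(q)
  expect_equal(g$k, 2)
  expect_equal(g$wcss + g$bcss_total, g$tss, tolerance = 1e-9)
  expect_equal(nrow(tidy(q)), 6)
})

test_that("select_k finds the true k with silhouette 1 on zero-noise data", {
  sim <- generate_anxiety(synthetic_spec(
    k = 3, cluster_means = c(20, 55, 90), cluster_sds = c(0, 0, 0),
    sizes = c(4, 4, 4), paired_shift_mean = 0, paired_shift_sd = 0, seed = 5
  ))
  ks <- select_k(sim$low, k_range = 2:6, fraction = 0.2)
  expect_equal(ks$chosen_k, 3)
  expect_equal(max(ks$profile$silhouette_mean), 1.0)
  expect_equal(ks$candidate_k, 3)
})

test_that("select_k reports the dendrogram-cut candidate and warns on disagreement", {
  t1 <- anx_fixture("table1_low")
  expect_warning(
    ks <- select_k(t1, k_range = 2:8, fraction = 0.20),
    class = "anx_kselect_disagreement"
  )
  # the 20% cut suggests the published five clusters; the silhouette
  # profile peaks one step later on this rounded data
  expect_equal(ks$candidate_k, 5)
  expect_equal(ks$profile$silhouette_mean[ks$profile$k == 5], 0.59, tolerance = 0.005)
  expect_error(select_k(t1, k_range = 1:3), class = "anx_validation_error")
})
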