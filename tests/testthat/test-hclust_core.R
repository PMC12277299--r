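test_that("distances are absolute differences for one feature", {
  d <- anx_distances(anx_fixture("table1_low"))
  expect_equal(d["Brazil", "Czech Republic"], 47)
  expect_true(all(diag(unclass(d)) == 0))
  expect_equal(unclass(d), t(unclass(d)))
})

test_that("multi-feature distances match a brute-force pairwise loop", {
  set.seed(11)
  data <- tibble::tibble(
    country = letters[1:5], group = "low",
    anxiety_pct = runif(5, 0, 100), f2 = rnorm(5), f3 = rnorm(5)
  )
  d <- anx_distances(data, cols = c("anxiety_pct", "f2", "f3"))
  expect_equal(unname(unclass(d)),
    oracle_distance(as.matrix(data[c("anxiety_pct", "f2", "f3")])),
    tolerance = 1e-12
  )
})

test_that("two points at distance 5 merge at height 5 under every linkage", {
  data <- make_dataset(c(10, 15))
  d <- anx_distances(data)
  for (lk in c("ward", "complete", "average", "single")) {
    dn <- anx_agglomerate(d, lk)
    expect_equal(dn$height, 5)
    expect_equal(dn$size, 2L)
  }
})

test_that("a forced merge order is respected: {0, 1, 10} under complete linkage", {
  data <- make_dataset(c(0, 1, 10), countries = c("a", "b", "c"))
  dn <- anx_agglomerate(anx_distances(data), "complete")
  expect_equal(dn$height, c(1, 10))
  expect_equal(cut_to_k(dn, 2)$cluster, c(1, 1, 2))
})

test_that("agglomeration matches an exhaustive pair-rescan oracle on tie-free data", {
  set.seed(21)
  for (rep in 1:12) {
    n <- sample(4:7, 1)
    data <- make_dataset(runif(n, 0, 100))
    d <- anx_distances(data)
    for (lk in c("complete", "average", "single")) {
      dn <- anx_agglomerate(d, lk)
      orc <- oracle_agglomerate(unclass(as.matrix(d)), lk)
      expect_equal(dn$height, orc$heights, tolerance = 1e-12)
      for (k in 2:(n - 1)) {
        orc_part <- orc$partitions[[n - k]]
        orc_cl <- integer(n)
        for (ci in seq_along(orc_part)) orc_cl[orc_part[[ci]]] <- ci
        expect_equal(canon(cut_to_k(dn, k)$cluster), canon(orc_cl))
      }
    }
  }
})

test_that("heights and cuts agree with stats::hclust on tie-free data", {
  set.seed(5)
  data <- make_dataset(runif(25, 0, 100))
  d <- anx_distances(data)
  ref_method <- c(ward = "ward.D2", complete = "complete", average = "average", single = "single")
  for (lk in names(ref_method)) {
    dn <- anx_agglomerate(d, lk)
    hc <- stats::hclust(stats::dist(data$anxiety_pct), method = ref_method[[lk]])
    expect_equal(dn$height, hc$height, tolerance = 1e-9)
    for (k in c(2, 4, 7)) {
      expect_equal(canon(cut_to_k(dn, k)$cluster), canon(unname(stats::cutree(hc, k))))
    }
  }
})

test_that("merge heights are monotone non-decreasing for every linkage", {
  set.seed(9)
  for (rep in 1:10) {
    data <- make_dataset(sample(0:100, 15, replace = TRUE))
    d <- anx_distances(data)
    for (lk in c("ward", "complete", "average", "single")) {
      dn <- anx_agglomerate(d, lk)
      expect_true(all(diff(dn$height) >= -1e-10))
    }
  }
})

test_that("1-D clusters are intervals of the sorted values", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 18
    data <- make_dataset(sample(0:100, n, replace = TRUE))
    d <- anx_distances(data)
    for (lk in c("ward", "complete", "average")) {
      dn <- anx_agglomerate(d, lk)
      for (k in c(2, 4, 6)) {
        part <- cut_to_k(dn, k)
        ranges <- part |>
          dplyr::mutate(value = data$anxiety_pct) |>
          dplyr::group_by(cluster) |>
          dplyr::summarize(lo = min(value), hi = max(value), .groups = "drop") |>
          dplyr::arrange(lo)
        # intervals must not overlap (equal boundary values may share a rank)
        expect_true(all(ranges$hi[-nrow(ranges)] <= ranges$lo[-1]))
      }
    }
  }
})

test_that("the dendrogram does not depend on the row order of the input", {
  set.seed(13)
  data <- make_dataset(sample(30:80, 20, replace = TRUE))
  d1 <- anx_agglomerate(anx_distances(data), "ward")
  perm <- sample(nrow(data))
  d2 <- anx_agglomerate(anx_distances(data[perm, ]), "ward")
  expect_equal(d1$height, d2$height)
  for (k in c(2, 3, 5)) {
    p1 <- cut_to_k(d1, k)
    p2 <- cut_to_k(d2, k)
    expect_equal(recovery_score(p1, p2), 1.0)
  }
})

test_that("cut_to_k handles the k = 1 and k = n extremes", {
  data <- make_dataset(c(1, 5, 30, 70))
  dn <- anx_agglomerate(anx_distances(data), "ward")
  expect_equal(cut_to_k(dn, 1)$cluster, rep(1L, 4))
  expect_equal(cut_to_k(dn, 4)$cluster, 1:4)
  expect_error(cut_to_k(dn, 0), class = "anx_validation_error")
  expect_error(cut_to_k(dn, 5), class = "anx_validation_error")
})

test_that("cut_at_fraction uses a strict threshold on the maximum height", {
  data <- make_dataset(c(1, 5, 30, 70))
  dn <- anx_agglomerate(anx_distances(data), "ward")
  # at fraction 1 the top merge is not below its own height: 2 clusters
  expect_equal(attr(cut_at_fraction(dn, 1), "k"), 2)
  # below the smallest merge height: all singletons
  tiny <- 0.5 * min(dn$height) / max(dn$height)
  expect_equal(attr(cut_at_fraction(dn, tiny), "k"), 4)
  expect_error(cut_at_fraction(dn, 0), class = "anx_validation_error")
  expect_error(cut_at_fraction(dn, 1.2), class = "anx_validation_error")
})

test_that("cut_at_fraction and cut_to_k agree whenever they produce the same k", {
  set.seed(17)
  data <- make_dataset(runif(20, 0, 100))
  dn <- anx_agglomerate(anx_distances(data), "ward")
  for (f in c(0.1, 0.2, 0.35, 0.6, 0.9)) {
    pf <- cut_at_fraction(dn, f)
    pk <- cut_to_k(dn, attr(pf, "k"))
    expect_equal(pf$cluster, pk$cluster)
  }
})

test_that("newick export has the documented trivial form and parses with 56 leaves", {
  two <- make_dataset(c(0, 4), countries = c("A", "B"))
  dn <- anx_agglomerate(anx_distances(two), "single")
  expect_equal(dendro_newick(dn), "(A:4,B:4);")

  skip_if_not_installed("ape")
  big <- anx_agglomerate(anx_distances(anx_fixture("table2_high")), "ward")
  tree <- ape::read.tree(text = dendro_newick(big))
  expect_s3_class(tree, "phylo")
  expect_equal(length(tree$tip.label), 56)
})

test_that("json export round-trips the merge list exactly", {
  dn <- anx_agglomerate(anx_distances(anx_fixture("table1_low")), "ward")
  back <- dendro_from_json(dendro_json(dn))
  expect_equal(back$merge, dn$merge)
  expect_equal(back$height, dn$height)
  expect_equal(back$labels, dn$labels)
  expect_equal(back$linkage, dn$linkage)
})

test_that("degenerate inputs are rejected", {
  expect_error(anx_agglomerate(matrix(0, 1, 1)), class = "anx_validation_error")
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(anx_agglomerate(bad), class = "anx_validation_error")
})
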