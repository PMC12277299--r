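#' Pairwise Euclidean distance matrix between countries
#'
#' For the single default feature (`anxiety_pct`) the Euclidean distance
#' between two countries reduces to the absolute difference of their
#' percentages; with several feature columns it is the usual
#' `sqrt(sum((x_i - x_j)^2))` straight-line distance.
#'
#' @param data A country dataset (tibble with a `country` column).
#' @param cols Character vector of numeric feature columns. Default
#'   `"anxiety_pct"`.
#' @return An `anx_dist` object: a symmetric numeric matrix with zero
#'   diagonal and country names as dimnames.
#' @export
#' @examples
#' d <- anx_distances(anx_fixture("table1_low"))
#' d["Brazil", "Czech Republic"] # |82 - 35| = 47
anx_distances <- function(data, cols = "anxiety_pct") {
  data <- validate_anxiety(data)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing feature column(s): ", paste(missing_cols, collapse = ", ")),
      class = "anx_schema_error"
    )
  }
  x <- as.matrix(data[cols])
  if (!all(is.finite(x))) {
    abort("non-finite feature value", class = "anx_validation_error")
  }
  m <- as.matrix(stats::dist(x, method = "euclidean"))
  dimnames(m) <- list(data$country, data$country)
  structure(m, class = c("anx_dist", class(m)))
}

#' @export
print.anx_dist <- function(x, ...) {
  cat("<anx_dist> ", nrow(x), " countries\n", sep = "")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))), drop = FALSE], ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Agglomerative hierarchical clustering
#'
#' Bottom-up clustering from a distance matrix: start from singletons and
#' repeatedly merge the two closest clusters under the chosen linkage,
#' recording the linkage distance as the merge height. The implementation
#' uses the nearest-neighbor-chain algorithm with Lance-Williams distance
#' updates (the standard O(n^2) scheme for reducible linkages); the
#' resulting merge list is then sorted by height into a monotone
#' dendrogram. Ward linkage uses the variance-increase criterion with the
#' conventional square-root scaling, so heights are on the scale of the
#' input distances and directly comparable to standard implementations.
#'
#' Results are independent of the row order of the input: leaves are
#' processed in a canonical order (labels sorted in the C locale), and
#' ties between equally close candidates are resolved toward the current
#' chain partner and then toward the earlier slot in that canonical
#' order. Integer-valued percentages produce many exact ties, so a fixed
#' convention like this is what makes the dendrogram reproducible.
#'
#' @param dist An [anx_distances()] matrix (or any symmetric matrix with
#'   labels as dimnames).
#' @param linkage `"ward"`, `"complete"`, `"average"` or `"single"`.
#' @return An `anx_dendrogram`: list with `labels` (leaf order = input row
#'   order), `merge` (an (n-1) x 2 matrix in `stats::hclust` convention:
#'   negative entries are leaves, positive entries earlier merges),
#'   `height`, `size` (cluster size after each merge) and `linkage`.
#' @export
#' @examples
#' d <- anx_distances(anx_fixture("table1_low"))
#' dn <- anx_agglomerate(d, "ward")
#' cut_at_fraction(dn, 0.20)
anx_agglomerate <- function(dist, linkage = c("ward", "complete", "average", "single")) {
  linkage <- match.arg(linkage)
  m <- unclass(as.matrix(dist))
  n <- nrow(m)
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("X", seq_len(n))
  if (n < 2) abort("need at least 2 countries", class = "anx_validation_error")
  if (any(!is.finite(m)) || any(m < 0) || any(abs(m - t(m)) > 1e-8)) {
    abort("distance matrix must be finite, non-negative and symmetric",
      class = "anx_validation_error"
    )
  }
  labels <- rownames(m)

  # Canonical leaf order: sorted labels (C locale), so the tree does not
  # depend on how the rows happened to be ordered.
  perm <- order(labels, method = "radix")
  D <- m[perm, perm]
  diag(D) <- Inf

  size <- rep(1L, n)
  chain <- integer(0)
  slot_a <- integer(n - 1L)
  slot_b <- integer(n - 1L)
  height <- numeric(n - 1L)

  for (s in seq_len(n - 1L)) {
    if (length(chain) == 0) chain <- which(size > 0)[1L]
    repeat {
      x <- chain[length(chain)]
      if (length(chain) > 1) {
        y <- chain[length(chain) - 1L]
        cmin <- D[x, y]
      } else {
        y <- NA_integer_
        cmin <- Inf
      }
      for (k in seq_len(n)) {
        if (size[k] == 0L || k == x) next
        if (D[x, k] < cmin) {
          cmin <- D[x, k]
          y <- k
        }
      }
      if (length(chain) > 1 && identical(y, chain[length(chain) - 1L])) break
      chain <- c(chain, y)
    }
    x <- chain[length(chain)]
    y <- chain[length(chain) - 1L]
    chain <- head(chain, -2L)
    if (x > y) {
      tmp <- x
      x <- y
      y <- tmp
    }
    dxy <- D[x, y]
    nx <- size[x]
    ny <- size[y]
    slot_a[s] <- x
    slot_b[s] <- y
    height[s] <- dxy
    # Lance-Williams update; the merged cluster takes slot y.
    for (i in seq_len(n)) {
      if (size[i] == 0L || i == y || i == x) next
      d <- switch(linkage,
        ward = {
          t <- 1.0 / (nx + ny + size[i])
          sqrt((size[i] + nx) * t * D[i, x] * D[i, x] +
            (size[i] + ny) * t * D[i, y] * D[i, y] -
            size[i] * t * dxy * dxy)
        },
        complete = max(D[i, x], D[i, y]),
        average = (nx * D[i, x] + ny * D[i, y]) / (nx + ny),
        single = min(D[i, x], D[i, y])
      )
      D[i, y] <- d
      D[y, i] <- d
    }
    size[y] <- nx + ny
    size[x] <- 0L
    D[x, ] <- Inf
    D[, x] <- Inf
  }

  # Sort merges by height (stable) and rebuild hclust-style codes: each
  # slot points at the latest node containing it in sorted order.
  ord <- order(height)
  merge <- matrix(0L, n - 1L, 2L)
  msize <- integer(n - 1L)
  node <- -perm # slot -> current node code (negative leaf = original row)
  root <- seq_len(n) # union-find over slots
  find <- function(a) {
    while (root[a] != a) a <- root[a]
    a
  }
  for (r in seq_len(n - 1L)) {
    s <- ord[r]
    ra <- find(slot_a[s])
    rb <- find(slot_b[s])
    pair <- c(node[ra], node[rb])
    # normalize rows as hclust does: leaves (by index) before earlier merges
    pair <- pair[order(pair >= 0, abs(pair))]
    merge[r, ] <- pair
    child_size <- function(code) if (code < 0) 1L else msize[code]
    msize[r] <- child_size(merge[r, 1]) + child_size(merge[r, 2])
    root[rb] <- ra
    node[ra] <- r
  }
  new_anx_dendrogram(labels, merge, height[ord], msize, linkage)
}

new_anx_dendrogram <- function(labels, merge, height, size, linkage) {
  n <- length(labels)
  stopifnot(nrow(merge) == n - 1L, length(height) == n - 1L)
  if (any(diff(height) < -1e-8 * (1 + max(height)))) {
    abort("merge heights must be non-decreasing for the supported linkages",
      class = "anx_validation_error"
    )
  }
  structure(
    list(
      labels = labels, merge = merge, height = as.numeric(height),
      size = as.integer(size), linkage = linkage
    ),
    class = "anx_dendrogram"
  )
}

#' @export
print.anx_dendrogram <- function(x, ...) {
  cat("<anx_dendrogram> ", length(x$labels), " leaves, ", x$linkage,
    " linkage, max height ", format(max(x$height), digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

# Leaf-index members of each internal node, in merge order.
merge_members <- function(dendro, n_merges = nrow(dendro$merge)) {
  members <- vector("list", n_merges)
  for (s in seq_len(n_merges)) {
    pick <- function(code) if (code < 0) -code else members[[code]]
    members[[s]] <- c(pick(dendro$merge[s, 1]), pick(dendro$merge[s, 2]))
  }
  members
}

# Perform the first `n_merges` merges and return integer cluster codes per
# leaf, numbered by first appearance in leaf order (cutree convention).
cut_codes <- function(dendro, n_merges) {
  n <- length(dendro$labels)
  comp <- seq_len(n)
  if (n_merges > 0) {
    members <- merge_members(dendro, n_merges)
    for (s in seq_len(n_merges)) comp[members[[s]]] <- n + s
  }
  as.integer(factor(comp, levels = unique(comp)))
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last `k - 1` merges; the connected components that remain are
#' the clusters. Clusters are numbered by first appearance in leaf order.
#'
#' @param dendro An [anx_agglomerate()] result.
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return A partition tibble with columns `country` and `cluster`
#'   (integer).
#' @export
cut_to_k <- function(dendro, k) {
  n <- length(dendro$labels)
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 1 || k > n) {
    abort(paste0("k must be an integer in [1, ", n, "]"), class = "anx_validation_error")
  }
  tibble::tibble(
    country = dendro$labels,
    cluster = cut_codes(dendro, n - as.integer(k))
  )
}

#' Cut a dendrogram at a fraction of its maximum merge height
#'
#' The threshold is `fraction` times the maximum merge height; clusters are
#' the components formed by all merges with height strictly below the
#' threshold (a horizontal line across the dendrogram at that fraction of
#' the y-axis). At `fraction = 1` the top merge is not below its own
#' height, so a dendrogram with a unique maximum yields two clusters.
#'
#' @inheritParams cut_to_k
#' @param fraction Height fraction in (0, 1].
#' @return A partition tibble (`country`, `cluster`) with attributes `k`
#'   and `threshold`.
#' @export
cut_at_fraction <- function(dendro, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
    !is.finite(fraction) || fraction <= 0 || fraction > 1) {
    abort("fraction must be in (0, 1]", class = "anx_validation_error")
  }
  n <- length(dendro$labels)
  thr <- fraction * max(dendro$height)
  nm <- sum(dendro$height < thr)
  out <- tibble::tibble(country = dendro$labels, cluster = cut_codes(dendro, nm))
  attr(out, "k") <- n - nm
  attr(out, "threshold") <- thr
  out
}

#' @export
as.hclust.anx_dendrogram <- function(x, ...) {
  n <- length(x$labels)
  members <- merge_members(x)
  leaf_order <- if (n == 1) 1L else members[[n - 1L]]
  structure(
    list(
      merge = x$merge, height = x$height, order = leaf_order,
      labels = x$labels, method = x$linkage,
      call = match.call(), dist.method = "euclidean"
    ),
    class = "hclust"
  )
}

#' @method tidy anx_dendrogram
#' @export
tidy.anx_dendrogram <- function(x, ...) {
  tibble::tibble(
    merge = seq_along(x$height),
    member_a = x$merge[, 1], member_b = x$merge[, 2],
    height = x$height, new_size = x$size
  )
}

#' @method glance anx_dendrogram
#' @export
glance.anx_dendrogram <- function(x, ...) {
  tibble::tibble(
    n_leaves = length(x$labels), linkage = x$linkage,
    max_height = max(x$height)
  )
}

#' Export a dendrogram as a newick string
#'
#' Branch lengths are derived from merge heights: the branch from a node to
#' its parent has length `parent height - node height` (leaves have height
#' 0). Labels containing newick metacharacters or spaces are single-quoted.
#'
#' @inheritParams cut_to_k
#' @return A single newick string terminated by `;`.
#' @export
dendro_newick <- function(dendro) {
  fmt <- function(x) sprintf("%.10g", x)
  qlab <- function(lab) {
    if (grepl("[ ,():;'\\[\\]]", lab)) {
      paste0("'", gsub("'", "''", lab), "'")
    } else {
      lab
    }
  }
  rec <- function(code, parent_h) {
    if (code < 0) {
      paste0(qlab(dendro$labels[-code]), ":", fmt(parent_h))
    } else {
      h <- dendro$height[code]
      paste0(
        "(", rec(dendro$merge[code, 1], h), ",",
        rec(dendro$merge[code, 2], h), "):", fmt(parent_h - h)
      )
    }
  }
  top <- nrow(dendro$merge)
  h <- dendro$height[top]
  paste0(
    "(", rec(dendro$merge[top, 1], h), ",",
    rec(dendro$merge[top, 2], h), ");"
  )
}

#' Export / import a dendrogram as JSON
#'
#' The JSON mirrors the merge list exactly (labels, linkage and one record
#' per merge with the two member codes, height and new cluster size), so
#' `dendro_from_json(dendro_json(x))` reproduces `x`.
#'
#' @inheritParams cut_to_k
#' @return `dendro_json()`: a JSON string. `dendro_from_json()`: an
#'   `anx_dendrogram`.
#' @export
dendro_json <- function(dendro) {
  as.character(jsonlite::toJSON(
    list(
      labels = dendro$labels,
      linkage = dendro$linkage,
      merges = data.frame(
        member_a = dendro$merge[, 1], member_b = dendro$merge[, 2],
        height = dendro$height, new_size = dendro$size
      )
    ),
    dataframe = "columns", digits = NA, auto_unbox = TRUE, pretty = TRUE
  ))
}

#' @rdname dendro_json
#' @param text A JSON string produced by `dendro_json()`.
#' @export
dendro_from_json <- function(text) {
  obj <- jsonlite::fromJSON(text)
  new_anx_dendrogram(
    labels = obj$labels,
    merge = cbind(as.integer(obj$merges$member_a), as.integer(obj$merges$member_b)),
    height = obj$merges$height,
    size = obj$merges$new_size,
    linkage = obj$linkage
  )
}
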