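# Independent brute-force oracles, written as plain double loops so they
# share no code path with the package implementations.

oracle_distance <- function(x) {
  n <- nrow(x)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- sqrt(sum((x[i, ] - x[j, ])^2))
    }
  }
  m
}

oracle_silhouette <- function(d, cl) {
  n <- length(cl)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i] & seq_len(n) != i)
    if (length(own) == 0) {
      s[i] <- 0
      next
    }
    a <- mean(d[i, own])
    b <- Inf
    for (c2 in setdiff(unique(cl), cl[i])) {
      b <- min(b, mean(d[i, cl == c2]))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  s
}

oracle_wcss <- function(x, cl) {
  tot <- 0
  for (c2 in unique(cl)) {
    xx <- x[cl == c2, , drop = FALSE]
    mu <- colMeans(xx)
    for (i in seq_len(nrow(xx))) tot <- tot + sum((xx[i, ] - mu)^2)
  }
  tot
}

oracle_bcss <- function(x, cl) {
  mu <- colMeans(x)
  tot <- 0
  for (c2 in unique(cl)) {
    xx <- x[cl == c2, , drop = FALSE]
    tot <- tot + nrow(xx) * sum((colMeans(xx) - mu)^2)
  }
  tot
}

# Adjusted Rand index straight from the contingency-table definition.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  exp_ <- sa * sb / choose(n, 2)
  denom <- (sa + sb) / 2 - exp_
  if (denom == 0) {
    return(if (sij == (sa + sb) / 2) 1 else 0)
  }
  (sij - exp_) / denom
}

# Exhaustive agglomeration: rescan every active cluster pair at each step
# and merge the global minimum under the linkage. Assumes tie-free input.
oracle_agglomerate <- function(d, linkage) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  link <- function(ci, cj) {
    dd <- d[ci, cj, drop = FALSE]
    switch(linkage,
      complete = max(dd),
      average = mean(dd),
      single = min(dd)
    )
  }
  while (length(clusters) > 1) {
    best <- Inf
    bi <- bj <- 0
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          v <- link(clusters[[i]], clusters[[j]])
          if (v < best) {
            best <- v
            bi <- i
            bj <- j
          }
        }
      }
    }
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
    heights <- c(heights, best)
    partitions[[length(partitions) + 1]] <- clusters
  }
  list(heights = heights, partitions = partitions)
}

# Canonical label vector: relabel clusters by first appearance so two
# partitions can be compared directly.
canon <- function(cl) as.integer(factor(cl, levels = unique(cl)))

make_dataset <- function(values, group = "low", countries = NULL) {
  if (is.null(countries)) countries <- sprintf("Country %02d", seq_along(values))
  tibble::tibble(country = countries, group = group, anxiety_pct = values)
}
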