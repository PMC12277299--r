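# Round half away from zero, the convention used for printed cluster means
# (a 77.89 mean displays as 78).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Configuration for a full clustering analysis
#'
#' @param low,high Country datasets for the two activity groups: a tibble,
#'   a bundled fixture name (e.g. `"table1_low"`), or a CSV path readable
#'   by [read_anxiety_csv()]. Either may be `NULL` to analyse one group.
#' @param paired Optional paired table for the group comparison (tibble,
#'   fixture name `"table3_paired"`, or CSV path).
#' @param linkage Linkage method, default `"ward"`.
#' @param fraction Dendrogram cut fraction, default `0.20`.
#' @param k_range Candidate cluster counts for the silhouette profile.
#' @param sensitivity_fractions Alternate cut fractions for
#'   [sensitivity_analysis()], default `c(0.15, 0.25)`.
#' @param seed Integer seed recorded in the run log (the pipeline itself is
#'   deterministic; the seed matters when inputs are generated).
#' @return An `anx_config` list.
#' @export
analysis_config <- function(low = NULL, high = NULL, paired = NULL,
                            linkage = "ward", fraction = 0.20,
                            k_range = 2:10,
                            sensitivity_fractions = c(0.15, 0.25),
                            seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1 ||
    any(sensitivity_fractions <= 0) || any(sensitivity_fractions > 1)) {
    abort("fractions must lie in (0, 1]", class = "anx_validation_error")
  }
  structure(
    list(
      low = low, high = high, paired = paired,
      linkage = match.arg(linkage, c("ward", "complete", "average", "single")),
      fraction = fraction, k_range = k_range,
      sensitivity_fractions = sensitivity_fractions,
      seed = as.integer(seed)
    ),
    class = "anx_config"
  )
}

resolve_input <- function(x, group) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) return(validate_anxiety(x))
  if (is.character(x) && length(x) == 1) {
    if (file.exists(x)) {
      if (group == "paired") {
        return(readr::read_csv(x, show_col_types = FALSE, progress = FALSE))
      }
      return(read_anxiety_csv(x, group = group))
    }
    if (group == "paired") return(anx_fixture(x))
    return(anx_fixture(x))
  }
  abort(paste0("cannot resolve input for group ", group), class = "anx_io_error")
}

#' Name clusters by their mean anxiety level
#'
#' Clusters are ordered by descending mean percentage; those whose mean
#' exceeds the group grand mean are labeled `H-1`, `H-2`, ... (highest
#' first) and the rest `L-1`, `L-2`, ... (again highest first).
#'
#' @inheritParams wcss_suite
#' @return The partition tibble with an added `label` column.
#' @export
label_clusters <- function(data, partition, cols = "anxiety_pct") {
  data <- validate_anxiety(data)
  cl <- align_partition(partition, data$country)
  x <- rowMeans(as.matrix(data[cols]))
  means <- vapply(split(x, cl), mean, numeric(1))
  grand <- mean(x)
  ord <- order(-means)
  side <- ifelse(means[ord] > grand, "H", "L")
  lab <- paste0(side, "-", stats::ave(seq_along(ord), side, FUN = seq_along))
  labels <- setNames(lab, names(means)[ord])
  tibble::tibble(
    country = data$country, cluster = cl,
    label = unname(labels[as.character(cl)])
  )
}

group_analysis <- function(data, config) {
  d <- anx_distances(data)
  dendro <- anx_agglomerate(d, config$linkage)
  part <- cut_at_fraction(dendro, config$fraction)
  k <- attr(part, "k")
  labeled <- label_clusters(data, part)
  membership <- labeled |>
    dplyr::left_join(data[c("country", "anxiety_pct")], by = "country") |>
    dplyr::group_by(.data$label) |>
    dplyr::summarize(
      n = dplyr::n(),
      mean_pct = mean(.data$anxiety_pct),
      mean_pct_rounded = round_half_up(mean(.data$anxiety_pct)),
      countries = paste(.data$country, collapse = "; "),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$mean_pct))
  profile <- tryCatch(
    select_k(data,
      linkage = config$linkage,
      k_range = config$k_range[config$k_range <= nrow(data) - 1],
      fraction = config$fraction
    ),
    anx_kselect_disagreement = function(w) {
      suppressWarnings(select_k(data,
        linkage = config$linkage,
        k_range = config$k_range[config$k_range <= nrow(data) - 1],
        fraction = config$fraction
      ))
    }
  )
  list(
    data = data,
    dendrogram = dendro,
    newick = dendro_newick(dendro),
    json = dendro_json(dendro),
    k = k,
    partition = labeled,
    membership = membership,
    quality = quality_report(data, part, dist = d),
    kselect = profile
  )
}

#' Run the full analysis pipeline
#'
#' For each supplied activity group: compute distances, build the
#' dendrogram, cut it at the configured height fraction, name and
#' summarize the clusters (member countries and rounded mean percentages),
#' and compute the full quality report plus the silhouette-vs-k profile.
#' When a paired table is supplied, the per-country two-group comparison is
#' added. Everything is deterministic given the configuration.
#'
#' @param config An [analysis_config()].
#' @return An `anx_report` list with elements `groups` (named list with
#'   per-group results: `dendrogram`, `newick`, `json`, `k`, `partition`,
#'   `membership`, `quality`, `kselect`), `comparison` (or `NULL`) and
#'   `log`.
#' @export
#' @examples
#' rep <- run_analysis(analysis_config(low = "table1_low"))
#' rep$groups$low$membership
run_analysis <- function(config) {
  if (!inherits(config, "anx_config")) abort("need an analysis_config()", class = "anx_validation_error")
  groups <- list()
  for (g in c("low", "high")) {
    data <- resolve_input(config[[g]], g)
    if (!is.null(data)) groups[[g]] <- group_analysis(data, config)
  }
  if (length(groups) == 0) {
    abort("stage input: no dataset supplied", class = "anx_io_error")
  }
  paired <- resolve_input(config$paired, "paired")
  comparison <- if (!is.null(paired)) compare_all(paired) else NULL
  structure(
    list(
      groups = groups,
      comparison = comparison,
      log = list(
        seed = config$seed, linkage = config$linkage,
        fraction = config$fraction,
        k_range = range(config$k_range),
        package_version = as.character(utils::packageVersion("anxclust"))
      ),
      config = config
    ),
    class = "anx_report"
  )
}

#' @export
print.anx_report <- function(x, ...) {
  cat("<anx_report> linkage ", x$log$linkage, ", cut fraction ",
    x$log$fraction, "\n",
    sep = ""
  )
  for (g in names(x$groups)) {
    cat("\n== ", g, " activity group: k = ", x$groups[[g]]$k, " ==\n", sep = "")
    print(x$groups[[g]]$membership)
  }
  if (!is.null(x$comparison)) {
    cat("\n== paired comparison ==\n")
    print(x$comparison)
  }
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes, per activity group, the dendrogram (`.nwk` and `.json`), the
#' labeled partition and the cluster membership table (CSV), and the
#' quality metrics (JSON); plus the paired comparison (CSV) and a run log
#' (JSON and plain text). Output is byte-identical across runs of the same
#' configuration.
#'
#' @param report An [run_analysis()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(name, writer) {
    path <- file.path(dir, name)
    writer(path)
    paths <<- c(paths, path)
  }
  for (g in names(report$groups)) {
    res <- report$groups[[g]]
    emit(paste0(g, "_dendrogram.nwk"), function(p) writeLines(res$newick, p))
    emit(paste0(g, "_dendrogram.json"), function(p) writeLines(res$json, p))
    emit(paste0(g, "_partition.csv"), function(p) readr::write_csv(res$partition, p, progress = FALSE))
    emit(paste0(g, "_membership.csv"), function(p) readr::write_csv(res$membership, p, progress = FALSE))
    emit(paste0(g, "_quality.json"), function(p) {
      writeLines(as.character(jsonlite::toJSON(
        c(
          as.list(glance(res$quality)),
          list(silhouette = res$quality$silhouette)
        ),
        dataframe = "columns", digits = NA, auto_unbox = TRUE, pretty = TRUE
      )), p)
    })
  }
  if (!is.null(report$comparison)) {
    emit("comparison.csv", function(p) readr::write_csv(report$comparison, p, progress = FALSE))
  }
  emit("run_log.json", function(p) {
    writeLines(as.character(jsonlite::toJSON(report$log,
      digits = NA, auto_unbox = TRUE, pretty = TRUE
    )), p)
  })
  emit("run_log.txt", function(p) {
    writeLines(c(
      paste0("seed: ", report$log$seed),
      paste0("linkage: ", report$log$linkage),
      paste0("fraction: ", report$log$fraction),
      paste0("anxclust version: ", report$log$package_version)
    ), p)
  })
  invisible(paths)
}

#' Cut-fraction sensitivity analysis
#'
#' Recuts each group's dendrogram at the configured alternate height
#' fractions and scores every alternate partition against the
#' default-fraction partition with the adjusted Rand index
#' ([recovery_score()]).
#'
#' @param config An [analysis_config()]; `sensitivity_fractions` supplies
#'   the alternates (the default fraction is always included).
#' @return A tibble with columns `group`, `fraction`, `k`,
#'   `ari_vs_default`; the partitions themselves are attached as the
#'   `"partitions"` attribute.
#' @export
#' @examples
#' sensitivity_analysis(analysis_config(low = "table1_low"))
sensitivity_analysis <- function(config) {
  fractions <- sort(unique(c(config$fraction, config$sensitivity_fractions)))
  if (length(fractions) < 2) {
    abort("need at least 2 distinct fractions", class = "anx_validation_error")
  }
  rows <- list()
  partitions <- list()
  for (g in c("low", "high")) {
    data <- resolve_input(config[[g]], g)
    if (is.null(data)) next
    dendro <- anx_agglomerate(anx_distances(data), config$linkage)
    ref <- cut_at_fraction(dendro, config$fraction)
    for (f in fractions) {
      part <- cut_at_fraction(dendro, f)
      partitions[[paste(g, f, sep = "_")]] <- part
      rows[[length(rows) + 1]] <- tibble::tibble(
        group = g, fraction = f, k = attr(part, "k"),
        ari_vs_default = recovery_score(ref, part)
      )
    }
  }
  if (length(rows) == 0) abort("no dataset supplied", class = "anx_io_error")
  out <- dplyr::bind_rows(rows)
  attr(out, "partitions") <- partitions
  out
}
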