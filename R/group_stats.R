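tier_levels <- c("ns", "p<0.05", "p<0.01", "p<0.001")

# |z| cutoffs for two-sided 0.05 / 0.01 / 0.001
significance_tier <- function(z) {
  az <- abs(z)
  factor(
    dplyr::case_when(
      az >= 3.29 ~ "p<0.001",
      az >= 2.58 ~ "p<0.01",
      az >= 1.96 ~ "p<0.05",
      TRUE ~ "ns"
    ),
    levels = tier_levels, ordered = TRUE
  )
}

#' Compare low- and high-activity anxiety percentages for a country
#'
#' Computes the difference in group means (`p_high - p_low`, so negative
#' values mean lower anxiety among physically active students), its
#' standard error under the independent-groups rule
#' `sqrt(se_low^2 + se_high^2)`, the Z statistic `diff / se_diff`, and a
#' significance tier from the two-sided cutoffs 1.96 / 2.58 / 3.29
#' (p < 0.05 / 0.01 / 0.001; the last is the "three standard deviations"
#' rule).
#'
#' All arguments are vectorized, so a whole paired table can be compared in
#' one call (see [compare_all()]).
#'
#' @param p_low,p_high Group mean percentages.
#' @param se_low,se_high Positive standard errors of the group means.
#' @param country Optional country name(s), carried through.
#' @return A tibble with the inputs plus `diff`, `se_diff`, `z`, `tier`.
#' @export
#' @examples
#' compare_groups(57.2, 2.42, 50.2, 0.86, country = "Austria")
compare_groups <- function(p_low, se_low, p_high, se_high, country = NULL) {
  if (anyNA(c(p_low, se_low, p_high, se_high))) {
    abort("missing mean or standard error", class = "anx_validation_error")
  }
  if (any(se_low <= 0) || any(se_high <= 0)) {
    abort("standard errors must be positive", class = "anx_validation_error")
  }
  diff <- p_high - p_low
  se_diff <- sqrt(se_low^2 + se_high^2)
  z <- diff / se_diff
  out <- tibble::tibble(
    p_low = p_low, se_low = se_low, p_high = p_high, se_high = se_high,
    diff = diff, se_diff = se_diff, z = z, tier = significance_tier(z)
  )
  if (!is.null(country)) out <- dplyr::bind_cols(tibble::tibble(country = country), out)
  out
}

#' Compare every country in a paired table
#'
#' Applies [compare_groups()] row-wise to a paired table with columns
#' `country`, `p_low`, `se_low`, `p_high`, `se_high` (the
#' `"table3_paired"` fixture layout). An aggregate summary row (e.g. the
#' OECD average, flagged by an `aggregate` column) is compared with the
#' same formula from its supplied aggregate means and standard errors.
#'
#' @param paired A paired table as above.
#' @return A tibble of per-row comparisons; the `aggregate` flag is
#'   carried through when present.
#' @export
#' @examples
#' compare_all(anx_fixture("table3_paired"))
compare_all <- function(paired) {
  required <- c("country", "p_low", "se_low", "p_high", "se_high")
  missing_cols <- setdiff(required, names(paired))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "anx_schema_error"
    )
  }
  out <- compare_groups(
    paired$p_low, paired$se_low, paired$p_high, paired$se_high,
    country = paired$country
  )
  if ("aggregate" %in% names(paired)) {
    out$aggregate <- paired$aggregate
  }
  out
}

#' Chi-square test of two simple proportions
#'
#' Reconstructs the 2x2 success/failure table implied by two proportions
#' and their sample sizes and computes the Pearson chi-square statistic
#' (1 degree of freedom, no continuity correction) with its p-value. When
#' any expected cell count falls below 1 the result is flagged.
#'
#' @param p1,p2 Proportions in \[0, 1\].
#' @param n1,n2 Group sample sizes (>= 1).
#' @return A one-row tibble: `chi2`, `df`, `p_value`, `small_expected`.
#' @export
#' @examples
#' chi2_two_proportions(0.5, 100, 0.7, 100)
chi2_two_proportions <- function(p1, n1, p2, n2) {
  if (any(c(p1, p2) < 0) || any(c(p1, p2) > 1) || any(c(n1, n2) < 1)) {
    abort("need proportions in [0, 1] and sizes >= 1", class = "anx_validation_error")
  }
  obs <- rbind(
    c(p1 * n1, (1 - p1) * n1),
    c(p2 * n2, (1 - p2) * n2)
  )
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  if (any(expected == 0)) {
    # pooled proportion 0 or 1: both samples identical on the tested margin
    chi2 <- 0
  } else {
    chi2 <- sum((obs - expected)^2 / expected)
  }
  tibble::tibble(
    chi2 = chi2, df = 1L,
    p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
    small_expected = any(expected < 1)
  )
}
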