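# Group-comparison statistics: the normality/variance-driven test-selection
# tree, significance labels, per-group summaries and redox-ratio arithmetic.

#' Significance label for a p-value
#'
#' GraphPad-style mapping: `ns` for p > 0.05, `*` for p <= 0.05, `**` for
#' p <= 0.01, `***` for p <= 0.001, `****` for p <= 0.0001.
#'
#' @param p P-value(s) in `[0, 1]`.
#' @return Character vector of labels.
#' @examples
#' stars_label(c(0.2, 0.03, 0.00005))
#' @export
stars_label <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("`p` must lie in [0, 1].", class = "flimredox_parameter_error")
  }
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns")) |> as.character()
}

# Exact two-sided Mann-Whitney p by full enumeration of group labelings.
# Handles ties (the U statistic is computed from midranks on every labeling).
# Feasible for pooled n up to ~20.
mann_whitney_exact <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  # two-sided: as extreme or more extreme in distance from the null mean
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
  list(statistic = u_obs, p_value = p)
}

# Mann-Whitney U with the policy: exact enumeration for pooled n <= 20,
# otherwise normal approximation with tie correction (continuity-corrected).
mann_whitney_test <- function(a, b) {
  ties <- anyDuplicated(c(a, b)) > 0
  if (length(a) + length(b) <= 20) {
    res <- mann_whitney_exact(a, b)
    return(list(statistic = res$statistic, p_value = res$p_value,
                exact = TRUE))
  }
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = !ties,
                correct = TRUE)
  )
  p <- wt$p.value
  if (!is.finite(p)) p <- 1  # degenerate: zero rank variance (all tied)
  list(statistic = unname(wt$statistic), p_value = p, exact = !ties)
}

# Median-centred (Brown-Forsythe) Levene test for two groups.
levene_p <- function(a, b) {
  values <- c(a, b)
  grp <- factor(rep(c("A", "B"), c(length(a), length(b))))
  out <- car::leveneTest(values, grp, center = median)
  out[["Pr(>F)"]][1]
}

#' Select and run the two-group significance test
#'
#' Implements the test-selection rule used throughout the analysis: each
#' group is checked for normality with Shapiro-Wilk at level `alpha`; if
#' either group rejects, a two-sided Mann-Whitney U test is used (exact
#' enumeration when the pooled sample is small, normal approximation with tie
#' correction otherwise). If both groups look normal, variance homogeneity is
#' checked with the median-centred Levene test at `alpha`: an unpaired
#' Student t-test when homogeneity holds, Welch's unpaired t-test otherwise.
#' All tests are two-sided. A constant-valued group (where Shapiro-Wilk is
#' undefined) falls to the Mann-Whitney branch with a warning.
#'
#' @param a,b Numeric samples, each with at least 3 observations.
#' @param alpha Level used for the normality and homogeneity checks (and for
#'   the `ns` cutoff of the significance label).
#' @return A one-row tibble: `test_name` (`"mann_whitney"`, `"t_unpaired"` or
#'   `"t_welch"`), `statistic`, `p_value`, `stars`, `n_a`, `n_b`.
#' @examples
#' choose_and_run_test(rnorm(30), rnorm(30, 1))
#' @export
choose_and_run_test <- function(a, b, alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3 || length(b) < 3) {
    abort("Each group needs at least 3 observations.",
          class = "flimredox_insufficient_sample_error")
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    abort("Samples must be finite.", class = "flimredox_parameter_error")
  }
  check_number(alpha, "alpha", lower = 1e-6, upper = 0.5)

  shapiro_p <- function(x) {
    if (length(unique(x)) < 3) return(NA_real_)
    shapiro.test(x)$p.value
  }
  pa <- shapiro_p(a); pb <- shapiro_p(b)
  degenerate <- is.na(pa) || is.na(pb)
  if (degenerate) {
    warn("Constant-valued group: normality not assessable, using Mann-Whitney.")
  }
  if (degenerate || pa < alpha || pb < alpha) {
    res <- mann_whitney_test(a, b)
    test_name <- "mann_whitney"
  } else if (levene_p(a, b) < alpha) {
    tt <- t.test(a, b, var.equal = FALSE)
    res <- list(statistic = unname(tt$statistic), p_value = tt$p.value)
    test_name <- "t_welch"
  } else {
    tt <- t.test(a, b, var.equal = TRUE)
    res <- list(statistic = unname(tt$statistic), p_value = tt$p.value)
    test_name <- "t_unpaired"
  }
  tibble(
    test_name = test_name,
    statistic = res$statistic,
    p_value = res$p_value,
    stars = stars_label(res$p_value),
    n_a = length(a), n_b = length(b)
  )
}

#' Summarize a per-cell quantity for one group
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of a fitted per-cell
#' quantity over converged fits only. `a1_over_a2` is computed per cell as
#' `a1 / a2` and then averaged (mean of per-cell ratios, matching the
#' per-cell violin summaries, not the ratio of means).
#'
#' @param records Per-cell tibble from [fit_cells()].
#' @param quantity One of `"tau_mean"`, `"a1_over_a2"`, `"tau_bound"`.
#' @param label Optional group label carried into the output.
#' @return A one-row tibble: `label`, `quantity`, `n`, `mean`, `sd`,
#'   `sd_defined` (FALSE when n = 1, where the sample SD is undefined and
#'   reported as 0).
#' @export
summarize_group <- function(records, quantity = c("tau_mean", "a1_over_a2",
                                                  "tau_bound"),
                            label = NA_character_) {
  quantity <- match.arg(quantity)
  rec <- dplyr::filter(records, .data$converged)
  if (nrow(rec) == 0) {
    abort("No converged records to summarize.",
          class = "flimredox_empty_group_error")
  }
  v <- switch(quantity,
              tau_mean = rec$tau_mean,
              a1_over_a2 = rec$a1 / rec$a2,
              tau_bound = rec$tau_bound)
  n <- length(v)
  tibble(
    label = label, quantity = quantity, n = n, mean = mean(v),
    sd = if (n > 1) sd(v) else 0,
    sd_defined = n > 1
  )
}

#' Per-cell values of a summary quantity
#'
#' @inheritParams summarize_group
#' @return Numeric vector over converged records.
#' @export
group_values <- function(records, quantity = c("tau_mean", "a1_over_a2",
                                               "tau_bound")) {
  quantity <- match.arg(quantity)
  rec <- dplyr::filter(records, .data$converged)
  switch(quantity,
         tau_mean = rec$tau_mean,
         a1_over_a2 = rec$a1 / rec$a2,
         tau_bound = rec$tau_bound)
}

#' Compare two fitted groups on the standard redox readouts
#'
#' Runs [choose_and_run_test()] on per-cell `tau_mean`, `a1/a2` and
#' `tau_bound` between two per-cell tables.
#'
#' @param records_a,records_b Per-cell tibbles from [fit_cells()].
#' @param label_a,label_b Group labels.
#' @param alpha Level for the test-selection tree.
#' @param quantities Which readouts to compare.
#' @return A tibble with one row per quantity: group labels and the
#'   [choose_and_run_test()] columns.
#' @export
compare_groups <- function(records_a, records_b,
                           label_a = "A", label_b = "B", alpha = 0.05,
                           quantities = c("tau_mean", "a1_over_a2",
                                          "tau_bound")) {
  rows <- lapply(quantities, function(q) {
    va <- group_values(records_a, q)
    vb <- group_values(records_b, q)
    if (length(va) < 3 || length(vb) < 3) {
      abort(sprintf("Fewer than 3 converged cells in a group for %s.", q),
            class = "flimredox_insufficient_sample_error")
    }
    res <- choose_and_run_test(va, vb, alpha = alpha)
    mutate(res, group_a = label_a, group_b = label_b, quantity = q,
           mean_a = mean(va), sd_a = sd(va),
           mean_b = mean(vb), sd_b = sd(vb))
  })
  out <- bind_rows(rows)
  select(out, "group_a", "group_b", "quantity", "n_a", "n_b",
         "mean_a", "sd_a", "mean_b", "sd_b",
         "test_name", "statistic", "p_value", "stars")
}

#' Redox ratios from cofactor concentrations
#'
#' Per-replicate ratios from measured concentrations of the four
#' pyridine-nucleotide pools: `NADH/NAD+`, `NADPH/NADP+`, and the combined
#' `NAD(P)H/NAD(P)+`. The combined ratio uses the pooled-sum convention
#' `(NADH + NADPH) / (NAD+ + NADP+)` by default; `combined = "mean_of_ratios"`
#' averages the two pair ratios instead.
#'
#' @param table Data frame with columns `nadh`, `nad`, `nadph`, `nadp` (same
#'   concentration units; one row per replicate). Extra columns (e.g.
#'   `sample`, `replicate`) are carried through.
#' @param combined `"pooled"` (default) or `"mean_of_ratios"`.
#' @return The input tibble with added columns `nadh_nad`, `nadph_nadp`,
#'   `nadph_nadp_combined`.
#' @examples
#' compute_redox_ratios(tibble::tibble(nadh = 2, nad = 4, nadph = 1, nadp = 1))
#' @export
compute_redox_ratios <- function(table, combined = c("pooled",
                                                     "mean_of_ratios")) {
  combined <- match.arg(combined)
  table <- as_tibble(table)
  need <- c("nadh", "nad", "nadph", "nadp")
  if (!all(need %in% names(table))) {
    abort(sprintf("`table` must have columns %s.",
                  paste(need, collapse = ", ")),
          class = "flimredox_parameter_error")
  }
  conc <- table[need]
  if (any(vapply(conc, function(x) any(!is.finite(x) | x < 0), logical(1)))) {
    abort("Concentrations must be finite and non-negative.",
          class = "flimredox_parameter_error")
  }
  if (any(table$nad <= 0) || any(table$nadp <= 0) ||
      any(table$nad + table$nadp <= 0)) {
    abort("Zero denominator: oxidized-pool concentrations must be positive.",
          class = "flimredox_undefined_ratio_error")
  }
  mutate(
    table,
    nadh_nad = .data$nadh / .data$nad,
    nadph_nadp = .data$nadph / .data$nadp,
    nadph_nadp_combined = if (combined == "pooled") {
      (.data$nadh + .data$nadph) / (.data$nad + .data$nadp)
    } else {
      (.data$nadh / .data$nad + .data$nadph / .data$nadp) / 2
    }
  )
}

#' Summarize redox ratios over replicates
#'
#' Mean and sample SD of each ratio, optionally per `sample` group.
#'
#' @param ratios Output of [compute_redox_ratios()].
#' @return A tibble with one row per (group x ratio): `ratio`, `n`, `mean`,
#'   `sd`.
#' @export
summarize_redox_ratios <- function(ratios) {
  long <- tidyr::pivot_longer(
    ratios, c("nadh_nad", "nadph_nadp", "nadph_nadp_combined"),
    names_to = "ratio", values_to = "value"
  )
  keys <- intersect("sample", names(long))
  long |>
    group_by(across(dplyr::all_of(c(keys, "ratio")))) |>
    summarise(n = dplyr::n(), mean = mean(.data$value),
              sd = if (dplyr::n() > 1) sd(.data$value) else 0,
              .groups = "drop")
}
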