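#' Assemble the per-compound analysis table
#'
#' Joins VRA classification records with descriptors and charge profiles into
#' the one-row-per-compound table used by the correlation, group-comparison
#' and rule-evaluation analyses. `is_vra` is encoded 1/0 in the `vra01`
#' column for correlation.
#'
#' @param records Tibble from [classify_vra()] (or any tibble with
#'   `compound_id`, `avg_rel_visc`, `is_vra`).
#' @param descriptors Descriptor tibble from [compute_descriptors()].
#' @param charge Charge-profile tibble from [charge_profile()].
#' @return The joined analysis tibble.
#' @export
build_analysis_table <- function(records, descriptors = NULL, charge = NULL) {
  out <- as_tibble(records)
  if (!is.null(descriptors)) {
    out <- out %>% left_join(descriptors, by = c(compound_id = "id"))
  }
  if (!is.null(charge)) {
    keep <- intersect(c("id", "n_pos", "n_neg", "n_charge_groups",
                        "net_charge", "abs_charge", "major_species_charge"),
                      names(charge))
    out <- out %>% left_join(charge[, keep], by = c(compound_id = "id"))
  }
  out %>% mutate(vra01 = as.integer(.data$is_vra))
}

#' Correlate the binary VRA classifier with descriptors
#'
#' Pearson correlation between the 1/0 VRA label and each requested
#' descriptor column. With a binary variable this is the point-biserial
#' correlation coefficient. A descriptor (or label) column with zero
#' variance has no defined correlation and is flagged rather than reported
#' as 0. Correlations are descriptive; no multiplicity correction is applied.
#'
#' @param table Analysis tibble from [build_analysis_table()] (needs `vra01`
#'   or `is_vra`).
#' @param descriptors Character vector of descriptor column names.
#' @return Tibble `descriptor`, `r`, `n`, `defined`.
#' @export
correlate_classifier <- function(table,
                                 descriptors = c("mw", "slogp", "hbd", "hba",
                                                 "rot_bonds", "frac_csp3",
                                                 "psa", "psa_sasa",
                                                 "n_charge_groups")) {
  table <- as_tibble(table)
  if (!("vra01" %in% names(table))) {
    stopifnot("is_vra" %in% names(table))
    table$vra01 <- as.integer(table$is_vra)
  }
  if (nrow(table) < 3L) {
    abort("need at least 3 rows to correlate", class = "vra_config_error")
  }
  missing_cols <- setdiff(descriptors, names(table))
  if (length(missing_cols) > 0L) {
    abort(paste0("missing descriptor column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  y <- table$vra01
  purrr::map_dfr(descriptors, function(d) {
    x <- table[[d]]
    ok <- stats::complete.cases(x, y)
    defined <- stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0 && sum(ok) >= 3L
    tibble(descriptor = d,
           r = if (defined) stats::cor(x[ok], y[ok]) else NA_real_,
           n = sum(ok),
           defined = defined)
  })
}

#' Two-sided Mann-Whitney U test
#'
#' The rank-sum test used for the charge-group comparison. `U` is counted
#' for the first sample (number of `(x, y)` pairs with `x > y`, ties
#' counting one half). For group sizes up to `exact_max` in both samples and
#' no ties, the two-sided p-value comes from full enumeration of the null
#' distribution of U over all arrangements; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest group size for the exact path (default 8).
#' @return List of class `vra_mwtest`: `U`, `p`, `n1`, `n2`, `method`.
#' @examples
#' mann_whitney_u(c(0.5, 0.6, 0.7), c(0.9, 1.0, 1.1))  # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) {
    abort("both groups must be non-empty", class = "vra_config_error")
  }
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0L
  if (!has_ties && n1 <= exact_max && n2 <= exact_max) {
    p <- exact_u_pvalue(U, n1, n2)
    method <- "exact"
  } else {
    p <- normal_u_pvalue(U, r, n1, n2)
    method <- "normal_approx"
  }
  structure(list(U = U, p = p, n1 = n1, n2 = n2, method = method),
            class = "vra_mwtest")
}

# exact null distribution of U by enumeration of all C(n1+n2, n1) rank splits
exact_u_pvalue <- function(U, n1, n2) {
  combos <- utils::combn(n1 + n2, n1)
  offset <- n1 * (n1 + 1) / 2
  us <- colSums(combos) - offset
  p_le <- mean(us <= U + 1e-9)
  p_ge <- mean(us >= U - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Normal approximation with continuity correction; without ties an Edgeworth
# kurtosis term (excess kurtosis of U under the null,
# gamma2 = -(6/5)(n1^2+n2^2+n1 n2+N) / (n1 n2 (N+1)), checked against
# enumeration) sharpens the tail so the approximation tracks the exact
# distribution closely at small group sizes. With ties, the tie-corrected
# variance is used and the kurtosis term dropped.
normal_u_pvalue <- function(U, r, n1, n2) {
  n <- n1 + n2
  mu <- n1 * n2 / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- max(0, (abs(U - mu) - 0.5) / sqrt(sigma2))
  if (U == mu) z <- 0
  tail <- stats::pnorm(-z)
  if (!has_ties && z <= 4) {
    # beyond z ~ 4 the polynomial term dwarfs the true tail; the plain normal
    # tail is already accurate there in the only sense that matters (p << alpha)
    g2 <- -(6 / 5) * (n1^2 + n2^2 + n1 * n2 + n) / (n1 * n2 * (n + 1))
    tail <- tail + g2 / 24 * (z^3 - 3 * z) * stats::dnorm(z)
  }
  min(1, max(0, 2 * tail))
}

#' @export
print.vra_mwtest <- function(x, ...) {
  cat("Mann-Whitney U test (", x$method, "): U = ", x$U,
      ", n = (", x$n1, ", ", x$n2, "), two-sided p = ",
      format(x$p, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.vra_mwtest <- function(x, ...) {
  tibble(U = x$U, p.value = x$p, n1 = x$n1, n2 = x$n2, method = x$method)
}

#' Compare relative viscosity between charge-group strata
#'
#' Two-sided Mann-Whitney U test of `avg_rel_visc` between the compounds
#' with at least `k` charge groups and those with fewer.
#'
#' @param table Analysis tibble with `avg_rel_visc` and `n_charge_groups`.
#' @param k Charge-group cutoff (default 3).
#' @param response Response column (default `"avg_rel_visc"`).
#' @return A `vra_mwtest` with the high-charge group first.
#' @export
group_comparison <- function(table, k = 3, response = "avg_rel_visc") {
  table <- as_tibble(table)
  hi <- table[[response]][table$n_charge_groups >= k]
  lo <- table[[response]][table$n_charge_groups < k]
  if (length(hi) == 0L || length(lo) == 0L) {
    abort("both charge-group strata must be non-empty",
          class = "vra_config_error")
  }
  mann_whitney_u(hi, lo)
}

#' Run the full descriptor analysis and serialize it
#'
#' Convenience wrapper bundling [correlate_classifier()],
#' [group_comparison()] and an [evaluate_rule()] sweep into one list, in the
#' shape written by [write_analysis_json()].
#'
#' @param table Analysis tibble from [build_analysis_table()].
#' @param descriptors Columns to correlate (defaults as in
#'   [correlate_classifier()], restricted to those present).
#' @param k Charge-group cutoffs to sweep (default 1..5).
#' @return List with `correlations`, `test` (`U`, `p`, `n1`, `n2`,
#'   `method`), and `rule_eval`.
#' @export
analyze_table <- function(table,
                          descriptors = c("mw", "slogp", "hbd", "hba",
                                          "rot_bonds", "frac_csp3", "psa",
                                          "psa_sasa", "n_charge_groups"),
                          k = 1:5) {
  descriptors <- intersect(descriptors, names(table))
  list(
    correlations = correlate_classifier(table, descriptors),
    test = tidy(group_comparison(table)),
    rule_eval = evaluate_rule(table, k)
  )
}

#' @rdname analyze_table
#' @param analysis List from [analyze_table()].
#' @param path JSON output path.
#' @export
write_analysis_json <- function(analysis, path) {
  jsonlite::write_json(analysis, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Evaluate the charge-group rule of thumb against the VRA label
#'
#' Confusion matrix and derived metrics for the predictor
#' "`n_charge_groups >= k`" against the observed `is_vra` label.
#'
#' @param table Analysis tibble with `is_vra` and `n_charge_groups`.
#' @param k Cutoff or vector of cutoffs to sweep (default 3).
#' @return Tibble with one row per `k`: `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `precision`, `accuracy`,
#'   `balanced_accuracy`.
#' @export
evaluate_rule <- function(table, k = 3) {
  table <- as_tibble(table)
  stopifnot(all(c("is_vra", "n_charge_groups") %in% names(table)),
            nrow(table) > 0L)
  purrr::map_dfr(k, function(kk) {
    pred <- table$n_charge_groups >= kk
    obs <- table$is_vra
    tp <- sum(pred & obs); fp <- sum(pred & !obs)
    tn <- sum(!pred & !obs); fn <- sum(!pred & obs)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    tibble(k = kk, tp = tp, fp = fp, tn = tn, fn = fn,
           sensitivity = sens, specificity = spec,
           precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
           accuracy = (tp + tn) / nrow(table),
           balanced_accuracy = mean(c(sens, spec)))
  })
}
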