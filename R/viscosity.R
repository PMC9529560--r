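#' Read a viscosity measurement table
#'
#' CSV columns: `sample_id`, `mab_id`, `compound_id` (empty for protein-only
#' baseline points), `concentration_mg_ml`, `viscosity_cp`, `ph`,
#' `excipient_mm`.
#'
#' @param path CSV path.
#' @return Measurement tibble with those columns; empty `compound_id` becomes
#'   `NA` (a baseline point).
#' @export
read_measurements <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "mab_id", "compound_id", "concentration_mg_ml",
            "viscosity_cp")
  if (!all(need %in% names(df))) {
    abort(paste0("measurement CSV needs columns: ", paste(need, collapse = ", ")),
          class = "vra_io_error")
  }
  df %>%
    mutate(compound_id = ifelse(is.na(.data$compound_id) |
                                  .data$compound_id == "",
                                NA_character_, as.character(.data$compound_id)))
}

#' Fit the exponential concentration-viscosity baseline
#'
#' Fits \eqn{\eta = a e^{b c}} to the protein-in-water baseline points
#' (rows with `compound_id` missing) of each antibody, by linear least
#' squares on \eqn{\ln \eta = \ln a + b c}. Fitting in log space weights
#' relative rather than absolute viscosity error, which matches the
#' multiplicative error structure of the measurement.
#'
#' @param measurements Measurement tibble (see [read_measurements()]); only
#'   baseline rows are used. A tibble containing solely baseline points (no
#'   `compound_id` column) is also accepted.
#' @return A tibble of class `vra_baseline_fit`: one row per `mab_id` with
#'   `a` (cP), `b` (mL/mg), `n_points`, `rms_log_residual`, `c_min`, `c_max`.
#' @examples
#' pts <- tibble::tibble(mab_id = "mabA", compound_id = NA,
#'                       concentration_mg_ml = c(120, 150, 180, 200),
#'                       viscosity_cp = 0.41 * exp(0.021 * c(120, 150, 180, 200)))
#' fit_baseline(pts)
#' @export
fit_baseline <- function(measurements) {
  m <- as_tibble(measurements)
  if (!("compound_id" %in% names(m))) m$compound_id <- NA_character_
  base <- m %>% filter(is.na(.data$compound_id))
  if (nrow(base) == 0L) {
    abort("no baseline points (rows with missing compound_id)",
          class = "vra_fit_error")
  }
  fits <- base %>%
    group_by(.data$mab_id) %>%
    group_modify(function(d, key) {
      if (length(unique(d$concentration_mg_ml)) < 2L) {
        abort(paste0("baseline for ", key$mab_id,
                     " needs >= 2 distinct concentrations"),
              class = "vra_fit_error")
      }
      if (any(d$viscosity_cp <= 0) || any(d$concentration_mg_ml <= 0)) {
        abort("viscosities and concentrations must be positive",
              class = "vra_fit_error")
      }
      fit <- stats::lm(log(viscosity_cp) ~ concentration_mg_ml, data = d)
      tibble(
        a = unname(exp(stats::coef(fit)[1])),
        b = unname(stats::coef(fit)[2]),
        n_points = nrow(d),
        rms_log_residual = sqrt(mean(stats::residuals(fit)^2)),
        c_min = min(d$concentration_mg_ml),
        c_max = max(d$concentration_mg_ml)
      )
    }) %>%
    ungroup()
  class(fits) <- c("vra_baseline_fit", class(fits))
  fits
}

#' @export
tidy.vra_baseline_fit <- function(x, ...) as_tibble(unclass_tbl(x))

#' @export
glance.vra_baseline_fit <- function(x, ...) {
  as_tibble(unclass_tbl(x)) %>%
    transmute(.data$mab_id, .data$n_points, .data$rms_log_residual,
              eta_150 = .data$a * exp(.data$b * 150))
}

unclass_tbl <- function(x) {
  class(x) <- setdiff(class(x), "vra_baseline_fit")
  x
}

#' Baseline viscosity predicted by a fit
#'
#' @param fits A `vra_baseline_fit`.
#' @param mab_id Antibody id.
#' @param concentration Protein concentration(s), mg/mL.
#' @return Predicted protein-in-water viscosity \eqn{\eta_0}, cP.
#' @export
predict_baseline <- function(fits, mab_id, concentration) {
  row <- fits[fits$mab_id == mab_id, ]
  if (nrow(row) == 0L) {
    abort(paste0("no baseline fit for ", mab_id), class = "vra_fit_error")
  }
  row$a * exp(row$b * concentration)
}

#' Relative viscosity of excipient measurements
#'
#' Divides each measured viscosity by the baseline viscosity \eqn{\eta_0}
#' predicted by the antibody's exponential fit at the measurement's own
#' protein concentration. Measurements whose concentration lies more than
#' 10% outside the fitted baseline range trigger an extrapolation warning
#' (not an error).
#'
#' @param measurements Measurement tibble; baseline rows pass through too.
#' @param fits A `vra_baseline_fit` covering every `mab_id` present.
#' @return `measurements` with `eta0_cp` and `rel_visc` columns appended.
#' @export
relative_viscosity <- function(measurements, fits) {
  m <- as_tibble(measurements)
  missing_fit <- setdiff(unique(m$mab_id), fits$mab_id)
  if (length(missing_fit) > 0L) {
    abort(paste0("no baseline fit for: ", paste(missing_fit, collapse = ", ")),
          class = "vra_fit_error")
  }
  f <- as_tibble(unclass_tbl(fits)) %>%
    select("mab_id", "a", "b", "c_min", "c_max")
  out <- m %>%
    left_join(f, by = "mab_id") %>%
    mutate(eta0_cp = .data$a * exp(.data$b * .data$concentration_mg_ml),
           rel_visc = .data$viscosity_cp / .data$eta0_cp)
  span <- out$c_max - out$c_min
  extra <- out$concentration_mg_ml < out$c_min - 0.1 * span |
    out$concentration_mg_ml > out$c_max + 0.1 * span
  if (any(extra)) {
    warn(paste0(sum(extra), " measurement(s) extrapolate > 10% beyond the ",
                "fitted baseline concentration range"))
  }
  out %>% select(-"a", -"b", -"c_min", -"c_max")
}

#' Classify compounds as viscosity-reducing agents
#'
#' Computes per-compound, per-antibody relative viscosities (averaging
#' replicate measurements), averages them across antibodies with an
#' unweighted arithmetic mean, and labels a compound a VRA when the average
#' relative viscosity is at or below `threshold` (inclusive; default 0.8,
#' chosen so that any compound with an arginine-like effect and measurement
#' error near 0.1 is retained).
#'
#' @param measurements Measurement tibble including excipient rows.
#' @param fits A `vra_baseline_fit`; computed from `measurements`' baseline
#'   rows when omitted.
#' @param threshold VRA threshold on average relative viscosity.
#' @return Tibble of class `vra_records`: `compound_id`, one
#'   `rel_visc_<mab>` column per antibody, `avg_rel_visc`, `is_vra`.
#' @export
classify_vra <- function(measurements, fits = NULL, threshold = 0.8) {
  m <- as_tibble(measurements)
  fits <- fits %||% fit_baseline(m)
  exc <- m %>% filter(!is.na(.data$compound_id))
  if (nrow(exc) == 0L) {
    warn("no excipient measurements; returning empty record set")
    return(tibble(compound_id = character(), avg_rel_visc = numeric(),
                  is_vra = logical()))
  }
  rel <- relative_viscosity(exc, fits)
  per_mab <- rel %>%
    group_by(.data$compound_id, .data$mab_id) %>%
    summarise(rel_visc = mean(.data$rel_visc), .groups = "drop")
  wide <- per_mab %>%
    mutate(mab_id = paste0("rel_visc_", .data$mab_id)) %>%
    arrange(.data$mab_id) %>%
    tidyr::pivot_wider(names_from = "mab_id", values_from = "rel_visc")
  avg <- per_mab %>%
    group_by(.data$compound_id) %>%
    summarise(avg_rel_visc = mean(.data$rel_visc), .groups = "drop")
  out <- wide %>%
    left_join(avg, by = "compound_id") %>%
    mutate(is_vra = .data$avg_rel_visc <= threshold) %>%
    arrange(.data$compound_id)
  attr(out, "threshold") <- threshold
  class(out) <- c("vra_records", class(out))
  out
}

#' Write VRA classification records as CSV
#'
#' @param records Tibble from [classify_vra()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vra_records <- function(records, path) {
  readr::write_csv(as_tibble(records), path)
  invisible(path)
}

#' Read a tested-compound relative-viscosity table
#'
#' Reads a user-supplied table of per-compound relative viscosities for two
#' antibodies (columns `compound_id`, `rel_visc_mabA`, `rel_visc_mabB`, plus
#' optional grouping columns) and applies the average-relative-viscosity
#' classifier. This is the entry point for re-analysing an existing
#' experimental summary table rather than raw measurements.
#'
#' @param path CSV path.
#' @param threshold VRA threshold (default 0.8, inclusive).
#' @return Tibble with `avg_rel_visc` and `is_vra` appended.
#' @export
read_tested_compounds <- function(path, threshold = 0.8) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  rel_cols <- grep("^rel_visc_", names(df), value = TRUE)
  if (!("compound_id" %in% names(df)) || length(rel_cols) == 0L) {
    abort("expected `compound_id` and `rel_visc_*` columns",
          class = "vra_io_error")
  }
  df %>%
    mutate(avg_rel_visc = rowMeans(dplyr::pick(dplyr::all_of(rel_cols))),
           is_vra = .data$avg_rel_visc <= threshold)
}
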