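#' Build a physicochemical filter specification
#'
#' Defaults are the second-campaign windows: molecular weight 100--300 Da,
#' SlogP -2..2, and at least three charge groups. All bounds are inclusive;
#' `NA` disables a bound (the third campaign, for instance, keeps SlogP < 2
#' with no lower bound and no MW window).
#'
#' @param mw_min,mw_max Molecular-weight window (Da); `NA` = unbounded.
#' @param slogp_min,slogp_max SlogP window; `NA` = unbounded.
#' @param min_charge_groups Minimum charge-group count (default 3).
#' @param rule [charge_rule()] used for the charge-group stage.
#' @param require_alert_free Gate on structural alerts (default `FALSE`)?
#' @return A `vra_filter_spec` object.
#' @export
filter_spec <- function(mw_min = 100, mw_max = 300,
                        slogp_min = -2, slogp_max = 2,
                        min_charge_groups = 3,
                        rule = charge_rule("threshold"),
                        require_alert_free = FALSE) {
  if (!is.na(mw_min) && !is.na(mw_max)) stopifnot(mw_min < mw_max)
  if (!is.na(slogp_min) && !is.na(slogp_max)) stopifnot(slogp_min < slogp_max)
  stopifnot(min_charge_groups >= 0)
  structure(list(mw_min = mw_min, mw_max = mw_max, slogp_min = slogp_min,
                 slogp_max = slogp_max, min_charge_groups = min_charge_groups,
                 rule = rule, require_alert_free = require_alert_free),
            class = "vra_filter_spec")
}

new_screen_report <- function(input_count, stages, passed) {
  structure(list(input_count = input_count, removed_by_stage = stages,
                 passed = passed),
            class = "vra_screen_report")
}

#' @export
print.vra_screen_report <- function(x, ...) {
  cat("<screen report> ", x$input_count, " compounds in, ",
      nrow(x$passed), " passed\n", sep = "")
  for (i in seq_len(nrow(x$removed_by_stage))) {
    cat("  - ", x$removed_by_stage$stage[i], ": removed ",
        x$removed_by_stage$removed[i], "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a screen report into a per-stage tibble
#'
#' @param x A `vra_screen_report`.
#' @param ... Unused.
#' @return Tibble `stage`, `removed`, `remaining`.
#' @export
tidy.vra_screen_report <- function(x, ...) {
  x$removed_by_stage %>%
    mutate(remaining = x$input_count - cumsum(.data$removed))
}

#' Apply the physicochemical filter cascade
#'
#' Stages run in the fixed order MW, SlogP, charge groups, then (optionally)
#' the structural-alert gate, so per-stage removal counts are reproducible;
#' because the stages are conjunctive, the final passed set does not depend
#' on the order. All window bounds are inclusive.
#'
#' @param library Compound tibble (`id`, `smiles`).
#' @param spec A [filter_spec()].
#' @param descriptors Optional precomputed descriptor table (must contain
#'   `id`, `mw`, `slogp`); computed when missing.
#' @param charge Optional precomputed charge profile (`id`,
#'   `n_charge_groups`); computed with `spec$rule` when missing. Pass the
#'   construction-time profile for synthetic libraries.
#' @param alerts Optional structural-alert database for the alert stage (see
#'   [toxicity_alerts()]).
#' @return A `vra_screen_report`; `$passed` holds the surviving compounds.
#' @export
apply_physchem_filter <- function(library, spec = filter_spec(),
                                  descriptors = NULL, charge = NULL,
                                  alerts = NULL) {
  stopifnot(inherits(spec, "vra_filter_spec"))
  library <- as_compound_tbl(library)
  if (nrow(library) == 0L) {
    return(new_screen_report(0L, tibble(stage = character(), removed = integer()),
                             library))
  }
  descriptors <- descriptors %||%
    compute_descriptors(library, which = c("mw", "slogp"))
  # the incoming library may already carry descriptor/charge columns (e.g. a
  # synthetic library); the filter works from the tables supplied to it
  cur <- library %>%
    select(-dplyr::any_of(c("mw", "slogp", "n_charge_groups"))) %>%
    left_join(descriptors, by = "id")
  stages <- list()
  drop_stage <- function(cur, keep, name) {
    stages[[length(stages) + 1L]] <<- tibble(stage = name,
                                             removed = sum(!keep))
    cur[keep, , drop = FALSE]
  }

  keep <- rep(TRUE, nrow(cur))
  if (!is.na(spec$mw_min)) keep <- keep & cur$mw >= spec$mw_min
  if (!is.na(spec$mw_max)) keep <- keep & cur$mw <= spec$mw_max
  cur <- drop_stage(cur, keep, "mw")

  keep <- rep(TRUE, nrow(cur))
  if (!is.na(spec$slogp_min)) keep <- keep & cur$slogp >= spec$slogp_min
  if (!is.na(spec$slogp_max)) keep <- keep & cur$slogp <= spec$slogp_max
  cur <- drop_stage(cur, keep, "slogp")

  if (spec$min_charge_groups > 0 && nrow(cur) > 0L) {
    cg <- charge %||% charge_profile(cur, rule = spec$rule)
    cur2 <- cur %>% left_join(cg %>% select("id", "n_charge_groups"), by = "id")
    keep <- !is.na(cur2$n_charge_groups) &
      cur2$n_charge_groups >= spec$min_charge_groups
  } else {
    keep <- rep(TRUE, nrow(cur))
  }
  cur <- drop_stage(cur, keep, "charge_groups")

  if (spec$require_alert_free && nrow(cur) > 0L) {
    if (is.null(alerts)) {
      abort("spec requires the alert gate but no alert database was given",
            class = "vra_config_error")
    }
    tox <- toxicity_alerts(cur, alerts)
    keep <- !(cur$id %in% tox$id[!tox$alert_free])
  } else {
    keep <- rep(TRUE, nrow(cur))
  }
  cur <- drop_stage(cur, keep, "alerts")

  new_screen_report(nrow(library), bind_rows(stages), as_tibble(cur))
}

#' Remove compounds matching exclusion substructure patterns
#'
#' Used for the assay-interference and reactive-functional-group exclusion
#' step. Patterns are SMARTS expressions matched through OpenBabel; a
#' compound matching one or more patterns is removed once. Two starter
#' pattern lists ship with the package (see
#' `system.file("extdata", c("assay_interference.csv", "reactive_groups.csv"),
#' package = "vrascreen")`); both are user-replaceable data files, not a
#' reproduction of any proprietary list.
#'
#' @param library Compound tibble.
#' @param patterns Tibble with `name` and `smarts` columns, a CSV path, or a
#'   character vector of SMARTS.
#' @return A `vra_screen_report` with one removal stage per pattern list
#'   entry aggregated as `"pattern_exclusion"`.
#' @export
apply_pattern_exclusions <- function(library, patterns) {
  library <- as_compound_tbl(library)
  patterns <- as_pattern_tbl(patterns)
  if (nrow(library) == 0L || nrow(patterns) == 0L) {
    return(new_screen_report(nrow(library),
                             tibble(stage = "pattern_exclusion", removed = 0L),
                             library))
  }
  hit <- rep(FALSE, nrow(library))
  for (k in seq_len(nrow(patterns))) {
    hit <- hit | smarts_hits(library$smiles, patterns$smarts[k],
                             patterns$name[k])
  }
  new_screen_report(
    nrow(library),
    tibble(stage = "pattern_exclusion", removed = sum(hit)),
    library[!hit, , drop = FALSE]
  )
}

# per-compound SMARTS match indicator; single-heavy-atom records are handled
# apart because the OpenBabel SDF round-trip degrades on bond-free molfiles
# (functional-group exclusion patterns span >= 2 atoms, so they never match)
smarts_hits <- function(smiles, smarts, name = smarts) {
  multi <- vapply(smiles, function(s) {
    tryCatch(mol_from_smiles(s)$n_heavy >= 2L, error = function(e) FALSE)
  }, logical(1), USE.NAMES = FALSE)
  out <- rep(FALSE, length(smiles))
  if (any(multi)) {
    sdfs <- suppressWarnings(
      ChemmineR::smiles2sdf(stats::setNames(smiles[multi],
                                            paste0("m", which(multi))))
    )
    counts <- tryCatch(
      ChemmineR::smartsSearchOB(sdfs, smarts, uniqueMatches = TRUE),
      error = function(e) {
        abort(paste0("invalid pattern '", name, "' (", smarts, "): ",
                     conditionMessage(e)),
              class = "vra_config_error")
      }
    )
    out[multi] <- as.numeric(counts) > 0
  }
  out
}

as_pattern_tbl <- function(patterns) {
  if (is.character(patterns) && length(patterns) == 1L && file.exists(patterns)) {
    patterns <- readr::read_csv(patterns, show_col_types = FALSE, progress = FALSE)
  }
  if (is.character(patterns)) {
    patterns <- tibble(name = paste0("pattern_", seq_along(patterns)),
                       smarts = patterns)
  }
  stopifnot(all(c("name", "smarts") %in% names(patterns)))
  as_tibble(patterns)
}

#' Structural-alert screen (pluggable toxicity stub)
#'
#' A transparent stand-in for rule-based toxicity expert systems: the alert
#' database is a plain table of SMARTS patterns with a toxicological endpoint
#' and a likelihood level. A compound is alert-free iff it triggers no alert
#' with likelihood at or above `"plausible"` (ordering: `improbable <
#' equivocal < plausible < probable < certain`).
#'
#' @param compounds Compound tibble.
#' @param alert_db Tibble (or CSV path) with `pattern`, `endpoint`,
#'   `likelihood` columns.
#' @return Tibble with one row per compound: `id`, `n_alerts`, `alert_free`,
#'   plus a `triggered` list-column of the matching alert rows.
#' @export
toxicity_alerts <- function(compounds, alert_db) {
  compounds <- as_compound_tbl(compounds)
  if (is.character(alert_db) && length(alert_db) == 1L) {
    alert_db <- readr::read_csv(alert_db, show_col_types = FALSE, progress = FALSE)
  }
  stopifnot(all(c("pattern", "endpoint", "likelihood") %in% names(alert_db)))
  levels <- c("improbable", "equivocal", "plausible", "probable", "certain")
  stopifnot(all(alert_db$likelihood %in% levels))
  if (nrow(alert_db) == 0L || nrow(compounds) == 0L) {
    return(compounds %>%
             transmute(.data$id, n_alerts = 0L, alert_free = TRUE,
                       triggered = list(alert_db[0, ])))
  }
  match_mat <- vapply(seq_len(nrow(alert_db)), function(k) {
    smarts_hits(compounds$smiles, alert_db$pattern[k])
  }, logical(nrow(compounds)))
  match_mat <- matrix(match_mat, nrow = nrow(compounds))
  gating <- match(alert_db$likelihood, levels) >= match("plausible", levels)
  tibble(
    id = compounds$id,
    n_alerts = as.integer(rowSums(match_mat)),
    alert_free = !apply(match_mat[, gating, drop = FALSE], 1, any),
    triggered = lapply(seq_len(nrow(compounds)), function(i) {
      alert_db[match_mat[i, ], , drop = FALSE]
    })
  )
}

#' Serialize a screen report
#'
#' Writes the report (input count, per-stage removals, passed ids) as JSON,
#' and optionally the passed set as a `.smi` file.
#'
#' @param report A `vra_screen_report`.
#' @param path JSON output path.
#' @param smi_path Optional `.smi` path for the passed compounds.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(report, path, smi_path = NULL) {
  stopifnot(inherits(report, "vra_screen_report"))
  jsonlite::write_json(
    list(input_count = report$input_count,
         removed_by_stage = report$removed_by_stage,
         passed = report$passed$id),
    path, auto_unbox = TRUE, digits = NA
  )
  if (!is.null(smi_path)) write_smi(report$passed, smi_path)
  invisible(path)
}

#' Run a virtual-screening campaign
#'
#' The three library campaigns of the cascade, plus the dipeptide design,
#' as one composable entry point:
#' * `"similarity"`: fingerprint similarity search of `config$queries`
#'   against the library at `config$threshold` (default 0.7), then a seeded
#'   diverse sample of `config$sample_size` hits (cluster-then-pick, one per
#'   cluster), standing in for manual diverse selection.
#' * `"chemspace"`: optional pattern exclusions, then the campaign-2
#'   physicochemical windows (MW 100--300, SlogP -2..2, >= 3 charge groups).
#' * `"safe_library"`: duplicate removal, SlogP <= 2 with no lower bound and
#'   no MW window, >= 3 charge groups at pH 6, and the structural-alert gate
#'   when `config$alert_db` is given.
#' * `"dipeptide"`: delegates to [dual_excipient_candidates()].
#'
#' @param library Compound tibble (ignored for `"dipeptide"` when
#'   `config$dipeptides` is supplied).
#' @param campaign One of `"similarity"`, `"chemspace"`, `"safe_library"`,
#'   `"dipeptide"`.
#' @param config Named list of campaign settings (see details above; unknown
#'   entries are ignored).
#' @return A `vra_screen_report` (for `"dipeptide"`, the candidate tibble).
#' @export
run_campaign <- function(library, campaign = c("similarity", "chemspace",
                                               "safe_library", "dipeptide"),
                         config = list()) {
  campaign <- match.arg(campaign)
  switch(campaign,
    similarity = {
      queries <- config$queries %||%
        abort("similarity campaign needs config$queries", class = "vra_config_error")
      hits <- similarity_search(queries, library,
                                threshold = config$threshold %||% 0.7,
                                strict = isTRUE(config$strict))
      hit_lib <- as_compound_tbl(library) %>% filter(.data$id %in% hits$hit_id)
      size <- config$sample_size %||% 18L
      picked <- if (nrow(hit_lib) > size) {
        cluster_and_pick(hit_lib, k = size, per_cluster = 1,
                         seed = config$seed %||% 1L)
      } else hit_lib
      new_screen_report(
        nrow(as_compound_tbl(library)),
        tibble(stage = c("similarity", "diverse_sample"),
               removed = c(nrow(as_compound_tbl(library)) - nrow(hit_lib),
                           nrow(hit_lib) - nrow(picked))),
        picked
      )
    },
    chemspace = {
      lib <- as_compound_tbl(library)
      pre <- if (!is.null(config$patterns)) {
        apply_pattern_exclusions(lib, config$patterns)
      } else {
        new_screen_report(nrow(lib), tibble(stage = "pattern_exclusion",
                                            removed = 0L), lib)
      }
      spec <- config$spec %||% filter_spec()
      rep2 <- apply_physchem_filter(pre$passed, spec,
                                    descriptors = config$descriptors,
                                    charge = config$charge)
      new_screen_report(nrow(lib),
                        bind_rows(pre$removed_by_stage, rep2$removed_by_stage),
                        rep2$passed)
    },
    safe_library = {
      lib <- as_compound_tbl(library)
      can <- canonical_smiles(lib$smiles)
      dedup <- lib[!duplicated(can), , drop = FALSE]
      spec <- config$spec %||% filter_spec(
        mw_min = NA, mw_max = NA, slogp_min = NA, slogp_max = 2,
        min_charge_groups = 3,
        rule = config$rule %||% charge_rule("threshold", ph = 6.0),
        require_alert_free = !is.null(config$alert_db)
      )
      rep2 <- apply_physchem_filter(dedup, spec,
                                    descriptors = config$descriptors,
                                    charge = config$charge,
                                    alerts = config$alert_db)
      new_screen_report(nrow(lib),
                        bind_rows(tibble(stage = "dedupe",
                                         removed = nrow(lib) - nrow(dedup)),
                                  rep2$removed_by_stage),
                        rep2$passed)
    },
    dipeptide = {
      dps <- config$dipeptides %||% enumerate_dipeptides()
      dual_excipient_candidates(
        dps,
        rule = config$rule %||% charge_rule("window", ph = 6.0),
        min_groups = config$min_groups %||% 3
      )
    }
  )
}
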