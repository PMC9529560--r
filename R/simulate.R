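# Ionizable and neutral substituents available to the scaffold grammar.
# Counting groups are charged under both the threshold rule and the window
# rule at pH 6, so the construction-time charge-group count is exact under
# either; decorations are neutral or ionizable-but-uncounted (phenol).
.sim_substituents <- list(
  acid = tibble::tribble(
    ~frag,              ~label,            ~kind,  ~pka, ~weight,
    "(CC(=O)O)",        "carboxylic_acid", "acid",  4.2, 0.8,
    "(CS(=O)(=O)O)",    "sulfonic_acid",   "acid",  1.0, 0.2
  ),
  base = tibble::tribble(
    ~frag,              ~label,            ~kind,  ~pka, ~weight,
    "(CN)",             "aliphatic_amine", "base", 10.6, 0.8,
    "(CNC(=N)N)",       "guanidine",       "base", 12.5, 0.2
  ),
  neutral = tibble::tribble(
    ~frag,              ~label,            ~kind,  ~pka, ~weight,
    "(C)",              NA,                NA,     NA,   0.4,
    "(CO)",             NA,                NA,     NA,   0.3,
    "(CC)",             NA,                NA,     NA,   0.2,
    "(Cc1ccc(O)cc1)",   "phenol",          "acid", 10.0, 0.1
  )
)

#' Simulation configuration for the synthetic viscosity study
#'
#' Defines the study conditions the generator emulates: a compound library
#' with a controlled charge-group distribution, and a two-antibody viscosity
#' experiment at a 150 mg/mL protein target with exponential baselines
#' spanning 120--200 mg/mL. Defaults encode the study design: both antibody
#' curves give 10--30 cP at 150 mg/mL, excipients are dosed at 25 mM,
#' reducers pull relative viscosity to an arginine-like 0.6 +/- 0.1 while
#' non-reducers stay at 1.0 +/- 0.1, the probability of being a reducer is
#' logistic in the charge-group count, and measurement noise is 5%
#' multiplicative (log-normal) with a 5 mg/mL spread in realised protein
#' concentration.
#'
#' @param seed Integer seed; every random draw derives from it.
#' @param n_compounds Library size (default 94, the study's tested-set size).
#' @param charge_group_distribution Probabilities over charge-group counts
#'   0..5 (must sum to 1).
#' @param effect_beta0,effect_beta1 Logistic intercept/slope of
#'   P(reducer | charge groups).
#' @param reducer_mean,reducer_sd,nonreducer_mean,nonreducer_sd Relative-
#'   viscosity effect magnitudes.
#' @param mab_params Tibble `mab_id`, `a`, `b` of baseline curves; each must
#'   satisfy `a * exp(150 b)` in `[10, 30]` cP.
#' @param noise_cv Multiplicative measurement noise CV (default 0.05).
#' @param baseline_concentrations Baseline design points, mg/mL.
#' @param conc_mean,conc_sd Realised excipient-sample protein concentration
#'   distribution, mg/mL.
#' @param ph,excipient_mm Metadata recorded on every measurement.
#' @return A `vra_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_compounds = 94L,
                       charge_group_distribution = c(0.10, 0.15, 0.20,
                                                     0.25, 0.20, 0.10),
                       effect_beta0 = -4,
                       effect_beta1 = 1.8,
                       reducer_mean = 0.6, reducer_sd = 0.1,
                       nonreducer_mean = 1.0, nonreducer_sd = 0.1,
                       mab_params = tibble(mab_id = c("mabA", "mabB"),
                                           a = c(0.278, 0.350),
                                           b = c(0.030, 0.025)),
                       noise_cv = 0.05,
                       baseline_concentrations = c(120, 135, 150,
                                                   165, 180, 200),
                       conc_mean = 150, conc_sd = 5,
                       ph = 6.0, excipient_mm = 25) {
  stopifnot(length(charge_group_distribution) == 6L,
            all(charge_group_distribution >= 0),
            abs(sum(charge_group_distribution) - 1) < 1e-8,
            noise_cv >= 0, n_compounds >= 1,
            all(c("mab_id", "a", "b") %in% names(mab_params)))
  eta150 <- mab_params$a * exp(mab_params$b * 150)
  if (any(eta150 < 10 | eta150 > 30)) {
    abort(paste0("baseline curves must give 10-30 cP at 150 mg/mL; got ",
                 paste(round(eta150, 1), collapse = ", ")),
          class = "vra_config_error")
  }
  structure(
    list(seed = as.integer(seed), n_compounds = as.integer(n_compounds),
         charge_group_distribution = charge_group_distribution,
         effect_beta0 = effect_beta0, effect_beta1 = effect_beta1,
         reducer_mean = reducer_mean, reducer_sd = reducer_sd,
         nonreducer_mean = nonreducer_mean, nonreducer_sd = nonreducer_sd,
         mab_params = mab_params, noise_cv = noise_cv,
         baseline_concentrations = baseline_concentrations,
         conc_mean = conc_mean, conc_sd = conc_sd,
         ph = ph, excipient_mm = excipient_mm),
    class = "vra_sim_config"
  )
}

#' Generate a synthetic compound library with exact charge ground truth
#'
#' Assembles compounds from a scaffold grammar: a short alkyl core decorated
#' with ionizable substituents (carboxylate, sulfonate, amine, guanidine
#' carriers) drawn to match the configured charge-group-count distribution,
#' plus neutral decorations. Because charge groups are placed by
#' construction, each compound's charge-group count is known exactly and is
#' identical under the threshold rule and the window rule at pH 6.
#'
#' @param cfg A [sim_config()].
#' @param validate Re-parse every generated SMILES (slower; default `FALSE`
#'   since the grammar only emits valid structures).
#' @return Compound tibble: `id`, `smiles`, `source`, `n_pos`, `n_neg`,
#'   `n_charge_groups`, and a `groups` list-column of ionizable groups.
#' @export
generate_library <- function(cfg = sim_config(), validate = FALSE) {
  stopifnot(inherits(cfg, "vra_sim_config"))
  lib <- withr::with_seed(cfg$seed, {
    counts <- sample(0:5, cfg$n_compounds, replace = TRUE,
                     prob = cfg$charge_group_distribution)
    rows <- lapply(seq_len(cfg$n_compounds), function(i) {
      build_scaffold(counts[i], sprintf("S%03d", i))
    })
    bind_rows(rows)
  })
  if (validate) {
    ok <- smiles_is_valid(lib$smiles)
    if (!all(ok)) {
      abort(paste0("scaffold grammar emitted unparsable SMILES: ",
                   paste(lib$id[!ok], collapse = ", ")))
    }
  }
  lib
}

# one compound: n_cg ionizable substituents (acid/base split ~ binomial) plus
# 0-2 neutral decorations on an alkyl chain; assumes caller seeded the RNG
build_scaffold <- function(n_cg, id) {
  n_neg <- stats::rbinom(1L, n_cg, 0.5)
  n_pos <- n_cg - n_neg
  pick <- function(tab, n) {
    if (n == 0L) return(tab[0, ])
    tab[sample.int(nrow(tab), n, replace = TRUE, prob = tab$weight), ]
  }
  subs <- bind_rows(
    pick(.sim_substituents$acid, n_neg),
    pick(.sim_substituents$base, n_pos),
    pick(.sim_substituents$neutral, sample(0:2, 1L))
  )
  n_sub <- nrow(subs)
  len <- max(2L, n_sub) + sample(0:3, 1L)
  slots <- rep("", len)
  if (n_sub > 0L) {
    slots[sample.int(len, n_sub)] <- subs$frag
  }
  smiles <- paste0("C", paste0(ifelse(nzchar(slots[-1]),
                                      paste0("C", slots[-1]), "C"),
                               collapse = ""))
  if (nzchar(slots[1])) smiles <- paste0("C", slots[1],
                                         substring(smiles, 2))
  groups <- subs %>%
    filter(!is.na(.data$label)) %>%
    select("label", "kind", "pka")
  tibble(id = id, smiles = smiles, source = "synthetic",
         n_pos = n_pos, n_neg = n_neg, n_charge_groups = n_cg,
         groups = list(groups))
}

#' Simulate the two-antibody viscosity experiment
#'
#' For each antibody, generates protein-in-water baseline measurements on
#' the exponential curve \eqn{\eta = a e^{b c}} at the configured design
#' concentrations, and one excipient measurement per compound per antibody
#' at a realised concentration drawn around the 150 mg/mL target. Each
#' compound is a true reducer with probability
#' \eqn{\mathrm{logit}^{-1}(\beta_0 + \beta_1 \cdot \mathrm{charge\ groups})};
#' its true relative-viscosity ratio (shared across antibodies) is drawn
#' from the reducer or non-reducer magnitude distribution, and all observed
#' viscosities carry multiplicative log-normal noise.
#'
#' @param library Library tibble from [generate_library()].
#' @param cfg The same [sim_config()].
#' @return List with `measurements` (tibble in the measurement-CSV layout)
#'   and `truth` (tibble `compound_id`, `n_charge_groups`, `is_reducer`,
#'   `true_ratio`).
#' @export
generate_measurements <- function(library, cfg = sim_config()) {
  stopifnot(inherits(cfg, "vra_sim_config"), nrow(library) >= 1L)
  sdlog <- sqrt(log(1 + cfg$noise_cv^2))
  withr::with_seed(cfg$seed + 1000000L, {
    p_red <- stats::plogis(cfg$effect_beta0 +
                             cfg$effect_beta1 * library$n_charge_groups)
    is_red <- stats::runif(nrow(library)) < p_red
    ratio <- ifelse(is_red,
                    stats::rnorm(nrow(library), cfg$reducer_mean, cfg$reducer_sd),
                    stats::rnorm(nrow(library), cfg$nonreducer_mean,
                                 cfg$nonreducer_sd))
    ratio <- pmax(ratio, 0.05)
    truth <- tibble(compound_id = library$id,
                    n_charge_groups = library$n_charge_groups,
                    is_reducer = is_red, true_ratio = ratio)
    rows <- lapply(seq_len(nrow(cfg$mab_params)), function(m) {
      a <- cfg$mab_params$a[m]; b <- cfg$mab_params$b[m]
      mab <- cfg$mab_params$mab_id[m]
      noise <- function(n) exp(stats::rnorm(n, 0, sdlog))
      base <- tibble(
        sample_id = paste0(mab, "_base_", seq_along(cfg$baseline_concentrations)),
        mab_id = mab, compound_id = NA_character_,
        concentration_mg_ml = cfg$baseline_concentrations,
        viscosity_cp = a * exp(b * cfg$baseline_concentrations) *
          noise(length(cfg$baseline_concentrations)),
        ph = cfg$ph, excipient_mm = 0
      )
      cc <- stats::rnorm(nrow(library), cfg$conc_mean, cfg$conc_sd)
      exc <- tibble(
        sample_id = paste0(mab, "_", library$id),
        mab_id = mab, compound_id = library$id,
        concentration_mg_ml = cc,
        viscosity_cp = ratio * a * exp(b * cc) * noise(nrow(library)),
        ph = cfg$ph, excipient_mm = cfg$excipient_mm
      )
      bind_rows(base, exc)
    })
    list(measurements = bind_rows(rows), truth = truth)
  })
}

#' Write a complete synthetic end-to-end fixture to disk
#'
#' Generates a library and its measurements and writes `library.smi`,
#' `measurements.csv`, `truth.csv` and a `sim_config.json` echo into `dir`.
#' Files are byte-identical for a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly; the generated data as
#'   attributes `library`, `measurements`, `truth`.
#' @export
end_to_end_fixture <- function(cfg = sim_config(), dir = tempfile("fixture")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib <- generate_library(cfg)
  sim <- generate_measurements(lib, cfg)
  paths <- list(
    library = file.path(dir, "library.smi"),
    measurements = file.path(dir, "measurements.csv"),
    truth = file.path(dir, "truth.csv"),
    config = file.path(dir, "sim_config.json")
  )
  write_smi(lib, paths$library)
  readr::write_csv(sim$measurements, paths$measurements)
  readr::write_csv(sim$truth, paths$truth)
  cfg_json <- cfg
  class(cfg_json) <- NULL
  jsonlite::write_json(cfg_json, paths$config, auto_unbox = TRUE, digits = NA)
  out <- paths
  attr(out, "library") <- lib
  attr(out, "measurements") <- sim$measurements
  attr(out, "truth") <- sim$truth
  invisible(out)
}
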