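aa_library <- function() {
  aas <- amino_acids()
  tibble::tibble(id = aas$code, smiles = aas$smiles)
}

test_that("physicochemical windows are inclusive and staged in order", {
  lib <- tibble::tibble(
    id = c("light", "edge", "heavy"),
    smiles = c("NCC(=O)O", "x", "y")
  )
  desc <- tibble::tibble(id = c("light", "edge", "heavy"),
                         mw = c(75.07, 300.00, 310),
                         slogp = c(-0.27, 1.0, 1.0))
  charge <- tibble::tibble(id = c("light", "edge", "heavy"),
                           n_charge_groups = c(2L, 3L, 3L))
  rep <- apply_physchem_filter(lib, filter_spec(), descriptors = desc,
                               charge = charge)
  expect_equal(rep$passed$id, "edge")  # 300.00 passes the inclusive bound
  st <- tidy(rep)
  expect_equal(st$removed[st$stage == "mw"], 2L)  # glycine below 100, heavy above
  expect_equal(rep$input_count, sum(st$removed) + nrow(rep$passed))
})

test_that("the campaign-2 windows keep arginine and drop glycine", {
  lib <- tibble::tibble(id = c("glycine", "arginine"),
                        smiles = c("NCC(=O)O", "NC(CCCNC(=N)N)C(=O)O"))
  rep <- apply_physchem_filter(lib, filter_spec())
  expect_equal(rep$passed$id, "arginine")
  expect_equal(tidy(rep)$removed[1], 1L)  # glycine out at the MW stage
})

test_that("chemspace campaign on amino acids passes exactly R, K, D, E", {
  rep <- run_campaign(aa_library(), "chemspace",
                      config = list(charge = count_charge_groups(
                        aa_groups(), charge_rule("threshold"))))
  expect_setequal(rep$passed$id, c("R", "K", "D", "E"))
})

test_that("pattern exclusions remove matching compounds once", {
  lib <- tibble::tibble(
    id = c("ald1", "ald2", "ok1", "ok2", "ok3"),
    smiles = c("CC=O", "CCC=O", "CCO", "CCN", "CCC")
  )
  rep <- apply_pattern_exclusions(lib, c("[CX3H1]=O"))
  expect_equal(nrow(rep$passed), 3)
  expect_false(any(c("ald1", "ald2") %in% rep$passed$id))

  # multiple matching patterns still remove the compound once
  rep2 <- apply_pattern_exclusions(lib, c("[CX3H1]=O", "C[CX3H1]=O"))
  expect_equal(rep2$removed_by_stage$removed, 2L)

  rep3 <- apply_pattern_exclusions(lib, character())
  expect_equal(nrow(rep3$passed), 5)

  expect_error(apply_pattern_exclusions(lib, "[[[bad"),
               class = "vra_config_error")
})

test_that("structural-alert stub gates at plausible likelihood", {
  db <- tibble::tibble(
    pattern = c("[CX3H1]=O", "NC(=S)N"),
    endpoint = c("mutagenicity", "thyroid toxicity"),
    likelihood = c("probable", "equivocal")
  )
  tox <- toxicity_alerts(tibble::tibble(
    id = c("ald", "thio", "clean"),
    smiles = c("CC=O", "NC(=S)N", "CCO")
  ), db)
  expect_false(tox$alert_free[tox$id == "ald"])      # probable >= plausible
  expect_true(tox$alert_free[tox$id == "thio"])      # sub-plausible only
  expect_true(tox$alert_free[tox$id == "clean"])
  expect_equal(tox$n_alerts[tox$id == "thio"], 1L)

  none <- toxicity_alerts(tibble::tibble(id = "x", smiles = "CC=O"), db[0, ])
  expect_true(none$alert_free)
})

test_that("safe-library campaign dedupes and applies charge and alert gates", {
  lib <- dplyr::bind_rows(
    aa_library()[c(2, 4, 8, 9, 12), ],            # R, D, G, H, K
    tibble::tibble(id = "R_dup", smiles = "NC(CCCNC(=N)N)C(=O)O"),
    # three charge groups but carries an aldehyde: must fall to the alert gate
    tibble::tibble(id = "ald", smiles = "O=CC(CN)CC(CN)CC(=O)O")
  )
  rep <- run_campaign(lib, "safe_library",
                      config = list(alert_db = system.file(
                        "extdata", "example_alerts.csv", package = "vrascreen")))
  expect_true(all(c("R", "D", "K") %in% rep$passed$id))
  expect_false("R_dup" %in% rep$passed$id)   # duplicate structure removed
  expect_false("H" %in% rep$passed$id)       # 2 groups under threshold rule
  expect_false("ald" %in% rep$passed$id)
  st <- rep$removed_by_stage
  expect_equal(st$removed[st$stage == "dedupe"], 1L)
  expect_equal(st$removed[st$stage == "alerts"], 1L)
})

test_that("similarity campaign at threshold 1.0 returns only structural duplicates", {
  lib <- dplyr::bind_rows(
    tiny_library(),
    tibble::tibble(id = "gly2", smiles = "C(C(=O)O)N")
  )
  rep <- run_campaign(lib, "similarity",
                      config = list(queries = tibble::tibble(
                        id = "q", smiles = "NCC(=O)O"),
                        threshold = 1.0, sample_size = 18, seed = 1))
  expect_setequal(rep$passed$id, c("glycine", "gly2"))
})

test_that("a fully open filter is the identity and tightening is monotone", {
  lib <- generate_library(sim_config(seed = 29, n_compounds = 30))
  desc <- compute_descriptors(lib[, c("id", "smiles")],
                              which = c("mw", "slogp"))
  charge <- lib[, c("id", "n_charge_groups")]
  open <- filter_spec(mw_min = NA, mw_max = NA, slogp_min = NA,
                      slogp_max = NA, min_charge_groups = 0)
  rep_open <- apply_physchem_filter(lib, open, desc, charge)
  expect_equal(rep_open$passed$id, lib$id)

  passed_k <- vapply(0:5, function(k) {
    spec <- filter_spec(mw_min = NA, mw_max = NA, slogp_min = NA,
                        slogp_max = NA, min_charge_groups = k)
    nrow(apply_physchem_filter(lib, spec, desc, charge)$passed)
  }, numeric(1))
  expect_true(all(diff(passed_k) <= 0))

  # conjunctive stages: pass set invariant to window order (counts aside)
  spec_a <- filter_spec(mw_min = 100, mw_max = 300, slogp_min = NA,
                        slogp_max = NA, min_charge_groups = 2)
  got_a <- apply_physchem_filter(lib, spec_a, desc, charge)$passed$id
  manual <- lib$id[desc$mw >= 100 & desc$mw <= 300 &
                     charge$n_charge_groups >= 2]
  expect_setequal(got_a, manual)
})

test_that("screen reports serialize with passed set as .smi", {
  lib <- tibble::tibble(id = c("glycine", "arginine"),
                        smiles = c("NCC(=O)O", "NC(CCCNC(=N)N)C(=O)O"))
  rep <- apply_physchem_filter(lib, filter_spec())
  fj <- tempfile(fileext = ".json"); fs <- tempfile(fileext = ".smi")
  write_screen_report(rep, fj, fs)
  back <- jsonlite::read_json(fj)
  expect_equal(back$input_count, 2)
  expect_equal(unlist(back$passed), "arginine")
  expect_equal(nrow(read_library(fs)), 1)
})
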