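test_that("classifier correlation equals the closed-form point-biserial", {
  tab <- tibble::tibble(is_vra = c(TRUE, TRUE, FALSE, FALSE),
                        x = c(3, 4, 1, 2))
  r <- correlate_classifier(tab, "x")
  expect_equal(r$r, 2 / sqrt(5), tolerance = 1e-12)

  # identical encoding gives r = 1
  tab2 <- tibble::tibble(is_vra = c(TRUE, FALSE, TRUE, FALSE),
                         same = c(1, 0, 1, 0))
  expect_equal(correlate_classifier(tab2, "same")$r, 1.0)

  # constant descriptor: undefined, not zero
  tab3 <- tibble::tibble(is_vra = c(TRUE, FALSE, TRUE), k = c(2, 2, 2))
  got <- correlate_classifier(tab3, "k")
  expect_false(got$defined)
  expect_true(is.na(got$r))

  expect_error(correlate_classifier(tab[1:2, ], "x"),
               class = "vra_config_error")

  # property: Pearson on 1/0 label == point-biserial closed form
  set.seed(8)
  for (i in 1:20) {
    y <- sample(c(0L, 1L), 15, replace = TRUE)
    if (length(unique(y)) < 2) next
    x <- rnorm(15)
    tabp <- tibble::tibble(is_vra = y == 1L, v = x)
    expect_equal(correlate_classifier(tabp, "v")$r,
                 oracle_point_biserial(y, x), tolerance = 1e-12)
  }
})

test_that("exact Mann-Whitney enumeration reproduces reference cases", {
  t1 <- mann_whitney_u(c(0.5, 0.6, 0.7), c(0.9, 1.0, 1.1))
  expect_equal(t1$U, 0)
  expect_equal(t1$p, 0.1, tolerance = 1e-12)  # 2/20 arrangements
  expect_equal(t1$method, "exact")

  same <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p, 1.0)

  expect_error(mann_whitney_u(numeric(), 1:3), class = "vra_config_error")
})

test_that("exact path agrees with wilcox.test across random instances", {
  set.seed(11)
  for (i in 1:25) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- rnorm(n1); y <- rnorm(n2, 0.4)
    ours <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("normal approximation tracks the exact path closely at 8/8", {
  worst <- 0
  for (U in 0:64) {
    pe <- vrascreen:::exact_u_pvalue(U, 8, 8)
    pa <- vrascreen:::normal_u_pvalue(U, r = 1:16, n1 = 8, n2 = 8)
    worst <- max(worst, abs(pe - pa))
  }
  expect_lte(worst, 0.01)
})

test_that("tied data falls back to the corrected normal approximation", {
  x <- c(1, 1, 2, 3); y <- c(2, 3, 3, 4)
  ours <- mann_whitney_u(x, y)
  expect_equal(ours$method, "normal_approx")
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
})

test_that("group comparison splits the analysis table at the cutoff", {
  tab <- tibble::tibble(
    avg_rel_visc = c(0.5, 0.6, 0.7, 0.9, 1.0, 1.1),
    n_charge_groups = c(3, 4, 5, 0, 1, 2)
  )
  t <- group_comparison(tab)
  expect_equal(t$U, 0)
  expect_equal(t$p, 0.1, tolerance = 1e-12)
  expect_equal(c(t$n1, t$n2), c(3L, 3L))
  expect_error(group_comparison(tab[1:3, ]), class = "vra_config_error")
  td <- tidy(t)
  expect_equal(td$p.value, t$p)
})

test_that("rule evaluation produces a coherent confusion matrix", {
  tab <- tibble::tibble(
    is_vra = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    n_charge_groups = c(3, 4, 5, 1, 2)
  )
  ev <- evaluate_rule(tab, 3)
  expect_equal(c(ev$tp, ev$fp, ev$tn, ev$fn), c(3L, 0L, 2L, 0L))
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  expect_equal(ev$balanced_accuracy, 1)

  # all-positive predictor
  ev0 <- evaluate_rule(tab, 0)
  expect_equal(ev0$sensitivity, 1)
  expect_equal(ev0$specificity, 0)

  # counts sum to table size and are permutation invariant
  sweep <- evaluate_rule(tab, 1:5)
  expect_true(all(sweep$tp + sweep$fp + sweep$tn + sweep$fn == nrow(tab)))
  perm <- evaluate_rule(tab[sample(nrow(tab)), ], 1:5)
  expect_equal(sweep, perm)
})

test_that("analysis table joins records, descriptors and charges", {
  rec <- tibble::tibble(compound_id = c("a", "b"),
                        avg_rel_visc = c(0.6, 1.0),
                        is_vra = c(TRUE, FALSE))
  desc <- tibble::tibble(id = c("a", "b"), mw = c(100, 200),
                         slogp = c(0, 1))
  chg <- tibble::tibble(id = c("a", "b"), n_charge_groups = c(3L, 1L))
  tab <- build_analysis_table(rec, desc, chg)
  expect_equal(tab$vra01, c(1L, 0L))
  expect_equal(tab$mw, c(100, 200))
  expect_equal(tab$n_charge_groups, c(3L, 1L))
})

test_that("analysis bundles serialize as JSON", {
  tab <- tibble::tibble(
    compound_id = paste0("c", 1:10),
    avg_rel_visc = c(0.5, 0.55, 0.6, 0.7, 0.75, 0.9, 0.95, 1.0, 1.05, 1.1),
    is_vra = c(rep(TRUE, 5), rep(FALSE, 5)),
    mw = seq(100, 280, by = 20), slogp = rnorm(10),
    n_charge_groups = c(3, 4, 3, 5, 3, 1, 2, 0, 2, 1)
  )
  an <- analyze_table(tab)
  expect_named(an, c("correlations", "test", "rule_eval"))
  expect_equal(nrow(an$rule_eval), 5)
  f <- tempfile(fileext = ".json")
  write_analysis_json(an, f)
  back <- jsonlite::read_json(f)
  # data frames serialize as arrays of row objects
  expect_equal(back$test[[1]]$p.value, an$test$p.value, tolerance = 1e-12)
  expect_equal(length(back$correlations), nrow(an$correlations))
})
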