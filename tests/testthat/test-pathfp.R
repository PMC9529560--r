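test_that("fragment enumeration matches hand-derived small cases", {
  expect_equal(nrow(enumerate_fragments("C")), 0)   # single C ignored
  expect_equal(nrow(enumerate_fragments("O")), 0)   # single O ignored

  but <- enumerate_fragments("CCCC")
  expect_equal(but$code, c("C-C", "C-C-C", "C-C-C-C"))

  cf <- enumerate_fragments("CF")
  expect_true("F" %in% cf$code)       # halogen single atom kept
  expect_true("C-F" %in% cf$code)

  benz <- enumerate_fragments("c1ccccc1")
  expect_true(any(benz$ring_closure))
  expect_true(all(grepl("^c", benz$code)))  # aromatic atom codes
})

test_that("fragment enumeration agrees with brute-force path enumeration", {
  mols <- c("CCO", "CC(C)C(=O)O", "c1ccccc1", "NC(Cc1c[nH]cn1)C(=O)O",
            "C1CCCCC1", "CC(=O)NC", "NCCS(=O)(=O)O", "c1ccncc1",
            "OCC1CCCO1", "N#CCC=C")
  for (s in mols) {
    got <- sort(enumerate_fragments(s)$code)
    expect_equal(got, oracle_fragments(s), label = s)
  }
})

test_that("fragment hashing is deterministic, symmetric and in range", {
  frags <- enumerate_fragments("NC(Cc1ccc(O)cc1)C(=O)O")$code
  expect_equal(hash_fragment(frags), hash_fragment(frags))
  expect_true(all(hash_fragment(frags) >= 0))
  expect_true(all(hash_fragment(frags) <= 1020))

  # canonical form first: reversed encodings share the canonical hash
  expect_equal(hash_fragment(min("C-C=O", "O=C-C")),
               hash_fragment(min("O=C-C", "C-C=O")))

  # broad range contract over many generated codes
  lib <- generate_library(sim_config(seed = 3, n_compounds = 60))
  codes <- unique(unlist(lapply(lib$smiles[1:30],
                                function(s) enumerate_fragments(s)$code)))
  h <- hash_fragment(codes)
  expect_true(all(h >= 0 & h <= 1020))
})

test_that("fingerprints are graph properties with bits confined to 0..1020", {
  expect_equal(fingerprint("C")$n_set, 0)
  expect_equal(fingerprint("CCO")$bits, fingerprint("OCC")$bits)
  fp <- fingerprint("NC(Cc1c[nH]cn1)C(=O)O")
  expect_true(all(fp$bits <= 1020))
  expect_lte(fingerprint("CCCC")$n_set, 3)
})

test_that("tanimoto obeys its identities and conventions", {
  f1 <- fingerprint("NCC(=O)O")
  expect_equal(tanimoto(f1, f1), 1.0)
  empty <- fingerprint("C")
  expect_equal(tanimoto(empty, empty), 1.0)  # 0/0 convention
  expect_equal(tanimoto(empty, f1), 0.0)

  a <- structure(list(bits = c(1L, 2L, 3L), n_set = 3L), class = "vra_fp")
  b <- structure(list(bits = c(2L, 3L, 4L), n_set = 3L), class = "vra_fp")
  expect_equal(tanimoto(a, b), 0.5)
  expect_equal(tanimoto(a, b), tanimoto(b, a))

  disj <- structure(list(bits = c(10L, 11L), n_set = 2L), class = "vra_fp")
  expect_equal(tanimoto(a, disj), 0.0)
})

test_that("similarity search finds self-hits and honours strictness", {
  lib <- tiny_library()
  hits <- similarity_search(lib[2, ], lib, threshold = 0.7)
  self <- hits[hits$hit_id == "glycine", ]
  expect_equal(self$tanimoto, 1.0)

  # threshold 1.0 against a library without the query: empty, not an error
  q <- tibble::tibble(id = "q", smiles = "CCCCCCO")
  none <- similarity_search(q, lib[5:10, ], threshold = 1.0)
  expect_equal(nrow(none), 0)

  expect_error(similarity_search(lib[0, ], lib, 0.7),
               class = "vra_config_error")

  # strict excludes hits sitting exactly at the threshold
  hits_t1 <- similarity_search(lib[2, ], lib, threshold = 1.0, strict = FALSE)
  hits_t1s <- similarity_search(lib[2, ], lib, threshold = 1.0, strict = TRUE)
  expect_true(nrow(hits_t1) > nrow(hits_t1s))
})

test_that("popcount-prescreened search equals the exhaustive scan", {
  lib <- generate_library(sim_config(seed = 21, n_compounds = 80))
  queries <- lib[seq(1, 80, by = 16), c("id", "smiles")]
  for (thr in c(0.3, 0.7, 0.9)) {
    fast <- similarity_search(queries, lib[, c("id", "smiles")],
                              threshold = thr)
    slow <- oracle_similarity(queries, lib[, c("id", "smiles")], thr)
    expect_equal(fast, slow, tolerance = 1e-12, label = paste("thr", thr))
  }
})

test_that("cluster_and_pick covers clusters and respects pick limits", {
  lib <- tiny_library()
  one <- cluster_and_pick(lib, k = 1, per_cluster = 2, seed = 5)
  expect_equal(nrow(one), 2)

  alln <- cluster_and_pick(lib, k = nrow(lib), per_cluster = 2, seed = 5)
  expect_equal(sort(alln$id), sort(lib$id))

  expect_error(cluster_and_pick(lib, k = nrow(lib) + 1),
               class = "vra_config_error")

  lib121 <- generate_library(sim_config(seed = 33, n_compounds = 121))
  picks <- cluster_and_pick(lib121[, c("id", "smiles")], k = 33,
                            per_cluster = 2, seed = 9)
  expect_lte(nrow(picks), 66)
  expect_equal(sort(unique(picks$cluster)), 1:33)
  # deterministic under a fixed seed
  picks2 <- cluster_and_pick(lib121[, c("id", "smiles")], k = 33,
                             per_cluster = 2, seed = 9)
  expect_equal(picks$id, picks2$id)
})

test_that("fingerprint hex export is a faithful 1024-bit encoding", {
  fp <- fingerprint("NC(CCCNC(=N)N)C(=O)O")
  hx <- fp_hex(fp)
  expect_equal(nchar(hx), 256)
  # decode back
  bits <- unlist(lapply(strsplit(hx, "")[[1]], function(ch) {
    v <- strtoi(ch, 16L)
    c(bitwAnd(v, 8L) > 0, bitwAnd(v, 4L) > 0, bitwAnd(v, 2L) > 0,
      bitwAnd(v, 1L) > 0)
  }))
  expect_equal(which(bits) - 1L, fp$bits)
})
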