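# Independent oracles and small fixtures used across the suite.

# a small diverse compound set with known chemistry
tiny_library <- function() {
  tibble::tibble(
    id = c("ethanol", "glycine", "arginine", "histidine", "benzene",
           "butylamine", "acetic", "taurine_like", "phenol_c", "butane"),
    smiles = c("CCO", "NCC(=O)O", "NC(CCCNC(=N)N)C(=O)O",
               "NC(Cc1c[nH]cn1)C(=O)O", "c1ccccc1", "CCCCN", "CC(=O)O",
               "NCCS(=O)(=O)O", "Oc1ccccc1", "CCCC")
  )
}

# brute-force fragment oracle: enumerates all simple paths of 1..7 atoms with
# igraph, encodes and canonicalises them independently of the package DFS
oracle_fragments <- function(smiles) {
  mol <- vrascreen::mol_from_smiles(smiles)
  n <- nrow(mol$atoms)
  acode <- ifelse(mol$atoms$arom, tolower(mol$atoms$elem), mol$atoms$elem)
  bsym <- function(i, j) {
    b <- mol$bonds
    k <- which((b$a1 == i & b$a2 == j) | (b$a1 == j & b$a2 == i))
    if (b$arom[k]) ":" else c("-", "=", "#")[min(b$order[k], 3)]
  }
  enc <- function(path) {
    if (length(path) == 1L) return(acode[path])
    parts <- acode[path[1]]
    for (k in 2:length(path)) {
      parts <- c(parts, bsym(path[k - 1], path[k]), acode[path[k]])
    }
    paste(parts, collapse = "")
  }
  canon <- function(path, closure = FALSE) {
    code <- min(enc(path), enc(rev(path)))
    if (closure) paste0(code, "@") else code
  }
  if (nrow(mol$bonds) == 0L) {
    if (n == 1L && !(mol$atoms$elem %in% c("C", "N", "O"))) {
      return(sort(acode))
    }
    return(character())
  }
  g <- igraph::graph_from_edgelist(as.matrix(mol$bonds[, c("a1", "a2")]),
                                   directed = FALSE)
  codes <- character()
  for (s in seq_len(n)) {
    paths <- igraph::all_simple_paths(g, from = s, cutoff = 6)
    for (p in paths) {
      p <- as.integer(p)
      codes <- c(codes, canon(p))
      # ring closure: last atom adjacent to an on-path atom other than its
      # predecessor (and a cycle of length >= 3)
      if (length(p) >= 3L) {
        nb <- as.integer(igraph::neighbors(g, p[length(p)]))
        if (any(nb %in% p[seq_len(length(p) - 2L)])) {
          codes <- c(codes, canon(p, closure = TRUE))
        }
      }
    }
  }
  singles <- acode[!(mol$atoms$elem %in% c("C", "N", "O"))]
  sort(unique(c(codes, singles)))
}

# exhaustive Tanimoto scan, computed straight from bit vectors
oracle_similarity <- function(queries, library, threshold) {
  qf <- vrascreen::fingerprint_library(queries)
  lf <- vrascreen::fingerprint_library(library)
  out <- list()
  for (i in seq_len(nrow(qf))) {
    for (j in seq_len(nrow(lf))) {
      a <- qf$fp[[i]]$bits
      b <- lf$fp[[j]]$bits
      cc <- length(intersect(a, b))
      t <- if (length(a) == 0 && length(b) == 0) 1 else
        cc / (length(a) + length(b) - cc)
      if (t >= threshold) {
        out[[length(out) + 1L]] <- tibble::tibble(
          query_id = qf$id[i], hit_id = lf$id[j], tanimoto = t)
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(query_id = character(), hit_id = character(),
                          tanimoto = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(out), query_id, dplyr::desc(tanimoto), hit_id)
}

# closed-form point-biserial correlation
oracle_point_biserial <- function(y01, x) {
  n <- length(x)
  n1 <- sum(y01 == 1)
  n0 <- n - n1
  sd_n <- sqrt(sum((x - mean(x))^2) / n)
  (mean(x[y01 == 1]) - mean(x[y01 == 0])) / sd_n * sqrt(n1 * n0 / n^2)
}

# reference amino-acid pKa overrides in the assign_pkas() override layout
glycine_overrides <- function() {
  tibble::tibble(
    compound_id = c("glycine", "glycine"),
    group_label = c("carboxylic_acid", "aliphatic_amine"),
    kind = c("acid", "base"),
    pka = c(2.34, 9.60)
  )
}

write_tmp_smi <- function(lines) {
  f <- tempfile(fileext = ".smi")
  writeLines(lines, f)
  f
}
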