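#' Enumerate linear fragments of a molecule
#'
#' Walks every simple path of 1--7 atoms in the hydrogen-suppressed molecular
#' graph. Single-atom fragments consisting of carbon, nitrogen or oxygen are
#' ignored. When a walk reaches an atom whose neighbour is already on the
#' path, the fragment is terminated there and flagged as a ring closure.
#' Each fragment is encoded from its atom codes (element symbol, lower case
#' when aromatic) and bond codes (`-`, `=`, `#`, `:`), and canonicalised as
#' the lexicographically smaller of the forward and reversed encodings, so
#' chemically identical fragments collapse to a single entry.
#'
#' @param x A SMILES string, a `vra_mol`, or a one-row compound tibble.
#' @return A tibble with columns `code` (canonical fragment code), `n_atoms`,
#'   and `ring_closure`.
#' @examples
#' enumerate_fragments("CCCC")  # 3 unique linear fragments
#' @export
enumerate_fragments <- function(x) {
  mol <- as_vra_mol(x)
  n <- nrow(mol$atoms)
  acode <- atom_codes(mol)
  bcode <- bond_code_matrix(mol)
  seen <- new.env(parent = emptyenv())

  record <- function(path, closure) {
    k <- length(path)
    if (k == 1L && mol$atoms$elem[path] %in% c("C", "N", "O")) return(invisible())
    fwd <- encode_path(path, acode, bcode)
    rev_ <- encode_path(rev(path), acode, bcode)
    code <- if (fwd <= rev_) fwd else rev_
    if (closure) code <- paste0(code, "@")
    if (is.null(seen[[code]])) {
      seen[[code]] <- c(n_atoms = k, ring_closure = as.integer(closure))
    }
    invisible()
  }

  walk <- function(path) {
    last <- path[length(path)]
    record(path, closure = FALSE)
    for (nb in mol$adj[[last]]) {
      if (nb %in% path) {
        # closing a cycle terminates the fragment; record the closure
        if (length(path) >= 3L && nb != path[length(path) - 1L]) {
          record(path, closure = TRUE)
        }
      } else if (length(path) < 7L) {
        walk(c(path, nb))
      }
    }
    invisible()
  }

  for (s in seq_len(n)) walk(s)

  codes <- ls(seen)
  if (length(codes) == 0L) {
    return(tibble(code = character(), n_atoms = integer(),
                  ring_closure = logical()))
  }
  meta <- do.call(rbind, mget(codes, envir = seen))
  tibble(code = codes,
         n_atoms = as.integer(meta[, "n_atoms"]),
         ring_closure = as.logical(meta[, "ring_closure"])) %>%
    arrange(.data$code)
}

as_vra_mol <- function(x) {
  if (inherits(x, "vra_mol")) return(x)
  if (is.character(x) && length(x) == 1L) return(mol_from_smiles(x))
  if (is.data.frame(x) && nrow(x) == 1L && "smiles" %in% names(x)) {
    return(mol_from_smiles(x$smiles[[1]], id = x$id[[1]]))
  }
  abort("expected a SMILES string, vra_mol, or one-row compound tibble")
}

atom_codes <- function(mol) {
  ifelse(mol$atoms$arom, tolower(mol$atoms$elem), mol$atoms$elem)
}

bond_code_matrix <- function(mol) {
  n <- nrow(mol$atoms)
  m <- matrix(NA_character_, n, n)
  b <- mol$bonds
  if (nrow(b) > 0L) {
    sym <- ifelse(b$arom, ":", c("-", "=", "#")[pmin(b$order, 3L)])
    m[cbind(b$a1, b$a2)] <- sym
    m[cbind(b$a2, b$a1)] <- sym
  }
  m
}

encode_path <- function(path, acode, bcode) {
  k <- length(path)
  if (k == 1L) return(acode[path])
  out <- character(2L * k - 1L)
  out[seq(1L, 2L * k - 1L, by = 2L)] <- acode[path]
  out[seq(2L, 2L * k - 2L, by = 2L)] <- bcode[cbind(path[-k], path[-1L])]
  paste(out, collapse = "")
}

#' Hash a canonical fragment code into the fingerprint bit range
#'
#' A fixed polynomial rolling hash (base 31) over the bytes of the canonical
#' fragment code, reduced modulo 1021, giving values in 0--1020. Identical
#' canonical fragments always map to the same bit; no compatibility with any
#' external fingerprint implementation is implied.
#'
#' @param code Character vector of canonical fragment codes.
#' @return Integer vector of hash values in `[0, 1020]`.
#' @export
hash_fragment <- function(code) {
  vapply(code, function(s) {
    h <- 0L
    for (b in utf8ToInt(s)) h <- (h * 31L + b) %% 1021L
    h
  }, integer(1), USE.NAMES = FALSE)
}

#' Compute the 1024-bit path fingerprint of a compound
#'
#' Sets bit `hash_fragment(f)` for every canonical linear fragment `f` of the
#' molecule (see [enumerate_fragments()]). Bits 1021--1023 are never set. The
#' fingerprint is a pure function of the molecular graph, invariant under
#' atom reordering of the input SMILES.
#'
#' @param x A SMILES string, `vra_mol`, or one-row compound tibble.
#' @return An object of class `vra_fp`: list with `bits` (sorted 0-based set
#'   bit positions) and `n_set`.
#' @examples
#' fp <- fingerprint("NCC(=O)O")
#' fp$n_set
#' @export
fingerprint <- function(x) {
  frags <- enumerate_fragments(x)
  bits <- sort(unique(hash_fragment(frags$code)))
  new_vra_fp(bits)
}

new_vra_fp <- function(bits) {
  structure(list(bits = as.integer(bits), n_set = length(bits)),
            class = "vra_fp")
}

#' @export
print.vra_fp <- function(x, ...) {
  cat("<vra_fp> 1024-bit path fingerprint,", x$n_set, "bits set\n")
  invisible(x)
}

#' Fingerprint every compound in a library
#'
#' @param compounds Compound tibble with `id` and `smiles`.
#' @return The input with list-column `fp` (`vra_fp` objects) and integer
#'   column `n_set` appended.
#' @export
fingerprint_library <- function(compounds) {
  compounds <- as_compound_tbl(compounds)
  fps <- lapply(seq_len(nrow(compounds)), function(i) {
    fingerprint(mol_from_smiles(compounds$smiles[i], id = compounds$id[i]))
  })
  compounds %>%
    mutate(fp = fps, n_set = vapply(fps, `[[`, integer(1), "n_set"))
}

#' Tanimoto similarity of two fingerprints
#'
#' \eqn{T = c / (a + b - c)} where `a` and `b` are the set-bit counts of the
#' two fingerprints and `c` the number of shared bits. Two all-zero
#' fingerprints have similarity 1 by convention; an all-zero against a
#' non-empty fingerprint gives 0.
#'
#' @param fa,fb `vra_fp` objects.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(fa, fb) {
  stopifnot(inherits(fa, "vra_fp"), inherits(fb, "vra_fp"))
  a <- fa$n_set
  b <- fb$n_set
  if (a == 0L && b == 0L) return(1)
  cc <- length(intersect(fa$bits, fb$bits))
  cc / (a + b - cc)
}

#' Fingerprint similarity search with popcount prescreen
#'
#' Reports every (query, library) pair whose Tanimoto similarity passes the
#' threshold. Candidate pairs are pruned with the popcount bound
#' \eqn{T \le \min(a,b)/\max(a,b)}: a library fingerprint with set-bit count
#' outside `[a*t, a/t]` cannot reach threshold `t` and is skipped without
#' computing the intersection. Results are identical to the exhaustive scan.
#'
#' @param queries,library Compound tibbles (`id`, `smiles`), or tibbles
#'   already carrying an `fp` list-column from [fingerprint_library()].
#' @param threshold Similarity threshold in `[0, 1]`; default 0.7, the
#'   screening threshold used throughout the cascade.
#' @param strict If `FALSE` (default) hits satisfy `T >= threshold`; if
#'   `TRUE`, `T > threshold`.
#' @param prescreen Use the popcount bound? (`FALSE` forces the exhaustive
#'   scan; useful for testing.)
#' @return Tibble `query_id`, `hit_id`, `tanimoto`, sorted by query then
#'   descending similarity.
#' @export
similarity_search <- function(queries, library, threshold = 0.7,
                              strict = FALSE, prescreen = TRUE) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (is.data.frame(queries) && nrow(queries) == 0L) {
    abort("empty query set", class = "vra_config_error")
  }
  qf <- ensure_fps(queries)
  lf <- ensure_fps(library)
  ln <- vapply(lf$fp, `[[`, integer(1), "n_set")
  res <- list()
  for (i in seq_len(nrow(qf))) {
    fq <- qf$fp[[i]]
    a <- fq$n_set
    cand <- seq_len(nrow(lf))
    if (prescreen && threshold > 0 && a > 0L) {
      lo <- a * threshold
      hi <- a / threshold
      cand <- cand[ln >= lo - 1e-9 & ln <= hi + 1e-9]
    }
    if (length(cand) == 0L) next
    tv <- vapply(cand, function(j) tanimoto(fq, lf$fp[[j]]), numeric(1))
    keep <- if (strict) tv > threshold else tv >= threshold
    if (any(keep)) {
      res[[length(res) + 1L]] <- tibble(
        query_id = qf$id[i],
        hit_id = lf$id[cand[keep]],
        tanimoto = tv[keep]
      )
    }
  }
  if (length(res) == 0L) {
    return(tibble(query_id = character(), hit_id = character(),
                  tanimoto = numeric()))
  }
  bind_rows(res) %>% arrange(.data$query_id, desc(.data$tanimoto), .data$hit_id)
}

ensure_fps <- function(x) {
  if (is.data.frame(x) && "fp" %in% names(x)) return(x)
  fingerprint_library(x)
}

#' Cluster a library in fingerprint space and pick cluster representatives
#'
#' k-means (k-means++ initialisation, Euclidean distance on the 0/1 bit
#' coordinates, 100 iteration cap) on the library fingerprints, followed by
#' selection of up to `per_cluster` members closest to each cluster centroid
#' (ties broken by lowest row index). This is the diverse-subset selection
#' used to pick screening queries and to sample diverse hits.
#'
#' @param library Compound tibble (with or without precomputed `fp` column).
#' @param k Number of clusters, `1 <= k <= nrow(library)`.
#' @param per_cluster Maximum picks per cluster (default 2).
#' @param seed Integer seed controlling initialisation.
#' @return Tibble of picked compounds with `cluster` and `centroid_dist`
#'   columns; at most `k * per_cluster` rows, every non-empty cluster
#'   represented.
#' @export
cluster_and_pick <- function(library, k, per_cluster = 2, seed = 1) {
  lf <- ensure_fps(library)
  n <- nrow(lf)
  if (k < 1 || k > n) {
    abort(paste0("k must be in [1, ", n, "]"), class = "vra_config_error")
  }
  X <- fp_matrix(lf$fp)
  km <- withr::with_seed(seed, {
    centers <- kmeanspp_init(X, k)
    tryCatch(
      stats::kmeans(X, centers = centers, iter.max = 100),
      error = function(e) stats::kmeans(X, centers = centers, iter.max = 100,
                                        algorithm = "MacQueen")
    )
  })
  assign <- km$cluster
  picks <- lapply(sort(unique(assign)), function(cl) {
    members <- which(assign == cl)
    d <- sqrt(rowSums((X[members, , drop = FALSE] -
                         matrix(km$centers[cl, ], length(members), ncol(X),
                                byrow = TRUE))^2))
    ord <- order(d, members)
    sel <- members[ord][seq_len(min(per_cluster, length(members)))]
    tibble(row = sel, cluster = cl,
           centroid_dist = d[ord][seq_len(length(sel))])
  })
  picks <- bind_rows(picks)
  out <- lf[picks$row, setdiff(names(lf), c("fp", "n_set")), drop = FALSE]
  out$cluster <- picks$cluster
  out$centroid_dist <- picks$centroid_dist
  out
}

# dense 0/1 matrix (rows = compounds, cols = 1024 bits)
fp_matrix <- function(fps) {
  X <- matrix(0L, length(fps), 1024L)
  for (i in seq_along(fps)) X[i, fps[[i]]$bits + 1L] <- 1L
  X
}

# k-means++ seeding (squared-distance weighted); assumes RNG seeded by caller
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- X[idx, ]
  if (k == 1L) return(centers)
  d2 <- rowSums((X - matrix(centers[1L, ], n, ncol(X), byrow = TRUE))^2)
  for (j in 2:k) {
    if (all(d2 == 0)) {
      idx <- sample.int(n, 1L)
    } else {
      idx <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2))
  }
  # duplicate centers make stats::kmeans error; jitter exact duplicates apart
  dup <- duplicated(centers)
  if (any(dup)) centers[dup, ] <- centers[dup, ] + 1e-6 * seq_len(sum(dup))
  centers
}

#' Fingerprint hex encoding
#'
#' Encodes the 1024-bit fingerprint as a 256-character hex string (big-endian
#' nibbles, bit 0 = most significant bit of the first nibble).
#'
#' @param fp A `vra_fp`.
#' @return A 256-character string.
#' @export
fp_hex <- function(fp) {
  stopifnot(inherits(fp, "vra_fp"))
  bits <- rep(0L, 1024L)
  bits[fp$bits + 1L] <- 1L
  nib <- matrix(bits, nrow = 4L)
  vals <- 8L * nib[1, ] + 4L * nib[2, ] + 2L * nib[3, ] + nib[4, ]
  paste(c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
          "a", "b", "c", "d", "e", "f")[vals + 1L], collapse = "")
}

#' Export fingerprints or similarity hits as CSV
#'
#' @param x Tibble from [fingerprint_library()] (written as `id, fp_hex`) or
#'   from [similarity_search()] (written as `query_id, hit_id, tanimoto`
#'   rounded to 4 decimals).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(x, path) {
  if ("fp" %in% names(x)) {
    out <- tibble(id = x$id,
                  fp_hex = vapply(x$fp, fp_hex, character(1)))
  } else if (all(c("query_id", "hit_id", "tanimoto") %in% names(x))) {
    out <- x %>% mutate(tanimoto = round(.data$tanimoto, 4))
  } else {
    abort("expected a fingerprint library or a hit list")
  }
  readr::write_csv(out, path)
  invisible(path)
}
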