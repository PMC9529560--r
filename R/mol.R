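#' @importFrom rlang %||% .data abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Bondi van der Waals radii (Angstrom); fallback 1.70 for elements not listed.
.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80, S = 1.80,
  Cl = 1.75, Br = 1.85, I = 1.98, B = 1.92, Si = 2.10, Se = 1.90
)

# Single-bond covalent radii (Angstrom), used for idealised bond lengths.
.cov_radii <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57, P = 1.07, S = 1.05,
  Cl = 1.02, Br = 1.20, I = 1.39, B = 0.84, Si = 1.11, Se = 1.20
)

# Default valences for implicit hydrogen assignment; multi-valent elements list
# every common valence state (lowest consistent with the bond-order sum wins).
.valences <- list(
  H = 1, C = 4, N = 3, O = 2, F = 1, Cl = 1, Br = 1, I = 1,
  S = c(2, 4, 6), P = c(3, 5), B = 3, Si = 4, Se = c(2, 4, 6)
)

.atomic_numbers <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, Se = 34, Br = 35, I = 53
)

#' Parse a SMILES string into an annotated molecular graph
#'
#' Converts a SMILES record into the hydrogen-suppressed molecular graph the
#' fingerprint, descriptor and ionization layers operate on. Structure
#' perception (SMILES parsing, kekulisation, ring finding) is delegated to
#' OpenBabel through ChemmineR/ChemmineOB; on top of that this function
#' annotates per-atom aromaticity (from perceived aromatic rings), ring
#' membership, implicit hydrogen counts (default-valence model) and an
#' adjacency list.
#'
#' @param smiles A single SMILES string.
#' @param id Optional identifier carried along for error messages.
#' @return An object of class `vra_mol`: a list with `atoms` (tibble: `idx`,
#'   `elem`, `arom`, `in_ring`, `n_h`, `degree`), `bonds` (tibble: `a1`, `a2`,
#'   `order`, `arom`, `in_ring`), `adj` (adjacency list), `n_heavy`, `smiles`.
#' @examples
#' m <- mol_from_smiles("NCC(=O)O")
#' m$atoms
#' @export
mol_from_smiles <- function(smiles, id = NULL) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  label <- id %||% smiles
  lines <- tryCatch({
    txt <- ChemmineOB::convertFormat("SMI", "SDF", source = paste0(smiles, "\n"))
    strsplit(txt, "\n", fixed = TRUE)[[1]]
  }, error = function(e) {
    abort(
      paste0("cannot parse structure '", label, "': ", conditionMessage(e)),
      class = "vra_structure_error"
    )
  })
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(lines))[[1]],
    error = function(e) {
      abort(paste0("cannot parse structure '", label, "'"),
            class = "vra_structure_error")
    }
  )
  mol_from_sdf(sdf, smiles = smiles, id = label, molfile = lines)
}

# Build a vra_mol from a ChemmineR SDF object plus its raw molfile lines.
mol_from_sdf <- function(sdf, smiles = NA_character_, id = NULL,
                         molfile = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  if (is.null(ab) || nrow(ab) == 0L) {
    abort(paste0("structure '", id %||% smiles, "' has no atoms"),
          class = "vra_structure_error")
  }
  if (!all(grepl("_", rownames(ab)))) {
    # ChemmineR's table accessors degrade on bond-free (single-atom) records;
    # recover the elements from the raw molfile atom lines instead
    elem <- molfile_elements(molfile)
  } else {
    elem <- sub("_.*$", "", rownames(ab))
  }
  n <- length(elem)

  bb <- ChemmineR::bondblock(sdf)
  if (is.null(bb) || nrow(bb) == 0L || ncol(bb) < 3L) {
    bonds <- tibble(a1 = integer(), a2 = integer(), order = integer(),
                    arom = logical(), in_ring = logical())
  } else {
    bonds <- tibble(
      a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
      order = as.integer(bb[, 3]), arom = FALSE, in_ring = FALSE
    )
  }

  arom_atom <- rep(FALSE, n)
  ring_atom <- rep(FALSE, n)
  if (n >= 2L && nrow(bonds) >= 3L) {
    rng <- tryCatch(
      ChemmineR::rings(sdf, type = "all", arom = TRUE),
      error = function(e) list(RINGS = list(), AROMATIC = logical())
    )
    ring_list <- lapply(rng$RINGS, function(r) as.integer(sub("^.*_", "", r)))
    arom_flags <- as.logical(rng$AROMATIC)
    for (k in seq_along(ring_list)) {
      members <- ring_list[[k]]
      ring_atom[members] <- TRUE
      # consecutive members (cyclically) are the ring bonds
      pairs <- cbind(members, c(members[-1], members[1]))
      hit <- (match_bond(bonds, pairs))
      bonds$in_ring[hit] <- TRUE
      if (isTRUE(arom_flags[k])) {
        arom_atom[members] <- TRUE
        bonds$arom[hit] <- TRUE
      }
    }
  }

  deg <- tabulate(c(bonds$a1, bonds$a2), nbins = n)
  bsum <- tabulate2_weighted(bonds, n)
  n_h <- vapply(seq_len(n), function(i) {
    vals <- .valences[[elem[i]]]
    if (is.null(vals)) return(0L)
    v <- vals[vals >= bsum[i]]
    if (length(v) == 0L) return(0L)
    as.integer(min(v) - bsum[i])
  }, integer(1))

  adj <- vector("list", n)
  for (i in seq_len(nrow(bonds))) {
    adj[[bonds$a1[i]]] <- c(adj[[bonds$a1[i]]], bonds$a2[i])
    adj[[bonds$a2[i]]] <- c(adj[[bonds$a2[i]]], bonds$a1[i])
  }

  structure(
    list(
      atoms = tibble(idx = seq_len(n), elem = elem, arom = arom_atom,
                     in_ring = ring_atom, n_h = n_h, degree = deg),
      bonds = bonds,
      adj = adj,
      n_heavy = sum(elem != "H"),
      smiles = smiles
    ),
    class = "vra_mol"
  )
}

# elements from the raw V2000 atom block (atom count from the counts line)
molfile_elements <- function(txt) {
  if (is.null(txt)) abort("degenerate record without molfile text",
                          class = "vra_structure_error")
  n_atoms <- as.integer(substr(txt[4], 1, 3))
  vapply(seq_len(n_atoms), function(i) {
    trimws(substr(txt[4 + i], 32, 34))
  }, character(1))
}

# rows of `bonds` matching unordered atom pairs in matrix `pairs`
match_bond <- function(bonds, pairs) {
  if (nrow(bonds) == 0L) return(integer())
  key <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2))
  want <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  which(key %in% want)
}

# per-atom bond-order sum (aromatic bonds arrive kekulised from the SDF)
tabulate2_weighted <- function(bonds, n) {
  out <- numeric(n)
  if (nrow(bonds) == 0L) return(out)
  for (i in seq_len(nrow(bonds))) {
    out[bonds$a1[i]] <- out[bonds$a1[i]] + bonds$order[i]
    out[bonds$a2[i]] <- out[bonds$a2[i]] + bonds$order[i]
  }
  out
}

#' @export
print.vra_mol <- function(x, ...) {
  cat("<vra_mol> ", x$smiles, " (", x$n_heavy, " heavy atoms, ",
      nrow(x$bonds), " bonds)\n", sep = "")
  invisible(x)
}

#' Canonical SMILES via OpenBabel
#'
#' Used as the duplicate-structure key throughout the package (stereo-aware
#' canonical form).
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES; `NA` where conversion fails.
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", source = s),
      error = function(e) NA_character_
    )
    if (is.na(out)) return(NA_character_)
    out <- strsplit(out, "[ \t\n]")[[1]]
    if (length(out) == 0L || !nzchar(out[1])) NA_character_ else out[1]
  }, character(1), USE.NAMES = FALSE)
}

# TRUE where the SMILES parses to >= 1 heavy atom
smiles_is_valid <- function(smiles) {
  vapply(smiles, function(s) {
    ok <- tryCatch({
      m <- mol_from_smiles(s)
      m$n_heavy >= 1L
    }, error = function(e) FALSE)
    isTRUE(ok)
  }, logical(1), USE.NAMES = FALSE)
}
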