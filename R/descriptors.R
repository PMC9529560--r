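#' Compute the molecular descriptor set
#'
#' Computes, per compound, the descriptor panel used by the screening filters
#' and the correlation analysis: molecular weight (average atomic masses, Da),
#' SlogP (atom-contribution octanol--water partition coefficient of the
#' neutral species, via OpenBabel), hydrogen-bond donor and acceptor counts,
#' rotatable bond count, ring count (cyclomatic), fraction of sp3 carbons,
#' topological polar surface area (\eqn{\mathrm{\AA}^2}), an approximate
#' conformer-free solvent-accessible surface area (overlapping-spheres
#' atomic-contribution model, \eqn{\mathrm{\AA}^2}), and their ratio
#' `psa_sasa`.
#'
#' SlogP, MW, TPSA, HBD and HBA come from the OpenBabel descriptor engine
#' (ChemmineOB); graph-derived counts and the approximate SASA are computed on
#' the package's annotated molecular graph. Structures are interpreted as
#' drawn, i.e. in their neutral (uncharged) form.
#'
#' @param compounds Tibble with `id` and `smiles` columns (as returned by
#'   [read_library()]), or a character vector of SMILES.
#' @param which Character vector of descriptor columns to compute; default all
#'   of `mw, slogp, hbd, hba, rot_bonds, rings, frac_csp3, psa, sasa,
#'   psa_sasa`. Restricting the set skips the molecular-graph pass when only
#'   engine descriptors (`mw`, `slogp`, `hbd`, `hba`, `psa`) are requested.
#' @return A tibble with `id` plus one column per requested descriptor.
#' @examples
#' compute_descriptors(tibble::tibble(id = "glycine", smiles = "NCC(=O)O"))
#' @export
compute_descriptors <- function(compounds,
                                which = c("mw", "slogp", "hbd", "hba",
                                          "rot_bonds", "rings", "frac_csp3",
                                          "psa", "sasa", "psa_sasa")) {
  compounds <- as_compound_tbl(compounds)
  which <- match.arg(which, several.ok = TRUE)
  if ("psa_sasa" %in% which) which <- union(which, c("psa", "sasa"))

  bad <- !smiles_is_valid(compounds$smiles)
  if (any(bad)) {
    abort(paste0("unparsable structure(s): ",
                 paste(compounds$id[bad], collapse = ", ")),
          class = "vra_structure_error")
  }

  out <- tibble(id = compounds$id)
  engine <- intersect(which, c("mw", "slogp", "hbd", "hba", "psa"))
  if (length(engine) > 0L) {
    props <- ob_properties(compounds$smiles)
    if ("mw" %in% engine) out$mw <- as.numeric(props$MW)
    if ("slogp" %in% engine) out$slogp <- as.numeric(props$logP)
    if ("hbd" %in% engine) out$hbd <- as.integer(props$HBD)
    if ("hba" %in% engine) out$hba <- as.integer(props$HBA1)
    if ("psa" %in% engine) out$psa <- as.numeric(props$TPSA)
  }

  graphy <- intersect(which, c("rot_bonds", "rings", "frac_csp3", "sasa"))
  if (length(graphy) > 0L) {
    mols <- lapply(seq_len(nrow(compounds)), function(i) {
      mol_from_smiles(compounds$smiles[i], id = compounds$id[i])
    })
    if ("rot_bonds" %in% graphy) {
      out$rot_bonds <- vapply(mols, count_rotatable_bonds, integer(1))
    }
    if ("rings" %in% graphy) {
      out$rings <- vapply(mols, count_rings, integer(1))
    }
    if ("frac_csp3" %in% graphy) {
      out$frac_csp3 <- vapply(mols, fraction_csp3, numeric(1))
    }
    if ("sasa" %in% graphy) {
      out$sasa <- vapply(mols, approx_sasa, numeric(1))
    }
  }
  if ("psa_sasa" %in% which) out$psa_sasa <- out$psa / out$sasa
  out[, c("id", intersect(c("mw", "slogp", "hbd", "hba", "rot_bonds", "rings",
                            "frac_csp3", "psa", "sasa", "psa_sasa"),
                          which)), drop = FALSE]
}

# batch OpenBabel descriptor engine straight from SMILES text (row order
# preserved); avoids intermediate SDF objects
ob_properties <- function(smiles) {
  input <- paste0(paste(smiles, seq_along(smiles)), "\n", collapse = "")
  ChemmineOB::forEachMol("SMILES", input, ChemmineOB::prop_OB,
                         reduce = function(...) rbind(...))
}

# accept a tibble with id/smiles or a bare character vector of SMILES
as_compound_tbl <- function(compounds) {
  if (is.character(compounds)) {
    return(tibble(id = if (!is.null(names(compounds)) && all(nzchar(names(compounds))))
                         names(compounds) else paste0("cmpd_", seq_along(compounds)),
                  smiles = unname(compounds)))
  }
  stopifnot(is.data.frame(compounds),
            all(c("id", "smiles") %in% names(compounds)))
  as_tibble(compounds)
}

# rotatable bond: single, acyclic, non-terminal, excluding amide C-N
count_rotatable_bonds <- function(mol) {
  b <- mol$bonds
  if (nrow(b) == 0L) return(0L)
  deg <- mol$atoms$degree
  cand <- b$order == 1L & !b$in_ring & deg[b$a1] > 1L & deg[b$a2] > 1L
  amide <- vapply(seq_len(nrow(b)), function(i) {
    is_amide_bond(mol, b$a1[i], b$a2[i])
  }, logical(1))
  as.integer(sum(cand & !amide))
}

# C-N single bond where the carbon carries a double-bonded O (amide/peptide)
is_amide_bond <- function(mol, i, j) {
  el <- mol$atoms$elem
  for (p in list(c(i, j), c(j, i))) {
    cc <- p[1]; nn <- p[2]
    if (el[cc] == "C" && el[nn] == "N") {
      nb <- mol$adj[[cc]]
      dbl_o <- any(vapply(nb, function(k) {
        el[k] == "O" && bond_order(mol, cc, k) == 2L
      }, logical(1)))
      if (dbl_o) return(TRUE)
    }
  }
  FALSE
}

bond_order <- function(mol, i, j) {
  b <- mol$bonds
  hit <- (b$a1 == i & b$a2 == j) | (b$a1 == j & b$a2 == i)
  if (!any(hit)) return(0L)
  b$order[which(hit)[1]]
}

# cyclomatic ring count: bonds - atoms + connected components
count_rings <- function(mol) {
  n <- nrow(mol$atoms)
  as.integer(nrow(mol$bonds) - n + n_components(mol$adj, n))
}

n_components <- function(adj, n) {
  seen <- rep(FALSE, n)
  comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue) > 0L) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  comps
}

fraction_csp3 <- function(mol) {
  at <- mol$atoms
  carbons <- which(at$elem == "C")
  if (length(carbons) == 0L) return(NA_real_)
  sp3 <- vapply(carbons, function(i) {
    if (at$arom[i]) return(FALSE)
    b <- mol$bonds
    touching <- b$order[b$a1 == i | b$a2 == i]
    all(touching == 1L)
  }, logical(1))
  mean(sp3)
}

#' Approximate solvent-accessible surface area without 3D coordinates
#'
#' An atomic-contribution SASA estimate: each heavy atom (and each implicit
#' hydrogen) contributes a probe-inflated van der Waals sphere (Bondi radii,
#' probe 1.4 A) from which the spherical caps buried by its bonded neighbours
#' at idealised single-bond distances are subtracted. 1-3 and through-space
#' overlaps are ignored, so values are generous relative to conformer-based
#' SASA; the quantity is used only as a polarity normaliser (`psa_sasa`).
#'
#' @param mol A `vra_mol`.
#' @return Approximate SASA in \eqn{\mathrm{\AA}^2}.
#' @export
approx_sasa <- function(mol) {
  probe <- 1.4
  at <- mol$atoms
  rad <- function(el) {
    r <- .vdw_radii[el]
    (if (is.na(r)) 1.70 else unname(r)) + probe
  }
  cov <- function(el) {
    r <- .cov_radii[el]
    if (is.na(r)) 0.77 else unname(r)
  }
  total <- 0
  for (i in seq_len(nrow(at))) {
    R1 <- rad(at$elem[i])
    area <- 4 * pi * R1^2
    neighbours <- mol$adj[[i]]
    for (j in neighbours) {
      d <- cov(at$elem[i]) + cov(at$elem[j])
      area <- area - cap_area(R1, rad(at$elem[j]), d)
    }
    # implicit hydrogens bury a cap on the parent and contribute their own
    # probe-inflated sphere minus the cap buried by the parent
    if (at$n_h[i] > 0L) {
      dh <- cov(at$elem[i]) + .cov_radii[["H"]]
      Rh <- .vdw_radii[["H"]] + probe
      area <- area - at$n_h[i] * cap_area(R1, Rh, dh)
      h_area <- 4 * pi * Rh^2 - cap_area(Rh, R1, dh)
      total <- total + at$n_h[i] * max(0, h_area)
    }
    total <- total + max(0, area)
  }
  total
}

# spherical cap of sphere radius R1 buried by sphere radius R2 at distance d
cap_area <- function(R1, R2, d) {
  if (d >= R1 + R2) return(0)
  if (d + R1 <= R2) return(4 * pi * R1^2)  # engulfed
  h <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  if (h <= 0) return(0)
  2 * pi * R1 * h
}

#' Write a descriptor table as CSV
#'
#' Column order is fixed to `id, mw, slogp, hbd, hba, rot_bonds, rings,
#' frac_csp3, psa, sasa, psa_sasa`.
#'
#' @param descriptors Tibble from [compute_descriptors()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(descriptors, path) {
  cols <- c("id", "mw", "slogp", "hbd", "hba", "rot_bonds", "rings",
            "frac_csp3", "psa", "sasa", "psa_sasa")
  stopifnot(all(cols %in% names(descriptors)))
  readr::write_csv(descriptors[, cols], path)
  invisible(path)
}
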