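#' Built-in functional-group pKa table
#'
#' The transparent pattern-to-pKa lookup used by [assign_pkas()]: one row per
#' ionizable functional-group class with a representative literature
#' micro-pKa. Per-compound values can be overridden through the `overrides`
#' argument of [assign_pkas()].
#'
#' @return Tibble with `label`, `kind` (`"acid"`/`"base"`), `pka`.
#' @export
pka_table <- function() {
  tibble::tribble(
    ~label,              ~kind,  ~pka,
    "carboxylic_acid",   "acid",  4.2,
    "phosphonic_acid_1", "acid",  2.0,
    "phosphonic_acid_2", "acid",  7.2,
    "sulfonic_acid",     "acid",  1.0,
    "tetrazole",         "acid",  4.9,
    "phenol",            "acid", 10.0,
    "thiol",             "acid",  8.3,
    "aliphatic_amine",   "base", 10.6,
    "guanidine",         "base", 12.5,
    "amidine",           "base", 11.5,
    "imidazole",         "base",  6.95,
    "pyridine",          "base",  5.2,
    "aniline",           "base",  4.6
  )
}

#' Assign ionizable groups and pKa values to compounds
#'
#' Matches every ionizable functional group of the built-in pattern table
#' (carboxylic, phosphonic, sulfonic acids, tetrazole, phenol, thiol,
#' aliphatic amines, guanidine, amidine, imidazole, pyridine, aniline)
#' against each compound's molecular graph and attaches the table pKa.
#' Override entries, keyed by `compound_id` + `group_label`, replace the
#' table pKa; when a compound carries several groups with the same label,
#' override rows are applied to them in atom-index order.
#'
#' @param compounds Compound tibble (`id`, `smiles`) or character vector of
#'   SMILES.
#' @param overrides Optional tibble or CSV path with columns `compound_id`,
#'   `group_label`, `kind`, `pka`.
#' @return Tibble with one row per ionizable group: `id`, `label`, `kind`,
#'   `pka`, `position` (anchor atom index), ordered by `id` then `position`.
#' @examples
#' assign_pkas(tibble::tibble(id = "ethanolamine", smiles = "NCCO"))
#' @export
assign_pkas <- function(compounds, overrides = NULL) {
  compounds <- as_compound_tbl(compounds)
  if (is.character(overrides)) {
    overrides <- readr::read_csv(overrides, show_col_types = FALSE,
                                 progress = FALSE)
  }
  if (!is.null(overrides)) {
    stopifnot(all(c("compound_id", "group_label", "pka") %in% names(overrides)))
  }
  out <- lapply(seq_len(nrow(compounds)), function(i) {
    mol <- mol_from_smiles(compounds$smiles[i], id = compounds$id[i])
    g <- detect_ionizable_groups(mol)
    if (nrow(g) > 0L) g$id <- compounds$id[i]
    g
  })
  groups <- bind_rows(out)
  if (nrow(groups) == 0L) {
    return(tibble(id = character(), label = character(), kind = character(),
                  pka = numeric(), position = integer()))
  }
  groups <- groups %>%
    select("id", "label", "kind", "pka", "position") %>%
    arrange(match(.data$id, compounds$id), .data$position)
  if (!is.null(overrides) && nrow(overrides) > 0L) {
    groups <- groups %>%
      group_by(.data$id, .data$label) %>%
      mutate(.occ = dplyr::row_number()) %>%
      ungroup()
    ov <- overrides %>%
      group_by(.data$compound_id, .data$group_label) %>%
      mutate(.occ = dplyr::row_number()) %>%
      ungroup() %>%
      select(id = "compound_id", label = "group_label", new_pka = "pka", ".occ")
    groups <- groups %>%
      left_join(ov, by = c("id", "label", ".occ")) %>%
      mutate(pka = ifelse(is.na(.data$new_pka), .data$pka, .data$new_pka)) %>%
      select(-".occ", -"new_pka")
  }
  groups
}

# Functional-group perception on the annotated graph. Returns one row per
# group with an anchor atom index. Nitrogens consumed by a higher-priority
# group (guanidine, amidine, amide) are excluded from the amine classes.
detect_ionizable_groups <- function(mol) {
  at <- mol$atoms
  el <- at$elem
  tab <- pka_table()
  rowfor <- function(label) tab[tab$label == label, ]
  res <- list()
  add <- function(label, pos) {
    r <- rowfor(label)
    res[[length(res) + 1L]] <<- tibble(label = label, kind = r$kind,
                                       pka = r$pka, position = as.integer(pos))
  }
  nbrs <- mol$adj
  ord <- function(i, j) bond_order(mol, i, j)
  consumed_n <- integer()

  carbons <- which(el == "C" & !at$arom)
  for (i in carbons) {
    nb <- nbrs[[i]]
    n_nb <- nb[el[nb] == "N" & !at$arom[nb]]
    has_imine <- any(vapply(n_nb, function(j) ord(i, j) == 2L, logical(1)))
    if (has_imine && length(n_nb) == 3L) {
      add("guanidine", i)
      consumed_n <- c(consumed_n, n_nb)
    } else if (has_imine && length(n_nb) == 2L) {
      add("amidine", i)
      consumed_n <- c(consumed_n, n_nb)
    }
  }

  # carbonyl carbons: classify carboxylic acids, and mark amide nitrogens
  for (i in carbons) {
    nb <- nbrs[[i]]
    o_dbl <- nb[el[nb] == "O" & vapply(nb, function(j) ord(i, j) == 2L, logical(1))]
    if (length(o_dbl) == 0L) next
    o_h <- nb[el[nb] == "O" & at$n_h[nb] >= 1L &
                vapply(nb, function(j) ord(i, j) == 1L, logical(1))]
    if (length(o_h) >= 1L) add("carboxylic_acid", i)
    consumed_n <- c(consumed_n, nb[el[nb] == "N"])  # amide N not basic
  }

  for (i in which(el == "P")) {
    nb <- nbrs[[i]]
    has_dbl_o <- any(el[nb] == "O" & vapply(nb, function(j) ord(i, j) == 2L,
                                            logical(1)))
    if (!has_dbl_o) next
    n_oh <- sum(el[nb] == "O" & at$n_h[nb] >= 1L &
                  vapply(nb, function(j) ord(i, j) == 1L, logical(1)))
    if (n_oh >= 1L) add("phosphonic_acid_1", i)
    if (n_oh >= 2L) add("phosphonic_acid_2", i)
  }

  for (i in which(el == "S")) {
    nb <- nbrs[[i]]
    n_dbl_o <- sum(el[nb] == "O" & vapply(nb, function(j) ord(i, j) == 2L,
                                          logical(1)))
    n_oh <- sum(el[nb] == "O" & at$n_h[nb] >= 1L &
                  vapply(nb, function(j) ord(i, j) == 1L, logical(1)))
    if (n_dbl_o >= 2L && n_oh >= 1L) add("sulfonic_acid", i)
    if (length(nb) == 1L && at$n_h[i] >= 1L && el[nb] == "C" && !at$arom[nb]) {
      add("thiol", i)
    }
  }

  # aromatic-ring nitrogen chemistry needs the perceived rings
  rings5 <- aromatic_rings_of_size(mol, 5L)
  for (r in rings5) {
    n_in_ring <- r[el[r] == "N"]
    if (length(n_in_ring) == 4L) {
      nh <- n_in_ring[at$n_h[n_in_ring] >= 1L]
      add("tetrazole", if (length(nh) > 0L) min(nh) else min(n_in_ring))
      consumed_n <- c(consumed_n, n_in_ring)
    } else if (length(n_in_ring) == 2L) {
      basic_n <- n_in_ring[at$n_h[n_in_ring] == 0L]
      add("imidazole", if (length(basic_n) > 0L) min(basic_n) else min(n_in_ring))
      consumed_n <- c(consumed_n, n_in_ring)
    }
  }
  rings6 <- aromatic_rings_of_size(mol, 6L)
  for (r in rings6) {
    for (i in r[el[r] == "N"]) {
      if (!(i %in% consumed_n)) {
        add("pyridine", i)
        consumed_n <- c(consumed_n, i)
      }
    }
  }

  for (i in which(el == "O" & at$n_h >= 1L)) {
    nb <- nbrs[[i]]
    if (length(nb) == 1L && at$arom[nb] && el[nb] == "C") add("phenol", i)
  }

  # remaining nitrogens: aliphatic amine vs aniline
  sulfonyl_n <- unlist(lapply(which(el == "S"), function(i) {
    nb <- nbrs[[i]]
    n_dbl_o <- sum(el[nb] == "O" & vapply(nb, function(j) ord(i, j) == 2L,
                                          logical(1)))
    if (n_dbl_o >= 1L) nb[el[nb] == "N"] else integer()
  }))
  consumed_n <- c(consumed_n, sulfonyl_n)
  for (i in which(el == "N" & !at$arom)) {
    if (i %in% consumed_n) next
    nb <- nbrs[[i]]
    if (any(vapply(nb, function(j) ord(i, j) > 1L, logical(1)))) next  # imine/nitrile
    if (any(el[nb] == "N") || any(el[nb] == "O")) next  # hydrazine/hydroxylamine-ish: skip
    if (any(at$arom[nb])) {
      add("aniline", i)
    } else if (length(nb) > 0L) {
      add("aliphatic_amine", i)
    }
  }

  if (length(res) == 0L) {
    return(tibble(label = character(), kind = character(), pka = numeric(),
                  position = integer()))
  }
  bind_rows(res) %>% arrange(.data$position, .data$label)
}

aromatic_rings_of_size <- function(mol, size) {
  if (nrow(mol$bonds) < 3L || !any(mol$atoms$arom)) return(list())
  # re-perceive rings from the bond graph: aromatic rings are those whose
  # every bond is flagged aromatic
  b <- mol$bonds[mol$bonds$arom, , drop = FALSE]
  if (nrow(b) == 0L) return(list())
  rings <- find_cycles(mol, size)
  Filter(function(r) {
    pairs <- cbind(r, c(r[-1], r[1]))
    all(vapply(seq_len(nrow(pairs)), function(k) {
      any((b$a1 == pairs[k, 1] & b$a2 == pairs[k, 2]) |
            (b$a2 == pairs[k, 1] & b$a1 == pairs[k, 2]))
    }, logical(1)))
  }, rings)
}

# all simple cycles of exactly `size` atoms (small molecules only)
find_cycles <- function(mol, size) {
  n <- nrow(mol$atoms)
  out <- list()
  seen <- character()
  walk <- function(path) {
    last <- path[length(path)]
    if (length(path) == size) {
      if (path[1] %in% mol$adj[[last]]) {
        key <- paste(sort(path), collapse = "-")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          out[[length(out) + 1L]] <<- path
        }
      }
      return(invisible())
    }
    for (nb in mol$adj[[last]]) {
      if (!(nb %in% path) && nb > path[1]) walk(c(path, nb))
    }
    invisible()
  }
  for (s in seq_len(n)) walk(s)
  out
}

#' Construct a charge-counting rule
#'
#' Two rules for deciding which ionizable groups count as charge groups:
#' * `"threshold"` (screening default): an acid counts as a negative charge
#'   group iff its pKa is below `acid_pka_max` (default 6.4); a base counts
#'   as positive iff its pKa is above `base_pka_min` (default 8.4). pH-free.
#' * `"window"`: a group counts iff its Henderson--Hasselbalch charged
#'   fraction at `ph` is at least `min_charged_fraction` (default 0.10).
#'   This reproduces the amino-acid counting in which histidine's imidazole
#'   (pKa near 6) is a charge group at formulation pH 6.
#'
#' @param mode `"threshold"` or `"window"`.
#' @param acid_pka_max,base_pka_min Threshold-mode cutoffs (pH units).
#' @param ph Window-mode target pH (default 6.0, the formulation pH).
#' @param min_charged_fraction Window-mode minimum charged fraction.
#' @return A `vra_charge_rule` object.
#' @export
charge_rule <- function(mode = c("threshold", "window"),
                        acid_pka_max = 6.4, base_pka_min = 8.4,
                        ph = 6.0, min_charged_fraction = 0.10) {
  mode <- match.arg(mode)
  stopifnot(acid_pka_max >= 0, acid_pka_max <= 14,
            base_pka_min >= 0, base_pka_min <= 14,
            ph >= 0, ph <= 14,
            min_charged_fraction > 0, min_charged_fraction <= 1)
  structure(list(mode = mode, acid_pka_max = acid_pka_max,
                 base_pka_min = base_pka_min, ph = ph,
                 min_charged_fraction = min_charged_fraction),
            class = "vra_charge_rule")
}

#' @export
print.vra_charge_rule <- function(x, ...) {
  if (x$mode == "threshold") {
    cat("<charge rule> threshold: acid pKa <", x$acid_pka_max,
        "-> negative; base pKa >", x$base_pka_min, "-> positive\n")
  } else {
    cat("<charge rule> window: charged fraction >=", x$min_charged_fraction,
        "at pH", x$ph, "\n")
  }
  invisible(x)
}

# Henderson-Hasselbalch charged fraction of a single group
charged_fraction <- function(kind, pka, ph) {
  ifelse(kind == "acid",
         1 / (1 + 10^(pka - ph)),   # deprotonated (-1) fraction
         1 / (1 + 10^(ph - pka)))   # protonated (+1) fraction
}

#' Count charge groups under a rule
#'
#' @param groups Tibble of ionizable groups (`kind`, `pka`, optionally `id`),
#'   as returned by [assign_pkas()] or carried by the amino-acid table.
#' @param rule A [charge_rule()].
#' @return Tibble with `n_pos`, `n_neg`, `n_charge_groups` (one row per `id`
#'   if present, else a single row).
#' @examples
#' gly <- tibble::tibble(kind = c("acid", "base"), pka = c(2.34, 9.60))
#' count_charge_groups(gly, charge_rule("threshold"))
#' @export
count_charge_groups <- function(groups, rule = charge_rule()) {
  stopifnot(inherits(rule, "vra_charge_rule"))
  groups <- as_tibble(groups)
  if (!("id" %in% names(groups))) groups$id <- "compound"
  counted <- group_counts_flag(groups, rule)
  groups %>%
    mutate(.counts = counted) %>%
    group_by(.data$id) %>%
    summarise(
      n_pos = sum(.data$.counts & .data$kind == "base"),
      n_neg = sum(.data$.counts & .data$kind == "acid"),
      .groups = "drop"
    ) %>%
    mutate(n_charge_groups = .data$n_pos + .data$n_neg)
}

group_counts_flag <- function(groups, rule) {
  if (nrow(groups) == 0L) return(logical())
  if (rule$mode == "threshold") {
    ifelse(groups$kind == "acid",
           groups$pka < rule$acid_pka_max,
           groups$pka > rule$base_pka_min)
  } else {
    charged_fraction(groups$kind, groups$pka, rule$ph) >= rule$min_charged_fraction
  }
}

#' Expected and major-species charge at a pH
#'
#' Under the independent-groups Henderson--Hasselbalch model: the net charge
#' is the sum of signed expected per-group charges (acids contribute
#' \eqn{-1/(1+10^{pKa-pH})}, bases \eqn{+1/(1+10^{pH-pKa})}), the absolute
#' charge is the sum of unsigned charged fractions, and the major-species
#' charge rounds each group independently (charged when its fraction exceeds
#' 0.5; ties round to the uncharged state).
#'
#' @inheritParams count_charge_groups
#' @param ph Target pH in `[0, 14]`.
#' @return Tibble with `net_charge`, `abs_charge`, `major_species_charge`
#'   (one row per `id` if present).
#' @examples
#' gly <- tibble::tibble(kind = c("acid", "base"), pka = c(2.34, 9.60))
#' charge_at_ph(gly, 6.0)  # zwitterion: net ~ 0, major species 0
#' @export
charge_at_ph <- function(groups, ph = 6.0) {
  if (ph < 0 || ph > 14) abort("ph must be in [0, 14]", class = "vra_domain_error")
  groups <- as_tibble(groups)
  if (!("id" %in% names(groups))) groups$id <- "compound"
  frac <- charged_fraction(groups$kind, groups$pka, ph)
  sign <- ifelse(groups$kind == "acid", -1, 1)
  groups %>%
    mutate(.frac = frac, .sign = sign) %>%
    group_by(.data$id) %>%
    summarise(
      net_charge = sum(.data$.sign * .data$.frac),
      abs_charge = sum(.data$.frac),
      major_species_charge = as.integer(sum(.data$.sign * (.data$.frac > 0.5))),
      .groups = "drop"
    )
}

#' Full charge profile of a compound set
#'
#' Convenience wrapper joining [count_charge_groups()] and [charge_at_ph()]
#' on groups from [assign_pkas()] (or a pre-built group table).
#'
#' @param compounds Compound tibble, or a group tibble already carrying
#'   `id`, `kind`, `pka` (detected by the presence of a `pka` column).
#' @param rule A [charge_rule()].
#' @param ph pH for the expected-charge calculation (default `rule$ph`).
#' @param overrides Optional pKa override table passed to [assign_pkas()].
#' @return Tibble `id`, `n_pos`, `n_neg`, `n_charge_groups`, `net_charge`,
#'   `abs_charge`, `major_species_charge`, `rule`, `ph`.
#' @export
charge_profile <- function(compounds, rule = charge_rule(), ph = NULL,
                           overrides = NULL) {
  ph <- ph %||% rule$ph
  if (is.data.frame(compounds) && "pka" %in% names(compounds)) {
    groups <- as_tibble(compounds)
    if (!("id" %in% names(groups))) groups$id <- "compound"
    all_ids <- unique(groups$id)
  } else {
    groups <- assign_pkas(compounds, overrides = overrides)
    all_ids <- if (is.data.frame(compounds)) compounds$id else
      as_compound_tbl(compounds)$id
  }
  counts <- count_charge_groups(groups, rule)
  charges <- charge_at_ph(groups, ph)
  tibble(id = all_ids) %>%
    left_join(counts, by = "id") %>%
    left_join(charges, by = "id") %>%
    mutate(
      across(c("n_pos", "n_neg", "n_charge_groups"),
             ~ tidyr::replace_na(.x, 0L)),
      across(c("net_charge", "abs_charge"), ~ tidyr::replace_na(.x, 0)),
      major_species_charge = tidyr::replace_na(.data$major_species_charge, 0L),
      rule = rule$mode, ph = ph
    )
}
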