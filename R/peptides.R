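#' The 20 canonical amino acids with reference pKa values
#'
#' Loads the packaged amino-acid table: one-letter code, name, SMILES
#' (written amine-first, carboxyl-last so residues condense by string
#' concatenation), and the textbook pKa values of the alpha-carboxyl,
#' alpha-amino and ionizable side-chain groups.
#'
#' @return A tibble with one row per amino acid: `code`, `name`, `smiles`,
#'   and a `groups` list-column of tibbles (`label`, `kind`, `pka`).
#' @examples
#' amino_acids()$code
#' @export
amino_acids <- function() {
  cached <- .vra_cache[["amino_acids"]]
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "amino_acids.csv", package = "vrascreen")
  df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  out <- df %>%
    tidyr::nest(groups = c("group_label", "kind", "pka")) %>%
    mutate(groups = lapply(.data$groups, function(g) {
      g %>% select(label = "group_label", "kind", "pka")
    }))
  .vra_cache[["amino_acids"]] <- out
  out
}

.vra_cache <- new.env(parent = emptyenv())

#' Amino-acid ionizable groups in long format
#'
#' @param aas Amino-acid tibble from [amino_acids()].
#' @return Tibble `id` (one-letter code), `label`, `kind`, `pka`.
#' @export
aa_groups <- function(aas = amino_acids()) {
  aas %>%
    select(id = "code", "groups") %>%
    tidyr::unnest("groups")
}

#' Enumerate all dipeptides of an amino-acid set
#'
#' Builds every ordered pair (sequence direction matters, so `n` amino acids
#' give exactly `n^2` dipeptides). The structure is the peptide-bond
#' condensation of the two residues (loss of one water), so the molecular
#' weight of each dipeptide equals the sum of the two amino-acid weights
#' minus 18.02 Da. Ionizable groups follow the independent-groups model: the
#' N-terminal amine and C-terminal carboxyl take backbone default pKas
#' (amide formation leaves the internal backbone groups non-ionizable), and
#' side-chain groups inherit their free-amino-acid pKas.
#'
#' @param aas Amino-acid tibble from [amino_acids()] (codes must be unique).
#' @param n_term_pka pKa of the free N-terminal amine (default 8.2).
#' @param c_term_pka pKa of the free C-terminal carboxyl (default 3.1).
#' @return Tibble with `id` (`dip_XY`), `seq` (two-letter code, N to C),
#'   `aa1`, `aa2`, `smiles`, `source`, and a `groups` list-column.
#' @examples
#' nrow(enumerate_dipeptides())  # 400
#' @export
enumerate_dipeptides <- function(aas = amino_acids(),
                                 n_term_pka = 8.2, c_term_pka = 3.1) {
  if (nrow(aas) == 0L) abort("empty amino-acid set", class = "vra_config_error")
  if (anyDuplicated(aas$code)) {
    abort("duplicate amino-acid codes", class = "vra_config_error")
  }
  if (!all(grepl("C\\(=O\\)O$", aas$smiles)) || !all(grepl("^N", aas$smiles))) {
    abort("amino-acid SMILES must be written amine-first, carboxyl-last",
          class = "vra_config_error")
  }
  n <- nrow(aas)
  i <- rep(seq_len(n), each = n)
  j <- rep(seq_len(n), times = n)
  side <- lapply(aas$groups, function(g) g[!grepl("^alpha_", g$label), ])
  groups <- lapply(seq_along(i), function(r) {
    s1 <- side[[i[r]]]
    s2 <- side[[j[r]]]
    tibble::new_tibble(list(
      label = c("n_terminal_amine", "c_terminal_carboxyl",
                if (nrow(s1)) paste0("res1_", s1$label),
                if (nrow(s2)) paste0("res2_", s2$label)),
      kind = c("base", "acid", s1$kind, s2$kind),
      pka = c(n_term_pka, c_term_pka, s1$pka, s2$pka)
    ), nrow = 2L + nrow(s1) + nrow(s2))
  })
  tibble(
    id = paste0("dip_", aas$code[i], aas$code[j]),
    seq = paste0(aas$code[i], aas$code[j]),
    aa1 = aas$code[i], aa2 = aas$code[j],
    smiles = paste0(sub("C\\(=O\\)O$", "C(=O)", aas$smiles[i]), aas$smiles[j]),
    source = "dipeptide",
    groups = groups
  )
}

#' Dipeptide ionizable groups in long format
#'
#' @param dps Dipeptide tibble from [enumerate_dipeptides()].
#' @return Tibble `id`, `label`, `kind`, `pka`.
#' @export
dipeptide_groups <- function(dps) {
  dps %>%
    select("id", "groups") %>%
    tidyr::unnest("groups")
}

#' Keep dipeptides with buffering capacity near a target pH
#'
#' Retains dipeptides that have at least one ionizable group with pKa inside
#' the closed window `[pka_low, pka_high]`. The default window 5--7 selects
#' compounds with high buffering capacity at formulation pH 6.0.
#'
#' @param dps Dipeptide tibble from [enumerate_dipeptides()].
#' @param pka_low,pka_high Window bounds (pH units), `pka_low < pka_high`.
#' @return The qualifying subset of `dps`.
#' @export
buffering_filter <- function(dps, pka_low = 5, pka_high = 7) {
  stopifnot(pka_low < pka_high)
  keep <- vapply(dps$groups, function(g) {
    any(g$pka >= pka_low & g$pka <= pka_high)
  }, logical(1))
  dps[keep, , drop = FALSE]
}

#' Dual-excipient candidates: buffering plus multiple charge groups
#'
#' Applies [buffering_filter()] and then keeps dipeptides whose charge-group
#' count under `rule` is at least `min_groups`. Per-survivor positive and
#' negative counts are appended so the characteristic (2 positive + 1
#' negative) / (1 positive + 2 negative) patterns are visible.
#'
#' @param dps Dipeptide tibble from [enumerate_dipeptides()].
#' @param rule A [charge_rule()]; the window rule at pH 6.0 by default, which
#'   counts the histidine imidazole.
#' @param min_groups Minimum charge-group count (default 3).
#' @param pka_low,pka_high Buffering window passed through (default 5--7).
#' @return Qualifying dipeptides with `n_pos`, `n_neg`, `n_charge_groups`.
#' @export
dual_excipient_candidates <- function(dps,
                                      rule = charge_rule("window", ph = 6.0),
                                      min_groups = 3,
                                      pka_low = 5, pka_high = 7) {
  stopifnot(min_groups >= 0)
  buffered <- buffering_filter(dps, pka_low, pka_high)
  if (nrow(buffered) == 0L) return(buffered)
  counts <- count_charge_groups(dipeptide_groups(buffered), rule)
  buffered %>%
    left_join(counts, by = "id") %>%
    filter(.data$n_charge_groups >= min_groups)
}
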