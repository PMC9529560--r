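#' Read a compound library
#'
#' Reads a small-molecule library from a `.smi` file (whitespace-separated
#' `SMILES id [name...]`, one record per line, `#` comments allowed), an SDF
#' file (MDL multi-record; the record title is used as id when present), or a
#' CSV with at least `smiles` and `id` columns. Records whose structure does
#' not parse to at least one heavy atom are skipped with a warning reporting
#' the count; with `dedupe = TRUE` duplicate structures (by stereo-aware
#' canonical SMILES) are removed, keeping the first occurrence.
#'
#' @param path Path to the library file.
#' @param format One of `"smi"`, `"sdf"`, `"csv"`; default guessed from the
#'   file extension.
#' @param dedupe Remove duplicate structures by canonical SMILES? Default
#'   `FALSE`.
#' @param source Provenance tag recorded per compound; one of `"literature"`,
#'   `"similarity_hit"`, `"chemspace"`, `"safe_library"`, `"dipeptide"`,
#'   `"synthetic"`.
#' @return A tibble with columns `id`, `smiles`, `name`, `source`, one row per
#'   valid (and, if requested, unique) compound.
#' @examples
#' f <- tempfile(fileext = ".smi")
#' writeLines(c("CCO ethanol", "NCC(=O)O glycine"), f)
#' read_library(f)
#' @export
read_library <- function(path,
                         format = c("auto", "smi", "sdf", "csv"),
                         dedupe = FALSE,
                         source = "literature") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("library file not found: ", path), class = "vra_io_error")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, smi = "smi", sdf = "sdf", csv = "csv",
                     abort(paste0("cannot guess library format from '.", ext,
                                  "'; pass `format`"), class = "vra_io_error"))
  }
  lib <- switch(format,
    smi = read_smi_file(path, source),
    sdf = read_sdf_file(path, source),
    csv = read_csv_library(path, source)
  )
  valid <- smiles_is_valid(lib$smiles)
  if (any(!valid)) {
    warn(paste0("skipped ", sum(!valid), " record(s) with unparsable structures: ",
                paste(utils::head(lib$id[!valid], 5), collapse = ", ")))
    lib <- lib[valid, , drop = FALSE]
  }
  if (nrow(lib) == 0L) {
    abort(paste0("no valid records in ", path), class = "vra_empty_library_error")
  }
  if (dedupe) {
    can <- canonical_smiles(lib$smiles)
    lib <- lib[!duplicated(can), , drop = FALSE]
  }
  if (anyDuplicated(lib$id)) {
    warn("duplicate compound ids present; ids should be unique within a library")
  }
  as_tibble(lib)
}

read_smi_file <- function(path, source) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[ \t]+")
  tibble(
    id = vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) >= 2) parts[[i]][2] else paste0("cmpd_", i)
    }, character(1)),
    smiles = vapply(parts, `[[`, character(1), 1),
    name = vapply(parts, function(p) {
      if (length(p) >= 3) paste(p[-(1:2)], collapse = " ") else NA_character_
    }, character(1)),
    source = source
  )
}

read_sdf_file <- function(path, source) {
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  ok <- ChemmineR::validSDF(sdfs)
  # validSDF also rejects legitimate single-atom, bond-free records; keep any
  # record that still yields atoms
  n <- length(sdfs)
  rows <- lapply(seq_len(n), function(i) {
    sdf <- sdfs[[i]]
    smi <- tryCatch({
      out <- ChemmineOB::convertFormat("SDF", "SMI",
                                       source = paste(ChemmineR::sdf2str(sdf),
                                                      collapse = "\n"))
      strsplit(out, "[ \t\n]")[[1]][1]
    }, error = function(e) NA_character_)
    ttl <- tryCatch(ChemmineR::header(sdf)[["Molecule_Name"]],
                    error = function(e) NA_character_)
    list(id = if (is.null(ttl) || is.na(ttl) || !nzchar(ttl)) paste0("cmpd_", i) else ttl,
         smiles = smi)
  })
  tibble(
    id = vapply(rows, `[[`, character(1), "id"),
    smiles = vapply(rows, `[[`, character(1), "smiles"),
    name = NA_character_,
    source = source
  ) %>% filter(!is.na(.data$smiles))
}

read_csv_library <- function(path, source) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("id", "smiles") %in% names(df))) {
    abort("CSV library needs `id` and `smiles` columns", class = "vra_io_error")
  }
  tibble(
    id = as.character(df$id),
    smiles = as.character(df$smiles),
    name = if ("name" %in% names(df)) as.character(df$name) else NA_character_,
    source = if ("source" %in% names(df)) as.character(df$source) else source
  )
}

#' Write a compound library as a .smi file
#'
#' @param compounds Tibble with `id` and `smiles` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_smi <- function(compounds, path) {
  stopifnot(all(c("id", "smiles") %in% names(compounds)))
  writeLines(paste(compounds$smiles, compounds$id), path)
  invisible(path)
}
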