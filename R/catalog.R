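#' Mutation catalogs and colony genotype tables
#'
#' A mutation catalog is a tibble describing the genotyping panel: columns
#' `id` (short unique identifier used as the genotype-matrix column name),
#' `gene`, `transcript`, `variant`, `protein_change`. A colony table records
#' amplification-free genotypes of single-cell-derived colonies for one
#' mutation: columns `colony`, `timepoint`, `call`, with calls restricted to
#' the three defined states (colonies are not subject to whole-genome
#' amplification, so missing calls are not expected).
#'
#' `mutation_catalog()` returns the package's built-in seven-mutation
#' myeloid panel (two TET2 hits, JAK2 V617F, ASXL1, SRSF2 P95H, TP53, FLT3
#' D835Y) used by the reference simulation.
#'
#' @return A tibble (see Details for columns).
#' @export
mutation_catalog <- function() {
  tibble::tribble(
    ~id,     ~gene,   ~transcript,    ~variant,                   ~protein_change,
    "TET2a", "TET2",  "NM_001127208", "c.3743T>C",                "p.Leu1248Pro",
    "JAK2",  "JAK2",  "NM_004972",    "c.1849G>T",                "p.Val617Phe",
    "TET2b", "TET2",  "NM_017628",    "c.3409_3416delGGTAATGT",   "p.Gly1137Profs*5",
    "ASXL1", "ASXL1", "NM_015338",    "c.1934dupG",               "p.Gly646Trpfs*12",
    "SRSF2", "SRSF2", "NM_003016",    "c.284C>A",                 "p.Pro95His",
    "TP53",  "TP53",  "NM_000546",    "c.713G>C",                 "p.Cys238Ser",
    "FLT3",  "FLT3",  "NM_004119",    "c.2503G>C",                "p.Asp835Tyr"
  )
}

#' @rdname mutation_catalog
#' @param path File path to a delimited text file.
#' @param delim Field delimiter (default tab).
#' @export
read_mutation_catalog <- function(path, delim = "\t") {
  x <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (!"id" %in% names(x)) rlang::abort("mutation catalog needs an `id` column")
  if (anyDuplicated(x$id) || any(is.na(x$id) | x$id == "")) {
    rlang::abort("mutation catalog ids must be non-empty and unique")
  }
  for (col in c("gene", "transcript", "variant", "protein_change")) {
    if (!col %in% names(x)) x[[col]] <- NA_character_
  }
  dplyr::select(x, "id", "gene", "transcript", "variant", "protein_change")
}

#' @rdname mutation_catalog
#' @param strict If `TRUE`, unknown call tokens are an error.
#' @export
read_colony_table <- function(path, delim = "\t", strict = TRUE) {
  x <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                         progress = FALSE, show_col_types = FALSE)
  if (!all(c("colony", "timepoint", "call") %in% names(x))) {
    rlang::abort("colony table needs `colony`, `timepoint`, `call` columns")
  }
  x$call <- normalize_calls(x$call, x$colony, "call", strict = strict)
  if (any(is.na(x$call))) rlang::abort("colony calls must be WT, HET or HOM (no missing)")
  tibble::as_tibble(x[c("colony", "timepoint", "call")])
}

#' @rdname mutation_catalog
#' @param colonies A colony tibble as returned by [simulate_colonies()] (one
#'   column per mutation).
#' @param mutation Mutation id to project on.
#' @export
colony_table <- function(colonies, mutation) {
  if (!mutation %in% names(colonies)) {
    rlang::abort(paste0("mutation ", dQuote(mutation), " not in colony genotypes"))
  }
  tibble::tibble(colony = colonies$colony,
                 timepoint = as.character(colonies$timepoint),
                 call = colonies[[mutation]])
}
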