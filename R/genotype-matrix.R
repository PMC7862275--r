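#' Single-cell genotype matrices
#'
#' A genotype matrix is a tibble with one row per cell: a `cell` identifier
#' column, a `timepoint` column (factor; its level order is the temporal
#' order), and one column per mutation holding calls in `"WT"`, `"HET"`,
#' `"HOM"`, or `NA` (missing / failed call). `genotype_matrix()` validates a
#' data frame and stamps the class; most other functions in the package take
#' such a tibble as their first argument.
#'
#' Validation enforces: unique cell identifiers, a timepoint for every cell,
#' calls restricted to the three defined states or `NA`, and at least one
#' defined call per retained cell. Cells whose calls are all missing carry no
#' information and are dropped with a warning.
#'
#' @param x A data frame with columns `cell`, `timepoint`, and one column per
#'   mutation.
#' @param timepoint_order Character vector giving the temporal order of the
#'   timepoint labels. Defaults to lexicographic order of the observed labels.
#' @param drop_empty Drop (with a warning) cells whose calls are all missing.
#' @return A `genotype_matrix` tibble.
#' @examples
#' gm <- genotype_matrix(tibble::tibble(
#'   cell = c("c1", "c2"), timepoint = "T1",
#'   TET2a = c("HET", "HOM"), JAK2 = c("WT", "HET")
#' ))
#' mutations(gm)
#' @export
genotype_matrix <- function(x, timepoint_order = NULL, drop_empty = TRUE) {
  x <- tibble::as_tibble(x)
  if (!all(c("cell", "timepoint") %in% names(x))) {
    rlang::abort("a genotype matrix needs `cell` and `timepoint` columns")
  }
  x <- dplyr::relocate(x, "cell", "timepoint")
  muts <- setdiff(names(x), c("cell", "timepoint"))
  if (length(muts) == 0L) rlang::abort("no mutation columns found")
  if (anyDuplicated(x$cell)) {
    dup <- unique(x$cell[duplicated(x$cell)])
    rlang::abort(paste0("duplicate cell id(s): ", paste(dup, collapse = ", ")))
  }
  if (any(is.na(x$timepoint) | x$timepoint == "")) {
    rlang::abort("every cell needs a timepoint label")
  }
  x$cell <- as.character(x$cell)
  tp <- as.character(x$timepoint)
  levels <- timepoint_order %||% sort(unique(tp))
  if (!all(tp %in% levels)) {
    rlang::abort(paste0("timepoint label(s) outside `timepoint_order`: ",
                        paste(setdiff(tp, levels), collapse = ", ")))
  }
  x$timepoint <- factor(tp, levels = levels)
  for (m in muts) {
    v <- as.character(x[[m]])
    bad <- !is.na(v) & !v %in% GT_STATES
    if (any(bad)) {
      i <- which(bad)[1L]
      rlang::abort(paste0("invalid call ", dQuote(v[i]), " for cell ",
                          dQuote(x$cell[i]), ", mutation ", dQuote(m)))
    }
    x[[m]] <- v
  }
  empty <- rowSums(!is.na(as.matrix(x[muts]))) == 0L
  if (any(empty)) {
    if (!drop_empty) rlang::abort("cells with all calls missing present and `drop_empty = FALSE`")
    rlang::warn(paste0("dropping ", sum(empty), " cell(s) with all calls missing: ",
                       paste(utils::head(x$cell[empty], 5L), collapse = ", ")))
    x <- x[!empty, , drop = FALSE]
  }
  if (nrow(x) == 0L) rlang::abort("no cells left after validation")
  class(x) <- c("genotype_matrix", class(tibble::tibble()))
  x
}

#' @describeIn genotype_matrix Mutation (column) identifiers, in panel order.
#' @param gm A genotype matrix.
#' @export
mutations <- function(gm) setdiff(names(gm), c("cell", "timepoint"))

#' @describeIn genotype_matrix Timepoint labels in temporal order.
#' @export
timepoints <- function(gm) {
  if (is.factor(gm$timepoint)) levels(gm$timepoint) else sort(unique(as.character(gm$timepoint)))
}

# Token normalization shared by the readers. Accepted (case-insensitive):
# WT/0, HET/0.5, HOM/1, and NA/./MISSING/"" for a missing call.
normalize_calls <- function(v, cells, mutation, strict = TRUE) {
  u <- toupper(trimws(as.character(v)))
  out <- rep(NA_character_, length(u))
  out[u %in% c("WT", "0")] <- "WT"
  out[u %in% c("HET", "0.5")] <- "HET"
  out[u %in% c("HOM", "1")] <- "HOM"
  known <- u %in% c("WT", "0", "HET", "0.5", "HOM", "1", "NA", ".", "MISSING", "") | is.na(v)
  if (any(!known)) {
    if (strict) {
      i <- which(!known)[1L]
      rlang::abort(paste0("unknown genotype token ", dQuote(v[i]), " for cell ",
                          dQuote(cells[i]), ", mutation ", dQuote(mutation),
                          " (set `strict = FALSE` to read unknown tokens as missing)"))
    }
    rlang::warn(paste0(sum(!known), " unknown token(s) in column ", dQuote(mutation),
                       " read as missing"))
  }
  out
}

#' Read and write genotype matrices
#'
#' Delimited-text interchange format: first column the cell identifier, second
#' column the timepoint label, remaining columns one per mutation. Accepted
#' call tokens (case-insensitive): `WT`/`0`, `HET`/`0.5`, `HOM`/`1`, and
#' `NA`/`.`/`MISSING`/empty for a missing call. The writer emits the canonical
#' form (tokens `WT`/`HET`/`HOM`/`NA`, tab-delimited by default), so
#' read-write-read round-trips are exact.
#'
#' @param path File path.
#' @param delim Field delimiter (default tab).
#' @param strict If `TRUE` (default), an unknown genotype token is an error
#'   naming the offending cell and mutation; if `FALSE`, unknown tokens are
#'   read as missing with a warning.
#' @param timepoint_order Optional explicit temporal order of timepoint labels.
#' @return `read_genotype_matrix()` returns a validated [genotype_matrix()];
#'   `write_genotype_matrix()` returns `path` invisibly.
#' @export
read_genotype_matrix <- function(path, delim = "\t", strict = TRUE, timepoint_order = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = character(), progress = FALSE, show_col_types = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 3L) {
    rlang::abort("malformed genotype file: need a header plus cell, timepoint and >=1 mutation column")
  }
  names(raw)[1:2] <- c("cell", "timepoint")
  muts <- setdiff(names(raw), c("cell", "timepoint"))
  if (anyDuplicated(muts)) rlang::abort("malformed header: duplicated mutation names")
  for (m in muts) raw[[m]] <- normalize_calls(raw[[m]], raw$cell, m, strict = strict)
  genotype_matrix(raw, timepoint_order = timepoint_order)
}

#' @rdname read_genotype_matrix
#' @param gm A genotype matrix.
#' @export
write_genotype_matrix <- function(gm, path, delim = "\t") {
  out <- tibble::as_tibble(gm)
  out$timepoint <- as.character(out$timepoint)
  readr::write_delim(out, path, delim = delim, na = "NA", progress = FALSE)
  invisible(path)
}

#' Encode genotype calls as VAF codes or presence/absence
#'
#' Maps calls to the numeric variant-allele-fraction code used throughout the
#' package: wild-type 0, heterozygous 0.5, homozygous 1, missing `NA`. The
#' `"presence"` projection further collapses heterozygous and homozygous to 1,
#' the encoding under which perfect-phylogeny conflicts are defined. The
#' presence projection is idempotent.
#'
#' @param gm A [genotype_matrix()].
#' @param projection `"vaf"` (0 / 0.5 / 1) or `"presence"` (0 / 1).
#' @return A tibble with `cell`, `timepoint`, and one numeric column per
#'   mutation.
#' @examples
#' gm <- genotype_matrix(tibble::tibble(
#'   cell = "c1", timepoint = "T1", A = "WT", B = "HET", C = "HOM"
#' ))
#' encode_vaf_matrix(gm)                         # 0, 0.5, 1
#' encode_vaf_matrix(gm, projection = "presence") # 0, 1, 1
#' @export
encode_vaf_matrix <- function(gm, projection = c("vaf", "presence")) {
  projection <- match.arg(projection)
  code <- if (projection == "vaf") c(WT = 0, HET = 0.5, HOM = 1) else c(WT = 0, HET = 1, HOM = 1)
  out <- tibble::as_tibble(gm)
  for (m in mutations(gm)) out[[m]] <- unname(code[out[[m]]])
  out
}

# cells x mutations numeric presence matrix (rownames = cell ids), NA = missing.
presence_matrix <- function(gm) {
  enc <- encode_vaf_matrix(gm, projection = "presence")
  m <- as.matrix(enc[mutations(gm)])
  storage.mode(m) <- "double"
  rownames(m) <- enc$cell
  m
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x), " cells x ", length(mutations(x)),
      " mutations; timepoints: ", paste(timepoints(x), collapse = " < "), "\n", sep = "")
  NextMethod()
}
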