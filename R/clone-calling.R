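#' Partition cells into clones by genotype signature
#'
#' Cells with a fully defined genotype are grouped by their exact signature at
#' the chosen resolution: `"zygosity"` distinguishes heterozygous from
#' homozygous states, `"presence"` collapses both to "mutated". Cells with
#' missing calls are assigned by exact match on their defined positions if and
#' only if a single clone is compatible; otherwise they are set aside as
#' unassigned (reported, never silently dropped). Clones are labelled
#' `A`, `B`, ... in decreasing pooled size (ties broken by signature).
#'
#' @param gm A [genotype_matrix()].
#' @param resolution `"zygosity"` (default) or `"presence"`.
#' @param min_cells Clones with fewer pooled member cells are flagged `minor`
#'   (they are retained; the flag is a display threshold, not a filter).
#' @return A `clone_partition`: list with `clones` (tibble `clone`, `n`,
#'   `minor`, plus one signature column per mutation), `counts` (long tibble
#'   `clone`, `timepoint`, `n`), `assignments` (tibble `cell`, `timepoint`,
#'   `clone`, `match` in `exact`/`partial`), `unassigned` (tibble `cell`,
#'   `timepoint`, `reason`), `resolution`, `mutations`, `timepoints`.
#' @examples
#' gm <- genotype_matrix(tibble::tibble(
#'   cell = paste0("c", 1:4), timepoint = "T1",
#'   A = c("HET", "HET", "HOM", "HET"), B = c("WT", "WT", "WT", "HET")
#' ))
#' call_clones(gm)$clones                       # 3 clones, sizes 2/1/1
#' call_clones(gm, resolution = "presence")$clones  # HET and HOM collapse
#' @export
call_clones <- function(gm, resolution = c("zygosity", "presence"), min_cells = 1L) {
  resolution <- match.arg(resolution)
  if (nrow(gm) == 0L) rlang::abort("empty genotype matrix")
  muts <- mutations(gm)
  calls <- as.matrix(tibble::as_tibble(gm)[muts])
  if (resolution == "presence") calls[calls %in% c("HET", "HOM")] <- "MUT"
  complete <- rowSums(is.na(calls)) == 0L
  if (!any(complete)) rlang::abort("no cell has a fully defined genotype")
  key <- apply(calls, 1L, paste, collapse = "|")
  key[!complete] <- NA
  sig_keys <- sort(unique(key[complete]))
  sizes <- table(factor(key[complete], levels = sig_keys))
  ord <- order(-as.integer(sizes), sig_keys)
  sig_keys <- sig_keys[ord]
  labels <- clone_labels(length(sig_keys))
  names(labels) <- sig_keys

  assigned <- tibble::tibble(cell = gm$cell[complete],
                             timepoint = gm$timepoint[complete],
                             clone = unname(labels[key[complete]]),
                             match = "exact")
  # partial-profile cells: unique compatibility on defined positions
  unassigned <- tibble::tibble(cell = character(), timepoint = gm$timepoint[0], reason = character())
  if (any(!complete)) {
    sig_mat <- do.call(rbind, strsplit(sig_keys, "|", fixed = TRUE))
    for (i in which(!complete)) {
      def <- !is.na(calls[i, ])
      hits <- which(colSums(t(sig_mat[, def, drop = FALSE]) != calls[i, def]) == 0L)
      if (length(hits) == 1L) {
        assigned <- dplyr::add_row(assigned, cell = gm$cell[i], timepoint = gm$timepoint[i],
                                   clone = unname(labels[sig_keys[hits]]), match = "partial")
      } else {
        unassigned <- dplyr::add_row(unassigned, cell = gm$cell[i], timepoint = gm$timepoint[i],
                                     reason = if (length(hits) == 0L) "no_compatible_clone"
                                              else "ambiguous")
      }
    }
  }
  sig_tbl <- tibble::as_tibble(do.call(rbind, strsplit(sig_keys, "|", fixed = TRUE)),
                               .name_repair = "minimal") |> rlang::set_names(muts)
  counts <- assigned |>
    dplyr::count(.data$clone, .data$timepoint) |>
    tidyr::complete(clone = unname(labels),
                    timepoint = factor(timepoints(gm), levels = timepoints(gm)),
                    fill = list(n = 0L)) |>
    dplyr::mutate(clone = factor(.data$clone, levels = unname(labels))) |>
    dplyr::arrange(.data$clone, .data$timepoint) |>
    dplyr::mutate(clone = as.character(.data$clone))
  clones <- dplyr::bind_cols(tibble::tibble(clone = unname(labels)), sig_tbl) |>
    dplyr::left_join(dplyr::count(assigned, .data$clone, name = "n"), by = "clone") |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L), minor = .data$n < min_cells) |>
    dplyr::relocate("clone", "n", "minor")
  structure(list(clones = clones, counts = counts, assignments = assigned,
                 unassigned = unassigned, resolution = resolution,
                 mutations = muts, timepoints = timepoints(gm)),
            class = "clone_partition")
}

#' @export
print.clone_partition <- function(x, ...) {
  cat("<clone_partition> ", nrow(x$clones), " clones at ", x$resolution,
      " resolution; ", nrow(x$assignments), " cells assigned, ",
      nrow(x$unassigned), " unassigned\n", sep = "")
  print(x$clones, ...)
  invisible(x)
}

#' Mutated-cell fraction of one mutation at one timepoint
#'
#' The mutational frequency of a variant: the fraction of mutated cells
#' (heterozygous or homozygous) among the cells of a timepoint with a defined
#' call, mirroring how per-variant frequencies are computed from single-cell
#' genotyping panels.
#'
#' @param gm A [genotype_matrix()].
#' @param mutation Mutation id (a column of `gm`).
#' @param timepoint Timepoint label; `NULL` pools all timepoints.
#' @return A proportion in `[0, 1]`.
#' @examples
#' gm <- genotype_matrix(tibble::tibble(
#'   cell = paste0("c", 1:10), timepoint = "T1",
#'   M = c("HET", "HET", "HOM", rep("WT", 7))
#' ))
#' mutated_fraction(gm, "M", "T1")  # 0.3
#' @export
mutated_fraction <- function(gm, mutation, timepoint = NULL) {
  if (!mutation %in% mutations(gm)) {
    rlang::abort(paste0("mutation ", dQuote(mutation), " not in the matrix"))
  }
  v <- gm[[mutation]]
  if (!is.null(timepoint)) {
    if (!timepoint %in% timepoints(gm)) {
      rlang::abort(paste0("timepoint ", dQuote(timepoint), " not present"))
    }
    v <- v[gm$timepoint == timepoint]
  }
  n_called <- sum(!is.na(v))
  if (n_called == 0L) rlang::abort("zero defined calls for this mutation/timepoint")
  sum(v %in% c("HET", "HOM")) / n_called
}

#' @describeIn mutated_fraction All mutations at all timepoints in one tidy
#'   table (`mutation`, `timepoint`, `n_mutated`, `n_called`,
#'   `mutated_fraction`).
#' @export
mutation_frequencies <- function(gm) {
  tibble::as_tibble(gm) |>
    tidyr::pivot_longer(dplyr::all_of(mutations(gm)), names_to = "mutation", values_to = "call") |>
    dplyr::group_by(.data$mutation, .data$timepoint) |>
    dplyr::summarise(n_mutated = sum(.data$call %in% c("HET", "HOM")),
                     n_called = sum(!is.na(.data$call)), .groups = "drop") |>
    dplyr::mutate(mutated_fraction = ifelse(.data$n_called > 0,
                                            .data$n_mutated / .data$n_called, NA_real_),
                  mutation = factor(.data$mutation, levels = mutations(gm))) |>
    dplyr::arrange(.data$mutation, .data$timepoint) |>
    dplyr::mutate(mutation = as.character(.data$mutation))
}

#' Zygosity distribution of a mutation
#'
#' Proportions of wild-type, heterozygous, homozygous, and missing calls for
#' one mutation among the cells of a timepoint, both over all cells
#' (`prop_all`, the four states sum to 1) and renormalized over cells with a
#' defined call (`prop_called`).
#'
#' @inheritParams mutated_fraction
#' @return A tibble with one row per state (`WT`, `HET`, `HOM`, `MISSING`) and
#'   columns `mutation`, `timepoint`, `n`, `prop_all`, `prop_called`.
#' @export
zygosity_distribution <- function(gm, mutation, timepoint = NULL) {
  if (!mutation %in% mutations(gm)) {
    rlang::abort(paste0("mutation ", dQuote(mutation), " not in the matrix"))
  }
  v <- gm[[mutation]]
  tp <- timepoint %||% "all"
  if (!is.null(timepoint)) {
    if (!timepoint %in% timepoints(gm)) {
      rlang::abort(paste0("timepoint ", dQuote(timepoint), " not present"))
    }
    v <- v[gm$timepoint == timepoint]
  }
  n_called <- sum(!is.na(v))
  if (n_called == 0L) rlang::abort("zero defined calls for this mutation/timepoint")
  n <- c(sum(v == "WT", na.rm = TRUE), sum(v == "HET", na.rm = TRUE),
         sum(v == "HOM", na.rm = TRUE), sum(is.na(v)))
  tibble::tibble(mutation = mutation, timepoint = tp,
                 state = c("WT", "HET", "HOM", "MISSING"), n = n,
                 prop_all = n / length(v),
                 prop_called = c(n[1:3] / n_called, NA_real_))
}

#' Clone-level heterogeneity per timepoint
#'
#' Number of distinct clones observed and the Shannon entropy (natural log) of
#' the clone-size distribution among assigned cells, per timepoint. Entropy is
#' a scale-free summary of clonal heterogeneity: it grows both with the number
#' of clones and with the evenness of their sizes.
#'
#' @param partition A [call_clones()] partition.
#' @return Tibble `timepoint`, `n_cells`, `n_clones`, `entropy`.
#' @export
clone_diversity <- function(partition) {
  stopifnot(inherits(partition, "clone_partition"))
  partition$counts |>
    dplyr::group_by(.data$timepoint) |>
    dplyr::summarise(n_cells = sum(.data$n),
                     n_clones = sum(.data$n > 0),
                     entropy = shannon_entropy(.data$n), .groups = "drop")
}
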