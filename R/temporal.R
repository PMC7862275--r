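#' Track clone prevalences across timepoints
#'
#' Clones are matched across timepoints by exact signature (a clone that
#' changes zygosity is a different clone). For every tree node and timepoint
#' the table reports `own_fraction` — cells of that exact clone over assigned
#' cells of the timepoint (inferred, unobserved nodes have own fraction 0) —
#' and `nested_fraction` — own plus all descendants, the quantity a fishplot
#' draws. Nested fractions are computed bottom-up, then passed through
#' [enforce_nesting()] so any externally-introduced nesting violation would be
#' rescaled (and logged), never silent. Cells left unassigned by
#' [call_clones()] are excluded from denominators and reported via the
#' partition.
#'
#' @param partition A [call_clones()] partition.
#' @param tree A [build_clone_tree()] tree built from (a superset of) the
#'   partition's clones.
#' @return A `prevalence_table` tibble: `clone`, `timepoint`, `n`,
#'   `own_fraction`, `nested_fraction`, `observed`; the tree is attached as
#'   attribute `tree`.
#' @export
track_clones <- function(partition, tree) {
  stopifnot(inherits(partition, "clone_partition"), inherits(tree, "clone_tree"))
  missing_cl <- setdiff(partition$clones$clone[partition$clones$n > 0], tree$nodes$label)
  if (length(missing_cl)) {
    rlang::abort(paste0("clone(s) in the partition but not in the tree: ",
                        paste(missing_cl, collapse = ", ")))
  }
  tps <- partition$timepoints
  counts <- partition$counts
  denom <- counts |> dplyr::group_by(.data$timepoint) |>
    dplyr::summarise(total = sum(.data$n), .groups = "drop")
  tbl <- tidyr::expand_grid(clone = tree$nodes$label,
                            timepoint = factor(tps, levels = tps)) |>
    dplyr::left_join(counts, by = c("clone", "timepoint")) |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L)) |>
    dplyr::left_join(denom, by = "timepoint") |>
    dplyr::mutate(own_fraction = ifelse(.data$total > 0, .data$n / .data$total, 0)) |>
    dplyr::select(-"total") |>
    dplyr::left_join(dplyr::select(tree$nodes, "label", "observed"),
                     by = c(clone = "label"))
  # nested = own + descendants, bottom-up over the tree
  children <- split(tree$edges$child, tree$edges$parent)
  nested_of <- function(label, own_by_clone) {
    kids <- children[[label]]
    own_by_clone[[label]] + if (is.null(kids)) 0 else sum(vapply(kids, nested_of, numeric(1), own_by_clone))
  }
  tbl <- tbl |> dplyr::group_by(.data$timepoint) |>
    dplyr::group_modify(function(df, key) {
      own <- stats::setNames(df$own_fraction, df$clone)
      df$nested_fraction <- unname(vapply(df$clone, nested_of, numeric(1), own))
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("clone", "timepoint", "n", "own_fraction", "nested_fraction", "observed")
  out <- enforce_nesting(tbl, tree)
  class(out) <- c("prevalence_table", class(tibble::tibble()))
  attr(out, "tree") <- tree
  out
}

#' Enforce fishplot nesting of prevalence tables
#'
#' A fishplot requires children's nested prevalences to fit inside their
#' parent's. When nested fractions are computed bottom-up from a single
#' partition this holds by construction; when they come from an external
#' source (e.g. per-mutation estimates), sampling noise can make the children
#' of a node sum beyond it. In that case each offending sibling set is scaled
#' proportionally (the whole subtree below each child is scaled with it), and
#' every rescale is recorded in the `rescales` attribute and reported via a
#' message — never applied silently.
#'
#' @param tbl A tibble with `clone`, `timepoint`, `nested_fraction`.
#' @param tree The [build_clone_tree()] tree the clones live on.
#' @return `tbl` with nesting enforced; attribute `rescales` lists
#'   `timepoint`, `clone` (the parent), and the applied `factor`.
#' @export
enforce_nesting <- function(tbl, tree) {
  children <- split(tree$edges$child, tree$edges$parent)
  descendants <- function(label) {
    kids <- children[[label]]
    if (is.null(kids)) character() else c(kids, unlist(lapply(kids, descendants)))
  }
  rescales <- list()
  for (tp in unique(tbl$timepoint)) {
    rows <- tbl$timepoint == tp
    nested <- stats::setNames(tbl$nested_fraction[rows], tbl$clone[rows])
    # top-down: parents first
    order_labels <- tree$nodes$label[order(tree$nodes$n_events)]
    for (lab in order_labels) {
      kids <- children[[lab]]
      if (is.null(kids) || !lab %in% names(nested)) next
      kid_sum <- sum(nested[kids])
      if (kid_sum > nested[[lab]] + 1e-9) {
        f <- nested[[lab]] / kid_sum
        for (k in kids) {
          sub <- c(k, descendants(k))
          nested[sub] <- nested[sub] * f
        }
        rescales <- c(rescales, list(tibble::tibble(timepoint = as.character(tp),
                                                    clone = lab, factor = f)))
      }
    }
    tbl$nested_fraction[rows] <- unname(nested[tbl$clone[rows]])
  }
  rescales <- if (length(rescales)) dplyr::bind_rows(rescales) else
    tibble::tibble(timepoint = character(), clone = character(), factor = numeric())
  if (nrow(rescales)) {
    rlang::inform(paste0("rescaled ", nrow(rescales),
                         " sibling set(s) to satisfy fishplot nesting (see attr 'rescales')"))
  }
  attr(tbl, "rescales") <- rescales
  tbl
}

#' Mutation frequency trajectories
#'
#' Mutated-cell fraction of every mutation at every timepoint (the
#' [mutated_fraction()] definition), joined with the acquisition rank from
#' [order_mutations()] — the table behind a mutation-level fishplot.
#'
#' @param gm A [genotype_matrix()].
#' @param order Optional `mutation_order`; computed from `gm` by default.
#' @return A `trajectory_table` tibble: `mutation`, `timepoint`,
#'   `mutated_fraction`, `rank`.
#' @export
frequency_trajectories <- function(gm, order = NULL) {
  order <- order %||% order_mutations(gm)
  out <- mutation_frequencies(gm) |>
    dplyr::left_join(dplyr::select(order, "mutation", "rank"), by = "mutation") |>
    dplyr::arrange(.data$rank, .data$timepoint) |>
    dplyr::select("mutation", "timepoint", "mutated_fraction", "rank")
  class(out) <- c("trajectory_table", class(tibble::tibble()))
  out
}

#' Zygosity evolution of one mutation over time
#'
#' One zygosity distribution per timepoint, in temporal order — the table
#' behind a zygosity joy plot (e.g. the appearance of homozygous calls only in
#' a late disease phase).
#'
#' @inheritParams frequency_trajectories
#' @param mutation Mutation id.
#' @return Tibble with one row per timepoint and state: `mutation`,
#'   `timepoint`, `state`, `n`, `prop_all`, `prop_called`.
#' @export
zygosity_evolution <- function(gm, mutation) {
  purrr::map_dfr(timepoints(gm), function(tp) zygosity_distribution(gm, mutation, tp)) |>
    dplyr::mutate(timepoint = factor(.data$timepoint, levels = timepoints(gm)),
                  state = factor(.data$state, levels = c("WT", "HET", "HOM", "MISSING")))
}

#' Write a fishplot/timescape-ready JSON document
#'
#' Serializes a prevalence table with its tree in the convention timeline
#' plotting tools expect: one record per clone per timepoint carrying the
#' clone id, its parent, and both own and nested prevalence.
#'
#' @param prevalence A [track_clones()] table.
#' @param path Output file path.
#' @export
write_fishplot_json <- function(prevalence, path) {
  tree <- attr(prevalence, "tree")
  stopifnot(!is.null(tree))
  parent_of <- stats::setNames(tree$edges$parent, tree$edges$child)
  recs <- prevalence |>
    dplyr::mutate(parent = unname(parent_of[.data$clone]),
                  parent = ifelse(is.na(.data$parent), "", .data$parent),
                  timepoint = as.character(.data$timepoint)) |>
    dplyr::select("clone", "parent", "timepoint", "own_fraction", "nested_fraction")
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
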