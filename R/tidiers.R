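#' Tidy and glance methods
#'
#' broom-style one-row-per-term (`tidy`) and one-row-per-object (`glance`)
#' summaries for the package's fitted objects.
#'
#' @param x An `ado_estimate`, `clone_partition`, or `clone_tree`.
#' @param ... Ignored.
#' @return A tibble.
#' @name clonearch-tidiers
NULL

#' @rdname clonearch-tidiers
#' @export
tidy.ado_estimate <- function(x, ...) {
  tibble::tibble(term = "ado_rate", estimate = x$d_hat,
                 conf.low = x$ci[1], conf.high = x$ci[2])
}

#' @rdname clonearch-tidiers
#' @export
glance.ado_estimate <- function(x, ...) {
  tibble::tibble(d_hat = x$d_hat, conf.low = x$ci[1], conf.high = x$ci[2],
                 nll = x$nll, identifiable = x$identifiable,
                 n_cells = sum(x$cell_counts), n_colonies = sum(x$colony_counts),
                 n_boot = length(x$boot))
}

#' @rdname clonearch-tidiers
#' @export
tidy.clone_partition <- function(x, ...) {
  sig <- x$clones[x$mutations]
  x$clones |>
    dplyr::mutate(signature = apply(sig, 1L, function(r) paste(r, collapse = "|"))) |>
    dplyr::select("clone", "n", "minor", "signature")
}

#' @rdname clonearch-tidiers
#' @export
glance.clone_partition <- function(x, ...) {
  tibble::tibble(n_clones = nrow(x$clones), n_assigned = nrow(x$assignments),
                 n_unassigned = nrow(x$unassigned), resolution = x$resolution,
                 n_mutations = length(x$mutations))
}

#' @rdname clonearch-tidiers
#' @export
tidy.clone_tree <- function(x, ...) x$edges

#' @rdname clonearch-tidiers
#' @export
glance.clone_tree <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$nodes), n_observed = sum(x$nodes$observed),
                 n_inferred = sum(!x$nodes$observed), n_edges = nrow(x$edges),
                 root = x$root, resolution = x$resolution)
}
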