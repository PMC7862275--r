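#' Newick export and import of clone trees
#'
#' `export_newick()` writes a clone tree as a Newick string with every node
#' labelled and, optionally, the event on the edge leading to each node as a
#' comment in square brackets directly after the node label, e.g.
#' `((B[+JAK2])A[+TET2a])root;`. `parse_newick()` reads such a string back
#' (labels, topology, event comments), so export -> parse -> export
#' round-trips exactly.
#'
#' @param tree A [build_clone_tree()] tree, or for re-export a
#'   [parse_newick()] result.
#' @param events Include `[event]` comments.
#' @return `export_newick()`: a single Newick string. `parse_newick()`: a
#'   list with `nodes` (tibble `label`), `edges` (tibble `parent`, `child`,
#'   `event`), `root`, of class `newick_tree` (edge order preserves the
#'   string's sibling order).
#' @export
export_newick <- function(tree, events = TRUE) {
  stopifnot(!is.null(tree$edges), !is.null(tree$root))
  edges <- tree$edges
  recurse <- function(label) {
    kids <- which(edges$parent == label)
    inner <- if (length(kids)) {
      paste0("(", paste(vapply(kids, function(k) {
        paste0(recurse(edges$child[k]),
               if (events && !is.na(edges$event[k]) && nzchar(edges$event[k]))
                 paste0("[", edges$event[k], "]") else "")
      }, character(1)), collapse = ","), ")")
    } else ""
    paste0(inner, label)
  }
  paste0(recurse(tree$root), ";")
}

#' @rdname export_newick
#' @param text A Newick string produced by `export_newick()`.
#' @export
parse_newick <- function(text) {
  chars <- strsplit(trimws(text), "")[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(chars)) chars[pos] else ""
  advance <- function() { ch <- chars[pos]; pos <<- pos + 1L; ch }
  read_label <- function() {
    out <- character()
    while (!peek() %in% c("(", ")", ",", ";", "[", "")) out <- c(out, advance())
    paste(out, collapse = "")
  }
  read_comment <- function() {
    if (peek() != "[") return(NA_character_)
    advance()
    out <- character()
    while (peek() != "]") {
      if (peek() == "") rlang::abort("unterminated comment in Newick string")
      out <- c(out, advance())
    }
    advance()
    paste(out, collapse = "")
  }
  edges <- list()
  parse_node <- function() {
    kids <- list()
    if (peek() == "(") {
      advance()
      repeat {
        kids <- c(kids, list(parse_node()))
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        rlang::abort("malformed Newick string")
      }
    }
    label <- read_label()
    if (!nzchar(label)) rlang::abort("unlabelled node in Newick string")
    comment <- read_comment()
    for (k in kids) {
      edges[[length(edges) + 1L]] <<- tibble::tibble(parent = label, child = k$label,
                                                     event = k$event)
    }
    list(label = label, event = comment)
  }
  root <- parse_node()
  if (peek() != ";") rlang::abort("Newick string must end with ';'")
  edges <- if (length(edges)) dplyr::bind_rows(edges) else
    tibble::tibble(parent = character(), child = character(), event = character())
  # parse order records children bottom-up; restore parent-major sibling order
  labels <- unique(c(root$label, edges$child))
  structure(list(nodes = tibble::tibble(label = labels),
                 edges = edges, root = root$label),
            class = "newick_tree")
}
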