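#' Mutation acquisition order
#'
#' Under the infinite-sites view of clonal growth, a mutation carried by more
#' cells was acquired earlier: every descendant clone inherits it. Mutations
#' are therefore ranked by their pooled mutated-cell fraction (all timepoints),
#' descending. Ties are broken by the first-timepoint fraction, then by panel
#' (column) order, so the ranking is deterministic and invariant under row
#' permutations of the matrix.
#'
#' @param gm A [genotype_matrix()].
#' @return A tibble `mutation`, `pooled_fraction`, `first_tp_fraction`, `rank`
#'   (class `mutation_order`), ordered by rank.
#' @export
order_mutations <- function(gm) {
  muts <- mutations(gm)
  first_tp <- timepoints(gm)[1L]
  pooled <- vapply(muts, function(m) mutated_fraction(gm, m), numeric(1))
  first <- vapply(muts, function(m) {
    v <- gm[[m]][gm$timepoint == first_tp]
    if (all(is.na(v))) 0 else sum(v %in% c("HET", "HOM")) / sum(!is.na(v))
  }, numeric(1))
  ord <- order(-pooled, -first, seq_along(muts))
  out <- tibble::tibble(mutation = muts[ord], pooled_fraction = unname(pooled[ord]),
                        first_tp_fraction = unname(first[ord]), rank = seq_along(muts))
  class(out) <- c("mutation_order", class(out))
  out
}

# Rank mutations from a clone partition (clone sizes reproduce cell counts).
order_from_partition <- function(partition) {
  sig <- as.matrix(partition$clones[partition$mutations])
  mutated <- sig != "WT"
  n_tot <- partition$counts |> dplyr::group_by(.data$clone) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  n_tot <- n_tot$n[match(partition$clones$clone, n_tot$clone)]
  first_tp <- partition$timepoints[1L]
  n_first <- partition$counts[partition$counts$timepoint == first_tp, ]
  n_first <- n_first$n[match(partition$clones$clone, n_first$clone)]
  pooled <- colSums(mutated * n_tot) / sum(n_tot)
  first <- if (sum(n_first) > 0) colSums(mutated * n_first) / sum(n_first) else pooled * 0
  muts <- partition$mutations
  ord <- order(-pooled, -first, seq_along(muts))
  out <- tibble::tibble(mutation = muts[ord], pooled_fraction = unname(pooled[ord]),
                        first_tp_fraction = unname(first[ord]), rank = seq_along(muts))
  class(out) <- c("mutation_order", class(out))
  out
}

# -- conflict detection ------------------------------------------------------

# Pairwise witness counts on a 0/1 presence matrix with NAs.
# A pair (i, j) is incompatible with a perfect phylogeny rooted at all-wild-type
# iff cells exhibiting patterns (1,1), (1,0) and (0,1) all exist.
conflict_pairs <- function(P) {
  A <- P; A[is.na(A)] <- 0
  B <- 1 - P; B[is.na(B)] <- 0
  n11 <- crossprod(A)         # t(A) %*% A
  n10 <- crossprod(A, B)
  n01 <- crossprod(B, A)
  muts <- colnames(P)
  idx <- which(upper.tri(n11), arr.ind = TRUE)
  conf <- n11[idx] > 0 & n10[idx] > 0 & n01[idx] > 0
  tibble::tibble(mut_i = muts[idx[conf, 1]], mut_j = muts[idx[conf, 2]],
                 n_11 = as.integer(n11[idx][conf]),
                 n_10 = as.integer(n10[idx][conf]),
                 n_01 = as.integer(n01[idx][conf]))
}

#' Perfect-phylogeny conflict detection
#'
#' On the presence/absence projection with an all-wild-type ancestor, two
#' mutations are compatible with a single tree iff the cell patterns
#' (mutated, mutated), (mutated, wild-type), (wild-type, mutated) do not all
#' occur. `find_conflicts()` reports every incompatible pair with its witness
#' counts; only cells with both calls defined contribute.
#'
#' @param gm A [genotype_matrix()].
#' @return Tibble `mut_i`, `mut_j`, `n_11`, `n_10`, `n_01`, one row per
#'   conflicting pair (empty when the matrix is tree-compatible).
#' @export
find_conflicts <- function(gm) {
  conflict_pairs(presence_matrix(gm))
}

# -- minimum-flip repair -----------------------------------------------------

first_conflict <- function(P) {
  m <- ncol(P)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    a <- P[, i]; b <- P[, j]
    def <- !is.na(a) & !is.na(b)
    if (any(def & a == 1 & b == 1) && any(def & a == 1 & b == 0) && any(def & a == 0 & b == 1)) {
      return(c(i, j))
    }
  }
  NULL
}

# Candidate flips that can help resolve the conflict (i, j): any defined entry
# of a witness cell in column i or j. Ordered by cell id then column.
conflict_candidates <- function(P, ij) {
  i <- ij[1L]; j <- ij[2L]
  def <- !is.na(P[, i]) & !is.na(P[, j])
  witness <- def & !(P[, i] == 0 & P[, j] == 0)
  cells <- which(witness)
  cand <- rbind(cbind(cells, i), cbind(cells, j))
  cand <- cand[order(rownames(P)[cand[, 1]], cand[, 2]), , drop = FALSE]
  cand
}

# Depth-limited search for a flip set of size <= k making P conflict-free.
# Sound branching: to resolve the first conflict, some witness class must end
# empty, so at least one flip hits a current witness cell in column i or j.
repair_search <- function(P, k, visited, path = integer()) {
  ij <- first_conflict(P)
  if (is.null(ij)) return(list())
  if (k == 0L) return(NULL)
  cand <- conflict_candidates(P, ij)
  for (r in seq_len(nrow(cand))) {
    c0 <- cand[r, 1L]; m0 <- cand[r, 2L]
    li <- (m0 - 1L) * nrow(P) + c0
    if (li %in% path) next  # undoing an earlier flip cannot be minimal
    Q <- P
    Q[c0, m0] <- 1 - Q[c0, m0]
    key <- paste0("k", paste(sort(c(path, li)), collapse = ","))
    prior <- visited[[key]]
    if (!is.null(prior) && prior >= k - 1L) next
    visited[[key]] <- k - 1L
    sub <- repair_search(Q, k - 1L, visited, c(path, li))
    if (!is.null(sub)) return(c(list(c(c0, m0)), sub))
  }
  NULL
}

#' Minimum-flip repair of a conflicting genotype matrix
#'
#' Genotyping noise (allele dropout, miscalls) can make the presence/absence
#' projection incompatible with any perfect phylogeny. `repair_min_flips()`
#' returns a conflict-free matrix obtained by flipping presence calls: for
#' instances up to 6 mutations x 30 cells an iterative-deepening
#' branch-and-bound finds a flip set of exactly minimal size; larger instances
#' use a deterministic greedy heuristic (repeatedly flip the defined call
#' participating in the most conflict witnesses; ties broken by cell id, then
#' panel order), which may exceed the minimum. Flipping a mutated call yields
#' `WT`; flipping a wild-type call yields `HET`. Missing calls are never
#' flipped.
#'
#' @param gm A [genotype_matrix()].
#' @param budget Maximum number of flips allowed; an error is raised when no
#'   conflict-free matrix is reachable within it.
#' @param method `"auto"` (exact for small instances), `"exact"`, or
#'   `"greedy"`.
#' @return List with `matrix` (the repaired [genotype_matrix()]) and `flips`
#'   (tibble `cell`, `mutation`, `from`, `to`).
#' @export
repair_min_flips <- function(gm, budget = Inf, method = c("auto", "exact", "greedy")) {
  method <- match.arg(method)
  if (budget < 0) rlang::abort("`budget` must be >= 0")
  P <- presence_matrix(gm)
  if (method == "auto") {
    method <- if (ncol(P) <= 6L && nrow(P) <= 30L) "exact" else "greedy"
  }
  flips <- NULL
  if (method == "exact") {
    cap <- min(budget, sum(!is.na(P)))
    k <- 0L
    repeat {
      visited <- new.env(parent = emptyenv())
      res <- repair_search(P, k, visited)
      if (!is.null(res)) { flips <- res; break }
      if (k >= cap) {
        rlang::abort(paste0("no conflict-free solution within budget ", budget,
                            "; conflicting pairs: ",
                            paste(unique(unlist(find_conflicts(gm)[1:2])), collapse = ", ")))
      }
      k <- k + 1L
    }
  } else {
    # Greedy: per conflicting pair, the cells of the *smallest* witness class
    # are the likely errors; score each defined entry by how many conflicts it
    # could resolve that way, flip the top scorer, repeat. An entry is never
    # flipped twice, so the loop terminates.
    Q <- P
    n_flips <- 0L
    flipped <- matrix(FALSE, nrow(Q), ncol(Q))
    repeat {
      conf <- conflict_pairs(Q)
      if (nrow(conf) == 0L) break
      if (n_flips >= budget) {
        rlang::abort(paste0("no conflict-free solution within budget ", budget,
                            "; conflicting pairs: ",
                            paste(unique(unlist(conf[1:2])), collapse = ", ")))
      }
      score <- matrix(0L, nrow(Q), ncol(Q), dimnames = dimnames(Q))
      muts <- colnames(Q)
      for (r in seq_len(nrow(conf))) {
        i <- match(conf$mut_i[r], muts); j <- match(conf$mut_j[r], muts)
        def <- !is.na(Q[, i]) & !is.na(Q[, j])
        classes <- list(def & Q[, i] == 1 & Q[, j] == 1,
                        def & Q[, i] == 1 & Q[, j] == 0,
                        def & Q[, i] == 0 & Q[, j] == 1)
        w <- classes[[which.min(vapply(classes, sum, numeric(1)))]]
        score[w, i] <- score[w, i] + 1L
        score[w, j] <- score[w, j] + 1L
      }
      score[is.na(Q) | flipped] <- -1L
      if (max(score) < 0L) {
        rlang::abort("greedy repair stalled: no flippable entry resolves a conflict")
      }
      best <- which(score == max(score), arr.ind = TRUE)
      best <- best[order(rownames(Q)[best[, 1]], best[, 2]), , drop = FALSE][1L, ]
      Q[best[1L], best[2L]] <- 1 - Q[best[1L], best[2L]]
      flipped[best[1L], best[2L]] <- TRUE
      n_flips <- n_flips + 1L
    }
    changed <- which(Q != P, arr.ind = TRUE)
    flips <- lapply(seq_len(nrow(changed)), function(r) unname(changed[r, ]))
  }
  out <- tibble::as_tibble(gm)
  rec <- purrr::map_dfr(flips, function(f) {
    cell_i <- f[1L]; mut <- mutations(gm)[f[2L]]
    from <- out[[mut]][cell_i]
    to <- if (from %in% c("HET", "HOM")) "WT" else "HET"
    out[[mut]][cell_i] <<- to
    tibble::tibble(cell = out$cell[cell_i], mutation = mut, from = from, to = to)
  })
  if (is.null(rec) || nrow(rec) == 0L) {
    rec <- tibble::tibble(cell = character(), mutation = character(),
                          from = character(), to = character())
  }
  list(matrix = genotype_matrix(out, timepoint_order = timepoints(gm)),
       flips = rec)
}

# -- clone tree construction -------------------------------------------------

STATE_LEVEL <- c(WT = 0L, HET = 1L, MUT = 1L, HOM = 2L)

sig_key <- function(s) paste(s, collapse = "|")

# Canonical event chain from signature `from` up to `to` (integer state
# vectors, from <= to): mutations in rank order, gain before escalation.
event_chain <- function(from, to, rank_order) {
  steps <- list()
  for (m in rank_order) {
    while (from[[m]] < to[[m]]) {
      from[[m]] <- from[[m]] + 1L
      steps <- c(steps, list(list(mut = m, level = from[[m]])))
    }
  }
  steps
}

event_label <- function(mut, level) {
  if (level == 1L) paste0("+", mut) else paste0(mut, ":HET>HOM")
}

#' Build a perfect-phylogeny clone tree
#'
#' Classic containment construction: clone signatures are partially ordered
#' (per mutation, wild-type < mutated, and heterozygous < homozygous at
#' zygosity resolution); each clone is attached beneath the deepest
#' already-placed node whose signature it contains, and any intermediate
#' signatures along the way are materialized as inferred (unobserved) nodes so
#' that every edge is exactly one event — a mutation gain (`+X`) or a zygosity
#' escalation (`X:HET>HOM`). Events on a materialized path follow the mutation
#' rank order (gains before escalations of the same mutation); parent ties
#' prefer deeper, then observed, nodes. The root is the all-wild-type
#' signature; when it is unobserved and has a single child it is contracted,
#' so the root becomes the minimal observed clone (founder).
#'
#' The presence projection of the signatures must be conflict-free
#' (see [find_conflicts()] / [repair_min_flips()]).
#'
#' @param partition A [call_clones()] partition.
#' @param order A `mutation_order` from [order_mutations()]; defaults to the
#'   order implied by the partition's clone sizes.
#' @return A `clone_tree`: list with `nodes` (tibble `label`, `observed`,
#'   `n_events`, plus one signature column per mutation), `edges` (tibble
#'   `parent`, `child`, `event`), `root`, `resolution`, `order`.
#' @export
build_clone_tree <- function(partition, order = NULL) {
  stopifnot(inherits(partition, "clone_partition"))
  order <- order %||% order_from_partition(partition)
  muts <- partition$mutations
  rank_order <- order$mutation
  if (!setequal(rank_order, muts)) rlang::abort("`order` must cover exactly the partition's mutations")
  sig_chr <- as.matrix(partition$clones[muts])
  sig_int <- matrix(STATE_LEVEL[sig_chr], nrow(sig_chr), dimnames = list(partition$clones$clone, muts))
  # presence-projection compatibility
  conf <- conflict_pairs(matrix(as.numeric(sig_int > 0), nrow(sig_int), dimnames = dimnames(sig_int)))
  if (nrow(conf) > 0L) {
    rlang::abort(paste0("clone signatures are not tree-compatible; conflicting pair(s): ",
                        paste(paste(conf$mut_i, conf$mut_j, sep = "/"), collapse = ", "),
                        " — repair the matrix first (see repair_min_flips())"))
  }
  chain_str <- function(s) paste(vapply(event_chain(stats::setNames(integer(length(muts)), muts), s, rank_order),
                                        function(e) paste0(e[["mut"]], e[["level"]]), character(1)),
                                 collapse = ">")
  row_sig <- function(i) stats::setNames(sig_int[i, ], muts)
  n_events <- rowSums(sig_int)
  ord <- order(n_events, vapply(seq_len(nrow(sig_int)), function(i) chain_str(row_sig(i)), character(1)))

  nodes <- list()   # key -> list(label, sig, observed, n_events)
  edges <- list()
  root_sig <- stats::setNames(integer(length(muts)), muts)
  root_key <- sig_key(root_sig)
  nodes[[root_key]] <- list(label = "root", sig = root_sig, observed = FALSE, n_events = 0L)
  n_inferred <- 0L

  for (i in ord) {
    s <- row_sig(i)
    lab <- partition$clones$clone[i]
    key <- sig_key(s)
    if (!is.null(nodes[[key]])) {  # the root, observed as a clone
      nodes[[key]]$observed <- TRUE
      nodes[[key]]$label <- lab
      next
    }
    # deepest placed ancestor; ties prefer observed, then canonical chain order
    anc_keys <- names(nodes)[vapply(nodes, function(nd) all(nd$sig <= s), logical(1))]
    depth <- vapply(anc_keys, function(k) nodes[[k]]$n_events, integer(1))
    obs <- vapply(anc_keys, function(k) nodes[[k]]$observed, logical(1))
    chs <- vapply(anc_keys, function(k) chain_str(nodes[[k]]$sig), character(1))
    best <- anc_keys[order(-depth, -obs, chs)][1L]
    cur <- nodes[[best]]
    steps <- event_chain(cur$sig, s, rank_order)
    for (k in seq_along(steps)) {
      st <- steps[[k]]
      nxt <- cur$sig
      nxt[st[["mut"]]] <- as.integer(st[["level"]])
      nxt_key <- sig_key(nxt)
      last <- k == length(steps)
      if (is.null(nodes[[nxt_key]])) {
        if (last) {
          nodes[[nxt_key]] <- list(label = lab, sig = nxt, observed = TRUE,
                                   n_events = cur$n_events + 1L)
        } else {
          n_inferred <- n_inferred + 1L
          nodes[[nxt_key]] <- list(label = paste0("n", n_inferred), sig = nxt,
                                   observed = FALSE, n_events = cur$n_events + 1L)
        }
        edges <- c(edges, list(tibble::tibble(
          parent = cur$label, child = nodes[[nxt_key]]$label,
          event = event_label(st[["mut"]], st[["level"]]),
          event_mutation = st[["mut"]],
          event_rank = match(st[["mut"]], rank_order) + ifelse(st[["level"]] == 2L, 0.5, 0)
        )))
      }
      cur <- nodes[[nxt_key]]
    }
  }
  edges <- if (length(edges)) dplyr::bind_rows(edges) else
    tibble::tibble(parent = character(), child = character(), event = character(),
                   event_mutation = character(), event_rank = numeric())
  # contract unobserved single-child roots so the root is the founder clone
  root <- nodes[[root_key]]$label
  repeat {
    kids <- edges$child[edges$parent == root]
    is_obs <- any(vapply(nodes, function(nd) nd$label == root && nd$observed, logical(1)))
    if (is_obs || length(kids) != 1L) break
    nodes <- nodes[vapply(nodes, function(nd) nd$label != root, logical(1))]
    edges <- edges[edges$parent != root, , drop = FALSE]
    root <- kids
  }
  node_tbl <- purrr::map_dfr(nodes, function(nd) {
    states <- if (partition$resolution == "zygosity") c("WT", "HET", "HOM") else c("WT", "MUT")
    sig <- stats::setNames(states[nd$sig + 1L], muts)
    dplyr::bind_cols(tibble::tibble(label = nd$label, observed = nd$observed,
                                    n_events = nd$n_events),
                     tibble::as_tibble(as.list(sig)))
  })
  # sibling order: by event rank (gains in mutation rank order, escalations after)
  edges <- dplyr::arrange(edges, match(.data$parent, node_tbl$label), .data$event_rank)
  structure(list(nodes = node_tbl, edges = dplyr::select(edges, -"event_rank"),
                 root = root, resolution = partition$resolution, order = order),
            class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("<clone_tree> ", nrow(x$nodes), " nodes (", sum(x$nodes$observed), " observed), ",
      nrow(x$edges), " edges, root ", dQuote(x$root), ", ", x$resolution, " resolution\n", sep = "")
  if (nrow(x$edges)) {
    print(x$edges, ...)
  }
  invisible(x)
}

#' Serialize a clone tree to JSON
#'
#' Writes nodes (label, observed flag, signature) and edges (parent, child,
#' event) as a JSON document.
#'
#' @param tree A [build_clone_tree()] tree.
#' @param path Output file path.
#' @export
write_clone_tree_json <- function(tree, path) {
  stopifnot(inherits(tree, "clone_tree"))
  jsonlite::write_json(list(root = tree$root, resolution = tree$resolution,
                            nodes = tree$nodes, edges = tree$edges),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
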