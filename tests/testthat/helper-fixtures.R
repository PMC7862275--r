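# Fixtures and independent oracles used across the test files.

# Small hand-built genotype matrix builder: `calls` is a named list of
# per-mutation call vectors, one entry per cell.
gm_fixture <- function(calls, timepoint = NULL, cells = NULL) {
  n <- length(calls[[1]])
  if (is.null(cells)) cells <- sprintf("c%02d", seq_len(n))
  if (is.null(timepoint)) timepoint <- "T1"
  tibble::as_tibble(calls) |>
    dplyr::mutate(cell = cells, timepoint = timepoint, .before = 1) |>
    genotype_matrix()
}

# Random conflict-free presence matrix: draw a random rooted mutation tree
# (each mutation's parent is the root or an earlier mutation), assign each
# cell to a random node, signature = the node's ancestral mutation set.
# Conflict-free by construction.
random_tree_matrix <- function(n_mut, n_cells, seed, p_missing = 0) {
  set.seed(seed)
  muts <- paste0("M", seq_len(n_mut))
  parent <- c(0L, vapply(2:max(2, n_mut), function(i) sample.int(i - 1L, 1L) *
                           sample(c(0L, 1L), 1L), integer(1)))[seq_len(n_mut)]
  anc_set <- function(i) { out <- integer(); while (i > 0L) { out <- c(out, i); i <- parent[i] }; out }
  node_sets <- c(list(integer()), lapply(seq_len(n_mut), anc_set))
  assign <- sample(seq_along(node_sets), n_cells, replace = TRUE)
  calls <- matrix("WT", n_cells, n_mut, dimnames = list(NULL, muts))
  for (r in seq_len(n_cells)) calls[r, node_sets[[assign[r]]]] <- "HET"
  if (p_missing > 0) {
    drop <- matrix(stats::runif(n_cells * n_mut) < p_missing, n_cells, n_mut)
    keep_one <- cbind(seq_len(n_cells), sample.int(n_mut, n_cells, replace = TRUE))
    drop[keep_one] <- FALSE  # keep every cell informative
    calls[drop] <- NA
  }
  gm_fixture(tibble::as_tibble(calls))
}

# --- perfect-phylogeny tree oracle ------------------------------------------
# Independent construction: each clone's presence set is sorted by mutation
# rank into an event chain; the tree is the prefix trie of those chains, with
# the all-wild-type root contracted while it is unobserved with one child.
# Returns edges as signature-key pairs plus the root key.
oracle_tree_edges <- function(presence_sigs, rank_order) {
  muts <- colnames(presence_sigs)
  key_of <- function(v) paste(v, collapse = "|")
  observed <- apply(presence_sigs, 1L, key_of)
  nodes <- new.env(parent = emptyenv())
  edges <- list()
  add_chain <- function(sig) {
    present <- muts[sig == 1]
    chain <- present[order(match(present, rank_order))]
    cur <- stats::setNames(rep(0L, length(muts)), muts)
    cur_key <- key_of(cur)
    nodes[[cur_key]] <- TRUE
    for (m in chain) {
      nxt <- cur; nxt[m] <- 1L
      nxt_key <- key_of(nxt)
      if (is.null(nodes[[nxt_key]])) {
        nodes[[nxt_key]] <- TRUE
        edges[[length(edges) + 1L]] <<- c(parent = cur_key, child = nxt_key,
                                          event = paste0("+", m))
      }
      cur <- nxt; cur_key <- nxt_key
    }
  }
  for (r in seq_len(nrow(presence_sigs))) add_chain(presence_sigs[r, ])
  ed <- if (length(edges)) do.call(rbind, edges) else
    matrix(character(), 0, 3, dimnames = list(NULL, c("parent", "child", "event")))
  ed <- tibble::as_tibble(ed)
  root <- key_of(stats::setNames(rep(0L, length(muts)), muts))
  repeat {
    kids <- ed$child[ed$parent == root]
    if (root %in% observed || length(kids) != 1L) break
    ed <- ed[ed$parent != root, , drop = FALSE]
    root <- kids
  }
  list(edges = ed, root = root)
}

# Convert a built clone_tree to the same signature-key edge representation.
tree_to_keys <- function(tree) {
  muts <- setdiff(names(tree$nodes), c("label", "observed", "n_events"))
  lvl <- c(WT = 0L, MUT = 1L, HET = 1L, HOM = 2L)
  sig_key <- apply(tree$nodes[muts], 1L, function(r) paste(lvl[r], collapse = "|"))
  names(sig_key) <- tree$nodes$label
  list(edges = tibble::tibble(parent = unname(sig_key[tree$edges$parent]),
                              child = unname(sig_key[tree$edges$child]),
                              event = tree$edges$event),
       root = unname(sig_key[tree$root]))
}

sorted_edges <- function(e) e[order(e$parent, e$child, e$event), , drop = FALSE]

# --- minimum-flip oracle ----------------------------------------------------
is_conflict_free <- function(P) {
  A <- P; A[is.na(A)] <- 0
  B <- 1 - P; B[is.na(B)] <- 0
  n11 <- crossprod(A); n10 <- crossprod(A, B); n01 <- crossprod(B, A)
  ut <- upper.tri(n11)
  !any(n11[ut] > 0 & n10[ut] > 0 & n01[ut] > 0)
}

# Exhaustive search for the minimum number of presence flips making P
# conflict-free (defined entries only). Independent of the package's search.
oracle_min_flips <- function(P, cap = 4L) {
  defined <- which(!is.na(P))
  if (is_conflict_free(P)) return(0L)
  for (k in seq_len(cap)) {
    combos <- utils::combn(defined, k)
    for (ci in seq_len(ncol(combos))) {
      Q <- P
      Q[combos[, ci]] <- 1 - Q[combos[, ci]]
      if (is_conflict_free(Q)) return(k)
    }
  }
  NA_integer_
}

# Presence matrix with planted flips on a conflict-free base.
plant_flips <- function(gm, k, seed) {
  set.seed(seed)
  tb <- tibble::as_tibble(gm)
  muts <- mutations(gm)
  flat <- which(!is.na(as.matrix(tb[muts])))
  picks <- sample(flat, k)
  m <- as.matrix(tb[muts])
  m[picks] <- ifelse(m[picks] == "WT", "HET", "WT")
  for (j in seq_along(muts)) tb[[muts[j]]] <- m[, j]
  genotype_matrix(tb, timepoint_order = timepoints(gm))
}

# Map partition clone labels to the simulator's true clone ids by signature.
match_truth_clones <- function(partition, config) {
  sig_part <- apply(as.matrix(partition$clones[partition$mutations]), 1L, paste, collapse = "|")
  sig_true <- apply(as.matrix(config$clones[config$mutations]), 1L, paste, collapse = "|")
  stats::setNames(config$clones$clone[match(sig_part, sig_true)], partition$clones$clone)
}
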