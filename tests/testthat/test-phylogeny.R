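# Mutation ordering, conflict detection, minimum-flip repair, clone-tree
# construction and Newick serialization.

test_that("mutations rank by pooled frequency with deterministic tie-breaks", {
  gm <- gm_fixture(list(X = c(rep("HET", 9), "WT"),
                        Y = c(rep("HET", 5), rep("WT", 5)),
                        Z = c("HET", rep("WT", 9))))
  ord <- order_mutations(gm)
  expect_equal(ord$mutation, c("X", "Y", "Z"))
  expect_equal(ord$pooled_fraction, c(0.9, 0.5, 0.1))
  expect_equal(ord$rank, 1:3)
  # identical pooled and first-timepoint fractions: panel order decides
  gm_tie <- gm_fixture(list(P = c("HET", "WT"), Q = c("WT", "HET")))
  expect_equal(order_mutations(gm_tie)$mutation, c("P", "Q"))
  # invariance under cell (row) permutation
  for (seed in 1:4) {
    gm0 <- random_tree_matrix(4, 15, seed = seed)
    perm <- tibble::as_tibble(gm0)[sample(nrow(gm0)), ] |>
      genotype_matrix(timepoint_order = timepoints(gm0))
    expect_equal(order_mutations(perm), order_mutations(gm0))
  }
})

test_that("first-timepoint frequency breaks pooled ties before panel order", {
  gm <- genotype_matrix(tibble::tibble(
    cell = paste0("c", 1:4),
    timepoint = c("T1", "T1", "T2", "T2"),
    P = c("WT", "WT", "HET", "HET"),   # pooled .5, T1 0
    Q = c("HET", "WT", "HET", "WT")    # pooled .5, T1 .5
  ))
  expect_equal(order_mutations(gm)$mutation, c("Q", "P"))
})

test_that("conflicts are exactly the pairs exhibiting all three witness patterns", {
  nested <- gm_fixture(list(A = c("HET", "HET"), B = c("WT", "HET")))
  expect_equal(nrow(find_conflicts(nested)), 0L)
  conf <- gm_fixture(list(A = c("HET", "WT", "HET"), B = c("WT", "HET", "HET")))
  rep <- find_conflicts(conf)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$mut_i, "A")
  expect_equal(rep$mut_j, "B")
  expect_equal(c(rep$n_11, rep$n_10, rep$n_01), c(1L, 1L, 1L))
  # missing calls do not witness
  conf_na <- gm_fixture(list(A = c("HET", "WT", NA), B = c("WT", "HET", "HET")))
  expect_equal(nrow(find_conflicts(conf_na)), 0L)
  # noiseless simulator output is tree-generated, hence conflict-free
  for (seed in 1:5) {
    ds <- simulate_cells(default_sim_config(ado_rate = 0, miscall_rate = 0,
                                            missing_rate = 0), seed = seed)
    expect_equal(nrow(find_conflicts(ds$observed)), 0L)
  }
})

test_that("repair returns identity on conflict-free input and one flip on the minimal conflicting pattern", {
  gm <- random_tree_matrix(4, 12, seed = 5)
  res <- repair_min_flips(gm)
  expect_equal(nrow(res$flips), 0L)
  expect_identical(tibble::as_tibble(res$matrix), tibble::as_tibble(gm))
  # 5 x {A}, 1 x {B}, 5 x {A,B}: single flip resolves the conflict
  gm1 <- gm_fixture(list(A = c(rep("HET", 5), "WT", rep("HET", 5)),
                         B = c(rep("WT", 5), "HET", rep("HET", 5))))
  res1 <- repair_min_flips(gm1, method = "exact")
  expect_equal(nrow(res1$flips), 1L)
  expect_equal(nrow(find_conflicts(res1$matrix)), 0L)
  expect_equal(res1$flips$cell, "c06")
  # budget 0 on a conflicting matrix errors and names the pair
  expect_error(repair_min_flips(gm1, budget = 0), "within budget 0.*A.*B")
})

test_that("exact repair matches the exhaustive oracle on planted-flip instances", {
  for (seed in 1:12) {
    base <- random_tree_matrix(n_mut = 4, n_cells = 10, seed = seed)
    k <- seed %% 3 + 1L
    noisy <- plant_flips(base, k, seed = seed + 100)
    oracle <- oracle_min_flips(presence_matrix(noisy), cap = 3L)
    res <- repair_min_flips(noisy, method = "exact")
    expect_equal(nrow(res$flips), oracle)
    expect_true(is_conflict_free(presence_matrix(res$matrix)))
  }
})

test_that("a single planted miscall is repaired back to the simulator truth", {
  cfg <- default_sim_config(ado_rate = 0, miscall_rate = 0, missing_rate = 0)
  cfg$n_cells <- c(T1 = 25L, T2 = 25L, T3 = 25L)
  ds <- simulate_cells(cfg, seed = 8)
  tb <- tibble::as_tibble(ds$observed)
  victim <- which(ds$truth$clone == "B")[1]  # TET2a+JAK2 cell gains a fake TP53
  tb$TP53[victim] <- "HET"
  noisy <- genotype_matrix(tb, timepoint_order = timepoints(ds$observed))
  expect_gt(nrow(find_conflicts(noisy)), 0L)
  res <- repair_min_flips(noisy, method = "exact")
  expect_equal(nrow(res$flips), 1L)
  expect_identical(tibble::as_tibble(res$matrix), tibble::as_tibble(ds$observed))
})

test_that("greedy repair resolves conflicts on large noisy matrices", {
  ds <- simulate_cells(default_sim_config(), seed = 77)
  res <- repair_min_flips(ds$observed, method = "greedy")
  expect_equal(nrow(find_conflicts(res$matrix)), 0L)
  expect_gt(nrow(res$flips), 0L)
})

test_that("clone trees follow the containment construction on canonical shapes", {
  # chain {}, {A}, {A,B}, {A,B,C} -> root -> +A -> +B -> +C
  gm <- gm_fixture(list(A = c("WT", "HET", "HET", "HET", "HET"),
                        B = c("WT", "WT", "HET", "HET", "HET"),
                        C = c("WT", "WT", "WT", "HET", "WT")))
  part <- call_clones(gm, resolution = "presence")
  tree <- build_clone_tree(part)
  expect_equal(nrow(tree$nodes), 4L)
  expect_equal(tree$edges$event, c("+A", "+B", "+C"))
  expect_true(all(tree$nodes$observed))
  # siblings {A}, {A,B}, {A,C}: root is the founder clone A, children by rank
  gm2 <- gm_fixture(list(A = c("HET", "HET", "HET", "HET"),
                         B = c("WT", "HET", "HET", "WT"),
                         C = c("WT", "WT", "WT", "HET")))
  part2 <- call_clones(gm2, resolution = "presence")
  tree2 <- build_clone_tree(part2)
  root_kids <- tree2$edges[tree2$edges$parent == tree2$root, ]
  expect_equal(root_kids$event, c("+B", "+C"))
  expect_equal(tree2$root, part2$clones$clone[part2$clones$A == "MUT" &
                                              part2$clones$B == "WT" &
                                              part2$clones$C == "WT"])
  # conflicting signatures refuse to build
  gm3 <- gm_fixture(list(A = c("HET", "WT", "HET"), B = c("WT", "HET", "HET")))
  expect_error(build_clone_tree(call_clones(gm3, resolution = "presence")),
               "not tree-compatible")
})

test_that("zygosity trees materialize unobserved intermediates, one event per edge", {
  # {A:HET} and {A:HOM, B:HET}: the A escalation is inferred on the path
  gm <- gm_fixture(list(A = c("HET", "HET", "HOM", "HOM"),
                        B = c("WT", "WT", "HET", "HET")))
  tree <- build_clone_tree(call_clones(gm))
  expect_equal(nrow(tree$nodes), 3L)
  inferred <- tree$nodes[!tree$nodes$observed, ]
  expect_equal(nrow(inferred), 1L)
  expect_equal(inferred$A, "HOM")
  expect_equal(inferred$B, "WT")
  expect_equal(sort(tree$edges$event), sort(c("A:HET>HOM", "+B")))
  # an observed node at the same depth is preferred over inferring one
  gm2 <- gm_fixture(list(A = c("HET", "HET", "HOM", "HOM"),
                         B = c("HET", "HET", "HET", "HET")))
  tree2 <- build_clone_tree(call_clones(gm2))
  expect_true(all(tree2$nodes$observed))
  expect_equal(tree2$edges$event, "A:HET>HOM")
})

test_that("every root-to-leaf path gains each mutation once, escalating at most once", {
  for (seed in 1:8) {
    ds <- simulate_cells(default_sim_config(missing_rate = 0), seed = seed)
    rep <- repair_min_flips(ds$observed, method = "greedy")
    tree <- build_clone_tree(call_clones(rep$matrix))
    kids <- split(seq_len(nrow(tree$edges)), tree$edges$parent)
    walk <- function(label, seen_gain, seen_esc) {
      ek <- kids[[label]]
      if (is.null(ek)) ek <- integer()
      for (e in ek) {
        ev <- tree$edges$event[e]
        mut <- tree$edges$event_mutation[e]
        if (startsWith(ev, "+")) {
          expect_false(mut %in% seen_gain)
          walk(tree$edges$child[e], c(seen_gain, mut), seen_esc)
        } else {
          expect_true(mut %in% seen_gain)   # escalation only after gain
          expect_false(mut %in% seen_esc)
          walk(tree$edges$child[e], seen_gain, c(seen_esc, mut))
        }
      }
    }
    walk(tree$root, character(), character())
    # root reachability: edges form a tree
    expect_equal(nrow(tree$edges), nrow(tree$nodes) - 1L)
  }
})

test_that("noiseless default simulations rebuild the 9-clone truth tree", {
  cfg <- default_sim_config(ado_rate = 0, miscall_rate = 0, missing_rate = 0)
  for (seed in c(3, 17)) {
    ds <- simulate_cells(cfg, seed = seed)
    part <- call_clones(ds$observed)
    tree <- build_clone_tree(part)
    map <- match_truth_clones(part, cfg)
    got <- tibble::tibble(parent = unname(map[tree$edges$parent]),
                          child = unname(map[tree$edges$child]))
    want <- cfg$clones[!is.na(cfg$clones$parent), c("parent", "clone")]
    expect_equal(dplyr::arrange(got, parent, child),
                 dplyr::arrange(tibble::tibble(parent = want$parent, child = want$clone),
                                parent, child))
  }
})

test_that("newick export writes labelled chains with event comments and round-trips", {
  gm <- gm_fixture(list(M1 = c("WT", "WT", "WT", "HET", "HET", "HET"),
                        M2 = c("WT", "WT", "WT", "WT", "WT", "HET")))
  tree <- build_clone_tree(call_clones(gm))
  expect_equal(export_newick(tree), "((C[+M2])B[+M1])A;")
  expect_equal(export_newick(tree, events = FALSE), "((C)B)A;")
  # single-node tree
  one <- build_clone_tree(call_clones(gm_fixture(list(M1 = rep("HET", 3)))))
  expect_equal(export_newick(one), "A;")
  # parse -> export round-trips, preserving events and sibling order
  for (seed in 1:6) {
    gm_r <- random_tree_matrix(5, 20, seed = seed)
    tr <- build_clone_tree(call_clones(gm_r, resolution = "presence"))
    nk <- export_newick(tr)
    expect_equal(export_newick(parse_newick(nk)), nk)
  }
  expect_error(parse_newick("((A)B"), "malformed|end with")
})

test_that("comment-free newick output is readable by standard phylogenetics tools", {
  gm <- random_tree_matrix(5, 25, seed = 42)
  tree <- build_clone_tree(call_clones(gm, resolution = "presence"))
  ph <- ape::read.tree(text = export_newick(tree, events = FALSE))
  expect_s3_class(ph, "phylo")
  n_leaves <- sum(!tree$nodes$label %in% tree$edges$parent)
  expect_equal(ape::Ntip(ph), n_leaves)
})
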