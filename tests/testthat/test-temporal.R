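# Temporal clone tracking, nesting, trajectories and zygosity evolution.

test_that("clones are matched across timepoints by signature, absentees get zero", {
  gm <- genotype_matrix(tibble::tibble(
    cell = paste0("c", 1:6),
    timepoint = c("T1", "T1", "T1", "T2", "T2", "T2"),
    A = c("HET", "HET", "HET", "HET", "HET", "HET"),
    B = c("WT", "WT", "WT", "HET", "HET", "WT")
  ))
  part <- call_clones(gm)
  tree <- build_clone_tree(part)
  prev <- track_clones(part, tree)
  derived <- part$clones$clone[part$clones$B == "HET"]
  own <- prev$own_fraction[prev$clone == derived]
  expect_equal(own, c(0, 2 / 3))   # absent at T1, present at T2
  # the founder's nested prevalence covers everything at both timepoints
  expect_equal(prev$nested_fraction[prev$clone == tree$root], c(1, 1))
})

test_that("proportional rescaling fits children into their parent and is logged", {
  gm <- gm_fixture(list(A = c("HET", "HET", "HET"), B = c("WT", "HET", "WT"),
                        C = c("WT", "WT", "HET")))
  tree <- build_clone_tree(call_clones(gm))
  lab <- function(b, c) tree$nodes$label[tree$nodes$B == b & tree$nodes$C == c]
  tbl <- tibble::tibble(
    clone = c(lab("WT", "WT"), lab("HET", "WT"), lab("WT", "HET")),
    timepoint = "T1",
    nested_fraction = c(0.5, 0.4, 0.2)   # children exceed the parent
  )
  expect_message(fixed <- enforce_nesting(tbl, tree), "rescaled 1")
  expect_equal(fixed$nested_fraction, c(0.5, 1 / 3, 1 / 6), tolerance = 1e-12)
  resc <- attr(fixed, "rescales")
  expect_equal(resc$clone, lab("WT", "WT"))
  expect_equal(resc$factor, 0.5 / 0.6, tolerance = 1e-12)
})

test_that("nested fractions are monotone along root-to-leaf paths", {
  for (seed in 1:4) {
    ds <- simulate_cells(default_sim_config(missing_rate = 0), seed = seed)
    rep <- repair_min_flips(ds$observed, method = "greedy")
    part <- call_clones(rep$matrix)
    tree <- build_clone_tree(part)
    prev <- track_clones(part, tree)
    for (tp in unique(prev$timepoint)) {
      nested <- stats::setNames(prev$nested_fraction[prev$timepoint == tp],
                                prev$clone[prev$timepoint == tp])
      ok <- vapply(seq_len(nrow(tree$edges)), function(e) {
        nested[[tree$edges$parent[e]]] >= nested[[tree$edges$child[e]]] - 1e-9
      }, logical(1))
      expect_true(all(ok))
    }
  }
})

test_that("the fully mutated clone's prevalence rises 9/15/23 percent in noiseless runs", {
  cfg <- default_sim_config(ado_rate = 0, miscall_rate = 0, missing_rate = 0)
  ds <- simulate_cells(cfg, seed = 19)
  part <- call_clones(ds$observed)
  tree <- build_clone_tree(part)
  prev <- track_clones(part, tree)
  map <- match_truth_clones(part, cfg)
  full_label <- names(map)[map == "I"]
  own <- prev$own_fraction[prev$clone == full_label]
  for (i in seq_along(own)) {
    p <- c(0.09, 0.15, 0.23)[i]
    expect_lt(abs(own[i] - p), 3 * sqrt(p * (1 - p) / 300))
  }
})

test_that("own-fraction estimates are unbiased over repeated noise-free sampling", {
  cfg <- default_sim_config(ado_rate = 0, miscall_rate = 0, missing_rate = 0)
  errs <- vapply(1:30, function(seed) {
    ds <- simulate_cells(cfg, seed = 100 + seed)
    part <- call_clones(ds$observed)
    map <- match_truth_clones(part, cfg)
    prev <- track_clones(part, build_clone_tree(part))
    i_label <- names(map)[map == "I"]
    prev$own_fraction[prev$clone == i_label & prev$timepoint == "T2"] - 0.15
  }, numeric(1))
  se <- sqrt(0.15 * 0.85 / 300) / sqrt(length(errs))
  expect_lt(abs(mean(errs)), 2 * se)
})

test_that("frequency trajectories match hand counts and carry acquisition ranks", {
  gm <- genotype_matrix(tibble::tibble(
    cell = paste0("c", 1:6),
    timepoint = rep(c("T1", "T2"), each = 3),
    M1 = c("HET", "HOM", "WT", "HET", "HET", "HET"),
    M2 = c("WT", "HET", "WT", "WT", "HET", "HOM"),
    M3 = rep("WT", 6)
  ))
  tr <- frequency_trajectories(gm)
  get <- function(m, tp) tr$mutated_fraction[tr$mutation == m & tr$timepoint == tp]
  expect_equal(get("M1", "T1"), 2 / 3)
  expect_equal(get("M1", "T2"), 1)
  expect_equal(get("M2", "T1"), 1 / 3)
  expect_equal(get("M2", "T2"), 2 / 3)
  expect_equal(get("M3", "T1"), 0)   # never mutated: all zeros
  expect_equal(get("M3", "T2"), 0)
  expect_equal(tr$rank[tr$mutation == "M1"], c(1L, 1L))
  expect_equal(tr$rank[tr$mutation == "M3"], c(3L, 3L))
})

test_that("zygosity evolution is constant for a constant matrix and detects late homozygosity", {
  gm_const <- genotype_matrix(tibble::tibble(
    cell = paste0("c", 1:4), timepoint = rep(c("T1", "T2"), each = 2),
    M = c("HET", "WT", "HET", "WT")
  ))
  ze <- zygosity_evolution(gm_const, "M")
  t1 <- ze[ze$timepoint == "T1", c("state", "prop_all")]
  t2 <- ze[ze$timepoint == "T2", c("state", "prop_all")]
  expect_equal(t1$prop_all, t2$prop_all)
  # FLT3 homozygosity appears only in the leukemic phase of the reference design
  ds <- simulate_cells(default_sim_config(ado_rate = 0, miscall_rate = 0,
                                          missing_rate = 0), seed = 6)
  zf <- zygosity_evolution(ds$observed, "FLT3")
  hom <- zf[zf$state == "HOM", ]
  expect_equal(hom$prop_all[hom$timepoint %in% c("T1", "T2")], c(0, 0))
  expect_gt(hom$prop_all[hom$timepoint == "T3"], 0)
})

test_that("fishplot JSON export carries parents and both prevalence kinds", {
  ds <- simulate_cells(default_sim_config(ado_rate = 0, miscall_rate = 0,
                                          missing_rate = 0), seed = 4)
  part <- call_clones(ds$observed)
  tree <- build_clone_tree(part)
  prev <- track_clones(part, tree)
  f <- withr::local_tempfile(fileext = ".json")
  write_fishplot_json(prev, f)
  rec <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_setequal(names(rec), c("clone", "parent", "timepoint", "own_fraction",
                                "nested_fraction"))
  expect_equal(nrow(rec), nrow(prev))
  expect_true(all(rec$parent[rec$clone == tree$root] == ""))
})
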