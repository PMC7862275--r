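#' Pipeline configuration
#'
#' A pipeline run is driven by a single config: either input paths (genotype
#' matrix, optional mutation catalog and colony table) or a simulation config
#' — exactly one of the two — plus the analysis knobs. All randomness in a run
#' descends from the single `seed`.
#'
#' @param matrix,catalog,colonies Input file paths (matrix required in file
#'   mode; the others optional).
#' @param simulation A [sim_config()] (or path to one written by
#'   [write_sim_config()]) for simulation mode.
#' @param resolution Clone-calling resolution, `"zygosity"` or `"presence"`.
#' @param min_cells Minor-clone display threshold for [call_clones()].
#' @param repair_budget Maximum flips for [repair_min_flips()] when the matrix
#'   has perfect-phylogeny conflicts.
#' @param ado_mutation Mutation used for the cell-versus-colony ADO validation
#'   (default `"SRSF2"` when present, else the first mutation).
#' @param seed Integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(matrix = NULL, catalog = NULL, colonies = NULL,
                            simulation = NULL, resolution = "zygosity",
                            min_cells = 1L, repair_budget = Inf,
                            ado_mutation = NULL, seed = 1L) {
  if (is.null(matrix) == is.null(simulation)) {
    rlang::abort("exactly one of `matrix` (file mode) or `simulation` must be given")
  }
  if (is.character(simulation)) simulation <- read_sim_config(simulation)
  structure(list(matrix = matrix, catalog = catalog, colonies = colonies,
                 simulation = simulation, resolution = resolution,
                 min_cells = min_cells, repair_budget = repair_budget,
                 ado_mutation = ado_mutation, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path Path to a YAML pipeline config.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- y$simulation
  if (isTRUE(sim) || identical(sim, "default")) sim <- default_sim_config()
  pipeline_config(matrix = y$matrix, catalog = y$catalog, colonies = y$colonies,
                  simulation = sim, resolution = y$resolution %||% "zygosity",
                  min_cells = y$min_cells %||% 1L,
                  repair_budget = y$repair_budget %||% Inf,
                  ado_mutation = y$ado_mutation, seed = y$seed %||% 1L)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
                 parent = e)
  })
}

#' Run the full clonal-architecture pipeline
#'
#' Executes read-or-simulate, conflict repair, clone calling, mutation
#' ordering, clone-tree construction, temporal prevalence and zygosity tables,
#' and (when colony genotypes are available) ADO validation; writes every
#' artifact to `out_dir` together with a JSON manifest of MD5 content hashes.
#' Identical config and seed give identical artifact hashes.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Overrides `config$seed`.
#' @return The manifest tibble (`file`, `md5`), invisibly; the full set of
#'   in-memory results is attached as attribute `results`.
#' @export
run_pipeline <- function(config, out_dir, seed = config$seed) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)
  files <- character()
  emit <- function(f) files <<- c(files, f)

  # 1. acquire
  colonies_full <- NULL
  if (!is.null(config$simulation)) {
    ds <- stage("simulate", simulate_cells(config$simulation, seed = seed))
    gm <- ds$observed
    colonies_full <- ds$colonies
    stage("simulate", {
      write_genotype_matrix(ds$observed, path("observed_matrix.tsv")); emit("observed_matrix.tsv")
      write_genotype_matrix(ds$truth_matrix, path("truth_matrix.tsv")); emit("truth_matrix.tsv")
      readr::write_tsv(ds$truth, path("truth_clones.tsv"), progress = FALSE); emit("truth_clones.tsv")
    })
  } else {
    gm <- stage("read", read_genotype_matrix(config$matrix))
    if (!is.null(config$colonies)) {
      colonies_file <- stage("read", read_colony_table(config$colonies))
    }
  }

  # 2. conflict detection / repair
  conflicts <- stage("repair", find_conflicts(gm))
  readr::write_tsv(conflicts, path("conflicts.tsv"), progress = FALSE); emit("conflicts.tsv")
  flips <- tibble::tibble(cell = character(), mutation = character(),
                          from = character(), to = character())
  if (nrow(conflicts) > 0L) {
    rep <- stage("repair", repair_min_flips(gm, budget = config$repair_budget))
    gm <- rep$matrix
    flips <- rep$flips
  }
  readr::write_tsv(flips, path("flips.tsv"), progress = FALSE); emit("flips.tsv")

  # 3. clones
  partition <- stage("clone_calling", call_clones(gm, resolution = config$resolution,
                                                  min_cells = config$min_cells))
  readr::write_tsv(partition$clones, path("clones.tsv"), progress = FALSE); emit("clones.tsv")
  readr::write_tsv(partition$assignments, path("cell_assignments.tsv"), progress = FALSE)
  emit("cell_assignments.tsv")
  readr::write_tsv(partition$unassigned, path("unassigned_cells.tsv"), progress = FALSE)
  emit("unassigned_cells.tsv")
  diversity <- clone_diversity(partition)
  readr::write_tsv(diversity, path("clone_diversity.tsv"), progress = FALSE)
  emit("clone_diversity.tsv")

  # 4. order + tree
  order <- stage("ordering", order_mutations(gm))
  readr::write_tsv(order, path("mutation_order.tsv"), progress = FALSE); emit("mutation_order.tsv")
  tree <- stage("tree", build_clone_tree(partition, order))
  writeLines(export_newick(tree), path("clone_tree.nwk")); emit("clone_tree.nwk")
  write_clone_tree_json(tree, path("clone_tree.json")); emit("clone_tree.json")

  # 5. temporal tables
  prevalence <- stage("temporal", track_clones(partition, tree))
  readr::write_tsv(prevalence, path("clone_prevalence.tsv"), progress = FALSE)
  emit("clone_prevalence.tsv")
  write_fishplot_json(prevalence, path("fishplot.json")); emit("fishplot.json")
  trajectories <- stage("temporal", frequency_trajectories(gm, order))
  readr::write_tsv(trajectories, path("mutation_trajectories.tsv"), progress = FALSE)
  emit("mutation_trajectories.tsv")
  zygosity <- stage("temporal", purrr::map_dfr(mutations(gm),
                                               function(m) zygosity_evolution(gm, m)))
  readr::write_tsv(zygosity, path("zygosity_evolution.tsv"), progress = FALSE)
  emit("zygosity_evolution.tsv")
  fisher <- stage("temporal", consecutive_fisher_tests(gm))
  readr::write_tsv(fisher, path("fisher_tests.tsv"), progress = FALSE); emit("fisher_tests.tsv")

  # 6. ADO validation against colonies
  ado <- NULL
  if (!is.null(colonies_full) || (is.null(config$simulation) && !is.null(config$colonies))) {
    ado_mut <- config$ado_mutation %||%
      (if ("SRSF2" %in% mutations(gm)) "SRSF2" else mutations(gm)[1])
    ado <- stage("ado", {
      purrr::map_dfr(timepoints(gm), function(tp) {
        cc <- genotype_counts(gm, ado_mut, tp)
        kk <- if (!is.null(colonies_full)) {
          ct <- colony_table(colonies_full[colonies_full$timepoint == tp, ], ado_mut)
          c(WT = sum(ct$call == "WT"), HET = sum(ct$call == "HET"), HOM = sum(ct$call == "HOM"))
        } else {
          ct <- colonies_file[colonies_file$timepoint == tp, ]
          c(WT = sum(ct$call == "WT"), HET = sum(ct$call == "HET"), HOM = sum(ct$call == "HOM"))
        }
        if (sum(kk) == 0) return(NULL)
        est <- suppressWarnings(
          estimate_ado_rate(cc[GT_STATES], kk, n_missing = unname(cc[["MISSING"]]),
                            n_boot = 200, seed = stream_seed(seed, paste0("ado:", tp))))
        fh <- genotype_distribution_test(cc[GT_STATES], kk,
                                         seed = stream_seed(seed, paste0("fh:", tp)))
        tibble::tibble(timepoint = tp, mutation = ado_mut,
                       d_hat = est$d_hat, ci_lower = est$ci[1], ci_upper = est$ci[2],
                       identifiable = est$identifiable,
                       fh_method = fh$method, fh_p_value = fh$p_value)
      })
    })
    if (!is.null(ado) && nrow(ado)) {
      readr::write_tsv(ado, path("ado_validation.tsv"), progress = FALSE)
      emit("ado_validation.tsv")
    }
  }

  # 7. manifest
  files <- sort(unique(files))
  manifest <- tibble::tibble(file = files,
                             md5 = unname(tools::md5sum(file.path(out_dir, files))))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE, digits = NA)
  results <- list(matrix = gm, conflicts = conflicts, flips = flips,
                  partition = partition, order = order, tree = tree,
                  prevalence = prevalence, trajectories = trajectories,
                  zygosity = zygosity, diversity = diversity, ado = ado)
  out <- manifest
  attr(out, "results") <- results
  invisible(out)
}

# Mutated-vs-wild-type Fisher tests between consecutive timepoints for every
# mutation: the standard way to ask whether a mutated-cell proportion changed.
consecutive_fisher_tests <- function(gm) {
  tps <- timepoints(gm)
  if (length(tps) < 2L) {
    return(tibble::tibble(mutation = character(), from = character(), to = character(),
                          odds_ratio = numeric(), p_value = numeric()))
  }
  purrr::map_dfr(mutations(gm), function(m) {
    purrr::map_dfr(seq_len(length(tps) - 1L), function(i) {
      c1 <- genotype_counts(gm, m, tps[i]); c2 <- genotype_counts(gm, m, tps[i + 1L])
      tab <- rbind(c(c1[["HET"]] + c1[["HOM"]], c1[["WT"]]),
                   c(c2[["HET"]] + c2[["HOM"]], c2[["WT"]]))
      res <- suppressWarnings(fisher_exact_2x2(tab))
      tibble::tibble(mutation = m, from = tps[i], to = tps[i + 1L],
                     odds_ratio = res$statistic, p_value = res$p_value)
    })
  })
}
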