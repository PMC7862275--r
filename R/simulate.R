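#' Simulation configurations with known clonal truth
#'
#' A simulation config fully describes a generative single-cell genotyping
#' experiment: a rooted clone tree in which each child differs from its parent
#' by exactly one event (mutation gain `WT -> HET` or zygosity escalation
#' `HET -> HOM`), per-timepoint clone prevalences summing to one, cell counts
#' per timepoint, and the observation noise of whole-genome-amplified
#' single-cell genotyping — a per-allele allele-dropout (ADO) probability, a
#' genotype miscall probability, and an extra missing-call probability.
#' Colony outgrowth is modelled by a positive per-clone `fitness` weight.
#'
#' @param clones Tibble with columns `clone`, `parent` (`NA` for the root),
#'   `fitness`, and one column per mutation holding the clone's true state
#'   (`"WT"`, `"HET"`, `"HOM"`).
#' @param prevalence Long tibble `clone`, `timepoint`, `prevalence`; per
#'   timepoint the prevalences must sum to 1.
#' @param n_cells Named integer vector: cells to draw per timepoint.
#' @param ado_rate Per-allele dropout probability, in `[0, 0.5]`.
#' @param miscall_rate Probability that a defined observed state is replaced by
#'   one of the other two defined states (uniformly), in `[0, 0.2]`.
#' @param missing_rate Probability of a missing call on top of ADO's
#'   both-allele dropout, in `[0, 0.2]`.
#' @param n_colonies Colonies to draw per timepoint in [simulate_colonies()].
#' @param seed Default integer seed for [simulate_cells()] /
#'   [simulate_colonies()]; every random draw in a simulation descends
#'   deterministically from it.
#' @return A `sim_config` object (a validated list).
#' @seealso [default_sim_config()] for the package's reference configuration.
#' @export
sim_config <- function(clones, prevalence, n_cells, ado_rate = 0, miscall_rate = 0,
                       missing_rate = 0, n_colonies = 0, seed = 1L) {
  clones <- tibble::as_tibble(clones)
  prevalence <- tibble::as_tibble(prevalence)
  if (!all(c("clone", "parent") %in% names(clones))) {
    rlang::abort("`clones` needs `clone` and `parent` columns")
  }
  if (!"fitness" %in% names(clones)) clones$fitness <- 1
  muts <- setdiff(names(clones), c("clone", "parent", "fitness"))
  if (length(muts) == 0L) rlang::abort("`clones` needs at least one mutation column")
  if (anyDuplicated(clones$clone)) rlang::abort("clone ids must be unique")
  if (!all(unlist(clones[muts]) %in% GT_STATES)) {
    rlang::abort("clone signatures must use states WT/HET/HOM")
  }
  if (any(clones$fitness < 0)) rlang::abort("fitness weights must be non-negative")
  roots <- clones$clone[is.na(clones$parent)]
  if (length(roots) != 1L) rlang::abort("the clone tree needs exactly one root (parent = NA)")
  if (!all(stats::na.omit(clones$parent) %in% clones$clone)) {
    rlang::abort("every parent must be a clone id")
  }
  # connectivity + single-event edges
  lvl <- c(WT = 0L, HET = 1L, HOM = 2L)
  sig <- as.matrix(clones[muts]); rownames(sig) <- clones$clone
  for (i in seq_len(nrow(clones))) {
    p <- clones$parent[i]
    if (is.na(p)) next
    step <- lvl[sig[i, ]] - lvl[sig[p, ]]
    if (any(step < 0) || sum(step) != 1L) {
      rlang::abort(paste0("clone ", dQuote(clones$clone[i]),
                          " must differ from its parent by exactly one gain or escalation"))
    }
  }
  seen <- roots; frontier <- roots
  while (length(frontier)) {
    frontier <- clones$clone[!is.na(clones$parent) & clones$parent %in% frontier & !clones$clone %in% seen]
    seen <- c(seen, frontier)
  }
  if (!setequal(seen, clones$clone)) rlang::abort("clone tree is not connected")
  if (!all(c("clone", "timepoint", "prevalence") %in% names(prevalence))) {
    rlang::abort("`prevalence` needs `clone`, `timepoint`, `prevalence` columns")
  }
  sums <- tapply(prevalence$prevalence, prevalence$timepoint, sum)
  if (any(abs(sums - 1) > 1e-8)) rlang::abort("prevalences must sum to 1 within each timepoint")
  if (any(prevalence$prevalence < 0)) rlang::abort("prevalences must be non-negative")
  if (is.null(names(n_cells))) rlang::abort("`n_cells` must be a named vector (one entry per timepoint)")
  if (ado_rate < 0 || ado_rate > 0.5) rlang::abort("`ado_rate` must be in [0, 0.5]")
  if (miscall_rate < 0 || miscall_rate > 0.2) rlang::abort("`miscall_rate` must be in [0, 0.2]")
  if (missing_rate < 0 || missing_rate > 0.2) rlang::abort("`missing_rate` must be in [0, 0.2]")
  structure(list(clones = clones, prevalence = prevalence, mutations = muts,
                 timepoints = names(n_cells), n_cells = n_cells,
                 ado_rate = ado_rate, miscall_rate = miscall_rate,
                 missing_rate = missing_rate, n_colonies = n_colonies,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Reference simulation: three-timepoint myelofibrosis-to-AML clonal history
#'
#' The package's reference configuration emulates a documented clinical course:
#' three sampling timepoints (chronic phase T1, accelerated phase T2, leukemic
#' phase T3; 300 CD34+ cells each), the seven-mutation panel of
#' [mutation_catalog()], and nine clones A-I on a tree that grows along the
#' acquisition order TET2a, JAK2, TET2b, ASXL1, SRSF2, TP53 (clone F), and
#' FLT3 last — completing the fully mutated clone I — before escalating to
#' homozygosity in two terminal clones: TP53-homozygous G and FLT3-homozygous
#' H, the latter present only in the leukemic phase.
#'
#' Prevalences are anchored so that, in expectation, the TP53 mutated-cell
#' fraction rises from 20.8% (T1) to 63% (T2) and falls back at T3, the FLT3
#' fraction rises linearly 16.6% / 25% / 35.6%, and the fully mutated clone
#' grows 9% / 15% / 23%. The remaining clone mass is an emulation chosen once
#' (see the `provenance` column of `$prevalence`) so that per-timepoint mutated
#' fractions follow the acquisition order and clone-size entropy rises from T1
#' to T3. Default noise: ADO 0.1 per allele, miscall 0.01, missing 0.02,
#' 50 colonies per timepoint.
#'
#' @inheritParams sim_config
#' @return A [sim_config()] object.
#' @export
default_sim_config <- function(ado_rate = 0.1, miscall_rate = 0.01, missing_rate = 0.02,
                               n_colonies = 50, seed = 1L) {
  clones <- tibble::tribble(
    ~clone, ~parent, ~TET2a, ~JAK2, ~TET2b, ~ASXL1, ~SRSF2, ~TP53, ~FLT3,
    "A", NA,  "HET", "WT",  "WT",  "WT",  "WT",  "WT",  "WT",
    "B", "A", "HET", "HET", "WT",  "WT",  "WT",  "WT",  "WT",
    "C", "B", "HET", "HET", "HET", "WT",  "WT",  "WT",  "WT",
    "D", "C", "HET", "HET", "HET", "HET", "WT",  "WT",  "WT",
    "E", "D", "HET", "HET", "HET", "HET", "HET", "WT",  "WT",
    "F", "E", "HET", "HET", "HET", "HET", "HET", "HET", "WT",
    "I", "F", "HET", "HET", "HET", "HET", "HET", "HET", "HET",
    "G", "I", "HET", "HET", "HET", "HET", "HET", "HOM", "HET",
    "H", "I", "HET", "HET", "HET", "HET", "HET", "HET", "HOM"
  )
  clones$fitness <- 1
  prev <- tibble::tibble(
    clone = rep(clones$clone, times = 3),
    timepoint = rep(c("T1", "T2", "T3"), each = 9),
    #              A      B      C      D      E      F      I      G      H
    prevalence = c(
      0.400, 0.160, 0.100, 0.080, 0.052, 0.042, 0.090, 0.076, 0.000,  # T1
      0.080, 0.080, 0.070, 0.070, 0.070, 0.380, 0.150, 0.100, 0.000,  # T2
      0.110, 0.110, 0.110, 0.110, 0.110, 0.094, 0.230, 0.086, 0.040   # T3
    ),
    provenance = rep(c("emulated", "emulated", "emulated", "emulated", "emulated",
                       "anchored", "anchored", "anchored", "anchored"), times = 3)
  )
  sim_config(clones, prev, n_cells = c(T1 = 300L, T2 = 300L, T3 = 300L),
             ado_rate = ado_rate, miscall_rate = miscall_rate,
             missing_rate = missing_rate, n_colonies = n_colonies, seed = seed)
}

# Expected (noise-free) mutated-cell fraction per mutation x timepoint implied
# by a config -- the truth the estimators are benchmarked against.
#' @rdname sim_config
#' @param config A `sim_config`.
#' @export
expected_mutated_fractions <- function(config) {
  sig <- config$clones[config$mutations]
  purrr::map_dfr(config$mutations, function(m) {
    carriers <- config$clones$clone[sig[[m]] != "WT"]
    config$prevalence |>
      dplyr::group_by(.data$timepoint) |>
      dplyr::summarise(mutated_fraction = sum(.data$prevalence[.data$clone %in% carriers]),
                       .groups = "drop") |>
      dplyr::mutate(mutation = m, .before = 1)
  })
}

# Apply the observation model to a character matrix of true states.
# ADO acts per allele (rate d, independent); miscall then replaces a defined
# state by one of the other two (rate e); extra missingness overrides all.
observe_genotypes <- function(truth, ado_rate, miscall_rate, missing_rate) {
  n <- length(truth)
  obs <- truth
  r1 <- stats::runif(n); r2 <- stats::runif(n)  # one draw per allele
  het <- truth == "HET"
  obs[het & r1 < ado_rate & r2 < ado_rate] <- NA       # both alleles dropped
  obs[het & r1 < ado_rate & r2 >= ado_rate] <- "HOM"   # wild-type allele dropped
  obs[het & r1 >= ado_rate & r2 < ado_rate] <- "WT"    # mutant allele dropped
  hom <- !het
  obs[hom & r1 < ado_rate & r2 < ado_rate] <- NA
  rmis <- stats::runif(n)
  pick <- stats::runif(n)
  mis <- !is.na(obs) & rmis < miscall_rate
  if (any(mis)) {
    others <- rbind(WT = c("HET", "HOM"), HET = c("WT", "HOM"), HOM = c("WT", "HET"))
    obs[mis] <- others[cbind(match(obs[mis], rownames(others)), 1L + (pick[mis] > 0.5))]
  }
  obs[stats::runif(n) < missing_rate] <- NA
  obs
}

#' Simulate single-cell genotyping data with known clonal truth
#'
#' Per timepoint, `n_cells` clone labels are drawn from the configured
#' prevalence distribution (multinomial sampling), the true genotype of a cell
#' is its clone's signature, and the observed genotype is
#' miscall(ADO(truth)) with extra missingness. Randomness is fully
#' reproducible: each timepoint uses a sub-stream derived deterministically
#' from `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A `sim_dataset` list: `truth` (tibble `cell`, `timepoint`, `clone`),
#'   `truth_matrix` and `observed` ([genotype_matrix()]s sharing cell ids),
#'   `colonies` (per-timepoint colony genotypes, see [simulate_colonies()]),
#'   and `config`. Cells whose calls all dropped out (complete amplification
#'   failure) are removed from truth and observation alike, with a message.
#' @examples
#' ds <- simulate_cells(default_sim_config(ado_rate = 0, miscall_rate = 0,
#'                                         missing_rate = 0), seed = 7)
#' identical(ds$observed, ds$truth_matrix)  # noiseless: observation = truth
#' @export
simulate_cells <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  sig <- as.matrix(config$clones[config$mutations])
  rownames(sig) <- config$clones$clone
  per_tp <- purrr::map(config$timepoints, function(tp) {
    n <- config$n_cells[[tp]]
    prev <- config$prevalence[config$prevalence$timepoint == tp, ]
    prev <- prev[match(config$clones$clone, prev$clone), ]
    set.seed(stream_seed(seed, paste0("cells:", tp)))
    cl <- sample(config$clones$clone, n, replace = TRUE, prob = prev$prevalence)
    truth <- sig[cl, , drop = FALSE]
    obs <- observe_genotypes(truth, config$ado_rate, config$miscall_rate, config$missing_rate)
    dim(obs) <- dim(truth)
    dimnames(obs) <- dimnames(truth)
    cells <- sprintf("%s_c%03d", tp, seq_len(n))
    # a cell whose every call dropped out carries no information: remove it
    # from truth and observation alike (they must share cell ids)
    keep <- rowSums(!is.na(obs)) > 0L
    list(truth = tibble::tibble(cell = cells[keep], timepoint = tp, clone = cl[keep]),
         n_failed = sum(!keep),
         tm = tibble::as_tibble(truth[keep, , drop = FALSE]) |>
           rlang::set_names(config$mutations) |>
           dplyr::mutate(cell = cells[keep], timepoint = tp, .before = 1),
         om = tibble::as_tibble(obs[keep, , drop = FALSE]) |>
           rlang::set_names(config$mutations) |>
           dplyr::mutate(cell = cells[keep], timepoint = tp, .before = 1))
  })
  n_failed <- sum(vapply(per_tp, function(x) x$n_failed, integer(1)))
  if (n_failed > 0L) {
    rlang::inform(paste0(n_failed, " simulated cell(s) had all calls missing and were removed"))
  }
  truth <- purrr::map_dfr(per_tp, "truth")
  truth$timepoint <- factor(truth$timepoint, levels = config$timepoints)
  colonies <- if (config$n_colonies >= 1) {
    purrr::map_dfr(config$timepoints, function(tp) simulate_colonies(config, tp, seed = seed))
  } else NULL
  structure(list(
    truth = truth,
    truth_matrix = genotype_matrix(purrr::map_dfr(per_tp, "tm"),
                                   timepoint_order = config$timepoints),
    observed = genotype_matrix(purrr::map_dfr(per_tp, "om"),
                               timepoint_order = config$timepoints),
    colonies = colonies,
    config = config
  ), class = "sim_dataset")
}

#' Simulate colony outgrowth genotypes
#'
#' Colonies are single-cell-derived and genotyped without whole-genome
#' amplification, so a colony's genotype is its founding clone's true
#' signature (no ADO, no miscalls). Semisolid culture can favor some clones:
#' founders are drawn with probability proportional to prevalence times the
#' clone's `fitness` weight, so fitness differences bias the colony genotype
#' distribution away from the cell-level truth.
#'
#' @inheritParams simulate_cells
#' @param timepoint Timepoint label to draw colonies for.
#' @param n Number of colonies (default `config$n_colonies`).
#' @return Tibble `colony`, `timepoint`, `clone`, plus one column per mutation.
#'   Project to the single-mutation file form with [colony_table()].
#' @export
simulate_colonies <- function(config, timepoint, n = config$n_colonies, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"), n >= 1)
  prev <- config$prevalence[config$prevalence$timepoint == timepoint, ]
  prev <- prev[match(config$clones$clone, prev$clone), ]
  w <- prev$prevalence * config$clones$fitness
  if (all(w == 0)) rlang::abort("all colony sampling weights are zero")
  set.seed(stream_seed(seed, paste0("colonies:", timepoint)))
  cl <- sample(config$clones$clone, n, replace = TRUE, prob = w)
  sig <- config$clones[match(cl, config$clones$clone), config$mutations]
  dplyr::bind_cols(
    tibble::tibble(colony = sprintf("%s_col%03d", timepoint, seq_len(n)),
                   timepoint = timepoint, clone = cl),
    sig
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", nrow(x$clones), " clones, ", length(x$mutations), " mutations, ",
      length(x$timepoints), " timepoints (", paste(x$n_cells, collapse = "/"), " cells)\n",
      "  ado_rate=", x$ado_rate, " miscall_rate=", x$miscall_rate,
      " missing_rate=", x$missing_rate, " n_colonies=", x$n_colonies,
      " seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset> ", nrow(x$truth), " cells (",
      paste(levels(x$truth$timepoint), collapse = "/"), "), ",
      length(unique(x$truth$clone)), " clones drawn",
      if (!is.null(x$colonies)) paste0(", ", nrow(x$colonies), " colonies"), "\n", sep = "")
  invisible(x)
}

# Config file round-trip (YAML), mirroring sim_config field-for-field.
#' @rdname sim_config
#' @param path File path for the YAML serialization.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(list(
    clones = lapply(seq_len(nrow(config$clones)), function(i) as.list(config$clones[i, ])),
    prevalence = lapply(seq_len(nrow(config$prevalence)), function(i) as.list(config$prevalence[i, ])),
    n_cells = as.list(config$n_cells),
    ado_rate = config$ado_rate, miscall_rate = config$miscall_rate,
    missing_rate = config$missing_rate, n_colonies = config$n_colonies,
    seed = config$seed
  ), path)
  invisible(path)
}

#' @rdname sim_config
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_config(
    clones = dplyr::bind_rows(lapply(y$clones, function(r) {
      r$parent <- r$parent %||% NA_character_
      tibble::as_tibble(r)
    })),
    prevalence = dplyr::bind_rows(lapply(y$prevalence, tibble::as_tibble)),
    n_cells = unlist(y$n_cells),
    ado_rate = y$ado_rate %||% 0, miscall_rate = y$miscall_rate %||% 0,
    missing_rate = y$missing_rate %||% 0, n_colonies = y$n_colonies %||% 0,
    seed = y$seed %||% 1L
  )
}
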