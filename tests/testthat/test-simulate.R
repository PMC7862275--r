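# The synthetic-data generator: config validation, determinism, sampling
# distributions, the ADO observation model, and colony fitness bias.

two_clone_config <- function(n = 10000L, prev = c(0.5, 0.5), fitness = c(1, 1),
                             n_colonies = 0L) {
  sim_config(
    clones = tibble::tibble(clone = c("anc", "der"), parent = c(NA, "anc"),
                            fitness = fitness, M1 = c("WT", "HET")),
    prevalence = tibble::tibble(clone = c("anc", "der"), timepoint = "T1",
                                prevalence = prev),
    n_cells = c(T1 = n), n_colonies = n_colonies
  )
}

test_that("config validation enforces tree shape, prevalence sums and rate ranges", {
  ok <- two_clone_config(10L)
  expect_s3_class(ok, "sim_config")
  # two roots
  expect_error(sim_config(
    clones = tibble::tibble(clone = c("a", "b"), parent = c(NA, NA), M1 = c("WT", "HET")),
    prevalence = tibble::tibble(clone = c("a", "b"), timepoint = "T1", prevalence = c(.5, .5)),
    n_cells = c(T1 = 5L)), "exactly one root")
  # multi-event edge
  expect_error(sim_config(
    clones = tibble::tibble(clone = c("a", "b"), parent = c(NA, "a"),
                            M1 = c("WT", "HET"), M2 = c("WT", "HET")),
    prevalence = tibble::tibble(clone = c("a", "b"), timepoint = "T1", prevalence = c(.5, .5)),
    n_cells = c(T1 = 5L)), "exactly one gain")
  # back-event edge (HOM parent, HET child)
  expect_error(sim_config(
    clones = tibble::tibble(clone = c("a", "b"), parent = c(NA, "a"), M1 = c("HOM", "HET")),
    prevalence = tibble::tibble(clone = c("a", "b"), timepoint = "T1", prevalence = c(.5, .5)),
    n_cells = c(T1 = 5L)), "exactly one gain")
  # prevalences must sum to one
  expect_error(sim_config(
    clones = tibble::tibble(clone = c("a", "b"), parent = c(NA, "a"), M1 = c("WT", "HET")),
    prevalence = tibble::tibble(clone = c("a", "b"), timepoint = "T1", prevalence = c(.5, .4)),
    n_cells = c(T1 = 5L)), "sum to 1")
  expect_error(two_clone_config(10L) |> (\(cfg) sim_config(cfg$clones, cfg$prevalence,
                                                           cfg$n_cells, ado_rate = 0.7))(),
               "ado_rate")
  expect_error(two_clone_config(10L) |> (\(cfg) sim_config(cfg$clones, cfg$prevalence,
                                                           cfg$n_cells, miscall_rate = 0.5))(),
               "miscall_rate")
})

test_that("the default config reproduces the reported clonal statistics in expectation", {
  cfg <- default_sim_config()
  expect_equal(nrow(cfg$clones), 9L)
  expect_equal(length(cfg$mutations), 7L)
  expect_equal(unname(cfg$n_cells), rep(300L, 3))
  ef <- expected_mutated_fractions(cfg)
  get <- function(m, tp) ef$mutated_fraction[ef$mutation == m & ef$timepoint == tp]
  expect_equal(get("TP53", "T1"), 0.208, tolerance = 1e-12)
  expect_equal(get("TP53", "T2"), 0.630, tolerance = 1e-12)
  expect_equal(get("FLT3", "T1"), 0.166, tolerance = 1e-12)
  expect_equal(get("FLT3", "T2"), 0.250, tolerance = 1e-12)
  expect_equal(get("FLT3", "T3"), 0.356, tolerance = 1e-12)
  prev_I <- cfg$prevalence$prevalence[cfg$prevalence$clone == "I"]
  expect_equal(prev_I, c(0.09, 0.15, 0.23))
  # prevalences sum to one at every timepoint
  sums <- tapply(cfg$prevalence$prevalence, cfg$prevalence$timepoint, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # FLT3 homozygosity is confined to the last timepoint
  h <- cfg$prevalence[cfg$prevalence$clone == "H", ]
  expect_equal(h$prevalence[h$timepoint != "T3"], c(0, 0))
  expect_gt(h$prevalence[h$timepoint == "T3"], 0)
  # mutated fractions follow the acquisition order at every timepoint
  ord <- c("TET2a", "JAK2", "TET2b", "ASXL1", "SRSF2", "TP53", "FLT3")
  for (tp in c("T1", "T2", "T3")) {
    fr <- vapply(ord, get, numeric(1), tp = tp)
    expect_true(all(diff(fr) < 0))
  }
})

test_that("simulation is deterministic under a seed and noiseless observation equals truth", {
  cfg <- default_sim_config(ado_rate = 0, miscall_rate = 0, missing_rate = 0)
  d1 <- simulate_cells(cfg, seed = 11)
  d2 <- simulate_cells(cfg, seed = 11)
  expect_identical(d1$observed, d2$observed)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$colonies, d2$colonies)
  expect_identical(d1$observed, d1$truth_matrix)
  d3 <- simulate_cells(cfg, seed = 12)
  expect_false(identical(d1$observed, d3$observed))
})

test_that("clone draws are multinomial: equal two-clone mix lands near half", {
  ds <- simulate_cells(two_clone_config(10000L), seed = 3)
  n_der <- sum(ds$truth$clone == "der")
  expect_lt(abs(n_der - 5000), 3 * sqrt(10000 * 0.25))
})

test_that("observed genotypes of truly heterozygous cells follow the ADO forward model", {
  cfg <- sim_config(
    clones = tibble::tibble(clone = c("anc", "het"), parent = c(NA, "anc"),
                            M1 = c("WT", "HET")),
    prevalence = tibble::tibble(clone = c("anc", "het"), timepoint = "T1",
                                prevalence = c(0, 1)),
    n_cells = c(T1 = 20000L), ado_rate = 0.1
  )
  ds <- simulate_cells(cfg, seed = 9)
  obs <- ds$observed$M1
  n <- length(obs)  # cells with all calls missing are dropped on validation
  counts <- c(WT = sum(obs == "WT", na.rm = TRUE), HET = sum(obs == "HET", na.rm = TRUE),
              HOM = sum(obs == "HOM", na.rm = TRUE), MISSING = 20000L - sum(!is.na(obs)))
  probs <- ado_genotype_probs("HET", 0.1)
  for (st in names(counts)) {
    p <- probs$prob[probs$observed == st]
    expect_lt(abs(counts[[st]] / 20000 - p), 3 * sqrt(p * (1 - p) / 20000))
  }
})

test_that("colony sampling honours prevalence and fitness weights", {
  # unbiased: equal fitness converges to the cell-level truth distribution
  cfg <- two_clone_config(10L, prev = c(0.3, 0.7), n_colonies = 10000L)
  col <- simulate_colonies(cfg, "T1", seed = 2)
  expect_lt(abs(mean(col$clone == "der") - 0.7), 3 * sqrt(0.7 * 0.3 / 10000))
  # a zero-fitness wild-type clone never grows out
  cfg0 <- two_clone_config(10L, fitness = c(0, 1), n_colonies = 500L)
  col0 <- simulate_colonies(cfg0, "T1", seed = 2)
  expect_true(all(col0$clone == "der"))
  expect_true(all(col0$M1 == "HET"))
  # fitness (2, 1) at prevalence (.5, .5) gives 2/3 of colonies from clone 1
  cfg2 <- two_clone_config(10L, fitness = c(2, 1), n_colonies = 10000L)
  col2 <- simulate_colonies(cfg2, "T1", seed = 4)
  p <- 2 / 3
  expect_lt(abs(mean(col2$clone == "anc") - p), 3 * sqrt(p * (1 - p) / 10000))
  # all-zero weights error
  expect_error(simulate_colonies(two_clone_config(10L, fitness = c(0, 0), n_colonies = 5L), "T1"),
               "zero")
})

test_that("sim config YAML round-trips field-for-field", {
  cfg <- default_sim_config(seed = 99)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  cfg2 <- read_sim_config(f)
  expect_equal(cfg2$clones, cfg$clones)
  expect_equal(cfg2$prevalence, cfg$prevalence)
  expect_equal(cfg2$n_cells, cfg$n_cells)
  expect_equal(cfg2$ado_rate, cfg$ado_rate)
  expect_equal(cfg2$seed, cfg$seed)
})
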