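#' Forward model of per-allele allele dropout
#'
#' Whole-genome amplification of a single cell can fail to amplify either
#' allele independently with probability `d` (the ADO rate). A heterozygous
#' locus then reads as homozygous mutant (wild-type allele dropped), wild-type
#' (mutant allele dropped), or missing (both dropped); homozygous and
#' wild-type loci can only stay themselves or go missing:
#'
#' * `HET` -> `WT` with `d(1-d)`, `HET` with `(1-d)^2`, `HOM` with `d(1-d)`,
#'   `MISSING` with `d^2`
#' * `HOM` -> `HOM` with `1-d^2`, `MISSING` with `d^2`
#' * `WT` -> `WT` with `1-d^2`, `MISSING` with `d^2`
#'
#' Each row of the returned table sums to one.
#'
#' @param true_state One or more of `"WT"`, `"HET"`, `"HOM"`.
#' @param d Per-allele dropout probability in `[0, 0.5]`.
#' @return Tibble `true_state`, `observed`, `prob`.
#' @examples
#' ado_genotype_probs("HET", 0.1)  # WT .09, HET .81, HOM .09, MISSING .01
#' @export
ado_genotype_probs <- function(true_state = c("WT", "HET", "HOM"), d) {
  true_state <- match.arg(true_state, several.ok = TRUE)
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d < 0 || d > 0.5) {
    rlang::abort("`d` must be a single value in [0, 0.5]")
  }
  purrr::map_dfr(true_state, function(s) {
    prob <- switch(s,
      WT  = c(WT = 1 - d^2, HET = 0, HOM = 0, MISSING = d^2),
      HET = c(WT = d * (1 - d), HET = (1 - d)^2, HOM = d * (1 - d), MISSING = d^2),
      HOM = c(WT = 0, HET = 0, HOM = 1 - d^2, MISSING = d^2)
    )
    tibble::tibble(true_state = s, observed = names(prob), prob = unname(prob))
  })
}

# Expected observed distribution over {WT, HET, HOM} (conditioned on a defined
# call) when a true genotype mix q = (WT, HET, HOM) is pushed through ADO.
ado_push_forward <- function(q, d) {
  q <- q / sum(q)
  p <- c(WT  = q[[1]] * (1 - d^2) + q[[2]] * d * (1 - d),
         HET = q[[2]] * (1 - d)^2,
         HOM = q[[3]] * (1 - d^2) + q[[2]] * d * (1 - d))
  p / sum(p)
}

#' Estimate the allele-dropout rate from cells versus colonies
#'
#' Single-cell-derived colonies are genotyped without whole-genome
#' amplification, so their genotype distribution is treated as the true one
#' (the estimator documents — and the simulator can probe — the caveat that
#' colony outgrowth may itself be fitness-biased). The colony distribution is
#' pushed through the ADO forward model [ado_genotype_probs()] and the
#' per-allele rate `d` is the minimizer of the multinomial negative
#' log-likelihood of the observed single-cell counts over `[0, 0.5]`
#' (golden-section search, tolerance 1e-6), conditioned on defined calls.
#' If the number of cells with missing calls is supplied via `n_missing`, the
#' likelihood additionally uses the ADO missing class (probability `d^2` per
#' cell), which sharpens the estimate when missingness is dropout-driven.
#'
#' `d` is unidentifiable when the colonies contain no heterozygotes (dropout
#' then leaves the defined-call distribution untouched); this is reported with
#' a warning and an `NA` estimate.
#'
#' A percentile bootstrap (default 1000 resamples of both count vectors,
#' seeded) gives the confidence interval.
#'
#' @param cell_counts Named counts over `WT`, `HET`, `HOM` from single cells.
#' @param colony_counts Named counts over `WT`, `HET`, `HOM` from colonies.
#' @param n_missing Optional count of single cells with a missing call at the
#'   locus, attributed to double dropout.
#' @param n_boot Bootstrap resamples (0 skips the interval).
#' @param conf Confidence level.
#' @param seed Integer seed for the bootstrap.
#' @return An `ado_estimate`: list with `d_hat`, `ci`, `nll`, `identifiable`,
#'   the inputs, and the bootstrap draws. Use [generics::tidy()] /
#'   [generics::glance()] for tabular views.
#' @export
estimate_ado_rate <- function(cell_counts, colony_counts, n_missing = NULL,
                              n_boot = 1000, conf = 0.95, seed = 1L) {
  cell_counts <- counts3(cell_counts, "cell_counts")
  colony_counts <- counts3(colony_counts, "colony_counts")
  if (sum(cell_counts) == 0 || sum(colony_counts) == 0) {
    rlang::abort("both count vectors need a positive total")
  }
  new_est <- function(d_hat, nll, identifiable, ci = c(NA_real_, NA_real_), boot = numeric()) {
    structure(list(d_hat = d_hat, ci = ci, nll = nll, identifiable = identifiable,
                   cell_counts = cell_counts, colony_counts = colony_counts,
                   n_missing = n_missing, n_boot = n_boot, conf = conf, boot = boot),
              class = "ado_estimate")
  }
  fit_one <- function(cells, colonies, miss) {
    if (colonies[["HET"]] == 0) return(NA_real_)
    q <- colonies / sum(colonies)
    nll <- function(d) {
      p <- ado_push_forward(q, d)
      ll <- sum(cells * log(pmax(p, 1e-300)))
      if (!is.null(miss)) {
        n_def <- sum(cells)
        ll <- ll + miss * log(max(d^2, 1e-300)) + n_def * log(1 - d^2)
      }
      -ll
    }
    d_opt <- stats::optimize(nll, c(0, 0.5), tol = 1e-6)$minimum
    if (nll(0) <= nll(d_opt)) 0 else d_opt  # golden section cannot land on the boundary
  }
  if (colony_counts[["HET"]] == 0) {
    rlang::warn("ADO rate is unidentifiable: no heterozygous colonies")
    return(new_est(NA_real_, NA_real_, FALSE))
  }
  d_hat <- fit_one(cell_counts, colony_counts, n_missing)
  q <- colony_counts / sum(colony_counts)
  nll_val <- -sum(cell_counts * log(pmax(ado_push_forward(q, d_hat), 1e-300)))
  est <- new_est(d_hat, nll_val, TRUE)
  if (n_boot > 0) {
    set.seed(stream_seed(seed, "ado-bootstrap"))
    boot <- vapply(seq_len(n_boot), function(b) {
      if (is.null(n_missing)) {
        bc <- stats::setNames(as.numeric(stats::rmultinom(1, sum(cell_counts),
                                                          cell_counts / sum(cell_counts))), GT_STATES)
        bm <- NULL
      } else {
        p4 <- c(cell_counts, n_missing) / (sum(cell_counts) + n_missing)
        draw <- as.numeric(stats::rmultinom(1, sum(cell_counts) + n_missing, p4))
        bc <- stats::setNames(draw[1:3], GT_STATES)
        bm <- draw[4]
      }
      bk <- stats::setNames(as.numeric(stats::rmultinom(1, sum(colony_counts), q)), GT_STATES)
      fit_one(bc, bk, bm)
    }, numeric(1))
    boot <- boot[!is.na(boot)]
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), type = 7))
    ci[1] <- min(ci[1], est$d_hat); ci[2] <- max(ci[2], est$d_hat)
    est$ci <- ci
    est$boot <- boot
  }
  est
}

counts3 <- function(x, what) {
  if (is.null(names(x))) {
    if (length(x) != 3L) rlang::abort(paste0("`", what, "` must have entries WT, HET, HOM"))
    names(x) <- GT_STATES
  }
  if (!all(GT_STATES %in% names(x))) {
    rlang::abort(paste0("`", what, "` must have entries WT, HET, HOM"))
  }
  x <- x[GT_STATES]
  if (any(x < 0) || any(is.na(x))) rlang::abort(paste0("`", what, "` must be non-negative counts"))
  x
}

# Tabulate the calls of one mutation at one timepoint into WT/HET/HOM counts
# (+ missing), ready for estimate_ado_rate().
#' @rdname estimate_ado_rate
#' @param gm A [genotype_matrix()].
#' @param mutation Mutation id.
#' @param timepoint Timepoint label; `NULL` pools all.
#' @export
genotype_counts <- function(gm, mutation, timepoint = NULL) {
  v <- gm[[mutation]]
  if (!is.null(timepoint)) v <- v[gm$timepoint == timepoint]
  c(WT = sum(v == "WT", na.rm = TRUE), HET = sum(v == "HET", na.rm = TRUE),
    HOM = sum(v == "HOM", na.rm = TRUE), MISSING = sum(is.na(v)))
}

#' @export
print.ado_estimate <- function(x, ...) {
  cat("<ado_estimate>\n")
  if (!x$identifiable) {
    cat("  unidentifiable (no heterozygous colonies); d_hat = NA\n")
  } else {
    cat(sprintf("  d_hat = %.4f", x$d_hat))
    if (!any(is.na(x$ci))) cat(sprintf("  [%.1f%% CI %.4f, %.4f]", 100 * x$conf, x$ci[1], x$ci[2]))
    cat(sprintf("\n  nll = %.3f; cells n = %d, colonies n = %d\n",
                x$nll, sum(x$cell_counts), sum(x$colony_counts)))
  }
  invisible(x)
}
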