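#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact conditional test with both margins fixed. The two-sided p-value uses
#' the point-probability rule: it is the sum of hypergeometric probabilities of
#' all tables (with the observed margins) whose probability does not exceed
#' that of the observed table — the convention of most exact-test software,
#' stated here so results are bit-reproducible. The reported statistic is the
#' sample odds ratio.
#'
#' @param table A 2x2 matrix of non-negative integer counts.
#' @return Tibble `method`, `statistic` (odds ratio), `p_value`, `n`.
#' @examples
#' fisher_exact_2x2(matrix(c(10, 0, 0, 10), 2))
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)) || any(table < 0) || any(table != round(table))) {
    rlang::abort("`table` must be a 2x2 matrix of non-negative integer counts")
  }
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  or <- (a * d) / (b * c_)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    rlang::warn("a margin of the table is zero; p = 1")
    p <- 1
  } else {
    m <- a + c_; n <- b + d; k <- a + b
    support <- max(0L, k - n):min(k, m)
    probs <- stats::dhyper(support, m, n, k)
    p_obs <- stats::dhyper(a, m, n, k)
    p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }
  tibble::tibble(method = "fisher_exact_2x2", statistic = or, p_value = p,
                 n = as.integer(sum(table)))
}

#' Exact test for a 2x3 genotype distribution difference
#'
#' Compares the `WT`/`HET`/`HOM` distribution of single cells against that of
#' colonies with an exact conditional test on the 2x3 contingency table
#' (Freeman-Halton extension of Fisher's test, point-probability rule). Tables
#' with total count up to `max_enumeration_total` are fully enumerated; larger
#' tables use a seeded Monte-Carlo null of `n_perm` fixed-margin tables
#' (Patefield sampling), with the add-one estimator. The method label records
#' which route was taken.
#'
#' @param cell_counts Named counts over `WT`, `HET`, `HOM` from single cells.
#' @param colony_counts Named counts over `WT`, `HET`, `HOM` from colonies.
#' @param max_enumeration_total Largest table total for full enumeration.
#' @param n_perm Monte-Carlo tables when enumeration is skipped.
#' @param seed Seed for the Monte-Carlo route.
#' @return Tibble `method`, `statistic` (probability of the observed table
#'   under the null), `p_value`, `n_cells`, `n_colonies`.
#' @export
genotype_distribution_test <- function(cell_counts, colony_counts,
                                       max_enumeration_total = 200L,
                                       n_perm = 1e5, seed = 1L) {
  cell_counts <- counts3(cell_counts, "cell_counts")
  colony_counts <- counts3(colony_counts, "colony_counts")
  if (sum(cell_counts) == 0 || sum(colony_counts) == 0) {
    rlang::abort("both count vectors need a positive total")
  }
  tab <- rbind(cells = cell_counts, colonies = colony_counts)
  r1 <- sum(tab[1, ]); N <- sum(tab)
  cols <- colSums(tab)
  log_p_table <- function(x1) {  # x1 = row-1 counts; margins fixed
    sum(lchoose(cols, x1)) - lchoose(N, r1)
  }
  lp_obs <- log_p_table(tab[1, ])
  if (N <= max_enumeration_total) {
    p <- 0
    for (x in 0:min(r1, cols[1])) for (y in 0:min(r1 - x, cols[2])) {
      z <- r1 - x - y
      if (z > cols[3]) next
      lp <- log_p_table(c(x, y, z))
      if (lp <= lp_obs + 1e-7) p <- p + exp(lp)
    }
    method <- "freeman_halton_exact"
    p <- min(1, p)
  } else {
    set.seed(stream_seed(seed, "freeman-halton-mc"))
    sims <- stats::r2dtable(n_perm, r = rowSums(tab), c = cols)
    lps <- vapply(sims, function(s) log_p_table(s[1, ]), numeric(1))
    p <- (1 + sum(lps <= lp_obs + 1e-7)) / (n_perm + 1)
    method <- "freeman_halton_mc"
  }
  tibble::tibble(method = method, statistic = exp(lp_obs), p_value = p,
                 n_cells = as.integer(sum(cell_counts)),
                 n_colonies = as.integer(sum(colony_counts)))
}
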