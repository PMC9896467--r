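# Tie-corrected Friedman rank test over a methods x datasets score table,
# the statistic used to compare prediction methods across the benchmark
# networks.

friedman_check <- function(score_table) {
  score_table <- as.matrix(score_table)
  if (!is.numeric(score_table) || anyNA(score_table)) {
    stopf("score table must be fully numeric with no missing cells")
  }
  score_table
}

#' Per-method average ranks across datasets
#'
#' Within each dataset column the k methods are ranked ascending by score
#' (the best method gets rank k); ties receive the average of their rank
#' positions. Ranks are then averaged across datasets per method.
#'
#' @param score_table numeric matrix, k methods in rows, n datasets in
#'   columns.
#' @return named numeric vector of average ranks.
#' @export
friedman_ranks <- function(score_table) {
  score_table <- friedman_check(score_table)
  rowMeans(apply(score_table, 2L, rank))
}

#' Tie-corrected Friedman test
#'
#' Computes the Friedman statistic over rank sums R_j,
#' \deqn{\chi^2_{raw} = \frac{12}{n k (k+1)} \sum_j R_j^2 - 3 n (k+1),}
#' divided by the tie-correction factor
#' \deqn{C = 1 - \frac{\sum (t^3 - t)}{n (k^3 - k)}}
#' over all tie groups of size t, with a p-value from the chi-square
#' distribution on k - 1 degrees of freedom.
#'
#' @param score_table numeric matrix, k >= 3 methods in rows, n >= 2
#'   datasets in columns.
#' @return object of class `friedman_result`: `average_ranks`,
#'   `rank_sums`, `chi_square` (tie-corrected), `chi_square_raw`,
#'   `correction`, `df`, `p_value`, `tie_groups` (per-column list of tied
#'   score values and group sizes).
#' @examples
#' tbl <- read_score_table(system.file("extdata", "benchmark_auc.tsv",
#'                                     package = "spherelm"))
#' friedman_test(tbl)
#' @export
friedman_test <- function(score_table) {
  score_table <- friedman_check(score_table)
  k <- nrow(score_table)
  n <- ncol(score_table)
  if (k < 3 || n < 2) stopf("need at least 3 methods and 2 datasets")
  ranks <- apply(score_table, 2L, rank)
  rank_sums <- rowSums(ranks)
  chi_raw <- 12 / (n * k * (k + 1)) * sum(rank_sums^2) - 3 * n * (k + 1)

  tie_sum <- 0
  tie_groups <- vector("list", n)
  for (j in seq_len(n)) {
    tab <- table(score_table[, j])
    tied <- tab[tab > 1]
    tie_groups[[j]] <- data.frame(value = as.numeric(names(tied)),
                                  size = as.integer(tied))
    tie_sum <- tie_sum + sum(tab^3 - tab)
  }
  correction <- 1 - tie_sum / (n * (k^3 - k))
  if (correction <= 0) {
    stopf("statistic undefined under complete ties")
  }
  chi <- chi_raw / correction
  names(tie_groups) <- colnames(score_table)

  structure(
    list(average_ranks = rank_sums / n, rank_sums = rank_sums,
         chi_square = chi, chi_square_raw = chi_raw,
         correction = correction, df = k - 1,
         p_value = stats::pchisq(chi, k - 1, lower.tail = FALSE),
         tie_groups = tie_groups),
    class = "friedman_result"
  )
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman test: chi-square = %.3f (df = %d), p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  cat("average ranks (higher = better score):\n")
  print(round(sort(x$average_ranks, decreasing = TRUE), 2))
  invisible(x)
}
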