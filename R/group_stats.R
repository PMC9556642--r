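#' Friedman test for replicated blocks
#'
#' Rank-based comparison of k conditions over n blocks with m replicated
#' measures per cell. Within each block all `m * k` values are jointly
#' ranked (mid-ranks for ties); the condition rank sums across blocks form
#' a chi-square statistic with `k - 1` degrees of freedom
#' (Benard-van Elteren form with equal cell counts):
#' `chi2 = (k - 1) / k * sum_j (S_j - E)^2 / V`, where `S_j` is the rank sum
#' of condition j, `E = n * m * (N + 1) / 2` its null expectation
#' (`N = m * k`), and `V = sum_i m * (N - m) / (N - 1) * sigma2_i` with
#' `sigma2_i` the population variance of the (mid-)ranks of block i — which
#' is how ties are corrected. For `m = 1` this reduces exactly to the
#' classical Friedman statistic.
#'
#' @details
#' For replicated designs (`m > 1`) the chi-square reference distribution
#' is not accurate at the small block counts typical here, so the default
#' p-value is computed from the within-block label-permutation null of the
#' same statistic (`n_perm` draws, deterministic internal random stream).
#' With `m = 1` (or `p_method = "chisq"`) the upper-tail chi-square
#' probability is reported, matching the classical test exactly.
#'
#' @param x either a 3-d array `(blocks, replicates, conditions)` or a
#'   data.frame with columns `block`, `replicate`, `condition`, `value`
#'   forming a complete design.
#' @param p_method `"auto"` (permutation when replicated, chi-square when
#'   `m = 1`), `"permutation"` or `"chisq"`.
#' @param n_perm permutation draws for the Monte Carlo p-value.
#' @return object of class `friedman_replicated`: list with `chi2`, `df`,
#'   `p`, `p_chisq`, `p_method`, `rank_sums`, `n_blocks`, `n_reps`, `k`,
#'   `tie_corrected` (TRUE if any ties were mid-ranked).
#' @export
friedman_replicated <- function(x, p_method = c("auto", "permutation", "chisq"),
                                n_perm = 10000) {
  p_method <- match.arg(p_method)
  if (is.data.frame(x)) x <- measure_df_to_array(x)
  stopifnot(is.array(x), length(dim(x)) == 3)
  if (anyNA(x)) stop("design is incomplete (missing values)", call. = FALSE)
  nb <- dim(x)[1]; m <- dim(x)[2]; k <- dim(x)[3]
  stopifnot(k >= 2, nb >= 1, m >= 1)
  N <- m * k
  S <- numeric(k)
  V <- 0
  ties <- FALSE
  rank_mat <- matrix(0, nb, N)
  for (i in seq_len(nb)) {
    vals <- as.vector(x[i, , ])
    r <- rank(vals)                       # mid-ranks
    ties <- ties || anyDuplicated(vals) > 0
    rank_mat[i, ] <- r
    S <- S + colSums(matrix(r, nrow = m, ncol = k))
    sigma2 <- mean((r - (N + 1) / 2)^2)   # tie-corrected rank variance
    V <- V + m * (N - m) / (N - 1) * sigma2
  }
  E <- nb * m * (N + 1) / 2
  chi2 <- if (V <= 0) 0 else (k - 1) / k * sum((S - E)^2) / V
  p_chisq <- pchisq(chi2, k - 1, lower.tail = FALSE)
  use_perm <- p_method == "permutation" || (p_method == "auto" && m > 1)
  p <- if (V <= 0) 1 else if (use_perm)
    .perm_friedman_cpp(rank_mat, m, k, V, chi2, as.integer(n_perm),
                       config_seed_stream(rank_mat)) else p_chisq
  structure(list(chi2 = chi2, df = k - 1, p = p, p_chisq = p_chisq,
                 p_method = if (use_perm) "permutation" else "chisq",
                 rank_sums = S, n_blocks = nb, n_reps = m, k = k,
                 tie_corrected = ties),
            class = "friedman_replicated")
}

# deterministic seed for the permutation stream, derived from the data so
# repeated calls on the same input give identical p-values
config_seed_stream <- function(rank_mat) {
  sum(rank_mat * seq_along(rank_mat)) %% 2147483647
}

#' @export
print.friedman_replicated <- function(x, ...) {
  cat(sprintf(paste0("Replicated-block Friedman: chi2(%d) = %.3f, p = %.4g ",
                     "(%d blocks x %d replicates x %d conditions%s)\n"),
              x$df, x$chi2, x$p, x$n_blocks, x$n_reps, x$k,
              if (x$tie_corrected) ", ties mid-ranked" else ""))
  invisible(x)
}

# long data.frame (block, replicate, condition, value) -> 3-d array;
# errors on duplicated or missing cells
measure_df_to_array <- function(df) {
  stopifnot(all(c("block", "replicate", "condition", "value") %in% names(df)))
  b <- sort(unique(df$block)); r <- sort(unique(df$replicate))
  k <- sort(unique(df$condition))
  if (nrow(df) != length(b) * length(r) * length(k) ||
      anyDuplicated(df[, c("block", "replicate", "condition")]))
    stop("design must have exactly one value per block x replicate x condition",
         call. = FALSE)
  a <- array(NA_real_, c(length(b), length(r), length(k)),
             dimnames = list(b, r, k))
  a[cbind(match(df$block, b), match(df$replicate, r),
          match(df$condition, k))] <- df$value
  a
}

#' Compare conditions for every measure of a study
#'
#' Per-measure descriptive statistics (mean and sd per condition across all
#' violinists and takes) and the replicated-block Friedman test with
#' violinists as blocks and takes as replicates. An optional grouping
#' column (e.g. conductor) re-runs the comparison within each stratum.
#'
#' @param table data.frame with columns `violinist`, `take`, `condition`,
#'   `measure`, `value` (one row per cell per measure; complete design
#'   required per measure).
#' @param group optional name of a stratification column in `table`.
#' @return data.frame with one row per measure (and stratum): condition
#'   means and sds, `chi2`, `df`, `p`. Measures with any missing value are
#'   skipped with a warning.
#' @export
compare_conditions <- function(table, group = NULL) {
  need <- c("violinist", "take", "condition", "measure", "value")
  stopifnot(all(need %in% names(table)))
  strata <- if (is.null(group)) list(all = table) else
    split(table, table[[group]])
  conds <- unique(table$condition)
  out <- list()
  for (gname in names(strata)) {
    tb <- strata[[gname]]
    for (ms in unique(tb$measure)) {
      d <- tb[tb$measure == ms, ]
      if (anyNA(d$value)) {
        warning("measure '", ms, "' has missing values; skipped",
                call. = FALSE)
        next
      }
      ft <- friedman_replicated(data.frame(block = d$violinist,
                                           replicate = d$take,
                                           condition = d$condition,
                                           value = d$value))
      row <- data.frame(measure = ms, chi2 = ft$chi2, df = ft$df, p = ft$p)
      for (cn in conds) {
        row[[paste0("mean_", cn)]] <- mean(d$value[d$condition == cn])
        row[[paste0("sd_", cn)]] <- sd(d$value[d$condition == cn])
      }
      if (!is.null(group)) row[[group]] <- gname
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
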