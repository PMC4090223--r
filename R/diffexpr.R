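#' Normalized expression
#'
#' NE = actual count / total count of clean reads in the same library, the
#' per-library normalization used for all fold-change work.
#'
#' @param count non-negative read count(s).
#' @param n total clean reads of the library (must be > 0).
#' @return numeric vector of normalized expression values.
#' @export
#' @examples
#' normalize_expression(260952, 14244946)
normalize_expression <- function(count, n) {
  if (any(n <= 0)) abort("total clean reads `n` must be > 0")
  if (any(count < 0)) abort("`count` must be non-negative")
  count / n
}

#' Log2 fold change between two libraries
#'
#' `log2(NE_1 / NE_2)` with `NE = count / total clean reads`. Returns `Inf`
#' or `-Inf` when exactly one count is zero and `NA` when both are (the fold
#' change is undefined there).
#'
#' @param x,y counts in library 1 and library 2.
#' @param n1,n2 total clean reads in library 1 and library 2.
#' @return numeric vector of log2 fold changes.
#' @export
#' @examples
#' # reference worked example: prints 5.12 at two decimals
#' round(log2_fold_change(260952, 14244946, 7158, 13558164), 2)
log2_fold_change <- function(x, n1, y, n2) {
  ne1 <- normalize_expression(x, n1)
  ne2 <- normalize_expression(y, n2)
  out <- suppressWarnings(log2(ne1 / ne2))
  out[x == 0 & y == 0] <- NA_real_
  out
}

# log pmf of the two-library exact model: probability of y in library 2
# given x in library 1, depths n1 and n2 (r = n2/n1):
#   p(y | x) = r^y * (x+y)! / (x! * y! * (1+r)^(x+y+1))
ac_log_prob <- function(y, x, n1, n2) {
  r <- n2 / n1
  y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(r)
}

#' Exact two-library count probability
#'
#' Probability of observing count `y` in the second library given count `x`
#' in the first, for libraries of `n1` and `n2` total clean reads, under the
#' classical exact model for comparing two sequencing libraries:
#' \deqn{p(y \mid x) = (N_2/N_1)^y \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}}}
#' evaluated in log space.
#'
#' @param y observed count in library 2 (vectorised).
#' @param x observed count in library 1.
#' @param n1,n2 total clean reads per library.
#' @return probabilities in \[0, 1\].
#' @export
#' @examples
#' ac_probability(0, x = 5, n1 = 1e4, n2 = 1e4)  # 1/2^6
ac_probability <- function(y, x, n1, n2) {
  if (any(x %% 1 != 0) || any(y %% 1 != 0)) abort("counts must be integers")
  if (any(x < 0) || any(y < 0)) abort("counts must be non-negative")
  if (any(c(n1, n2) <= 0)) abort("library totals must be > 0")
  exp(ac_log_prob(y, x, n1, n2))
}

# log-sum-exp
lse <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

# lower tail P(Y <= y | x), exact summation in log space
ac_lower_tail <- function(x, y, n1, n2) {
  min(1, exp(lse(ac_log_prob(0:y, x, n1, n2))))
}

# upper tail P(Y >= y | x): direct summation upward until terms vanish
ac_upper_tail <- function(x, y, n1, n2) {
  acc <- -Inf
  t0 <- y
  repeat {
    ts <- t0:(t0 + 2047)
    acc <- lse(c(acc, ac_log_prob(ts, x, n1, n2)))
    last <- ac_log_prob(t0 + 2047, x, n1, n2)
    if (last < acc - 45) break
    t0 <- t0 + 2048
  }
  min(1, exp(acc))
}

#' Exact two-sided p-value for a two-library count comparison
#'
#' Doubled smaller-tail conversion of the exact model in [ac_probability()]:
#' `p = min(1, 2 * min(P(Y <= y | x), P(Y >= y | x)))`, computed by stable
#' tail summation in log space. Swapping the libraries (and their totals)
#' changes the p-value by at most the observed point probabilities, since
#' the model conditions on the first library's count.
#'
#' @inheritParams ac_probability
#' @return p-values in (0, 1\].
#' @export
#' @examples
#' ac_pvalue(50, 0, n1 = 1e4, n2 = 1e4)
ac_pvalue <- function(x, y, n1, n2) {
  if (any(x %% 1 != 0) || any(y %% 1 != 0)) abort("counts must be integers")
  stopifnot(length(n1) == 1, length(n2) == 1)
  mapply(function(xi, yi) {
    lo <- ac_lower_tail(xi, yi, n1, n2)
    hi <- ac_upper_tail(xi, yi, n1, n2)
    min(1, 2 * min(lo, hi))
  }, x, y)
}

#' Expression category on the linear fold-change scale
#'
#' The three scatter-plot categories used for the two-library comparison:
#' `up` for a linear NE ratio > 2, `mid` for 1/2 < ratio <= 2 and `down`
#' for ratio <= 1/2. Ratios of `Inf`/0 (one library at zero) map to
#' `up`/`down`; undefined ratios (both zero) give `NA`.
#'
#' @param ratio linear ratio `NE_1 / NE_2`.
#' @return factor with levels `up`, `mid`, `down`.
#' @export
#' @examples
#' categorize_expression(c(34.7, 1, 0.5, 0.2))
categorize_expression <- function(ratio) {
  out <- dplyr::case_when(
    is.na(ratio) ~ NA_character_,
    ratio > 2 ~ "up",
    ratio > 0.5 ~ "mid",
    TRUE ~ "down"
  )
  factor(out, levels = c("up", "mid", "down"))
}

#' Differential expression table for two libraries
#'
#' One exact-test record per feature: normalized expression in each library,
#' log2 fold change, two-sided exact p-value, Benjamini-Hochberg adjusted
#' p-value, linear-ratio category and an expressed flag (raw count above
#' `min_reads` in at least one library by default, or in both with
#' `expressed_rule = "both"`). No multiple-testing filter is applied; the
#' adjusted column is provided for downstream use.
#'
#' @param counts a data frame with a feature id column and two count columns.
#' @param n1,n2 total clean reads of library 1 and 2 (denominators for NE).
#' @param id_col,count_cols names of the id column and the two count columns;
#'   by default the first column is the id and the next two are the counts
#'   (library 1 then library 2).
#' @param min_reads expressed-flag threshold: strictly more than `min_reads`
#'   raw reads.
#' @param expressed_rule `"either"` (default) or `"both"` libraries must
#'   exceed `min_reads`.
#' @return a tibble of class `mir_de` with columns `id`, `x`, `y`, `ne_x`,
#'   `ne_y`, `ratio`, `log2fc`, `p_value`, `q_value`, `category`,
#'   `expressed`; library totals kept as attributes `n1`, `n2`.
#' @seealso [tidy.mir_de()], [glance.mir_de()], [autoplot.mir_de()].
#' @export
de_table <- function(counts, n1, n2, id_col = NULL, count_cols = NULL,
                     min_reads = 10, expressed_rule = c("either", "both")) {
  expressed_rule <- match.arg(expressed_rule)
  counts <- as_tibble(counts)
  if (nrow(counts) == 0) {
    out <- tibble(id = character(), x = integer(), y = integer(),
                  ne_x = double(), ne_y = double(), ratio = double(),
                  log2fc = double(), p_value = double(), q_value = double(),
                  category = factor(levels = c("up", "mid", "down")),
                  expressed = logical())
    return(structure(out, class = c("mir_de", class(out)), n1 = n1, n2 = n2))
  }
  id_col <- id_col %||% names(counts)[1]
  count_cols <- count_cols %||% setdiff(names(counts), id_col)[1:2]
  x <- counts[[count_cols[1]]]
  y <- counts[[count_cols[2]]]
  ne_x <- normalize_expression(x, n1)
  ne_y <- normalize_expression(y, n2)
  ratio <- ifelse(x == 0 & y == 0, NA_real_,
                  suppressWarnings(ne_x / ne_y))
  p <- ac_pvalue(x, y, n1, n2)
  expressed <- if (expressed_rule == "either") x > min_reads | y > min_reads
               else x > min_reads & y > min_reads
  out <- tibble(
    id = counts[[id_col]], x = x, y = y, ne_x = ne_x, ne_y = ne_y,
    ratio = ratio,
    log2fc = log2_fold_change(x, n1, y, n2),
    p_value = p,
    q_value = p.adjust(p, method = "BH"),
    category = categorize_expression(ratio),
    expressed = expressed
  ) |> arrange(.data$id)
  structure(out, class = c("mir_de", class(out)), n1 = n1, n2 = n2)
}

#' @describeIn de_table return the record table as a plain tibble.
#' @param x a `mir_de` object.
#' @param ... unused.
#' @export
tidy.mir_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mir_de")
  attr(out, "n1") <- NULL; attr(out, "n2") <- NULL
  as_tibble(out)
}

#' @describeIn de_table one-row summary: feature counts and up/mid/down
#'   tallies among expressed features.
#' @export
glance.mir_de <- function(x, ...) {
  expressed <- dplyr::filter(tidy(x), .data$expressed)
  tibble(
    n_features = nrow(x),
    n_expressed = nrow(expressed),
    n_up = sum(expressed$category == "up", na.rm = TRUE),
    n_mid = sum(expressed$category == "mid", na.rm = TRUE),
    n_down = sum(expressed$category == "down", na.rm = TRUE),
    n1 = attr(x, "n1"), n2 = attr(x, "n2")
  )
}
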