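#' Duncan's multiple range test
#'
#' Stepwise multiple-range comparison of group means on a one-way ANOVA
#' error term.  Means are sorted descending; the least significant range
#' for a span of `p` consecutive ordered means is
#' `q_duncan(p, df, alpha) * sqrt(MSE / n_h)`, where `n_h` is the harmonic
#' mean group size and `q_duncan` the studentized-range quantile at the
#' protected level `(1 - alpha)^(p - 1)` (computed numerically via
#' `stats::qtukey`, no tabulated values).  Spans are tested widest first;
#' a span declared non-significant protects all its sub-spans.  The
#' resulting non-significant spans are maximal intervals of the ordered
#' means and yield the letter display: two groups share no letter exactly
#' when the procedure declares them different.
#'
#' @param values Either a named list of numeric vectors (one per group) or
#'   a numeric vector accompanied by `groups`.
#' @param groups Grouping vector when `values` is numeric.
#' @param alpha Significance level (default 0.05).
#' @return Object of class `duncan_grouping`: list with `groups`
#'   (data.frame `group`, `n`, `mean`, `letters`, sorted by descending
#'   mean), `alpha`, `df` (error df), `mse`, `n_harmonic`, `lsr` (least
#'   significant range per span width), and `nonsig` (logical span
#'   matrix in sorted order).
#' @export
duncan_mrt <- function(values, groups = NULL, alpha = 0.05) {
  if (!is.list(values)) {
    stopifnot(!is.null(groups), length(groups) == length(values))
    values <- split(as.numeric(values), groups)
  }
  g <- length(values)
  if (g < 2L) stop("need at least 2 groups", call. = FALSE)
  n_i <- lengths(values)
  if (any(n_i < 2L)) stop("every group needs n >= 2", call. = FALSE)
  N <- sum(n_i)
  df <- N - g
  if (df < 1L) stop("residual df < 1", call. = FALSE)
  means <- vapply(values, mean, 0)
  sse <- sum(vapply(values, function(v) sum((v - mean(v))^2), 0))
  mse <- sse / df
  if (mse <= 0) {
    stop("zero within-group variance everywhere: range test undefined",
         call. = FALSE)
  }
  nh <- g / sum(1 / n_i)
  ord <- order(means, decreasing = TRUE)
  m_sorted <- means[ord]
  lsr <- c(NA_real_, vapply(2:g, function(p)
    stats::qtukey((1 - alpha)^(p - 1), p, df) * sqrt(mse / nh), 0))
  # widest spans first; a non-significant span protects all sub-spans
  ns <- diag(TRUE, g)
  for (p in seq(g, 2L)) {
    for (i in seq_len(g - p + 1L)) {
      j <- i + p - 1L
      if (ns[i, j]) next
      if (m_sorted[i] - m_sorted[j] <= lsr[p]) {
        for (a in i:j) for (b in a:j) ns[a, b] <- TRUE
      }
    }
  }
  # letter display from maximal non-significant intervals
  reach <- vapply(seq_len(g), function(i) max(which(ns[i, i:g])) + i - 1L, 0L)
  intervals <- list()
  for (i in seq_len(g)) {
    if (length(intervals) > 0L &&
        intervals[[length(intervals)]][2L] >= reach[i]) next
    intervals[[length(intervals) + 1L]] <- c(i, reach[i])
  }
  letter_of <- rep("", g)
  for (k in seq_along(intervals)) {
    iv <- intervals[[k]]
    idx <- iv[1L]:iv[2L]
    letter_of[idx] <- paste0(letter_of[idx], letters[k])
  }
  groups_df <- data.frame(
    group = names(values)[ord], n = as.integer(n_i[ord]),
    mean = m_sorted, letters = letter_of,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(
    list(groups = groups_df, alpha = alpha, df = df, mse = mse,
         n_harmonic = nh, lsr = lsr, nonsig = ns),
    class = "duncan_grouping"
  )
}

#' @export
print.duncan_grouping <- function(x, ...) {
  cat(sprintf("<duncan_grouping> alpha = %g, error df = %d, MSE = %.4g\n",
              x$alpha, x$df, x$mse))
  print(x$groups)
  invisible(x)
}

#' Do two groups differ under a Duncan grouping?
#'
#' @param grouping A `duncan_grouping`.
#' @param a,b Group names.
#' @return TRUE when the groups share no letter.
#' @export
duncan_different <- function(grouping, a, b) {
  gdf <- grouping$groups
  la <- strsplit(gdf$letters[gdf$group == a], "")[[1L]]
  lb <- strsplit(gdf$letters[gdf$group == b], "")[[1L]]
  length(intersect(la, lb)) == 0L
}
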