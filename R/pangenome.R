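#' Classify gene families by genome occupancy
#'
#' Families present in all N genomes are core; in `[softcore_min, N-1]`
#' genomes softcore; in `[2, softcore_min-1]` dispensable; in exactly one
#' genome private.  The classes are mutually exclusive and partition the
#' families.  With the default `softcore_min = N - 1` the softcore class
#' is exactly the families missing from a single genome.
#'
#' @param matrix A [pa_matrix()].
#' @param softcore_min Minimum occupancy for the softcore class; must lie
#'   in `[2, N-1]`.
#' @return Object of class `family_classification`: list with `class`
#'   (named per-family factor), `counts`, `proportions` (% of families, 2
#'   decimals, largest-remainder rounded so the composition totals exactly
#'   100), `gene_counts` and `gene_proportions` (% of genes, same
#'   rounding), and `n_families`.
#' @export
classify_families <- function(matrix, softcore_min = NULL) {
  stopifnot(inherits(matrix, "pa_matrix"))
  n <- ncol(matrix$occupancy)
  if (n < 3L) stop("classification needs at least 3 genomes", call. = FALSE)
  if (is.null(softcore_min)) softcore_min <- n - 1L
  if (softcore_min < 2L || softcore_min >= n) {
    stop("softcore_min must be in [2, N-1]", call. = FALSE)
  }
  occ <- rowSums(matrix$occupancy)
  if (any(occ == 0L)) stop("family with zero occupancy", call. = FALSE)
  lv <- c("core", "softcore", "dispensable", "private")
  cls <- factor(ifelse(occ == n, "core",
                ifelse(occ >= softcore_min, "softcore",
                ifelse(occ >= 2L, "dispensable", "private"))), levels = lv)
  names(cls) <- matrix$family_ids
  counts <- table(cls)
  genes_per_family <- rowSums(matrix$counts)
  gene_counts <- tapply(genes_per_family, cls, sum, default = 0)
  structure(
    list(class = cls,
         counts = as.integer(counts),
         class_names = lv,
         # largest-remainder rounding: composition shares total exactly 100
         proportions = percentages_lr(as.integer(counts)),
         gene_counts = as.numeric(gene_counts),
         gene_proportions = percentages_lr(as.numeric(gene_counts)),
         n_families = length(cls), softcore_min = softcore_min),
    class = "family_classification"
  )
}

#' @export
print.family_classification <- function(x, ...) {
  cat("<family_classification>", x$n_families, "families\n")
  print(data.frame(class = x$class_names, families = x$counts,
                   pct = x$proportions, genes = x$gene_counts,
                   gene_pct = x$gene_proportions))
  invisible(x)
}

#' Count singleton genes
#'
#' Singletons are genes in no orthogroup: members of a genome's gene-id
#' universe absent from every family's member list.
#'
#' @param orthogroups An `orthogroup_table`.
#' @param gene_universe Named list: per-genome character vectors of all
#'   gene ids in that genome.  Universes must be disjoint across genomes.
#' @return Integer singleton count.
#' @export
count_singletons <- function(orthogroups, gene_universe) {
  stopifnot(inherits(orthogroups, "orthogroup_table"), is.list(gene_universe))
  uni <- unlist(gene_universe, use.names = FALSE)
  if (anyDuplicated(uni)) {
    stop("gene id universes overlap across genomes", call. = FALSE)
  }
  clustered <- unlist(orthogroups$members, use.names = FALSE)
  rogue <- setdiff(clustered, uni)
  if (length(rogue) > 0L) {
    stop("gene(s) in a family but missing from every universe: ",
         paste(utils::head(rogue, 5L), collapse = ", "), call. = FALSE)
  }
  length(setdiff(uni, clustered))
}

#' Rarefaction simulation of pan- and core-genome size
#'
#' For each subset size k in 1..N, draws `reps` uniform k-subsets of
#' genomes (each subset sampled without replacement; subsets independent
#' across replicates) and records the pan size (families present in at
#' least one subset genome) and core size (families present in all of
#' them).  When the number of distinct k-subsets `choose(N, k)` does not
#' exceed `reps`, all subsets are enumerated exactly once instead and the
#' size is flagged exhaustive.
#'
#' @param matrix A [pa_matrix()].
#' @param reps Replicates per subset size (default 1000).
#' @param seed Integer seed.
#' @return Object of class `rarefaction_result`: list with `k`,
#'   `pan` and `core` (lists of per-replicate integer vectors),
#'   `pan_median`, `core_median`, `exhaustive` (logical per k), `n_genomes`,
#'   `n_families`, `reps`.
#' @export
rarefy <- function(matrix, reps = 1000L, seed = 1L) {
  stopifnot(inherits(matrix, "pa_matrix"), reps >= 1L)
  occ <- matrix$occupancy
  storage.mode(occ) <- "double"
  n <- ncol(occ)
  f <- nrow(occ)
  pan <- core <- vector("list", n)
  exhaustive <- logical(n)
  with_seed(seed, {
    for (k in seq_len(n)) {
      n_subsets <- choose(n, k)
      if (n_subsets <= reps) {
        subsets <- utils::combn(n, k)
        exhaustive[k] <- TRUE
      } else {
        subsets <- vapply(seq_len(reps), function(i) sort(sample.int(n, k)),
                          integer(k))
        if (k == 1L) subsets <- matrix(subsets, nrow = 1L)
      }
      # indicator matrix of subsets lets BLAS count per-family hits
      s_ind <- Matrix_indicator(subsets, n)
      hits <- occ %*% s_ind                  # families x replicates
      pan[[k]] <- as.integer(colSums(hits > 0))
      core[[k]] <- as.integer(colSums(hits == k))
    }
  })
  structure(
    list(k = seq_len(n), pan = pan, core = core,
         pan_median = vapply(pan, stats::median, 0),
         core_median = vapply(core, stats::median, 0),
         exhaustive = exhaustive, n_genomes = n, n_families = f,
         reps = as.integer(reps)),
    class = "rarefaction_result"
  )
}

# n x (number of subsets) 0/1 indicator from a k x m subset matrix
Matrix_indicator <- function(subsets, n) {
  m <- ncol(subsets)
  out <- matrix(0, n, m)
  out[cbind(as.vector(subsets), rep(seq_len(m), each = nrow(subsets)))] <- 1
  out
}

#' @export
print.rarefaction_result <- function(x, ...) {
  cat(sprintf("<rarefaction_result> %d genomes, %d families, %d reps\n",
              x$n_genomes, x$n_families, x$reps))
  print(data.frame(k = x$k, pan_median = x$pan_median,
                   core_median = x$core_median, exhaustive = x$exhaustive))
  invisible(x)
}

#' Detect the pan-genome plateau point
#'
#' The plateau is the smallest subset size k >= 2 from which every
#' subsequent step adds less than `rel_threshold` (default 0.5%) to the
#' median pan-genome size:
#' `(pan(j) - pan(j-1)) / pan(j-1) < rel_threshold` for all `j >= k`.
#' Requiring the condition for every later step, not just once, keeps a
#' noisy early dip from being read as a plateau.
#'
#' @param result A `rarefaction_result` (or any list with `pan_median`).
#' @param rel_threshold Relative growth threshold (default 0.005).
#' @return Integer plateau size, or `NA_integer_` when the curve never
#'   settles.
#' @export
detect_plateau <- function(result, rel_threshold = 0.005) {
  med <- result$pan_median
  if (length(med) < 2L) stop("need medians for at least 2 subset sizes", call. = FALSE)
  if (any(med <= 0)) stop("zero or negative median pan size", call. = FALSE)
  rel <- diff(med) / med[-length(med)]      # rel[j-1] = growth at step j
  ok <- rel < rel_threshold
  # smallest k with all steps j >= k below threshold
  below_from <- rev(cumprod(rev(ok))) == 1
  if (!any(below_from)) return(NA_integer_)
  as.integer(which(below_from)[1L] + 1L)
}
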