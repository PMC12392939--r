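#' Merge structural variants across samples
#'
#' Single-linkage clustering of SV records in the SURVIVOR style: two
#' records link iff they share chromosome, type (when `require_type`) and
#' strand pair (when `require_strand`), and both breakpoints agree within
#' `max_dist` (`|start - start'| <= max_dist` and `|end - end'| <=
#' max_dist`; for insertions the second condition compares inserted
#' lengths, since an insertion's end is its insertion point).  Records
#' shorter than `min_len` are dropped first.  Each cluster is represented
#' by its medoid member (smallest summed breakpoint distance to the other
#' members, ties to the first in coordinate order), so the result is
#' invariant to sample and record order and merging a merged catalogue is
#' a no-op.
#'
#' @param callsets Either a list of per-sample data.frames or one
#'   data.frame; columns `sample`, `chrom`, `start`, `end`, `type`,
#'   `strands`, `length`.
#' @param max_dist Maximum breakpoint distance in bp (default 1000).
#' @param require_type,require_strand Demand identical type / strands
#'   within a cluster (default both TRUE).
#' @param min_len Minimum SV length in bp (default 50).
#' @return Data.frame of merged records: `chrom`, `start`, `end`, `type`,
#'   `strands`, `length` (medoid coordinates), `support` (number of
#'   distinct samples), `n_members`, `members` (list column of member row
#'   data.frames).
#' @export
merge_svs <- function(callsets, max_dist = 1000L, require_type = TRUE,
                      require_strand = TRUE, min_len = 50L) {
  stopifnot(min_len >= 1L)
  records <- if (is.data.frame(callsets)) callsets else
    do.call(rbind, c(callsets, list(make.row.names = FALSE)))
  needed <- c("sample", "chrom", "start", "end", "type", "strands", "length")
  missing_col <- setdiff(needed, names(records))
  if (length(missing_col)) {
    stop("SV records need column(s): ", paste(missing_col, collapse = ", "),
         call. = FALSE)
  }
  records <- records[records$length >= min_len, , drop = FALSE]
  if (nrow(records) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), type = character(0),
                      strands = character(0), length = integer(0),
                      support = integer(0), n_members = integer(0)))
  }
  # canonical order makes the result independent of input order
  ord <- order(records$chrom, records$start, records$end, records$type,
               records$strands, records$sample)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  key <- paste(records$chrom,
               if (require_type) records$type else "",
               if (require_strand) records$strands else "")
  merged <- list()
  for (grp in split(seq_len(nrow(records)), key)) {
    sub <- records[grp, , drop = FALSE]
    m <- nrow(sub)
    # second breakpoint: inserted length for INS, else end coordinate
    b2 <- ifelse(sub$type == "INS", sub$length, sub$end)
    # single linkage via union-find over linked pairs
    parent <- seq_len(m)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (i in seq_len(m - 1L)) {
      for (j in seq((i + 1L), m)) {
        if (abs(sub$start[i] - sub$start[j]) <= max_dist &&
            abs(b2[i] - b2[j]) <= max_dist) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    roots <- vapply(seq_len(m), find, 0L)
    for (cl in split(seq_len(m), roots)) {
      mem <- sub[cl, , drop = FALSE]
      d <- outer(mem$start, mem$start, function(a, b) abs(a - b)) +
        outer(b2[cl], b2[cl], function(a, b) abs(a - b))
      medoid <- which.min(rowSums(d))
      merged[[length(merged) + 1L]] <- data.frame(
        chrom = mem$chrom[medoid], start = mem$start[medoid],
        end = mem$end[medoid], type = mem$type[medoid],
        strands = mem$strands[medoid], length = mem$length[medoid],
        support = length(unique(mem$sample)), n_members = nrow(mem),
        stringsAsFactors = FALSE)
      merged[[length(merged)]]$members <- list(mem)
    }
  }
  out <- do.call(rbind, merged)
  out <- out[order(out$chrom, out$start, out$end, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a merged SV catalogue
#'
#' Per-type and per-chromosome counts plus, when gene models are given,
#' the number of unique genes whose span intersects any merged SV span.
#'
#' @param merged Output of [merge_svs()] (or any data.frame with `chrom`,
#'   `start`, `end`, `type`).
#' @param genes Optional named list of [gene_model()] objects.
#' @return List: `total`, `by_type` (named vector), `by_chrom` (named
#'   vector), `genes_overlapped` (integer, `NA` when no gene models).
#' @export
summarize_svs <- function(merged, genes = NULL) {
  by_type <- table(merged$type)
  by_chrom <- table(merged$chrom)
  genes_hit <- NA_integer_
  if (!is.null(genes) && length(genes) > 0L && nrow(merged) > 0L) {
    g_gr <- GenomicRanges::GRanges(
      vapply(genes, `[[`, "", "chrom"),
      IRanges::IRanges(vapply(genes, function(g) gene_span(g)[1L], 0L),
                       vapply(genes, function(g) gene_span(g)[2L], 0L)))
    sv_gr <- GenomicRanges::GRanges(
      merged$chrom, IRanges::IRanges(merged$start, merged$end))
    hits <- GenomicRanges::findOverlaps(g_gr, sv_gr)
    genes_hit <- length(unique(S4Vectors::queryHits(hits)))
  } else if (!is.null(genes)) {
    genes_hit <- 0L
  }
  list(total = nrow(merged),
       by_type = stats::setNames(as.integer(by_type), names(by_type)),
       by_chrom = stats::setNames(as.integer(by_chrom), names(by_chrom)),
       genes_overlapped = genes_hit)
}
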