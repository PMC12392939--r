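#' Per-chromosome variant summary
#'
#' Counts, densities per Mb (1 Mb = 10^6 bp) and shares of the total (%)
#' per chromosome.  Accepts either a [variant_table()] or a named count
#' vector (as printed in variation-catalogue tables); densities are
#' reported only when chromosome lengths are supplied.
#'
#' @param x A `variant_table` or a named numeric vector of per-chromosome
#'   counts.
#' @param chrom_lengths Optional named vector of chromosome lengths in bp;
#'   required for densities, and every counted chromosome must then have a
#'   positive length.
#' @return Data.frame: `chrom`, `count`, `density_per_mb`, `share_pct`
#'   (share to 2 decimals); counts sum to the total and shares to 100
#'   within rounding.
#' @export
summarize_by_chromosome <- function(x, chrom_lengths = NULL) {
  counts <- if (inherits(x, "variant_table")) {
    tab <- table(x$records$chrom)
    stats::setNames(as.numeric(tab), names(tab))
  } else {
    stopifnot(is.numeric(x), !is.null(names(x)))
    x
  }
  total <- sum(counts)
  dens <- rep(NA_real_, length(counts))
  if (!is.null(chrom_lengths)) {
    missing_len <- setdiff(names(counts), names(chrom_lengths))
    if (length(missing_len) > 0L) {
      stop("no length for chromosome(s): ",
           paste(missing_len, collapse = ", "), call. = FALSE)
    }
    len <- chrom_lengths[names(counts)]
    if (any(len <= 0)) stop("zero-length chromosome", call. = FALSE)
    dens <- as.numeric(counts) / (len / 1e6)
  }
  data.frame(chrom = names(counts), count = as.numeric(counts),
             density_per_mb = dens,
             share_pct = round_half_up(100 * as.numeric(counts) / total, 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize variants over a gene set
#'
#' Counts the variants whose affected gene is in the set, the unique genes
#' hit, and the mean variants per hit gene (2 decimals).  Genes of the set
#' with no variant do not enter the denominator.  An empty intersection is
#' reported as mean 0 with `undefined_mean = TRUE`.
#'
#' @param effects Effect table from [classify_variant_effects()] (any
#'   data.frame with a `gene_id` column; one row per variant).
#' @param gene_set Character vector of gene ids.
#' @return List: `n_variants`, `n_genes`, `mean_per_gene`,
#'   `undefined_mean`.
#' @export
summarize_gene_set <- function(effects, gene_set) {
  hit <- !is.na(effects$gene_id) & effects$gene_id %in% gene_set
  n_var <- sum(hit)
  n_genes <- length(unique(effects$gene_id[hit]))
  list(n_variants = n_var, n_genes = n_genes,
       mean_per_gene = if (n_genes > 0L) round_half_up(n_var / n_genes, 2) else 0,
       undefined_mean = n_genes == 0L)
}

#' Variant breakdown for a genomic region
#'
#' Totals by size class, genic vs intergenic, intronic vs exonic, and
#' exonic subclass counts for all variants inside `[start, end]` on
#' `chrom`, with the bookkeeping identities enforced
#' (genic + intergenic = total; intronic + exonic = genic; subclasses sum
#' to exonic).
#'
#' @param x A [variant_table()].
#' @param effects Matching effect table from [classify_variant_effects()].
#' @param chrom Chromosome name.
#' @param start,end Region bounds, 1-based closed; `end < start` is an
#'   error.
#' @return List of counts: `total`, `snps`, `indels`, `svs`, `genic`,
#'   `intergenic`, `intronic`, `exonic`, and `exonic_subclasses` (named
#'   vector over missense/nonsense/synonymous/UTR/frameshift/inframe).
#' @export
region_report <- function(x, effects, chrom, start, end) {
  stopifnot(inherits(x, "variant_table"))
  if (end < start) stop("empty interval: end < start", call. = FALSE)
  r <- x$records
  stopifnot(nrow(r) == nrow(effects))
  sel <- r$chrom == chrom & r$pos >= start & r$pos <= end
  cls <- variant_size_class(x)[sel]
  eff <- effects[sel, , drop = FALSE]
  sub_levels <- c("missense", "nonsense", "synonymous", "UTR",
                  "frameshift", "inframe")
  sub <- table(factor(eff$subclass[eff$region == "exonic"], levels = sub_levels))
  out <- list(
    total = sum(sel),
    snps = sum(cls == "SNP"), indels = sum(cls == "InDel"),
    svs = sum(cls == "SV"),
    genic = sum(eff$region != "intergenic"),
    intergenic = sum(eff$region == "intergenic"),
    intronic = sum(eff$region == "intronic"),
    exonic = sum(eff$region == "exonic"),
    exonic_subclasses = stats::setNames(as.integer(sub), sub_levels)
  )
  stopifnot(out$genic + out$intergenic == out$total,
            out$intronic + out$exonic == out$genic,
            sum(out$exonic_subclasses) == out$exonic)
  out
}
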