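#' Enumerate gene haplotypes from a SNP genotype matrix
#'
#' The haplotype of an accession over the region's SNP sites is its
#' ordered allele string (ref base for hom-ref calls, alt base for
#' hom-alt).  Accessions with any heterozygous call in the region are
#' excluded (reason `het`); accessions with any missing call are excluded
#' (reason `missing`; het takes precedence when both occur).  Labels H1,
#' H2, ... are assigned by descending carrier frequency, ties broken by
#' first occurrence in accession order.
#'
#' @param matrix A [snp_matrix()].
#' @param chrom Chromosome of the region (default: the only chromosome in
#'   the matrix).
#' @param start,end Region bounds (1-based closed; defaults span all
#'   sites).
#' @return Object of class `haplotype_table`: list with `assignment`
#'   (named accession -> label), `strings` (label -> allele string),
#'   `frequencies` (label -> carrier count), `excluded` (data.frame
#'   `accession`, `reason`), and `sites` (the region's site metadata).
#' @export
enumerate_haplotypes <- function(matrix, chrom = NULL, start = -Inf, end = Inf) {
  stopifnot(inherits(matrix, "snp_matrix"))
  sites <- matrix$sites
  if (is.null(chrom)) {
    chrom <- unique(sites$chrom)
    if (length(chrom) > 1L) stop("several chromosomes; supply `chrom`", call. = FALSE)
  }
  in_region <- sites$chrom == chrom & sites$pos >= start & sites$pos <= end
  if (!any(in_region)) stop("no SNPs in region", call. = FALSE)
  calls <- matrix$calls[, in_region, drop = FALSE]
  ref <- sites$ref[in_region]
  alt <- sites$alt[in_region]
  has_het <- apply(calls, 1L, function(r) any(!is.na(r) & r == 1L))
  has_miss <- apply(calls, 1L, function(r) any(is.na(r)))
  excluded <- data.frame(
    accession = matrix$accessions[has_het | has_miss],
    reason = ifelse(has_het[has_het | has_miss], "het", "missing"),
    stringsAsFactors = FALSE)
  keep <- which(!has_het & !has_miss)
  if (length(keep) == 0L) {
    return(structure(
      list(assignment = stats::setNames(character(0), character(0)),
           strings = stats::setNames(character(0), character(0)),
           frequencies = stats::setNames(integer(0), character(0)),
           excluded = excluded,
           sites = sites[in_region, , drop = FALSE]),
      class = "haplotype_table"))
  }
  strings <- vapply(keep, function(i)
    paste(ifelse(calls[i, ] == 2L, alt, ref), collapse = ""), "")
  names(strings) <- matrix$accessions[keep]
  # H1, H2, ... by descending frequency; ties by first occurrence
  uniq <- unique(strings)
  freq <- vapply(uniq, function(s) sum(strings == s), 0L)
  ord <- order(-freq, match(uniq, strings))
  labels <- stats::setNames(paste0("H", seq_along(uniq)), uniq[ord])
  assignment <- stats::setNames(unname(labels[strings]), names(strings))
  label_strings <- if (length(labels)) {
    stats::setNames(names(labels), unname(labels))
  } else {
    stats::setNames(character(0), character(0))
  }
  structure(
    list(assignment = assignment,
         strings = label_strings,
         frequencies = stats::setNames(as.integer(freq[uniq[ord]]),
                                       unname(labels)),
         excluded = excluded,
         sites = sites[in_region, , drop = FALSE]),
    class = "haplotype_table"
  )
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("<haplotype_table> %d haplotypes over %d accessions (%d excluded)\n",
              length(x$strings), length(x$assignment), nrow(x$excluded)))
  print(data.frame(label = names(x$strings), string = unname(x$strings),
                   n = unname(x$frequencies[names(x$strings)])))
  invisible(x)
}

#' Call the superior haplotype for a trait
#'
#' Joins the haplotype table with a phenotype table, keeps haplotypes with
#' at least `min_n` phenotyped carriers, runs [duncan_mrt()] across them,
#' and calls the maximum-mean qualifying haplotype superior when its
#' letter set is disjoint from that of the minimum-mean qualifying
#' haplotype (i.e. the best and worst groups are significantly
#' different); otherwise no superior haplotype is declared.  The
#' minimum-mean qualifying haplotype is reported as the inferior one.
#'
#' @param table A `haplotype_table`.
#' @param phenotypes Data.frame with columns `accession`, `value`.
#' @param min_n Minimum phenotyped carriers for a haplotype to qualify
#'   (default 5).
#' @param alpha Significance level for the range test (default 0.05).
#' @return List: `superior` (label or `NA`), `inferior` (label or `NA`),
#'   `reason` (when no call), `grouping` (the `duncan_grouping`, or `NULL`),
#'   `stats` (per-haplotype `n`, `mean` over all haplotypes with
#'   phenotypes), `min_n`.
#' @export
call_superior_haplotype <- function(table, phenotypes, min_n = 5L,
                                    alpha = 0.05) {
  stopifnot(inherits(table, "haplotype_table"),
            all(c("accession", "value") %in% names(phenotypes)))
  lab <- table$assignment[phenotypes$accession]
  ok <- !is.na(lab)
  by_hap <- split(phenotypes$value[ok], lab[ok])
  stats_df <- data.frame(
    haplotype = names(by_hap), n = lengths(by_hap),
    mean = vapply(by_hap, mean, 0), row.names = NULL,
    stringsAsFactors = FALSE)
  qualifying <- by_hap[lengths(by_hap) >= min_n]
  if (length(qualifying) < 2L) {
    return(list(superior = NA_character_, inferior = NA_character_,
                reason = "fewer than 2 haplotypes with enough phenotyped carriers",
                grouping = NULL, stats = stats_df, min_n = min_n))
  }
  grouping <- duncan_mrt(qualifying, alpha = alpha)
  gdf <- grouping$groups
  top <- gdf$group[1L]
  bottom <- gdf$group[nrow(gdf)]
  distinct <- duncan_different(grouping, top, bottom)
  list(
    superior = if (distinct) top else NA_character_,
    inferior = bottom,
    reason = if (distinct) NA_character_ else
      "best and worst haplotype means not significantly different",
    grouping = grouping, stats = stats_df, min_n = min_n)
}

#' Assign catalogue haplotypes to new accessions
#'
#' Matches each accession's allele string over the catalogue's SNP sites
#' against the catalogue labels.  Heterozygous or missing calls exclude
#' the accession (same rule as enumeration); an unseen allele string is
#' labelled `novel`.
#'
#' @param matrix A [snp_matrix()] covering the catalogue's sites (same
#'   chrom/pos/ref/alt; a mismatch is an error).
#' @param catalogue A `haplotype_table`.
#' @return Data.frame: `accession`, `label` (catalogue label, `"novel"`,
#'   or `NA` when excluded), `reason` (`het`/`missing`/`NA`), `string`.
#' @export
assign_haplotypes <- function(matrix, catalogue) {
  stopifnot(inherits(matrix, "snp_matrix"), inherits(catalogue, "haplotype_table"))
  cs <- catalogue$sites
  key <- function(s) paste(s$chrom, s$pos, s$ref, s$alt)
  idx <- match(key(cs), key(matrix$sites))
  if (any(is.na(idx))) {
    stop("genotype matrix does not cover the catalogue's SNP sites",
         call. = FALSE)
  }
  calls <- matrix$calls[, idx, drop = FALSE]
  out <- data.frame(accession = matrix$accessions, label = NA_character_,
                    reason = NA_character_, string = NA_character_,
                    stringsAsFactors = FALSE)
  lookup <- stats::setNames(names(catalogue$strings), catalogue$strings)
  for (i in seq_len(nrow(calls))) {
    r <- calls[i, ]
    if (any(!is.na(r) & r == 1L)) { out$reason[i] <- "het"; next }
    if (any(is.na(r))) { out$reason[i] <- "missing"; next }
    s <- paste(ifelse(r == 2L, cs$alt, cs$ref), collapse = "")
    out$string[i] <- s
    out$label[i] <- if (s %in% names(lookup)) lookup[[s]] else "novel"
  }
  out
}
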