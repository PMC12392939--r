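#' Synthetic 'QTL-hotspot'-style region
#'
#' Builds a fully synthetic single-chromosome region that mirrors the
#' variant composition reported for the drought-adaptive 'QTL-hotspot'
#' interval of chickpea chromosome 4: 700 polymorphic variants (534 SNPs,
#' 166 InDels) over 26 genes, 42 of them genic (17 intronic, of which one
#' a splice donor, and 25 exonic: 11 missense + 14 synonymous) and 658
#' intergenic.  The planted class histogram is exact by construction, so
#' the region summary identities can be validated end to end.  This is a
#' synthetic stand-in; the real interval requires the deposited study
#' data.
#'
#' @param seed Integer seed.
#' @return List: `genome`, `genes`, `variants` (a [variant_table()]),
#'   `effects` (from [classify_variant_effects()]), `truth`, and `region`
#'   (`chrom`, `start`, `end` spanning the toy chromosome).
#' @export
synthetic_qtl_hotspot <- function(seed = 1L) {
  sim <- generate_annotated_genome(n_chroms = 1L, n_genes = 26L,
                                   seed = derive_seed(seed, "qtl"),
                                   chrom_names = "Ca4")
  req <- c(intergenic = 499L, intergenic_indel = 159L,
           intronic = 9L, intronic_indel = 7L, splice_donor = 1L,
           synonymous = 14L, missense = 11L)
  vv <- generate_variants(sim$genome, sim$genes, req,
                          seed = derive_seed(seed, "qtl_variants"))
  effects <- classify_variant_effects(vv$variants, sim$genes, sim$genome)
  list(genome = sim$genome, genes = sim$genes, variants = vv$variants,
       effects = effects, truth = vv$truth,
       region = list(chrom = "Ca4", start = 1L,
                     end = Biostrings::width(sim$genome)[[1L]]))
}
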