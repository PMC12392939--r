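# hand-built single-gene genome: 16 bp 5' UTR, CDS ATG AAA CCC TGG TAA,
# 10 bp 3' UTR, plus intergenic flanks
tiny_scenario <- function() {
  cds <- "ATGAAACCCTGGTAA"
  seqs <- paste0(strrep("G", 50), strrep("T", 16), cds, strrep("T", 10),
                 strrep("G", 50))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- "Ca1"
  gene <- gene_model("geneA", "Ca1", "+",
                     exons = cbind(51L, 51L + 16L + 15L + 10L - 1L),
                     cds = cbind(67L, 81L))
  list(genome = genome, genes = list(geneA = gene))
}

variant_at <- function(pos, ref, alt, qual = 50, depth = 100) {
  variant_table(data.frame(chrom = "Ca1", pos = pos, id = ".", ref = ref,
                           alt = alt, qual = qual, filter = "PASS",
                           depth = depth, svtype = NA_character_,
                           end = NA_integer_, strands = NA_character_,
                           svlen = NA_integer_, split = FALSE,
                           stringsAsFactors = FALSE))
}

test_that("quality/depth filtering honours inclusive boundaries", {
  mk <- function(qual, depth) {
    data.frame(chrom = "Ca1", pos = seq_along(qual), id = ".", ref = "A",
               alt = "G", qual = qual, filter = ".", depth = depth,
               stringsAsFactors = FALSE)
  }
  x <- variant_table(mk(c(19.9, 20, 25, NA), c(60, 50, NA, 80)))
  res <- filter_variants(x)
  expect_equal(res$variants$records$pos, 2L)
  expect_equal(res$report$fail_qual, 2L)
  expect_equal(res$report$fail_depth, 1L)
  expect_equal(res$report$n_retained, 1L)
  # random records vs the filtering predicate applied directly
  set.seed(5)
  qual <- sample(c(NA, 10:30), 300L, replace = TRUE)
  depth <- sample(c(NA, 30:70), 300L, replace = TRUE)
  x <- variant_table(mk(qual, depth))
  keep <- !is.na(qual) & qual >= 20 & !is.na(depth) & depth >= 50
  expect_equal(filter_variants(x)$variants$records$pos, which(keep))
})

test_that("codon-local classification handles the canonical cases", {
  sc <- tiny_scenario()
  # between genes
  eff <- classify_variant_effects(variant_at(10L, "G", "A"), sc$genes, sc$genome)
  expect_equal(eff$region, "intergenic")
  # AAA -> AAG, both Lys
  eff <- classify_variant_effects(variant_at(72L, "A", "G"), sc$genes, sc$genome)
  expect_equal(eff$subclass, "synonymous")
  expect_equal(eff$aa_change, "Lys2Lys")
  # TGG -> TGA: stop gained
  eff <- classify_variant_effects(variant_at(78L, "G", "A"), sc$genes, sc$genome)
  expect_equal(eff$subclass, "nonsense")
  expect_equal(eff$aa_change, "Trp4Ter")
  # AAA -> ACA missense
  eff <- classify_variant_effects(variant_at(71L, "A", "C"), sc$genes, sc$genome)
  expect_equal(eff$subclass, "missense")
  expect_equal(eff$aa_change, "Lys2Thr")
  # 5' UTR position
  eff <- classify_variant_effects(variant_at(60L, "T", "C"), sc$genes, sc$genome)
  expect_equal(eff$region, "exonic")
  expect_equal(eff$subclass, "UTR")
  # ref mismatch is a named error
  expect_error(
    classify_variant_effects(variant_at(60L, "A", "C"), sc$genes, sc$genome),
    "Ca1:60")
})

test_that("classifier agrees 100% with generator truth from full re-translation", {
  sim <- generate_annotated_genome(n_chroms = 3L, n_genes = 24L, seed = 71L)
  req <- c(intergenic = 120L, intronic = 90L, utr = 60L, synonymous = 70L,
           missense = 70L, nonsense = 25L, splice_donor = 20L,
           splice_acceptor = 20L, frameshift = 15L, inframe = 10L)
  vv <- generate_variants(sim$genome, sim$genes, req, seed = 97L)
  expect_equal(nrow(vv$variants$records), 500L)
  eff <- classify_variant_effects(vv$variants, sim$genes, sim$genome)
  expect_identical(effect_truth_label(eff), vv$truth$class)
})

test_that("classification is strand-symmetric under reverse complement", {
  sim <- generate_annotated_genome(n_chroms = 2L, n_genes = 10L, seed = 55L)
  vv <- generate_variants(
    sim$genome, sim$genes,
    c(intergenic = 15L, intronic = 15L, utr = 10L, synonymous = 15L,
      missense = 15L, nonsense = 8L, splice_donor = 6L, splice_acceptor = 6L),
    seed = 61L)
  eff <- classify_variant_effects(vv$variants, sim$genes, sim$genome)
  rc <- suppressWarnings(revcomp_scenario(sim$genome, sim$genes, vv$variants))
  eff_rc <- classify_variant_effects(rc$variants, rc$genes, rc$genome)
  expect_identical(eff_rc$region, eff$region)
  expect_identical(eff_rc$subclass, eff$subclass)
  expect_identical(eff_rc$splice, eff$splice)
  expect_identical(eff_rc$aa_change, eff$aa_change)
})

test_that("chromosome summaries satisfy count and share identities", {
  set.seed(3)
  chroms <- sample(paste0("Ca", 1:5), 400L, replace = TRUE)
  x <- variant_table(data.frame(chrom = chroms, pos = 1:400, id = ".",
                                ref = "A", alt = "G", qual = 50,
                                filter = ".", depth = 60,
                                stringsAsFactors = FALSE))
  lens <- stats::setNames(rep(2e6, 5L), paste0("Ca", 1:5))
  s <- summarize_by_chromosome(x, lens)
  expect_equal(sum(s$count), 400)
  expect_equal(sum(s$share_pct), 100, tolerance = 0.03)
  expect_equal(s$count[s$chrom == "Ca1"], sum(chroms == "Ca1"))
  expect_equal(s$density_per_mb, s$count / 2, tolerance = 1e-12)
  expect_error(summarize_by_chromosome(x, lens[-1L]), "no length")
  expect_error(summarize_by_chromosome(x, stats::setNames(c(0, lens[-1L]),
                                                          names(lens))),
               "zero-length")
})

test_that("gene-set summaries match a direct group-by and flag empty sets", {
  set.seed(9)
  genes <- sprintf("g%02d", 1:30)
  eff <- data.frame(gene_id = sample(c(genes, NA), 500L, replace = TRUE),
                    stringsAsFactors = FALSE)
  set1 <- sample(genes, 12L)
  s <- summarize_gene_set(eff, set1)
  hit <- eff$gene_id[!is.na(eff$gene_id) & eff$gene_id %in% set1]
  expect_equal(s$n_variants, length(hit))
  expect_equal(s$n_genes, length(unique(hit)))
  expect_equal(s$mean_per_gene, round(length(hit) / length(unique(hit)), 2),
               tolerance = 0.005)
  empty <- summarize_gene_set(eff, "absent_gene")
  expect_equal(empty$n_variants, 0L)
  expect_true(empty$undefined_mean)
  expect_equal(empty$mean_per_gene, 0)
})

test_that("region reports enforce their bookkeeping identities", {
  sim <- generate_annotated_genome(n_chroms = 1L, n_genes = 8L, seed = 12L)
  vv <- generate_variants(sim$genome, sim$genes,
                          c(intergenic = 30L, intronic = 10L, utr = 8L,
                            missense = 6L, frameshift = 4L), seed = 19L)
  eff <- classify_variant_effects(vv$variants, sim$genes, sim$genome)
  L <- Biostrings::width(sim$genome)[1L]
  rep_all <- region_report(vv$variants, eff, "Ca1", 1L, L)
  expect_equal(rep_all$total, 58L)
  expect_equal(rep_all$genic + rep_all$intergenic, rep_all$total)
  expect_equal(rep_all$intronic + rep_all$exonic, rep_all$genic)
  expect_equal(sum(rep_all$exonic_subclasses), rep_all$exonic)
  expect_equal(rep_all$indels, 4L)  # frameshifts are the only InDels planted
  # empty window
  rep_none <- region_report(vv$variants, eff, "Ca1", 1L, 5L)
  expect_equal(rep_none$total, sum(vv$variants$records$pos <= 5L))
  expect_error(region_report(vv$variants, eff, "Ca1", 10L, 5L), "empty interval")
  # random windows vs a direct interval filter
  set.seed(77)
  for (r in 1:20) {
    a <- sample.int(L, 1L); b <- min(L, a + sample.int(2000L, 1L))
    rr <- region_report(vv$variants, eff, "Ca1", a, b)
    expect_equal(rr$total,
                 sum(vv$variants$records$pos >= a & vv$variants$records$pos <= b))
  }
})
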