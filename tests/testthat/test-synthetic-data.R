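test_that("pan-genome generator realizes class counts and histograms exactly", {
  sp <- pangenome_sim_spec(n_genomes = 9L, n_core = 40L, n_softcore = 12L,
                           n_dispensable = 60L, n_private = 7L, seed = 8L)
  pg <- generate_pangenome_matrix(sp)
  expect_equal(nrow(pg$matrix$occupancy), 119L)
  expect_equal(as.integer(table(pg$truth)), c(40L, 12L, 60L, 7L))
  # occupancy histogram of dispensable rows matches the exact partition
  occ <- rowSums(pg$matrix$occupancy[pg$truth == "dispensable", ])
  want <- panhap:::exact_partition(60L, sp$dispensable_occupancy)
  expect_equal(as.integer(table(factor(occ, levels = sp$occ_levels))), want)
  # private families fall round-robin
  priv <- pg$matrix$occupancy[pg$truth == "private", ]
  expect_equal(unname(which(priv[1L, ])), 1L)
  expect_equal(unname(which(priv[2L, ])), 2L)
})

test_that("an all-core spec classifies 100% core downstream", {
  sp <- pangenome_sim_spec(n_genomes = 5L, n_core = 30L, n_softcore = 0L,
                           n_dispensable = 0L, n_private = 0L, seed = 1L)
  cl <- classify_families(generate_pangenome_matrix(sp)$matrix)
  expect_equal(cl$proportions, c(100, 0, 0, 0))
})

test_that("generators are pure functions of their seed", {
  a <- generate_pangenome_matrix(pangenome_sim_spec(6L, 10L, 4L, 8L, 2L, seed = 5L))
  b <- generate_pangenome_matrix(pangenome_sim_spec(6L, 10L, 4L, 8L, 2L, seed = 5L))
  expect_identical(a, b)
  s1 <- generate_sv_callsets(4L, 6L, 30, seed = 7L)
  s2 <- generate_sv_callsets(4L, 6L, 30, seed = 7L)
  expect_identical(s1, s2)
  h1 <- generate_haplotype_dataset(haplotype_sim_spec(seed = 9L))
  h2 <- generate_haplotype_dataset(haplotype_sim_spec(seed = 9L))
  expect_identical(h1, h2)
  # and the global RNG stream is left untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_haplotype_dataset(haplotype_sim_spec(seed = 2L)))
  expect_identical(runif(1), before)
})

test_that("variant generator histograms equal the request and impossible requests fail", {
  sim <- generate_annotated_genome(2L, 8L, seed = 21L)
  req <- c(intergenic = 6L, intronic = 4L, utr = 3L, synonymous = 4L,
           missense = 4L, nonsense = 2L, frameshift = 3L, inframe = 2L)
  vv <- generate_variants(sim$genome, sim$genes, req, seed = 13L)
  expect_equal(table(vv$truth$class)[names(req)], table(rep(names(req), req))[names(req)])
  # gene-free genome: intergenic everywhere, coding classes impossible
  empty <- generate_annotated_genome(1L, 0L, seed = 2L, chrom_lengths = 5000L)
  v0 <- generate_variants(empty$genome, empty$genes, c(intergenic = 10L), seed = 1L)
  expect_true(all(v0$truth$class == "intergenic"))
  expect_error(
    generate_variants(empty$genome, empty$genes, c(nonsense = 1L), seed = 1L),
    "no coding genes")
})

test_that("SV generator enforces separability and plants recoverable support", {
  expect_error(generate_sv_callsets(3L, 4L, jitter_sd = 9000, gap = 10000L),
               "not separable")
  sv <- generate_sv_callsets(n_samples = 6L, n_clusters = 10L, jitter_sd = 0,
                             seed = 3L)
  m <- merge_svs(sv$callsets, max_dist = 1000L)
  expect_equal(nrow(m), 10L)
  expect_equal(sort(m$support), sort(sv$truth$support))
})

test_that("haplotype generator honours noise, het and capacity limits", {
  # vanishing noise: group means equal planted means
  sp <- haplotype_sim_spec(n_accessions = 60L, n_snps = 4L, n_haplotypes = 3L,
                           means = c(30, 20, 10), noise_sd = 1e-9,
                           het_rate = 0, missing_rate = 0, seed = 6L)
  d <- generate_haplotype_dataset(sp)
  agg <- tapply(d$phenotypes$value, d$truth$assignment, mean)
  expect_equal(as.numeric(agg[as.character(1:3)]), c(30, 20, 10),
               tolerance = 1e-6)
  # het rate 1: every accession excluded downstream
  sp_het <- haplotype_sim_spec(n_accessions = 20L, n_snps = 3L,
                               n_haplotypes = 2L, means = c(2, 1),
                               noise_sd = 1, het_rate = 1, seed = 1L)
  ht <- enumerate_haplotypes(generate_haplotype_dataset(sp_het)$genotypes)
  expect_equal(length(ht$assignment), 0L)
  expect_equal(nrow(ht$excluded), 20L)
  expect_error(
    haplotype_sim_spec(n_snps = 2L, n_haplotypes = 5L, means = 1:5),
    "2\\^n_snps")
})
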