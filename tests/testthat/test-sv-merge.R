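sv_rec <- function(sample, start, end, type = "DEL", strands = "+-",
                   chrom = "Ca1", length = end - start + 1L) {
  data.frame(sample = sample, chrom = chrom, start = start, end = end,
             type = type, strands = strands, length = length,
             stringsAsFactors = FALSE)
}

test_that("identical calls merge with full support; types never mix", {
  recs <- rbind(sv_rec("S1", 1000L, 1500L), sv_rec("S2", 1000L, 1500L),
                sv_rec("S3", 1000L, 1500L))
  m <- merge_svs(recs)
  expect_equal(nrow(m), 1L)
  expect_equal(m$support, 3L)
  two <- rbind(sv_rec("S1", 1000L, 1500L, type = "DEL"),
               sv_rec("S2", 1000L, 1500L, type = "INS", length = 501L))
  expect_equal(nrow(merge_svs(two)), 2L)
  # strand pairs also separate clusters
  st <- rbind(sv_rec("S1", 1000L, 1500L, strands = "+-"),
              sv_rec("S2", 1000L, 1500L, strands = "-+"))
  expect_equal(nrow(merge_svs(st)), 2L)
  expect_equal(nrow(merge_svs(st, require_strand = FALSE)), 1L)
})

test_that("records under min_len are dropped and never resurface", {
  recs <- rbind(sv_rec("S1", 100L, 130L), sv_rec("S2", 1000L, 1500L))
  m <- merge_svs(recs)
  expect_equal(nrow(m), 1L)
  expect_true(all(m$length >= 50L))
})

test_that("merge is idempotent and invariant to input order", {
  sv <- generate_sv_callsets(n_samples = 6L, n_clusters = 15L, jitter_sd = 60,
                             seed = 29L)
  m <- merge_svs(sv$callsets, max_dist = 1000L)
  # re-merging the representatives changes nothing
  reps <- m[, c("chrom", "start", "end", "type", "strands", "length")]
  reps$sample <- "merged"
  m2 <- merge_svs(reps, max_dist = 1000L)
  expect_equal(nrow(m2), nrow(m))
  expect_equal(m2$start, m$start)
  expect_equal(m2$end, m$end)
  # shuffled record order gives the identical catalogue
  all_rec <- do.call(rbind, c(sv$callsets, list(make.row.names = FALSE)))
  set.seed(4)
  for (r in 1:5) {
    shuf <- all_rec[sample.int(nrow(all_rec)), ]
    ms <- merge_svs(shuf, max_dist = 1000L)
    expect_identical(ms, m)
  }
})

test_that("planted clusters are recovered exactly across random specs", {
  set.seed(83)
  for (r in 1:12) {
    sv <- generate_sv_callsets(n_samples = sample(3:8, 1L),
                               n_clusters = sample(5:20, 1L),
                               jitter_sd = sample(c(0, 20, 100), 1L),
                               seed = r)
    m <- merge_svs(sv$callsets, max_dist = 1000L)
    expect_equal(nrow(m), nrow(sv$truth))
    expect_equal(sort(m$support), sort(sv$truth$support))
    # cluster membership equals the brute-force single-linkage oracle
    comp <- oracle_sv_clusters(sv$records, max_dist = 1000L)
    expect_equal(nrow(m), length(unique(comp)))
  }
})

test_that("support bookkeeping: supports sum to surviving record count", {
  sv <- generate_sv_callsets(n_samples = 5L, n_clusters = 10L, jitter_sd = 30,
                             seed = 37L)
  m <- merge_svs(sv$callsets, max_dist = 1000L)
  expect_equal(sum(m$support), nrow(sv$records))
})

test_that("gene overlap counting matches an interval-intersection oracle", {
  sim <- generate_annotated_genome(n_chroms = 1L, n_genes = 10L, seed = 44L)
  set.seed(15)
  n <- 40L
  start <- sample.int(Biostrings::width(sim$genome)[1L] - 600L, n)
  recs <- sv_rec(paste0("S", 1:n), start, start + sample(50:500, n, replace = TRUE))
  m <- merge_svs(recs, max_dist = 0L)
  s <- summarize_svs(m, sim$genes)
  spans <- vapply(sim$genes, gene_span, c(0L, 0L))
  hit <- vapply(seq_len(ncol(spans)), function(i)
    any(m$start <= spans[2L, i] & m$end >= spans[1L, i]), TRUE)
  expect_equal(s$genes_overlapped, sum(hit))
  expect_equal(s$total, nrow(m))
  expect_equal(sum(s$by_type), s$total)
  # empty catalogue
  e <- summarize_svs(merge_svs(sv_rec("S1", 1L, 20L)), sim$genes)
  expect_equal(e$total, 0L)
  expect_equal(e$genes_overlapped, 0L)
})
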