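mk_snp_matrix <- function(calls, pos = NULL) {
  n_sites <- ncol(calls)
  if (is.null(pos)) pos <- 100L * seq_len(n_sites)
  snp_matrix(calls,
             data.frame(chrom = "Ca4", pos = pos,
                        ref = rep_len(c("A", "C"), n_sites),
                        alt = rep_len(c("G", "T"), n_sites),
                        stringsAsFactors = FALSE))
}

test_that("het and missing carriers are excluded with the right reason", {
  calls <- rbind(acc1 = c(0L, 0L, 0L), acc2 = c(2L, 2L, 2L),
                 acc3 = c(0L, 1L, 0L), acc4 = c(0L, NA, 2L),
                 acc5 = c(0L, 1L, NA))
  ht <- enumerate_haplotypes(mk_snp_matrix(calls))
  expect_setequal(names(ht$assignment), c("acc1", "acc2"))
  expect_equal(ht$excluded$reason[ht$excluded$accession == "acc3"], "het")
  expect_equal(ht$excluded$reason[ht$excluded$accession == "acc4"], "missing")
  expect_equal(ht$excluded$reason[ht$excluded$accession == "acc5"], "het")
})

test_that("labels follow descending frequency with first-occurrence ties", {
  calls <- rbind(a1 = c(0L, 0L), a2 = c(2L, 2L), a3 = c(2L, 2L),
                 a4 = c(0L, 2L), a5 = c(2L, 2L))
  ht <- enumerate_haplotypes(mk_snp_matrix(calls))
  expect_equal(unname(ht$assignment[c("a2", "a3", "a5")]), rep("H1", 3L))
  # tie between the strings of a1 and a4 -> first occurrence (a1) gets H2
  expect_equal(unname(ht$assignment["a1"]), "H2")
  expect_equal(unname(ht$assignment["a4"]), "H3")
  expect_equal(unname(ht$frequencies), c(3L, 1L, 1L))
})

test_that("haplotype partitions equal a direct tuple-grouping oracle", {
  set.seed(61)
  for (r in 1:30) {
    n_acc <- sample(10:40, 1L)
    n_site <- sample(2:6, 1L)
    calls <- matrix(sample(c(0L, 2L), n_acc * n_site, replace = TRUE),
                    n_acc, dimnames = list(sprintf("a%02d", seq_len(n_acc)), NULL))
    ht <- enumerate_haplotypes(mk_snp_matrix(calls))
    # oracle: group accessions by their raw call tuple
    key <- apply(calls, 1L, paste, collapse = "")
    same_oracle <- outer(key, key, `==`)
    lab <- ht$assignment[rownames(calls)]
    same_impl <- outer(lab, lab, `==`)
    expect_identical(unname(same_impl), unname(same_oracle))
  }
})

test_that("region selection restricts sites and empty regions error", {
  calls <- rbind(a1 = c(0L, 2L, 0L), a2 = c(2L, 2L, 0L))
  m <- mk_snp_matrix(calls, pos = c(100L, 200L, 300L))
  ht <- enumerate_haplotypes(m, chrom = "Ca4", start = 150L, end = 250L)
  expect_equal(nrow(ht$sites), 1L)
  expect_equal(unname(ht$assignment), c("H1", "H1"))
  expect_error(enumerate_haplotypes(m, chrom = "Ca4", start = 400L, end = 500L),
               "no SNPs")
})

test_that("assignment round-trips enumeration and labels novel strings", {
  d <- generate_haplotype_dataset(haplotype_sim_spec(
    n_accessions = 80L, n_snps = 5L, n_haplotypes = 4L,
    means = c(30, 25, 20, 15), noise_sd = 1, seed = 19L))
  ht <- enumerate_haplotypes(d$genotypes)
  back <- assign_haplotypes(d$genotypes, ht)
  incl <- names(ht$assignment)
  expect_identical(back$label[match(incl, back$accession)],
                   unname(ht$assignment[incl]))
  # novel string: flip every site of one accession to an unseen pattern
  calls <- d$genotypes$calls
  novel <- calls[1L, , drop = FALSE]
  seen <- unique(apply(calls, 1L, paste, collapse = "/"))
  repeat {
    cand <- sample(c(0L, 2L), ncol(calls), replace = TRUE)
    if (!paste(cand, collapse = "/") %in% seen) break
  }
  novel[1L, ] <- cand
  rownames(novel) <- "newacc"
  nm <- snp_matrix(novel, d$genotypes$sites)
  res <- assign_haplotypes(nm, ht)
  expect_equal(res$label, "novel")
  # site mismatch
  wrong <- d$genotypes
  bad <- snp_matrix(wrong$calls, transform(wrong$sites, pos = pos + 1L))
  expect_error(assign_haplotypes(bad, ht), "does not cover")
})

test_that("superior haplotype calls demand significance and enough carriers", {
  d <- generate_haplotype_dataset(haplotype_sim_spec(
    n_accessions = 100L, n_snps = 5L, n_haplotypes = 2L,
    means = c(29.84, 14.66), noise_sd = 1, het_rate = 0, missing_rate = 0,
    seed = 27L))
  ht <- enumerate_haplotypes(d$genotypes)
  call <- call_superior_haplotype(ht, d$phenotypes)
  planted_acc <- names(d$truth$assignment)[d$truth$assignment == d$truth$superior]
  planted_label <- unique(unname(ht$assignment[planted_acc]))
  expect_equal(call$superior, planted_label)
  expect_true(duncan_different(call$grouping, call$superior, call$inferior))
  # equal planted means: no superior call
  d0 <- generate_haplotype_dataset(haplotype_sim_spec(
    n_accessions = 100L, n_snps = 5L, n_haplotypes = 2L,
    means = c(20, 20), noise_sd = 1, het_rate = 0, missing_rate = 0,
    seed = 33L))
  ht0 <- enumerate_haplotypes(d0$genotypes)
  call0 <- call_superior_haplotype(ht0, d0$phenotypes)
  expect_true(is.na(call0$superior))
  # min_n gate: one haplotype too rare to qualify
  calls <- rbind(matrix(0L, 8L, 2L), matrix(2L, 2L, 2L))
  rownames(calls) <- sprintf("a%02d", 1:10)
  htr <- enumerate_haplotypes(mk_snp_matrix(calls))
  ph <- data.frame(accession = rownames(calls), value = rnorm(10L))
  res <- call_superior_haplotype(htr, ph, min_n = 5L)
  expect_true(is.na(res$superior))
  expect_match(res$reason, "fewer than 2")
})
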