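random_pa <- function(f, n) {
  occ <- matrix(runif(f * n) < 0.5, f, n)
  occ[rowSums(occ) == 0L, 1L] <- TRUE
  pa_matrix(occ)
}

test_that("classification matches the row-sum oracle on random matrices", {
  set.seed(101)
  for (rep in 1:200) {
    m <- random_pa(20L, 8L)
    cl <- classify_families(m)
    expect_identical(as.character(cl$class), oracle_classify(m$occupancy))
    expect_equal(sum(cl$counts), 20L)
    expect_equal(sum(cl$proportions), 100, tolerance = 0.03)
  }
})

test_that("a 3-genome family present everywhere is core and guards hold", {
  m <- pa_matrix(matrix(TRUE, 1L, 3L))
  expect_identical(as.character(classify_families(m)$class), "core")
  expect_error(classify_families(pa_matrix(matrix(TRUE, 2L, 2L))),
               "at least 3 genomes")
  expect_error(classify_families(pa_matrix(matrix(TRUE, 2L, 4L)),
                                 softcore_min = 4L), "softcore_min")
})

test_that("singleton counting equals the set-difference oracle", {
  og <- structure(list(
    family_ids = "OG1", genomes = c("G1", "G2"),
    members = matrix(list(c("a1", "a2"), c("b1")), 1L, 2L,
                     dimnames = list("OG1", c("G1", "G2")))),
    class = "orthogroup_table")
  uni <- list(G1 = c("a1", "a2", "a3", "a4"), G2 = c("b1", "b2"))
  expect_equal(count_singletons(og, uni), 3L)
  expect_equal(count_singletons(og, list(G1 = c("a1", "a2"), G2 = "b1")), 0L)
  expect_error(count_singletons(og, list(G1 = "a1", G2 = "b1")),
               "missing from every universe")
  set.seed(7)
  for (rep in 1:25) {
    genes <- sprintf("g%03d", 1:40)
    uni <- split(genes, rep(1:4, each = 10))
    names(uni) <- paste0("G", 1:4)
    clustered <- lapply(uni, function(g) sample(g, sample(0:10, 1)))
    og <- structure(list(
      family_ids = "OG1", genomes = names(uni),
      members = matrix(clustered, 1L, 4L,
                       dimnames = list("OG1", names(uni)))),
      class = "orthogroup_table")
    expect_equal(count_singletons(og, uni),
                 length(setdiff(genes, unlist(clustered))))
  }
})

test_that("rarefaction endpoints, exhaustiveness and medians are exact", {
  sp <- pangenome_sim_spec(4L, 6L, 2L, 3L, 1L, seed = 5L)
  m <- generate_pangenome_matrix(sp)$matrix
  rr <- rarefy(m, reps = 1000L, seed = 11L)
  f <- nrow(m$occupancy)
  core_n <- sum(rowSums(m$occupancy) == 4L)
  # k = N: single subset, pan = F, core = core-class count
  expect_true(all(rr$pan[[4L]] == f))
  expect_true(all(rr$core[[4L]] == core_n))
  # k = 1: pan = core = that genome's family count
  expect_true(all(rr$pan[[1L]] == rr$core[[1L]]))
  expect_setequal(unique(rr$pan[[1L]]), unname(colSums(m$occupancy)))
  # every k enumerable within 1000 reps -> exhaustive, equal to the oracle
  expect_true(all(rr$exhaustive))
  for (k in 1:4) {
    ora <- oracle_rarefaction_exhaustive(m$occupancy, k)
    expect_equal(stats::median(rr$pan[[k]]), stats::median(ora$pan))
    expect_equal(stats::median(rr$core[[k]]), stats::median(ora$core))
  }
  # median monotonicity
  expect_true(all(diff(rr$pan_median) >= 0))
  expect_true(all(diff(rr$core_median) <= 0))
})

test_that("sampled medians agree with exhaustive enumeration on 5-6 genomes", {
  set.seed(23)
  for (n in 5:6) {
    sp <- pangenome_sim_spec(n, 10L, 3L, 8L, 2L, seed = n)
    m <- generate_pangenome_matrix(sp)$matrix
    # small reps forces the sampling path for mid k
    rr <- rarefy(m, reps = 9L, seed = 3L)
    expect_false(all(rr$exhaustive))
    rr_big <- rarefy(m, reps = 2000L, seed = 4L)
    for (k in seq_len(n)) {
      ora <- oracle_rarefaction_exhaustive(m$occupancy, k)
      expect_equal(stats::median(rr_big$pan[[k]]), stats::median(ora$pan),
                   tolerance = 1e-12)
      expect_equal(stats::median(rr_big$core[[k]]), stats::median(ora$core))
    }
  }
})

test_that("plateau detection matches its definition and the scan oracle", {
  med <- c(100, 150, 160, 160.1, 160.1)
  expect_equal(detect_plateau(list(pan_median = med)), 4L)
  expect_true(is.na(detect_plateau(list(pan_median = cumprod(rep(1.01, 10)) * 100))))
  expect_error(detect_plateau(list(pan_median = c(0, 1, 2))), "zero")
  set.seed(31)
  for (rep in 1:300) {
    n <- sample(4:12, 1L)
    med <- 100 * cumprod(1 + stats::runif(n, 0, 0.02))
    expect_identical(detect_plateau(list(pan_median = med)),
                     oracle_plateau(med))
  }
})

test_that("growth models recover zero-noise parameters and beat a grid search", {
  k <- 1:10
  rr <- list(k = k, pan_median = 500 * k^0.4 + 100,
             core_median = 2000 * exp(-0.3 * k) + 900)
  fit <- fit_growth_models(rr)
  expect_equal(fit$pan$A, 500, tolerance = 1e-6)
  expect_equal(fit$pan$B, 0.4, tolerance = 1e-6)
  expect_equal(fit$pan$C, 100, tolerance = 1e-6)
  expect_equal(fit$core$A, 2000, tolerance = 1e-6)
  expect_equal(fit$core$B, 0.3, tolerance = 1e-6)
  expect_equal(fit$core$C, 900, tolerance = 1e-6)
  # constant core: degenerate decay with zero amplitude
  flat <- list(k = 1:6, pan_median = 100 * (1:6)^0.5,
               core_median = rep(42, 6L))
  ffit <- fit_growth_models(flat)
  expect_equal(ffit$core$A, 0)
  expect_equal(ffit$core$C, 42)
  expect_equal(ffit$core$rss, 0)
  # fitted RSS never worse than a 50^3 grid search
  set.seed(41)
  for (rep in 1:8) {
    kk <- 1:8
    y_pan <- runif(1, 100, 800) * kk^runif(1, 0.2, 0.9) +
      runif(1, 0, 500) + rnorm(8L, 0, 5)
    y_core <- runif(1, 200, 900) * exp(-runif(1, 0.1, 0.8) * kk) +
      runif(1, 100, 600) + rnorm(8L, 0, 5)
    fit <- fit_growth_models(list(k = kk, pan_median = y_pan,
                                  core_median = y_core))
    expect_lte(fit$pan$rss, oracle_grid_rss(kk, y_pan, "power") + 1e-8)
    expect_lte(fit$core$rss, oracle_grid_rss(kk, y_core, "expdecay") + 1e-8)
  }
})
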