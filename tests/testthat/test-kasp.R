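mk_kasp <- function(calls, superior = rep("A", nrow(calls)), donor = "donor") {
  kasp_matrix(calls, superior, donor)
}

test_that("markers where all cultivars share the donor call are monomorphic", {
  calls <- matrix("A", 4L, 5L,
                  dimnames = list(paste0("M", 1:4), c("donor", paste0("c", 1:4))))
  sc <- score_markers(mk_kasp(calls))
  expect_false(any(sc$markers$polymorphic))
})

test_that("a 23-marker matrix with 20 planted differences scores 20 polymorphic", {
  calls <- matrix("A", 23L, 16L,
                  dimnames = list(sprintf("CKAM%04d", 2207 + 1:23),
                                  c("donor", sprintf("cv%02d", 1:15))))
  set.seed(2)
  poly <- sample(23L, 20L)
  for (m in poly) {
    calls[m, 1L + sample(15L, sample(1:15, 1L))] <- "B"
  }
  sc <- score_markers(mk_kasp(calls))
  expect_equal(sum(sc$markers$polymorphic), 20L)
  expect_setequal(which(sc$markers$polymorphic), poly)
})

test_that("H and NA are excluded from comparison; all-NA markers flagged", {
  calls <- matrix(c("A", "H", NA, "A",
                    "A", "B", "H", NA,
                    NA, NA, NA, NA),
                  3L, 4L, byrow = TRUE,
                  dimnames = list(paste0("M", 1:3),
                                  c("donor", "c1", "c2", "c3")))
  sc <- score_markers(mk_kasp(calls))
  expect_false(sc$markers$polymorphic[1L])   # only H/NA differ
  expect_true(sc$markers$polymorphic[2L])
  expect_true(sc$markers$uninformative[3L])
  expect_equal(sc$markers$n_het[1L], 1L)
  expect_equal(sc$markers$n_missing[1L], 1L)
})

test_that("superior-allele carriage requires a homozygous superior call", {
  calls <- matrix(c("A", "B", "H", NA), 1L, 4L,
                  dimnames = list("M1", c("donor", "c1", "c2", "c3")))
  sc <- score_markers(mk_kasp(calls, superior = "A"))
  expect_identical(unname(sc$presence["M1", ]), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("polymorphism flags equal a direct column-comparison oracle", {
  set.seed(93)
  for (r in 1:30) {
    n_m <- sample(5:25, 1L); n_c <- sample(4:16, 1L)
    calls <- matrix(sample(c("A", "B", "H", NA), n_m * n_c, replace = TRUE,
                           prob = c(0.4, 0.4, 0.1, 0.1)),
                    n_m, n_c,
                    dimnames = list(paste0("M", seq_len(n_m)),
                                    c("donor", paste0("c", seq_len(n_c - 1L)))))
    sc <- score_markers(mk_kasp(calls))
    for (i in seq_len(n_m)) {
      d <- calls[i, "donor"]
      oth <- calls[i, -1L]
      oth <- oth[!is.na(oth) & oth != "H"]
      ora_uninf <- all(is.na(calls[i, ])) || is.na(d) || d == "H" ||
        length(oth) == 0L
      if (ora_uninf) {
        expect_true(sc$markers$uninformative[i])
        expect_false(sc$markers$polymorphic[i])
      } else {
        expect_identical(sc$markers$polymorphic[i], any(oth != d))
      }
    }
    # column permutation leaves flags unchanged
    perm <- c("donor", sample(colnames(calls)[-1L]))
    sc2 <- score_markers(mk_kasp(calls[, perm]))
    expect_identical(sc2$markers$polymorphic, sc$markers$polymorphic)
  }
})
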