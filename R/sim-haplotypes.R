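#' SNP genotype matrix
#'
#' Accessions x biallelic SNP sites with calls coded `0` (hom-ref), `1`
#' (het), `2` (hom-alt) or `NA` (missing), plus per-site metadata.
#'
#' @param calls Integer matrix (accessions in rows, sites in columns) with
#'   values in `{0, 1, 2, NA}`.
#' @param sites Data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (single bases; sites must be sorted by position within chromosome).
#' @param accessions Accession names (default rownames of `calls`).
#' @return Object of class `snp_matrix`.
#' @export
snp_matrix <- function(calls, sites, accessions = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(ncol(calls) == nrow(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  if (!all(calls %in% c(0L, 1L, 2L, NA_integer_))) {
    stop("calls must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (any(nchar(sites$ref) != 1L | nchar(sites$alt) != 1L)) {
    stop("sites must be biallelic SNPs", call. = FALSE)
  }
  if (is.unsorted(order(sites$chrom, sites$pos))) {
    ord <- order(sites$chrom, sites$pos)
    sites <- sites[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
  }
  if (is.null(accessions)) accessions <- sprintf("acc%04d", seq_len(nrow(calls)))
  rownames(calls) <- accessions
  structure(list(calls = calls, sites = sites, accessions = accessions),
            class = "snp_matrix")
}

#' Specification for a synthetic haplotype-phenotype dataset
#'
#' Defaults emulate a single-gene haplotype/100-seed-weight analysis: two
#' planted haplotypes whose means are the published extremes for a
#' superior/inferior haplotype pair (29.84 g and 14.66 g), homoscedastic
#' Gaussian noise, and low heterozygous/missing call rates.
#'
#' @param n_accessions Number of accessions.
#' @param n_snps Number of SNP sites in the gene.
#' @param n_haplotypes Number of planted haplotypes (<= 2^n_snps).
#' @param means Per-haplotype trait means in grams.
#' @param noise_sd Trait noise sd in grams (> 0).
#' @param het_rate,missing_rate Per-cell probabilities of a heterozygous /
#'   missing call overwriting the planted genotype.
#' @param seed Integer seed.
#' @return Object of class `haplotype_sim_spec`.
#' @export
haplotype_sim_spec <- function(n_accessions = 200L, n_snps = 6L,
                               n_haplotypes = 2L,
                               means = c(29.84, 14.66), noise_sd = 3,
                               het_rate = 0.02, missing_rate = 0.02,
                               seed = 1L) {
  stopifnot(n_accessions >= 2L, n_snps >= 1L, noise_sd > 0,
            length(means) == n_haplotypes,
            het_rate >= 0, het_rate <= 1, missing_rate >= 0, missing_rate <= 1)
  if (n_haplotypes > 2^n_snps) {
    stop("n_haplotypes exceeds the 2^n_snps distinct allele strings",
         call. = FALSE)
  }
  structure(
    list(n_accessions = as.integer(n_accessions), n_snps = as.integer(n_snps),
         n_haplotypes = as.integer(n_haplotypes), means = as.numeric(means),
         noise_sd = noise_sd, het_rate = het_rate,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "haplotype_sim_spec"
  )
}

#' Generate a SNP matrix and phenotype table with planted haplotype effects
#'
#' Assigns accessions to haplotypes near-evenly, builds their hom-ref /
#' hom-alt allele strings from distinct binary patterns, overwrites calls
#' with het or missing at the spec rates, and draws the trait as the
#' haplotype mean plus Gaussian noise.  The truth records each accession's
#' planted haplotype and the superior haplotype (largest mean).
#'
#' @param spec A [haplotype_sim_spec()].
#' @return List with `genotypes` (a [snp_matrix()]), `phenotypes`
#'   (data.frame `accession`, `value`), and `truth` (list: `assignment`
#'   named integer vector, `patterns` haplotype x site 0/2 matrix,
#'   `means`, `superior` index of the planted superior haplotype).
#' @export
generate_haplotype_dataset <- function(spec) {
  stopifnot(inherits(spec, "haplotype_sim_spec"))
  with_seed(derive_seed(spec$seed, "haplotypes"), {
    # distinct binary site patterns, one per haplotype
    max_pat <- 2^spec$n_snps
    pat_idx <- sample.int(max_pat, spec$n_haplotypes) - 1L
    patterns <- t(vapply(pat_idx, function(v)
      as.integer(intToBits(v))[seq_len(spec$n_snps)] * 2L,
      integer(spec$n_snps)))
    # near-even assignment, order shuffled
    assignment <- sample(rep_len(seq_len(spec$n_haplotypes), spec$n_accessions))
    calls <- patterns[assignment, , drop = FALSE]
    n_cell <- length(calls)
    het <- matrix(stats::runif(n_cell) < spec$het_rate, nrow(calls))
    calls[het] <- 1L
    miss <- matrix(stats::runif(n_cell) < spec$missing_rate, nrow(calls))
    calls[miss & !het] <- NA_integer_
    accessions <- sprintf("acc%04d", seq_len(spec$n_accessions))
    rownames(calls) <- accessions
    sites <- data.frame(chrom = "Ca4",
                        pos = 13239546L + 100L * seq_len(spec$n_snps),
                        ref = rep_len(c("A", "C", "G", "T"), spec$n_snps),
                        alt = rep_len(c("G", "T", "A", "C"), spec$n_snps),
                        stringsAsFactors = FALSE)
    phenotypes <- data.frame(
      accession = accessions,
      value = spec$means[assignment] +
        stats::rnorm(spec$n_accessions, 0, spec$noise_sd),
      stringsAsFactors = FALSE)
    names(assignment) <- accessions
    list(genotypes = snp_matrix(calls, sites, accessions),
         phenotypes = phenotypes,
         truth = list(assignment = assignment, patterns = patterns,
                      means = spec$means, superior = which.max(spec$means)))
  })
}

#' Read a phenotype table
#'
#' CSV with a header row and columns `accession` and one trait value
#' column; values must be finite and unique per accession.
#'
#' @param path CSV path.
#' @param trait Name of the value column (default: the second column).
#' @return Data.frame with columns `accession`, `value`.
#' @export
read_phenotypes <- function(path, trait = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"accession" %in% names(df)) {
    stop("phenotype table needs an 'accession' column", call. = FALSE)
  }
  if (is.null(trait)) trait <- setdiff(names(df), "accession")[1L]
  out <- data.frame(accession = as.character(df$accession),
                    value = as.numeric(df[[trait]]),
                    stringsAsFactors = FALSE)
  if (any(!is.finite(out$value))) {
    stop("non-finite trait value(s) in phenotype table", call. = FALSE)
  }
  if (anyDuplicated(out$accession)) {
    stop("duplicate accession(s) in phenotype table", call. = FALSE)
  }
  out
}
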