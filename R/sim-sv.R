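#' Generate per-sample SV call sets with known cluster structure
#'
#' Plants `n_clusters` SV cluster centroids on one chromosome, spaced by
#' `gap` bp, each with a random type, strand pair and length (>= 50 bp).
#' Every cluster is observed in a random subset of samples (at least one);
#' member coordinates are the centroid plus Gaussian jitter of sd
#' `jitter_sd`.  Clusters are separable by construction: `jitter_sd` above
#' half the minimum inter-cluster gap is an error, so a correct merge can
#' be scored exactly against the planted truth.
#'
#' @param n_samples Number of samples.
#' @param n_clusters Number of planted clusters.
#' @param jitter_sd Coordinate jitter sd in bp (default 50).
#' @param seed Integer seed.
#' @param gap Distance between consecutive cluster centroids (default 10000).
#' @param chrom Chromosome name.
#' @return List with `callsets` (named list of per-sample data.frames with
#'   columns `sample`, `chrom`, `start`, `end`, `type`, `strands`,
#'   `length`), `truth` (per-cluster data.frame: `cluster`, `chrom`,
#'   `start`, `end`, `type`, `strands`, `support`), and `records` (all
#'   records with their true `cluster` id).
#' @export
generate_sv_callsets <- function(n_samples = 5L, n_clusters = 20L,
                                 jitter_sd = 50, seed = 1L,
                                 gap = 10000L, chrom = "Ca1") {
  stopifnot(n_samples >= 1L, n_clusters >= 1L)
  if (jitter_sd > gap / 2) {
    stop("jitter_sd exceeds half the inter-cluster gap; clusters not separable",
         call. = FALSE)
  }
  types <- c("INS", "DEL", "INV", "DUP")
  strand_pairs <- c("+-", "-+", "++", "--")
  samples <- sprintf("S%02d", seq_len(n_samples))
  with_seed(derive_seed(seed, "sv"), {
    cent_start <- 10000L + gap * (seq_len(n_clusters) - 1L)
    cent_type <- sample(types, n_clusters, replace = TRUE)
    cent_strands <- sample(strand_pairs, n_clusters, replace = TRUE)
    cent_len <- sample(50:5000, n_clusters, replace = TRUE)
    cent_end <- ifelse(cent_type == "INS", cent_start,
                       cent_start + cent_len - 1L)
    support <- vapply(seq_len(n_clusters), function(i)
      sample.int(n_samples, 1L), 0L)
    members <- list()
    for (i in seq_len(n_clusters)) {
      carriers <- sort(sample.int(n_samples, support[i]))
      for (s in carriers) {
        st <- cent_start[i] +
          as.integer(round(stats::rnorm(1L, 0, jitter_sd)))
        len <- max(50L, cent_len[i] +
                     as.integer(round(stats::rnorm(1L, 0, jitter_sd / 5))))
        en <- if (cent_type[i] == "INS") st else st + len - 1L
        members[[length(members) + 1L]] <- data.frame(
          sample = samples[s], chrom = chrom, start = st, end = en,
          type = cent_type[i], strands = cent_strands[i], length = len,
          cluster = i, stringsAsFactors = FALSE)
      }
    }
    records <- do.call(rbind, members)
    rownames(records) <- NULL
    callsets <- split(records[, setdiff(names(records), "cluster")],
                      records$sample)
    truth <- data.frame(cluster = seq_len(n_clusters), chrom = chrom,
                        start = cent_start, end = cent_end,
                        type = cent_type, strands = cent_strands,
                        support = support, stringsAsFactors = FALSE)
    list(callsets = callsets, truth = truth, records = records)
  })
}
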