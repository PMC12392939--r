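#' Specification for a synthetic pan-genome matrix
#'
#' Defaults reproduce the composition of a 17-genome cultivated-chickpea
#' pan-genome: 17,483 core, 2,656 softcore, 13,986 dispensable and 220
#' private gene families (34,345 in total).  The dispensable occupancy
#' profile defaults to a decreasing `1/o` weight over occupancies
#' `2..n_genomes-2`, the shape typical of crop pan-genome occupancy
#' histograms.
#'
#' @param n_genomes Number of genomes (>= 3).
#' @param n_core,n_softcore,n_dispensable,n_private Family counts per class.
#' @param dispensable_occupancy Probability vector over occupancies
#'   `2..n_genomes-2` (normalised internally).
#' @param seed Integer seed.
#' @return Object of class `pangenome_sim_spec`.
#' @export
pangenome_sim_spec <- function(n_genomes = 17L, n_core = 17483L,
                               n_softcore = 2656L, n_dispensable = 13986L,
                               n_private = 220L,
                               dispensable_occupancy = NULL, seed = 1L) {
  if (n_genomes < 3L) stop("need at least 3 genomes", call. = FALSE)
  if (any(c(n_core, n_softcore, n_dispensable, n_private) < 0L)) {
    stop("class counts must be non-negative", call. = FALSE)
  }
  occ_levels <- seq(2L, n_genomes - 2L)
  if (is.null(dispensable_occupancy)) {
    dispensable_occupancy <- (1 / occ_levels) / sum(1 / occ_levels)
  }
  if (length(dispensable_occupancy) != length(occ_levels)) {
    stop("dispensable_occupancy must cover occupancies 2..n_genomes-2",
         call. = FALSE)
  }
  if (any(dispensable_occupancy < 0)) {
    stop("occupancy weights must be non-negative", call. = FALSE)
  }
  dispensable_occupancy <- dispensable_occupancy / sum(dispensable_occupancy)
  structure(
    list(n_genomes = as.integer(n_genomes), n_core = as.integer(n_core),
         n_softcore = as.integer(n_softcore),
         n_dispensable = as.integer(n_dispensable),
         n_private = as.integer(n_private),
         dispensable_occupancy = dispensable_occupancy,
         occ_levels = occ_levels, seed = as.integer(seed)),
    class = "pangenome_sim_spec"
  )
}

# integer allocation of `total` across weights: floor + largest remainder,
# so realized occupancy histograms match the spec exactly
exact_partition <- function(total, weights) {
  raw <- weights * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a presence/absence matrix with known class structure
#'
#' Core families occupy every genome; each softcore family is absent from
#' one (randomly chosen) genome; dispensable family occupancies follow the
#' spec's occupancy distribution by exact partition (not sampling), with
#' member genomes drawn uniformly; private families are assigned to
#' genomes round-robin.  Realized per-class counts equal the spec counts
#' exactly.
#'
#' @param spec A [pangenome_sim_spec()].
#' @return List with `matrix` (a [pa_matrix()]) and `truth` (factor of
#'   planted classes, named by family id).
#' @export
generate_pangenome_matrix <- function(spec) {
  stopifnot(inherits(spec, "pangenome_sim_spec"))
  n <- spec$n_genomes
  f <- spec$n_core + spec$n_softcore + spec$n_dispensable + spec$n_private
  occ <- matrix(FALSE, f, n)
  truth <- character(f)
  with_seed(derive_seed(spec$seed, "pangenome"), {
    i <- 0L
    if (spec$n_core > 0L) {
      occ[i + seq_len(spec$n_core), ] <- TRUE
      truth[i + seq_len(spec$n_core)] <- "core"
      i <- i + spec$n_core
    }
    if (spec$n_softcore > 0L) {
      rows <- i + seq_len(spec$n_softcore)
      occ[rows, ] <- TRUE
      miss <- sample.int(n, spec$n_softcore, replace = TRUE)
      occ[cbind(rows, miss)] <- FALSE
      truth[rows] <- "softcore"
      i <- i + spec$n_softcore
    }
    if (spec$n_dispensable > 0L) {
      per_occ <- exact_partition(spec$n_dispensable, spec$dispensable_occupancy)
      for (j in seq_along(spec$occ_levels)) {
        o <- spec$occ_levels[j]
        for (r in seq_len(per_occ[j])) {
          i <- i + 1L
          occ[i, sample.int(n, o)] <- TRUE
          truth[i] <- "dispensable"
        }
      }
    }
    if (spec$n_private > 0L) {
      rows <- i + seq_len(spec$n_private)
      occ[cbind(rows, rep_len(seq_len(n), spec$n_private))] <- TRUE
      truth[rows] <- "private"
      i <- i + spec$n_private
    }
  })
  family_ids <- sprintf("OG%06d", seq_len(f))
  genome_ids <- sprintf("G%02d", seq_len(n))
  truth <- factor(truth, levels = c("core", "softcore", "dispensable", "private"))
  names(truth) <- family_ids
  list(matrix = pa_matrix(occ, family_ids = family_ids, genome_ids = genome_ids),
       truth = truth)
}

#' Build an orthogroup table from a presence/absence matrix
#'
#' Inflates a [pa_matrix()] into an `orthogroup_table` with one synthetic
#' gene id per present cell, so the TSV writer/reader round trip can be
#' exercised on generated data.
#'
#' @param matrix A [pa_matrix()].
#' @return An `orthogroup_table`.
#' @export
pa_matrix_to_orthogroups <- function(matrix) {
  occ <- matrix$occupancy
  members <- base::matrix(rep(list(character(0)), length(occ)),
                          nrow = nrow(occ), dimnames = dimnames(occ))
  for (j in seq_len(ncol(occ))) {
    present <- which(occ[, j])
    ids <- paste0(matrix$genome_ids[j], "_g", seq_along(present))
    members[cbind(present, j)] <- as.list(ids)
  }
  structure(
    list(family_ids = matrix$family_ids, genomes = matrix$genome_ids,
         members = members),
    class = "orthogroup_table"
  )
}
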