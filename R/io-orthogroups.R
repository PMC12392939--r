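#' Presence/absence matrix of gene families across genomes
#'
#' The substrate of all pan-genome computation: a families x genomes
#' occupancy grid, optionally with per-cell gene counts (a family may hold
#' several genes of one genome).
#'
#' @param occupancy Logical matrix, families in rows, genomes in columns.
#' @param counts Optional integer matrix of per-cell gene counts; defaults
#'   to `occupancy` coerced to 0/1.  Must be positive exactly where
#'   `occupancy` is `TRUE`.
#' @param family_ids,genome_ids Row / column identifiers; default to the
#'   dimnames of `occupancy`.
#' @return An object of class `pa_matrix`: a list with elements
#'   `occupancy`, `counts`, `family_ids`, `genome_ids`.
#' @export
pa_matrix <- function(occupancy, counts = NULL, family_ids = rownames(occupancy),
                      genome_ids = colnames(occupancy)) {
  occupancy <- as.matrix(occupancy)
  storage.mode(occupancy) <- "logical"
  if (ncol(occupancy) < 2L) {
    stop("a presence/absence matrix needs at least 2 genomes", call. = FALSE)
  }
  if (is.null(family_ids)) family_ids <- paste0("OG", seq_len(nrow(occupancy)))
  if (is.null(genome_ids)) genome_ids <- paste0("G", seq_len(ncol(occupancy)))
  empty <- which(rowSums(occupancy) == 0L)
  if (length(empty) > 0L) {
    stop("families with no member genome: ", paste(family_ids[empty], collapse = ", "),
         call. = FALSE)
  }
  if (is.null(counts)) {
    counts <- matrix(as.integer(occupancy), nrow(occupancy))
  } else {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (!all((counts > 0L) == occupancy)) {
      stop("counts must be positive exactly where occupancy is TRUE", call. = FALSE)
    }
  }
  dimnames(occupancy) <- dimnames(counts) <- list(family_ids, genome_ids)
  structure(
    list(occupancy = occupancy, counts = counts,
         family_ids = family_ids, genome_ids = genome_ids),
    class = "pa_matrix"
  )
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat(sprintf("<pa_matrix> %d gene families x %d genomes (%d genes)\n",
              nrow(x$occupancy), ncol(x$occupancy), sum(x$counts)))
  invisible(x)
}

#' Read an orthogroup membership table
#'
#' Reads the tab-separated orthogroup dialect written by ortholog-inference
#' tools: a header row of genome names (first column the family id), then
#' one row per gene family with comma+space separated gene identifiers per
#' genome (empty cell = family absent from that genome).
#'
#' @param path Path to the TSV file.
#' @return A list with components `orthogroups` (class `orthogroup_table`:
#'   `family_ids`, `genomes`, and `members`, a families x genomes list
#'   matrix of gene-id character vectors) and `matrix` (a [pa_matrix] whose
#'   cell counts are the per-cell gene counts).
#' @export
read_orthogroups <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("orthogroup file has no data rows", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  n_col <- length(header)
  genomes <- header[-1L]
  # trailing empty cells are dropped by strsplit; pad, but flag over-long rows
  widths <- lengths(fields[-1L])
  bad <- which(widths > n_col)
  if (length(bad) > 0L) {
    stop(sprintf("ragged orthogroup row at line %d: %d fields, expected %d",
                 bad[1L] + 1L, widths[bad[1L]], n_col), call. = FALSE)
  }
  rows <- lapply(fields[-1L], function(f) c(f, rep("", n_col - length(f))))
  family_ids <- vapply(rows, `[[`, "", 1L)
  dup <- family_ids[duplicated(family_ids)]
  if (length(dup) > 0L) {
    stop("duplicated orthogroup id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  cell_mat <- matrix(unlist(rows), nrow = length(rows), byrow = TRUE)[, -1L,
                                                                     drop = FALSE]
  members <- strsplit(cell_mat, ", ", fixed = TRUE)
  members[cell_mat == ""] <- list(character(0))
  dim(members) <- dim(cell_mat)
  dimnames(members) <- list(family_ids, genomes)
  counts <- matrix(lengths(members), nrow = length(rows),
                   dimnames = dimnames(members))
  all_genes <- unlist(members, use.names = FALSE)
  dup_gene <- unique(all_genes[duplicated(all_genes)])
  if (length(dup_gene) > 0L) {
    stop("gene id assigned to more than one family: ",
         paste(utils::head(dup_gene, 5L), collapse = ", "), call. = FALSE)
  }
  og <- structure(
    list(family_ids = family_ids, genomes = genomes, members = members),
    class = "orthogroup_table"
  )
  list(orthogroups = og,
       matrix = pa_matrix(counts > 0L, counts, family_ids, genomes))
}

#' Write an orthogroup membership table
#'
#' Inverse of [read_orthogroups()]; the written file round-trips exactly.
#'
#' @param orthogroups An `orthogroup_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(orthogroups, path) {
  stopifnot(inherits(orthogroups, "orthogroup_table"))
  m <- orthogroups$members
  cells <- vapply(m, paste, "", collapse = ", ")
  dim(cells) <- dim(m)
  body <- do.call(paste, c(list(orthogroups$family_ids),
                           lapply(seq_len(ncol(cells)), function(j) cells[, j]),
                           sep = "\t"))
  writeLines(c(paste(c("Orthogroup", orthogroups$genomes), collapse = "\t"), body),
             path)
  invisible(path)
}
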