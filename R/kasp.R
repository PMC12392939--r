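#' KASP genotype matrix
#'
#' Markers x cultivars call matrix from a KASP (Kompetitive Allele-Specific
#' PCR) assay panel.  Calls are matrix-local allele codes `A`/`B`, `H`
#' (heterozygous) or `NA`; per-marker metadata names the allele linked to
#' the superior haplotype and the donor genotype carrying it.
#'
#' @param calls Character matrix (markers in rows, cultivars in columns)
#'   with values in `{"A","B","H",NA}`.
#' @param superior_allele Character vector (`"A"` or `"B"` per marker).
#' @param donor Donor cultivar id; must be a column of `calls`.
#' @return Object of class `kasp_matrix`.
#' @export
kasp_matrix <- function(calls, superior_allele, donor) {
  calls <- as.matrix(calls)
  if (!all(calls %in% c("A", "B", "H", NA_character_))) {
    stop("calls must be A, B, H or NA", call. = FALSE)
  }
  if (length(superior_allele) != nrow(calls) ||
      !all(superior_allele %in% c("A", "B"))) {
    stop("superior_allele must be A or B for every marker", call. = FALSE)
  }
  if (!donor %in% colnames(calls)) {
    stop("donor ", donor, " not among cultivar columns", call. = FALSE)
  }
  structure(list(calls = calls, superior_allele = superior_allele,
                 donor = donor,
                 markers = rownames(calls), cultivars = colnames(calls)),
            class = "kasp_matrix")
}

#' Read a KASP matrix from CSV
#'
#' Header row of cultivar names; first column `marker`, second column
#' `superior_allele`, remaining columns the per-cultivar calls.
#'
#' @param path CSV path.
#' @param donor Donor cultivar id.
#' @return A [kasp_matrix()].
#' @export
read_kasp <- function(path, donor) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("marker", "superior_allele") %in% names(df)))
  calls <- as.matrix(df[, setdiff(names(df), c("marker", "superior_allele"))])
  calls[calls == ""] <- NA_character_
  rownames(calls) <- df$marker
  kasp_matrix(calls, df$superior_allele, donor)
}

#' Score KASP markers for polymorphism and superior-allele presence
#'
#' A marker is polymorphic when at least one non-donor cultivar's call
#' differs from the donor's call; heterozygous and missing calls are
#' excluded from that comparison (but reported).  A cultivar carries the
#' superior allele at a marker iff it is homozygous for the
#' superior-linked allele (heterozygous calls never count).  Markers with
#' all calls missing, or no usable donor call, are flagged uninformative.
#'
#' @param x A [kasp_matrix()].
#' @return List: `markers` (data.frame `marker`, `polymorphic`,
#'   `uninformative`, `n_compared`, `n_het`, `n_missing`) and `presence`
#'   (markers x cultivars logical matrix of superior-allele carriage).
#' @export
score_markers <- function(x) {
  stopifnot(inherits(x, "kasp_matrix"))
  donor_calls <- x$calls[, x$donor]
  others <- x$calls[, setdiff(x$cultivars, x$donor), drop = FALSE]
  n_m <- nrow(x$calls)
  res <- data.frame(marker = x$markers, polymorphic = FALSE,
                    uninformative = FALSE, n_compared = 0L,
                    n_het = 0L, n_missing = 0L, stringsAsFactors = FALSE)
  for (i in seq_len(n_m)) {
    calls <- others[i, ]
    res$n_het[i] <- sum(!is.na(calls) & calls == "H")
    res$n_missing[i] <- sum(is.na(calls))
    usable <- !is.na(calls) & calls %in% c("A", "B")
    res$n_compared[i] <- sum(usable)
    if (all(is.na(x$calls[i, ])) ||
        is.na(donor_calls[i]) || !donor_calls[i] %in% c("A", "B") ||
        sum(usable) == 0L) {
      res$uninformative[i] <- TRUE
      next
    }
    res$polymorphic[i] <- any(calls[usable] != donor_calls[i])
  }
  presence <- x$calls == matrix(x$superior_allele, n_m, ncol(x$calls))
  presence[is.na(x$calls)] <- FALSE
  dimnames(presence) <- dimnames(x$calls)
  list(markers = res, presence = presence)
}
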