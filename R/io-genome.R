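#' Construct a gene model
#'
#' One protein-coding gene: chromosome, strand, exon and CDS intervals
#' (1-based closed, stored ascending regardless of strand; transcription
#' order on the minus strand is handled downstream).  5'/3' UTR intervals
#' are derived as exon minus CDS, sided by strand.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome / sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (start, end) of exon intervals.
#' @param cds Two-column matrix of CDS intervals; may have zero rows for a
#'   non-coding model.
#' @param phase Integer vector of CDS phases (bases to skip before the
#'   first complete codon), one per CDS interval; defaults to zeros.
#' @return Object of class `gene_model` with fields `gene_id`, `chrom`,
#'   `strand`, `exons`, `cds`, `phase`, `utr5`, `utr3`, and `coding`
#'   (FALSE when the CDS length fails the mod-3 rule; such genes are
#'   excluded from coding-effect classification).
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds = NULL, phase = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] < exons[, 1L])) {
    stop("gene ", gene_id, ": exon end before start", call. = FALSE)
  }
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] <= exons[-nrow(exons), 2L])) {
    stop("gene ", gene_id, ": overlapping exons", call. = FALSE)
  }
  if (is.null(cds) || length(cds) == 0L) {
    cds <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  } else {
    cds <- matrix(as.integer(cds), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
    cds <- cds[order(cds[, 1L]), , drop = FALSE]
  }
  if (is.null(phase)) phase <- rep(0L, nrow(cds))
  phase <- as.integer(phase)[order(cds[, 1L])]
  # each CDS interval must sit inside an exon
  for (i in seq_len(nrow(cds))) {
    inside <- any(cds[i, 1L] >= exons[, 1L] & cds[i, 2L] <= exons[, 2L])
    if (!inside) {
      stop("gene ", gene_id, ": CDS interval [", cds[i, 1L], ",", cds[i, 2L],
           "] not contained in any exon", call. = FALSE)
    }
  }
  coding <- nrow(cds) > 0L
  if (coding) {
    first_phase <- if (strand == "+") phase[1L] else phase[length(phase)]
    total <- sum(cds[, 2L] - cds[, 1L] + 1L)
    if ((total - first_phase) %% 3L != 0L) {
      warning("gene ", gene_id,
              ": CDS length not a multiple of 3; excluded from coding-effect calls",
              call. = FALSE)
      coding <- FALSE
    }
  }
  # UTRs: exon minus CDS, sided by position relative to the CDS span
  utr5 <- utr3 <- matrix(integer(0), ncol = 2L,
                         dimnames = list(NULL, c("start", "end")))
  if (nrow(cds) > 0L) {
    ex <- IRanges::IRanges(exons[, 1L], exons[, 2L])
    cd <- IRanges::IRanges(cds[, 1L], cds[, 2L])
    rest <- IRanges::setdiff(ex, cd)
    if (length(rest) > 0L) {
      left <- IRanges::end(rest) < min(cds[, 1L])
      right <- IRanges::start(rest) > max(cds[, 2L])
      up <- if (strand == "+") left else right
      down <- if (strand == "+") right else left
      as_mat <- function(r) matrix(c(IRanges::start(r), IRanges::end(r)),
                                   ncol = 2L, dimnames = list(NULL, c("start", "end")))
      utr5 <- as_mat(rest[up])
      utr3 <- as_mat(rest[down])
    }
  }
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         exons = exons, cds = cds, phase = phase,
         utr5 = utr5, utr3 = utr3, coding = coding),
    class = "gene_model"
  )
}

#' Gene span (1-based closed)
#' @param gene A `gene_model`.
#' @return Integer vector `c(start, end)`.
#' @export
gene_span <- function(gene) {
  c(min(gene$exons[, 1L]), max(gene$exons[, 2L]))
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 with the gene -> mRNA -> exon/CDS hierarchy via
#' \pkg{rtracklayer} and materialises one [gene_model()] per gene.  When a
#' gene has several transcripts the primary (first listed) transcript is
#' used by default; `transcripts = "all"` returns one model per
#' transcript, named `gene_id|mrna_id`.
#'
#' @param path Path to a GFF3 file.
#' @param genome Optional `DNAStringSet`; when supplied, GFF3 seqids must
#'   all be present among its names.
#' @param transcripts `"primary"` (default) or `"all"`.
#' @return Named list of `gene_model` objects.
#' @export
read_gene_models <- function(path, genome = NULL, transcripts = c("primary", "all")) {
  transcripts <- match.arg(transcripts)
  gr <- rtracklayer::import(path, format = "gff3")
  if (!is.null(genome)) {
    missing_seq <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                           names(genome))
    if (length(missing_seq) > 0L) {
      stop("GFF3 seqids absent from genome: ",
           paste(missing_seq, collapse = ", "), call. = FALSE)
    }
  }
  df <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    parent = vapply(as.list(gr$Parent), function(p)
      if (length(p)) as.character(p[[1L]]) else NA_character_, ""),
    phase = if (!is.null(gr$phase)) as.integer(gr$phase) else NA_integer_,
    stringsAsFactors = FALSE
  )
  genes <- df[df$type == "gene", ]
  mrnas <- df[df$type == "mRNA", ]
  out <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$id[i]
    tx <- mrnas[mrnas$parent == gid, , drop = FALSE]
    if (nrow(tx) == 0L) next
    use <- if (transcripts == "primary") 1L else seq_len(nrow(tx))
    for (t in use) {
      tid <- tx$id[t]
      ex <- df[df$type == "exon" & df$parent == tid, , drop = FALSE]
      cd <- df[df$type == "CDS" & df$parent == tid, , drop = FALSE]
      nm <- if (transcripts == "all") paste0(gid, "|", tid) else gid
      phase <- cd$phase
      phase[is.na(phase)] <- 0L
      out[[nm]] <- gene_model(
        gene_id = gid, chrom = genes$seqid[i], strand = genes$strand[i],
        exons = as.matrix(ex[, c("start", "end")]),
        cds = if (nrow(cd)) as.matrix(cd[, c("start", "end")]) else NULL,
        phase = if (nrow(cd)) phase else NULL
      )
    }
  }
  out
}

#' Write gene models to GFF3
#'
#' Emits the gene -> mRNA -> exon/CDS hierarchy consumed by
#' [read_gene_models()] through \pkg{rtracklayer}.
#'
#' @param genes Named list of `gene_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  rows <- list()
  for (g in genes) {
    span <- gene_span(g)
    tid <- paste0(g$gene_id, ".t1")
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = g$chrom, start = span[1L], end = span[2L], strand = g$strand,
      type = c("gene", "mRNA"), id = c(g$gene_id, tid),
      parent = c(NA_character_, g$gene_id), phase = NA_integer_,
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = g$chrom, start = g$exons[, 1L], end = g$exons[, 2L],
      strand = g$strand, type = "exon", id = NA_character_, parent = tid,
      phase = NA_integer_, stringsAsFactors = FALSE)
    if (nrow(g$cds) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = g$chrom, start = g$cds[, 1L], end = g$cds[, 2L],
        strand = g$strand, type = "CDS", id = NA_character_, parent = tid,
        phase = g$phase, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand
  )
  gr$source <- "panhap"
  gr$type <- df$type
  gr$ID <- df$id
  gr$Parent <- IRanges::CharacterList(lapply(df$parent, function(p)
    if (is.na(p)) character(0) else p))
  gr$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read / write genome FASTA
#'
#' Thin wrappers over \pkg{Biostrings}.
#'
#' @param path FASTA path.
#' @return `read_genome_fasta`: a `DNAStringSet` named by sequence id.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' @rdname read_genome_fasta
#' @param genome A named `DNAStringSet`.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Coding sequence of a gene model in translation order
#'
#' Concatenates the CDS intervals (ascending), reverse-complements on the
#' minus strand, and trims the leading phase bases so translation starts
#' on a complete codon.
#'
#' @param gene A `gene_model`.
#' @param genome Named `DNAStringSet` containing `gene$chrom`.
#' @return A `DNAString`.
#' @export
cds_sequence <- function(gene, genome) {
  stopifnot(gene$chrom %in% names(genome))
  chrom_seq <- genome[[gene$chrom]]
  parts <- lapply(seq_len(nrow(gene$cds)), function(i)
    Biostrings::subseq(chrom_seq, gene$cds[i, 1L], gene$cds[i, 2L]))
  s <- do.call(Biostrings::xscat, parts)
  if (gene$strand == "-") s <- Biostrings::reverseComplement(s)
  first_phase <- if (gene$strand == "+") gene$phase[1L] else gene$phase[length(gene$phase)]
  if (length(first_phase) && !is.na(first_phase) && first_phase > 0L) {
    s <- Biostrings::subseq(s, first_phase + 1L)
  }
  s
}
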