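#' Generate a toy annotated genome with known gene structures
#'
#' Builds random chromosomes carrying non-overlapping protein-coding genes
#' on both strands, each with 1-4 exons, optional 5'/3' UTRs and a CDS
#' that starts with ATG, ends with a stop codon, contains no internal stop
#' and obeys the mod-3 rule.  Chromosome lengths are sized to the gene
#' budget unless supplied; supplied lengths too small for the packing are
#' an error.  The generator is a pure function of `seed`: identical calls
#' give byte-identical FASTA and GFF3 output.
#'
#' @param n_chroms Number of chromosomes.
#' @param n_genes Number of genes (assigned to chromosomes round-robin).
#' @param seed Integer seed.
#' @param margin Minimum intergenic gap in bp (default 200).
#' @param chrom_lengths Optional integer vector of chromosome lengths.
#' @param chrom_names Optional chromosome names (default `Ca1`, `Ca2`, ...).
#' @return List with `genome` (named `DNAStringSet`), `genes` (named list
#'   of [gene_model()]), and `truth` (per-gene data.frame: `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `n_exons`, `cds_len`).
#' @export
generate_annotated_genome <- function(n_chroms = 2L, n_genes = 20L, seed = 1L,
                                      margin = 200L, chrom_lengths = NULL,
                                      chrom_names = NULL) {
  stopifnot(n_chroms >= 1L, n_genes >= 0L, margin >= 50L)
  bases <- c("A", "C", "G", "T")
  sense_codons <- setdiff(
    apply(expand.grid(bases, bases, bases), 1L, paste, collapse = ""),
    c("TAA", "TAG", "TGA"))
  stops <- c("TAA", "TAG", "TGA")

  with_seed(derive_seed(seed, "genome"), {
    chrom_of <- if (n_genes > 0L) rep_len(seq_len(n_chroms), n_genes) else integer(0)
    plans <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      n_exons <- sample(1:4, 1L)
      utr5 <- sample(c(0L, 10:60), 1L)
      utr3 <- sample(c(0L, 10:60), 1L)
      cds_len <- 3L * sample(40:120, 1L)
      exonic <- utr5 + cds_len + utr3
      # split the exonic run into n_exons pieces of >= 30 bp
      if (n_exons > 1L) {
        cuts <- sort(sample(seq(30L, exonic - 30L), n_exons - 1L))
        while (any(diff(c(0L, cuts, exonic)) < 30L)) {
          cuts <- sort(sample(seq(30L, exonic - 30L), n_exons - 1L))
        }
        exon_len <- diff(c(0L, cuts, exonic))
        intron_len <- sample(60:200, n_exons - 1L, replace = TRUE)
      } else {
        exon_len <- exonic
        intron_len <- integer(0)
      }
      plans[[g]] <- list(
        strand = sample(c("+", "-"), 1L),
        n_exons = n_exons, utr5 = utr5, utr3 = utr3, cds_len = cds_len,
        exon_len = exon_len, intron_len = intron_len,
        span = sum(exon_len) + sum(intron_len),
        cds_seq = paste0("ATG",
                         paste(sample(sense_codons, cds_len / 3L - 2L,
                                      replace = TRUE), collapse = ""),
                         sample(stops, 1L))
      )
    }
    # pack genes per chromosome with `margin` gaps
    need <- vapply(seq_len(n_chroms), function(cc) {
      idx <- which(chrom_of == cc)
      margin * (length(idx) + 1L) + sum(vapply(plans[idx], `[[`, 0L, "span"))
    }, 0L)
    if (is.null(chrom_lengths)) {
      chrom_lengths <- need + margin
    } else {
      chrom_lengths <- as.integer(rep_len(chrom_lengths, n_chroms))
      if (any(chrom_lengths < need)) {
        stop("gene packing infeasible: chromosome(s) shorter than the gene budget",
             call. = FALSE)
      }
    }
    if (is.null(chrom_names)) chrom_names <- sprintf("Ca%d", seq_len(n_chroms))
    stopifnot(length(chrom_names) == n_chroms)
    chrom_seq <- lapply(chrom_lengths, function(L)
      sample(bases, L, replace = TRUE))
    names(chrom_seq) <- chrom_names

    genes <- list()
    truth <- list()
    cursor <- rep(margin + 1L, n_chroms)
    for (g in seq_len(n_genes)) {
      p <- plans[[g]]
      cc <- chrom_of[g]
      start <- cursor[cc]
      cursor[cc] <- start + p$span + margin
      # genomic-ascending exon layout; transcription order reversed on "-"
      len_asc <- if (p$strand == "+") p$exon_len else rev(p$exon_len)
      int_asc <- if (p$strand == "+") p$intron_len else rev(p$intron_len)
      ex_start <- integer(p$n_exons)
      ex_end <- integer(p$n_exons)
      pos <- start
      for (e in seq_len(p$n_exons)) {
        ex_start[e] <- pos
        ex_end[e] <- pos + len_asc[e] - 1L
        pos <- ex_end[e] + 1L + if (e < p$n_exons) int_asc[e] else 0L
      }
      # transcript offsets in transcription order
      tx_order <- if (p$strand == "+") seq_len(p$n_exons) else rev(seq_len(p$n_exons))
      tx_off <- cumsum(c(0L, p$exon_len))[seq_len(p$n_exons)]
      cds_t <- c(p$utr5 + 1L, p$utr5 + p$cds_len)   # CDS transcript range
      cds_iv <- NULL
      for (e in seq_len(p$n_exons)) {                # e indexes transcription order
        t1 <- tx_off[e] + 1L
        t2 <- tx_off[e] + p$exon_len[e]
        lo <- max(t1, cds_t[1L]); hi <- min(t2, cds_t[2L])
        if (lo > hi) next
        gi <- tx_order[e]
        if (p$strand == "+") {
          g1 <- ex_start[gi] + (lo - t1); g2 <- ex_start[gi] + (hi - t1)
        } else {
          g2 <- ex_end[gi] - (lo - t1); g1 <- ex_end[gi] - (hi - t1)
        }
        cds_iv <- rbind(cds_iv, c(g1, g2))
      }
      cds_iv <- cds_iv[order(cds_iv[, 1L]), , drop = FALSE]
      # write the CDS bases into the chromosome (genomic sense)
      gcds <- if (p$strand == "+") p$cds_seq else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(p$cds_seq)))
      gcds_chars <- strsplit(gcds, "")[[1L]]
      off <- 0L
      for (r in seq_len(nrow(cds_iv))) {
        w <- cds_iv[r, 2L] - cds_iv[r, 1L] + 1L
        chrom_seq[[cc]][cds_iv[r, 1L]:cds_iv[r, 2L]] <-
          gcds_chars[(off + 1L):(off + w)]
        off <- off + w
      }
      gid <- sprintf("gene%03d", g)
      genes[[gid]] <- gene_model(
        gene_id = gid, chrom = chrom_names[cc], strand = p$strand,
        exons = cbind(ex_start, ex_end), cds = cds_iv)
      truth[[g]] <- data.frame(
        gene_id = gid, chrom = chrom_names[cc], strand = p$strand,
        start = start, end = start + p$span - 1L,
        n_exons = p$n_exons, cds_len = p$cds_len, stringsAsFactors = FALSE)
    }
    genome <- Biostrings::DNAStringSet(vapply(chrom_seq, paste, "", collapse = ""))
    names(genome) <- chrom_names
    list(genome = genome, genes = genes,
         truth = if (n_genes > 0L) do.call(rbind, truth) else
           data.frame(gene_id = character(0)))
  })
}
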