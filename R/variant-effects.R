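#' Filter variants on quality and depth
#'
#' Retains records with `qual >= min_qual` and `depth >= min_depth`
#' (boundaries inclusive).  A missing quality or depth fails the
#' respective rule.
#'
#' @param x A [variant_table()].
#' @param min_qual Minimum variant quality (default 20).
#' @param min_depth Minimum site read depth (default 50).
#' @return List with `variants` (filtered table) and `report` (counts:
#'   `n_input`, `fail_qual`, `fail_depth`, `n_removed`, `n_retained`).
#' @export
filter_variants <- function(x, min_qual = 20, min_depth = 50) {
  stopifnot(inherits(x, "variant_table"))
  r <- x$records
  ok_q <- !is.na(r$qual) & r$qual >= min_qual
  ok_d <- !is.na(r$depth) & r$depth >= min_depth
  keep <- ok_q & ok_d
  out <- variant_table(r[keep, , drop = FALSE],
                       gt = if (!is.null(x$gt)) x$gt[keep, , drop = FALSE],
                       dp = if (!is.null(x$dp)) x$dp[keep, , drop = FALSE],
                       samples = x$samples)
  list(variants = out,
       report = list(n_input = nrow(r), fail_qual = sum(!ok_q),
                     fail_depth = sum(!ok_d), n_removed = sum(!keep),
                     n_retained = sum(keep)))
}

effect_severity <- c(nonsense = 1, frameshift = 2, missense = 3, inframe = 3.5,
                     splice_donor = 4, splice_acceptor = 4, synonymous = 5,
                     UTR = 6, splice_region = 7, intronic = 8)

aa3 <- function(a) {
  code <- Biostrings::AMINO_ACID_CODE
  vapply(a, function(x) if (x == "*") "Ter" else unname(code[x]), "")
}

# ascending genomic CDS positions and their transcript indices
cds_position_map <- function(gene) {
  gpos <- unlist(lapply(seq_len(nrow(gene$cds)), function(r)
    gene$cds[r, 1L]:gene$cds[r, 2L]))
  total <- length(gpos)
  t_idx <- if (gene$strand == "+") seq_len(total) else rev(seq_len(total))
  first_phase <- if (length(gene$phase) == 0L) 0L else
    if (gene$strand == "+") gene$phase[1L] else gene$phase[length(gene$phase)]
  list(gpos = gpos, t = t_idx, total = total,
       phase = if (is.na(first_phase)) 0L else first_phase)
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

# codon-local SNP consequence within a coding gene
classify_cds_snp <- function(gene, genome, pos, alt) {
  map <- cds_position_map(gene)
  t <- map$t[match(pos, map$gpos)]
  tp <- t - map$phase
  if (is.na(tp) || tp < 1L) return(NULL)
  codon_i <- (tp - 1L) %/% 3L + 1L
  within <- (tp - 1L) %% 3L + 1L
  t3 <- map$phase + (codon_i - 1L) * 3L + 1:3
  if (any(t3 > map$total)) return(NULL)   # trailing partial codon
  g3 <- map$gpos[match(t3, map$t)]
  fetch <- function(p) as.character(Biostrings::subseq(genome[[gene$chrom]], p, p))
  bases <- vapply(g3, fetch, "")
  if (gene$strand == "-") bases <- comp_base(bases)
  ref_codon <- paste(bases, collapse = "")
  alt_base <- if (gene$strand == "-") comp_base(alt) else alt
  alt_bases <- bases
  alt_bases[within] <- alt_base
  alt_codon <- paste(alt_bases, collapse = "")
  gc <- Biostrings::GENETIC_CODE
  aa_ref <- unname(gc[ref_codon])
  aa_alt <- unname(gc[alt_codon])
  subclass <- if (aa_ref == aa_alt) "synonymous"
    else if (aa_alt == "*") "nonsense" else "missense"
  list(subclass = subclass,
       aa_change = paste0(aa3(aa_ref), codon_i, aa3(aa_alt)))
}

# consequence of one variant record within one gene; NULL when outside span
classify_in_gene <- function(gene, genome, pos, ref, alt, size_class) {
  span <- gene_span(gene)
  if (pos < span[1L] || pos > span[2L]) return(NULL)
  ex <- gene$exons
  n_ex <- nrow(ex)
  ref_end <- pos + nchar(ref) - 1L
  in_exon <- which(pos >= ex[, 1L] & pos <= ex[, 2L])
  # boundary-spanning: ref allele crosses an exon/intron edge
  spans_boundary <- any(pos < ex[, 1L] & ref_end >= ex[, 1L]) ||
    any(pos <= ex[, 2L] & ref_end > ex[, 2L])
  splice <- "none"
  if (length(in_exon) == 1L) {
    region <- "exonic"
    # exonic splice shoulder: <= 3 exonic bases from a junction with an intron
    e <- in_exon
    d <- Inf
    if (e > 1L) d <- min(d, pos - ex[e, 1L] + 1L)
    if (e < n_ex) d <- min(d, ex[e, 2L] - pos + 1L)
    if (d <= 3L) splice <- "splice_region"
    in_cds <- nrow(gene$cds) > 0L &&
      any(pos >= gene$cds[, 1L] & pos <= gene$cds[, 2L])
    if (in_cds && gene$coding) {
      if (size_class == "SNP") {
        res <- classify_cds_snp(gene, genome, pos, alt)
        if (is.null(res)) {
          subclass <- "UTR"; aa <- NA_character_
        } else {
          subclass <- res$subclass; aa <- res$aa_change
        }
      } else {
        indel_size <- abs(nchar(ref) - nchar(alt))
        subclass <- if (indel_size %% 3L == 0L) "inframe" else "frameshift"
        aa <- NA_character_
      }
    } else {
      subclass <- "UTR"
      aa <- NA_character_
    }
  } else {
    region <- "intronic"
    subclass <- "none"
    aa <- NA_character_
    # locate the intron and the distance to each end
    prev_ex <- max(which(ex[, 2L] < pos))
    a <- ex[prev_ex, 2L] + 1L
    b <- ex[prev_ex + 1L, 1L] - 1L
    d_left <- pos - a + 1L
    d_right <- b - pos + 1L
    donor_side <- if (gene$strand == "+") d_left else d_right
    accept_side <- if (gene$strand == "+") d_right else d_left
    if (donor_side <= 2L) splice <- "splice_donor"
    else if (accept_side <= 2L) splice <- "splice_acceptor"
    else if (min(d_left, d_right) <= 8L) splice <- "splice_region"
  }
  key <- if (region == "exonic" && subclass != "UTR" && subclass != "none") {
    subclass
  } else if (splice %in% c("splice_donor", "splice_acceptor")) {
    splice
  } else if (region == "exonic") {
    "UTR"
  } else if (splice == "splice_region") {
    "splice_region"
  } else "intronic"
  list(region = region, subclass = subclass, splice = splice,
       gene_id = gene$gene_id, aa_change = aa,
       boundary_spanning = spans_boundary,
       severity = effect_severity[[key]])
}

#' Classify functional effects of variants against gene models
#'
#' Region assignment tests exon membership first (exonic includes UTR
#' positions), then intron membership, else intergenic.  Exonic SNPs in a
#' CDS are translated codon-locally, strand aware (reverse-complementing
#' alleles on minus-strand genes): same amino acid is synonymous, stop
#' gained nonsense, otherwise missense, with the amino-acid change
#' reported as e.g. `Leu90Trp`.  Exonic SNPs outside the CDS are UTR
#' variants; CDS InDels are frameshift when the length difference is not
#' a multiple of 3, else inframe.  Splice annotation uses the first/last
#' 2 intronic bases (donor/acceptor by transcription direction) and a
#' splice_region window of <= 8 intronic or <= 3 exonic bases from a
#' junction.  A variant under several genes is assigned the most severe
#' consequence (nonsense > frameshift > missense > splice donor/acceptor
#' > synonymous > UTR > splice_region > intronic), ties broken by the
#' smaller gene id.  InDels spanning an exon-intron boundary are classed
#' by their leftmost affected base and flagged.
#'
#' @param x A [variant_table()].
#' @param genes Named list of [gene_model()] objects.
#' @param genome Named `DNAStringSet`; every record's `ref` allele must
#'   match the genome (checked; mismatch is an error naming the position).
#' @return Data.frame (one row per record): `region`, `subclass`,
#'   `splice`, `gene_id`, `aa_change`, `boundary_spanning`.
#' @export
classify_variant_effects <- function(x, genes, genome) {
  stopifnot(inherits(x, "variant_table"))
  r <- x$records
  size_class <- variant_size_class(x)
  genes_by_chrom <- split(genes, vapply(genes, `[[`, "", "chrom"))
  n <- nrow(r)
  out <- data.frame(region = character(n), subclass = character(n),
                    splice = character(n), gene_id = NA_character_,
                    aa_change = NA_character_, boundary_spanning = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    chrom <- r$chrom[i]; pos <- r$pos[i]
    ref <- r$ref[i]; alt <- r$alt[i]
    if (!chrom %in% names(genome)) {
      stop("variant chromosome ", chrom, " absent from genome", call. = FALSE)
    }
    if (!grepl("^<", alt)) {   # sequence-explicit record: verify ref
      obs <- as.character(Biostrings::subseq(genome[[chrom]], pos,
                                             pos + nchar(ref) - 1L))
      if (!identical(obs, ref)) {
        stop("ref allele mismatch at ", chrom, ":", pos, " (VCF ", ref,
             ", genome ", obs, ")", call. = FALSE)
      }
    }
    hits <- list()
    for (g in genes_by_chrom[[chrom]]) {
      h <- classify_in_gene(g, genome, pos, ref, alt, size_class[i])
      if (!is.null(h)) hits[[length(hits) + 1L]] <- h
    }
    if (length(hits) == 0L) {
      out$region[i] <- "intergenic"
      out$subclass[i] <- "none"
      out$splice[i] <- "none"
    } else {
      sev <- vapply(hits, `[[`, 0, "severity")
      ids <- vapply(hits, `[[`, "", "gene_id")
      best <- hits[[order(sev, ids)[1L]]]
      out$region[i] <- best$region
      out$subclass[i] <- best$subclass
      out$splice[i] <- best$splice
      out$gene_id[i] <- best$gene_id
      out$aa_change[i] <- best$aa_change
      out$boundary_spanning[i] <- best$boundary_spanning
    }
  }
  out
}
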