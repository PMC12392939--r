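#' Generate variants of known functional class on a toy genome
#'
#' Plants SNPs and small InDels whose true effect class is established by
#' construction: candidate sites are drawn from the appropriate genomic
#' compartment and, for coding changes, the class is determined by full
#' CDS re-extraction and re-translation of the mutated genome (an oracle
#' independent of the codon-local classifier).  Positions are chosen away
#' from splice windows so each planted variant has a single unambiguous
#' label.  The realized class histogram equals the request exactly; an
#' unachievable request (e.g. coding classes on a gene-free genome) is an
#' error.
#'
#' @param genome Named `DNAStringSet`.
#' @param genes Named list of [gene_model()] objects (may be empty).
#' @param class_counts Named integer vector; names from
#'   `intergenic, intronic, utr, synonymous, missense, nonsense,
#'   splice_donor, splice_acceptor, frameshift, inframe` (SNPs and CDS
#'   InDels) plus `intergenic_indel, intronic_indel` (small non-coding
#'   InDels).
#' @param seed Integer seed.
#' @param sample_name Sample column name for the emitted genotypes.
#' @return List with `variants` (a [variant_table()], hom-alt genotypes,
#'   qualities 30-60 and depths 60-150 so default filters retain all) and
#'   `truth` (data.frame: `chrom`, `pos`, `ref`, `alt`, `class`,
#'   `gene_id`).
#' @export
generate_variants <- function(genome, genes, class_counts, seed = 1L,
                              sample_name = "S1") {
  known <- c("intergenic", "intronic", "utr", "synonymous", "missense",
             "nonsense", "splice_donor", "splice_acceptor", "frameshift",
             "inframe", "intergenic_indel", "intronic_indel")
  bad <- setdiff(names(class_counts), known)
  if (length(bad)) stop("unknown class(es): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  class_counts <- class_counts[class_counts > 0]
  bases <- c("A", "C", "G", "T")
  used <- new.env(parent = emptyenv())    # chrom:pos occupancy across variants
  mark_used <- function(chrom, lo, hi) {
    for (p in lo:hi) assign(paste0(chrom, ":", p), TRUE, envir = used)
  }
  is_free <- function(chrom, lo, hi) {
    !any(vapply(lo:hi, function(p)
      exists(paste0(chrom, ":", p), envir = used), TRUE))
  }

  comp <- variant_site_compartments(genome, genes)
  coding_genes <- Filter(function(g) g$coding && nrow(g$cds) > 0L, genes)
  oracle_cache <- lapply(coding_genes, cds_translation_cache, genome = genome)
  chrom_str <- lapply(seq_along(genome), function(i) as.character(genome[[i]]))
  names(chrom_str) <- names(genome)

  rows <- list()
  truth <- list()
  add_variant <- function(chrom, pos, ref, alt, class, gene_id) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = chrom, pos = pos, id = ".", ref = ref, alt = alt,
      qual = NA_real_, filter = "PASS", depth = NA_real_,
      svtype = NA_character_, end = NA_integer_, strands = NA_character_,
      svlen = NA_integer_, split = FALSE, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <<- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt, class = class,
      gene_id = gene_id, stringsAsFactors = FALSE)
  }
  base_at <- function(chrom, pos, len = 1L) {
    substr(chrom_str[[chrom]], pos, pos + len - 1L)
  }

  with_seed(derive_seed(seed, "variants"), {
    for (class in names(class_counts)) {
      want <- class_counts[[class]]
      got <- 0L
      if (class %in% c("intergenic", "intronic", "utr",
                       "splice_donor", "splice_acceptor")) {
        cand <- comp[[class]]
        if (nrow(cand) > 0L) cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
        for (i in seq_len(nrow(cand))) {
          if (got >= want) break
          ch <- cand$chrom[i]; p <- cand$pos[i]
          if (!is_free(ch, p, p)) next
          ref <- base_at(ch, p)
          alt <- sample(setdiff(bases, ref), 1L)
          add_variant(ch, p, ref, alt, class, cand$gene_id[i])
          mark_used(ch, p, p)
          got <- got + 1L
        }
      } else if (class %in% c("synonymous", "missense", "nonsense")) {
        if (length(coding_genes) == 0L && want > 0L) {
          stop("cannot plant ", class, " variants: no coding genes", call. = FALSE)
        }
        cand <- comp$cds_interior
        if (nrow(cand) > 0L) cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
        for (i in seq_len(nrow(cand))) {
          if (got >= want) break
          ch <- cand$chrom[i]; p <- cand$pos[i]; gid <- cand$gene_id[i]
          if (!is_free(ch, p, p)) next
          ref <- base_at(ch, p)
          for (alt in sample(setdiff(bases, ref))) {
            lab <- coding_snp_class_by_translation(genes[[gid]],
                                                   oracle_cache[[gid]], p, alt)
            if (identical(lab, class)) {
              add_variant(ch, p, ref, alt, class, gid)
              mark_used(ch, p, p)
              got <- got + 1L
              break
            }
          }
        }
      } else if (class %in% c("intergenic_indel", "intronic_indel")) {
        # small (< 50 bp) InDels fully inside one compartment
        cand <- if (class == "intergenic_indel") comp$intergenic else comp$intronic
        mask <- comp$intergenic_mask
        if (nrow(cand) > 0L) cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
        for (i in seq_len(nrow(cand))) {
          if (got >= want) break
          ch <- cand$chrom[i]; p <- cand$pos[i]
          L <- sample(1:8, 1L)
          del <- sample(c(TRUE, FALSE), 1L)
          if (del) {
            span_ok <- if (class == "intergenic_indel") {
              p + L <= length(mask[[ch]]) && all(mask[[ch]][p:(p + L)])
            } else {
              # stay in the same clean intron zone
              any(comp$intron_zones$chrom == ch &
                    comp$intron_zones$lo <= p &
                    comp$intron_zones$hi >= p + L)
            }
            if (!span_ok || !is_free(ch, p, p + L)) next
            ref <- base_at(ch, p, L + 1L)
            alt <- substr(ref, 1L, 1L)
          } else {
            if (!is_free(ch, p, p)) next
            ref <- base_at(ch, p)
            alt <- paste0(ref, paste(sample(bases, L, replace = TRUE),
                                     collapse = ""))
          }
          add_variant(ch, p, ref, alt, class, cand$gene_id[i])
          mark_used(ch, p, p + if (del) L else 0L)
          got <- got + 1L
        }
      } else { # frameshift / inframe CDS InDels
        if (length(coding_genes) == 0L && want > 0L) {
          stop("cannot plant ", class, " variants: no coding genes", call. = FALSE)
        }
        lens <- if (class == "frameshift") c(1L, 2L, 4L) else 3L
        cand <- comp$cds_indel_anchor
        if (nrow(cand) > 0L) cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
        for (i in seq_len(nrow(cand))) {
          if (got >= want) break
          ch <- cand$chrom[i]; p <- cand$pos[i]; gid <- cand$gene_id[i]
          L <- sample(rep(lens, 2L), 1L)
          del <- sample(c(TRUE, FALSE), 1L)
          if (del) {
            if (p + L > cand$max_end[i] || !is_free(ch, p, p + L)) next
            ref <- base_at(ch, p, L + 1L)
            alt <- substr(ref, 1L, 1L)
          } else {
            if (!is_free(ch, p, p)) next
            ref <- base_at(ch, p)
            alt <- paste0(ref, paste(sample(bases, L, replace = TRUE),
                                     collapse = ""))
          }
          add_variant(ch, p, ref, alt, class, gid)
          mark_used(ch, p, p + if (del) L else 0L)
          got <- got + 1L
        }
      }
      if (got < want) {
        stop("impossible request: only ", got, " of ", want, " ", class,
             " variants could be planted", call. = FALSE)
      }
    }
    records <- do.call(rbind, rows)
    truth_df <- do.call(rbind, truth)
    ord <- order(records$chrom, records$pos)
    records <- records[ord, , drop = FALSE]
    truth_df <- truth_df[ord, , drop = FALSE]
    rownames(records) <- rownames(truth_df) <- NULL
    n <- nrow(records)
    records$qual <- round(stats::runif(n, 30, 60), 1)
    dp <- matrix(sample(60:150, n, replace = TRUE), ncol = 1L,
                 dimnames = list(NULL, sample_name))
    records$depth <- as.numeric(dp[, 1L])
    gt <- matrix("1/1", n, 1L, dimnames = list(NULL, sample_name))
    list(variants = variant_table(records, gt = gt, dp = dp,
                                  samples = sample_name),
         truth = truth_df)
  })
}

# enumerate candidate sites per genomic compartment, avoiding splice
# windows so planted labels are unambiguous
variant_site_compartments <- function(genome, genes) {
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      gene_id = character(0), stringsAsFactors = FALSE)
  out <- list(intergenic = empty, intronic = empty, utr = empty,
              splice_donor = empty, splice_acceptor = empty,
              cds_interior = empty,
              cds_indel_anchor = cbind(empty, max_end = integer(0)),
              intergenic_mask = list(),
              intron_zones = data.frame(chrom = character(0), lo = integer(0),
                                        hi = integer(0),
                                        stringsAsFactors = FALSE))
  add <- function(slot, chrom, pos, gene_id = NA_character_, max_end = NULL) {
    if (length(pos) == 0L) return()
    df <- data.frame(chrom = chrom, pos = as.integer(pos), gene_id = gene_id,
                     stringsAsFactors = FALSE)
    if (!is.null(max_end)) df$max_end <- as.integer(max_end)
    out[[slot]] <<- rbind(out[[slot]], df)
  }
  # intergenic: complement of gene spans
  for (ch in names(genome)) {
    covered <- rep(FALSE, Biostrings::nchar(genome[[ch]]))
    for (g in genes) {
      if (g$chrom != ch) next
      sp <- gene_span(g)
      covered[sp[1L]:sp[2L]] <- TRUE
    }
    add("intergenic", ch, which(!covered))
    out$intergenic_mask[[ch]] <- !covered
  }
  for (g in genes) {
    ex <- g$exons
    n_ex <- nrow(ex)
    # introns with donor/acceptor ends (transcription-aware)
    if (n_ex > 1L) {
      for (i in seq_len(n_ex - 1L)) {
        a <- ex[i, 2L] + 1L
        b <- ex[i + 1L, 1L] - 1L
        if (b < a) next
        donor <- if (g$strand == "+") c(a, a + 1L) else c(b - 1L, b)
        accept <- if (g$strand == "+") c(b - 1L, b) else c(a, a + 1L)
        add("splice_donor", g$chrom, donor, g$gene_id)
        add("splice_acceptor", g$chrom, accept, g$gene_id)
        if (b - a + 1L > 16L) {
          add("intronic", g$chrom, seq(a + 8L, b - 8L), g$gene_id)
          out$intron_zones <- rbind(out$intron_zones, data.frame(
            chrom = g$chrom, lo = a + 8L, hi = b - 8L,
            stringsAsFactors = FALSE))
        }
      }
    }
    # exonic splice_region shoulder: <=3 exonic bases from a junction
    shoulder <- integer(0)
    for (i in seq_len(n_ex)) {
      if (i > 1L) shoulder <- c(shoulder, ex[i, 1L]:min(ex[i, 1L] + 2L, ex[i, 2L]))
      if (i < n_ex) shoulder <- c(shoulder, max(ex[i, 2L] - 2L, ex[i, 1L]):ex[i, 2L])
    }
    for (u in list(g$utr5, g$utr3)) {
      for (r in seq_len(nrow(u))) {
        pos <- setdiff(u[r, 1L]:u[r, 2L], shoulder)
        add("utr", g$chrom, pos, g$gene_id)
      }
    }
    if (g$coding && nrow(g$cds) > 0L) {
      # CDS interior: skip the first and last codon and splice shoulders
      total <- sum(g$cds[, 2L] - g$cds[, 1L] + 1L)
      cds_pos <- unlist(lapply(seq_len(nrow(g$cds)), function(r)
        g$cds[r, 1L]:g$cds[r, 2L]))
      # transcript index of each CDS base (ascending genomic)
      t_idx <- if (g$strand == "+") seq_len(total) else rev(seq_len(total))
      keep <- t_idx > 3L & t_idx <= total - 3L & !(cds_pos %in% shoulder)
      add("cds_interior", g$chrom, cds_pos[keep], g$gene_id)
      # InDel anchors: runs inside a single CDS interval with >= 6 bp slack
      for (r in seq_len(nrow(g$cds))) {
        lo <- g$cds[r, 1L] + 4L
        hi <- g$cds[r, 2L] - 9L
        if (hi < lo) next
        pos <- lo:hi
        t_sub <- t_idx[match(pos, cds_pos)]
        pos <- pos[t_sub > 3L & t_sub <= total - 12L]
        if (length(pos)) {
          add("cds_indel_anchor", g$chrom, pos, g$gene_id,
              max_end = g$cds[r, 2L] - 4L)
        }
      }
    }
  }
  out
}

# full-CDS translation through the standard code, base R string ops only
translate_full_cds <- function(s) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(s) - nchar(s) %% 3L
  codons <- substring(s, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# per-gene cache for the full-CDS translation oracle
cds_translation_cache <- function(gene, genome) {
  cds <- as.character(cds_sequence(gene, genome))
  gpos <- unlist(lapply(seq_len(nrow(gene$cds)), function(r)
    gene$cds[r, 1L]:gene$cds[r, 2L]))
  first_phase <- if (gene$strand == "+") gene$phase[1L] else
    gene$phase[length(gene$phase)]
  if (is.na(first_phase)) first_phase <- 0L
  list(cds = cds, prot_ref = translate_full_cds(cds),
       gpos = gpos, total = length(gpos), phase = first_phase)
}

# truth label for a coding SNP: substitute the base at its CDS coordinate
# and re-translate the whole coding sequence (protein-level comparison,
# independent of the classifier's codon-local path)
coding_snp_class_by_translation <- function(gene, cache, pos, alt) {
  i <- match(pos, cache$gpos)
  t <- if (gene$strand == "+") i else cache$total - i + 1L
  tp <- t - cache$phase
  if (is.na(tp) || tp < 1L || tp > nchar(cache$cds)) return(NA_character_)
  s <- cache$cds
  substr(s, tp, tp) <- if (gene$strand == "-") chartr("ACGT", "TGCA", alt) else alt
  prot_alt <- translate_full_cds(s)
  if (identical(cache$prot_ref, prot_alt)) return("synonymous")
  core_alt <- substr(prot_alt, 1L, nchar(prot_alt) - 1L)
  if (grepl("*", core_alt, fixed = TRUE)) return("nonsense")
  "missense"
}
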