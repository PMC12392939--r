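# Independent brute-force oracles used across the suite.  Each recomputes
# the quantity under test by the most direct method available, sharing no
# code with the implementation path it checks.

# per-family class from a plain row-sum loop
oracle_classify <- function(occ, softcore_min = ncol(occ) - 1L) {
  n <- ncol(occ)
  out <- character(nrow(occ))
  for (i in seq_len(nrow(occ))) {
    o <- sum(occ[i, ])
    out[i] <- if (o == n) "core" else if (o >= softcore_min) "softcore"
      else if (o >= 2) "dispensable" else "private"
  }
  out
}

# exhaustive rarefaction: pan/core for every k-subset by direct set logic
oracle_rarefaction_exhaustive <- function(occ, k) {
  subsets <- utils::combn(ncol(occ), k)
  pan <- core <- integer(ncol(subsets))
  for (s in seq_len(ncol(subsets))) {
    cols <- subsets[, s]
    pan[s] <- sum(apply(occ[, cols, drop = FALSE], 1L, any))
    core[s] <- sum(apply(occ[, cols, drop = FALSE], 1L, all))
  }
  list(pan = pan, core = core)
}

# plateau by literal forward scan of the definition
oracle_plateau <- function(med, thr = 0.005) {
  n <- length(med)
  for (k in 2:n) {
    all_ok <- TRUE
    for (j in k:n) {
      if ((med[j] - med[j - 1]) / med[j - 1] >= thr) { all_ok <- FALSE; break }
    }
    if (all_ok) return(k)
  }
  NA_integer_
}

# best RSS over a coarse parameter grid for the growth models
oracle_grid_rss <- function(k, y, model, n_grid = 50L) {
  rng <- max(diff(range(y)), 1e-6)
  A_grid <- seq(-2 * rng, 2 * rng, length.out = n_grid)
  B_grid <- if (model == "power") seq(0.01, 2, length.out = n_grid)
    else seq(0.01, 2, length.out = n_grid)
  C_grid <- seq(min(y) - rng, max(y) + rng, length.out = n_grid)
  best <- Inf
  for (B in B_grid) {
    base <- if (model == "power") k^B else exp(-B * k)
    for (A in A_grid) {
      resid0 <- y - A * base
      for (C in C_grid) {
        rss <- sum((resid0 - C)^2)
        if (rss < best) best <- rss
      }
    }
  }
  best
}

# single-linkage SV clustering by BFS over the pairwise link matrix
oracle_sv_clusters <- function(records, max_dist = 1000, min_len = 50) {
  records <- records[records$length >= min_len, , drop = FALSE]
  m <- nrow(records)
  if (m == 0L) return(integer(0))
  b2 <- ifelse(records$type == "INS", records$length, records$end)
  link <- matrix(FALSE, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      link[i, j] <- records$chrom[i] == records$chrom[j] &&
        records$type[i] == records$type[j] &&
        records$strands[i] == records$strands[j] &&
        abs(records$start[i] - records$start[j]) <= max_dist &&
        abs(b2[i] - b2[j]) <= max_dist
    }
  }
  comp <- rep(NA_integer_, m)
  cid <- 0L
  for (s in seq_len(m)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(link[v, ] & is.na(comp)))
    }
  }
  comp
}

# Duncan stepwise span significance straight from the recursive definition:
# a span is non-significant iff its range fails the LSR or any super-span
# is non-significant
oracle_duncan_pair_different <- function(values, alpha = 0.05) {
  g <- length(values)
  n_i <- lengths(values)
  df <- sum(n_i) - g
  mse <- sum(vapply(values, function(v) sum((v - mean(v))^2), 0)) / df
  nh <- g / sum(1 / n_i)
  means <- sort(vapply(values, mean, 0), decreasing = TRUE)
  nms <- names(means)
  lsr <- function(p) qtukey((1 - alpha)^(p - 1), p, df) * sqrt(mse / nh)
  nonsig <- function(i, j) {
    if (i == j) return(TRUE)
    if (means[i] - means[j] <= lsr(j - i + 1)) return(TRUE)
    if (i > 1 && nonsig(i - 1, j)) return(TRUE)
    if (j < g && nonsig(i, j + 1)) return(TRUE)
    FALSE
  }
  out <- matrix(FALSE, g, g, dimnames = list(nms, nms))
  for (i in seq_len(g - 1)) {
    for (j in seq((i + 1), g)) {
      out[i, j] <- out[j, i] <- !nonsig(i, j)
    }
  }
  out
}

# map classifier output onto the generator's single truth label
effect_truth_label <- function(effects) {
  ifelse(effects$region == "intergenic", "intergenic",
  ifelse(effects$splice %in% c("splice_donor", "splice_acceptor"),
         effects$splice,
  ifelse(effects$region == "intronic", "intronic",
  ifelse(effects$subclass == "UTR", "utr", effects$subclass))))
}

# reverse-complement an annotated-genome scenario: every coordinate x on a
# chromosome of length L maps to L - x + 1, strands flip, alleles revcomp
revcomp_scenario <- function(genome, genes, variants) {
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  rc_genome <- Biostrings::reverseComplement(genome)
  names(rc_genome) <- names(genome)
  rc_genes <- lapply(genes, function(g) {
    L <- lens[[g$chrom]]
    flip <- function(m) {
      if (nrow(m) == 0L) return(m)
      out <- cbind(L - m[, 2L] + 1L, L - m[, 1L] + 1L)
      out[order(out[, 1L]), , drop = FALSE]
    }
    gene_model(g$gene_id, g$chrom, if (g$strand == "+") "-" else "+",
               flip(g$exons), if (nrow(g$cds)) flip(g$cds) else NULL,
               if (nrow(g$cds)) rev(g$phase) else NULL)
  })
  names(rc_genes) <- names(genes)
  r <- variants$records
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  L <- lens[r$chrom]
  new_r <- r
  new_r$pos <- as.integer(L - (r$pos + nchar(r$ref) - 1L) + 1L)
  new_r$ref <- vapply(r$ref, rc, "")
  new_r$alt <- vapply(r$alt, rc, "")
  list(genome = rc_genome, genes = rc_genes,
       variants = variant_table(new_r, gt = variants$gt, dp = variants$dp,
                                samples = variants$samples))
}
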