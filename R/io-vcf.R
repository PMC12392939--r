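#' Construct a variant table
#'
#' The package's working container for SNPs, InDels and SVs: a record
#' data.frame plus optional per-sample genotype (GT) and depth (DP)
#' matrices.  Positions are 1-based as in VCF; internal interval
#' arithmetic converts at the boundary.
#'
#' @param records A data.frame with columns `chrom`, `pos`, `id`, `ref`,
#'   `alt`, `qual`, `filter`, `depth`, `svtype`, `end`, `strands`, `svlen`,
#'   `split` (missing optional columns are filled with `NA`).
#' @param gt,dp Optional records x samples character / integer matrices.
#' @param samples Sample names (default from `gt` columns).
#' @param load_report Optional list of parse diagnostics.
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(records, gt = NULL, dp = NULL,
                          samples = colnames(gt), load_report = NULL) {
  needed <- c("chrom", "pos", "id", "ref", "alt", "qual", "filter", "depth",
              "svtype", "end", "strands", "svlen", "split")
  for (col in setdiff(needed, names(records))) {
    records[[col]] <- switch(col,
      pos = , end = , svlen = NA_integer_,
      qual = NA_real_, depth = NA_real_,
      split = FALSE,
      NA_character_)
  }
  records <- records[, needed]
  records$pos <- as.integer(records$pos)
  bad <- which(!is.na(records$ref) & !is.na(records$alt) &
                 records$ref == records$alt)
  if (length(bad) > 0L) {
    stop("ref allele equals alt allele at row ", bad[1L], call. = FALSE)
  }
  structure(
    list(records = records, gt = gt, dp = dp,
         samples = if (is.null(samples)) character(0) else samples,
         load_report = load_report),
    class = "variant_table"
  )
}

#' @export
print.variant_table <- function(x, ...) {
  cls <- table(variant_size_class(x))
  cat(sprintf("<variant_table> %d records (%s), %d sample(s)\n",
              nrow(x$records),
              paste(names(cls), as.integer(cls), sep = ":", collapse = " "),
              length(x$samples)))
  invisible(x)
}

#' Size class of each variant
#'
#' SNP (both alleles single bases), InDel (allele length difference
#' < 50 bp) or SV (difference or annotated SV length >= 50 bp, or any
#' record carrying an SVTYPE tag).
#'
#' @param x A `variant_table`.
#' @param sv_min Minimum SV size in bp (default 50).
#' @return Character vector in `{"SNP","InDel","SV"}`.
#' @export
variant_size_class <- function(x, sv_min = 50L) {
  r <- x$records
  size <- variant_size(x)
  cls <- ifelse(!is.na(r$svtype) | size >= sv_min, "SV",
                ifelse(nchar(r$ref) == 1L & nchar(r$alt) == 1L, "SNP", "InDel"))
  cls
}

#' Variant size in bp
#'
#' SNPs have size 1.  For sequence-explicit InDels the size is the allele
#' length difference.  For symbolic SVs the size is SVLEN when annotated,
#' otherwise the closed-interval span `end - pos + 1`.
#'
#' @inheritParams variant_size_class
#' @return Integer vector of sizes.
#' @export
variant_size <- function(x) {
  r <- x$records
  size <- abs(nchar(r$ref) - nchar(r$alt))
  size[nchar(r$ref) == 1L & nchar(r$alt) == 1L] <- 1L
  has_len <- !is.na(r$svlen)
  size[has_len] <- abs(r$svlen[has_len])
  span <- !has_len & !is.na(r$end)
  size[span] <- r$end[span] - r$pos[span] + 1L
  as.integer(size)
}

parse_info_field <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(?:^|;)", key, "=([^;]+)"), info, perl = TRUE))
  out <- rep(NA_character_, length(info))
  hit <- grepl(paste0("(?:^|;)", key, "="), info, perl = TRUE)
  out[hit] <- sub(paste0(".*(?:^|;)", key, "=([^;]+).*"), "\\1", info[hit], perl = TRUE)
  out
}

gt_is_valid <- function(gt) {
  grepl("^(\\.|[0-9]+)([/|](\\.|[0-9]+))?$", gt)
}

#' Read a VCF 4.2 file into a variant table
#'
#' Parsing is delegated to \pkg{vcfR}; this wrapper extracts the field set
#' the pipeline consumes (positions, alleles, QUAL, per-sample GT/DP, and
#' the SVTYPE/END/STRANDS/SVLEN INFO keys), splits multi-allelic sites
#' into biallelic records (flagged in the `split` column), and skips
#' records with malformed genotypes with a warning counted in the load
#' report.
#'
#' @param path Path to a VCF file.
#' @return A [variant_table()].  Its `load_report` lists `n_parsed`,
#'   `n_skipped` and `n_split`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  has_gt <- ncol(v@gt) > 1L
  samples <- if (has_gt) colnames(v@gt)[-1L] else character(0)
  gt_raw <- if (has_gt) vcfR::extract.gt(v, element = "GT") else NULL
  dp_raw <- if (has_gt) suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)) else NULL

  # record-level genotype validation
  skip <- rep(FALSE, n)
  if (has_gt) {
    for (i in seq_len(n)) {
      g <- gt_raw[i, ]
      g[is.na(g)] <- "."
      if (!all(gt_is_valid(g))) skip[i] <- TRUE
    }
    if (any(skip)) {
      warning(sum(skip), " record(s) with malformed genotypes skipped",
              call. = FALSE)
    }
  }

  info <- fix[, "INFO"]
  info[is.na(info)] <- "."
  svtype <- parse_info_field(info, "SVTYPE")
  endv <- suppressWarnings(as.integer(parse_info_field(info, "END")))
  strands <- parse_info_field(info, "STRANDS")
  svlen <- suppressWarnings(as.integer(parse_info_field(info, "SVLEN")))
  info_dp <- suppressWarnings(as.numeric(parse_info_field(info, "DP")))

  keep <- which(!skip)
  out_rows <- list()
  out_gt <- list()
  out_dp <- list()
  n_split <- 0L
  for (i in keep) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    is_multi <- length(alts) > 1L
    if (is_multi) n_split <- n_split + 1L
    # site depth: INFO/DP when present, else summed sample depth
    depth <- if (!is.na(info_dp[i])) info_dp[i] else if (has_gt) {
      d <- dp_raw[i, ]
      if (all(is.na(d))) NA_real_ else sum(d, na.rm = TRUE)
    } else NA_real_
    for (a in seq_along(alts)) {
      out_rows[[length(out_rows) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        id = ifelse(is.na(fix[i, "ID"]), ".", fix[i, "ID"]),
        ref = fix[i, "REF"], alt = alts[a],
        qual = suppressWarnings(as.numeric(fix[i, "QUAL"])),
        filter = ifelse(is.na(fix[i, "FILTER"]), ".", fix[i, "FILTER"]),
        depth = depth, svtype = svtype[i], end = endv[i],
        strands = strands[i], svlen = svlen[i],
        split = is_multi, stringsAsFactors = FALSE)
      if (has_gt) {
        g <- gt_raw[i, ]
        g[is.na(g)] <- "./."
        if (is_multi) {
          # re-index genotype alleles against this alt; other alts -> missing
          g <- vapply(g, function(s) {
            parts <- strsplit(s, "[/|]")[[1L]]
            parts <- vapply(parts, function(p) {
              if (p == ".") "." else if (p == "0") "0"
              else if (p == as.character(a)) "1" else "."
            }, "")
            paste(parts, collapse = "/")
          }, "")
        }
        out_gt[[length(out_gt) + 1L]] <- g
        out_dp[[length(out_dp) + 1L]] <- dp_raw[i, ]
      }
    }
  }
  records <- if (length(out_rows)) do.call(rbind, out_rows) else
    data.frame(chrom = character(0), pos = integer(0), id = character(0),
               ref = character(0), alt = character(0), qual = numeric(0),
               filter = character(0), depth = numeric(0),
               svtype = character(0), end = integer(0),
               strands = character(0), svlen = integer(0),
               split = logical(0))
  gt <- if (has_gt && length(out_gt)) {
    m <- do.call(rbind, out_gt); colnames(m) <- samples; m
  } else NULL
  dp <- if (has_gt && length(out_dp)) {
    m <- do.call(rbind, out_dp); colnames(m) <- samples
    storage.mode(m) <- "integer"; m
  } else NULL
  variant_table(records, gt = gt, dp = dp, samples = samples,
                load_report = list(n_parsed = length(out_rows),
                                   n_skipped = sum(skip),
                                   n_split = n_split))
}

#' Write a variant table as VCF 4.2
#'
#' Emits the consumed field set ([read_vcf()] round-trips it losslessly):
#' fixed columns, SVTYPE/END/STRANDS/SVLEN/DP INFO keys when present, and
#' GT/DP sample columns when the table carries genotypes.
#'
#' @param x A `variant_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "variant_table"))
  r <- x$records
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=STRANDS,Number=1,Type=String,Description=\"Strand orientation\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of structural variant\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Site read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Sample read depth\">"
  )
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  has_gt <- !is.null(x$gt)
  if (has_gt) cols <- c(cols, "FORMAT", x$samples)
  lines <- c(header, paste(cols, collapse = "\t"))
  if (nrow(r) > 0L) {
    info <- vapply(seq_len(nrow(r)), function(i) {
      parts <- character(0)
      if (!is.na(r$svtype[i])) parts <- c(parts, paste0("SVTYPE=", r$svtype[i]))
      if (!is.na(r$end[i])) parts <- c(parts, paste0("END=", r$end[i]))
      if (!is.na(r$strands[i])) parts <- c(parts, paste0("STRANDS=", r$strands[i]))
      if (!is.na(r$svlen[i])) parts <- c(parts, paste0("SVLEN=", r$svlen[i]))
      if (!is.na(r$depth[i])) parts <- c(parts, paste0("DP=", format(r$depth[i], scientific = FALSE)))
      if (length(parts) == 0L) "." else paste(parts, collapse = ";")
    }, "")
    qual <- ifelse(is.na(r$qual), ".", format(r$qual, scientific = FALSE, trim = TRUE))
    body <- paste(r$chrom, r$pos, r$id, r$ref, r$alt, qual, r$filter, info,
                  sep = "\t")
    if (has_gt) {
      fmt <- if (!is.null(x$dp)) "GT:DP" else "GT"
      sample_cells <- vapply(seq_len(nrow(r)), function(i) {
        g <- x$gt[i, ]
        if (!is.null(x$dp)) {
          d <- x$dp[i, ]
          g <- paste0(g, ":", ifelse(is.na(d), ".", d))
        }
        paste(g, collapse = "\t")
      }, "")
      body <- paste(body, fmt, sample_cells, sep = "\t")
    }
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}
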