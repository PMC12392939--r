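#' Derive a reproducible sub-stream seed
#'
#' All generators in the package accept a single global seed.  Independent
#' stages (pan-genome matrix, genome, variants, SV call sets, haplotype
#' data) draw from sub-streams derived deterministically from that seed and
#' a stream label, so any stage can be regenerated on its own without
#' replaying the others.
#'
#' @param seed Integer global seed.
#' @param stream Character stream label, e.g. `"pangenome"`.
#' @return An integer seed below 2^31, a deterministic function of
#'   `(seed, stream)`.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 16807 + h * 2971) %% 2147483629)
}

# Evaluate `code` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Write a run manifest
#'
#' Every analysis driver records its fully resolved configuration, the
#' package version and the global seed next to its outputs, so a run can be
#' reproduced byte-for-byte from the manifest alone.
#'
#' @param path File to write (plain `key: value` text).
#' @param config Named list of resolved parameters.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config) {
  stopifnot(is.list(config), !is.null(names(config)))
  vals <- vapply(config, function(x) paste(format(x), collapse = ","), "")
  lines <- c(
    paste0("package: panhap ", as.character(utils::packageVersion("panhap"))),
    paste0(names(vals), ": ", vals)
  )
  writeLines(lines, path)
  invisible(path)
}

# round half away from zero to `digits`, matching how percentages are
# conventionally printed in tables (base round() is banker's rounding)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# largest-remainder percentage rounding: the composition table convention
# in which class shares are rounded to `digits` decimals yet still total
# exactly 100
percentages_lr <- function(counts, digits = 2) {
  p <- 10^digits
  raw <- 100 * counts / sum(counts) * p
  base <- floor(raw)
  short <- round(100 * p - sum(base))
  if (short > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  base / p
}
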