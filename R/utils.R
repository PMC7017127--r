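#' @useDynLib somaticmap, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx cor dnorm kmeans lowess quantile rbinom rpois runif
#' @importFrom utils read.table write.table
NULL

#' Derive a reproducible sub-stream seed
#'
#' Maps a global seed and a stage tag to a deterministic 31-bit integer so
#' each pipeline stage draws from its own reproducible stream and can be
#' rerun in isolation.
#'
#' @param seed integer global seed.
#' @param tag character stage tag, e.g. `"genome"`.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(tag) == 1L)
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(as.character(tag))) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

#' Phred-scale a probability
#'
#' `-10 * log10(p)`, capped so that saturated posteriors (p ~ 0) do not
#' produce infinities.
#'
#' @param p probability (vectorized).
#' @param cap maximum Phred score returned (default 200).
#' @return Numeric vector of Phred scores.
#' @export
phred <- function(p, cap = 200) {
  out <- -10 * log10(pmax(p, 0))
  pmin(out, cap)
}

# log10(sum(10^x)) without overflow; x may contain -Inf
log10_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log10(sum(10^(x - m)))
}

# fixed-format numeric rendering so written artifacts are byte-stable
fmt_num <- function(x, digits = 6) {
  out <- formatC(x, digits = digits, format = "g")
  out[is.na(x)] <- "NA"
  out
}

# FNV-1a hash of a string, returned as 8 hex digits (manifest fingerprints)
fnv1a_hash <- function(s) {
  h <- 2166136261
  for (code in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), code)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# strict tab-separated writer with stable formatting
write_tsv_stable <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.numeric(df2[[j]]) && !is.integer(df2[[j]])) {
      df2[[j]] <- fmt_num(df2[[j]], digits = 10)
    }
  }
  write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv_plain <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "", quote = "", ...)
}
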