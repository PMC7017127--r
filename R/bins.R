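#' Partition a reference into bins of fixed mappable length
#'
#' Walks each chromosome and cuts a new bin every `target_mappable`
#' mappable positions, so genomic bin widths vary wherever the mappability
#' track has holes; the last bin of a chromosome keeps the remainder. GC
#' fraction is computed over mappable positions only. Without a mappability
#' track every position counts as mappable.
#'
#' @param reference a [Biostrings::DNAStringSet] (or path to a FASTA file).
#' @param mappability optional data.frame of mappable intervals
#'   (`chrom,start,end`, 0-based half-open, e.g. read from BED); intervals
#'   are unioned per chromosome. Chromosomes absent from the table are
#'   fully unmappable.
#' @param target_mappable mappable bases per bin (default 10000).
#' @return data.frame of bins: `chrom,start,end` (0-based half-open bp),
#'   `mappable_bases`, `gc`.
#' @export
build_bins <- function(reference, mappability = NULL,
                       target_mappable = 10000L) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  if (length(reference) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), mappable_bases = integer(0),
                      gc = numeric(0), stringsAsFactors = FALSE))
  }
  if (!is.null(mappability)) {
    unknown <- setdiff(unique(mappability$chrom), names(reference))
    if (length(unknown) > 0) {
      stop("input error: mappability references unknown chromosome(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  out <- vector("list", length(reference))
  for (k in seq_along(reference)) {
    ch <- names(reference)[k]
    L <- length(reference[[k]])
    rv <- charToRaw(as.character(reference[[k]]))
    is_gc <- rv == as.raw(71L) | rv == as.raw(67L) |
      rv == as.raw(103L) | rv == as.raw(99L)          # G C g c
    if (is.null(mappability)) {
      mappable <- rep(TRUE, L)
    } else {
      mappable <- rep(FALSE, L)
      iv <- mappability[mappability$chrom == ch, , drop = FALSE]
      for (r in seq_len(nrow(iv))) {
        s <- max(0L, as.integer(iv$start[r]))
        e <- min(L, as.integer(iv$end[r]))
        if (e > s) mappable[(s + 1L):e] <- TRUE
      }
    }
    pos_map <- which(mappable)                        # 1-based positions
    n_map <- length(pos_map)
    if (n_map == 0L) {
      out[[k]] <- NULL
      next
    }
    n_bins <- ceiling(n_map / target_mappable)
    idx_start <- (seq_len(n_bins) - 1L) * target_mappable + 1L
    idx_end <- pmin(seq_len(n_bins) * target_mappable, n_map)
    cum_gc <- cumsum(is_gc[pos_map])
    gc_in_bin <- cum_gc[idx_end] - c(0L, cum_gc[idx_end[-n_bins]])
    out[[k]] <- data.frame(
      chrom = ch,
      start = pos_map[idx_start] - 1L,
      end = pos_map[idx_end],
      mappable_bases = idx_end - idx_start + 1L,
      gc = gc_in_bin / (idx_end - idx_start + 1L),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), mappable_bases = integer(0),
                      gc = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Count fragments into bins by midpoint
#'
#' Each fragment falls in the unique bin whose half-open interval
#' `[start, end)` contains its midpoint, so a midpoint sitting exactly on a
#' bin start belongs to that bin. Fragments on unknown chromosomes or in
#' inter-bin gaps are tallied as discarded, not fatal.
#'
#' @param fragments data.frame with columns `chrom` and `midpoint`
#'   (0-based bp).
#' @param bins bin data.frame from [build_bins()].
#' @param column name of the count column to fill (default `"count"`).
#' @return list with `bins` (counts filled) and `discarded` (integer tally).
#' @export
count_fragments <- function(fragments, bins, column = "count") {
  counts <- integer(nrow(bins))
  discarded <- 0L
  for (ch in unique(fragments$chrom)) {
    sel <- which(bins$chrom == ch)
    mids <- fragments$midpoint[fragments$chrom == ch]
    if (length(sel) == 0L) {
      discarded <- discarded + length(mids)
      message("discarding ", length(mids),
              " fragment(s) on unknown chromosome ", ch)
      next
    }
    starts <- bins$start[sel]
    ends <- bins$end[sel]
    idx <- findInterval(mids, starts)                 # 0 if before first bin
    inside <- idx >= 1L & mids < ends[pmax(idx, 1L)]
    discarded <- discarded + sum(!inside)
    tab <- tabulate(idx[inside], nbins = length(sel))
    counts[sel] <- counts[sel] + tab
  }
  bins[[column]] <- counts
  list(bins = bins, discarded = discarded)
}

#' GC-bias diagnostic table by GC decile
#'
#' Summarizes raw counts (and normalized ratios, when present) within GC
#' deciles, the usual quick look for residual coverage bias: on unbiased
#' data the post-normalization decile means are flat.
#'
#' @param bins bin data.frame carrying `gc`, `count_<sample>` and
#'   optionally `ratio_<sample>` columns.
#' @param sample `"tumor"` or `"normal"`.
#' @return data.frame with one row per occupied GC decile:
#'   `decile,gc_lo,gc_hi,n,mean_count,mean_ratio`.
#' @export
gc_bias_diagnostic <- function(bins, sample = c("normal", "tumor")) {
  sample <- match.arg(sample)
  empty <- data.frame(decile = integer(0), gc_lo = numeric(0),
                      gc_hi = numeric(0), n = integer(0),
                      mean_count = numeric(0), mean_ratio = numeric(0))
  if (nrow(bins) == 0) return(empty)
  cnt <- bins[[paste0("count_", sample)]]
  ratio_col <- paste0("ratio_", sample)
  ratio <- if (ratio_col %in% names(bins)) bins[[ratio_col]] else
    rep(NA_real_, nrow(bins))
  ok <- is.finite(bins$gc) & is.finite(cnt)
  if (!any(ok)) return(empty)
  gc <- bins$gc[ok]; cnt <- cnt[ok]; ratio <- ratio[ok]
  brk <- unique(quantile(gc, probs = seq(0, 1, 0.1), names = FALSE))
  dec <- if (length(brk) > 1) {
    cut(gc, breaks = brk, include.lowest = TRUE, labels = FALSE)
  } else rep(1L, length(gc))
  agg <- lapply(sort(unique(dec)), function(d) {
    in_d <- dec == d
    data.frame(decile = d, gc_lo = min(gc[in_d]), gc_hi = max(gc[in_d]),
               n = sum(in_d), mean_count = mean(cnt[in_d]),
               mean_ratio = mean(ratio[in_d], na.rm = TRUE))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
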