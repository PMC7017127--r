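#' Circular binary segmentation of a normalized coverage series
#'
#' Recursively segments `log2(ratio + pseudocount)`: within each current
#' segment the arc `(i, j]` maximizing the pooled two-sample t statistic
#' against its complement is located (exhaustive scan, compiled); the split
#' is accepted when its permutation p-value falls below `alpha`, and the
#' resulting pieces are segmented recursively. Adjacent segments whose
#' log2 means differ by less than `merge_threshold` are merged afterwards.
#' Missing ratios are excluded from the statistics but remain covered by
#' the output tiling, so segments always partition `[0, length(ratios))` in
#' bin indices.
#'
#' @param ratios numeric vector of normalized coverage ratios for one
#'   chromosome (may contain `NA`).
#' @param alpha permutation significance level for accepting a split
#'   (default 0.01).
#' @param n_permutations permutations per candidate split (default 1000).
#' @param min_width minimum arc and complement width in bins (default 2).
#' @param seed integer seed for the permutation stream.
#' @param pseudocount added to ratios before the log2 transform.
#' @param merge_threshold minimum |log2-mean| difference for two adjacent
#'   segments to stay separate.
#' @return data.frame of segments: `start_bin,end_bin` (half-open indices
#'   into `ratios`), `n_bins`, `n_finite`, `mean_ratio`, `mean_log2`.
#' @export
segment_cbs <- function(ratios, alpha = 0.01, n_permutations = 1000L,
                        min_width = 2L, seed = 1L, pseudocount = 1e-3,
                        merge_threshold = 0.1) {
  n_total <- length(ratios)
  stopifnot(n_total >= 1)
  finite_idx <- which(is.finite(ratios) & ratios >= 0)
  x <- log2(ratios[finite_idx] + pseudocount)
  m <- length(x)

  boundaries <- integer(0)                      # cuts in finite-index space
  if (m >= 2 * min_width) {
    withr::with_seed(derive_seed(seed, "cbs"), {
      # iterative recursion over (lo, hi] half-open finite-index windows
      queue <- list(c(0L, m))
      while (length(queue) > 0) {
        win <- queue[[1]]
        queue <- queue[-1]
        lo <- win[1]; hi <- win[2]
        nn <- hi - lo
        if (nn < 2 * min_width) next
        xi <- x[(lo + 1L):hi]
        scan <- cbs_max_arc(xi, as.integer(min_width))
        if (scan$i < 0 || is.na(scan$abs_t) || scan$abs_t == 0) next
        p <- cbs_perm_pvalue(xi, scan$abs_t, min_width,
                             n_permutations, alpha)
        if (p < alpha) {
          cuts <- sort(unique(c(scan$i, scan$j)))
          cuts <- cuts[cuts > 0 & cuts < nn]
          if (length(cuts) == 0) next
          pieces <- cbind(c(0L, cuts), c(cuts, nn))
          for (r in seq_len(nrow(pieces))) {
            queue[[length(queue) + 1L]] <- c(lo + pieces[r, 1],
                                             lo + pieces[r, 2])
          }
          boundaries <- c(boundaries, lo + cuts)
        }
      }
    })
  }
  boundaries <- sort(unique(boundaries))

  # merge adjacent segments with close log2 means, smallest gap first
  repeat {
    cuts <- c(0L, boundaries, m)
    if (length(boundaries) == 0) break
    means <- vapply(seq_len(length(cuts) - 1L), function(s) {
      mean(x[(cuts[s] + 1L):cuts[s + 1L]])
    }, numeric(1))
    gaps <- abs(diff(means))
    if (all(gaps >= merge_threshold)) break
    drop <- which.min(gaps)
    boundaries <- boundaries[-drop]
  }

  # map finite-index cuts back to original bin indices: a cut before
  # finite position k+1 lands at that bin's original index
  cuts_fin <- c(0L, boundaries, m)
  orig_cuts <- c(0L, finite_idx[boundaries + 1L] - 1L, n_total)
  if (m == 0) orig_cuts <- c(0L, n_total)
  segs <- data.frame(start_bin = orig_cuts[-length(orig_cuts)],
                     end_bin = orig_cuts[-1])
  segs$n_bins <- segs$end_bin - segs$start_bin
  segs$n_finite <- vapply(seq_len(nrow(segs)), function(s) {
    sum(finite_idx > segs$start_bin[s] & finite_idx <= segs$end_bin[s])
  }, integer(1))
  segs$mean_ratio <- vapply(seq_len(nrow(segs)), function(s) {
    sel <- finite_idx[finite_idx > segs$start_bin[s] &
                        finite_idx <= segs$end_bin[s]]
    if (length(sel) == 0) NA_real_ else mean(ratios[sel])
  }, numeric(1))
  segs$mean_log2 <- vapply(seq_len(nrow(segs)), function(s) {
    if (m == 0) return(NA_real_)
    lo <- cuts_fin[s]; hi <- cuts_fin[s + 1L]
    if (hi <= lo) NA_real_ else mean(x[(lo + 1L):hi])
  }, numeric(1))
  segs
}

# permutation p-value for the max-|t| statistic with early rejection:
# once the exceedance count guarantees p >= alpha the loop stops without
# changing the accept/reject decision
cbs_perm_pvalue <- function(x, obs_abs_t, min_width, n_permutations,
                            alpha) {
  if (!is.finite(obs_abs_t)) {
    # infinite t (zero within-variance, distinct means): no permutation
    # can exceed it unless it also reaches +Inf; count those directly
    count <- 0L
    for (b in seq_len(n_permutations)) {
      tb <- cbs_max_abs_t(sample(x), as.integer(min_width))
      if (is.finite(tb)) next
      count <- count + 1L
      if (1 + count >= alpha * (1 + n_permutations)) break
    }
    return((1 + count) / (1 + n_permutations))
  }
  reject_at <- alpha * (1 + n_permutations) - 1     # count making p >= alpha
  count <- 0L
  for (b in seq_len(n_permutations)) {
    tb <- cbs_max_abs_t(sample(x), as.integer(min_width))
    if (!is.na(tb) && tb >= obs_abs_t) {
      count <- count + 1L
      if (count >= reject_at) break
    }
  }
  (1 + count) / (1 + n_permutations)
}

#' Segment every chromosome of a normalized bin table
#'
#' Applies [segment_cbs()] per chromosome to `ratio_<sample>` and returns
#' genome-wide segments with genomic coordinates attached.
#'
#' @param bins normalized bin data.frame (see [normalize_coverage()]).
#' @param sample `"tumor"` or `"normal"`.
#' @param ... passed to [segment_cbs()]; the per-chromosome seed is derived
#'   from `seed` and the chromosome name.
#' @param seed integer seed.
#' @return data.frame of segments with `chrom`, genomic `start`/`end`,
#'   `start_bin`/`end_bin` (indices within the chromosome) and the
#'   [segment_cbs()] summary columns.
#' @export
segment_coverage <- function(bins, sample = "tumor", seed = 1L, ...) {
  ratio_col <- paste0("ratio_", sample)
  stopifnot(ratio_col %in% names(bins))
  out <- list()
  for (ch in unique(bins$chrom)) {
    sub <- bins[bins$chrom == ch, , drop = FALSE]
    segs <- segment_cbs(sub[[ratio_col]],
                        seed = derive_seed(seed, paste0("cbs_", ch)), ...)
    segs$chrom <- ch
    segs$start <- sub$start[segs$start_bin + 1L]
    segs$end <- sub$end[segs$end_bin]
    out[[ch]] <- segs[, c("chrom", "start", "end", "start_bin", "end_bin",
                          "n_bins", "n_finite", "mean_ratio", "mean_log2")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
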