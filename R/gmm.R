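#' Genotype copy-number segments with a 1-D Gaussian mixture
#'
#' Fits Gaussian mixtures to the segment mean ratios, weighted by segment
#' length in bins, by EM with k-means initialization and multiple restarts;
#' the number of components is selected by BIC over `k = 1 .. max_copy+1`.
#' Components share a floored variance so near-noiseless segment means keep
#' the likelihood bounded. Each component is mapped to the integer copy
#' state `c` minimizing `|component_mean - c/2|` (diploid baseline);
#' components landing on the same state are merged. Every segment receives
#' the state of its maximum-posterior component together with that
#' posterior probability.
#'
#' @param segments segment data.frame from [segment_coverage()] (needs
#'   `mean_ratio` and `n_finite` or `n_bins`).
#' @param max_copy largest copy state considered (default 6).
#' @param seed integer seed (k-means restarts).
#' @param baseline_ploidy normal ploidy (default 2); a ratio of 1
#'   corresponds to this state.
#' @param n_restarts EM restarts per k.
#' @param max_iter,tol EM stopping rule.
#' @param var_floor lower bound on the shared component variance.
#' @return Object of class `cnv_map`: list with `segments` (input plus
#'   `copy_state`, `posterior`), `components`
#'   (`mean,sd,weight,copy_state`), `k`, `baseline_ploidy`.
#' @export
genotype_segments <- function(segments, max_copy = 6L, seed = 1L,
                              baseline_ploidy = 2L, n_restarts = 5L,
                              max_iter = 200L, tol = 1e-8,
                              var_floor = 1e-4) {
  w_all <- if ("n_finite" %in% names(segments)) segments$n_finite else
    segments$n_bins
  usable <- is.finite(segments$mean_ratio) & w_all > 0
  if (!any(usable)) stop("no segment with a finite mean ratio", call. = FALSE)
  x <- segments$mean_ratio[usable]
  w <- as.numeric(w_all[usable])

  fit <- withr::with_seed(derive_seed(seed, "gmm"), {
    best <- NULL
    for (k in seq_len(max_copy + 1L)) {
      if (k > length(unique(x))) break
      f <- gmm1d_fit(x, w, k, n_restarts = n_restarts,
                     max_iter = max_iter, tol = tol, var_floor = var_floor)
      if (is.null(f)) next
      if (is.null(best) || f$bic < best$bic) best <- f
    }
    best
  })
  if (is.null(fit)) {   # single distinct value: one forced component
    fit <- list(mu = x[1], sd = sqrt(var_floor), pi = 1, k = 1L,
                loglik = NA_real_, bic = NA_real_, converged = TRUE)
  }

  states <- vapply(fit$mu, function(m) {
    candidates <- 0:max_copy
    candidates[which.min(abs(m - candidates / baseline_ploidy))]
  }, integer(1))

  # merge components that map to the same copy state
  if (anyDuplicated(states)) {
    merged <- lapply(sort(unique(states)), function(s) {
      sel <- states == s
      pw <- fit$pi[sel]
      c(mu = sum(fit$mu[sel] * pw) / sum(pw), pi = sum(pw), state = s)
    })
    mm <- do.call(rbind, merged)
    fit$mu <- mm[, "mu"]
    fit$pi <- mm[, "pi"]
    states <- as.integer(mm[, "state"])
    fit$k <- length(states)
  }

  # responsibilities of every usable segment under the final components
  resp <- gmm1d_responsibilities(x, fit$mu, fit$sd, fit$pi)
  comp <- max.col(resp, ties.method = "first")
  segments$copy_state <- NA_integer_
  segments$posterior <- NA_real_
  segments$copy_state[usable] <- states[comp]
  segments$posterior[usable] <- resp[cbind(seq_len(nrow(resp)), comp)]

  out <- list(segments = segments,
              components = data.frame(mean = fit$mu, sd = fit$sd,
                                      weight = fit$pi,
                                      copy_state = states),
              k = fit$k,
              baseline_ploidy = baseline_ploidy,
              converged = fit$converged)
  class(out) <- "cnv_map"
  out
}

# weighted 1-D Gaussian mixture with shared variance; returns NULL when k
# exceeds the data's support
gmm1d_fit <- function(x, w, k, n_restarts, max_iter, tol, var_floor) {
  n_eff <- sum(w)
  best <- NULL
  if (k == 1L) n_restarts <- 1L
  for (r in seq_len(n_restarts)) {
    ux <- unique(x)
    mu <- if (k == 1L) {
      sum(w * x) / n_eff
    } else if (length(ux) <= k) {
      sort(ux)                            # one center per distinct value
    } else {
      km <- tryCatch(kmeans(x, centers = k, nstart = 1),
                     error = function(e) NULL)
      if (is.null(km)) {
        quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
      } else {
        as.numeric(km$centers)
      }
    }
    s2 <- max(var_floor, sum(w * (x - mean(x))^2) / n_eff)
    pi_k <- rep(1 / k, k)
    ll_prev <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(k), function(j) {
        pi_k[j] * dnorm(x, mu[j], sqrt(s2))
      }, numeric(length(x)))
      dens <- matrix(dens, nrow = length(x))
      tot <- rowSums(dens)
      tot[tot == 0] <- .Machine$double.xmin
      resp <- dens / tot
      ll <- sum(w * log(tot))
      wr <- resp * w
      nk <- colSums(wr)
      nk[nk == 0] <- .Machine$double.xmin
      mu <- colSums(wr * x) / nk
      s2 <- max(var_floor,
                sum(wr * (matrix(x, length(x), k) -
                            matrix(mu, length(x), k, byrow = TRUE))^2) /
                  n_eff)
      pi_k <- nk / n_eff
      if (is.finite(ll) && abs(ll - ll_prev) < tol * (1 + abs(ll))) {
        converged <- TRUE
        break
      }
      ll_prev <- ll
    }
    if (!converged) {
      warning("EM did not converge for k = ", k,
              "; best restart retained", call. = FALSE)
    }
    n_par <- 2 * k                       # k means + (k-1) weights + 1 var
    bic <- -2 * ll + n_par * log(n_eff)
    cand <- list(mu = mu, sd = sqrt(s2), pi = pi_k, k = k, loglik = ll,
                 bic = bic, converged = converged)
    if (is.null(best) || cand$loglik > best$loglik) best <- cand
  }
  best
}

gmm1d_responsibilities <- function(x, mu, sd, pi_k) {
  k <- length(mu)
  dens <- vapply(seq_len(k), function(j) pi_k[j] * dnorm(x, mu[j], sd),
                 numeric(length(x)))
  dens <- matrix(dens, nrow = length(x))
  tot <- rowSums(dens)
  tot[tot == 0] <- .Machine$double.xmin
  dens / tot
}

#' Write a copy-number map as BED plus a segment TSV
#'
#' BED columns: `chrom,start,end,name=copy_state,score=round(1000*posterior)`.
#' The companion TSV keeps mean ratios and bin bookkeeping.
#'
#' @param map a `cnv_map` from [genotype_segments()].
#' @param bed_path,tsv_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the segment data.frame written.
#' @export
write_cnv_map <- function(map, bed_path = NULL, tsv_path = NULL) {
  seg <- map$segments
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = seg$chrom, start = seg$start, end = seg$end,
                      name = ifelse(is.na(seg$copy_state), "unassigned",
                                    as.character(seg$copy_state)),
                      score = ifelse(is.na(seg$posterior), 0L,
                                     as.integer(round(1000 * seg$posterior))))
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE, eol = "\n")
  }
  if (!is.null(tsv_path)) write_tsv_stable(seg, tsv_path)
  invisible(seg)
}

#' Expand a copy-number map to per-bin state calls
#'
#' @param map a `cnv_map`.
#' @param bins the bin table the segments were built from.
#' @return Integer vector of called states, one per row of `bins` (`NA`
#'   where unassigned).
#' @export
bin_copy_states <- function(map, bins) {
  seg <- map$segments
  out <- rep(NA_integer_, nrow(bins))
  for (ch in unique(seg$chrom)) {
    rows <- which(bins$chrom == ch)
    sch <- seg[seg$chrom == ch, , drop = FALSE]
    for (s in seq_len(nrow(sch))) {
      idx <- rows[(sch$start_bin[s] + 1L):sch$end_bin[s]]
      out[idx] <- sch$copy_state[s]
    }
  }
  out
}
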