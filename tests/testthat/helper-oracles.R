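# Independent oracles used across tests.

# Exhaustive single change-point scan: pooled two-sample t over every split
# k (left = 1..k, right = k+1..n), written independently of the package's
# arc scan.  Returns the argmax split and its |t|.
oracle_best_split <- function(x, min_width = 2) {
  n <- length(x)
  best_k <- NA_integer_
  best_t <- -Inf
  for (k in min_width:(n - min_width)) {
    a <- x[1:k]
    b <- x[(k + 1):n]
    sp <- ((k - 1) * var(a) + (n - k - 1) * var(b)) / (n - 2)
    tt <- if (sp <= 0) {
      if (mean(a) == mean(b)) 0 else Inf
    } else {
      abs(mean(a) - mean(b)) / sqrt(sp * (1 / k + 1 / (n - k)))
    }
    if (tt > best_t) {
      best_t <- tt
      best_k <- k
    }
  }
  list(k = best_k, abs_t = best_t)
}

# Arbitrary-precision somatic-labelling oracle: re-derives flat-prior
# posteriors and the labelling rules in Python/mpmath at 50 digits,
# completely outside the package code path.
oracle_labels_mpmath <- function(sites, thresholds = somatic_thresholds()) {
  tsv <- tempfile(fileext = ".tsv")
  cols <- c("qual", "t_gl_rr", "t_gl_ra", "t_gl_aa", "t_ad_alt", "t_dp",
            "n_gl_rr", "n_gl_ra", "n_gl_aa", "n_ad_alt", "n_dp")
  write.table(format(sites[, cols], digits = 17, scientific = FALSE,
                     trim = TRUE),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  script <- test_path("oracle_label.py")
  out <- system2("python", c(script, tsv,
                             format(thresholds$min_evidence_phred),
                             format(thresholds$low_af_cutoff),
                             format(thresholds$min_af),
                             format(thresholds$min_alt_reads),
                             format(thresholds$min_site_qual)),
                 stdout = TRUE)
  stopifnot(length(out) == nrow(sites))
  out
}

# Minimal site-record constructor for labelling tests.
make_site <- function(qual, t_gl, t_ad, t_dp, n_gl, n_ad, n_dp,
                      chrom = "chr1", pos = 100) {
  data.frame(chrom = chrom, pos = pos, id = ".", ref = "A", alt = "T",
             qual = qual,
             t_gl_rr = t_gl[1], t_gl_ra = t_gl[2], t_gl_aa = t_gl[3],
             t_ad_ref = t_ad[1], t_ad_alt = t_ad[2], t_dp = t_dp,
             n_gl_rr = n_gl[1], n_gl_ra = n_gl[2], n_gl_aa = n_gl[3],
             n_ad_ref = n_ad[1], n_ad_alt = n_ad[2], n_dp = n_dp,
             stringsAsFactors = FALSE)
}

# Zero-row site table in the simulator's layout.
cfg_sites_empty <- function() {
  make_site(1, c(0, 0, 0), c(0, 0), 1, c(0, 0, 0), c(0, 0), 1)[0, ]
}

# Small flat-GC test genome (one sequence per entry of lengths).
make_flat_reference <- function(lengths, gc = 0.5, seed = 1) {
  withr::with_seed(seed, {
    seqs <- vapply(lengths, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = "")
    }, character(1))
  })
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- paste0("chr", seq_along(lengths))
  dss
}
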