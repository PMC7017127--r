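#' Thresholds for site filtering and somatic labelling
#'
#' Defaults follow the analysis this package implements: a site must reach
#' allele fraction 0.1 in at least one sample with at least 2 supporting
#' reads and a site quality strictly greater than 5; somatic calls need
#' both Phred-scaled evidence scores (tumor non-reference, normal
#' reference) at or above 10; tumor variants below allele fraction 0.25
#' that also appear at low frequency in the normal are removed as shared
#' artifacts; the downstream gene-level filter demands quality strictly
#' greater than 20.
#'
#' @param min_evidence_phred minimum Phred evidence for both somatic
#'   posteriors (default 10).
#' @param low_af_cutoff allele fraction below which a variant counts as
#'   low-frequency (default 0.25; must be < 0.5).
#' @param min_af minimum allele fraction in at least one sample (0.1).
#' @param min_alt_reads minimum alternate-supporting reads in the best
#'   sample (2).
#' @param min_site_qual minimum Phred site quality, strict (5).
#' @param min_impact_qual site quality for the gene-level filter, strict
#'   (20).
#' @return Object of class `somatic_thresholds`.
#' @export
somatic_thresholds <- function(min_evidence_phred = 10,
                               low_af_cutoff = 0.25,
                               min_af = 0.1,
                               min_alt_reads = 2,
                               min_site_qual = 5,
                               min_impact_qual = 20) {
  stopifnot(low_af_cutoff < 0.5,
            min_evidence_phred >= 0, min_af >= 0, min_alt_reads >= 0,
            min_site_qual >= 0, min_impact_qual >= 0)
  out <- list(min_evidence_phred = min_evidence_phred,
              low_af_cutoff = low_af_cutoff,
              min_af = min_af,
              min_alt_reads = min_alt_reads,
              min_site_qual = min_site_qual,
              min_impact_qual = min_impact_qual)
  class(out) <- "somatic_thresholds"
  out
}

#' Site-level filters on paired variant records
#'
#' A site passes when the allele fraction reaches `min_af` in at least one
#' sample, the best sample carries at least `min_alt_reads` alternate
#' reads, and QUAL is strictly greater than `min_site_qual`. Failures
#' report the first violated rule, checked in the order `no_coverage`
#' (both depths zero), `min_alt_reads`, `min_af`, `min_site_qual`.
#'
#' @param sites data.frame of variant records (columns `qual`,
#'   `t_ad_alt`, `t_dp`, `n_ad_alt`, `n_dp`; see [simulate_variants()]).
#' @param thresholds a [somatic_thresholds()].
#' @return Character vector, one element per site: `NA` for pass,
#'   otherwise the name of the first violated rule.
#' @export
site_filter <- function(sites, thresholds = somatic_thresholds()) {
  af_t <- ifelse(sites$t_dp > 0, sites$t_ad_alt / sites$t_dp, 0)
  af_n <- ifelse(sites$n_dp > 0, sites$n_ad_alt / sites$n_dp, 0)
  max_af <- pmax(af_t, af_n)
  max_alt <- pmax(sites$t_ad_alt, sites$n_ad_alt)
  or_false <- function(v) { v[is.na(v)] <- FALSE; v }
  reason <- rep(NA_character_, nrow(sites))
  reason[or_false(sites$qual <= thresholds$min_site_qual)] <- "min_site_qual"
  reason[or_false(max_af < thresholds$min_af)] <- "min_af"
  reason[or_false(max_alt < thresholds$min_alt_reads)] <- "min_alt_reads"
  reason[or_false(sites$t_dp == 0 & sites$n_dp == 0)] <- "no_coverage"
  reason
}

#' Flat-prior genotype posteriors from log10 likelihoods
#'
#' Normalizes `10^GL` over the three diploid genotypes (hom-ref, het,
#' hom-alt) under a flat prior, in log space for numerical safety.
#'
#' @param gl numeric vector of 3 log10 GLs, or an n x 3 matrix.
#' @return Posterior probabilities in the same shape; rows with no finite
#'   GL become `NA`.
#' @export
genotype_posteriors <- function(gl) {
  vec_in <- is.null(dim(gl))
  m <- if (vec_in) matrix(gl, nrow = 1) else as.matrix(gl)
  stopifnot(ncol(m) == 3)
  out <- matrix(NA_real_, nrow(m), 3)
  for (i in seq_len(nrow(m))) {
    g <- m[i, ]
    g[is.na(g)] <- -Inf
    if (all(!is.finite(g))) next
    z <- log10_sum_exp(g)
    out[i, ] <- 10^(g - z)
  }
  colnames(out) <- c("hom_ref", "het", "hom_alt")
  if (vec_in) out[1, ] else out
}

#' Label paired variant records as somatic, germline or filtered
#'
#' For each record that passes [site_filter()], flat-prior genotype
#' posteriors are computed for both samples. The tumor evidence is the
#' Phred-scaled posterior that the tumor is non-reference,
#' `-10*log10(1 - max(P(het), P(hom-alt)))`, and the normal evidence the
#' Phred-scaled posterior that the normal is reference,
#' `-10*log10(1 - P(hom-ref))`; both are capped at 200. Labels:
#'
#' * `shared_low_frequency` -- tumor allele fraction below
#'   `low_af_cutoff`, with at least one alternate read in the normal also
#'   below `low_af_cutoff` (the contamination-artifact removal; applied
#'   before the evidence rule);
#' * `somatic` -- both evidence scores at or above `min_evidence_phred`;
#' * `germline` -- the normal's non-reference posterior reaches the same
#'   evidence threshold;
#' * `reference` -- everything else;
#' * `failed_site_filter` -- a site filter fired, or a sample has no
#'   usable genotype likelihood (`no_likelihood`).
#'
#' @param sites data.frame of variant records (see [simulate_variants()]
#'   for the column layout).
#' @param thresholds a [somatic_thresholds()].
#' @return `sites` with columns `label`, `filter_reason`,
#'   `tumor_nonref_phred`, `normal_ref_phred` added.
#' @export
label_somatic <- function(sites, thresholds = somatic_thresholds()) {
  n <- nrow(sites)
  reason <- site_filter(sites, thresholds)
  gl_t <- as.matrix(sites[, c("t_gl_rr", "t_gl_ra", "t_gl_aa")])
  gl_n <- as.matrix(sites[, c("n_gl_rr", "n_gl_ra", "n_gl_aa")])
  post_t <- genotype_posteriors(gl_t)
  post_n <- genotype_posteriors(gl_n)
  no_lik <- !is.finite(post_t[, 1]) | !is.finite(post_n[, 1])

  t_nonref <- pmax(post_t[, 2], post_t[, 3])
  tumor_nonref_phred <- phred(1 - t_nonref)
  normal_ref_phred <- phred(1 - post_n[, 1])
  normal_nonref_phred <- phred(post_n[, 1])

  af_t <- ifelse(sites$t_dp > 0, sites$t_ad_alt / sites$t_dp, 0)
  af_n <- ifelse(sites$n_dp > 0, sites$n_ad_alt / sites$n_dp, 0)

  or_false <- function(v) { v[is.na(v)] <- FALSE; v }
  label <- rep("reference", n)
  label[or_false(normal_nonref_phred >= thresholds$min_evidence_phred)] <-
    "germline"
  ok_somatic <- tumor_nonref_phred >= thresholds$min_evidence_phred &
    normal_ref_phred >= thresholds$min_evidence_phred
  label[or_false(ok_somatic)] <- "somatic"
  shared <- af_t < thresholds$low_af_cutoff & sites$n_ad_alt >= 1 &
    af_n < thresholds$low_af_cutoff
  label[or_false(shared)] <- "shared_low_frequency"
  label[no_lik] <- "failed_site_filter"
  reason[no_lik & is.na(reason)] <- "no_likelihood"
  label[!is.na(reason)] <- "failed_site_filter"

  sites$label <- label
  sites$filter_reason <- reason
  sites$tumor_nonref_phred <- tumor_nonref_phred
  sites$normal_ref_phred <- normal_ref_phred
  sites
}

#' Read a paired-sample VCF into the flat site table
#'
#' Uses `vcfR` to parse a VCF 4.2 with `GL` or `PL`, `AD` and `DP` FORMAT
#' fields; PL values are converted to GL as `-PL/10`. Multi-allelic
#' records are split into biallelic records: allele `k` keeps the diploid
#' GL triple for genotypes `0/0`, `0/k`, `k/k` and the AD pair
#' `(ref_depth, depth of allele k)`.
#'
#' @param path VCF path.
#' @param tumor_name,normal_name sample column names (must exist in the
#'   header).
#' @return data.frame of sites in the layout of [simulate_variants()],
#'   plus `orig_row` (input record index) and `n_alt_alleles`.
#' @export
read_paired_vcf <- function(path, tumor_name = "TUMOR",
                            normal_name = "NORMAL") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (!all(c(tumor_name, normal_name) %in% samples)) {
    stop("sample(s) not found in VCF header: ",
         paste(setdiff(c(tumor_name, normal_name), samples),
               collapse = ", "), call. = FALSE)
  }
  n_rec <- nrow(vcf@fix)
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      id = character(0), ref = character(0),
                      alt = character(0), qual = numeric(0),
                      t_gl_rr = numeric(0), t_gl_ra = numeric(0),
                      t_gl_aa = numeric(0), t_ad_ref = integer(0),
                      t_ad_alt = integer(0), t_dp = integer(0),
                      n_gl_rr = numeric(0), n_gl_ra = numeric(0),
                      n_gl_aa = numeric(0), n_ad_ref = integer(0),
                      n_ad_alt = integer(0), n_dp = integer(0),
                      orig_row = integer(0), n_alt_alleles = integer(0),
                      stringsAsFactors = FALSE)
  if (n_rec == 0) return(empty)

  gl_chr <- suppressWarnings(vcfR::extract.gt(vcf, element = "GL"))
  pl_chr <- suppressWarnings(vcfR::extract.gt(vcf, element = "PL"))
  ad_chr <- suppressWarnings(vcfR::extract.gt(vcf, element = "AD"))
  dp_chr <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP"))
  use_gl <- !all(is.na(gl_chr))
  use_pl <- !use_gl && !all(is.na(pl_chr))
  if (!use_gl && !use_pl) {
    stop("format error: VCF has neither GL nor PL FORMAT fields (first record ",
         vcf@fix[1, "CHROM"], ":", vcf@fix[1, "POS"], ")", call. = FALSE)
  }
  lik_chr <- if (use_gl) gl_chr else pl_chr

  split_num <- function(s) {
    if (is.na(s)) return(numeric(0))
    suppressWarnings(as.numeric(strsplit(s, ",", fixed = TRUE)[[1]]))
  }
  parse_sample <- function(rec, sample, allele_k) {
    lik <- split_num(lik_chr[rec, sample])
    if (use_pl) lik <- -lik / 10
    # diploid genotype index (0-based) for pair (a, b), a<=b: b(b+1)/2 + a
    idx <- c(1L,
             allele_k * (allele_k + 1L) / 2L + 1L,
             allele_k * (allele_k + 1L) / 2L + allele_k + 1L)
    gl <- if (length(lik) >= max(idx)) lik[idx] else rep(NA_real_, 3)
    ad <- split_num(ad_chr[rec, sample])
    ad_ref <- if (length(ad) >= 1) ad[1] else NA_real_
    ad_alt <- if (length(ad) >= allele_k + 1) ad[allele_k + 1] else NA_real_
    dp <- suppressWarnings(as.numeric(dp_chr[rec, sample]))
    if (is.na(dp)) dp <- sum(ad, na.rm = TRUE)
    list(gl = gl, ad_ref = ad_ref, ad_alt = ad_alt, dp = dp)
  }

  rows <- vector("list", n_rec)
  for (rec in seq_len(n_rec)) {
    alts <- strsplit(vcf@fix[rec, "ALT"], ",", fixed = TRUE)[[1]]
    per_alt <- lapply(seq_along(alts), function(k) {
      tu <- parse_sample(rec, tumor_name, k)
      no <- parse_sample(rec, normal_name, k)
      data.frame(chrom = vcf@fix[rec, "CHROM"],
                 pos = as.integer(vcf@fix[rec, "POS"]),
                 id = vcf@fix[rec, "ID"],
                 ref = vcf@fix[rec, "REF"], alt = alts[k],
                 qual = suppressWarnings(as.numeric(vcf@fix[rec, "QUAL"])),
                 t_gl_rr = tu$gl[1], t_gl_ra = tu$gl[2], t_gl_aa = tu$gl[3],
                 t_ad_ref = tu$ad_ref, t_ad_alt = tu$ad_alt, t_dp = tu$dp,
                 n_gl_rr = no$gl[1], n_gl_ra = no$gl[2], n_gl_aa = no$gl[3],
                 n_ad_ref = no$ad_ref, n_ad_alt = no$ad_alt, n_dp = no$dp,
                 orig_row = rec, n_alt_alleles = length(alts),
                 stringsAsFactors = FALSE)
    })
    rows[[rec]] <- do.call(rbind, per_alt)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run somatic labelling over a paired VCF
#'
#' Reads the VCF, splits multi-allelic records, applies [site_filter()]
#' and [label_somatic()], and writes (optionally) a labelled VCF -- each
#' record gains `LABEL`, `SSC` (tumor non-reference Phred), `NRP` (normal
#' reference Phred) INFO keys and a `SOMATIC` flag on somatic calls -- and
#' a label-count summary TSV.
#'
#' @param vcf_in input VCF path.
#' @param tumor_name,normal_name sample column names.
#' @param thresholds a [somatic_thresholds()].
#' @param out_vcf,out_summary optional output paths.
#' @return list with `calls` (labelled site table), `summary`
#'   (data.frame `label,count`), and the output paths.
#' @export
run_labelling <- function(vcf_in, tumor_name = "TUMOR",
                          normal_name = "NORMAL",
                          thresholds = somatic_thresholds(),
                          out_vcf = NULL, out_summary = NULL) {
  sites <- read_paired_vcf(vcf_in, tumor_name, normal_name)
  calls <- if (nrow(sites) > 0) label_somatic(sites, thresholds) else {
    sites$label <- character(0)
    sites$filter_reason <- character(0)
    sites$tumor_nonref_phred <- numeric(0)
    sites$normal_ref_phred <- numeric(0)
    sites
  }
  lab_levels <- c("somatic", "germline", "reference",
                  "shared_low_frequency", "failed_site_filter")
  counts <- vapply(lab_levels, function(l) sum(calls$label == l), integer(1))
  summary_df <- data.frame(label = lab_levels, count = counts,
                           row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(out_vcf)) {
    write_labelled_vcf(vcf_in, calls, out_vcf)
  }
  if (!is.null(out_summary)) {
    write_tsv_stable(summary_df, out_summary)
  }
  list(calls = calls, summary = summary_df, out_vcf = out_vcf,
       out_summary = out_summary)
}

# rewrite the input VCF with labelling INFO keys; one output line per
# (possibly split) biallelic call
write_labelled_vcf <- function(vcf_in, calls, out_path) {
  lines <- readLines(vcf_in)
  meta <- lines[startsWith(lines, "##")]
  header_row <- lines[startsWith(lines, "#CHROM")]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  extra <- c(
    "##INFO=<ID=SOMATIC,Number=0,Type=Flag,Description=\"Somatic call\">",
    "##INFO=<ID=LABEL,Number=1,Type=String,Description=\"Somatic labelling outcome\">",
    "##INFO=<ID=SSC,Number=1,Type=Float,Description=\"Phred posterior tumor is non-reference\">",
    "##INFO=<ID=NRP,Number=1,Type=Float,Description=\"Phred posterior normal is reference\">")
  out_body <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    rec <- calls$orig_row[i]
    fields <- strsplit(body[rec], "\t", fixed = TRUE)[[1]]
    fields[5] <- calls$alt[i]
    info <- sprintf("LABEL=%s;SSC=%.2f;NRP=%.2f", calls$label[i],
                    calls$tumor_nonref_phred[i], calls$normal_ref_phred[i])
    if (calls$label[i] == "somatic") info <- paste0("SOMATIC;", info)
    old_info <- fields[8]
    fields[8] <- if (old_info %in% c(".", "")) info else
      paste0(old_info, ";", info)
    if (calls$n_alt_alleles[i] > 1) {
      # decomposed record: rewrite FORMAT fields for the split allele
      fields[9] <- "GL:AD:DP"
      fields[10] <- sprintf("%.4f,%.4f,%.4f:%d,%d:%d",
                            calls$t_gl_rr[i], calls$t_gl_ra[i],
                            calls$t_gl_aa[i], as.integer(calls$t_ad_ref[i]),
                            as.integer(calls$t_ad_alt[i]),
                            as.integer(calls$t_dp[i]))
      fields[11] <- sprintf("%.4f,%.4f,%.4f:%d,%d:%d",
                            calls$n_gl_rr[i], calls$n_gl_ra[i],
                            calls$n_gl_aa[i], as.integer(calls$n_ad_ref[i]),
                            as.integer(calls$n_ad_alt[i]),
                            as.integer(calls$n_dp[i]))
    }
    out_body[i] <- paste(fields, collapse = "\t")
  }
  writeLines(c(meta, extra, header_row, out_body), out_path)
  invisible(out_path)
}
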