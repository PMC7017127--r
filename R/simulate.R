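#' Default planted copy-number truth
#'
#' Tumor copy-number segments planted over a diploid baseline in the default
#' synthetic genome: states 1, 3 and 4 on a copy-2 background, each segment
#' at least 30 bins long at the default 10 kb bin size.
#'
#' @param n_chromosomes,chrom_length_bp genome shape (see
#'   [simulation_config()]).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open bp) and `copy`.
#' @export
default_cnv_truth <- function(n_chromosomes = 4L, chrom_length_bp = 5e6) {
  plan <- data.frame(
    chrom = c("chr1", "chr2", "chr3", "chr4"),
    start = c(1.5e6, 1.0e6, 3.0e6, 0.5e6),
    end   = c(2.5e6, 1.5e6, 3.6e6, 1.0e6),
    copy  = c(3L, 1L, 4L, 3L),
    stringsAsFactors = FALSE
  )
  keep <- plan$chrom %in% paste0("chr", seq_len(n_chromosomes)) &
    plan$end <= chrom_length_bp
  plan[keep, , drop = FALSE]
}

#' Configuration for the synthetic paired tumor/normal dataset
#'
#' Bundles every knob of the generator: genome shape, GC composition,
#' coverage model, planted copy-number truth, variant class counts and the
#' sequencing error model. Identical config + seed yields byte-identical
#' artifacts.
#'
#' The coverage model is Poisson: normal bins draw
#' `Poisson(mean_fragments_per_bin * f(gc))` and tumor bins
#' `Poisson(mean_fragments_per_bin * (c/2) * f(gc))` with `c` the true copy
#' number and GC bias `f(gc) = exp(a*(gc-0.5) + b*(gc-0.5)^2)`.
#'
#' @param seed integer seed; all randomness flows from it.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp length of each chromosome in bp.
#' @param gc_profile piecewise-constant target GC fraction, recycled across
#'   consecutive `gc_window_bp` windows of each chromosome; values must lie
#'   in (0, 1) and should stay within \[0.2, 0.8\] to look genome-like.
#' @param gc_window_bp width of one constant-GC window.
#' @param mean_fragments_per_bin expected fragments per diploid unbiased bin.
#' @param gc_bias named vector `c(a = , b = )` of bias coefficients.
#' @param cnv_truth data.frame of planted tumor segments
#'   (`chrom,start,end,copy`, 0-based half-open, copy in 0..6);
#'   non-overlapping within a chromosome.
#' @param n_germline_variants,n_somatic_variants,n_artifact_variants number
#'   of variant sites per truth class (germline sites are split between
#'   heterozygous and homozygous); artifact sites are shared low-frequency
#'   in both samples.
#' @param site_depth_mean mean per-sample sequencing depth at variant sites.
#' @param base_error_rate per-base error rate epsilon in (0, 0.1] used both
#'   to perturb allele counts and inside the diploid genotype-likelihood
#'   model.
#' @param bin_target_mappable mappable bases per coverage bin.
#' @param tumor_name,normal_name VCF sample column names.
#' @param n_genes size of the synthetic gene universe used for annotations,
#'   homolog mapping and the cancer-gene-census fixture.
#' @return An object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 4L,
                              chrom_length_bp = 5e6,
                              gc_profile = c(0.35, 0.45, 0.55, 0.65),
                              gc_window_bp = 50000L,
                              mean_fragments_per_bin = 100,
                              gc_bias = c(a = 2, b = 0),
                              cnv_truth = default_cnv_truth(n_chromosomes,
                                                            chrom_length_bp),
                              n_germline_variants = 100L,
                              n_somatic_variants = 50L,
                              n_artifact_variants = 20L,
                              site_depth_mean = 30,
                              base_error_rate = 0.01,
                              bin_target_mappable = 10000L,
                              tumor_name = "TUMOR",
                              normal_name = "NORMAL",
                              n_genes = 30L) {
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.integer(chrom_length_bp),
              gc_profile = as.numeric(gc_profile),
              gc_window_bp = as.integer(gc_window_bp),
              mean_fragments_per_bin = as.numeric(mean_fragments_per_bin),
              gc_bias = c(a = unname(gc_bias["a"]), b = unname(gc_bias["b"])),
              cnv_truth = cnv_truth,
              n_germline_variants = as.integer(n_germline_variants),
              n_somatic_variants = as.integer(n_somatic_variants),
              n_artifact_variants = as.integer(n_artifact_variants),
              site_depth_mean = as.numeric(site_depth_mean),
              base_error_rate = as.numeric(base_error_rate),
              bin_target_mappable = as.integer(bin_target_mappable),
              tumor_name = tumor_name,
              normal_name = normal_name,
              n_genes = as.integer(n_genes))
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  if (any(cfg$gc_profile <= 0 | cfg$gc_profile >= 1)) {
    stop("configuration error: gc_profile values must lie in (0, 1)",
         call. = FALSE)
  }
  if (cfg$base_error_rate <= 0 || cfg$base_error_rate > 0.1) {
    stop("configuration error: base_error_rate must lie in (0, 0.1]",
         call. = FALSE)
  }
  if (cfg$mean_fragments_per_bin <= 0 || cfg$site_depth_mean <= 0) {
    stop("configuration error: coverage means must be positive",
         call. = FALSE)
  }
  tr <- cfg$cnv_truth
  if (nrow(tr) > 0) {
    if (any(!tr$copy %in% 0:6)) {
      stop("configuration error: cnv_truth copy numbers must be in 0..6",
           call. = FALSE)
    }
    for (ch in unique(tr$chrom)) {
      seg <- tr[tr$chrom == ch, , drop = FALSE]
      seg <- seg[order(seg$start), , drop = FALSE]
      if (any(seg$end <= seg$start) ||
          (nrow(seg) > 1 && any(seg$start[-1] < seg$end[-nrow(seg)]))) {
        stop("configuration error: cnv_truth segments overlap on ", ch,
             call. = FALSE)
      }
    }
  }
  invisible(cfg)
}

#' Simulate a reference genome with a targeted GC profile
#'
#' Draws each base independently so that successive `gc_window_bp` windows
#' hit the piecewise-constant GC targets in `config$gc_profile` (G/C vs A/T
#' is a Bernoulli draw per position; strand choice is uniform).
#'
#' @param config a [simulation_config()].
#' @return list with `sequences` (a [Biostrings::DNAStringSet]) and
#'   `windows` (data.frame `chrom,start,end,target_gc,observed_gc`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(derive_seed(config$seed, "genome"), {
    seqs <- character(config$n_chromosomes)
    win_rows <- vector("list", config$n_chromosomes)
    for (k in seq_len(config$n_chromosomes)) {
      L <- config$chrom_length_bp
      starts <- seq(0L, L - 1L, by = config$gc_window_bp)
      ends <- pmin(starts + config$gc_window_bp, L)
      targets <- rep_len(config$gc_profile, length(starts))
      p <- rep(targets, times = ends - starts)
      is_gc <- runif(L) < p
      pick <- runif(L) < 0.5
      base <- character(L)
      base[is_gc] <- ifelse(pick[is_gc], "G", "C")
      base[!is_gc] <- ifelse(pick[!is_gc], "A", "T")
      seqs[k] <- paste(base, collapse = "")
      obs <- vapply(seq_along(starts), function(i) {
        mean(is_gc[(starts[i] + 1L):ends[i]])
      }, numeric(1))
      win_rows[[k]] <- data.frame(chrom = paste0("chr", k),
                                  start = starts, end = ends,
                                  target_gc = targets, observed_gc = obs,
                                  stringsAsFactors = FALSE)
    }
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- paste0("chr", seq_len(config$n_chromosomes))
    list(sequences = dss, windows = do.call(rbind, win_rows))
  })
}

# GC-dependent coverage bias, centered at gc = 0.5
gc_bias_factor <- function(gc, coef) {
  exp(coef[["a"]] * (gc - 0.5) + coef[["b"]] * (gc - 0.5)^2)
}

# true tumor copy number per bin, assigned by bin midpoint
true_copy_per_bin <- function(bins, cnv_truth, baseline = 2L) {
  copy <- rep.int(baseline, nrow(bins))
  if (!is.null(cnv_truth) && nrow(cnv_truth) > 0) {
    mid <- (bins$start + bins$end) / 2
    for (r in seq_len(nrow(cnv_truth))) {
      hit <- bins$chrom == cnv_truth$chrom[r] &
        mid >= cnv_truth$start[r] & mid < cnv_truth$end[r]
      copy[hit] <- cnv_truth$copy[r]
    }
  }
  as.integer(copy)
}

#' Simulate per-bin fragment counts for the tumor/normal pair
#'
#' Bins the reference into intervals of `bin_target_mappable` mappable
#' bases, records the true tumor copy state per bin, and draws Poisson
#' fragment counts with the configured GC bias (shared between samples, so
#' the expected tumor/normal ratio per bin is `c/2` regardless of GC).
#'
#' @param config a [simulation_config()].
#' @param genome result of [simulate_genome()].
#' @return data.frame of bins: `chrom,start,end,mappable_bases,gc,
#'   count_normal,count_tumor,true_copy`.
#' @export
simulate_coverage <- function(config, genome) {
  stopifnot(inherits(config, "simulation_config"))
  bins <- build_bins(genome$sequences,
                     target_mappable = config$bin_target_mappable)
  bins$true_copy <- true_copy_per_bin(bins, config$cnv_truth)
  withr::with_seed(derive_seed(config$seed, "coverage"), {
    f <- gc_bias_factor(bins$gc, config$gc_bias)
    lam_n <- config$mean_fragments_per_bin * f
    lam_t <- config$mean_fragments_per_bin * (bins$true_copy / 2) * f
    bins$count_normal <- rpois(nrow(bins), lam_n)
    bins$count_tumor <- rpois(nrow(bins), lam_t)
  })
  ok <- bins$mappable_bases > 0
  bins$count_normal[!ok] <- NA_integer_
  bins$count_tumor[!ok] <- NA_integer_
  bins
}

#' Diploid genotype log10-likelihoods from allele counts
#'
#' Under the standard diploid read-error model with per-base error rate
#' `eps`, a read supports the alternate allele with probability `eps`
#' (hom-ref), `1/2` (het) or `1 - eps` (hom-alt). The GL for genotype `g` is
#' the sum over reads of `log10 P(base | g, eps)` (binomial coefficient
#' omitted, as in standard callers -- it cancels in posteriors).
#'
#' @param n_ref,n_alt reference / alternate read counts (vectorized).
#' @param eps base error rate.
#' @return Matrix with columns `hom_ref`, `het`, `hom_alt` of log10 GLs.
#' @export
gl_diploid <- function(n_ref, n_alt, eps) {
  cbind(hom_ref = n_ref * log10(1 - eps) + n_alt * log10(eps),
        het = (n_ref + n_alt) * log10(0.5),
        hom_alt = n_ref * log10(eps) + n_alt * log10(1 - eps))
}

# VCF QUAL: Phred-scaled probability that every sample is hom-ref under
# flat-prior genotype posteriors
site_qual <- function(gl_tumor, gl_normal) {
  pt <- genotype_posteriors(gl_tumor)
  pn <- genotype_posteriors(gl_normal)
  phred(pt[, 1] * pn[, 1])
}

# deterministic synthetic gene universe: rat-style symbols, their human
# homolog mapping (some renamed, some unmapped) and census membership
synthetic_gene_tables <- function(n_genes) {
  i <- seq_len(n_genes)
  rat <- sprintf("sgene%02d", i)
  human <- toupper(rat)
  renamed <- i %% 5 == 0 & i %% 10 != 0
  human[renamed] <- sprintf("HMLG%02d", i[renamed])
  unmapped <- i %% 10 == 0
  homologs <- data.frame(source_symbol = rat[!unmapped],
                         target_symbol = human[!unmapped],
                         stringsAsFactors = FALSE)
  in_cgc <- !unmapped & i %% 3 == 0
  cgc <- data.frame(human_symbol = human[in_cgc],
                    tier = ifelse(i[in_cgc] %% 2 == 0, 1L, 2L),
                    stringsAsFactors = FALSE)
  list(genes = rat, homologs = homologs, cgc = cgc)
}

#' Simulate paired-sample variant records with genotype likelihoods
#'
#' Plants germline (het/hom), somatic (tumor-only het) and shared
#' low-frequency artifact sites on the simulated genome. Read support per
#' sample is `Binomial(depth, af')` with `af' = af(1-eps) + (1-af)eps`, the
#' truth allele fraction perturbed by sequencing error; GLs follow
#' [gl_diploid()] and QUAL is the Phred-scaled flat-prior probability that
#' at least one sample carries the alternate allele. Sites where either
#' sample draws zero depth are dropped (with a message).
#'
#' Each variant is also assigned a gene and an impact class, producing the
#' annotation, homolog and cancer-gene-census tables the prioritization
#' stage consumes.
#'
#' @param config a [simulation_config()].
#' @param genome result of [simulate_genome()].
#' @return list with `sites` (variant records, one row per site),
#'   `truth` (class and true allele fractions per site), `annotations`
#'   (variant-to-gene impact rows), `homologs` and `cgc` tables.
#' @export
simulate_variants <- function(config, genome) {
  stopifnot(inherits(config, "simulation_config"))
  eps <- config$base_error_rate
  classes <- c(rep("germline", config$n_germline_variants),
               rep("somatic", config$n_somatic_variants),
               rep("artifact_shared_lowfreq", config$n_artifact_variants))
  n <- length(classes)
  tables <- synthetic_gene_tables(config$n_genes)
  chrom_names <- names(genome$sequences)
  L <- config$chrom_length_bp

  withr::with_seed(derive_seed(config$seed, "variants"), {
    repeat {
      chrom <- sample(chrom_names, n, replace = TRUE)
      pos <- sample.int(L, n, replace = TRUE)           # 1-based
      if (!anyDuplicated(paste(chrom, pos))) break
    }
    ref <- vapply(seq_len(n), function(i) {
      as.character(Biostrings::subseq(genome$sequences[[chrom[i]]],
                                      pos[i], pos[i]))
    }, character(1))
    alt <- vapply(ref, function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, character(1))

    class <- classes
    is_germ <- class == "germline"
    zygo <- runif(n) < 0.5
    class[is_germ] <- ifelse(zygo[is_germ], "germline_het", "germline_hom")

    af_t <- numeric(n)
    af_n <- numeric(n)
    af_t[class == "germline_het"] <- 0.5
    af_n[class == "germline_het"] <- 0.5
    af_t[class == "germline_hom"] <- 1.0
    af_n[class == "germline_hom"] <- 1.0
    af_t[class == "somatic"] <- 0.5
    af_n[class == "somatic"] <- 0.0
    is_art <- class == "artifact_shared_lowfreq"
    art_af <- runif(sum(is_art), 0.05, 0.20)
    af_t[is_art] <- art_af
    af_n[is_art] <- art_af

    dp_t <- rpois(n, config$site_depth_mean)
    dp_n <- rpois(n, config$site_depth_mean)
    p_t <- af_t * (1 - eps) + (1 - af_t) * eps
    p_n <- af_n * (1 - eps) + (1 - af_n) * eps
    alt_t <- rbinom(n, dp_t, p_t)
    alt_n <- rbinom(n, dp_n, p_n)

    gene_idx <- sample.int(config$n_genes, n, replace = TRUE)
    impact <- sample(c("HIGH", "MODERATE", "LOW", "MODIFIER"), n,
                     replace = TRUE, prob = c(0.25, 0.35, 0.2, 0.2))

    keep <- dp_t > 0 & dp_n > 0
    if (any(!keep)) {
      message("dropping ", sum(!keep), " zero-depth site(s)")
    }
    ord <- order(match(chrom, chrom_names), pos)
    ord <- ord[keep[ord]]

    chrom <- chrom[ord]; pos <- pos[ord]; ref <- ref[ord]; alt <- alt[ord]
    class <- class[ord]; af_t <- af_t[ord]; af_n <- af_n[ord]
    dp_t <- dp_t[ord]; dp_n <- dp_n[ord]
    alt_t <- alt_t[ord]; alt_n <- alt_n[ord]
    gene <- tables$genes[gene_idx[ord]]
    impact <- impact[ord]

    gl_t <- gl_diploid(dp_t - alt_t, alt_t, eps)
    gl_n <- gl_diploid(dp_n - alt_n, alt_n, eps)
    qual <- site_qual(gl_t, gl_n)

    sites <- data.frame(chrom = chrom, pos = pos, id = ".",
                        ref = ref, alt = alt, qual = qual,
                        t_gl_rr = gl_t[, 1], t_gl_ra = gl_t[, 2],
                        t_gl_aa = gl_t[, 3],
                        t_ad_ref = dp_t - alt_t, t_ad_alt = alt_t,
                        t_dp = dp_t,
                        n_gl_rr = gl_n[, 1], n_gl_ra = gl_n[, 2],
                        n_gl_aa = gl_n[, 3],
                        n_ad_ref = dp_n - alt_n, n_ad_alt = alt_n,
                        n_dp = dp_n,
                        stringsAsFactors = FALSE)
    truth <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                        class = class, af_tumor = af_t, af_normal = af_n,
                        stringsAsFactors = FALSE)
    annotations <- data.frame(chrom = chrom, pos = pos, ref = ref,
                              alt = alt, gene_symbol = gene,
                              impact = impact, stringsAsFactors = FALSE)
    list(sites = sites, truth = truth, annotations = annotations,
         homologs = tables$homologs, cgc = tables$cgc)
  })
}

#' Write simulated variant records as VCF 4.2
#'
#' Emits a two-sample VCF with `GL:AD:DP` (or `PL:AD:DP`) FORMAT fields.
#' PL values are the usual Phred-scaled integers `round(-10 * GL)`
#' normalized so the best genotype is 0.
#'
#' @param sites the `sites` data.frame from [simulate_variants()].
#' @param path output path.
#' @param config the [simulation_config()] (sample names, contigs).
#' @param likelihood_field `"GL"` (log10 likelihoods) or `"PL"`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sites, path, config,
                      likelihood_field = c("GL", "PL")) {
  likelihood_field <- match.arg(likelihood_field)
  contigs <- sprintf("##contig=<ID=chr%d,length=%d>",
                     seq_len(config$n_chromosomes), config$chrom_length_bp)
  lik_hdr <- if (likelihood_field == "GL") {
    "##FORMAT=<ID=GL,Number=G,Type=Float,Description=\"Genotype log10 likelihoods\">"
  } else {
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">"
  }
  header <- c("##fileformat=VCFv4.2",
              "##source=somaticmap_synthetic",
              contigs,
              lik_hdr,
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", config$tumor_name, config$normal_name,
                    sep = "\t"))
  fmt_sample <- function(gl, ad_ref, ad_alt, dp) {
    lik <- if (likelihood_field == "GL") {
      apply(gl, 1, function(g) paste(sprintf("%.4f", g), collapse = ","))
    } else {
      apply(gl, 1, function(g) {
        pl <- round(-10 * (g - max(g)))
        paste(sprintf("%d", pl), collapse = ",")
      })
    }
    paste0(lik, ":", ad_ref, ",", ad_alt, ":", dp)
  }
  body <- character(0)
  if (nrow(sites) > 0) {
    t_col <- fmt_sample(as.matrix(sites[, c("t_gl_rr", "t_gl_ra", "t_gl_aa")]),
                        sites$t_ad_ref, sites$t_ad_alt, sites$t_dp)
    n_col <- fmt_sample(as.matrix(sites[, c("n_gl_rr", "n_gl_ra", "n_gl_aa")]),
                        sites$n_ad_ref, sites$n_ad_alt, sites$n_dp)
    body <- paste(sites$chrom, sites$pos, sites$id, sites$ref, sites$alt,
                  sprintf("%.2f", sites$qual), ".", ".",
                  paste0(likelihood_field, ":AD:DP"), t_col, n_col,
                  sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the simulated reference as FASTA
#'
#' @param genome result of [simulate_genome()].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$sequences, path, width = 80)
  invisible(path)
}

#' Write the bin-count table as TSV
#'
#' Columns: `chrom,start,end,mappable_bases,gc,count_normal,count_tumor`
#' plus `true_copy` when present (truth tables travel with the synthetic
#' data).
#'
#' @param bins bin data.frame from [simulate_coverage()] or
#'   [count_fragments()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bins <- function(bins, path) {
  cols <- c("chrom", "start", "end", "mappable_bases", "gc",
            "count_normal", "count_tumor", "true_copy")
  write_tsv_stable(bins[, intersect(cols, names(bins)), drop = FALSE], path)
}

#' Read a bin-count TSV written by [write_bins()]
#' @param path TSV path.
#' @return bin data.frame.
#' @export
read_bins <- function(path) read_tsv_plain(path)

#' Write a simulation config as a flat key=value file
#' @param config a [simulation_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  flat <- function(x) paste(fmt_num(unlist(x), digits = 10), collapse = ",")
  keys <- setdiff(names(config), "cnv_truth")
  lines <- vapply(keys, function(k) paste0(k, "=", flat(config[[k]])),
                  character(1))
  tr <- config$cnv_truth
  if (nrow(tr) > 0) {
    lines <- c(lines, paste0("cnv_truth=", paste(
      sprintf("%s:%d-%d:%d", tr$chrom, as.integer(tr$start),
              as.integer(tr$end), as.integer(tr$copy)), collapse = ",")))
  }
  writeLines(lines, path)
  invisible(path)
}
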