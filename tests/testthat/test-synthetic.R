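test_that("simulated genome hits its GC targets and is reproducible", {
  cfg <- simulation_config(seed = 42, n_chromosomes = 1,
                           chrom_length_bp = 1e6,
                           gc_profile = 0.5, gc_window_bp = 50000L,
                           cnv_truth = data.frame())
  g <- simulate_genome(cfg)
  freq <- Biostrings::letterFrequency(g$sequences, "GC", as.prob = TRUE)
  expect_gt(freq[1], 0.47)
  expect_lt(freq[1], 0.53)

  cfg2 <- simulation_config(seed = 42, n_chromosomes = 1,
                            chrom_length_bp = 2e5,
                            gc_profile = c(0.3, 0.7), gc_window_bp = 1e5L,
                            cnv_truth = data.frame())
  g2 <- simulate_genome(cfg2)
  expect_equal(nrow(g2$windows), 2)
  expect_lt(abs(g2$windows$observed_gc[1] - 0.3), 0.03)
  expect_lt(abs(g2$windows$observed_gc[2] - 0.7), 0.03)

  # byte-identical FASTA under the same seed
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(g2, f1)
  write_fasta(simulate_genome(cfg2), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  expect_error(simulation_config(gc_profile = c(0.5, 1.2)),
               "configuration error")
})

test_that("coverage follows the Poisson copy-number/GC-bias model", {
  # no bias, diploid: per-bin mean within 3 SE of the configured mean
  cfg <- simulation_config(seed = 5, n_chromosomes = 2,
                           chrom_length_bp = 1e6, gc_bias = c(a = 0, b = 0),
                           cnv_truth = data.frame())
  g <- simulate_genome(cfg)
  bins <- simulate_coverage(cfg, g)
  se <- sqrt(cfg$mean_fragments_per_bin / nrow(bins))
  expect_lt(abs(mean(bins$count_normal) - cfg$mean_fragments_per_bin),
            3 * se)

  # a c=4 segment doubles the tumor mean relative to flanking diploid bins
  cfg4 <- simulation_config(seed = 6, n_chromosomes = 1,
                            chrom_length_bp = 4e6,
                            gc_bias = c(a = 0, b = 0),
                            cnv_truth = data.frame(chrom = "chr1",
                                                   start = 1e6, end = 3e6,
                                                   copy = 4))
  g4 <- simulate_genome(cfg4)
  b4 <- simulate_coverage(cfg4, g4)
  in_seg <- b4$true_copy == 4
  expect_gte(sum(in_seg), 100)
  ratio <- mean(b4$count_tumor[in_seg]) / mean(b4$count_tumor[!in_seg])
  expect_lt(abs(ratio - 2), 0.1)

  # GC bias induces a positive rank correlation in diploid regions
  cfgb <- simulation_config(seed = 7, n_chromosomes = 2,
                            chrom_length_bp = 1e6,
                            gc_bias = c(a = 2, b = 0),
                            cnv_truth = data.frame())
  gb <- simulate_genome(cfgb)
  bb <- simulate_coverage(cfgb, gb)
  expect_gt(cor(bb$gc, bb$count_normal, method = "spearman"), 0.3)
})

test_that("tumor/normal count ratio per segment is c/2, GC bias cancelling", {
  cfg <- simulation_config(seed = 8, n_chromosomes = 2,
                           chrom_length_bp = 3e6,
                           gc_bias = c(a = 2, b = 0),
                           cnv_truth = data.frame(
                             chrom = c("chr1", "chr2"),
                             start = c(1e6, 0), end = c(2e6, 1.5e6),
                             copy = c(4, 1)))
  g <- simulate_genome(cfg)
  bins <- simulate_coverage(cfg, g)
  for (c_state in unique(bins$true_copy)) {
    sel <- bins$true_copy == c_state
    obs <- sum(bins$count_tumor[sel]) / sum(bins$count_normal[sel])
    expect_lt(abs(obs - c_state / 2) / (c_state / 2 + 1e-9), 0.05,
              label = paste("segment ratio at copy", c_state))
  }
})

test_that("genotype likelihoods follow the diploid error model", {
  # closed form: 10 ref reads, 0 alt, eps = 0.01
  gl <- gl_diploid(10, 0, 0.01)
  expect_equal(unname(gl[1, "hom_ref"]), 10 * log10(0.99),
               tolerance = 1e-12)
  expect_equal(unname(gl[1, "het"]), 10 * log10(0.5), tolerance = 1e-12)
  expect_equal(unname(gl[1, "hom_alt"]), 10 * log10(0.01),
               tolerance = 1e-12)

  # dominant-allele sanity: hom-alt truth at depth 30
  gl_hom <- gl_diploid(0, 30, 0.01)
  expect_equal(unname(which.max(gl_hom[1, ])), 3L)
  # somatic-like normal: 30 ref, 0 alt -> hom-ref is the ML genotype
  gl_norm <- gl_diploid(30, 0, 0.01)
  expect_equal(unname(which.max(gl_norm[1, ])), 1L)
})

test_that("variant simulation is deterministic and classes behave", {
  cfg <- simulation_config(seed = 9, n_chromosomes = 2,
                           chrom_length_bp = 5e5, cnv_truth = data.frame(),
                           n_germline_variants = 40,
                           n_somatic_variants = 20,
                           n_artifact_variants = 10)
  g <- simulate_genome(cfg)
  v1 <- simulate_variants(cfg, g)
  v2 <- simulate_variants(cfg, g)
  expect_identical(v1, v2)
  expect_equal(nrow(v1$sites), nrow(v1$truth))
  expect_true(all(table(v1$truth$class)[c("somatic")] == 20))
  expect_true(all(v1$truth$class %in%
                    c("germline_het", "germline_hom", "somatic",
                      "artifact_shared_lowfreq")))
  # artifact allele fractions are low in both samples
  art <- v1$truth$class == "artifact_shared_lowfreq"
  expect_true(all(v1$truth$af_tumor[art] < 0.25))
  expect_true(all(v1$truth$af_normal[art] < 0.25))
  # VCF bytes reproduce
  p1 <- tempfile(fileext = ".vcf"); p2 <- tempfile(fileext = ".vcf")
  write_vcf(v1$sites, p1, cfg)
  write_vcf(v2$sites, p2, cfg)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the truth genotype dominates the GL at depth 30", {
  cfg <- simulation_config(seed = 10, n_chromosomes = 2,
                           chrom_length_bp = 2e6, cnv_truth = data.frame(),
                           n_germline_variants = 700,
                           n_somatic_variants = 350,
                           n_artifact_variants = 0)
  g <- simulate_genome(cfg)
  v <- simulate_variants(cfg, g)
  s <- v$sites
  truth_gt_tumor <- c(germline_het = 2L, germline_hom = 3L, somatic = 2L)
  truth_gt_normal <- c(germline_het = 2L, germline_hom = 3L, somatic = 1L)
  ml_t <- max.col(as.matrix(s[, c("t_gl_rr", "t_gl_ra", "t_gl_aa")]))
  ml_n <- max.col(as.matrix(s[, c("n_gl_rr", "n_gl_ra", "n_gl_aa")]))
  hit <- ml_t == truth_gt_tumor[v$truth$class] &
    ml_n == truth_gt_normal[v$truth$class]
  expect_gte(length(hit), 1000)
  expect_gte(mean(hit), 0.99)
})

test_that("zero-depth sites are dropped with a message", {
  cfg <- simulation_config(seed = 11, n_chromosomes = 1,
                           chrom_length_bp = 2e5, cnv_truth = data.frame(),
                           n_germline_variants = 50,
                           n_somatic_variants = 0,
                           n_artifact_variants = 0,
                           site_depth_mean = 1)
  g <- simulate_genome(cfg)
  expect_message(v <- simulate_variants(cfg, g), "zero-depth")
  expect_true(all(v$sites$t_dp > 0 & v$sites$n_dp > 0))
  expect_lt(nrow(v$sites), 50)
})
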