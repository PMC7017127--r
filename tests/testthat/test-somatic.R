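eps <- 0.01

test_that("site filters honour their strict boundaries and report order", {
  thr <- somatic_thresholds()
  pass <- make_site(40, gl_diploid(20, 10, eps)[1, ], c(20, 10), 30,
                    gl_diploid(30, 0, eps)[1, ], c(30, 0), 30)
  expect_true(is.na(site_filter(pass, thr)))

  one_read <- make_site(40, gl_diploid(29, 1, eps)[1, ], c(29, 1), 30,
                        gl_diploid(30, 0, eps)[1, ], c(30, 0), 30)
  expect_equal(site_filter(one_read, thr), "min_alt_reads")

  low_af <- make_site(40, gl_diploid(58, 2, eps)[1, ], c(58, 2), 60,
                      gl_diploid(60, 0, eps)[1, ], c(60, 0), 60)
  expect_equal(site_filter(low_af, thr), "min_af")

  # qual exactly 5 fails the strict > 5 rule
  q5 <- make_site(5, gl_diploid(20, 10, eps)[1, ], c(20, 10), 30,
                  gl_diploid(30, 0, eps)[1, ], c(30, 0), 30)
  expect_equal(site_filter(q5, thr), "min_site_qual")

  nocov <- make_site(40, c(0, 0, 0), c(0, 0), 0, c(0, 0, 0), c(0, 0), 0)
  expect_equal(site_filter(nocov, thr), "no_coverage")
})

test_that("flat-prior posteriors normalize the likelihood triple", {
  expect_equal(genotype_posteriors(c(0, 0, 0)),
               c(hom_ref = 1, het = 1, hom_alt = 1) / 3)
  expect_equal(unname(genotype_posteriors(c(0, -1, -1))),
               c(10, 1, 1) / 12, tolerance = 1e-12)
  p <- genotype_posteriors(c(-300, 0, -300))
  expect_gt(p[["het"]], 1 - 1e-9)
  # posteriors sum to one
  withr::with_seed(51, m <- matrix(-runif(30, 0, 50), ncol = 3))
  expect_true(all(abs(rowSums(genotype_posteriors(m)) - 1) < 1e-9))
  expect_true(all(is.na(genotype_posteriors(c(-Inf, -Inf, -Inf)))))
})

test_that("labelling follows the dual-likelihood somatic rule", {
  thr <- somatic_thresholds()
  som <- make_site(90, c(-20, 0, -20), c(15, 15), 30,
                   c(0, -20, -20), c(30, 0), 30)
  lab <- label_somatic(som, thr)
  expect_equal(lab$label, "somatic")
  expect_gte(lab$tumor_nonref_phred, 10)
  expect_gte(lab$normal_ref_phred, 10)
  expect_equal(lab$tumor_nonref_phred, 200)  # saturated posterior capped

  # shared low-frequency: both AFs below 0.25 with normal alt support
  shared <- make_site(40, gl_diploid(27, 3, eps)[1, ], c(27, 3), 30,
                      gl_diploid(28, 2, eps)[1, ], c(28, 2), 30)
  expect_equal(label_somatic(shared, thr)$label, "shared_low_frequency")

  # both samples confidently hom-ref: reference
  refs <- make_site(40, c(0, -20, -20), c(27, 3), 30,
                    c(0, -20, -20), c(27, 3), 30)
  refs$n_ad_alt <- 0
  lab_ref <- label_somatic(refs, thr)
  expect_equal(lab_ref$label, "reference")
  expect_lt(lab_ref$tumor_nonref_phred, 1)

  # strong alternate in the normal: germline
  germ <- make_site(90, gl_diploid(15, 15, eps)[1, ], c(15, 15), 30,
                    gl_diploid(14, 16, eps)[1, ], c(14, 16), 30)
  expect_equal(label_somatic(germ, thr)$label, "germline")

  # missing likelihoods fail with no_likelihood
  nolik <- make_site(40, c(NA, NA, NA), c(20, 10), 30,
                     c(0, -20, -20), c(30, 0), 30)
  labn <- label_somatic(nolik, thr)
  expect_equal(labn$label, "failed_site_filter")
  expect_equal(labn$filter_reason, "no_likelihood")
})

test_that("raising the evidence threshold never increases somatic calls", {
  cfg <- simulation_config(seed = 52, n_chromosomes = 2,
                           chrom_length_bp = 1e6, cnv_truth = data.frame())
  g <- simulate_genome(cfg)
  sites <- simulate_variants(cfg, g)$sites
  counts <- vapply(c(0, 5, 10, 20, 50, 100), function(th) {
    thr <- somatic_thresholds(min_evidence_phred = th)
    sum(label_somatic(sites, thr)$label == "somatic")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("every record receives exactly one label and counts add up", {
  cfg <- simulation_config(seed = 53, n_chromosomes = 2,
                           chrom_length_bp = 1e6, cnv_truth = data.frame())
  g <- simulate_genome(cfg)
  v <- simulate_variants(cfg, g)
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(v$sites, vcf, cfg)
  res <- run_labelling(vcf)
  expect_equal(sum(res$summary$count), nrow(v$sites))
  expect_true(all(res$calls$label %in% res$summary$label))
})

test_that("PL-encoded records label identically to their GL form", {
  cfg <- simulation_config(seed = 54, n_chromosomes = 2,
                           chrom_length_bp = 1e6, cnv_truth = data.frame(),
                           n_germline_variants = 40,
                           n_somatic_variants = 25,
                           n_artifact_variants = 10)
  g <- simulate_genome(cfg)
  v <- simulate_variants(cfg, g)
  vcf_gl <- tempfile(fileext = ".vcf")
  vcf_pl <- tempfile(fileext = ".vcf")
  write_vcf(v$sites, vcf_gl, cfg, likelihood_field = "GL")
  write_vcf(v$sites, vcf_pl, cfg, likelihood_field = "PL")
  lab_gl <- run_labelling(vcf_gl)
  lab_pl <- run_labelling(vcf_pl)
  expect_equal(lab_pl$calls$label, lab_gl$calls$label)
})

test_that("empty and malformed VCF inputs are handled", {
  cfg <- simulation_config(seed = 1, n_chromosomes = 1,
                           chrom_length_bp = 1e5, cnv_truth = data.frame())
  empty <- tempfile(fileext = ".vcf")
  write_vcf(cfg_sites_empty(), empty, cfg)
  res <- suppressWarnings(run_labelling(empty))
  expect_equal(nrow(res$calls), 0)
  expect_true(all(res$summary$count == 0))

  # GT-only VCF: format error naming the record
  bad <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "TUMOR", "NORMAL", sep = "\t"),
               paste("chr1", "100", ".", "A", "T", "50", ".", ".",
                     "GT", "0/1", "0/0", sep = "\t")), bad)
  expect_error(suppressWarnings(run_labelling(bad)), "format error")
})

test_that("multi-allelic records are split with AD/GL decomposition", {
  vcf <- tempfile(fileext = ".vcf")
  # GL order for 2 alts: 0/0, 0/1, 1/1, 0/2, 1/2, 2/2
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GL,Number=G,Type=Float,Description=\"gl\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "TUMOR", "NORMAL", sep = "\t"),
               paste("chr1", "500", ".", "A", "T,G", "80", ".", ".",
                     "GL:AD:DP",
                     "-10,0,-12,-11,-13,-14:10,9,1:20",
                     "0,-9,-20,-8,-21,-19:18,1,1:20", sep = "\t")), vcf)
  sites <- read_paired_vcf(vcf)
  expect_equal(nrow(sites), 2)
  expect_equal(sites$alt, c("T", "G"))
  # allele 1 keeps GL indices (0/0, 0/1, 1/1)
  expect_equal(unlist(sites[1, c("t_gl_rr", "t_gl_ra", "t_gl_aa")],
                      use.names = FALSE), c(-10, 0, -12))
  # allele 2 keeps GL indices (0/0, 0/2, 2/2)
  expect_equal(unlist(sites[2, c("t_gl_rr", "t_gl_ra", "t_gl_aa")],
                      use.names = FALSE), c(-10, -11, -14))
  expect_equal(sites$t_ad_alt, c(9, 1))
  expect_equal(sites$t_ad_ref, c(10, 10))

  out <- tempfile(fileext = ".vcf")
  res <- run_labelling(vcf, out_vcf = out)
  lines <- readLines(out)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 2)
  expect_match(body[1], "LABEL=")
})

test_that("labelled VCF output carries the evidence scores", {
  cfg <- simulation_config(seed = 55, n_chromosomes = 1,
                           chrom_length_bp = 5e5, cnv_truth = data.frame(),
                           n_germline_variants = 10,
                           n_somatic_variants = 10,
                           n_artifact_variants = 0)
  g <- simulate_genome(cfg)
  v <- simulate_variants(cfg, g)
  vcf <- tempfile(fileext = ".vcf")
  out <- tempfile(fileext = ".vcf")
  summ <- tempfile(fileext = ".tsv")
  write_vcf(v$sites, vcf, cfg)
  res <- run_labelling(vcf, out_vcf = out, out_summary = summ)
  lines <- readLines(out)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), nrow(v$sites))
  expect_true(all(grepl("LABEL=", body) & grepl("SSC=", body)))
  n_som_flag <- sum(grepl("SOMATIC;", body, fixed = TRUE))
  expect_equal(n_som_flag,
               res$summary$count[res$summary$label == "somatic"])
  expect_true(file.exists(summ))
})
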