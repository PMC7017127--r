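#' Configuration for an end-to-end synthetic pipeline run
#'
#' One validated bag of parameters for every stage: synthetic-data
#' generation, GC correction, segmentation, copy-state genotyping,
#' somatic labelling and gene prioritization. Unknown keys are rejected.
#' Every parameter defaults to the module-level default it overrides.
#'
#' @param out_dir directory for all artifacts (created if needed).
#' @param seed global seed; per-stage sub-streams are derived from it with
#'   [derive_seed()] so stages can be rerun in isolation.
#' @param sim named list of overrides for [simulation_config()] (except
#'   `seed`, which comes from the global seed).
#' @param smoothing_fraction LOWESS span for [fit_gc_curve()].
#' @param alpha,n_permutations,min_width,merge_threshold,pseudocount
#'   segmentation parameters for [segment_cbs()].
#' @param max_copy largest copy state for [genotype_segments()].
#' @param thresholds a [somatic_thresholds()].
#' @param likelihood_field `"GL"` or `"PL"` for the simulated VCF.
#' @param evaluate run the truth evaluation stage (default `TRUE`).
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, sim = list(),
                       smoothing_fraction = 0.3, alpha = 0.01,
                       n_permutations = 1000L, min_width = 2L,
                       merge_threshold = 0.1, pseudocount = 1e-3,
                       max_copy = 6L, thresholds = somatic_thresholds(),
                       likelihood_field = "GL", evaluate = TRUE) {
  allowed_sim <- setdiff(names(formals(simulation_config)), "seed")
  unknown <- setdiff(names(sim), allowed_sim)
  if (length(unknown) > 0) {
    stop("unknown simulation key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
              smoothing_fraction = smoothing_fraction, alpha = alpha,
              n_permutations = as.integer(n_permutations),
              min_width = as.integer(min_width),
              merge_threshold = merge_threshold, pseudocount = pseudocount,
              max_copy = as.integer(max_copy), thresholds = thresholds,
              likelihood_field = match.arg(likelihood_field, c("GL", "PL")),
              evaluate = isTRUE(evaluate))
  class(cfg) <- "run_config"
  cfg
}

#' Run the full synthetic tumor/normal analysis pipeline
#'
#' Stages, in order: simulate (genome, coverage, variants and truth
#' tables), copy-number map (GC curve, normalization, CBS, GMM
#' genotyping), somatic labelling, gene prioritization, and -- when truth
#' is available -- evaluation against it. All artifacts are written under
#' `config$out_dir` together with a manifest recording the seed and a
#' config fingerprint; a rerun with the same config and seed reproduces
#' identical bytes.
#'
#' @param config a [run_config()].
#' @return list with `paths` (named artifact paths), `cnv_map`, `calls`,
#'   `report` and `evaluation` (`NULL` when disabled).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  paths <- c(fasta = p("reference.fa"), bins = p("bins.tsv"),
             vcf = p("variants.vcf"), truth_variants = p("truth_variants.tsv"),
             annotations = p("annotations.tsv"), homologs = p("homologs.tsv"),
             cgc = p("cgc.tsv"), config = p("sim_config.txt"),
             cnv_bed = p("cnv_map.bed"), cnv_tsv = p("cnv_segments.tsv"),
             gc_diag_normal = p("gc_diagnostic_normal.tsv"),
             gc_diag_tumor = p("gc_diagnostic_tumor.tsv"),
             labelled_vcf = p("labelled.vcf"),
             label_summary = p("label_summary.tsv"),
             gene_report = p("gene_report.tsv"),
             evaluation = p("evaluation.json"),
             manifest = p("manifest.json"))

  message("[simulate] generating synthetic paired dataset")
  sim_cfg <- do.call(simulation_config,
                     c(list(seed = config$seed), config$sim))
  genome <- simulate_genome(sim_cfg)
  write_fasta(genome, paths[["fasta"]])
  bins <- simulate_coverage(sim_cfg, genome)
  write_bins(bins, paths[["bins"]])
  vars <- simulate_variants(sim_cfg, genome)
  write_vcf(vars$sites, paths[["vcf"]], sim_cfg,
            likelihood_field = config$likelihood_field)
  write_tsv_stable(vars$truth, paths[["truth_variants"]])
  write_tsv_stable(vars$annotations, paths[["annotations"]])
  write_tsv_stable(vars$homologs, paths[["homologs"]])
  write_tsv_stable(vars$cgc, paths[["cgc"]])
  write_config(sim_cfg, paths[["config"]])
  message("[simulate] ", nrow(bins), " bins, ", nrow(vars$sites),
          " variant sites")

  message("[cnvmap] GC correction and segmentation")
  for (s in c("normal", "tumor")) {
    curve <- fit_gc_curve(bins, sample = s,
                          smoothing_fraction = config$smoothing_fraction)
    bins <- normalize_coverage(bins, curve, sample = s)
  }
  write_tsv_stable(gc_bias_diagnostic(bins, "normal"),
                   paths[["gc_diag_normal"]])
  write_tsv_stable(gc_bias_diagnostic(bins, "tumor"),
                   paths[["gc_diag_tumor"]])
  segs <- segment_coverage(bins, sample = "tumor",
                           seed = derive_seed(config$seed, "segment"),
                           alpha = config$alpha,
                           n_permutations = config$n_permutations,
                           min_width = config$min_width,
                           merge_threshold = config$merge_threshold,
                           pseudocount = config$pseudocount)
  cnv <- genotype_segments(segs, max_copy = config$max_copy,
                           seed = derive_seed(config$seed, "genotype"))
  write_cnv_map(cnv, paths[["cnv_bed"]], paths[["cnv_tsv"]])
  message("[cnvmap] ", nrow(cnv$segments), " segments, ",
          cnv$k, " mixture component(s)")

  message("[somatic-label] labelling variant records")
  lab <- run_labelling(paths[["vcf"]], tumor_name = sim_cfg$tumor_name,
                       normal_name = sim_cfg$normal_name,
                       thresholds = config$thresholds,
                       out_vcf = paths[["labelled_vcf"]],
                       out_summary = paths[["label_summary"]])
  message("[somatic-label] ",
          paste(sprintf("%s=%d", lab$summary$label, lab$summary$count),
                collapse = " "))

  message("[gene-report] impact filter, homolog map, census intersection")
  fi <- filter_impact(lab$calls, vars$annotations,
                      min_qual = config$thresholds$min_impact_qual)
  hm <- map_homologs(unique(fi$pairs$gene_symbol), vars$homologs)
  report <- intersect_cgc(hm$mapped, vars$cgc, fi$pairs)
  render_report(report, paths[["gene_report"]])
  message("[gene-report] ", nrow(report), " census gene(s) reported")

  evaluation <- NULL
  if (config$evaluate) {
    message("[evaluate] scoring against truth")
    evaluation <- evaluate_against_truth(
      bins = bins, called_states = bin_copy_states(cnv, bins),
      calls = lab$calls, truth = vars$truth,
      annotations = vars$annotations, homologs = vars$homologs,
      cgc = vars$cgc, report = report,
      min_impact_qual = config$thresholds$min_impact_qual)
    writeLines(jsonlite::toJSON(evaluation, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, na = "null"),
               paths[["evaluation"]])
  }

  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                               auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  manifest <- list(seed = config$seed,
                   config_hash = fnv1a_hash(as.character(cfg_json)),
                   artifacts = basename(unname(
                     paths[file.exists(paths)])))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             paths[["manifest"]])

  list(paths = paths, cnv_map = cnv, calls = lab$calls, report = report,
       evaluation = evaluation)
}

#' Score pipeline output against the simulation truth
#'
#' Computes per-bin copy-state accuracy, the truth-class x label confusion
#' matrix, somatic sensitivity and per-class somatic mislabel rates, and
#' whether the gene report matches the planted expectation exactly (the
#' census genes carrying somatic-truth variants of HIGH/MODERATE impact
#' with quality above the gene-level cutoff).
#'
#' @param bins bin table with `true_copy`.
#' @param called_states integer copy states per bin ([bin_copy_states()]).
#' @param calls labelled site table.
#' @param truth truth table from [simulate_variants()].
#' @param annotations,homologs,cgc the synthetic gene tables.
#' @param report the rendered gene report ([intersect_cgc()] shape).
#' @param min_impact_qual strict quality bound used by the gene filter.
#' @return list with `copy_state_accuracy`, `confusion` (data.frame),
#'   `somatic_sensitivity`, `somatic_rate_by_class`,
#'   `gene_report_exact_match`, `expected_genes`, `reported_genes`.
#' @export
evaluate_against_truth <- function(bins, called_states, calls, truth,
                                   annotations, homologs, cgc, report,
                                   min_impact_qual = 20) {
  stopifnot(nrow(bins) == length(called_states))
  acc <- mean(!is.na(called_states) & called_states == bins$true_copy)

  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = "\r")
  idx <- match(key(truth), key(calls))
  if (any(is.na(idx))) {
    stop("coordinate mismatch: truth site(s) absent from calls",
         call. = FALSE)
  }
  label <- calls$label[idx]
  classes <- sort(unique(truth$class))
  labels <- sort(unique(label))
  confusion <- as.data.frame.matrix(table(truth$class, label))
  confusion <- cbind(truth_class = rownames(confusion), confusion,
                     stringsAsFactors = FALSE)
  rownames(confusion) <- NULL

  is_som <- truth$class == "somatic"
  sens <- if (any(is_som)) mean(label[is_som] == "somatic") else NA_real_
  rate_by_class <- vapply(classes, function(cl) {
    mean(label[truth$class == cl] == "somatic")
  }, numeric(1))

  qual <- calls$qual[idx]
  ann_idx <- match(key(truth), key(annotations))
  impact <- annotations$impact[ann_idx]
  gene <- annotations$gene_symbol[ann_idx]
  expected_src <- sort(unique(gene[is_som & impact %in% c("HIGH", "MODERATE") &
                                     qual > min_impact_qual]))
  hm <- map_homologs(expected_src, homologs)
  expected <- hm$mapped$source_symbol[
    hm$mapped$target_symbol %in% cgc$human_symbol]
  reported <- sort(report$gene_symbol)
  list(copy_state_accuracy = acc,
       confusion = confusion,
       somatic_sensitivity = sens,
       somatic_rate_by_class = as.list(rate_by_class),
       gene_report_exact_match = identical(sort(expected), reported),
       expected_genes = sort(expected),
       reported_genes = reported)
}
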