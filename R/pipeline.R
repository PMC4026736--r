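# End-to-end pipeline: simulate -> ancestry/sex -> per-chip imputation ->
# info filtering -> star-allele translation -> frequency report ->
# validation against the simulation truth.

#' Pipeline configuration
#'
#' All knobs of a full run in one serializable list.  Seeds for the
#' individual stages are derived deterministically from `seed`.
#'
#' @param seed Master integer seed.
#' @param n_samples Total cohort size across the four groups.
#' @param pop_specs List of [population_spec()]; default
#'   [default_population_specs()]`(n_samples)`.
#' @param n_panel_haps_per_pop Reference-panel haplotypes per population.
#' @param n_flank Flanking tag markers at the locus.
#' @param ld_r Flank copy fidelity.
#' @param chip_fraction_quad Fraction of samples on the quad-like design.
#' @param genotyping_error_rate,switch_error_rate Cohort corruption rates.
#' @param params [imputation_params()].
#' @param n_ancestry_markers,fst,n_ref_per_pop Ancestry marker set.
#' @param n_x_markers X markers for sex inference.
#' @param r2_max,window,step LD pruning parameters.
#' @param n_components,k PCA components and nearest-neighbor count.
#' @param all_chips_probe_causal If TRUE both chip designs probe both
#'   causal SNPs directly (the noiseless reference scenario).
#' @return A `tpmt_config` list.
#' @export
tpmt_config <- function(seed = 1L, n_samples = 2000L, pop_specs = NULL,
                        n_panel_haps_per_pop = 500L, n_flank = 10L,
                        ld_r = 0.95, chip_fraction_quad = 0.5,
                        genotyping_error_rate = 0, switch_error_rate = 0,
                        params = imputation_params(),
                        n_ancestry_markers = 2000L, fst = 0.1,
                        n_ref_per_pop = 50L, n_x_markers = 500L,
                        r2_max = 0.2, window = 50L, step = 5L,
                        n_components = 10L, k = 9L,
                        all_chips_probe_causal = FALSE) {
  if (is.null(pop_specs)) pop_specs <- default_population_specs(n_samples)
  structure(as.list(environment()), class = "tpmt_config")
}

.stage_seed <- function(seed, stage) {
  # distinct 32-bit streams per stage, derived from the master seed
  (as.integer(seed) * 101L + stage * 7919L) %% 2147483629L
}

#' Run the full pipeline on a synthetic cohort
#'
#' Stages: (1) build an imputation reference panel and an independent
#' population pool from the same specifications; (2) draw the cohort from
#' the pool, typed on two chip designs; (3) simulate ancestry and X
#' markers, LD-prune, fit PCA on the labelled references, classify
#' study samples by nearest neighbors, infer sex; (4) impute each chip
#' against the reference panel, score and filter variants by info;
#' (5) hard-call the two causal SNPs and translate to star diplotypes and
#' phenotypes; (6) tabulate allele/genotype/phenotype frequencies by
#' assigned super-group; (7) validate imputed diplotypes against the
#' simulation truth at diplotype and defective-count resolution.
#'
#' @param config A [tpmt_config()].
#' @param out_dir Optional directory: stage outputs are written as
#'   VCF/TSV/JSON together with a run manifest carrying the config and its
#'   hash.
#' @param quiet Suppress per-stage messages.
#' @return A `tpmt_run` list (see elements in the implementation);
#'   notable: `ancestry`, `sex`, `imputation`, `calls`, `tables`,
#'   `validation`, `truth`.
#' @export
run_pipeline <- function(config = tpmt_config(), out_dir = NULL,
                         quiet = TRUE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  say("stage 1: panels")
  panel_ref <- build_locus_panel(config$pop_specs,
                                 config$n_panel_haps_per_pop,
                                 config$n_flank, config$ld_r,
                                 seed = .stage_seed(config$seed, 1L))
  panel_pop <- build_locus_panel(config$pop_specs,
                                 config$n_panel_haps_per_pop,
                                 config$n_flank, config$ld_r,
                                 seed = .stage_seed(config$seed, 2L))
  if (isTRUE(config$all_chips_probe_causal)) {
    panel_ref$variants$quad_like <- TRUE
    panel_ref$variants$x550_like <- TRUE
    panel_pop$variants$quad_like <- TRUE
    panel_pop$variants$x550_like <- TRUE
  }

  say("stage 2: cohort")
  cohort <- simulate_cohort(panel_pop, config$pop_specs,
                            config$chip_fraction_quad,
                            config$genotyping_error_rate,
                            config$switch_error_rate,
                            seed = .stage_seed(config$seed, 3L))
  truth <- cohort$truth

  say("stage 3: ancestry and sex")
  anc <- simulate_ancestry_markers(config$n_ancestry_markers,
                                   config$pop_specs, config$fst,
                                   config$n_ref_per_pop,
                                   seed = .stage_seed(config$seed, 4L))
  kept <- ld_prune(anc$ref, config$r2_max, config$window, config$step)
  pca <- fit_pca(anc$ref[, kept, drop = FALSE], config$n_components)
  study_scores <- predict(pca, anc$study[, kept, drop = FALSE])
  ancestry <- classify_population(study_scores, pca$scores, anc$ref_pop,
                                  config$k)
  ancestry$sample <- truth$sample_id
  xg <- simulate_x_markers(config$n_x_markers, truth$sex,
                           error_rate = config$genotyping_error_rate,
                           seed = .stage_seed(config$seed, 5L))
  rownames(xg) <- truth$sample_id
  sex <- infer_sex(xg)

  say("stage 4: imputation per chip")
  imput <- lapply(cohort$typed, impute_chip, panel = panel_ref,
                  params = config$params)
  info_all <- do.call(rbind, lapply(names(imput), function(ch) {
    df <- imput[[ch]]$info; df$chip <- ch; df
  }))
  # info QC is applied per chip run, as the imputation itself is; it is a
  # quality filter for imputed genotypes, so markers directly typed on a
  # chip are exempt on that chip
  pass_by_chip <- lapply(names(imput), function(ch)
    union(cohort$typed[[ch]]$probed_ids,
          filter_variants(imput[[ch]]$info, config$params$info_threshold)))
  names(pass_by_chip) <- names(imput)

  say("stage 5: translation")
  n <- nrow(truth)
  d460 <- rep(NA_integer_, n); d345 <- rep(NA_integer_, n)
  for (ch in names(imput)) {
    rows <- match(imput[[ch]]$sample_ids, truth$sample_id)
    P <- imput[[ch]]$posteriors
    passed <- pass_by_chip[[ch]]
    hard <- function(vid) {
      if (!vid %in% passed) return(rep(NA_integer_, length(rows)))
      best_guess_genotype(cbind(P$p0[, vid], P$p1[, vid], P$p2[, vid]),
                          config$params$call_threshold)
    }
    d460[rows] <- hard("rs1800460")
    d345[rows] <- hard("rs1142345")
  }
  diplotype <- diplotype_from_dosages(d460, d345)
  calls <- data.frame(sample_id = truth$sample_id,
                      g460 = d460, g345 = d345,
                      diplotype = diplotype,
                      defective = defective_count(diplotype),
                      phenotype = phenotype_of(diplotype),
                      stringsAsFactors = FALSE)

  say("stage 6: frequency tables")
  called <- !is.na(diplotype)
  tables <- list(
    alleles = allele_frequency_table(diplotype, ancestry$super_group),
    genotypes = genotype_frequency_table(diplotype, ancestry$super_group),
    phenotypes = phenotype_frequency_table(diplotype, ancestry$super_group))

  say("stage 7: validation against truth")
  classes <- .all_genotypes()
  vp <- validation_pairs(truth$sample_id[called], diplotype[called],
                         truth$diplotype[called])
  cm <- confusion_matrix(vp, classes)
  cm_def <- confusion_matrix(collapse_to_defective_count(vp),
                             c("0", "1", "2"))
  validation <- list(
    pairs = vp,
    confusion_diplotype = cm,
    confusion_defective = cm_def,
    concordance_diplotype = concordance_percent(cm),
    concordance_defective = concordance_percent(cm_def),
    metrics_defective = all_metrics(cm_def),
    n_called = sum(called), n_no_call = sum(!called))

  res <- structure(list(
    config = config, panel = panel_ref, cohort = cohort, truth = truth,
    ancestry = ancestry, sex = sex, pca = pca, kept_markers = kept,
    imputation = imput, info = info_all, passed_by_chip = pass_by_chip,
    calls = calls, tables = tables, validation = validation,
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "tpmt_run")
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

#' @export
print.tpmt_run <- function(x, ...) {
  cat(sprintf("tpmtstar pipeline run (seed %d): %d samples, %d called\n",
              x$config$seed, nrow(x$truth), x$validation$n_called))
  cat(sprintf("  ancestry super-group recovery: %.2f%%\n",
              100 * mean(x$ancestry$super_group == x$truth$super_group)))
  cat(sprintf("  sex recovery: %.2f%% (%.2f%% undetermined)\n",
              100 * mean(x$sex$sex == x$truth$sex),
              100 * mean(x$sex$sex == "undetermined")))
  for (ch in names(x$passed_by_chip))
    cat(sprintf("  variants passing info >= %.2f on %s: %d / %d\n",
                x$config$params$info_threshold, ch,
                length(x$passed_by_chip[[ch]]), nrow(x$panel$variants)))
  cat(sprintf("  diplotype concordance vs truth: %.2f%%\n",
              x$validation$concordance_diplotype))
  cat(sprintf("  defective-count concordance:    %.2f%%\n",
              x$validation$concordance_defective))
  invisible(x)
}

#' @export
summary.tpmt_run <- function(object, ...) {
  print(object)
  cat("\nphenotype table:\n")
  print(object$tables$phenotypes)
  cat("\ndefective-count metrics:\n")
  print(object$validation$metrics_defective, row.names = FALSE)
  invisible(object)
}

#' Write pipeline outputs to a directory
#'
#' Emits the reference panel VCF, per-chip posterior VCFs (GP/DS fields),
#' an info-score sidecar TSV, the sample manifest, the calls table, the
#' three frequency tables, validation metrics JSON, and a run manifest
#' JSON echoing the configuration and its hash.
#'
#' @param run A `tpmt_run`.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  write_panel_vcf(run$panel, fp("panel.vcf"))
  for (ch in names(run$imputation)) {
    im <- run$imputation[[ch]]
    g <- best_guess_genotype
    hard_gt <- matrix("./.", length(im$sample_ids),
                      ncol(im$dosage),
                      dimnames = list(im$sample_ids, colnames(im$dosage)))
    for (v in colnames(im$dosage)) {
      bg <- g(cbind(im$posteriors$p0[, v], im$posteriors$p1[, v],
                    im$posteriors$p2[, v]),
              run$config$params$call_threshold)
      hard_gt[, v] <- ifelse(is.na(bg), "./.",
                             c("0/0", "0/1", "1/1")[bg + 1L])
    }
    write_vcf(run$panel$variants, hard_gt,
              fp(sprintf("imputed_%s.vcf", gsub("[^a-z0-9]", "_", ch))),
              gp = run$imputation[[ch]]$posteriors, ds = im$dosage)
  }
  utils::write.table(run$info, fp("info_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- data.frame(sample_id = run$truth$sample_id,
                         population = run$ancestry$population,
                         super_group = run$ancestry$super_group,
                         f_stat = run$sex$f_stat, sex = run$sex$sex,
                         chip = run$truth$chip)
  utils::write.table(manifest, fp("samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(run$calls, fp("calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(run$truth, fp("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (nm in names(run$tables))
    write_freq_table(run$tables[[nm]], fp(sprintf("table_%s.tsv", nm)))
  jsonlite::write_json(
    list(concordance_diplotype = run$validation$concordance_diplotype,
         concordance_defective = run$validation$concordance_defective,
         metrics_defective = run$validation$metrics_defective),
    fp("validation.json"), auto_unbox = TRUE, digits = NA, na = "null")
  cfg <- run$config
  cfg$pop_specs <- lapply(cfg$pop_specs, unclass)
  cfg$params <- unclass(cfg$params)
  cfg_path <- fp("config.json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  jsonlite::write_json(
    list(config_hash = unname(tools::md5sum(cfg_path)),
         elapsed_seconds = run$elapsed,
         n_samples = nrow(run$truth)),
    fp("run_manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
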