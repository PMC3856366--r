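#' @include stability.R enrichment.R association.R mirna.R
NULL

#' Assemble a pipeline configuration
#'
#' @param expression,metadata,signals,gene_sets,mirna_targets,
#'   mirna_expression input file paths (expression/metadata TSV,
#'   intron-exon TSV, GMT, TargetScan-style TSV, miRNA expression TSV).
#' @param output_dir directory for the report bundle.
#' @param bottom_quantile expression filter quantile (default 0.20).
#' @param tail_fraction extreme-tail fraction (default 0.05).
#' @param stratum_threshold RPKM threshold splitting the regression strata
#'   (default 1).
#' @param bins expression-bin data.frame (default
#'   \code{\link{defaultExpressionBins}()}).
#' @param bootstrap_samples bootstrap replicates (default 10000).
#' @param fdr_threshold per-family FDR flag threshold (default 0.05).
#' @param seed RNG seed for the bootstrap stage.
#' @param ie_orientation \code{"intron_over_exon"} or
#'   \code{"exon_over_intron"}.
#' @return list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(expression, metadata, signals, gene_sets,
                           mirna_targets, mirna_expression, output_dir,
                           bottom_quantile = 0.20, tail_fraction = 0.05,
                           stratum_threshold = 1,
                           bins = defaultExpressionBins(),
                           bootstrap_samples = 10000L,
                           fdr_threshold = 0.05, seed = 1L,
                           ie_orientation = "intron_over_exon") {
  cfg <- list(inputs = list(expression = expression, metadata = metadata,
                            signals = signals, gene_sets = gene_sets,
                            mirna_targets = mirna_targets,
                            mirna_expression = mirna_expression),
              output_dir = output_dir,
              params = list(bottom_quantile = bottom_quantile,
                            tail_fraction = tail_fraction,
                            stratum_threshold = stratum_threshold,
                            bins = bins,
                            bootstrap_samples = as.integer(bootstrap_samples),
                            fdr_threshold = fdr_threshold,
                            seed = as.integer(seed),
                            ie_orientation = ie_orientation))
  missing.in <- !vapply(cfg$inputs, file.exists, logical(1))
  if (any(missing.in))
    .valueError("input file(s) not found: %s",
                paste(unlist(cfg$inputs[missing.in]), collapse = ", "))
  with(cfg$params, {
    if (bottom_quantile < 0 || bottom_quantile >= 1)
      .valueError("bottom_quantile out of range")
    if (tail_fraction <= 0 || tail_fraction >= 0.5)
      .valueError("tail_fraction out of range")
    if (bootstrap_samples < 1) .valueError("bootstrap_samples must be >= 1")
  })
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML mirrors \code{\link{pipelineConfig}}: an \code{inputs} mapping,
#' an \code{output_dir}, and an optional \code{params} mapping (absent
#' parameters take their defaults; \code{bins} is a list of
#' \code{lower:upper} strings).
#'
#' @param path YAML file path.
#' @return A \code{"PipelineConfig"}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  p <- y$params
  if (is.null(p)) p <- list()
  bins <- defaultExpressionBins()
  if (!is.null(p$bins)) {
    parts <- strsplit(unlist(p$bins), ":", fixed = TRUE)
    lo <- as.numeric(vapply(parts, `[`, character(1), 1))
    hi <- as.numeric(vapply(parts, `[`, character(1), 2))
    bins <- data.frame(lower = lo, upper = hi,
                       label = sprintf("%g-%g", lo, hi),
                       stringsAsFactors = FALSE)
  }
  defaults <- list(bottom_quantile = 0.20, tail_fraction = 0.05,
                   stratum_threshold = 1, bootstrap_samples = 10000L,
                   fdr_threshold = 0.05, seed = 1L,
                   ie_orientation = "intron_over_exon")
  for (nm in names(defaults))
    if (is.null(p[[nm]])) p[[nm]] <- defaults[[nm]]
  pipelineConfig(expression = y$inputs$expression,
                 metadata = y$inputs$metadata,
                 signals = y$inputs$signals,
                 gene_sets = y$inputs$gene_sets,
                 mirna_targets = y$inputs$mirna_targets,
                 mirna_expression = y$inputs$mirna_expression,
                 output_dir = y$output_dir,
                 bottom_quantile = p$bottom_quantile,
                 tail_fraction = p$tail_fraction,
                 stratum_threshold = p$stratum_threshold,
                 bins = bins,
                 bootstrap_samples = p$bootstrap_samples,
                 fdr_threshold = p$fdr_threshold,
                 seed = p$seed,
                 ie_orientation = p$ie_orientation)
}

#' Run the full PA/TR analysis pipeline
#'
#' Executes filter, PA/TR, intron/exon, extreme-tail, gene-set enrichment
#' (panel shift tests plus top/bottom-tail over-representation against the
#' expressed background), expression-association (stratified regression,
#' RPKM bins, ANOVA over 20-80 RPKM, bin shift tests) and miRNA-target
#' stages (partition, Mann-Whitney + seeded bootstrap, per-family tests,
#' expression-stability Spearman), writing one TSV per stage plus a YAML
#' run manifest with all parameters, the seed and per-stage record counts.
#' Any stage error aborts with the stage name; stages completed before the
#' failure are flagged in the manifest.
#'
#' @param config a \code{"PipelineConfig"} (from
#'   \code{\link{pipelineConfig}} or \code{\link{readPipelineConfig}}).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  prm <- config$params
  manifest <- list(package_version = as.character(utils::packageVersion("patrseq")),
                   parameters = prm[setdiff(names(prm), "bins")],
                   bins = sprintf("%g:%g", prm$bins$lower, prm$bins$upper),
                   stages = list(), counts = list())
  results <- list()
  .finish <- function() {
    yaml::write_yaml(manifest, file.path(config$output_dir, "manifest.yaml"))
  }
  stage <- function(name, code) {
    r <- tryCatch(force(code), error = function(e) {
      manifest$stages[[name]] <<- "failed"
      .finish()
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    manifest$stages[[name]] <<- "complete"
    r
  }

  expr <- stage("read_inputs", readExpressionTable(config$inputs$expression,
                                                   config$inputs$metadata))
  manifest$counts$n_input_transcripts <- nrow(expr)

  filt <- stage("filter", filterTranscripts(expr, prm$bottom_quantile))
  manifest$counts$n_after_filter <- nrow(filt)
  manifest$counts$n_noncoding_removed <-
    metadata(filt)$filter_log$n_noncoding_removed
  manifest$counts$n_lowexpr_removed <- metadata(filt)$filter_log$n_lowexpr_removed

  stab <- stage("patr", {
    s <- computePatr(filt)
    sig <- readFeatureSignals(config$inputs$signals)
    s <- computeIeRatio(sig, s, orientation = prm$ie_orientation)
    selectExtremes(s, prm$tail_fraction)
  })
  manifest$counts$n_stability <- length(stab)
  manifest$counts$n_dropped_zero_tr <- provenance(stab)$n_dropped_zero_tr
  manifest$counts$n_per_tail <- sum(tailFlag(stab) == "top")
  writeStabilityTable(stab, file.path(config$output_dir, "stability.tsv"))
  results$stability <- stab

  results$tail_profiles <- stage("tail_profiles", {
    tp <- lapply(c("top", "bottom"), function(t) {
      pr <- tailRankProfile(stab, t)
      data.frame(tail = t, n = pr$n, t(pr$quartiles))
    })
    tp <- do.call(rbind, tp)
    .writeTsv(tp, file.path(config$output_dir, "tail_ie_rank_profiles.tsv"))
    tp
  })

  results$geneset_shift <- stage("geneset_shift", {
    sets <- readGeneSets(config$inputs$gene_sets)
    sh <- geneSetShiftTests(stab, sets)
    .writeTsv(sh, file.path(config$output_dir, "geneset_shift.tsv"))
    background <- transcriptIds(stab)
    for (t in c("top", "bottom")) {
      sel <- names(tailFlag(stab))[tailFlag(stab) == t]
      ora <- oraTest(sel, background, sets)
      .writeTsv(ora, file.path(config$output_dir, sprintf("ora_%s.tsv", t)))
      results[[paste0("ora_", t)]] <- ora
    }
    sh
  })

  results$association <- stage("association", {
    thr <- prm$stratum_threshold
    strata <- list(
      all = regressStabilityOnExpression(stab),
      high = regressStabilityOnExpression(stab, min_rpkm = thr),
      low = regressStabilityOnExpression(stab, max_rpkm = thr))
    reg <- do.call(rbind, lapply(names(strata), function(nm)
      data.frame(stratum = nm, as.data.frame(strata[[nm]]))))
    .writeTsv(reg, file.path(config$output_dir, "regression.tsv"))
    manifest$counts$n_stratum_low <- strata$low$n
    manifest$counts$n_stratum_high <- strata$high$n
    binned <- binByExpression(stab, prm$bins)
    lo <- suppressWarnings(as.numeric(sub("-.*$", "", names(binned))))
    av.labels <- names(binned)[!is.na(lo) & lo >= 20 & lo <= 80 &
                                 lengths(binned) >= 2L]
    if (length(av.labels) < 2L)
      .degenerateError("fewer than 2 populated bins in the 20-80 RPKM range")
    av <- anovaAcrossBins(binned, av.labels)
    bt <- pairwiseBinShiftTests(binned, logPatr(stab))
    .writeTsv(bt, file.path(config$output_dir, "bin_shift_tests.tsv"))
    .writeTsv(data.frame(k_groups = av$k_groups,
                         f_statistic = av$f_statistic,
                         p_value = av$p_value),
              file.path(config$output_dir, "anova.tsv"))
    list(strata = strata, binned = binned, anova = av, bin_tests = bt)
  })

  results$mirna <- stage("mirna", {
    tmap <- readMirnaTargets(config$inputs$mirna_targets)
    mexpr <- readMirnaExpression(config$inputs$mirna_expression)
    part <- partitionByTargets(stab, tmap)
    manifest$counts$n_targets <- length(part$target_set)
    manifest$counts$n_nontargets <- length(part$nontarget_set)
    tvn <- targetsVsNontargetsTest(stab, part$target_set, part$nontarget_set,
                                   b = prm$bootstrap_samples, seed = prm$seed)
    fam <- perFamilyTests(stab, tmap, prm$fdr_threshold)
    .writeTsv(fam, file.path(config$output_dir, "mirna_families.tsv"))
    corr <- expressionStabilityCorrelation(fam, mexpr)
    .writeTsv(data.frame(
      n_targets = tvn$shift$n_targets,
      n_nontargets = tvn$shift$n_nontargets,
      mw_p = tvn$shift$p_value,
      boot_diff = tvn$bootstrap$observed_diff,
      boot_ci_low = tvn$bootstrap$ci_low,
      boot_ci_high = tvn$bootstrap$ci_high,
      boot_p = tvn$bootstrap$p_value,
      n_families = corr$n_families,
      spearman_rho = corr$spearman_rho,
      spearman_p = corr$p_value),
      file.path(config$output_dir, "mirna_summary.tsv"))
    manifest$counts$n_families_tested <- nrow(fam)
    manifest$counts$n_families_lower <- sum(fam$lower_than_population)
    list(partition = part, test = tvn, families = fam, correlation = corr)
  })

  .finish()
  results$manifest <- manifest
  invisible(results)
}
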