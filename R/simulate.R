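#' @include methods.R
NULL

#' Build a validated simulation configuration
#'
#' Parameters of the generative model behind \code{\link{simulateDataset}}.
#' Each transcript gets a transcription rate \code{k_tx} and a degradation
#' rate \code{k_deg} (stable and unstable classes occupy low and high
#' degradation regimes), a steady-state abundance \code{M = k_tx / k_deg},
#' and a fully-polyadenylated fraction \code{f_polyA} drawn from the
#' class's Beta distribution and coupled anti-monotonically to \code{k_deg}
#' within the class. Noise-free signals are \code{PA = f_polyA * M},
#' \code{TR = M} (exonic) and \code{0.1 * k_tx} (intronic, nascent
#' proportionality); observed RPKM multiplies each by independent
#' log-normal noise per sample.
#'
#' @param n_transcripts number of transcripts.
#' @param unstable_fraction probability a transcript is in the unstable
#'   (high-degradation) class.
#' @param seed RNG seed; the seed fully determines the dataset.
#' @param noise_sigma SD of the log-normal multiplicative measurement noise.
#' @param n_replicates replicates per timepoint (default 2).
#' @param timepoints_zt mRNA-library timepoints in zeitgeber hours
#'   (default \code{c(0, 12)}).
#' @param polyA_beta_stable,polyA_beta_unstable Beta shape pairs (a, b) for
#'   the polyadenylated fraction of each class.
#' @param lowexpr_unstable_coupling downward shift (in log units) of
#'   \code{k_tx} for unstable transcripts; plants the pattern where lowly
#'   expressed transcripts are disproportionately unstable.
#' @param n_gene_sets number of gene sets.
#' @param planted_set_odds sampling-odds weighting of planted sets toward
#'   one stability class (1 = no planted structure).
#' @param planted_set_size member count of each planted set.
#' @param n_mirna_families number of miRNA families.
#' @param target_odds odds weighting of the miRNA target pool toward the
#'   unstable class (1 = no skew).
#' @param target_pool_fraction fraction of transcripts eligible as miRNA
#'   targets (families sample within this pool, so the union of targets
#'   stays near this coverage).
#' @param mirna_timepoints number of miRNA-expression timepoints (default 6).
#' @param noncoding_fraction fraction of non-coding transcripts.
#' @param no_intron_fraction fraction of transcripts without introns.
#' @return list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(n_transcripts = 5000L,
                             unstable_fraction = 0.3,
                             seed = 1L,
                             noise_sigma = 0.25,
                             n_replicates = 2L,
                             timepoints_zt = c(0, 12),
                             polyA_beta_stable = c(2, 1),
                             polyA_beta_unstable = c(0.6, 4),
                             lowexpr_unstable_coupling = 0,
                             n_gene_sets = 50L,
                             planted_set_odds = 1,
                             planted_set_size = 200L,
                             n_mirna_families = 90L,
                             target_odds = 1,
                             target_pool_fraction = 0.48,
                             mirna_timepoints = 6L,
                             noncoding_fraction = 0.05,
                             no_intron_fraction = 0.15) {
  cfg <- list(n_transcripts = as.integer(n_transcripts),
              unstable_fraction = unstable_fraction,
              seed = as.integer(seed),
              noise_sigma = noise_sigma,
              n_replicates = as.integer(n_replicates),
              timepoints_zt = as.numeric(timepoints_zt),
              polyA_beta_stable = as.numeric(polyA_beta_stable),
              polyA_beta_unstable = as.numeric(polyA_beta_unstable),
              lowexpr_unstable_coupling = lowexpr_unstable_coupling,
              n_gene_sets = as.integer(n_gene_sets),
              planted_set_odds = planted_set_odds,
              planted_set_size = as.integer(planted_set_size),
              n_mirna_families = as.integer(n_mirna_families),
              target_odds = target_odds,
              target_pool_fraction = target_pool_fraction,
              mirna_timepoints = as.integer(mirna_timepoints),
              noncoding_fraction = noncoding_fraction,
              no_intron_fraction = no_intron_fraction)
  with(cfg, {
    if (n_transcripts < 10L) .specError("n_transcripts must be >= 10")
    if (unstable_fraction <= 0 || unstable_fraction >= 1)
      .specError("unstable_fraction must be in (0, 1)")
    if (noise_sigma < 0) .specError("noise_sigma must be >= 0")
    if (n_replicates < 1L || mirna_timepoints < 1L ||
        n_gene_sets < 1L || n_mirna_families < 1L)
      .specError("all counts must be >= 1")
    if (any(c(polyA_beta_stable, polyA_beta_unstable) <= 0))
      .specError("Beta shape parameters must be positive")
    if (planted_set_odds < 1 || target_odds < 1)
      .specError("odds parameters must be >= 1")
    if (lowexpr_unstable_coupling < 0)
      .specError("lowexpr_unstable_coupling must be >= 0")
    if (target_pool_fraction <= 0 || target_pool_fraction > 1)
      .specError("target_pool_fraction must be in (0, 1]")
    if (noncoding_fraction < 0 || noncoding_fraction >= 1 ||
        no_intron_fraction < 0 || no_intron_fraction >= 1)
      .specError("noncoding/no-intron fractions must be in [0, 1)")
  })
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Study-shaped default configuration
#'
#' A configuration echoing the study design at desk scale: 2 replicates at
#' ZT0 and ZT12 for the paired polyA/total mRNA libraries, 6 miRNA
#' timepoints, 5,000 transcripts, 50 gene sets, 90 miRNA families, planted
#' gene-set odds 4 and miRNA-target odds 3, log-normal noise sigma 0.25,
#' fixed seed.
#'
#' @param seed RNG seed (default 101).
#' @return A \code{"SimulationConfig"}.
#' @export
defaultStudyShapedConfig <- function(seed = 101L) {
  simulationConfig(n_transcripts = 5000L, unstable_fraction = 0.3,
                   seed = seed, noise_sigma = 0.25,
                   n_replicates = 2L, timepoints_zt = c(0, 12),
                   lowexpr_unstable_coupling = 1,
                   n_gene_sets = 50L, planted_set_odds = 4,
                   planted_set_size = 200L,
                   n_mirna_families = 90L, target_odds = 3,
                   mirna_timepoints = 6L)
}

#' Simulate a complete input bundle with known ground truth
#'
#' Deterministic in the configuration (including its seed). Draw order:
#' stability class, degradation rates, transcription rates, polyA
#' fractions, biotype and intron flags, per-sample measurement noise
#' (polyA then total, column by column), intronic-signal noise, gene sets,
#' miRNA target pool and families, miRNA expression.
#'
#' @param config a \code{"SimulationConfig"} from
#'   \code{\link{simulationConfig}}.
#' @return list with \code{expression} (\linkS4class{RpkmExperiment}),
#'   \code{signals} (feature-signal data.frame, intron-bearing transcripts
#'   only), \code{geneSets} (\linkS4class{GeneSetCollection}),
#'   \code{setTruth} (data.frame: which sets were planted and toward which
#'   class), \code{mirnaTargets} (\linkS4class{MirnaTargetMap}),
#'   \code{mirnaExpression} (data.frame), \code{truth} (data.frame with
#'   \code{transcript_id}, \code{k_tx}, \code{k_deg}, \code{f_polyA},
#'   \code{class}), and \code{config}.
#' @export
simulateDataset <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  .withSeed(config$seed, {
    n <- config$n_transcripts
    ids <- sprintf("TX%05d", seq_len(n))
    unstable <- stats::runif(n) < config$unstable_fraction
    if (!any(unstable) || all(unstable))
      .specError("configuration produced an empty stability class")
    class.lab <- ifelse(unstable, "unstable", "stable")

    k.deg <- numeric(n)
    k.deg[!unstable] <- stats::rlnorm(sum(!unstable), log(0.25), 0.4)
    k.deg[unstable] <- stats::rlnorm(sum(unstable), log(1), 0.4)

    mu.tx <- log(20) - config$lowexpr_unstable_coupling * unstable
    k.tx <- stats::rlnorm(n, mu.tx, 1)
    M <- k.tx / k.deg

    ## f_polyA: class Beta draws, coupled anti-monotonically to k_deg
    ## within each class (slowest-degrading members get the largest f).
    f <- numeric(n)
    for (cls in c(FALSE, TRUE)) {
      idx <- which(unstable == cls)
      sh <- if (cls) config$polyA_beta_unstable else config$polyA_beta_stable
      draws <- stats::rbeta(length(idx), sh[1], sh[2])
      draws <- pmax(draws, 1e-6)
      r <- rank(k.deg[idx], ties.method = "first")
      f[idx] <- sort(draws, decreasing = TRUE)[r]
    }

    biotype <- ifelse(stats::runif(n) < config$noncoding_fraction,
                      "non_coding", "coding")
    has.introns <- stats::runif(n) >= config$no_intron_fraction

    ## sample grid: (timepoint x replicate) x (polyA, total)
    grid <- expand.grid(replicate = seq_len(config$n_replicates),
                        timepoint_zt = config$timepoints_zt)
    grid <- grid[order(grid$timepoint_zt, grid$replicate), ]
    pa.ids <- sprintf("PA_ZT%g_r%d", grid$timepoint_zt, grid$replicate)
    tr.ids <- sprintf("TR_ZT%g_r%d", grid$timepoint_zt, grid$replicate)
    noise <- function() {
      if (config$noise_sigma == 0) rep(1, n)
      else stats::rlnorm(n, 0, config$noise_sigma)
    }
    pa.mat <- vapply(seq_len(nrow(grid)), function(j) f * M * noise(), numeric(n))
    tr.mat <- vapply(seq_len(nrow(grid)), function(j) M * noise(), numeric(n))
    colnames(pa.mat) <- pa.ids
    colnames(tr.mat) <- tr.ids
    rpkm <- cbind(pa.mat, tr.mat)

    samples <- data.frame(
      sample_id = c(pa.ids, tr.ids),
      library_type = rep(c("polyA", "total"), each = nrow(grid)),
      replicate = rep(grid$replicate, 2),
      timepoint_zt = rep(grid$timepoint_zt, 2),
      stringsAsFactors = FALSE)
    annotations <- data.frame(
      transcript_id = ids,
      gene_id = sub("^TX", "GN", ids),
      biotype = biotype, has_introns = has.introns,
      stringsAsFactors = FALSE)
    expr <- RpkmExperiment(rpkm, annotations, samples)

    ## intron/exon signals from the total library (intron-bearing only):
    ## exonic = the TR sample values themselves; intronic = 0.1 * k_tx
    ## (nascent proportionality) with fresh per-sample noise.
    intr.mat <- vapply(seq_len(nrow(grid)), function(j) 0.1 * k.tx * noise(),
                       numeric(n))
    signals <- data.frame(transcript_id = ids,
                          exonic_rpkm = rowMeans(tr.mat),
                          intronic_rpkm = rowMeans(intr.mat),
                          stringsAsFactors = FALSE)
    signals <- signals[has.introns, , drop = FALSE]

    ## gene sets: planted sets oversample one class with the given odds
    n.planted <- if (config$planted_set_odds > 1)
      max(1L, as.integer(round(0.2 * config$n_gene_sets))) else 0L
    set.ids <- sprintf("SET%03d", seq_len(config$n_gene_sets))
    set.dir <- rep(NA_character_, config$n_gene_sets)
    if (n.planted > 0)
      set.dir[seq_len(n.planted)] <- rep(c("unstable", "stable"),
                                         length.out = n.planted)
    sets <- vector("list", config$n_gene_sets)
    for (i in seq_len(config$n_gene_sets)) {
      if (!is.na(set.dir[i])) {
        w <- ifelse(class.lab == set.dir[i], config$planted_set_odds, 1)
        size <- min(config$planted_set_size, n)
      } else {
        w <- rep(1, n)
        size <- sample(20:min(200, n), 1)
      }
      sets[[i]] <- sample(ids, size, prob = w)
    }
    names(sets) <- set.ids
    gene.sets <- GeneSetCollection(sets, paste("synthetic set", seq_along(sets)))
    set.truth <- data.frame(term_id = set.ids, planted = !is.na(set.dir),
                            direction = set.dir, stringsAsFactors = FALSE)

    ## miRNA targets: a pool skewed toward the unstable class, from which
    ## families draw, keeping union coverage near target_pool_fraction.
    pool.size <- max(1L, round(config$target_pool_fraction * n))
    w <- ifelse(unstable, config$target_odds, 1)
    pool <- sample(ids, pool.size, prob = w)
    fam.ids <- sprintf("miR-fam%03d", seq_len(config$n_mirna_families))
    fam.sizes <- sample(30:300, config$n_mirna_families, replace = TRUE)
    fam.sizes <- pmin(fam.sizes, pool.size)
    targets <- lapply(fam.sizes, function(s) sample(pool, s))
    names(targets) <- fam.ids
    target.map <- MirnaTargetMap(targets)

    ## miRNA expression: independent of target stability by construction.
    mu <- stats::rlnorm(config$n_mirna_families, log(100), 1)
    tp <- vapply(seq_len(config$mirna_timepoints),
                 function(j) mu * stats::rlnorm(config$n_mirna_families, 0, 0.05),
                 numeric(config$n_mirna_families))
    tp <- matrix(tp, nrow = config$n_mirna_families)
    colnames(tp) <- paste0("tp", seq_len(config$mirna_timepoints))
    mirna.expr <- data.frame(family_id = fam.ids, tp,
                             stringsAsFactors = FALSE, check.names = FALSE)
    mirna.expr$mean_expression <- rowMeans(tp)

    truth <- data.frame(transcript_id = ids, k_tx = k.tx, k_deg = k.deg,
                        f_polyA = f, class = class.lab,
                        stringsAsFactors = FALSE)

    list(expression = expr, signals = signals,
         geneSets = gene.sets, setTruth = set.truth,
         mirnaTargets = target.map, mirnaExpression = mirna.expr,
         truth = truth, config = config)
  })
}

#' Write a simulated bundle as the pipeline's input files
#'
#' Writes expression + metadata TSVs, the intron/exon signal TSV, the GMT
#' gene sets, the miRNA target TSV, the miRNA expression TSV and the
#' ground-truth TSV into a directory, with the file names
#' \code{\link{runPipeline}} expects.
#'
#' @param sim output of \code{\link{simulateDataset}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
writeDatasetBundle <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    metadata = file.path(dir, "samples.tsv"),
    signals = file.path(dir, "intron_exon.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    mirna_targets = file.path(dir, "mirna_targets.tsv"),
    mirna_expression = file.path(dir, "mirna_expression.tsv"),
    truth = file.path(dir, "ground_truth.tsv"))
  writeExpressionTable(sim$expression, paths$expression, paths$metadata)
  writeFeatureSignals(sim$signals, paths$signals)
  writeGeneSets(sim$geneSets, paths$gene_sets)
  writeMirnaTargets(sim$mirnaTargets, paths$mirna_targets)
  writeMirnaExpression(sim$mirnaExpression, paths$mirna_expression)
  .writeTsv(sim$truth, paths$truth)
  invisible(paths)
}
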