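#' Pipeline configuration
#'
#' Collects every stage parameter of the two analysis arms with the study's
#' defaults, plus the seeds all randomness flows from. The configuration is
#' serialized (JSON) into every output directory for provenance.
#'
#' @param qc a [qc_thresholds()].
#' @param hvg_alpha HVG significance threshold, default 0.01.
#' @param min_module_size dynamic-tree-cut minimum cluster size, default 30.
#' @param perplexity t-SNE perplexity, default 50.
#' @param tsne_seed default 42.
#' @param diffusion a [diffusion_params()] (k = 21, 3 components).
#' @param n_states meta-stable states, default 4.
#' @param de_fdr DE FDR threshold, default 0.01.
#' @param tau_tra,tau_const tau classification thresholds (0.8 / 0.4).
#' @param expressed_min expressed-gene rule threshold, default 1.
#' @param downsample_target bulk downsampling depth, default 2e7 reads.
#' @param downsample_seed default 1.
#' @param offset log2 pseudo-count, default 1.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(qc = qc_thresholds(), hvg_alpha = 0.01,
                            min_module_size = 30, perplexity = 50,
                            tsne_seed = 42, diffusion = diffusion_params(),
                            n_states = 4, de_fdr = 0.01,
                            tau_tra = 0.8, tau_const = 0.4,
                            expressed_min = 1, downsample_target = 2e7,
                            downsample_seed = 1, offset = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

write_config <- function(config, out_dir) {
  plain <- lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)
  jsonlite::write_json(plain, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the single-cell analysis arm
#'
#' Executes qc-norm, HVG detection, clustering (+ optional t-SNE), diffusion
#' pseudotime with meta-stable states, and differential expression between
#' the two clusters (blocked on donor and plate column) in order, writing
#' every artifact plus the configuration to `out_dir`. Re-running with the
#' same inputs and configuration reproduces byte-identical outputs.
#'
#' @param counts a [count_matrix()] or path to a counts TSV (with metadata
#'   TSV via `unit_meta_path`).
#' @param out_dir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @param anchors optional [gene_set()] of maturation markers used to orient
#'   pseudotime.
#' @param unit_meta_path metadata TSV when `counts` is a path.
#' @param run_tsne compute the t-SNE embedding (requires Rtsne and enough
#'   cells for the configured perplexity), default TRUE.
#' @return invisibly, a list of the in-memory artifacts: `qc`, `normed`,
#'   `hvgs`, `clusters`, `trajectory`, `de` (and `tsne` if run).
#' @export
run_single_cell_arm <- function(counts, out_dir, config = pipeline_config(),
                                anchors = NULL, unit_meta_path = NULL,
                                run_tsne = TRUE) {
  if (is.character(counts)) {
    if (!file.exists(counts)) stop("missing input path: ", counts)
    counts <- read_count_matrix(counts, "tsv", unit_meta_path = unit_meta_path)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, out_dir)

  message("[qc-norm] ", ncol(counts$counts), " cells in")
  fc <- filter_cells(counts, config$qc)
  jsonlite::write_json(list(n_in = ncol(counts$counts),
                            n_retained = ncol(fc$retained$counts),
                            removed = fc$report),
                       file.path(out_dir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  kept <- filter_genes(fc$retained, config$qc$max_gene_zero_fraction)
  sf <- deconvolution_size_factors(kept)
  normed <- normalize_log2(kept, sf, offset = config$offset)
  write_matrix_tsv(round(normed$values, 6), file.path(out_dir, "normalized.tsv"))

  message("[hvg]")
  fit <- fit_cv2_trend(normed)
  hvgs <- call_hvgs(fit, alpha = config$hvg_alpha)
  utils::write.table(hvgs, file.path(out_dir, "hvgs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  hvg_ids <- hvgs$gene_id[hvgs$hvg]
  if (length(hvg_ids) < 3) stop("stage hvg failed: fewer than 3 HVGs detected")
  hv <- normed$values[hvg_ids, , drop = FALSE]

  message("[cluster] ", length(hvg_ids), " HVGs")
  d <- spearman_dissimilarity(hv)
  tree <- average_linkage_tree(d)
  clusters <- dynamic_tree_cut(tree, d, config$min_module_size)
  cl_df <- data.frame(unit_id = clusters$unit_ids, cluster = clusters$labels,
                      stringsAsFactors = FALSE)
  tsne <- NULL
  if (run_tsne && config$perplexity < (ncol(hv) - 1) / 3) {
    tsne <- tsne_embed(hv, perplexity = config$perplexity,
                       seed = config$tsne_seed)
    utils::write.table(
      data.frame(unit_id = rownames(tsne), round(tsne, 6)),
      file.path(out_dir, "tsne.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  utils::write.table(cl_df, file.path(out_dir, "clusters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  message("[pseudotime]")
  cn <- cosine_normalize(hv)
  traj <- diffusion_map(cn, config$diffusion)
  if (!is.null(anchors))
    traj <- orient_and_annotate(traj, anchors, normed, n_states = config$n_states)
  else
    traj$states <- assign_metastable_states(traj$pseudotime, config$n_states)
  traj_df <- data.frame(unit_id = traj$unit_ids,
                        round(traj$components, 8),
                        pseudotime = round(traj$pseudotime, 8),
                        state = traj$states$labels,
                        stringsAsFactors = FALSE)
  utils::write.table(traj_df, file.path(out_dir, "trajectory.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  message("[de] cluster 1 vs 2")
  de <- NULL
  if (length(unique(clusters$labels)) >= 2) {
    in12 <- clusters$labels %in% c(1, 2)
    blocks <- normed$unit_meta[in12, intersect(c("donor", "plate_col"),
                                               colnames(normed$unit_meta)),
                               drop = FALSE]
    if (ncol(blocks) == 0) blocks <- NULL
    de <- run_de(normed$values[, in12, drop = FALSE],
                 group = factor(clusters$labels[in12]),
                 blocks = blocks, fdr = config$de_fdr)
    utils::write.table(
      cbind(de[1], lapply(de[-1], function(x)
        if (is.numeric(x)) signif(x, 8) else x)),
      file.path(out_dir, "de.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(list(qc = fc, normed = normed, hvgs = hvgs, clusters = clusters,
                 tsne = tsne, trajectory = traj, de = de))
}

#' Run the tissue-restricted-antigen analysis arm
#'
#' Executes tau classification on the atlas, count downsampling to a common
#' depth, median-of-ratios normalization, and the TRA report (per-population
#' category proportions, tau-distribution shift, PCA on expressed TRA genes,
#' Pearson-correlation clades, homolog panel), writing artifacts and the
#' configuration to `out_dir`. Aborts if the atlas and bulk gene universes
#' overlap by less than 50%.
#'
#' @param atlas a [tissue_atlas()].
#' @param bulk a [count_matrix()] of bulk samples with a `population` column
#'   in its unit metadata.
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @param homologs optional [gene_set()] for the homolog panel.
#' @return invisibly, a list: `classification`, `downsampled`, `normed`,
#'   `proportions`, `tau_shift`, `pca`, `clades`, `homologs`.
#' @export
run_tra_arm <- function(atlas, bulk, out_dir, config = pipeline_config(),
                        homologs = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, out_dir)
  overlap <- mean(rownames(bulk$counts) %in% rownames(atlas$expression))
  message(sprintf("[tau] gene-universe overlap %.1f%%", 100 * overlap))
  if (overlap < 0.5)
    stop(sprintf("gene-universe overlap %.1f%% below 50%%: aborting", 100 * overlap))

  cls <- classify_genes(atlas, tau_tra = config$tau_tra,
                        tau_const = config$tau_const)
  utils::write.table(
    data.frame(gene_id = cls$gene_id, tau = round(cls$tau, 6),
               category = cls$category),
    file.path(out_dir, "tau.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  message("[downsample] target ", config$downsample_target)
  ds <- downsample_counts(bulk, config$downsample_target,
                          seed = config$downsample_seed)
  sf <- median_ratio_size_factors(ds)
  normed <- normalize_log2(ds, sf, offset = config$offset)
  pops <- factor(ds$unit_meta$population)

  message("[tra-report]")
  props <- tra_proportions(normed$linear, pops, cls, config$expressed_min)
  shift <- tau_shift_summary(normed$linear, pops, cls, config$expressed_min)
  tra_ids <- cls$gene_id[cls$category == "TRA"]
  expressed_any <- rownames(normed$linear)[
    rowMeans(normed$linear) >= config$expressed_min]
  tra_expressed <- intersect(tra_ids, expressed_any)
  pca <- pca_on_tra(normed$values, tra_expressed)
  clades <- correlation_clades(normed$values[tra_expressed, , drop = FALSE])
  hp <- if (!is.null(homologs)) homolog_panel(normed$values, homologs, pops)

  utils::write.table(props, file.path(out_dir, "tra_proportions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(overlap = overlap,
         expressed_min = config$expressed_min,
         n_tra_expressed = length(tra_expressed),
         pca_variance_fraction = round(pca$variance_fraction, 6),
         clades = as.list(clades$clades),
         tau_quantiles = apply(shift$quantiles, 1, as.list, simplify = FALSE)),
    file.path(out_dir, "tra_summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(list(classification = cls, downsampled = ds, normed = normed,
                 proportions = props, tau_shift = shift, pca = pca,
                 clades = clades, homologs = hp))
}
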