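#' Significance thresholds per branch
#'
#' The volcano thresholds: arrays use a 2-fold change with adjusted
#' p <= 0.05, NGS a 4-fold change with adjusted p <= 0.01 (each fold cut-off
#' justified by the 5th percentile of the respective fold-change
#' distribution, see [tail_cutoff()]).
#'
#' @param branch `"array"` or `"ngs"`.
#' @param fold_cutoff,alpha overrides.
#' @return list with `fold_cutoff` (linear) and `alpha`.
#' @export
thresholds <- function(branch = c("array", "ngs"), fold_cutoff = NULL,
                       alpha = NULL) {
  branch <- match.arg(branch)
  th <- if (branch == "array") list(fold_cutoff = 2, alpha = 0.05)
  else list(fold_cutoff = 4, alpha = 0.01)
  if (!is.null(fold_cutoff)) th$fold_cutoff <- fold_cutoff
  if (!is.null(alpha)) th$alpha <- alpha
  stopifnot(th$fold_cutoff >= 1, th$alpha > 0, th$alpha < 1)
  th
}

#' Classify genes into feedback-regulation classes
#'
#' Encodes the interpretive logic applied to the volcano results. Each gene
#' gets exactly one class:
#' * `primary_lesion` — the gene carries an engineered lesion;
#' * `operon_secondary` — it shares a transcription unit with a lesion, so a
#'   change is explained by the polycistron (readthrough, destabilization),
#'   not feedback;
#' * `translational_feedback_candidate` — translation output changes
#'   significantly (fold + adjusted-p rule) while RNA does not, or the TE
#'   shift itself exceeds the fold cut-off alongside a significant TO change
#'   (the psbB-in-a-psbD-mutant pattern);
#' * `transcript_level_candidate` — TO and RNA both significant with TE
#'   below the cut-off: the translational change follows the transcript;
#' * `unchanged` — otherwise.
#'
#' `cross_complex` flags candidates whose complex differs from every lesion
#' gene's complex (the PSII-mutant -> PSI-genes observation pattern).
#'
#' @param diff a `DiffResult` data.frame ([fit_diff_array()] /
#'   [fit_diff_ngs()]).
#' @param lesions character vector of lesion gene ids.
#' @param annotation the [plastome_annotation()].
#' @param th a [thresholds()] list.
#' @return data.frame `gene_id`, `class`, `cross_complex`, `direction`.
#' @export
classify_genes <- function(diff, lesions, annotation, th) {
  to <- diff[diff$assay == "TO", ]
  rna <- diff[diff$assay == "RNA", ]
  if (!nrow(to) || !nrow(rna)) stop("DiffResult must contain TO and RNA assays")
  genes <- to$gene_id
  rna <- rna[match(genes, rna$gene_id), ]
  if (anyNA(rna$gene_id)) stop("missing RNA assay for some genes")

  lfc <- log2(th$fold_cutoff)
  sig_to <- abs(to$mean_log2fc) >= lfc & !is.na(to$padj) & to$padj <= th$alpha
  sig_rna <- abs(rna$mean_log2fc) >= lfc & !is.na(rna$padj) &
    rna$padj <= th$alpha
  te <- to$log2fc_te

  tu_of <- vapply(annotation$genes, `[[`, "", "transcription_unit_id")
  cx_of <- vapply(annotation$genes, `[[`, "", "complex_label")
  lesion_tus <- unique(tu_of[lesions])
  lesion_cx <- unique(cx_of[lesions])

  cls <- character(length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    cls[i] <- if (g %in% lesions) "primary_lesion"
    else if (tu_of[g] %in% lesion_tus) "operon_secondary"
    else if ((sig_to[i] && !sig_rna[i]) || (abs(te[i]) >= lfc && sig_to[i]))
      "translational_feedback_candidate"
    else if (sig_to[i] && sig_rna[i] && abs(te[i]) < lfc)
      "transcript_level_candidate"
    else "unchanged"
  }
  candidate <- cls %in% c("translational_feedback_candidate",
                          "transcript_level_candidate")
  data.frame(gene_id = genes, class = cls,
             cross_complex = candidate & !(cx_of[genes] %in% lesion_cx),
             direction = ifelse(to$mean_log2fc >= 0, "up", "down"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Volcano table
#'
#' The plotted quantities of the volcano representation: log2 fold change
#' against -log10 adjusted p, with the threshold labels (`up` in red, `down`
#' in blue, `none`).
#'
#' @param diff a `DiffResult` data.frame.
#' @param th a [thresholds()] list.
#' @return data.frame `gene_id`, `assay`, `log2fc`, `neg_log10_padj`,
#'   `label`, `colour`.
#' @export
volcano_table <- function(diff, th) {
  lfc <- log2(th$fold_cutoff)
  sig <- abs(diff$mean_log2fc) >= lfc & !is.na(diff$padj) &
    diff$padj <= th$alpha
  label <- ifelse(!sig, "none", ifelse(diff$mean_log2fc > 0, "up", "down"))
  data.frame(gene_id = diff$gene_id, assay = diff$assay,
             log2fc = diff$mean_log2fc,
             neg_log10_padj = -log10(diff$padj),
             label = label,
             colour = c(none = "none", up = "red", down = "blue")[label],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the whole pipeline from a config
#'
#' Simulate (preset scenario) -> quantify (array or NGS branch) -> moderated
#' tests -> classify -> report. With an output directory, writes the
#' DiffResult, classification, volcano and truth-vs-estimate recovery tables
#' as TSV plus a YAML run log of every parameter. Deterministic given the
#' seed.
#'
#' @param config named list or path to a YAML/JSON file with fields:
#'   `branch` (`"array"`/`"ngs"`), `preset` (name in [scenario_presets()]),
#'   `seed`, optional `n_extra_genes` (filler ORFs of the toy plastome,
#'   default 59 for an 80-gene annotation), optional `thresholds`
#'   (`fold_cutoff`, `alpha`), optional `outdir`, optional `depth` (NGS).
#' @return (invisibly) list with `annotation`, `scenario`, `truth`, `quant`,
#'   `diff`, `classification`, `volcano`, `recovery`, `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(
    list(branch = "array", preset = "kd_psbD", seed = 1L,
         n_extra_genes = 59L, thresholds = list(), outdir = NULL,
         depth = 0.25),
    config)
  cfg$branch <- match.arg(cfg$branch, c("array", "ngs"))
  th <- do.call(thresholds, c(list(branch = cfg$branch), cfg$thresholds))
  other <- thresholds(if (cfg$branch == "array") "ngs" else "array")
  if (length(cfg$thresholds) && identical(th[names(other)], other))
    warning("thresholds match the ", if (cfg$branch == "array") "ngs"
            else "array", " defaults; applying them to the ", cfg$branch,
            " branch as requested")

  annotation <- toy_plastome(n_extra = cfg$n_extra_genes)
  sc <- scenario_presets(seed = cfg$seed)[[cfg$preset]]
  if (is.null(sc)) stop("unknown preset: ", cfg$preset)
  truth <- simulate_truth(annotation, sc)

  if (cfg$branch == "array") {
    design <- array_design(annotation)
    emitted <- emit_probe_tables(truth, design, sc)
    quant <- quantify_array(emitted$tables, design)
    diff <- fit_diff_array(quant)
  } else {
    aln <- emit_alignment_sets(truth, annotation, sc,
                               read_params = list(depth = cfg$depth))
    quant <- quantify_ngs(aln, annotation)
    diff <- fit_diff_ngs(quant)
  }

  cls <- classify_genes(diff, sc$lesions$gene_id, annotation, th)
  volc <- volcano_table(diff, th)

  affected <- unique(c(sc$lesions$gene_id, sc$feedback$gene_id))
  to <- diff[diff$assay == "TO", ]
  rna <- diff[diff$assay == "RNA", ]
  recovery <- data.frame(
    gene_id = affected,
    true_log2fc_to = truth$log2fc_to[match(affected, truth$gene_id)],
    est_log2fc_to = to$mean_log2fc[match(affected, to$gene_id)],
    true_log2fc_rna = truth$log2fc_rna[match(affected, truth$gene_id)],
    est_log2fc_rna = rna$mean_log2fc[match(affected, rna$gene_id)],
    stringsAsFactors = FALSE)

  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) utils::write.table(
      x, file.path(cfg$outdir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(as.data.frame(diff), "diff_results.tsv")
    wt(cls, "classification.tsv")
    wt(volc, "volcano.tsv")
    wt(recovery, "recovery.tsv")
    yaml::write_yaml(list(config = cfg[setdiff(names(cfg), "outdir")],
                          thresholds = th,
                          scenario = sc$name,
                          n_genes = length(gene_ids(annotation))),
                     file.path(cfg$outdir, "run_log.yaml"))
  }
  invisible(list(annotation = annotation, scenario = sc, truth = truth,
                 quant = quant, diff = diff, classification = cls,
                 volcano = volc, recovery = recovery,
                 config = cfg, thresholds = th))
}
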