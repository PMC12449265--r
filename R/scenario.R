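#' Declarative mutant scenario
#'
#' A scenario bundles the engineered lesions of a transplastomic line (with
#' their direct effects on transcript level and translation efficiency), the
#' feedback effects the simulation injects (the signal the pipeline is meant
#' to recover), replicate number, and the noise model.
#'
#' Lesion kinds mirror the mutant classes of transplastomic lines: `knockout`
#' (reading-frame deletion, RNA to background), `knockdown` (aadA insertion
#' reducing transcription of the cistron), and `readthrough_overexpression`
#' (aadA readthrough transcription raising the whole downstream operon).
#'
#' @param name scenario name.
#' @param lesions data.frame with columns `gene_id`, `kind`, `rna_factor`,
#'   `te_factor` (linear fold changes applied to the lesion gene itself).
#' @param feedback data.frame with columns `gene_id`, `level` (`transcript`
#'   or `translational`), `factor` (linear fold change).
#' @param n_replicates biological replicates per genotype (default 3, the
#'   study design).
#' @param noise list with `spot_cv` (lognormal CV of spot intensities),
#'   `count_dispersion` (Gamma overdispersion of read counts; 0 = Poisson),
#'   `bad_spot_rate` (fraction of flagged bad spots).
#' @param seed integer seed; all generator randomness derives from it.
#' @return object of class `Scenario`.
#' @export
scenario <- function(name, lesions = NULL, feedback = NULL,
                     n_replicates = 3L,
                     noise = list(spot_cv = 0.15, count_dispersion = 0,
                                  bad_spot_rate = 0.02),
                     seed = 1L) {
  empty_lesions <- data.frame(gene_id = character(0), kind = character(0),
                              rna_factor = numeric(0), te_factor = numeric(0),
                              stringsAsFactors = FALSE)
  empty_fb <- data.frame(gene_id = character(0), level = character(0),
                         factor = numeric(0), stringsAsFactors = FALSE)
  lesions <- if (is.null(lesions)) empty_lesions else as.data.frame(lesions)
  feedback <- if (is.null(feedback)) empty_fb else as.data.frame(feedback)
  if (nrow(lesions)) {
    stopifnot(all(c("gene_id", "kind", "rna_factor", "te_factor") %in%
                    names(lesions)),
              all(lesions$kind %in% c("knockout", "knockdown",
                                      "readthrough_overexpression")),
              all(lesions$rna_factor > 0), all(lesions$te_factor > 0))
  }
  if (nrow(feedback)) {
    stopifnot(all(c("gene_id", "level", "factor") %in% names(feedback)),
              all(feedback$level %in% c("transcript", "translational")),
              all(feedback$factor > 0))
  }
  both <- intersect(lesions$gene_id, feedback$gene_id)
  if (length(both))
    warning("genes in both lesion and feedback sets: ",
            paste(both, collapse = ", "))
  noise <- utils::modifyList(list(spot_cv = 0.15, count_dispersion = 0,
                                  bad_spot_rate = 0.02), as.list(noise))
  structure(list(name = name, lesions = lesions, feedback = feedback,
                 n_replicates = as.integer(n_replicates), noise = noise,
                 seed = as.integer(seed)),
            class = "Scenario")
}

#' @export
print.Scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': %d lesion(s), %d feedback effect(s), %d replicates, seed %d\n",
              x$name, nrow(x$lesions), nrow(x$feedback), x$n_replicates, x$seed))
  invisible(x)
}

#' Preset scenarios mirroring the studied mutant classes
#'
#' * `null` — control vs control, no injected effects.
#' * `kd_psbD` — aadA-insertion knockdown of a psbD/C operon (direct ~2-fold
#'   RNA reduction of psbD and psbC, strong direct translational defect of
#'   psbD so its translation output drops ~11-fold, milder for psbC), plus
#'   injected translational feedback on two genes in other transcription
#'   units: psbB (PSII, ~3-fold down) and psaA (PSI, ~2-fold down) — the
#'   cross-complex PSII->PSI pattern.
#' * `ko_petBD` — deletion knockout of petB and petD (RNA to background),
#'   plus translational feedback on psbA (~7-fold down).
#' * `ox_psaI` — aadA readthrough overexpression inserted in psaI: the
#'   downstream operon genes (ycf4, cemA, petA) gain ~5-fold RNA, and petB
#'   (different transcription unit) gains ~2.5-fold translational feedback.
#'
#' @param seed seed stored in each preset (default 1).
#' @param n_replicates replicates per genotype (default 3).
#' @return named list of [scenario()] objects.
#' @export
scenario_presets <- function(seed = 1L, n_replicates = 3L) {
  list(
    null = scenario("null", seed = seed, n_replicates = n_replicates),
    kd_psbD = scenario(
      "kd_psbD",
      lesions = data.frame(
        gene_id = c("psbD", "psbC"),
        kind = "knockdown",
        rna_factor = c(0.5, 0.5),
        te_factor = c(0.18, 0.7)),
      feedback = data.frame(
        gene_id = c("psbB", "psaA"),
        level = "translational",
        factor = c(0.30, 0.45)),
      seed = seed, n_replicates = n_replicates),
    ko_petBD = scenario(
      "ko_petBD",
      lesions = data.frame(
        gene_id = c("petB", "petD"),
        kind = "knockout",
        rna_factor = 0.01,
        te_factor = 1),
      feedback = data.frame(
        gene_id = "psbA", level = "translational", factor = 0.14),
      seed = seed, n_replicates = n_replicates),
    ox_psaI = scenario(
      "ox_psaI",
      lesions = data.frame(
        gene_id = "psaI", kind = "readthrough_overexpression",
        rna_factor = 5, te_factor = 1),
      feedback = data.frame(
        gene_id = "petB", level = "translational", factor = 2.5),
      seed = seed, n_replicates = n_replicates)
  )
}

#' Simulate per-gene ground truth for a scenario
#'
#' Draws baseline control expression per gene (lognormal, meanlog = log 1000,
#' sdlog = 1; translation efficiency 1), then applies the scenario's lesion
#' and feedback factors multiplicatively. Readthrough-overexpression lesions
#' propagate their `rna_factor` to genes downstream (in transcription order)
#' within the same transcription unit — the operon-coupling the aadA marker
#' causes. Deterministic given `(scenario, seed)`.
#'
#' @param annotation a [plastome_annotation()].
#' @param scenario a [scenario()].
#' @param seed integer; defaults to `scenario$seed`.
#' @return object of class `GroundTruth`: data.frame with per-gene control and
#'   mutant linear RNA / TE / TO levels and `log2fc_rna`, `log2fc_to`,
#'   `log2fc_te` (the TE column is computed as TO - RNA so the identity holds
#'   exactly).
#' @export
simulate_truth <- function(annotation, scenario, seed = scenario$seed) {
  ids <- gene_ids(annotation)
  unknown <- setdiff(c(scenario$lesions$gene_id, scenario$feedback$gene_id), ids)
  if (length(unknown))
    stop("scenario references unknown gene(s): ", paste(unknown, collapse = ", "))

  n <- length(ids)
  truth <- withr::with_seed(seed, {
    rna_c <- stats::rlnorm(n, meanlog = log(1000), sdlog = 1)
    data.frame(gene_id = ids, rna_control = rna_c, te_control = 1,
               stringsAsFactors = FALSE)
  })
  rna_f <- stats::setNames(rep(1, n), ids)
  te_f <- stats::setNames(rep(1, n), ids)

  les <- scenario$lesions
  for (i in seq_len(nrow(les))) {
    gid <- les$gene_id[i]
    rna_f[gid] <- rna_f[gid] * les$rna_factor[i]
    te_f[gid] <- te_f[gid] * les$te_factor[i]
    if (les$kind[i] == "readthrough_overexpression") {
      for (ds in downstream_tu_genes(annotation, gid))
        rna_f[ds] <- rna_f[ds] * les$rna_factor[i]
    }
  }
  fb <- scenario$feedback
  for (i in seq_len(nrow(fb))) {
    gid <- fb$gene_id[i]
    if (fb$level[i] == "transcript") rna_f[gid] <- rna_f[gid] * fb$factor[i]
    else te_f[gid] <- te_f[gid] * fb$factor[i]
  }

  truth$rna_mutant <- truth$rna_control * rna_f
  truth$te_mutant <- truth$te_control * te_f
  truth$to_control <- truth$rna_control * truth$te_control
  truth$to_mutant <- truth$rna_mutant * truth$te_mutant
  truth$log2fc_rna <- log2(truth$rna_mutant) - log2(truth$rna_control)
  truth$log2fc_to <- log2(truth$to_mutant) - log2(truth$to_control)
  truth$log2fc_te <- truth$log2fc_to - truth$log2fc_rna
  attr(truth, "scenario") <- scenario$name
  class(truth) <- c("GroundTruth", class(truth))
  truth
}

# genes after `gid` in transcription order within the same transcription unit
downstream_tu_genes <- function(annotation, gid) {
  g0 <- annotation$genes[[gid]]
  tu <- g0$transcription_unit_id
  mates <- Filter(function(g) g$transcription_unit_id == tu &&
                    g$gene_id != gid, annotation$genes)
  if (!length(mates)) return(character(0))
  pos <- function(g) {
    s <- min(g$exons[, 1])
    if (g$strand == "+") s else -max(g$exons[, 2])
  }
  p0 <- pos(g0)
  ds <- Filter(function(g) pos(g) > p0, mates)
  vapply(ds, `[[`, "", "gene_id")
}
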