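#' Summarize the technical replicate spots of one probe
#'
#' Spot QC and probe summary: flagged spots (`flag < 0`) are discarded; a
#' probe needs at least `min_good` good spots to survive. The probe value is
#' the median over good spots of foreground minus local background (negatives
#' allowed at this point); a median at or below `floor` counts as below
#' background and is set to zero.
#'
#' @param foreground,background,flag numeric vectors over one probe's spots
#'   in one channel.
#' @param min_good minimum good spots (default 2 of the 4 technical spots).
#' @param floor below-background threshold (default 100).
#' @return list with `value` and `n_good_spots`, or `NULL` when the probe is
#'   dropped.
#' @export
summarize_probe <- function(foreground, background, flag,
                            min_good = 2L, floor = 100) {
  if (length(foreground) == 0L) stop("no spots supplied")
  stopifnot(length(background) == length(foreground),
            length(flag) == length(foreground))
  good <- flag >= 0
  if (sum(good) < min_good) return(NULL)
  v <- stats::median(foreground[good] - background[good])
  if (v <= floor) v <- 0
  list(value = v, n_good_spots = sum(good))
}

# vectorized probe summary over a whole table; one row per surviving probe
# and channel, same rules as summarize_probe()
summarize_probes <- function(tbl, min_good = 2L, floor = 100) {
  dt <- data.table::as.data.table(tbl)
  good <- dt[Flags >= 0]
  per <- good[, .(v635 = stats::median(F635 - B635),
                  v532 = stats::median(F532 - B532),
                  n_good = .N), by = Probe_ID]
  per <- per[n_good >= min_good]
  per[, `:=`(v635 = data.table::fifelse(v635 <= floor, 0, v635),
             v532 = data.table::fifelse(v532 <= floor, 0, v532))]
  out <- data.frame(probe_id = per$Probe_ID,
                    value_635 = per$v635, value_532 = per$v532,
                    n_good_spots = per$n_good, stringsAsFactors = FALSE)
  n_drop <- length(unique(dt$Probe_ID)) - nrow(out)
  attr(out, "n_dropped") <- n_drop
  out
}

#' Normalize one channel of one array
#'
#' Scales all probe values by a single positive factor so that the mean value
#' of probes covering protein-coding regions equals the normalization anchor
#' (4,000). The anchor is arbitrary — all downstream quantities are ratios or
#' self-normalized relative abundances, so results are provably invariant to
#' it (asserted by the test suite).
#'
#' @param values numeric probe values of one channel.
#' @param is_cds logical; which probes cover protein-coding regions.
#' @param anchor target mean of CDS-probe values (default 4000).
#' @return list with `values` (rescaled, all probes) and `factor`.
#' @export
normalize_array <- function(values, is_cds, anchor = 4000) {
  m <- mean(values[is_cds])
  if (!is.finite(m) || m <= 0)
    stop("array failed: no positive CDS probe signal")
  f <- anchor / m
  list(values = values * f, factor = f)
}

#' Per-gene relative abundance on one channel
#'
#' Averages a gene's surviving probe values (floored zeros are averaged in as
#' zeros: excluding them would bias knockouts upward) and expresses each gene
#' relative to the array on a log2 scale: `log2(orf_mean)` minus the mean of
#' `log2(orf_mean)` over genes with positive signal. Genes with zero mean are
#' below the measurement floor: they are censored at the smallest positive
#' ORF mean of the array and flagged, so downstream fold changes become
#' bounds rather than point estimates.
#'
#' @param values normalized probe values of one channel.
#' @param probe_gene gene id per probe (`NA` = intergenic).
#' @param drop_zero_probes if `TRUE`, zero-valued probes are excluded from
#'   the ORF mean instead (default `FALSE`).
#' @return data.frame `gene_id`, `orf_mean`, `rel_abundance`, `censored`.
#' @export
orf_relative_abundance <- function(values, probe_gene,
                                   drop_zero_probes = FALSE) {
  keep <- !is.na(probe_gene)
  v <- values[keep]; g <- probe_gene[keep]
  if (drop_zero_probes) {
    pos <- v > 0
    means_pos <- tapply(v[pos], g[pos], mean)
    all_genes <- unique(g)
    orf_mean <- stats::setNames(rep(0, length(all_genes)), all_genes)
    orf_mean[names(means_pos)] <- means_pos
  } else {
    orf_mean <- tapply(v, g, mean)
  }
  gene <- names(orf_mean)
  orf_mean <- as.numeric(orf_mean)
  pos <- orf_mean > 0
  if (!any(pos)) stop("array failed: all ORF means are zero")
  ref <- mean(log2(orf_mean[pos]))
  floorv <- min(orf_mean[pos])
  eff <- ifelse(pos, orf_mean, floorv)
  data.frame(gene_id = gene,
             orf_mean = orf_mean,
             rel_abundance = log2(eff) - ref,
             censored = !pos,
             stringsAsFactors = FALSE)
}

#' Per-replicate mutant-vs-control log2 fold change
#'
#' Subtracts the control channel's relative abundance from the mutant
#' channel's, gene by gene, within one array (the two channels are paired by
#' co-hybridization). Censoring propagates to a bound: a mutant below floor
#' gives an upper bound (`<=`, the ">n-fold reduced" reporting style), a
#' censored control a lower bound (`>=`); both censored gives an
#' uninformative value.
#'
#' @param mutant,control data.frames from [orf_relative_abundance()] for the
#'   635 (mutant) and 532 (control) channels.
#' @return data.frame `gene_id`, `log2fc`, `censored`, `bound` (`""`, `"<="`,
#'   `">="`, `"both"`). Genes present on only one side are dropped with a
#'   warning.
#' @export
replicate_log2fc <- function(mutant, control) {
  common <- intersect(mutant$gene_id, control$gene_id)
  lost <- setdiff(union(mutant$gene_id, control$gene_id), common)
  if (length(lost))
    warning("unpaired gene(s) excluded: ", paste(lost, collapse = ", "))
  m <- mutant[match(common, mutant$gene_id), ]
  c_ <- control[match(common, control$gene_id), ]
  bound <- ifelse(m$censored & c_$censored, "both",
                  ifelse(m$censored, "<=", ifelse(c_$censored, ">=", "")))
  data.frame(gene_id = common,
             log2fc = m$rel_abundance - c_$rel_abundance,
             censored = m$censored | c_$censored,
             bound = bound, stringsAsFactors = FALSE)
}

#' Microarray branch: probe tables to per-replicate fold changes
#'
#' Runs the probe-level pipeline for every assay and biological replicate:
#' spot QC and probe medians, below-background flooring, per-channel
#' normalization to the 4,000 anchor, per-gene relative abundances, and the
#' paired mutant-minus-control log2 fold change.
#'
#' @param tables nested list as produced by [emit_probe_tables()]
#'   (`tables$RF[[rep]]`, `tables$RNA[[rep]]`), or data.frames read with
#'   [read_probe_table()] arranged the same way.
#' @param design an [array_design()] (supplies the probe-to-gene map).
#' @param min_good,floor,anchor see the stage functions.
#' @return data.frame `gene_id`, `assay` (`RF`/`RNA`), `replicate`, `log2fc`,
#'   `censored`, `bound`, `rel_mutant`, `rel_control`.
#' @export
quantify_array <- function(tables, design, min_good = 2L, floor = 100,
                           anchor = 4000) {
  gene_of <- stats::setNames(design$gene_id, design$probe_id)
  out <- list()
  for (assay in names(tables)) {
    for (r in seq_along(tables[[assay]])) {
      tbl <- tables[[assay]][[r]]
      pv <- summarize_probes(tbl, min_good = min_good, floor = floor)
      pg <- unname(gene_of[pv$probe_id])
      is_cds <- !is.na(pg)
      n635 <- normalize_array(pv$value_635, is_cds, anchor = anchor)
      n532 <- normalize_array(pv$value_532, is_cds, anchor = anchor)
      rel_m <- orf_relative_abundance(n635$values, pg)
      rel_c <- orf_relative_abundance(n532$values, pg)
      fc <- replicate_log2fc(rel_m, rel_c)
      fc$rel_mutant <- rel_m$rel_abundance[match(fc$gene_id, rel_m$gene_id)]
      fc$rel_control <- rel_c$rel_abundance[match(fc$gene_id, rel_c$gene_id)]
      fc$assay <- assay
      fc$replicate <- r
      out[[length(out) + 1L]] <- fc
    }
  }
  res <- do.call(rbind, out)
  res[, c("gene_id", "assay", "replicate", "log2fc", "censored", "bound",
          "rel_mutant", "rel_control")]
}
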