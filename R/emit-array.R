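#' Emit two-channel probe tables for a scenario
#'
#' Simulates the co-hybridization measurement: mutant RNA/footprint material
#' is labelled in channel 635, the control in channel 532, on the same array
#' (one array per assay per biological replicate). Spot foreground equals a
#' local background plus `gain` times the gene's expression with
#' multiplicative lognormal spot noise (unit mean, CV `noise$spot_cv`);
#' intergenic probes carry background only. A fraction `noise$bad_spot_rate`
#' of spots is flagged bad (negative flag) and its foreground corrupted, so
#' downstream QC must discard them.
#'
#' @param truth a [simulate_truth()] result.
#' @param design an [array_design()].
#' @param scenario the [scenario()] (supplies replicate count and noise).
#' @param dir if non-`NULL`, tables are also written there as tab-delimited
#'   GenePix-like files (`<assay>_rep<i>.txt`).
#' @param gain linear scale from expression to fluorescence (default 1).
#' @param bg_mean,bg_sd local background distribution, Normal truncated at 0
#'   (defaults 200 / 20; sd is forced to 0 when `spot_cv = 0` so that the
#'   noiseless mode is exactly invertible).
#' @param seed RNG seed (default `scenario$seed + 1`).
#' @return list with `tables` (per assay, a list of per-replicate
#'   data.frames with columns `Probe_ID`, `Spot`, `F635`, `B635`, `F532`,
#'   `B532`, `Flags`), `files` (paths or `NULL`) and `design`.
#' @export
emit_probe_tables <- function(truth, design, scenario, dir = NULL,
                              gain = 1, bg_mean = 200, bg_sd = 20,
                              seed = scenario$seed + 1L) {
  spots <- attr(design, "spots_per_probe")
  cv <- scenario$noise$spot_cv
  bad_rate <- scenario$noise$bad_spot_rate
  sig <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  if (cv == 0) bg_sd <- 0

  expr_of <- function(assay, genotype) {
    col <- paste0(if (assay == "RF") "to" else "rna", "_", genotype)
    v <- stats::setNames(truth[[col]], truth$gene_id)
    e <- ifelse(is.na(design$gene_id), 0, v[design$gene_id])
    unname(e)
  }

  n_probe <- nrow(design)
  n_spot <- n_probe * spots
  probe_idx <- rep(seq_len(n_probe), each = spots)

  make_table <- function(assay) {
    em <- expr_of(assay, "mutant")[probe_idx]
    ec <- expr_of(assay, "control")[probe_idx]
    bg6 <- pmax(0, stats::rnorm(n_spot, bg_mean, bg_sd))
    bg5 <- pmax(0, stats::rnorm(n_spot, bg_mean, bg_sd))
    noise6 <- if (sig > 0) exp(stats::rnorm(n_spot, -sig^2 / 2, sig)) else 1
    noise5 <- if (sig > 0) exp(stats::rnorm(n_spot, -sig^2 / 2, sig)) else 1
    f6 <- bg6 + gain * em * noise6
    f5 <- bg5 + gain * ec * noise5
    flags <- integer(n_spot)
    bad <- stats::runif(n_spot) < bad_rate
    if (any(bad)) {
      flags[bad] <- -100L
      corrupt <- stats::runif(sum(bad), 0.01, 20)
      f6[bad] <- f6[bad] * corrupt
      f5[bad] <- f5[bad] * corrupt
    }
    data.frame(Probe_ID = design$probe_id[probe_idx],
               Spot = rep(seq_len(spots), times = n_probe),
               F635 = f6, B635 = bg6, F532 = f5, B532 = bg5,
               Flags = flags, stringsAsFactors = FALSE)
  }

  tables <- withr::with_seed(seed, {
    lapply(stats::setNames(c("RF", "RNA"), c("RF", "RNA")), function(assay)
      lapply(seq_len(scenario$n_replicates), function(r) make_table(assay)))
  })

  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list()
    for (assay in names(tables)) {
      for (r in seq_along(tables[[assay]])) {
        f <- file.path(dir, sprintf("%s_rep%d.txt", assay, r))
        write_probe_table(tables[[assay]][[r]], f,
                          title = sprintf("%s %s replicate %d",
                                          scenario$name, assay, r))
        files[[sprintf("%s_rep%d", assay, r)]] <- f
      }
    }
  }
  list(tables = tables, files = files, design = design)
}

#' Write a probe table in the GenePix-like dialect
#'
#' A short free-text preamble precedes the column header row, as in real GPR
#' exports; [read_probe_table()] skips to the header.
#'
#' @param tbl probe-table data.frame.
#' @param path output file.
#' @param title preamble line.
#' @export
write_probe_table <- function(tbl, path, title = "probe table") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# ", title),
               "# dialect: Probe_ID/Spot/F635/B635/F532/B532/Flags"), con)
  utils::write.table(tbl, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GenePix-like probe table
#'
#' Skips any header/preamble lines before the row whose first field is
#' `Probe_ID` (so real GPR exports with metadata blocks load too).
#'
#' @param path tab-delimited file.
#' @return data.frame with the probe-table columns.
#' @export
read_probe_table <- function(path) {
  lines <- readLines(path, n = 200L)
  hdr <- grep("^\"?Probe_ID\\b", lines)
  if (!length(hdr)) stop("no Probe_ID header row found in ", path)
  utils::read.delim(path, skip = hdr[1] - 1L, stringsAsFactors = FALSE)
}
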