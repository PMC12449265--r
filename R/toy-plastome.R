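#' Miniature circular plastome for desk-scale simulation
#'
#' Builds a small circular plastome annotation that reproduces the structural
#' features the pipeline has to cope with: polycistronic transcription units
#' (a psbD/C/Z-like and a psbB/T/H-petB/D-like operon, a minus-strand
#' psaA/B-rps14-like operon, a psaI-ycf4-cemA-petA-like tetracistron),
#' intron-containing genes (petB, petD, ndhB), a same-strand overlapping gene
#' pair (atpB/atpE), and a gene wrapping the circular origin (rpl2). Optional
#' filler ORFs (own transcription units, `Other` complex) pad the gene set for
#' calibration studies.
#'
#' @param n_extra number of 300-nt filler ORFs to append (default 0; 59 gives
#'   an 80-gene annotation).
#' @return a [plastome_annotation()] (parsed from GFF3 via [load_annotation()],
#'   so the writer/loader round trip is exercised on every construction).
#' @export
toy_plastome <- function(n_extra = 0L) {
  path <- tempfile(fileext = ".gff3")
  on.exit(unlink(path), add = TRUE)
  toy_plastome_gff(path, n_extra = n_extra)
  load_annotation(path)
}

#' Write the miniature plastome as GFF3
#'
#' @param path output file.
#' @param n_extra filler ORFs, see [toy_plastome()].
#' @return `path`, invisibly. Origin-wrapping genes are written in the
#'   circular dialect (`end < start`, 1-based closed), which
#'   [load_annotation()] unwraps.
#' @export
toy_plastome_gff <- function(path, n_extra = 0L) {
  n_extra <- as.integer(n_extra)
  L <- max(30000L, 24100L + 400L * n_extra + 200L)

  g <- function(id, strand, exons, tu, cx)
    list(id = id, strand = strand, exons = exons, tu = tu, cx = cx)

  base <- list(
    g("psbD", "+", iv(1000, 2062), "psbD_op", "PSII"),
    g("psbC", "+", iv(2100, 3522), "psbD_op", "PSII"),
    g("psbZ", "+", iv(3600, 3900), "psbD_op", "PSII"),
    g("psbA", "+", iv(3950, 5012), "psbA_op", "PSII"),
    g("psbB", "+", iv(5100, 6624), "psbB_op", "PSII"),
    g("psbT", "+", iv(6650, 6752), "psbB_op", "PSII"),
    g("psbH", "+", iv(6800, 7022), "psbB_op", "PSII"),
    g("petB", "+", iv(c(7100, 7861), c(7106, 8500)), "psbB_op", "CytB6F"),
    g("petD", "+", iv(c(8600, 9200), c(8608, 9672)), "psbB_op", "CytB6F"),
    g("rps14", "-", iv(9300, 9600), "psaA_op", "ExpressionMachinery"),
    g("psaB", "-", iv(9750, 11952), "psaA_op", "PSI"),
    g("psaA", "-", iv(12000, 14250), "psaA_op", "PSI"),
    g("psaI", "+", iv(15000, 15300), "petA_op", "PSI"),
    g("ycf4", "+", iv(15400, 15955), "petA_op", "Other"),
    g("cemA", "+", iv(16050, 16740), "petA_op", "Other"),
    g("petA", "+", iv(16800, 17763), "petA_op", "CytB6F"),
    g("rbcL", "+", iv(18000, 19434), "rbcL_op", "Rubisco"),
    g("atpE", "-", iv(20100, 20502), "atpB_op", "ATPase"),
    g("atpB", "-", iv(20500, 21994), "atpB_op", "ATPase"),
    g("ndhB", "+", iv(c(22000, 23450), c(22756, 23978)), "ndhB_op", "NDH"),
    # wraps the circular origin: written as end < start below
    g("rpl2", "+", iv(c(L - 15L, 0L), c(L, 801L)), "rpl2_op",
      "ExpressionMachinery")
  )
  extras <- lapply(seq_len(n_extra), function(i) {
    s <- 24200L + 400L * (i - 1L)
    g(sprintf("orf%03d", i), if (i %% 2L) "+" else "-", iv(s, s + 300L),
      sprintf("orf%03d_op", i), "Other")
  })
  genes <- c(base, extras)

  lines <- c("##gff-version 3",
             sprintf("##sequence-region plastome 1 %d", L))
  for (gn in genes) {
    ex <- gn$exons
    wrap <- gn$id == "rpl2"
    attrs <- sprintf("ID=%s;transcription_unit=%s;complex=%s",
                     gn$id, gn$tu, gn$cx)
    if (wrap) {
      # circular dialect: one feature with end < start (1-based closed)
      s1 <- L - 15L + 1L; e1 <- 801L
      lines <- c(lines,
                 sprintf("plastome\ttoy\tgene\t%d\t%d\t.\t%s\t.\t%s",
                         s1, e1, gn$strand, attrs),
                 sprintf("plastome\ttoy\tCDS\t%d\t%d\t.\t%s\t0\tID=cds_%s;Parent=%s",
                         s1, e1, gn$strand, gn$id, gn$id))
    } else {
      lines <- c(lines,
                 sprintf("plastome\ttoy\tgene\t%d\t%d\t.\t%s\t.\t%s",
                         min(ex[, 1]) + 1L, max(ex[, 2]), gn$strand, attrs))
      for (j in seq_len(nrow(ex))) {
        lines <- c(lines,
                   sprintf("plastome\ttoy\tCDS\t%d\t%d\t.\t%s\t0\tID=cds_%s_%d;Parent=%s",
                           ex[j, 1] + 1L, ex[j, 2], gn$strand, gn$id, j, gn$id))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Tiling-array probe design over a plastome
#'
#' Tiles each gene's exons with fixed-length probes lying fully within a
#' single exon (probes straddling gene boundaries would double-count on
#' operons, so assignment requires full containment), plus a handful of
#' intergenic control probes carrying background only.
#'
#' @param annotation a [plastome_annotation()].
#' @param probe_length probe length in nt (default 50).
#' @param step tiling step in nt (default 120).
#' @param n_intergenic number of intergenic control probes.
#' @param spots_per_probe technical replicate spots per probe (default 4).
#' @return object of class `ArrayDesign`: a data.frame with columns
#'   `probe_id`, `start`, `end` (0-based half-open), `gene_id` (`NA` for
#'   intergenic), and attribute `spots_per_probe`.
#' @export
array_design <- function(annotation, probe_length = 50L, step = 120L,
                         n_intergenic = 6L, spots_per_probe = 4L) {
  stopifnot(spots_per_probe >= 2L)
  rows <- list()
  for (g in annotation$genes) {
    k <- 0L
    for (j in seq_len(nrow(g$exons))) {
      s <- g$exons[j, 1]; e <- g$exons[j, 2]
      if (e - s < probe_length) next
      starts <- seq.int(s, e - probe_length, by = step)
      for (ps in starts) {
        k <- k + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          probe_id = sprintf("p_%s_%02d", g$gene_id, k),
          start = ps, end = ps + probe_length, gene_id = g$gene_id,
          stringsAsFactors = FALSE)
      }
    }
    if (k == 0L)
      warning("gene ", g$gene_id, " received no probes (exons shorter than ",
              probe_length, " nt)")
  }
  # intergenic controls in gaps between gene spans
  spans <- do.call(rbind, lapply(annotation$genes, function(g)
    iv(min(g$exons[, 1]), max(g$exons[, 2]))))
  gaps <- iv_setdiff(iv(0L, annotation$genome_length), spans)
  gaps <- gaps[gaps[, 2] - gaps[, 1] >= probe_length + 20L, , drop = FALSE]
  n_ig <- min(n_intergenic, nrow(gaps))
  for (i in seq_len(n_ig)) {
    mid <- (gaps[i, 1] + gaps[i, 2]) %/% 2L
    rows[[length(rows) + 1L]] <- data.frame(
      probe_id = sprintf("ig_%02d", i),
      start = mid, end = mid + probe_length, gene_id = NA_character_,
      stringsAsFactors = FALSE)
  }
  design <- do.call(rbind, rows)
  rownames(design) <- NULL
  attr(design, "spots_per_probe") <- as.integer(spots_per_probe)
  class(design) <- c("ArrayDesign", class(design))
  design
}
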