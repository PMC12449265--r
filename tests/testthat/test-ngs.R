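mini_ann <- function() {
  L <- 3000L
  plastome_annotation(L, list(
    gene_model("plain", "+", iv(0, 300), genome_length = L),
    gene_model("ig", "+", iv(c(500, 1000), c(620, 1400)), genome_length = L),
    gene_model("minus", "-", iv(1600, 2100), genome_length = L)
  ))
}

aln_df <- function(ids, strands, blocks, ref = "plastome") {
  data.frame(read_id = ids, ref = ref, strand = strands,
             blocks = I(blocks), stringsAsFactors = FALSE)
}

test_that("sequential tier assignment keeps the first tier only", {
  t1 <- aln_df("dual", "+", list(iv(10, 40)), ref = "rRNA_contam")
  t2 <- aln_df(c("dual", "chl_only"), "+",
               list(iv(100, 130), iv(150, 180)))
  t3 <- plastidCES:::empty_alignments()
  t4 <- aln_df("nuc_only", "+", list(iv(5, 105)), ref = "nuclear1")
  res <- enforce_sequential(list(rRNA_tRNA = t1, chloroplast = t2,
                                 mitochondrial = t3, nuclear = t4))
  a <- stats::setNames(res$assignment$tier, res$assignment$read_id)
  expect_equal(a[["dual"]], "rRNA_tRNA")
  expect_equal(a[["chl_only"]], "chloroplast")
  expect_equal(a[["nuc_only"]], "nuclear")
  expect_equal(res$chloroplast$read_id, "chl_only")
  expect_equal(unname(res$summary),
               c(1L, 1L, 0L, 1L))
  expect_error(enforce_sequential(list(a = t1)), "tiers")
})

test_that("counting applies strand, masks, the junction rule and ambiguity", {
  ann <- mini_ann()
  reads <- aln_df(
    c("in_mask", "interior", "wrong_strand", "minus_ok",
      "unspliced_60", "unspliced_40", "spliced", "outside"),
    c("+", "+", "-", "-", "+", "+", "+", "+"),
    list(iv(5, 35),                     # overlaps the 5' mask window
         iv(100, 130),                  # interior of 'plain'
         iv(100, 130),                  # same span, wrong strand
         iv(1700, 1800),                # interior of the minus gene
         iv(560, 680),                  # 60 nt into the intron of 'ig'
         iv(580, 660),                  # 40 nt overhang: tolerated
         rbind(iv(570, 620), iv(1000, 1050)),  # mature spliced junction read
         iv(2600, 2700)))               # intergenic
  ct <- count_genes(reads, ann, assay = "RNA")
  counts <- stats::setNames(ct$count, ct$gene_id)
  expect_equal(counts[["plain"]], 1L)   # interior only
  expect_equal(counts[["ig"]], 2L)      # 40-nt overhang + spliced read
  expect_equal(counts[["minus"]], 1L)

  # for footprints on the intron gene only the last exon counts
  rf <- aln_df(c("exon1", "exon2"), c("+", "+"),
               list(iv(520, 550), iv(1100, 1130)))
  ct_rf <- count_genes(rf, ann, assay = "RF")
  expect_equal(ct_rf$count[ct_rf$gene_id == "ig"], 1L)

  # a read overlapping two same-strand counting regions is ambiguous
  L <- 2000L
  ann2 <- plastome_annotation(L, list(
    gene_model("gA", "+", iv(0, 300), genome_length = L),
    gene_model("gB", "+", iv(250, 550), genome_length = L)))
  amb <- aln_df("straddle", "+", list(iv(262, 292)))
  ct2 <- count_genes(amb, ann2, assay = "RF")
  expect_true(all(ct2$count == 0L))

  expect_error(count_genes(aln_df("x", "+", list(iv(0, 30)), ref = "mars"),
                           ann, "RF"), "unknown reference")
})

test_that("RPKM uses counted length, counted total and the pseudocount", {
  ct <- data.frame(gene_id = c("a", "b"), assay = "RF",
                   count = c(50L, 99950L), counted_length = c(500, 2000),
                   flagged = FALSE)
  r <- rpkm_table(ct)
  expect_equal(r$rpkm[1], (50 + 1) / (0.5 * 0.1))  # = 1020
  # zero count stays log-safe
  ct0 <- data.frame(gene_id = c("a", "b"), assay = "RF",
                    count = c(0L, 1000L), counted_length = c(500, 2000),
                    flagged = FALSE)
  expect_gt(rpkm_table(ct0)$rpkm[1], 0)
  # depth invariance up to the vanishing pseudocount
  for (k in c(2, 5, 10)) {
    rk <- rpkm_table(transform(ct, count = count * k))
    expect_equal(rk$rpkm / r$rpkm, rep(1, 2), tolerance = 2 / 50)
  }
  expect_error(rpkm_table(transform(ct, count = 0L)), "no counted reads")
})

test_that("counting agrees with the literal per-(read,gene) oracle", {
  withr::with_seed(2024, {
    for (i in 1:60) {
      set <- random_alignment_set(n_reads = 12L)
      for (assay in c("RF", "RNA")) {
        got <- count_genes(set$alignments, set$annotation, assay)
        want <- bf_count_genes(set$alignments, set$annotation, assay)
        expect_equal(stats::setNames(got$count, got$gene_id), want)
      }
    }
  })
})

test_that("counts are invariant under genome mirroring", {
  set <- withr::with_seed(5150, random_alignment_set(n_reads = 30L))
  L <- set$annotation$genome_length
  m_genes <- lapply(set$annotation$genes, mirror_gene, L = L)
  m_ann <- plastome_annotation(L, m_genes)
  m_alns <- set$alignments
  m_alns$strand <- ifelse(m_alns$strand == "+", "-", "+")
  m_alns$blocks <- I(lapply(m_alns$blocks, mirror_blocks, L = L))
  for (assay in c("RF", "RNA")) {
    a <- count_genes(set$alignments, set$annotation, assay)
    b <- count_genes(m_alns, m_ann, assay)
    expect_equal(stats::setNames(b$count, b$gene_id),
                 stats::setNames(a$count, a$gene_id))
  }
})

test_that("SAM files round-trip through Rsamtools identically", {
  ann <- toy_plastome()
  sc <- scenario_presets(seed = 17)$null
  sc$n_replicates <- 1L
  truth <- simulate_truth(ann, sc)
  d <- tempfile()
  aln <- emit_alignment_sets(truth, ann, sc,
                             read_params = list(depth = 0.03,
                                                leak_contaminants = TRUE),
                             dir = d)
  expect_length(list.files(d, pattern = "\\.sam$"), 16L)
  q_mem <- quantify_ngs(aln, ann)
  q_file <- quantify_ngs(aln, ann, from_files = TRUE)
  expect_identical(q_mem, q_file)
})
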