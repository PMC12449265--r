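write_gff <- function(lines) {
  path <- tempfile(fileext = ".gff3")
  writeLines(lines, path)
  path
}

test_that("GFF3 parsing preserves strands and reorders minus-strand exons", {
  path <- write_gff(c(
    "##gff-version 3",
    "##sequence-region plastome 1 5000",
    "plastome\ttoy\tgene\t101\t400\t.\t+\t.\tID=gPlus",
    "plastome\ttoy\tCDS\t101\t400\t.\t+\t0\tID=c1;Parent=gPlus",
    "plastome\ttoy\tgene\t1001\t2000\t.\t-\t.\tID=gMinus",
    "plastome\ttoy\tCDS\t1001\t1300\t.\t-\t0\tID=c2a;Parent=gMinus",
    "plastome\ttoy\tCDS\t1701\t2000\t.\t-\t0\tID=c2b;Parent=gMinus"))
  ann <- load_annotation(path)
  expect_length(ann$genes, 2L)
  expect_equal(ann$genes[["gPlus"]]$strand, "+")
  expect_equal(ann$genes[["gPlus"]]$exons, iv(100, 400),
               ignore_attr = TRUE)
  # minus strand: downstream-genomic exon comes first in transcription order
  expect_equal(ann$genes[["gMinus"]]$exons,
               iv(c(1700, 1000), c(2000, 1300)), ignore_attr = TRUE)
  expect_equal(ann$genes[["gMinus"]]$introns, iv(1300, 1700),
               ignore_attr = TRUE)
})

test_that("origin-wrapping CDS is unwrapped into two intervals, length kept", {
  path <- write_gff(c(
    "##gff-version 3",
    "##sequence-region plastome 1 5000",
    "plastome\ttoy\tgene\t4901\t200\t.\t+\t.\tID=gWrap",
    "plastome\ttoy\tCDS\t4901\t200\t.\t+\t0\tID=cw;Parent=gWrap"))
  ann <- load_annotation(path)
  g <- ann$genes[["gWrap"]]
  expect_equal(nrow(g$exons), 2L)
  expect_true(g$wrap_join)
  # brute-force base enumeration across the origin: 4900..4999 plus 0..199
  expect_equal(g$cds_length, length(c(4900:4999, 0:199)))
  expect_equal(nrow(g$introns), 0L)  # origin junction is not an intron
  # transcription order: the piece touching the end comes first on +
  expect_equal(g$exons[1, ], c(start = 4900L, end = 5000L))
})

test_that("malformed annotations are rejected with context", {
  bad_overlap <- write_gff(c(
    "##gff-version 3",
    "##sequence-region plastome 1 5000",
    "plastome\ttoy\tgene\t101\t600\t.\t+\t.\tID=gBad",
    "plastome\ttoy\tCDS\t101\t400\t.\t+\t0\tID=b1;Parent=gBad",
    "plastome\ttoy\tCDS\t301\t600\t.\t+\t0\tID=b2;Parent=gBad"))
  expect_error(load_annotation(bad_overlap), "gBad")

  orphan <- write_gff(c(
    "##gff-version 3",
    "##sequence-region plastome 1 5000",
    "plastome\ttoy\tgene\t101\t400\t.\t+\t.\tID=gOK",
    "plastome\ttoy\tCDS\t101\t400\t.\t+\t0\tID=o1;Parent=gGhost"))
  expect_error(load_annotation(orphan), "parent")

  not_gff <- tempfile()
  writeLines("plastome\ttoy\tgene\t1\t10\t.\t+\t.\tID=x", not_gff)
  expect_error(load_annotation(not_gff), "gff-version")
})

test_that("counting regions follow the 10/30-nt end masks", {
  L <- 2000L
  g <- gene_model("g1", "+", iv(0, 300), genome_length = L)
  r <- counting_region(g, "RF")
  expect_equal(r$intervals, iv(10, 270), ignore_attr = TRUE)
  expect_equal(r$total_length, 260L)
  expect_equal(attr(r, "masks")$intervals, iv(c(0, 270), c(10, 300)),
               ignore_attr = TRUE)

  short <- gene_model("tiny", "+", iv(0, 35), genome_length = L)
  rs <- counting_region(short, "RF")
  expect_true(rs$flagged)
  expect_equal(rs$total_length, 0L)

  two_ex <- gene_model("g2", "+", iv(c(0, 500), c(120, 800)),
                       genome_length = L)
  r2 <- counting_region(two_ex, "RF")
  # intron gene, RF: last exon only, 3' mask applied, no 5' mask
  expect_equal(r2$intervals, iv(500, 770), ignore_attr = TRUE)
  expect_equal(r2$total_length, 270L)
  # RNA assay still uses the whole spliced CDS
  r2rna <- counting_region(two_ex, "RNA")
  expect_equal(r2rna$intervals, iv(c(10, 500), c(120, 770)),
               ignore_attr = TRUE)
  expect_equal(r2rna$total_length, 380L)
})

test_that("counting regions match base-by-base enumeration on random geometries", {
  withr::with_seed(421, {
    for (i in 1:250) {
      g <- random_gene()
      assay <- sample(c("RF", "RNA"), 1L)
      pos <- bf_region_positions(g, assay)
      r <- counting_region(g, assay)
      expect_equal(r$total_length, length(pos))
      if (length(pos)) {
        ir <- sort(unique(pos))
        expect_setequal(bf_block_positions(r$intervals), ir)
      } else {
        expect_true(r$flagged)
      }
      # masks + region partition the (possibly last-exon-restricted) CDS
      m <- attr(r, "masks")
      expect_equal(iv_length(iv_intersect(r$intervals, m$intervals)), 0L)
    }
  })
})

test_that("counting regions are strand-symmetric under genome mirroring", {
  L <- 5000L
  withr::with_seed(77, {
    for (i in 1:60) {
      g <- random_gene(L)
      if (g$wrap_join) next
      gm <- mirror_gene(g, L)
      for (assay in c("RF", "RNA")) {
        r <- counting_region(g, assay)
        rm <- counting_region(gm, assay)
        expect_equal(rm$total_length, r$total_length)
        if (nrow(r$intervals))
          expect_equal(rm$intervals,
                       iv_reduce(iv(L - r$intervals[, 2],
                                    L - r$intervals[, 1])))
      }
    }
  })
})

test_that("intron overhang counts intronic nt of exon-touching blocks only", {
  g <- gene_model("ig", "+", iv(c(0, 500), c(120, 800)),
                  genome_length = 2000L)
  expect_equal(intron_overhang(iv(10, 50), g), 0L)          # fully exonic
  expect_equal(intron_overhang(iv(80, 180), g), 60L)        # 40 exon + 60 intron
  expect_equal(intron_overhang(rbind(iv(80, 120), iv(500, 540)), g), 0L)
  expect_equal(intron_overhang(iv(900, 950), g), 0L)        # beyond the gene

  # accounting identity on random contiguous alignments
  withr::with_seed(99, {
    for (i in 1:100) {
      s <- sample(0:900, 1L); w <- sample(10:300, 1L)
      b <- iv(s, s + w)
      p <- bf_block_positions(b)
      in_ex <- sum(p %in% bf_cds_positions(g))
      in_intron <- sum(p %in% 120:499)
      expected <- if (in_ex > 0L) in_intron else 0L
      expect_equal(intron_overhang(b, g), expected)
      expect_equal(in_ex + in_intron + sum(!(p %in% 0:799)), w)
    }
  })
})
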