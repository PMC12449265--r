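test_that("probe summary applies QC, median and the below-background floor", {
  # four spots, one flagged bad; surviving F-B = 200/300/400 -> median 300
  r <- summarize_probe(foreground = c(400, 500, 600, 9000),
                       background = c(200, 200, 200, 100),
                       flag = c(0, 0, 0, -100))
  expect_equal(r$value, 300)
  expect_equal(r$n_good_spots, 3L)

  # fewer than two good of four spots: probe dropped
  expect_null(summarize_probe(c(400, 1, 1, 1), c(200, 0, 0, 0),
                              flag = c(0, -50, -50, -50)))

  # median at the floor is below background and zeroed
  expect_equal(summarize_probe(rep(190, 4), rep(100, 4), rep(0, 4))$value, 0)
  # negative spot differences enter the median un-truncated
  expect_equal(summarize_probe(c(50, 60, 5000, 5010), rep(100, 4),
                               rep(0, 4))$value, 2430)
  expect_equal(summarize_probe(c(50, 60, 70, 80), rep(100, 4),
                               rep(0, 4))$value, 0)
  expect_error(summarize_probe(numeric(0), numeric(0), numeric(0)), "spots")
})

test_that("batch probe summary agrees with the single-probe rule and is
           invariant to spot order and flagged values", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      n_probe <- 8L
      tbl <- data.frame(
        Probe_ID = rep(sprintf("p%02d", 1:n_probe), each = 4),
        Spot = rep(1:4, n_probe),
        F635 = stats::runif(4 * n_probe, 0, 2000),
        B635 = stats::runif(4 * n_probe, 100, 300),
        F532 = stats::runif(4 * n_probe, 0, 2000),
        B532 = stats::runif(4 * n_probe, 100, 300),
        Flags = sample(c(0L, 0L, 0L, -100L), 4 * n_probe, replace = TRUE))
      got <- plastidCES:::summarize_probes(tbl)
      for (p in unique(tbl$Probe_ID)) {
        sub <- tbl[tbl$Probe_ID == p, ]
        ref <- summarize_probe(sub$F635, sub$B635, sub$Flags)
        if (is.null(ref)) {
          expect_false(p %in% got$probe_id)
        } else {
          expect_equal(got$value_635[got$probe_id == p], ref$value)
        }
      }
      # permute spots and corrupt flagged foregrounds: identical output
      perm <- sample(nrow(tbl))
      tbl2 <- tbl[perm, ]
      tbl2$F635[tbl2$Flags < 0] <- tbl2$F635[tbl2$Flags < 0] * 100 + 7
      got2 <- plastidCES:::summarize_probes(tbl2)
      expect_equal(got2[order(got2$probe_id), ],
                   got[order(got$probe_id), ], ignore_attr = TRUE)
    }
  })
})

test_that("array normalization anchors CDS probes at 4,000 and fails on dead arrays", {
  r <- normalize_array(c(1000, 2000, 5000), is_cds = rep(TRUE, 3))
  expect_equal(r$factor, 1.5)
  expect_equal(r$values, c(1500, 3000, 7500))
  expect_equal(mean(r$values), 4000)
  expect_error(normalize_array(c(0, 0, 0), rep(TRUE, 3)), "array failed")
  # rescaling the input leaves relative abundances unchanged
  v <- c(500, 1500, 4000, 250)
  pg <- c("a", "a", "b", "c")
  r1 <- orf_relative_abundance(normalize_array(v, rep(TRUE, 4))$values, pg)
  r2 <- orf_relative_abundance(normalize_array(v * 37, rep(TRUE, 4))$values, pg)
  expect_equal(r1$rel_abundance, r2$rel_abundance)
})

test_that("relative abundance is self-normalized, with floor censoring", {
  r <- orf_relative_abundance(c(8000, 2000), c("g1", "g2"))
  expect_equal(r$rel_abundance, c(1, -1))

  # zero gene censored at the smallest positive ORF mean
  r2 <- orf_relative_abundance(c(0, 50, 5000), c("gz", "ga", "gb"))
  expect_true(r2$censored[r2$gene_id == "gz"])
  expect_equal(r2$rel_abundance[r2$gene_id == "gz"],
               r2$rel_abundance[r2$gene_id == "ga"])

  expect_equal(orf_relative_abundance(c(777), "solo")$rel_abundance, 0)
  expect_error(orf_relative_abundance(c(0, 0), c("a", "b")), "array failed")
})

test_that("per-replicate fold change pairs channels and propagates censoring", {
  m <- data.frame(gene_id = c("a", "b"), orf_mean = c(10, 10),
                  rel_abundance = c(1.0, 0.2), censored = c(FALSE, TRUE))
  c_ <- data.frame(gene_id = c("a", "b"), orf_mean = c(10, 10),
                   rel_abundance = c(-0.5, 2.0), censored = FALSE)
  fc <- replicate_log2fc(m, c_)
  expect_equal(fc$log2fc[fc$gene_id == "a"], 1.5)
  expect_equal(fc$bound, c("", "<="))

  same <- replicate_log2fc(m, m)
  expect_true(all(same$log2fc == 0))

  m2 <- rbind(m, data.frame(gene_id = "only_m", orf_mean = 1,
                            rel_abundance = 0, censored = FALSE))
  expect_warning(replicate_log2fc(m2, c_), "unpaired")
})

test_that("noiseless generator round-trips exactly through the pipeline", {
  ann <- toy_plastome(n_extra = 10)
  sc <- scenario("kd_noiseless",
                 lesions = scenario_presets()$kd_psbD$lesions,
                 feedback = scenario_presets()$kd_psbD$feedback,
                 noise = list(spot_cv = 0, bad_spot_rate = 0), seed = 31)
  truth <- simulate_truth(ann, sc)
  design <- array_design(ann)
  em <- emit_probe_tables(truth, design, sc)
  q <- quantify_array(em$tables, design)
  for (assay in c("RF", "RNA")) {
    want <- expected_measured_lfc(truth, assay)
    for (r in 1:3) {
      sub <- q[q$assay == assay & q$replicate == r & !q$censored, ]
      expect_gt(nrow(sub), 20)
      expect_equal(sub$log2fc, unname(want[sub$gene_id]), tolerance = 1e-9)
    }
  }
})

test_that("null arrays have exactly zero mean fold change across genes", {
  ann <- toy_plastome()
  sc <- scenario_presets(seed = 12)$null
  sc$noise$bad_spot_rate <- 0
  truth <- simulate_truth(ann, sc)
  # keep all genes comfortably above the floor so no censoring interferes
  truth$rna_control <- truth$rna_control + 500
  truth$rna_mutant <- truth$rna_mutant + 500
  truth$to_control <- truth$to_control + 500
  truth$to_mutant <- truth$to_mutant + 500
  design <- array_design(ann)
  em <- emit_probe_tables(truth, design, sc)
  q <- quantify_array(em$tables, design)
  for (assay in c("RF", "RNA")) for (r in 1:3) {
    sub <- q[q$assay == assay & q$replicate == r, ]
    expect_false(any(sub$censored))
    expect_lt(abs(mean(sub$log2fc)), 1e-9)
  }
})

test_that("raising one gene's mutant signal never lowers its fold change", {
  ann <- toy_plastome()
  sc <- scenario_presets(seed = 3)$null
  truth <- simulate_truth(ann, sc)
  design <- array_design(ann)
  em <- emit_probe_tables(truth, design, sc)
  tbl <- em$tables$RF[[1]]
  base <- quantify_array(list(RF = list(tbl)), design)
  probes <- design$probe_id[!is.na(design$gene_id) & design$gene_id == "rbcL"]
  for (mult in c(1.5, 4, 20)) {
    tbl2 <- tbl
    sel <- tbl2$Probe_ID %in% probes
    tbl2$F635[sel] <- tbl2$B635[sel] +
      (tbl2$F635[sel] - tbl2$B635[sel]) * mult
    up <- quantify_array(list(RF = list(tbl2)), design)
    expect_gte(up$log2fc[up$gene_id == "rbcL"],
               base$log2fc[base$gene_id == "rbcL"])
  }
})

test_that("probe tables survive the GenePix-dialect file round trip", {
  ann <- toy_plastome()
  sc <- scenario_presets(seed = 9)$kd_psbD
  truth <- simulate_truth(ann, sc)
  design <- array_design(ann)
  d <- tempfile()
  em <- emit_probe_tables(truth, design, sc, dir = d)
  expect_length(em$files, 6L)
  back <- read_probe_table(em$files[["RF_rep1"]])
  expect_equal(back$F635, em$tables$RF[[1]]$F635, tolerance = 1e-9)
  q1 <- quantify_array(list(RF = list(back)), design)
  q2 <- quantify_array(list(RF = list(em$tables$RF[[1]])), design)
  expect_equal(q1$log2fc, q2$log2fc, tolerance = 1e-9)
})
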