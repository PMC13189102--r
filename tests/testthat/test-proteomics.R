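# Small hand-built LFQ fixture: 6 proteins x (3 neurite + 3 soma) samples.
toy_lfq <- function() {
  m <- matrix(NA_real_, 6, 6,
              dimnames = list(paste0("P", 1:6),
                              c("n1", "n2", "n3", "s1", "s2", "s3")))
  m["P1", ] <- c(20, 21, 20, 20, 21, 20)          # complete, no effect
  m["P2", ] <- c(25, 25.5, 24.5, 20, 20.5, 19.5)  # strong neurite shift
  m["P3", ] <- c(22, NA, 22, 22, 22, NA)          # 4/6 detected
  m["P4", ] <- c(18, 18, NA, NA, NA, NA)          # neurite-exclusive
  m["P5", ] <- c(NA, NA, NA, 23, NA, 23)          # soma-exclusive
  m["P6", ] <- c(NA, 21, NA, NA, 21, NA)          # 2/6 detected
  meta <- data.frame(sample = colnames(m),
                     compartment = rep(c("neurite", "soma"), each = 3),
                     genotype = "wildtype", clone = "c1", replicate = 1:3,
                     stringsAsFactors = FALSE)
  lfq_table(m, meta)
}

test_that("detection filter keeps proteins at >= 70% and is idempotent", {
  tab <- toy_lfq()
  filt <- filter_detection(tab, 0.7)
  # P1 (6/6) and P2 (6/6) pass; P3 is 4/6 = 0.667 < 0.7 and is removed
  expect_setequal(rownames(filt$log2), c("P1", "P2"))
  refilt <- filter_detection(filt, 0.7)
  expect_identical(filt$log2, refilt$log2)
  # 7/10 kept, 6/10 removed at the 70% rule
  m <- matrix(c(rep(1, 7), rep(NA, 3), rep(1, 6), rep(NA, 4)), 2, 10,
              byrow = TRUE, dimnames = list(c("a", "b"), paste0("x", 1:10)))
  t2 <- lfq_table(m, data.frame(sample = paste0("x", 1:10),
                                compartment = "neurite"))
  expect_equal(rownames(filter_detection(t2)$log2), "a")
  expect_error(filter_detection(tab, 1.2), "min_fraction")
})

test_that("detection filter matches a brute-force count oracle on random missingness", {
  set.seed(10)
  for (i in 1:20) {
    m <- matrix(rnorm(20 * 8, 20), 20, 8,
                dimnames = list(sprintf("p%02d", 1:20), paste0("s", 1:8)))
    m[runif(length(m)) < 0.35] <- NA
    tab <- lfq_table(m, data.frame(sample = colnames(m),
                                   compartment = rep(c("neurite", "soma"), 4)))
    kept <- c(rownames(filter_detection(tab, 0.7)$log2), character(0))
    oracle <- rownames(m)[rowSums(!is.na(m)) >= 0.7 * ncol(m)]
    expect_identical(kept, oracle)
  }
})

test_that("compartment-exclusive sets follow the detection pattern exactly", {
  ex <- exclusive_proteins(toy_lfq())
  expect_equal(ex$neurite_only, "P4")
  expect_equal(ex$soma_only, "P5")
  expect_length(intersect(ex$neurite_only, ex$soma_only), 0)
})

test_that("planted exclusives are recovered exactly from the simulator", {
  sim <- generate_lfq_table(lfq_sim_config(
    n_proteins = 300, n_neurite_exclusive = 12, n_soma_exclusive = 5,
    missing_midpoint = 14, missing_slope = 1.2, rng_seed = 3))
  ex <- exclusive_proteins(sim$table)
  expect_setequal(ex$neurite_only, sim$truth$neurite_exclusive)
  expect_setequal(ex$soma_only, sim$truth$soma_exclusive)
})

test_that("differential test flags planted 3-log2 shifts and respects both thresholds", {
  sim <- generate_lfq_table(lfq_sim_config(
    n_proteins = 200, n_per_group = 2, n_neurite_exclusive = 0,
    n_soma_exclusive = 0, n_differential = 15, differential_log2fc = 3,
    within_sd = 0.3, missing_midpoint = 14, rng_seed = 8))
  # n = 6 per compartment (2 per genotype x 3 genotypes)
  de <- compartment_de(filter_detection(sim$table, 0.7))
  planted <- de$protein %in% sim$truth$differential
  expect_true(all(de$pass[planted]))
  expect_equal(sum(de$pass & !planted), 0)
  # identical group values -> nothing passes
  m <- matrix(rep(c(20, 21, 22, 20, 21, 22), each = 3), 3, 6, byrow = FALSE,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:6)))
  tab <- lfq_table(m, data.frame(sample = paste0("s", 1:6),
                                 compartment = rep(c("neurite", "soma"),
                                                   each = 3)))
  expect_equal(sum(compartment_de(tab)$pass), 0)
})

test_that("the pass rule needs both adjusted p < 0.05 and |log2FC| > 1.5", {
  # large |t| but |log2FC| = 1.4 must fail
  m <- matrix(c(20, 20.01, 19.99, 20.02, 18.6, 18.61, 18.59, 18.62), 1, 8,
              dimnames = list("p1", paste0("s", 1:8)))
  tab <- lfq_table(m, data.frame(sample = paste0("s", 1:8),
                                 compartment = rep(c("neurite", "soma"),
                                                   each = 4)))
  de <- compartment_de(tab)
  expect_lt(de$p_adj, 0.001)
  expect_equal(de$log2fc, 1.4, tolerance = 0.01)
  expect_false(de$pass)
})

test_that("sensitivity is monotone in the planted effect size", {
  sens <- vapply(c(0.5, 1.6, 3), function(fx) {
    sim <- generate_lfq_table(lfq_sim_config(
      n_proteins = 150, n_per_group = 2, n_neurite_exclusive = 0,
      n_soma_exclusive = 0, n_differential = 25, differential_log2fc = fx,
      within_sd = 0.3, missing_midpoint = 14, rng_seed = 11))
    de <- compartment_de(sim$table)
    mean(de$pass[de$protein %in% sim$truth$differential])
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
  expect_equal(sens[1], 0)   # below the fold-change gate entirely
  expect_gt(sens[3], 0.95)
})

test_that("genotype t test matches the hand-evaluated pooled formula", {
  m <- matrix(c(1, 2, 3, 2, 3, 4), 1, 6,
              dimnames = list("p1", paste0("s", 1:6)))
  meta <- data.frame(sample = paste0("s", 1:6), compartment = "neurite",
                     genotype = rep(c("wildtype", "hom"), each = 3),
                     clone = "c", replicate = 1:6)
  tab <- lfq_table(m, meta)
  res <- genotype_t_test(tab, "p1", "neurite", c("wildtype", "hom"))
  expect_equal(res$t, -1.224745, tolerance = 1e-6)
  expect_equal(res$df, 4)
  # df after missing-value drop equals observed n1 + n2 - 2
  m2 <- m; m2[1, 2] <- NA
  res2 <- genotype_t_test(lfq_table(m2, meta), "p1", "neurite",
                          c("wildtype", "hom"))
  expect_equal(res2$df, 3)
  # identical groups -> t = 0, p = 1
  m3 <- matrix(rep(c(1, 2, 3), 2), 1, 6,
               dimnames = list("p1", paste0("s", 1:6)))
  res3 <- genotype_t_test(lfq_table(m3, meta), "p1", "neurite",
                          c("wildtype", "hom"))
  expect_equal(res3$p, 1)
})

test_that("moderated-statistics cross-check: ordinary t agrees with limma on strong effects", {
  skip_if_not_installed("limma")
  sim <- generate_lfq_table(lfq_sim_config(
    n_proteins = 120, n_per_group = 2, n_neurite_exclusive = 0,
    n_soma_exclusive = 0, n_differential = 10, differential_log2fc = 3,
    within_sd = 0.3, missing_midpoint = 12, missing_slope = 2, rng_seed = 21))
  tab <- filter_detection(sim$table, 0.7)
  de <- compartment_de(tab)
  design <- stats::model.matrix(~ 0 + factor(tab$meta$compartment,
                                             c("neurite", "soma")))
  colnames(design) <- c("neurite", "soma")
  fit <- limma::lmFit(tab$log2, design)
  fit <- limma::eBayes(limma::contrasts.fit(
    fit, limma::makeContrasts(neurite - soma, levels = design)))
  mod <- limma::topTable(fit, number = Inf, sort.by = "none")
  expect_equal(de$log2fc, mod$logFC, tolerance = 1e-6)
  hits <- rownames(mod)[mod$adj.P.Val < 0.05 & abs(mod$logFC) > 1.5]
  expect_setequal(de$protein[de$pass], hits)
})

test_that("abundance ratios divide matched log2 values, soma over neurite", {
  tab <- toy_lfq()
  rr <- abundance_ratio(tab, "P1")
  expect_equal(rr$ratio, c(1, 1, 1))
  m <- matrix(c(20, 30), 1, 2, dimnames = list("pX", c("n1", "s1")))
  t2 <- lfq_table(m, data.frame(sample = c("n1", "s1"),
                                compartment = c("neurite", "soma"),
                                genotype = "wt", clone = "c1", replicate = 1))
  r2 <- abundance_ratio(t2, "pX")
  expect_equal(r2$ratio, 1.5)       # soma 30 / neurite 20
  expect_equal(r2$log2_diff, 10)
  # unmatched replicate skipped with a warning
  m3 <- matrix(c(20, 30, 25), 1, 3,
               dimnames = list("pX", c("n1", "s1", "n2")))
  t3 <- lfq_table(m3, data.frame(sample = c("n1", "s1", "n2"),
                                 compartment = c("neurite", "soma", "neurite"),
                                 genotype = "wt", clone = "c1",
                                 replicate = c(1, 1, 2)))
  expect_warning(r3 <- abundance_ratio(t3, "pX"), "unmatched")
  expect_equal(nrow(r3), 1)
})

test_that("LFQ simulator honours missingness settings and determinism", {
  cfg <- lfq_sim_config(n_proteins = 50,
                        missing_midpoint = -Inf, n_neurite_exclusive = 0,
                        n_soma_exclusive = 0, n_differential = 0,
                        rng_seed = 2)
  sim <- generate_lfq_table(cfg)
  expect_false(anyNA(sim$table$log2))   # zero missingness -> complete table
  expect_identical(generate_lfq_table(cfg)$table$log2, sim$table$log2)
  expect_error(lfq_sim_config(n_proteins = 10, n_neurite_exclusive = 8,
                              n_soma_exclusive = 5), "exceed")
})
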