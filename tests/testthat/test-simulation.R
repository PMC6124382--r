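test_that("sim_config carries the two published logistic designs", {
  s1 <- sim_config("sim1")
  expect_equal(s1$logit_terms$coef, c(0.18, 0.57, 0.29, 0.41, 1.02))
  expect_equal(s1$logit_terms$gene, c(rep("F13A1", 4), "GSTM1"))
  expect_equal(s1$logit_terms$timepoint, c("T1", "T2", "T3", "T4", "T3"))
  expect_equal(s1$n_genes, 1000L)        # 998 noise + 2 causal
  expect_equal(s1$n_subjects, 43L)       # 25 + 18 cohort
  expect_equal(s1$replicates, 50L)
  s2 <- sim_config("sim2")
  expect_equal(s2$logit_terms$coef, c(0.56, -0.91))
  expect_equal(s2$logit_terms$gene, c("COX4I2", "RP9"))
  expect_equal(s2$logit_terms$timepoint, c("T1", "T5"))
  expect_error(sim_config("custom"), "logit_terms")
  # doubling scales every coefficient
  expect_equal(sim_config("sim1", effect_multiplier = 2)$logit_terms$coef,
               2 * c(0.18, 0.57, 0.29, 0.41, 1.02))
})

test_that("the synthetic backbone is reproducible, standardized, and honors rho_time", {
  cfg <- sim_config("sim1", n_genes = 60, n_subjects = 400,
                    block_size = 20, rho_time = 0.6)
  bb <- make_backbone(cfg, seed = 5)
  expect_identical(bb, make_backbone(cfg, seed = 5))
  expect_equal(dim(bb), c(60L, 400L, 5L))
  # per-(gene, time) standardization
  expect_equal(max(abs(apply(bb, c(1, 3), mean))), 0, tolerance = 1e-12)
  expect_equal(max(abs(apply(bb, c(1, 3), stats::sd) - 1)), 0,
               tolerance = 1e-12)

  lag1 <- function(b) {
    x <- b[, , 1:4]; y <- b[, , 2:5]
    stats::cor(as.vector(x), as.vector(y))
  }
  # empirical lag-1 autocorrelation tracks the configured value
  expect_equal(lag1(bb), 0.6, tolerance = 3 / sqrt(60 * 400))
  cfg0 <- sim_config("sim1", n_genes = 60, n_subjects = 400,
                     rho_time = 0)
  expect_lt(abs(lag1(make_backbone(cfg0, seed = 5))),
            3 / sqrt(60 * 400 * 4))

  # within-block gene-gene correlation near rho_gene, across blocks ~ 0
  g <- bb[, , 1]
  within_ <- stats::cor(g[2, ], g[3, ])       # same block (block 1)
  across <- stats::cor(g[2, ], g[25, ])       # different blocks
  expect_equal(within_, 0.3, tolerance = 0.15)
  expect_lt(abs(across), 0.15)
})

test_that("simulate_outcome implements the logistic model exactly", {
  cfg <- sim_config("sim1", n_genes = 40, n_subjects = 6, block_size = 20)
  bb <- make_backbone(cfg, seed = 1)
  bb[] <- 0
  out <- simulate_outcome(bb, cfg$logit_terms, seed = 3)
  expect_true(all(attr(out, "eta") == 0))     # P(complicated) = 1/2 exactly
  expect_s3_class(out, "factor")
  expect_equal(levels(out), c("uncomplicated", "complicated"))

  # unit covariates at the causal cells reproduce the printed sums
  bb1 <- bb
  bb1["F13A1", 1, c("T1", "T2", "T3", "T4")] <- 1
  bb1["GSTM1", 1, "T3"] <- 1
  eta <- attr(simulate_outcome(bb1, cfg$logit_terms, seed = 3), "eta")
  expect_equal(unname(eta[1]), 2.47, tolerance = 1e-12)

  cfg2 <- sim_config("sim2", n_genes = 40, n_subjects = 6, block_size = 20)
  bb2 <- bb
  dimnames(bb2)[[1]][1:2] <- c("COX4I2", "RP9")
  bb2["COX4I2", 1, "T1"] <- 1; bb2["RP9", 1, "T5"] <- 1
  eta2 <- attr(simulate_outcome(bb2, cfg2$logit_terms, seed = 3), "eta")
  expect_equal(unname(eta2[1]), -0.35, tolerance = 1e-12)

  # labels depend on the backbone only through eta
  bb3 <- bb1
  bb3["NOISE0003", , ] <- 99       # a cell no logit term references
  expect_identical(simulate_outcome(bb1, cfg$logit_terms, seed = 8),
                   simulate_outcome(bb3, cfg$logit_terms, seed = 8))
})

test_that("an overwhelming planted effect is recovered in a single replicate", {
  # small blocks and a larger cohort so the single planted cell is not
  # diluted across the 5 x block_size cells of its set
  cfg <- sim_config("custom", n_genes = 40, n_subjects = 60,
                    block_size = 5, replicates = 1,
                    logit_terms = data.frame(gene = "CAUSAL",
                                             timepoint = "T2",
                                             coef = 10))
  # the longitudinal screen adjusts over all 40 genes, so the q-value
  # floor (1/(B+1)) * n_genes must sit below 0.05: B = 999
  out <- run_replicates(cfg, methods = c("longitudinal", "two_level"),
                        B = 999, seed = 6)
  freq <- out$frequency
  for (m in c("longitudinal", "two_level")) {
    hit <- freq[freq$method == m & freq$quantity == "CAUSAL", "T2"]
    expect_equal(hit, 100)
  }
  expect_true(all(out$avg_unique_genes <= cfg$n_genes))
  # determinism of the whole replicate pipeline
  out2 <- run_replicates(cfg, methods = "longitudinal", B = 999, seed = 6)
  expect_identical(out$frequency[out$frequency$method == "longitudinal", ],
                   out2$frequency)
})

test_that("a fully null design selects almost nothing", {
  cfg <- sim_config("custom", n_genes = 100, n_subjects = 20,
                    block_size = 20, replicates = 3,
                    logit_terms = data.frame(gene = "NULLGENE",
                                             timepoint = "T1",
                                             coef = 0))
  out <- run_replicates(cfg, methods = "longitudinal", B = 99, seed = 9)
  expect_lt(out$avg_unique_genes[["longitudinal"]], 0.05 * cfg$n_genes)
})

test_that("the aggregate table writes in the benchmark's shape", {
  cfg <- sim_config("custom", n_genes = 20, n_subjects = 16,
                    block_size = 10, replicates = 1,
                    logit_terms = data.frame(gene = "CAUSAL",
                                             timepoint = "T1", coef = 8))
  out <- run_replicates(cfg, methods = "longitudinal", B = 99, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_outcome_table(out, path)
  tab <- read.delim(path)
  expect_true(all(c("method", "quantity", "T1") %in% colnames(tab)))
  expect_true("avg_unique_genes" %in% tab$quantity)
  expect_true("CAUSAL" %in% tab$quantity)
})
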