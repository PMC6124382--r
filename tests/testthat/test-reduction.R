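# helper: a sam_stat_matrix with prescribed d values
mock_sam <- function(d) {
  structure(list(d = d, genes = rownames(d), timepoints = colnames(d),
                 s0 = rep(0.1, ncol(d)), pooling = "within",
                 fudge_method = "median"),
            class = "sam_stat_matrix")
}

test_that("order_features sorts by |d| (time level) and RSS (gene level), stably", {
  d <- matrix(c(0.5, 2.0, 1.0), 1, 3,
              dimnames = list("g1", c("T1", "T2", "T3")))
  sam <- mock_sam(d)
  ord <- order_features(sam, gene_cells("g1", c("T1", "T2", "T3")),
                        level = "timepoint")
  expect_equal(ord$timepoint, c("T2", "T3", "T1"))

  # gene level: identical aggregate magnitudes keep input order
  d2 <- rbind(g1 = c(3, 4), g2 = c(-4, 3), g3 = c(0, 1))
  colnames(d2) <- c("T1", "T2")
  sam2 <- mock_sam(d2)
  expect_equal(order_features(sam2, c("g2", "g1", "g3"), level = "gene"),
               c("g2", "g1", "g3"))

  # random instance vs naive sort oracle
  set.seed(31)
  d3 <- matrix(rnorm(40), 8, 5,
               dimnames = list(paste0("g", 1:8), paste0("T", 1:5)))
  sam3 <- mock_sam(d3)
  key <- sqrt(rowSums(d3^2))
  expect_equal(order_features(sam3, paste0("g", 1:8), level = "gene"),
               names(sort(key, decreasing = TRUE)))
})

test_that("singleton feature sets are their own core, no test performed", {
  expr <- make_toy_expr(G = 4, t = 3, seed = 2)
  res <- reduce_set(expr, features = "g1", level = "gene",
                    cutoff = 0.2, B = 10, seed = 1)
  expect_equal(res$core, "g1")
  expect_equal(res$k_star, 1L)
  expect_length(res$ck_sequence, 0L)
  rt <- reduce_set(expr, features = data.frame(gene = "g1",
                                               timepoint = "T2"),
                   level = "timepoint", cutoff = 0.2, B = 10, seed = 1)
  expect_equal(rt$core$timepoint, "T2")
})

test_that("strong feature plus constant residual reduces to the single core", {
  # g1 carries a large effect; g2, g3 are constant (permuted residual
  # statistics identically zero -> c_1 = 1 > cutoff -> k* = 1)
  arr <- array(1, c(3, 8, 2),
               dimnames = list(paste0("g", 1:3),
                               paste0("s", 1:8), c("T1", "T2")))
  arr[1, , ] <- withr::with_seed(11, rnorm(16))
  arr[1, 1:4, ] <- arr[1, 1:4, ] + 5
  expr <- long_expr_set(arr, rep(c("case", "ctrl"), each = 4))
  res <- suppressWarnings(
    reduce_set(expr, features = paste0("g", 1:3), level = "gene",
               cutoff = 0.2, B = 99, seed = 3))
  expect_equal(res$core, "g1")
  expect_equal(res$residual, c("g2", "g3"))
  expect_equal(res$ck_sequence[[1]], 1)
})

test_that("uniformly strong sets keep every feature (k* = S)", {
  sig <- data.frame(gene = paste0("g", 1:3),
                    timepoint = "T1", delta = 3)
  expr <- make_toy_expr(G = 4, n_d = 10, n_c = 10, t = 1, seed = 17,
                        signal = sig)
  res <- reduce_set(expr, features = paste0("g", 1:3), level = "gene",
                    cutoff = 0.05, B = 400, seed = 5)
  expect_equal(res$k_star, 3L)
  expect_setequal(res$core, paste0("g", 1:3))
  expect_length(res$residual, 0L)
  expect_true(all(res$ck_sequence <= 0.05))
})

test_that("partition invariant and the stopping rule hold on random instances", {
  for (seed in 1:5) {
    expr <- make_toy_expr(G = 6, n_d = 4, n_c = 4, t = 2, seed = seed)
    res <- reduce_set(expr, features = paste0("g", 1:5), level = "gene",
                      cutoff = 0.3, B = 60, seed = seed)
    expect_setequal(c(res$core, res$residual), paste0("g", 1:5))
    expect_length(intersect(res$core, res$residual), 0L)
    expect_equal(length(res$core), res$k_star)
    if (res$k_star < 5L) {
      expect_gt(res$ck_sequence[[res$k_star]], 0.3)
      if (res$k_star > 1L)
        expect_true(all(res$ck_sequence[seq_len(res$k_star - 1L)] <= 0.3))
    }
  }
})

test_that("k_star is nondecreasing in the cutoff on a fixed permutation stream", {
  # a larger cutoff demands a *less* significant residual before
  # stopping, so the core can only grow
  expr <- make_toy_expr(G = 8, n_d = 6, n_c = 6, t = 2, seed = 23,
                        signal = data.frame(gene = c("g1", "g2"),
                                            timepoint = "T1",
                                            delta = c(2.5, 1.5)))
  eng <- sam_perm_engine(expr, B = 300, seed = 7)
  ks <- vapply(c(0.05, 0.2, 0.5, 0.8), function(cf)
    reduce_set(features = paste0("g", 1:6), level = "gene",
               cutoff = cf, engine = eng)$k_star, integer(1))
  expect_true(all(diff(ks) >= 0))
})

test_that("constant data with cutoff near 1 stops immediately", {
  const <- make_toy_expr(G = 4, t = 2, constant = TRUE)
  res <- suppressWarnings(
    reduce_set(const, features = paste0("g", 1:4), level = "gene",
               cutoff = 0.999, B = 30, seed = 1))
  expect_equal(res$k_star, 1L)
  expect_error(reduce_set(const, features = "g1", cutoff = 0,
                          level = "gene"), "strictly inside")
  expect_error(reduce_set(const, features = "g1", cutoff = 1,
                          level = "gene"), "strictly inside")
})

test_that("reduction results serialize to JSON and back", {
  expr <- make_toy_expr(G = 4, t = 2, seed = 3)
  res <- reduce_set(expr, features = paste0("g", 1:3), level = "gene",
                    cutoff = 0.2, B = 20, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  reduction_to_json(res, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$k_star, res$k_star)
  expect_equal(back$core, res$core)
  expect_equal(back$ck_sequence, res$ck_sequence)
})
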