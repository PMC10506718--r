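test_that("expression calls use the inclusive >= 2 TPM boundary", {
  m <- matrix(c(0, 1.9, 2.0,
                0, 0, 0,
                1.99, 1.98, 1.2,
                5, 100, 0), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), c("s1", "s2", "s3")))
  flags <- call_expressed(m)
  expect_equal(unname(flags), c(TRUE, FALSE, FALSE, TRUE))
  # monotone in the threshold: raising it never adds expressed genes
  for (th in c(1, 2, 5, 50, 200)) {
    expect_true(all(call_expressed(m, th + 1) <= call_expressed(m, th)))
  }
})

test_that("heatmap rows are standardized and clustered deterministically", {
  withr::local_seed(10)
  m <- matrix(runif(60, 0, 50), nrow = 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  m[3, ] <- m[1, ]         # identical pair
  m[7, ] <- 4              # constant row
  h <- heatmap_matrix(m)
  ok <- !h$constant_rows
  expect_equal(unname(rowMeans(h$z[ok, ])), rep(0, sum(ok)), tolerance = 1e-9)
  expect_equal(unname(apply(h$z[ok, ], 1, sd)), rep(1, sum(ok)), tolerance = 1e-9)
  expect_true(h$constant_rows[7])
  expect_equal(unname(h$z[7, ]), rep(0, 6))
  # identical rows are adjacent in the clustering order (zero distance first)
  pos <- match(c(1, 3), h$row_order)
  expect_equal(abs(diff(pos)), 1L)
  # row order is a permutation and reruns are identical
  expect_setequal(h$row_order, 1:10)
  expect_identical(heatmap_matrix(m)$row_order, h$row_order)
  expect_error(heatmap_matrix(m[1, , drop = FALSE]), ">= 2 genes")
})

test_that("log2 and z transforms match hand computation", {
  m <- matrix(c(0, 1, 3,
                0, 1, 3), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  h <- heatmap_matrix(m)
  expect_equal(unname(h$z["a", ]), c(-1, 0, 1))
})

test_that("per-species expression summaries mirror the 6-of-7 arithmetic", {
  tpm <- matrix(c(rep(5, 6), rep(0.5, 1)), ncol = 1)
  tpm <- cbind(tpm, 0)
  rownames(tpm) <- paste0("amp", 1:7)
  colnames(tpm) <- c("L1", "L3")
  cands <- data.frame(id = paste0("amp", 1:7), species = "Trichuris-like",
                      stringsAsFactors = FALSE)
  s <- summarize_expression(list("Trichuris-like" = tpm), cands)
  expect_equal(s$per_species$n_expressed, 6L)
  expect_equal(s$per_species$fraction_expressed, 6 / 7, tolerance = 1e-12)
  expect_equal(round(s$per_species$fraction_expressed, 3), 0.857)

  # all genes expressed -> fraction 1
  tpm2 <- matrix(10, nrow = 3, ncol = 2,
                 dimnames = list(paste0("amp", 1:3), c("L1", "L3")))
  cands2 <- data.frame(id = paste0("amp", 1:3), species = "spA")
  expect_equal(summarize_expression(list(spA = tpm2), cands2)$pooled_fraction, 1)

  # missing ids counted unexpressed with a warning; empty species excluded
  cands3 <- data.frame(id = c("amp1", "ghost"), species = "spA")
  expect_warning(s3 <- summarize_expression(list(spA = tpm2), cands3),
                 "missing")
  expect_equal(s3$per_species$n_expressed, 1L)
  cands4 <- data.frame(id = character(0), species = character(0))
  expect_message(s4 <- summarize_expression(list(spA = tpm2), cands4),
                 "zero AMP genes")
  expect_null(s4$per_species)
})

test_that("the synthetic corpus reproduces its expressed fraction end-to-end", {
  study <- small_study()
  res <- small_pipeline()
  mats <- lapply(split(study$meta$genome_id, study$meta$species), function(gids) {
    ids <- study$truth$id[study$truth$genome_id %in% gids]
    study$tpm[rownames(study$tpm) %in% ids, , drop = FALSE]
  })
  s <- suppressWarnings(summarize_expression(mats, res$candidates))
  expect_gt(s$pooled_fraction, 0.75)
  expect_lte(s$pooled_fraction, 1)
})
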