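test_that("align_local equals the naive DP oracle on 100 random pairs", {
  withr::local_seed(2024)
  for (r in seq_len(100)) {
    a <- random_seq(sample(5:40, 1))
    b <- random_seq(sample(5:40, 1))
    expect_identical(align_local(a, b)$score, naive_sw(a, b))
  }
})

test_that("align_local has exact self-scores, symmetry and empty behavior", {
  a <- "HEAGAWGHEE"
  sub <- nemamp:::blosum62_matrix()
  self_score <- sum(diag(sub[strsplit(a, "")[[1]], strsplit(a, "")[[1]]]))
  r <- align_local(a, a)
  expect_equal(r$score, self_score)
  expect_equal(c(r$a_start, r$a_end), c(1L, 10L))

  expect_equal(align_local("", "MKV")$score, 0)
  expect_equal(align_local("MKV", "")$score, 0)

  withr::local_seed(9)
  for (r in seq_len(25)) {
    a <- random_seq(sample(5:50, 1)); b <- random_seq(sample(5:50, 1))
    expect_equal(align_local(a, b)$score, align_local(b, a)$score)
  }
})

test_that("profiles are built from low-gap columns with Laplace emissions", {
  s <- tiny_seed_set(rep("ACDEFGHIKL", 3))
  p <- build_profile(s)
  expect_equal(p$M, 10L)
  expect_equal(AA20[apply(p$emission_probs, 1, which.max)],
               strsplit("ACDEFGHIKL", "")[[1]])
  # emission probabilities normalize (before log)
  expect_equal(unname(rowSums(p$emission_probs)), rep(1, 10))

  # a column with 2/3 gaps is not a match state
  rec <- protein_records(c("a", "b", "c"), c("ACDEFGHIKL", "ADEFGHIKL", "ADEFGHIKL"))
  aln <- c(a = "ACDEFGHIKL", b = "A-DEFGHIKL", c = "A-DEFGHIKL")
  p2 <- build_profile(seed_set("Cecropin", rec, aln))
  expect_equal(p2$M, 9L)

  expect_error(build_profile(tiny_seed_set("ACDEFGHIKL")), ">= 2")
})

test_that("profile scores separate training sequences from shuffles", {
  seeds <- shipped_seeds()
  for (nm in c("cecropin", "diapausin", "grsp")) {
    p <- build_profile(seeds[[nm]])
    withr::local_seed(77)
    for (q in seeds[[nm]]$records$sequence[1:3]) {
      true_score <- score_profile(p, q)
      shuffles <- vapply(seq_len(100), function(i) {
        score_profile(p, paste(sample(strsplit(q, "")[[1]]), collapse = ""))
      }, numeric(1))
      expect_gt(true_score, max(shuffles))
      expect_gt(true_score, quantile(shuffles, 0.95))
    }
  }
})

test_that("X residues are unscorable and scores are local", {
  p <- build_profile(shipped_seeds()$cecropin)
  expect_equal(score_profile(p, strrep("X", 60)), 0)
  withr::local_seed(15)
  q <- shipped_seeds()$cecropin$records$sequence[1]
  base <- score_profile(p, q)
  for (r in 1:5) {
    flanked <- paste0(random_seq(100), q, random_seq(100))
    expect_lt(abs(score_profile(p, flanked) - base), 0.5)
  }
})

test_that("E-value calibration gives a decreasing, db-linear Gumbel", {
  study <- small_study()
  p <- build_profile(shipped_seeds()$diapausin)
  em <- calibrate_evalue(p, study$proteins, seed = 42)
  s <- seq(5, 80, by = 5)
  ev <- evalue(em, s)
  expect_true(all(diff(ev) < 0))
  expect_equal(evalue(em, 30, db_size = 2 * em$db_size),
               2 * evalue(em, 30))
  # fitted tail probability at the decoy median corresponds to P ~ 0.5
  med <- stats::median(em$decoy_scores)
  p_tail <- 1 - exp(-exp(-em$lambda * (med - em$mu)))
  expect_gt(p_tail, 0.25)
  expect_lt(p_tail, 1)
  # degenerate variance errors
  rec <- protein_records("a", strrep("A", 200))
  expect_error(calibrate_evalue(p, rec, seed = 1), "degenerate")
})

test_that("iterative expansion follows transitive chains to a fixed point", {
  withr::local_seed(30)
  x1 <- random_seq(30); x2 <- random_seq(30); x3 <- random_seq(30); x4 <- random_seq(30)
  db <- protein_records(c("a", "b", "c", "d"),
                        c(paste0(x1, x2), paste0(x2, x3), paste0(x3, x4),
                          random_seq(60)))
  similar <- function(qseqs, cand) {
    vapply(cand$sequence, function(t) {
      any(vapply(qseqs, function(q) align_local(q, t)$score >= 100, logical(1)))
    }, logical(1), USE.NAMES = FALSE)
  }
  r <- iterative_expand("a", db, accept = function(row) TRUE, similar = similar)
  expect_setequal(r$ids, c("a", "b", "c"))
  expect_equal(r$rounds, 2L)
  expect_true(r$converged)

  # no acceptable hit -> seeds unchanged, 0 rounds
  r0 <- iterative_expand("a", db, accept = function(row) FALSE, similar = similar)
  expect_equal(r0$ids, "a")
  expect_equal(r0$rounds, 0L)

  # result independent of database iteration order
  perm <- db[c(3, 1, 4, 2), ]
  r2 <- iterative_expand("a", perm, accept = function(row) TRUE, similar = similar)
  expect_setequal(r2$ids, r$ids)

  # idempotent at the fixed point
  r3 <- iterative_expand(r$ids, db, accept = function(row) TRUE, similar = similar)
  expect_setequal(r3$ids, r$ids)
  expect_equal(r3$rounds, 0L)
})

test_that("reciprocal top-5 ranks by E then bits then id", {
  withr::local_seed(44)
  grsp_seq <- shipped_seeds()$grsp$records$sequence[1]
  decoys <- vapply(1:6, function(i) random_seq(60), character(1))
  refs <- data.frame(id = c("g1", paste0("n", 1:6)),
                     sequence = c(grsp_seq, decoys),
                     is_grsp = c(TRUE, rep(FALSE, 6)))
  # candidate identical to the known GRSP -> rank 1 -> pass
  expect_true(reciprocal_top5(grsp_seq, refs)$pass)

  # candidate matching 5 non-GRSP entries better than any GRSP -> fail
  near <- decoys[1:5]
  cand <- paste(substr(near, 1, 40), collapse = "")
  refs2 <- data.frame(id = c("g1", paste0("n", 1:5)),
                      sequence = c(grsp_seq, near),
                      is_grsp = c(TRUE, rep(FALSE, 5)))
  r <- reciprocal_top5(cand, refs2)
  expect_false(r$pass)
  expect_equal(nrow(r$top), 5L)

  # all-GRSP 5-entry reference -> pass for any scorable candidate
  refs3 <- data.frame(id = paste0("g", 1:5),
                      sequence = replicate(5, random_seq(50)),
                      is_grsp = TRUE)
  expect_true(reciprocal_top5(random_seq(50), refs3)$pass)

  expect_error(reciprocal_top5("MKV", refs3[0, ]), "empty")
})

test_that("external hit adapters map onto the internal schema", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#query_ref\ttarget_id\tbits\tevalue\ttstart\ttend",
               "q1\tt1\t55.2\t1e-12\t3\t60"), f)
  h <- read_hits_adapter(f)
  expect_equal(h$target_id, "t1")
  expect_equal(h$tend, 60L)
  writeLines(c("#query_ref\ttarget_id\tbits\tevalue\ttstart\ttend",
               "q1\tt1\t55.2\t0\t3\t60"), f)
  expect_error(read_hits_adapter(f), "> 0")
})
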