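test_that("motif definitions validate spacers and connectivity", {
  expect_error(motif_definition("bad", 4, list(c(1, 2), c(3, 2))), "pairs")
  expect_error(motif_definition("bad", 3, list(c(2, 1), c(1, 2))), "mins")
  expect_error(motif_definition("bad", 4, list(c(1, 2), c(1, 2), c(1, 2)),
                                connectivity = list(c(1, 2), c(2, 3))),
               "disjoint")
  expect_error(motif_definition("bad", 4, list(c(1, 2), c(1, 2), c(1, 2)),
                                connectivity = list(c(1, 2))), "cover")
  m <- motif_definition("ok", 4, list(c(1, 2), c(1, 2), c(1, 2)),
                        connectivity = list(c(1, 3), c(2, 4)))
  expect_s3_class(m, "motif_definition")
})

test_that("find_motif detects single, tandem and boundary cases", {
  withr::local_seed(31)
  motifs <- shipped_motifs()
  dia <- motifs$Diapausin

  one <- motif_instance(dia)
  m <- find_motif(one, dia)
  expect_length(m, 1)
  expect_length(m[[1]]$positions, 6)
  expect_true(all(substring(one, m[[1]]$positions, m[[1]]$positions) == "C"))

  # two complete arrays in tandem -> 2 matches (12 cysteines)
  two <- paste0(one, motif_instance(dia))
  expect_length(find_motif(two, dia), 2)

  # one spacer 1 below its minimum -> no match
  sp <- dia$spacers[, 1]
  sp[2] <- sp[2] - 1L
  low <- motif_instance(dia, spacers = sp)
  expect_length(find_motif(low, dia), 0)

  # exact-minimum spacers everywhere -> 1 match
  expect_length(find_motif(motif_instance(dia, spacers = dia$spacers[, 1]), dia), 1)

  # 'X' at a cysteine position voids the match; 'X' in a spacer does not
  chars <- strsplit(one, "")[[1]]
  pos <- m[[1]]$positions
  spacer_idx <- pos[1] + 1L
  chars[spacer_idx] <- "X"
  expect_length(find_motif(paste(chars, collapse = ""), dia), 1)
  chars[pos[1]] <- "X"
  expect_length(find_motif(paste(chars, collapse = ""), dia), 0)
})

test_that("find_motif agrees with the brute-force oracle on random sequences", {
  withr::local_seed(4711)
  motifs <- shipped_motifs()
  defs <- motifs[c("Diapausin", "TID", "MND_6Cys", "SaposinB")]
  alphabet_cys_rich <- c(rep("C", 4), setdiff(AA20, "C"))
  n_checked <- 0L
  for (r in seq_len(500)) {
    len <- sample(40:120, 1)
    seq <- random_seq(len, alphabet = alphabet_cys_rich)
    if (lengths(regmatches(seq, gregexpr("C", seq))) > 20) next
    m <- defs[[sample(length(defs), 1)]]
    got <- find_motif(seq, m)
    want <- brute_force_motif_oracle(seq, m)
    expect_identical(lapply(got, `[[`, "positions"),
                     lapply(want, `[[`, "positions"))
    n_checked <- n_checked + 1L
  }
  expect_gt(n_checked, 400)

  expect_length(brute_force_motif_oracle("MKVLNNQR", shipped_motifs()$TID), 0)
  expect_error(brute_force_motif_oracle(strrep("C", 25), shipped_motifs()$TID),
               "cysteines")
})

test_that("every reported match re-validates its own evidence", {
  withr::local_seed(99)
  motifs <- shipped_motifs()
  for (r in 1:50) {
    m <- motifs[[sample(length(motifs), 1)]]
    seq <- motif_instance(m)
    for (match in find_motif(seq, m)) {
      p <- match$positions
      expect_true(all(substring(seq, p, p) == "C"))
      gaps <- diff(p) - 1L
      expect_true(all(gaps >= m$spacers[, 1] & gaps <= m$spacers[, 2]))
    }
  }
})

test_that("CSab classification assigns each reference array uniquely", {
  withr::local_seed(12)
  motifs <- shipped_motifs()
  refs <- csab_reference_arrays(motifs)
  for (sub in names(refs)) {
    for (r in 1:20) {
      seq <- motif_instance(refs[[sub]])
      cls <- classify_csab(seq, refs)
      expect_equal(cls$status, "assigned")
      expect_equal(cls$subgroup, sub)
    }
  }
  # no-cysteine sequence -> none; never a fuzzy fallback
  expect_equal(classify_csab(random_seq(80, setdiff(AA20, "C")), refs)$status,
               "none")
})

test_that("CSab ambiguity is reported, never silently tie-broken", {
  motifs <- shipped_motifs()
  refs <- csab_reference_arrays(motifs)
  withr::local_seed(3)
  # a concatemer carrying two different arrays matches both
  seq <- paste0(motif_instance(refs$TID), strrep("A", 9),
                motif_instance(refs$MND))
  cls <- classify_csab(seq, refs)
  expect_equal(cls$status, "ambiguous")
  expect_setequal(cls$matched_subgroups, c("TID", "MND"))
  expect_true(is.na(cls$subgroup))
})

test_that("Saposin B domain counting is leftmost-greedy and exact", {
  withr::local_seed(21)
  motifs <- shipped_motifs()
  sap <- motifs$SaposinB
  one <- motif_instance(sap)
  expect_equal(count_saposin_domains(one, sap), 1L)
  seven <- paste(replicate(7, motif_instance(sap)), collapse = "GSNQ")
  expect_equal(count_saposin_domains(seven, sap), 7L)
  # 5 scattered cysteines cannot form the 6-cysteine array
  scattered <- paste0("MK", paste(rep("CAGSTN", 5), collapse = "LQ"))
  expect_equal(count_saposin_domains("MKVLNQ", sap), 0L)
  expect_equal(count_saposin_domains(scattered, sap), 0L)
})
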