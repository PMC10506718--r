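test_that("planted AMPs satisfy their group's acceptance rules by construction", {
  withr::local_seed(61)
  seeds <- shipped_seeds()
  motifs <- shipped_motifs()
  cfg <- sim_config()
  # GRSP: glycine in (17, 74], precursor <= 200
  for (r in 1:15) {
    p <- plant_amp("GRSP", seeds = seeds, motifs = motifs, cfg = cfg)
    expect_gt(p$truth$mature_glycine_pct, 17)
    expect_lte(p$truth$mature_glycine_pct, 74)
    expect_lte(p$truth$length, 200)
    expect_true(p$truth$has_signal_peptide)
  }
  # Macin: exactly 10 cysteines in the Macin array
  p <- plant_amp("CSab", "Macin", seeds, motifs, cfg)
  m <- find_motif(p$record$sequence, motifs$Macin)
  expect_length(m, 1)
  expect_length(m[[1]]$positions, 10)
  # Nemapore with 7 tandem Saposin B arrays
  p7 <- plant_amp("Nemapore", seeds = seeds, motifs = motifs, cfg = cfg,
                  n_domains = 7)
  expect_equal(count_saposin_domains(p7$record$sequence, motifs$SaposinB), 7L)
  expect_equal(p7$truth$n_saposin_domains, 7L)
  expect_equal(nrow(p7$domains), 7L)
  # Diapausin: one complete six-cysteine array
  pd <- plant_amp("Diapausin", seeds = seeds, motifs = motifs, cfg = cfg)
  expect_length(find_motif(pd$record$sequence, motifs$Diapausin), 1)
  expect_error(plant_amp("CSab", "NotASubgroup", seeds, motifs, cfg))
})

test_that("each hard decoy violates exactly its targeted rule", {
  withr::local_seed(62)
  seeds <- shipped_seeds()
  motifs <- shipped_motifs()
  cfg <- sim_config()
  refs <- do.call(rbind, lapply(seeds, function(s) {
    data.frame(id = s$records$id, sequence = s$records$sequence,
               is_grsp = s$group == "GRSP")
  }))
  for (r in 1:10) {
    d <- make_decoy("glycine_rich_long", seeds, motifs, cfg)
    expect_equal(nchar(d$record$sequence), 250L)
    checks <- rule_grsp(d$record$sequence, d$record$id, refs)$checks
    expect_equal(names(checks)[!checks], "length")

    d <- make_decoy("glycine_rich_no_sp", seeds, motifs, cfg)
    checks <- rule_grsp(d$record$sequence, d$record$id, refs)$checks
    expect_equal(names(checks)[!checks], "signal_peptide")

    d <- make_decoy("saplip_extra_domain", seeds, motifs, cfg)
    checks <- rule_motif_group("Nemapore", d$record$sequence, d$record$id,
                               motifs, d$domains)$checks
    expect_equal(names(checks)[!checks], "no_extra_domain")

    d <- make_decoy("cys_rich_wrong_spacing", seeds, motifs, cfg)
    expect_length(find_motif(d$record$sequence, motifs$Diapausin), 0)
    # it still looks diapausin-like: 6 cysteines, valid signal peptide
    expect_equal(unname(lengths(regmatches(d$record$sequence,
                                           gregexpr("C", d$record$sequence)))), 6L)
    expect_false(is.na(predict_signal_peptide(d$record$sequence)))
  }
})

test_that("the generated corpus is deterministic and correctly bookkept", {
  cfg <- sim_config(seed = 7, n_genomes = 2, n_decoys_per_genome = 50,
                    planted_per_group = 4)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1, s2)
  # byte-identical files on disk
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_study(cfg, out_dir = d1)
  generate_study(cfg, out_dir = d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # bookkeeping: planted + decoy rows
  expect_equal(sum(s1$truth$planted_group %in%
                     c("Cecropin", "Diapausin", "CSab", "Nemapore", "GRSP")),
               2L * 5L * 4L)
  expect_equal(sum(s1$truth$planted_group %in% c("decoy", "hard_decoy")),
               2L * 50L)
  expect_equal(nrow(s1$proteins), nrow(s1$truth))
  # a different seed changes the corpus
  s3 <- generate_study(sim_config(seed = 8, n_genomes = 2,
                                  n_decoys_per_genome = 50,
                                  planted_per_group = 4))
  expect_false(identical(s1$proteins$sequence, s3$proteins$sequence))
})

test_that("the TPM table hits the expressed fraction by exact counting", {
  cfg <- sim_config(seed = 3, n_genomes = 2, n_decoys_per_genome = 10,
                    planted_per_group = 10, expressed_fraction = 0.86)
  study <- generate_study(cfg)
  # 100 planted genes at fraction 0.86 -> exactly 86 expressed
  expect_equal(nrow(study$tpm), 100L)
  expect_equal(sum(apply(study$tpm, 1, max) >= 2), 86L)
  expect_true(all(study$tpm >= 0))
})

test_that("truncated planted AMPs lack their signal peptide", {
  withr::local_seed(90)
  seeds <- shipped_seeds(); motifs <- shipped_motifs()
  p <- plant_amp("Diapausin", seeds = seeds, motifs = motifs,
                 cfg = sim_config(), truncate = TRUE)
  expect_false(p$truth$has_signal_peptide)
  expect_true(is.na(predict_signal_peptide(p$record$sequence)))
  # the motif survives truncation
  expect_length(find_motif(p$record$sequence, motifs$Diapausin), 1)
})
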