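toy_meta <- function() {
  data.frame(genome_id = c("g1", "g2", "g3"),
             species = c("sp1", "sp2", "sp3"),
             clade = c("9/V", "9/V", "2/I"),
             lifestyle = c("FLN", "APN", "FLN"),
             pcg_count = c(10000, 15000, 20000),
             busco_complete = c(99, 95, 90), stringsAsFactors = FALSE)
}

toy_cands <- function(ids, genomes, groups) {
  data.frame(id = ids, genome_id = genomes, group = groups,
             stringsAsFactors = FALSE)
}

test_that("per-genome tallies count all candidates and relative abundance", {
  meta <- toy_meta()
  cands <- toy_cands(paste0("c", 1:3), c("g1", "g1", "g1"),
                     c("Nemapore", "Nemapore", "GRSP"))
  prof <- tally(cands, meta)
  expect_equal(unlist(prof[prof$genome_id == "g1",
                           c("Cecropin", "Diapausin", "CSab", "Nemapore", "GRSP")],
                      use.names = FALSE), c(0, 0, 0, 2, 1))
  expect_equal(prof$total_amp, c(3, 0, 0))
  # 82 AMP genes in 10000 protein-coding genes -> 0.82%
  cands82 <- toy_cands(paste0("x", 1:82), rep("g1", 82), rep("GRSP", 82))
  expect_equal(tally(cands82, meta)$rel_abundance[1], 0.82)
  # empty candidate set -> all-zero profiles
  expect_equal(tally(cands82[0, ], meta)$total_amp, c(0, 0, 0))
  expect_error(tally(toy_cands("c", "gX", "GRSP"), meta), "unknown genome_id")
})

test_that("group summaries report mean, SEM and the n=1 flag", {
  meta <- toy_meta()
  prof <- tally(toy_cands(paste0("c", 1:60),
                          rep(c("g1", "g2", "g3"), c(10, 20, 30)),
                          rep("GRSP", 60)), meta)
  s <- summarize_profiles(prof, meta, by = "lifestyle")
  fln <- s[s$group == "FLN", ]
  # values {10, 30}: mean 20, SEM = sd/sqrt(2)
  expect_equal(fln$mean_amp, 20)
  expect_equal(fln$sem_amp, sd(c(10, 30)) / sqrt(2))
  apn <- s[s$group == "APN", ]
  expect_equal(apn$sem_amp, 0)
  expect_true(apn$n1_flag)
  # hand-checked SEM for {10, 20, 30}
  expect_equal(sd(c(10, 20, 30)) / sqrt(3), 5.7735, tolerance = 1e-4)
  # invariant to genome ordering
  s2 <- summarize_profiles(prof[3:1, ], meta, by = "lifestyle")
  expect_equal(s2$mean_amp, s$mean_amp)
  # clade grouping over a 2-clade corpus -> 2 rows
  expect_equal(nrow(summarize_profiles(prof, meta, by = "clade")), 2L)
})

test_that("Lilliefors KS normality test matches nortest and detects skew", {
  withr::local_seed(3)
  x <- rnorm(200, mean = 5, sd = 2)
  mine <- ks_normality(x, mc_reps = 4000)
  ref <- nortest::lillie.test(x)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_gt(mine$p_value, 0.05)
  # strongly skewed data is rejected
  y <- rexp(200)
  expect_lt(ks_normality(y, mc_reps = 4000)$p_value, 0.01)
  expect_error(ks_normality(rep(1, 10)), "zero variance")
  expect_error(ks_normality(c(1, 2)), "n >= 5")
})

test_that("Lilliefors p-values are calibrated under the null", {
  withr::local_seed(29)
  reject <- vapply(seq_len(300), function(i) {
    ks_normality(rnorm(60), mc_reps = 2000)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.02)
  expect_lt(mean(reject), 0.08)
})

test_that("Kruskal-Wallis H matches hand computation; Dunn p are adjusted", {
  # identical groups -> H ~ 0, p ~ 1
  r0 <- kruskal_dunn(list(c(1, 2, 3), c(1, 2, 3)))
  expect_lt(r0$H, 0.1)
  expect_gt(r0$p_overall, 0.9)
  # ranks 1..9 in three separated groups: H = 7.2 with df 2
  r <- kruskal_dunn(list(c(1, 2, 3), c(10, 11, 12), c(20, 21, 22)))
  expect_equal(r$H, 7.2, tolerance = 1e-10)
  expect_equal(r$df, 2)
  expect_equal(nrow(r$pairwise), 3L)
  expect_true(all(r$pairwise$p_adjusted <= 1))
  # Dunn z for the extreme pair, from pooled mean ranks by hand:
  # rbar1 = 2, rbar3 = 8, se = sqrt((9*10/12)*(2/3))
  z_hand <- (2 - 8) / sqrt((9 * 10 / 12) * (2 / 3))
  expect_equal(r$pairwise$z[r$pairwise$group1 == "g1" &
                              r$pairwise$group2 == "g3"], z_hand)
  expect_error(kruskal_dunn(list(c(1, 1), c(1, 1))), "identical")
})

test_that("planted 4x lifestyle effects are detected", {
  withr::local_seed(41)
  fln <- rpois(15, 100)
  apn <- rpois(15, 25)
  ppn <- rpois(15, 30)
  r <- kruskal_dunn(list(FLN = fln, APN = apn, PPN = ppn))
  expect_lt(r$p_overall, 0.001)
  expect_lt(r$pairwise$p_adjusted[r$pairwise$group1 == "FLN" &
                                    r$pairwise$group2 == "APN"], 0.001)
})

test_that("group shares normalize to 100 with two decimals", {
  r <- group_shares(c(1, 0, 0, 0, 0))
  expect_equal(unname(r$shares), c(100, 0, 0, 0, 0))
  withr::local_seed(6)
  for (i in 1:20) {
    counts <- sample(1:5000, 5)
    s <- group_shares(counts)
    expect_lt(abs(sum(s$shares) - 100), 0.021)
  }
  expect_error(group_shares(c(0, 0, 0, 0, 0)), "zero")
})
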