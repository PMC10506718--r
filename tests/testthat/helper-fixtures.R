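# Shared fixtures built in code at test time.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seq <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# A tiny ungapped seed set: n copies of one sequence with point differences.
tiny_seed_set <- function(seqs, group = "Cecropin", ids = NULL) {
  ids <- ids %||% paste0("s", seq_along(seqs))
  rec <- protein_records(ids, seqs)
  seed_set(group, rec, stats::setNames(seqs, ids))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cached shipped fixtures (loaded once per test run).
shipped_seeds <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_seed_sets()
    cache
  }
})

shipped_motifs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_motifs()
    cache
  }
})

# A small synthetic study shared across tests (2 genomes, light corpus).
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_study(sim_config(seed = 11, n_genomes = 2,
                                          n_decoys_per_genome = 60,
                                          planted_per_group = 5))
    }
    cache
  }
})

# Cached pipeline result on the small study.
small_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      study <- small_study()
      cache <<- run_pipeline(study$proteins, seeds = shipped_seeds(),
                             motifs = shipped_motifs(),
                             domains = study$domains,
                             config = pipeline_config(seed = 3))
    }
    cache
  }
})

# Naive full-matrix affine-gap Smith-Waterman oracle (plain R, independent
# of the compiled engine). A gap of length k costs open + k * ext.
naive_sw <- function(a, b, open = 11, ext = 1) {
  sub <- nemamp:::blosum62_matrix()
  ea <- strsplit(a, "")[[1]]; eb <- strsplit(b, "")[[1]]
  n <- length(ea); m <- length(eb)
  if (n == 0 || m == 0) return(0)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sub[ea[i], eb[j]]
      M[i + 1, j + 1] <- max(0, M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Build a synthetic sequence carrying a given motif with chosen spacers.
motif_instance <- function(m, spacers = NULL, flank = 4, alphabet = setdiff(AA20, "C")) {
  spacers <- spacers %||% floor((m$spacers[, 1] + m$spacers[, 2]) / 2)
  out <- sample(alphabet, flank, replace = TRUE)
  for (i in seq_len(m$n_cys - 1)) {
    out <- c(out, "C", sample(alphabet, spacers[i], replace = TRUE))
  }
  paste(c(out, "C", sample(alphabet, flank, replace = TRUE)), collapse = "")
}
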