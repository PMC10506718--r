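# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed; kept below 2^31.
child_seed <- function(seed, offset) {
  (as.numeric(seed) * 7919 + 104729 * as.numeric(offset)) %% 2147483647
}

str_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

chars_str <- function(x) paste(x, collapse = "")

# Fisher-Yates shuffle of a sequence string (composition-preserving null).
shuffle_seq <- function(s) chars_str(sample(str_chars(s)))

count_char <- function(s, ch) {
  lengths(regmatches(s, gregexpr(ch, s, fixed = TRUE)))
}

# All TSVs in this package are tab-delimited UTF-8 with a '#'-prefixed header.
write_tsv_hashed <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df) > 0) {
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE, na = "NA")
  }
  invisible(path)
}

read_tsv_hashed <- function(path, colClasses = NA) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#")) {
    stop("expected '#'-prefixed header in ", path)
  }
  cols <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1]]
  df <- read.delim(path, header = FALSE, skip = 1L, sep = "\t",
                   col.names = cols, colClasses = colClasses,
                   stringsAsFactors = FALSE, comment.char = "")
  if (nrow(df) == 0) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                        stringsAsFactors = FALSE)
  }
  df
}

# BLOSUM62 restricted to the 20 standard residues plus 'X', as an integer
# matrix in a fixed row/column order (loaded once from Biostrings).
blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      m <- env$BLOSUM62
      keep <- c(AA20, "X")
      cache <<- m[keep, keep]
      storage.mode(cache) <<- "integer"
    }
    cache
  }
})

# Sample a substitute residue for `aa` from the BLOSUM62-conditional
# distribution P(b | a) proportional to q_b * 2^(s(a,b)/2), b != a.
blosum_substitute <- function(aa, n = 1L) {
  m <- blosum62_matrix()
  if (!aa %in% AA20) return(rep(aa, n))
  w <- AA_BACKGROUND * 2^(m[aa, AA20] / 2)
  w[aa] <- 0
  sample(AA20, n, replace = TRUE, prob = w / sum(w))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
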