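#' Rule-based signal peptide prediction
#'
#' A self-contained Sec/SPI-style heuristic: within the first 35 residues it
#' requires an n-region (at least one K/R in the first five residues), an
#' h-region (a window of >= 7 residues with mean Kyte-Doolittle hydropathy
#' >= 1.6) and a small-residue cleavage site \code{[AGSTC]-X-[AGST]} ending at
#' or after the h-region. An adapter table of externally predicted cleavage
#' positions overrides the heuristic wherever it has an entry.
#'
#' @param seq Amino-acid sequence string.
#' @param id Sequence id (used for adapter lookup).
#' @param adapter Optional data frame with columns \code{id},
#'   \code{sp_position} (0 = no signal peptide), e.g. parsed output of an
#'   external predictor.
#' @return The 1-based position of the last signal-peptide residue, or
#'   \code{NA} if none.
#' @export
predict_signal_peptide <- function(seq, id = NA_character_, adapter = NULL) {
  if (!is.null(adapter) && !is.na(id) && id %in% adapter$id) {
    p <- adapter$sp_position[match(id, adapter$id)]
    return(if (p == 0) NA_integer_ else as.integer(p))
  }
  L <- nchar(seq)
  win <- min(35L, L)
  x <- str_chars(substr(seq, 1, win))
  # n-region: basic residue early on
  if (!any(x[seq_len(min(5L, win))] %in% c("K", "R"))) return(NA_integer_)
  kd <- unname(KYTE_DOOLITTLE[x])
  kd[is.na(kd)] <- 0
  if (win < 10L) return(NA_integer_)
  # h-region: first 7-window with mean hydropathy >= 1.6, extended greedily
  h_start <- NA_integer_
  for (i in seq_len(win - 6L)) {
    if (mean(kd[i:(i + 6L)]) >= 1.6) { h_start <- i; break }
  }
  if (is.na(h_start)) return(NA_integer_)
  h_end <- h_start + 6L
  while (h_end + 1L <= win && kd[h_end + 1L] >= 1.6) h_end <- h_end + 1L
  # cleavage site: [AGSTC]-X-[AGST] ending at c, cleave after c
  small13 <- c("A", "G", "S", "T", "C")
  small1 <- c("A", "G", "S", "T")
  for (cpos in (h_end + 1L):win) {
    if (cpos - 2L < 1L) next
    if (cpos > win) break
    if (x[cpos - 2L] %in% small13 && x[cpos] %in% small1 && cpos < L) {
      return(as.integer(cpos))
    }
  }
  NA_integer_
}

#' Find furin propeptide cleavage sites (R-X-[KR]-R)
#'
#' @param seq Amino-acid sequence string.
#' @return Integer vector of 1-based positions of the final R of each site
#'   (cleavage occurs after this residue), ascending; empty if none.
#' @export
predict_furin_sites <- function(seq) {
  m <- gregexpr("(?=R.[KR]R)", seq, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  as.integer(m + 3L)
}

#' Derive the putative mature peptide from signal/propeptide predictions
#'
#' Removes the signal peptide, then any pro-region up to the last furin site
#' that precedes the group motif (or the last furin site overall when no
#' motif anchor is given). When no signal peptide is predicted the whole
#' sequence is retained for reporting and the result is flagged incomplete.
#'
#' @param seq Amino-acid precursor sequence.
#' @param sp Signal-peptide end position (\code{NA} = none), e.g. from
#'   \code{\link{predict_signal_peptide}}.
#' @param furin_sites Positions from \code{\link{predict_furin_sites}}.
#' @param motif_start Optional 1-based position of the group motif's first
#'   residue; only furin sites before it are applied.
#' @return \code{list(sp_cleavage, furin_sites, mature_seq,
#'   mature_glycine_pct, complete)}.
#' @export
derive_mature <- function(seq, sp = NA_integer_, furin_sites = integer(0),
                          motif_start = NA_integer_) {
  L <- nchar(seq)
  if (length(furin_sites) && !is.na(sp) && any(furin_sites <= sp)) {
    warning("furin site(s) within the signal peptide ignored")
    furin_sites <- furin_sites[furin_sites > sp]
  }
  if (is.na(sp)) {
    mature <- seq
    start <- 1L
    complete <- FALSE
  } else {
    start <- sp + 1L
    eligible <- furin_sites[furin_sites >= start &
                              (is.na(motif_start) | furin_sites < motif_start)]
    if (length(eligible)) start <- max(eligible) + 1L
    mature <- if (start <= L) substr(seq, start, L) else ""
    complete <- nchar(mature) > 0
  }
  list(sp_cleavage = sp,
       furin_sites = furin_sites,
       mature_seq = mature,
       mature_start = start,
       mature_glycine_pct = if (nchar(mature) > 0) glycine_fraction(mature) else NA_real_,
       complete = complete)
}

#' Percent glycine of a mature peptide
#'
#' Reported to two decimals; the GRSP gate is strict (\code{> 17}), so a
#' peptide at exactly 17.00 fails it.
#'
#' @param mature Non-empty amino-acid string.
#' @return Percentage, rounded to 2 decimals.
#' @export
glycine_fraction <- function(mature) {
  if (nchar(mature) < 1) stop("empty mature peptide")
  round(100 * count_char(mature, "G") / nchar(mature), 2)
}

#' Read a signal-peptide adapter TSV
#'
#' @param path TSV with '#'-prefixed header and columns \code{id},
#'   \code{sp_position} (0 = none).
#' @return Data frame usable as the \code{adapter} argument of
#'   \code{\link{predict_signal_peptide}}.
#' @export
read_sp_adapter <- function(path) {
  df <- read_tsv_hashed(path)
  stopifnot(all(c("id", "sp_position") %in% names(df)))
  df$sp_position <- as.integer(df$sp_position)
  df
}
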