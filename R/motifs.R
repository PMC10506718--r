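#' Define a cysteine-array motif
#'
#' A motif is an ordered array of \code{n_cys} cysteines with allowed residue
#' counts between consecutive cysteines (spacers) and a putative disulfide
#' connectivity (metadata only; matching uses positions and spacers).
#'
#' @param name Motif name (e.g. \code{"Diapausin"}, \code{"SaposinB"}).
#' @param n_cys Number of cysteines (>= 2).
#' @param spacers List or matrix of \code{n_cys - 1} \code{(min, max)} residue
#'   counts between consecutive cysteines.
#' @param connectivity List of 1-based cysteine index pairs (putative
#'   disulfide bonds); pairs must be disjoint and cover all cysteines when
#'   \code{n_cys} is even.
#' @param flank_before,flank_after Optional minimum number of residues
#'   required before the first / after the last cysteine (default 0).
#' @return An object of class \code{"motif_definition"}.
#' @export
motif_definition <- function(name, n_cys, spacers, connectivity = list(),
                             flank_before = 0L, flank_after = 0L) {
  sp <- do.call(rbind, lapply(spacers, as.integer))
  if (nrow(sp) != n_cys - 1 || ncol(sp) != 2) {
    stop("spacers must be ", n_cys - 1, " (min,max) pairs")
  }
  if (any(sp[, 1] > sp[, 2]) || any(sp < 0)) stop("spacer mins must be <= maxs, >= 0")
  conn <- lapply(connectivity, as.integer)
  idx <- unlist(conn)
  if (length(idx)) {
    if (anyDuplicated(idx)) stop("connectivity pairs must be disjoint")
    if (any(idx < 1 | idx > n_cys)) stop("connectivity index out of range")
    if (n_cys %% 2 == 0 && length(idx) != n_cys) {
      stop("connectivity must cover all cysteines when n_cys is even")
    }
  }
  structure(list(name = name, n_cys = as.integer(n_cys), spacers = sp,
                 connectivity = conn, flank_before = as.integer(flank_before),
                 flank_after = as.integer(flank_after)),
            class = "motif_definition")
}

#' Load motif definitions from a JSON file
#'
#' Motif arrays are shipped as editable data
#' (\code{inst/extdata/motifs.json}); every pipeline report records the file's
#' MD5 checksum so results remain auditable against the arrays used.
#'
#' @param path JSON file (default: the installed defaults).
#' @return Named list of \code{\link{motif_definition}} objects; attribute
#'   \code{"checksum"} holds the file MD5.
#' @export
load_motifs <- function(path = system.file("extdata", "motifs.json", package = "nemamp")) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  defs <- lapply(raw, function(m) {
    motif_definition(m$name, m$n_cys, m$spacers, m$connectivity %||% list(),
                     m$flank_before %||% 0L, m$flank_after %||% 0L)
  })
  names(defs) <- vapply(defs, `[[`, character(1), "name")
  attr(defs, "checksum") <- unname(tools::md5sum(path))
  defs
}

cys_positions <- function(seq) {
  which(str_chars(seq) == "C")
}

# All valid motif tuples anchored at first-cysteine position p1, by depth-first
# extension over later cysteine positions with spacer-range pruning.
tuples_from_anchor <- function(p1, cpos, m, L) {
  if (m$flank_before > 0 && (p1 - 1) < m$flank_before) return(list())
  res <- list()
  recurse <- function(tuple) {
    k <- length(tuple)
    if (k == m$n_cys) {
      if (m$flank_after > 0 && (L - tuple[k]) < m$flank_after) return()
      res[[length(res) + 1L]] <<- tuple
      return()
    }
    lo <- tuple[k] + m$spacers[k, 1] + 1L
    hi <- tuple[k] + m$spacers[k, 2] + 1L
    for (p in cpos[cpos >= lo & cpos <= hi]) recurse(c(tuple, p))
  }
  recurse(p1)
  res
}

# Leftmost-greedy reduction of candidate tuples to a non-overlapping set:
# repeatedly take the tuple with the smallest first position (ties: smallest
# span, then lexicographic), then drop tuples starting at or before its last
# cysteine.
greedy_reduce <- function(tuples) {
  out <- list()
  while (length(tuples)) {
    firsts <- vapply(tuples, `[`, integer(1), 1L)
    lasts <- vapply(tuples, function(t) t[length(t)], integer(1))
    keyord <- order(firsts, lasts - firsts,
                    vapply(tuples, function(t) paste(sprintf("%06d", t), collapse = ""),
                           character(1)))
    best <- tuples[[keyord[1]]]
    out[[length(out) + 1L]] <- best
    cut <- best[length(best)]
    tuples <- tuples[firsts > cut]
  }
  out
}

as_motif_matches <- function(tuples, m, seq_id) {
  lapply(tuples, function(t) {
    list(motif = m$name, positions = t,
         span = c(t[1], t[length(t)]), seq_id = seq_id)
  })
}

#' Find all non-overlapping occurrences of a cysteine-array motif
#'
#' Matches are tuples of cysteine positions whose consecutive spacings fall
#' within the motif's ranges. Overlapping alternatives are resolved
#' leftmost-first, then shortest span; after a match, scanning resumes after
#' its last cysteine. \code{'X'} is permitted inside spacer windows but a
#' cysteine position must hold a literal \code{'C'}.
#'
#' @param seq Amino-acid sequence string.
#' @param m A \code{\link{motif_definition}}.
#' @param seq_id Optional id recorded in the matches.
#' @return List of matches, each \code{list(motif, positions, span, seq_id)}
#'   with 1-based inclusive coordinates.
#' @export
find_motif <- function(seq, m, seq_id = NA_character_) {
  cpos <- cys_positions(seq)
  if (length(cpos) < m$n_cys) return(list())
  L <- nchar(seq)
  out <- list()
  bound <- 0L
  repeat {
    anchors <- cpos[cpos > bound]
    found <- NULL
    for (p1 in anchors) {
      tuples <- tuples_from_anchor(p1, cpos, m, L)
      if (length(tuples)) {
        lasts <- vapply(tuples, function(t) t[length(t)], integer(1))
        keyord <- order(lasts, vapply(tuples, function(t)
          paste(sprintf("%06d", t), collapse = ""), character(1)))
        found <- tuples[[keyord[1]]]
        break
      }
    }
    if (is.null(found)) break
    out[[length(out) + 1L]] <- found
    bound <- found[length(found)]
  }
  as_motif_matches(out, m, seq_id)
}

#' Brute-force motif oracle (exhaustive tuple enumeration)
#'
#' Independent reference for \code{\link{find_motif}}: enumerates every
#' strictly increasing \code{n_cys}-tuple of cysteine positions, keeps tuples
#' satisfying all spacer ranges and flank constraints, and reduces to the
#' non-overlapping leftmost-greedy set.
#'
#' @inheritParams find_motif
#' @param max_cys Combinatorial guard on the number of cysteines (default 20).
#' @return Same shape as \code{\link{find_motif}}.
#' @export
brute_force_motif_oracle <- function(seq, m, seq_id = NA_character_, max_cys = 20L) {
  cpos <- cys_positions(seq)
  if (length(cpos) > max_cys) stop("more than ", max_cys, " cysteines")
  if (length(cpos) < m$n_cys) return(list())
  L <- nchar(seq)
  combos <- utils::combn(cpos, m$n_cys, simplify = FALSE)
  ok <- Filter(function(t) {
    gaps <- diff(t) - 1L
    all(gaps >= m$spacers[, 1] & gaps <= m$spacers[, 2]) &&
      (m$flank_before == 0 || (t[1] - 1) >= m$flank_before) &&
      (m$flank_after == 0 || (L - t[m$n_cys]) >= m$flank_after)
  }, combos)
  as_motif_matches(greedy_reduce(ok), m, seq_id)
}

#' Classify a CSab sequence into a subgroup by its cysteine reference array
#'
#' Evaluates all reference arrays; exactly one matching array gives the
#' subgroup, more than one is reported as ambiguous (never silently
#' tie-broken), none as no call. No fuzzy fallback: a subgroup is only
#' returned when its array literally matches.
#'
#' @param seq Amino-acid sequence string.
#' @param reference_arrays Named list of \code{\link{motif_definition}}s, one
#'   per CSab subgroup (default: the shipped reference arrays).
#' @return \code{list(status, subgroup, match, matched_subgroups)} with
#'   \code{status} one of \code{"assigned"}, \code{"ambiguous"}, \code{"none"}.
#' @export
classify_csab <- function(seq, reference_arrays = csab_reference_arrays()) {
  hits <- lapply(reference_arrays, function(m) find_motif(seq, m))
  has <- vapply(hits, function(h) length(h) > 0, logical(1))
  matched <- names(reference_arrays)[has]
  if (length(matched) == 1) {
    list(status = "assigned", subgroup = matched,
         match = hits[[matched]][[1]], matched_subgroups = matched)
  } else if (length(matched) > 1) {
    list(status = "ambiguous", subgroup = NA_character_,
         match = NULL, matched_subgroups = matched)
  } else {
    list(status = "none", subgroup = NA_character_,
         match = NULL, matched_subgroups = character(0))
  }
}

#' The shipped CSab cysteine reference arrays
#'
#' @param motifs Motif definition list (default: the installed defaults).
#' @return Named list of the five subgroup arrays (MND, TID, Macin,
#'   Drosomycin, MND_6Cys).
#' @export
csab_reference_arrays <- function(motifs = load_motifs()) {
  motifs[CSAB_SUBGROUPS]
}

#' Count non-overlapping Saposin B domains in a sequence
#'
#' Saposin B domains are six-cysteine arrays in a specific arrangement;
#' Nemapore precursors carry one or more in tandem.
#'
#' @param seq Amino-acid sequence string.
#' @param saposin_def The Saposin B \code{\link{motif_definition}} (default:
#'   the shipped array).
#' @return Integer count (0 allowed).
#' @export
count_saposin_domains <- function(seq, saposin_def = load_motifs()[["SaposinB"]]) {
  length(find_motif(seq, saposin_def))
}
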