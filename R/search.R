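#' Build a lightweight profile model from a seed alignment
#'
#' Match states are the alignment columns with gap fraction < 0.5. Emissions
#' are observed residue counts plus a Laplace pseudocount of 1, converted to
#' log2-odds against background frequencies. Insert/delete transitions use a
#' simple fixed linear penalty (bits per inserted residue / skipped state).
#'
#' @param seed A \code{\link{seed_set}} with >= 2 aligned sequences.
#' @param background Background amino-acid frequencies (default: Robinson &
#'   Robinson).
#' @param ins_pen,del_pen Linear gap penalties in bits (default 2 each).
#' @return An object of class \code{"profile_model"}: group/subgroup labels,
#'   match-state count \code{M}, \code{M x 20} emission probabilities and
#'   log2-odds, background, transitions and match-column indices.
#' @export
build_profile <- function(seed, background = AA_BACKGROUND,
                          ins_pen = 2, del_pen = 2) {
  aln <- seed$alignment
  if (length(aln) < 2) stop("need >= 2 aligned seed sequences")
  if (length(unique(nchar(aln))) != 1) stop("alignment rows unequal length")
  mat <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-")
  match_cols <- which(gap_frac < 0.5)
  M <- length(match_cols)
  if (M < 5) stop("fewer than 5 match states")
  probs <- matrix(0, nrow = M, ncol = 20, dimnames = list(NULL, AA20))
  for (k in seq_len(M)) {
    col <- mat[, match_cols[k]]
    cnt <- table(factor(col[col %in% AA20], levels = AA20))
    p <- (as.numeric(cnt) + 1) / (sum(cnt) + 20)
    probs[k, ] <- p
  }
  logodds <- log2(sweep(probs, 2, background[AA20], "/"))
  structure(list(group = seed$group, subgroup = seed$subgroup, M = M,
                 emission_probs = probs, emissions = logodds,
                 background = background[AA20],
                 transitions = c(ins = -ins_pen, del = -del_pen),
                 match_cols = match_cols),
            class = "profile_model")
}

#' Best local profile score of a sequence, in bits
#'
#' Smith-Waterman-style local alignment over the profile's match states; the
#' score of the empty alignment is 0, and \code{'X'} residues cannot be
#' scored (an all-\code{'X'} sequence scores 0 bits).
#'
#' @param model A \code{\link{build_profile}} model.
#' @param seq Amino-acid sequence string.
#' @return Score in bits (>= 0).
#' @export
score_profile <- function(model, seq) {
  profile_align(model, seq)$score
}

#' Local profile alignment with intervals and coverage
#'
#' @inheritParams score_profile
#' @return \code{list(score, t_start, t_end, q_start, q_end, coverage)} with
#'   1-based inclusive target (\code{t}) and profile-state (\code{q})
#'   intervals; \code{coverage} = matched state span / \code{M}.
#' @export
profile_align <- function(model, seq) {
  r <- .profile_align_cpp(seq, model$emissions, paste(AA20, collapse = ""),
                          -model$transitions[["ins"]], -model$transitions[["del"]])
  r$coverage <- if (r$q_end >= r$q_start) (r$q_end - r$q_start + 1) / model$M else 0
  r
}

#' Calibrate a Gumbel E-value function for a profile model
#'
#' Fits Gumbel parameters by the method of moments to the scores of \code{n}
#' composition-preserving shuffled decoys of fixed length drawn from the
#' database, giving \code{E(s) = K * db_size * exp(-lambda * s)} (expected
#' chance hits at score >= s in a database of \code{db_size} residues).
#'
#' @param model A \code{\link{build_profile}} model.
#' @param db Protein record data frame the decoys are drawn from.
#' @param db_size Database size in residues (default: total residues in
#'   \code{db}).
#' @param n Number of shuffled decoys (default 200).
#' @param len Decoy length (default 150).
#' @param seed RNG seed.
#' @return An object of class \code{"evalue_model"}: \code{lambda}, \code{K},
#'   \code{mu}, \code{db_size}, and \code{evalue(s)} / usable via
#'   \code{\link{evalue}}.
#' @export
calibrate_evalue <- function(model, db, db_size = sum(db$length),
                             n = 200, len = 150, seed = 1) {
  scores <- with_seed(seed, {
    picks <- sample(nrow(db), n, replace = TRUE)
    decoys <- vapply(picks, function(i) {
      s <- str_chars(db$sequence[i])
      if (length(s) >= len) {
        start <- sample(length(s) - len + 1L, 1L)
        chars_str(sample(s[start:(start + len - 1L)]))
      } else {
        chars_str(sample(s, len, replace = TRUE))
      }
    }, character(1))
    .profile_scores_cpp(decoys, model$emissions, paste(AA20, collapse = ""),
                        -model$transitions[["ins"]], -model$transitions[["del"]])
  })
  if (sd(scores) < 1e-8) stop("degenerate decoy score variance")
  lambda <- pi / (sd(scores) * sqrt(6))
  mu <- mean(scores) - 0.57721566 / lambda
  K <- exp(lambda * mu) / len
  structure(list(lambda = lambda, K = K, mu = mu, db_size = db_size,
                 n = n, len = len, decoy_scores = scores),
            class = "evalue_model")
}

#' Evaluate an E-value model at one or more scores
#'
#' @param em An \code{"evalue_model"} from \code{\link{calibrate_evalue}} or
#'   \code{\link{calibrate_pairwise}}.
#' @param s Score(s).
#' @param db_size Optional override of the database size (E is linear in it).
#' @return E-value(s), strictly decreasing in \code{s}.
#' @export
evalue <- function(em, s, db_size = em$db_size) {
  em$K * db_size * exp(-em$lambda * s)
}

#' Smith-Waterman local alignment with BLOSUM62 and affine gaps
#'
#' Exhaustive dynamic programming (no seeding heuristics) with the BLOSUM62
#' scoring matrix and affine gap costs (open 11, extend 1; a gap of length k
#' costs 11 + k). Traceback is deterministic: the highest-scoring cell wins,
#' ties resolved to the smallest (row, column).
#'
#' @param a,b Amino-acid sequence strings.
#' @param gap_open,gap_ext Gap open/extension costs (defaults 11, 1).
#' @return \code{list(score, a_start, a_end, b_start, b_end)} with 1-based
#'   inclusive intervals; score 0 and empty intervals when no positive-scoring
#'   local alignment exists.
#' @export
align_local <- function(a, b, gap_open = 11L, gap_ext = 1L) {
  .sw_align_cpp(a, b, blosum62_matrix(), paste(c(AA20, "X"), collapse = ""),
                as.integer(gap_open), as.integer(gap_ext))
}

# Score-only SW of one query against many targets.
sw_scores <- function(a, targets, gap_open = 11L, gap_ext = 1L) {
  .sw_scores_cpp(a, targets, blosum62_matrix(), paste(c(AA20, "X"), collapse = ""),
                 as.integer(gap_open), as.integer(gap_ext))
}

#' Calibrate a pooled Gumbel E-value model for pairwise searches
#'
#' Same moment fit as \code{\link{calibrate_evalue}}, applied to the maximal
#' Smith-Waterman score of each shuffled decoy against a sample of query
#' sequences. Used by iterative expansion and the GRSP reciprocal check.
#'
#' @param queries Character vector of query sequences.
#' @param db Protein record data frame.
#' @param db_size,n,len,seed As in \code{\link{calibrate_evalue}}.
#' @param max_queries Cap on the number of queries scored per decoy.
#' @return An \code{"evalue_model"}.
#' @export
calibrate_pairwise <- function(queries, db, db_size = sum(db$length),
                               n = 200, len = 150, seed = 1, max_queries = 10) {
  qs <- with_seed(child_seed(seed, 17), {
    if (length(queries) > max_queries) sample(queries, max_queries) else queries
  })
  scores <- with_seed(seed, {
    picks <- sample(nrow(db), n, replace = TRUE)
    decoys <- vapply(picks, function(i) {
      s <- str_chars(db$sequence[i])
      if (length(s) >= len) chars_str(sample(s)[seq_len(len)])
      else chars_str(sample(s, len, replace = TRUE))
    }, character(1))
    vapply(decoys, function(d) max(sw_scores(d, qs)), numeric(1))
  })
  if (sd(scores) < 1e-8) stop("degenerate decoy score variance")
  lambda <- pi / (sd(scores) * sqrt(6))
  mu <- mean(scores) - 0.57721566 / lambda
  K <- exp(lambda * mu) / len
  structure(list(lambda = lambda, K = K, mu = mu, db_size = db_size,
                 n = n, len = len, decoy_scores = scores),
            class = "evalue_model")
}

#' Iterative homology query expansion to convergence
#'
#' Starting from a set of confirmed ids, repeatedly uses newly accepted hits
#' as queries against the database until no new results are retrieved (a
#' fixed point; monotone and guaranteed to terminate on a finite database).
#'
#' @param seed_ids Ids of the initial confirmed set (must exist in \code{db}).
#' @param db Protein record data frame.
#' @param accept Pure predicate: \code{accept(record_row)} -> logical (the
#'   group acceptance rule).
#' @param similar Function \code{similar(query_seqs, target_df)} returning a
#'   logical vector: is each target similar to at least one query.
#' @param max_rounds Safety cap; exceeded -> returned with
#'   \code{converged = FALSE}.
#' @return \code{list(ids, rounds, converged)}; \code{ids} sorted.
#' @export
iterative_expand <- function(seed_ids, db, accept, similar, max_rounds = 10L) {
  stopifnot(all(seed_ids %in% db$id))
  S <- unique(seed_ids)
  new_queries <- S
  rounds <- 0L
  converged <- TRUE
  while (length(new_queries) > 0) {
    if (rounds >= max_rounds) { converged <- FALSE; break }
    cand <- db[!db$id %in% S, , drop = FALSE]
    if (nrow(cand) == 0) break
    qseqs <- db$sequence[match(new_queries, db$id)]
    sim <- similar(qseqs, cand)
    hits <- cand[sim, , drop = FALSE]
    if (nrow(hits) > 0) {
      ok <- vapply(seq_len(nrow(hits)), function(i) isTRUE(accept(hits[i, ])),
                   logical(1))
      hits <- hits$id[ok]
    } else {
      hits <- character(0)
    }
    if (length(hits) == 0) break
    rounds <- rounds + 1L
    S <- union(S, hits)
    new_queries <- hits
  }
  list(ids = sort(S), rounds = rounds, converged = converged)
}

#' GRSP reciprocal top-5 check
#'
#' Aligns a candidate against a labelled reference database and sorts hits by
#' E-value ascending (ties: higher bit score first, then lexicographic id).
#' The candidate passes if at least one known GRSP appears within the first
#' five scorable hits.
#'
#' @param candidate_seq Candidate amino-acid sequence.
#' @param refs Reference data frame with columns \code{id}, \code{sequence},
#'   \code{is_grsp} (logical).
#' @param em Optional \code{"evalue_model"} used to attach E-values; ranking
#'   is by E (monotone in score).
#' @param top_n Number of top hits examined (default 5).
#' @return \code{list(pass, top)} where \code{top} is the ranked head of the
#'   hit table.
#' @export
reciprocal_top5 <- function(candidate_seq, refs, em = NULL, top_n = 5L) {
  if (is.null(refs) || nrow(refs) == 0) stop("empty reference database")
  stopifnot(all(c("id", "sequence", "is_grsp") %in% names(refs)))
  scores <- sw_scores(candidate_seq, refs$sequence)
  ev <- if (!is.null(em)) evalue(em, scores) else exp(-scores)
  tab <- data.frame(id = refs$id, bits = scores, evalue = ev,
                    is_grsp = refs$is_grsp, stringsAsFactors = FALSE)
  tab <- tab[tab$bits > 0, , drop = FALSE]
  tab <- tab[order(tab$evalue, -tab$bits, tab$id), , drop = FALSE]
  top <- head(tab, top_n)
  list(pass = any(top$is_grsp), top = top)
}

#' Read external search-engine hits from an adapter TSV
#'
#' Lets users substitute HMMER/BLAST tabular output for the in-repo engines;
#' columns map onto the same hit schema (1-based inclusive target interval).
#'
#' @param path TSV with '#'-prefixed header and columns \code{query_ref},
#'   \code{target_id}, \code{bits}, \code{evalue}, \code{tstart}, \code{tend}.
#' @return Validated hit data frame.
#' @export
read_hits_adapter <- function(path) {
  df <- read_tsv_hashed(path)
  need <- c("query_ref", "target_id", "bits", "evalue", "tstart", "tend")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("missing column(s): ", paste(missing, collapse = ", "))
  for (cl in c("bits", "evalue")) df[[cl]] <- as.numeric(df[[cl]])
  for (cl in c("tstart", "tend")) df[[cl]] <- as.integer(df[[cl]])
  if (any(df$evalue <= 0)) stop("evalue must be > 0")
  df[need]
}
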