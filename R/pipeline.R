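#' Pipeline configuration
#'
#' Gates and thresholds for candidate intake and acceptance. Defaults follow
#' the study design: profile-search intake at E < 0.01 for
#' Cecropin/Diapausin/CSab/Nemapore and E <= 10 for the glycine-rich GRSPs;
#' "high peptide similarity" for Cecropins is operationalized as alignment
#' coverage >= 60\% of the profile length (an interpretation, recorded in
#' every run report); GRSP authenticity requires precursor <= 200 aa, a
#' signal peptide, mature glycine > 17\% (strict) and the reciprocal top-5
#' check.
#'
#' @param e_gate Intake E-value gate for the four non-GRSP groups.
#' @param grsp_e_gate Intake E-value gate for GRSPs.
#' @param coverage_min Minimum profile coverage for Cecropin acceptance.
#' @param grsp_max_len Maximum GRSP precursor length (aa).
#' @param grsp_gly_min Strict lower bound on mature glycine percent.
#' @param expand_max_rounds Cap on iterative-expansion rounds.
#' @param calib_n,calib_len Decoy count/length for E-value calibration.
#' @param seed RNG seed for calibration decoys.
#' @return A list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(e_gate = 0.01, grsp_e_gate = 10,
                            coverage_min = 0.6, grsp_max_len = 200L,
                            grsp_gly_min = 17, expand_max_rounds = 10L,
                            calib_n = 200L, calib_len = 150L, seed = 1L) {
  structure(list(e_gate = e_gate, grsp_e_gate = grsp_e_gate,
                 coverage_min = coverage_min, grsp_max_len = grsp_max_len,
                 grsp_gly_min = grsp_gly_min,
                 expand_max_rounds = as.integer(expand_max_rounds),
                 calib_n = as.integer(calib_n), calib_len = as.integer(calib_len),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Strip the predicted signal peptide from a query before pairwise search:
# Sec signal peptides are near-degenerate hydrophobic runs, and unmasked
# they dominate local alignments between unrelated secreted precursors.
mask_signal_peptide <- function(seq) {
  sp <- predict_signal_peptide(seq)
  if (is.na(sp) || sp >= nchar(seq)) seq else substr(seq, sp + 1L, nchar(seq))
}

# Does this id carry any annotated domain other than Saposin B?
has_extra_domain <- function(id, domains) {
  if (is.null(domains) || nrow(domains) == 0) return(FALSE)
  any(domains$id == id & domains$domain != "SaposinB")
}

#' Cecropin acceptance rule: similarity only
#'
#' Cecropin hits are accepted on similarity to the queries alone: intake
#' E-value below the gate and profile coverage at or above the threshold (no
#' motif requirement).
#'
#' @param ev Intake E-value of the hit.
#' @param coverage Profile coverage of the hit alignment.
#' @param config A \code{\link{pipeline_config}}.
#' @return \code{list(accept, checks)} with named logical \code{checks}.
#' @export
rule_cecropin <- function(ev, coverage, config = pipeline_config()) {
  checks <- c(evalue = ev < config$e_gate,
              coverage = coverage >= config$coverage_min)
  list(accept = all(checks), checks = checks)
}

#' Motif-group acceptance rule (CSab, Diapausin, Nemapore)
#'
#' Accepts a gated hit iff the group's conserved cysteine motif is present:
#' CSab requires any reference array (classification recorded; ambiguity is
#' reported, never tie-broken), Diapausin its six-cysteine array, Nemapore at
#' least one Saposin B domain and, additionally, no annotated non-Saposin
#' domain (excluding SAPLIPs with likely other functions).
#'
#' @param group \code{"CSab"}, \code{"Diapausin"} or \code{"Nemapore"}.
#' @param seq Full precursor sequence.
#' @param id Sequence id (domain-table lookup).
#' @param motifs Motif definitions.
#' @param domains Optional domain annotation table (\code{id}, \code{domain},
#'   \code{start}, \code{end}).
#' @return \code{list(accept, checks, subgroup, status, matches, n_motifs,
#'   n_saposin_domains)}.
#' @export
rule_motif_group <- function(group, seq, id, motifs, domains = NULL) {
  group <- match.arg(group, c("CSab", "Diapausin", "Nemapore"))
  subgroup <- NA_character_
  status <- NA_character_
  matches <- list()
  n_dom <- 0L
  if (group == "Diapausin") {
    matches <- find_motif(seq, motifs$Diapausin, seq_id = id)
    checks <- c(motif = length(matches) > 0)
  } else if (group == "CSab") {
    cls <- classify_csab(seq, motifs[CSAB_SUBGROUPS])
    status <- cls$status
    subgroup <- cls$subgroup
    if (!is.null(cls$match)) matches <- list(cls$match)
    checks <- c(motif = cls$status != "none")
  } else {
    matches <- find_motif(seq, motifs$SaposinB, seq_id = id)
    n_dom <- length(matches)
    checks <- c(motif = n_dom >= 1,
                no_extra_domain = !has_extra_domain(id, domains))
  }
  list(accept = all(checks), checks = checks, subgroup = subgroup,
       status = status, matches = matches, n_motifs = length(matches),
       n_saposin_domains = n_dom)
}

#' GRSP acceptance rule
#'
#' A gated GRSP hit is authentic iff the precursor is <= 200 amino acids,
#' carries a predicted signal peptide, has mature glycine content strictly
#' above 17\% (computed after signal-peptide removal), and passes the
#' reciprocal top-5 check against the labelled reference database.
#'
#' @param seq Full precursor sequence.
#' @param id Sequence id.
#' @param refs Reference database for \code{\link{reciprocal_top5}}.
#' @param config A \code{\link{pipeline_config}}.
#' @param sp_adapter Optional signal-peptide adapter table.
#' @param em Optional pairwise E-value model for reciprocal ranking.
#' @return \code{list(accept, checks, sp_end, mature, gly)}.
#' @export
rule_grsp <- function(seq, id, refs, config = pipeline_config(),
                      sp_adapter = NULL, em = NULL) {
  sp <- predict_signal_peptide(seq, id = id, adapter = sp_adapter)
  len_ok <- nchar(seq) <= config$grsp_max_len
  sp_ok <- !is.na(sp)
  gly <- if (sp_ok && sp < nchar(seq)) {
    glycine_fraction(substr(seq, sp + 1L, nchar(seq)))
  } else if (!sp_ok) {
    glycine_fraction(seq)
  } else NA_real_
  gly_ok <- !is.na(gly) && gly > config$grsp_gly_min
  rec_ok <- if (len_ok && sp_ok && gly_ok) {
    reciprocal_top5(seq, refs, em = em)$pass
  } else {
    # evaluated anyway so decoy diagnostics can localize the failing rule
    tryCatch(reciprocal_top5(seq, refs, em = em)$pass, error = function(e) FALSE)
  }
  checks <- c(length = len_ok, signal_peptide = sp_ok,
              glycine = gly_ok, reciprocal = rec_ok)
  list(accept = all(checks), checks = checks,
       sp_end = if (sp_ok) sp else NA_integer_, gly = gly)
}

# Profile search of one group (possibly several subgroup profiles) against
# the database; returns per-protein best E, bits and coverage for gated ids.
profile_search_group <- function(profiles, proteins, config) {
  alpha <- paste(AA20, collapse = "")
  best_ev <- rep(Inf, nrow(proteins))
  best_bits <- rep(0, nrow(proteins))
  best_model <- rep(NA_integer_, nrow(proteins))
  for (pi in seq_along(profiles)) {
    model <- profiles[[pi]]
    em <- calibrate_evalue(model, proteins, n = config$calib_n,
                           len = config$calib_len,
                           seed = child_seed(config$seed, pi))
    scores <- .profile_scores_cpp(proteins$sequence, model$emissions, alpha,
                                  -model$transitions[["ins"]],
                                  -model$transitions[["del"]])
    ev <- evalue(em, scores)
    upd <- ev < best_ev
    best_ev[upd] <- ev[upd]
    best_bits[upd] <- scores[upd]
    best_model[upd] <- pi
  }
  cov <- rep(NA_real_, nrow(proteins))
  gate <- if (profiles[[1]]$group == "GRSP") config$grsp_e_gate else config$e_gate
  gated <- which(best_ev <= gate)
  for (i in gated) {
    cov[i] <- profile_align(profiles[[best_model[i]]],
                            proteins$sequence[i])$coverage
  }
  data.frame(id = proteins$id, evalue = best_ev, bits = best_bits,
             coverage = cov, stringsAsFactors = FALSE)
}

#' Run the AMP discovery pipeline end-to-end
#'
#' Per group: profile search with Gumbel-calibrated E-values, E-gate intake,
#' group-specific acceptance rules, iterative query expansion with the same
#' rule to convergence, CSab subgroup classification, maturation, and the
#' candidate table. The run report logs counts per stage, rounds to
#' convergence, the motif-file checksum, a config echo, and an audit pass
#' re-validating every accepted candidate's evidence. Deterministic given
#' \code{config$seed}.
#'
#' @param proteins Protein record data frame (the concatenated database).
#' @param seeds Seed-set list from \code{\link{load_seed_sets}}.
#' @param motifs Motif definitions from \code{\link{load_motifs}}.
#' @param domains Optional domain annotation table.
#' @param sp_adapter Optional signal-peptide adapter table.
#' @param config A \code{\link{pipeline_config}}.
#' @return \code{list(candidates, report)}.
#' @export
run_pipeline <- function(proteins, seeds = load_seed_sets(),
                         motifs = load_motifs(), domains = NULL,
                         sp_adapter = NULL, config = pipeline_config()) {
  if (is.null(proteins) || nrow(proteins) == 0) stop("empty proteome database")
  if (is.null(motifs)) stop("missing motif definitions")
  seed_groups <- vapply(seeds, `[[`, character(1), "group")
  refs <- do.call(rbind, lapply(seeds, function(s) {
    data.frame(id = s$records$id, sequence = s$records$sequence,
               is_grsp = s$group == "GRSP", stringsAsFactors = FALSE)
  }))
  rows <- list()
  report <- list(groups = list(),
                 motif_checksum = attr(motifs, "checksum") %||% NA_character_,
                 config = unclass(config))
  for (grp in AMP_GROUPS) {
    grp_seeds <- seeds[seed_groups == grp]
    profiles <- lapply(grp_seeds, build_profile)
    hits <- profile_search_group(profiles, proteins, config)
    gate <- if (grp == "GRSP") config$grsp_e_gate else config$e_gate
    intake <- hits[hits$evalue <= gate, , drop = FALSE]
    if (grp != "GRSP") intake <- intake[intake$evalue < gate, , drop = FALSE]
    accept_fun <- make_accept_fun(grp, motifs, domains, refs, config, sp_adapter)
    ok <- vapply(seq_len(nrow(intake)), function(i) {
      row <- proteins[match(intake$id[i], proteins$id), ]
      accept_fun(row, ev = intake$evalue[i], coverage = intake$coverage[i])
    }, logical(1))
    accepted_ids <- intake$id[ok]
    # iterative expansion with the same rule
    exp_res <- list(ids = sort(accepted_ids), rounds = 0L, converged = TRUE)
    if (length(accepted_ids) > 0) {
      qseqs0 <- vapply(proteins$sequence[match(accepted_ids, proteins$id)],
                       mask_signal_peptide, character(1), USE.NAMES = FALSE)
      pem <- calibrate_pairwise(qseqs0, proteins, n = config$calib_n,
                                len = config$calib_len,
                                seed = child_seed(config$seed, 7 + match(grp, AMP_GROUPS)))
      similar <- function(qseqs, cand) {
        hit <- rep(FALSE, nrow(cand))
        for (q in qseqs) {
          sc <- sw_scores(mask_signal_peptide(q), cand$sequence)
          hit <- hit | (evalue(pem, sc) < config$e_gate)
        }
        hit
      }
      accept_exp <- function(row) {
        accept_fun(row, ev = 0, coverage = 1, expansion = TRUE)
      }
      exp_res <- iterative_expand(accepted_ids, proteins, accept_exp, similar,
                                  max_rounds = config$expand_max_rounds)
    }
    final_ids <- exp_res$ids
    for (cid in final_ids) {
      row <- proteins[match(cid, proteins$id), ]
      h <- hits[match(cid, hits$id), ]
      rows[[length(rows) + 1L]] <-
        candidate_row(row, grp, h, motifs, domains, refs, config, sp_adapter,
                      stage = if (cid %in% accepted_ids) "profile" else "expansion")
    }
    report$groups[[grp]] <- list(
      n_db = nrow(proteins), n_intake = nrow(intake),
      n_rule_pass = length(accepted_ids), n_final = length(final_ids),
      rounds = exp_res$rounds, converged = exp_res$converged)
  }
  cands <- if (length(rows)) do.call(rbind, rows) else empty_candidates()
  # cross-group flags: a protein matching two groups is reported once per
  # group with a flag, never silently deduplicated
  dup <- cands$id[duplicated(cands$id)]
  if (length(dup)) {
    flag <- cands$id %in% dup
    cands$accepted_by[flag] <- paste0(cands$accepted_by[flag], ";cross_group")
  }
  report$cross_group_ids <- sort(unique(dup))
  report$audit_pass <- audit_candidates(cands, proteins, motifs, domains,
                                        refs, config, sp_adapter)
  list(candidates = cands, report = report)
}

empty_candidates <- function() {
  cols <- candidate_columns()
  out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  out$complete <- logical(0)
  for (cl in c("evalue", "bits", "coverage", "mature_glycine_pct"))
    out[[cl]] <- numeric(0)
  for (cl in c("n_motifs", "n_saposin_domains", "sp_end")) out[[cl]] <- integer(0)
  out
}

# Acceptance closure for one group; `expansion = TRUE` skips the intake-E
# component (expansion hits were gated by pairwise similarity instead).
make_accept_fun <- function(grp, motifs, domains, refs, config, sp_adapter) {
  function(row, ev, coverage, expansion = FALSE) {
    if (grp == "Cecropin") {
      if (expansion) return(TRUE)
      rule_cecropin(ev, coverage, config)$accept
    } else if (grp == "GRSP") {
      rule_grsp(row$sequence, row$id, refs, config, sp_adapter)$accept
    } else {
      rule_motif_group(grp, row$sequence, row$id, motifs, domains)$accept
    }
  }
}

candidate_row <- function(row, grp, h, motifs, domains, refs, config,
                          sp_adapter, stage) {
  seq <- row$sequence
  subgroup <- NA_character_
  motif_name <- NA_character_
  motif_span <- NA_character_
  n_motifs <- 0L
  n_dom <- 0L
  accepted_by <- character(0)
  motif_start <- NA_integer_
  if (grp == "Cecropin") {
    accepted_by <- c("evalue", "coverage")
  } else if (grp == "GRSP") {
    accepted_by <- c("evalue", "length", "signal_peptide", "glycine", "reciprocal")
  } else {
    r <- rule_motif_group(grp, seq, row$id, motifs, domains)
    subgroup <- if (grp == "CSab") {
      if (r$status == "ambiguous") "ambiguous" else r$subgroup
    } else NA_character_
    if (length(r$matches)) {
      m1 <- r$matches[[1]]
      motif_name <- m1$motif
      motif_span <- paste(vapply(r$matches, function(m)
        paste0(m$span[1], "-", m$span[2]), character(1)), collapse = ",")
      motif_start <- m1$span[1]
    }
    n_motifs <- r$n_motifs
    n_dom <- r$n_saposin_domains
    accepted_by <- c("evalue", names(r$checks)[r$checks])
  }
  sp <- predict_signal_peptide(seq, id = row$id, adapter = sp_adapter)
  furin <- predict_furin_sites(seq)
  mat <- suppressWarnings(derive_mature(seq, sp, furin, motif_start = motif_start))
  complete <- mat$complete && (grp %in% c("Cecropin", "GRSP") || n_motifs >= 1)
  data.frame(id = row$id, genome_id = row$genome_id, species = row$species,
             group = grp, subgroup = subgroup, complete = complete,
             evalue = h$evalue, bits = h$bits,
             coverage = ifelse(is.na(h$coverage), 0, h$coverage),
             motif = motif_name, motif_span = motif_span,
             n_motifs = n_motifs, n_saposin_domains = n_dom,
             sp_end = ifelse(is.na(sp), 0L, sp),
             furin_sites = paste(furin, collapse = ","),
             mature_seq = mat$mature_seq,
             mature_glycine_pct = mat$mature_glycine_pct,
             accepted_by = paste(accepted_by, collapse = ";"),
             stage = stage, stringsAsFactors = FALSE)
}

# Re-validate every accepted candidate's stored evidence against the rules.
audit_candidates <- function(cands, proteins, motifs, domains, refs, config,
                             sp_adapter) {
  if (nrow(cands) == 0) return(TRUE)
  all(vapply(seq_len(nrow(cands)), function(i) {
    row <- proteins[match(cands$id[i], proteins$id), ]
    grp <- cands$group[i]
    if (grp == "Cecropin") {
      cands$stage[i] == "expansion" ||
        (cands$evalue[i] < config$e_gate && cands$coverage[i] >= config$coverage_min)
    } else if (grp == "GRSP") {
      rule_grsp(row$sequence, row$id, refs, config, sp_adapter)$accept
    } else {
      r <- rule_motif_group(grp, row$sequence, row$id, motifs, domains)
      r$accept && r$n_motifs == cands$n_motifs[i]
    }
  }, logical(1)))
}

#' Re-scan null genomes with relatives' accepted candidates as queries
#'
#' For each (genome, group) with zero candidates, re-runs a pairwise search
#' of that genome's proteins using the neighbouring genome's accepted
#' candidates as queries (protein level only). New hits must still pass the
#' group rule to be flagged \code{"rescued"}; genomes with no passing hit are
#' flagged \code{"confirmed_null"}.
#'
#' @param result A \code{\link{run_pipeline}} result.
#' @param proteins Protein record data frame.
#' @param neighbor_map Data frame with columns \code{genome_id},
#'   \code{neighbor_id}.
#' @param motifs,domains,config,sp_adapter,seeds As in \code{\link{run_pipeline}}.
#' @return Data frame: \code{genome_id}, \code{group}, \code{status},
#'   \code{rescued_ids}.
#' @export
relatives_rescan <- function(result, proteins, neighbor_map,
                             seeds = load_seed_sets(), motifs = load_motifs(),
                             domains = NULL, config = pipeline_config(),
                             sp_adapter = NULL) {
  cands <- result$candidates
  refs <- do.call(rbind, lapply(seeds, function(s) {
    data.frame(id = s$records$id, sequence = s$records$sequence,
               is_grsp = s$group == "GRSP", stringsAsFactors = FALSE)
  }))
  out <- list()
  genomes <- unique(proteins$genome_id)
  for (g in genomes) {
    nb <- neighbor_map$neighbor_id[match(g, neighbor_map$genome_id)]
    for (grp in AMP_GROUPS) {
      n_here <- sum(cands$genome_id == g & cands$group == grp)
      if (n_here > 0) next
      queries <- cands[cands$genome_id %in% nb & cands$group == grp, ]
      rescued <- character(0)
      if (!is.na(nb) && nrow(queries) > 0) {
        targets <- proteins[proteins$genome_id == g, , drop = FALSE]
        pem <- calibrate_pairwise(
          vapply(proteins$sequence[match(queries$id, proteins$id)],
                 mask_signal_peptide, character(1), USE.NAMES = FALSE), proteins,
          n = config$calib_n, len = config$calib_len,
          seed = child_seed(config$seed, 31 + match(grp, AMP_GROUPS)))
        accept_fun <- make_accept_fun(grp, motifs, domains, refs, config, sp_adapter)
        for (qid in queries$id) {
          qseq <- mask_signal_peptide(proteins$sequence[match(qid, proteins$id)])
          sc <- sw_scores(qseq, targets$sequence)
          hit_idx <- which(evalue(pem, sc) < config$e_gate)
          for (i in hit_idx) {
            row <- targets[i, ]
            if (accept_fun(row, ev = 0, coverage = 1, expansion = TRUE)) {
              rescued <- union(rescued, row$id)
            }
          }
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        genome_id = g, group = grp,
        status = if (length(rescued)) "rescued" else "confirmed_null",
        rescued_ids = paste(sort(rescued), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Compare a candidate table against planted ground truth
#'
#' @param candidates Candidate table from \code{\link{run_pipeline}}.
#' @param truth Truth table from \code{\link{generate_study}}.
#' @return \code{list(sensitivity, fdr, per_group, n_tp, n_fp, n_planted)}
#'   pooled over all groups.
#' @export
evaluate_against_truth <- function(candidates, truth) {
  planted <- truth[truth$planted_group %in% AMP_GROUPS, ]
  key <- function(id, grp) paste(id, grp, sep = "\r")
  cand_keys <- unique(key(candidates$id, candidates$group))
  truth_keys <- key(planted$id, planted$planted_group)
  n_tp <- sum(truth_keys %in% cand_keys)
  n_fp <- sum(!cand_keys %in% truth_keys)
  per_group <- lapply(setNames(AMP_GROUPS, AMP_GROUPS), function(g) {
    tk <- truth_keys[planted$planted_group == g]
    ck <- cand_keys[grepl(paste0("\r", g, "$"), cand_keys)]
    list(sensitivity = if (length(tk)) mean(tk %in% ck) else NA_real_,
         fdr = if (length(ck)) mean(!ck %in% tk) else 0,
         n_candidates = length(ck), n_planted = length(tk))
  })
  list(sensitivity = n_tp / nrow(planted),
       fdr = if (length(cand_keys)) n_fp / length(cand_keys) else 0,
       per_group = per_group, n_tp = n_tp, n_fp = n_fp,
       n_planted = nrow(planted))
}

#' Species-by-group presence/absence matrix
#'
#' @param candidates Candidate table.
#' @param meta Species metadata.
#' @return 0/1 integer matrix, species as rows, the five groups as columns.
#' @export
presence_absence <- function(candidates, meta) {
  m <- matrix(0L, nrow = nrow(meta), ncol = length(AMP_GROUPS),
              dimnames = list(meta$species, AMP_GROUPS))
  for (i in seq_len(nrow(candidates))) {
    sp <- meta$species[match(candidates$genome_id[i], meta$genome_id)]
    m[sp, candidates$group[i]] <- 1L
  }
  m
}

#' Export an all-vs-all candidate similarity edge list (CLANS-input style)
#'
#' @param candidates Candidate table.
#' @param proteins Protein record data frame.
#' @param config A \code{\link{pipeline_config}}.
#' @return Data frame \code{id1}, \code{id2}, \code{evalue} for all unordered
#'   candidate pairs with a positive local alignment score.
#' @export
edge_list <- function(candidates, proteins, config = pipeline_config()) {
  ids <- unique(candidates$id)
  seqs <- proteins$sequence[match(ids, proteins$id)]
  if (length(ids) < 2) {
    return(data.frame(id1 = character(0), id2 = character(0),
                      evalue = numeric(0)))
  }
  pem <- calibrate_pairwise(seqs, proteins, n = config$calib_n,
                            len = config$calib_len,
                            seed = child_seed(config$seed, 53))
  out <- list()
  for (i in seq_len(length(ids) - 1L)) {
    sc <- sw_scores(seqs[i], seqs[(i + 1L):length(ids)])
    pos <- which(sc > 0)
    if (length(pos)) {
      out[[length(out) + 1L]] <- data.frame(
        id1 = ids[i], id2 = ids[i + pos],
        evalue = evalue(pem, sc[pos]), stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(id1 = character(0), id2 = character(0), evalue = numeric(0))
}
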