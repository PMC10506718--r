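# Synthetic study generator: proteomes with planted AMPs of every group,
# decoys that each violate exactly one acceptance rule, species metadata,
# ground-truth and domain tables, and a life-stage TPM matrix.

# Residue pools used when composing synthetic regions. The GRSP / linker
# pools avoid hydrophobic residues so no spurious signal-peptide h-region
# can arise, and avoid 'C' so no spurious cysteine arrays can arise.
POOL_HYDROPHILIC <- c("G", "S", "N", "Q", "Y", "E", "D", "T", "K", "R", "P", "H")
POOL_LINKER <- c("S", "T", "N", "Q", "G", "P", "E", "K", "D")
# Non-glycine residues of glycine-rich matures, matching the residue usage
# of the curated GRSP seed family (planted members stay in the family's
# compositional basin).
POOL_GRSP_SPACER <- c("Y", "N", "S", "Q", "E", "K", "T", "D")

#' Default configuration for the synthetic study
#'
#' The defaults define the study conditions used throughout the package's
#' validation: 6 genomes, 500 decoy proteins per genome, 10 planted AMPs per
#' group per genome, a 10\% per-residue substitution rate on seed-derived
#' regions, 2\% of decoys per hard-decoy class, and an expressed fraction of
#' 0.86 (at least one life stage at >= 2 TPM) among planted genes.
#'
#' @param seed Master seed; per-genome streams are derived at fixed offsets.
#' @param n_genomes,n_decoys_per_genome,planted_per_group Corpus sizes.
#' @param mutation_rate Per-residue substitution probability on seed-derived
#'   planted regions (BLOSUM62-conditional; in [0, 0.5]).
#' @param hard_decoy_fractions Named fractions of
#'   \code{n_decoys_per_genome} for the four targeted decoy classes.
#' @param expressed_fraction Fraction of planted genes given >= 1 stage at
#'   >= 2 TPM (exact counting, not sampling).
#' @param stages Life-stage labels for the TPM table.
#' @param truncate_fraction Fraction of planted motif-group AMPs emitted
#'   without their signal peptide (emulating incomplete gene models).
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 7L, n_genomes = 6L, n_decoys_per_genome = 500L,
                       planted_per_group = 10L, mutation_rate = 0.1,
                       hard_decoy_fractions = c(glycine_rich_long = 0.02,
                                                glycine_rich_no_sp = 0.02,
                                                saplip_extra_domain = 0.02,
                                                cys_rich_wrong_spacing = 0.02),
                       expressed_fraction = 0.86,
                       stages = c("egg", "L1", "L3", "adult_male", "adult_female"),
                       truncate_fraction = 0) {
  if (length(planted_per_group) == 1 && is.null(names(planted_per_group))) {
    planted_per_group <- setNames(rep(as.integer(planted_per_group),
                                      length(AMP_GROUPS)), AMP_GROUPS)
  } else {
    stopifnot(setequal(names(planted_per_group), AMP_GROUPS))
    planted_per_group <- as.integer(planted_per_group[AMP_GROUPS])
    names(planted_per_group) <- AMP_GROUPS
  }
  stopifnot(mutation_rate >= 0, mutation_rate <= 0.5,
            n_genomes >= 1, n_decoys_per_genome >= 0,
            all(planted_per_group >= 0),
            all(hard_decoy_fractions >= 0), sum(hard_decoy_fractions) <= 1,
            expressed_fraction >= 0, expressed_fraction <= 1)
  structure(list(seed = as.integer(seed), n_genomes = as.integer(n_genomes),
                 n_decoys_per_genome = as.integer(n_decoys_per_genome),
                 planted_per_group = planted_per_group,
                 mutation_rate = mutation_rate,
                 hard_decoy_fractions = hard_decoy_fractions,
                 expressed_fraction = expressed_fraction,
                 stages = stages,
                 truncate_fraction = truncate_fraction),
            class = "sim_config")
}

# Canonical synthetic signal peptide: M + n-region (>= 1 K/R in the first
# five residues), h-region of >= 7 hydrophobic residues (A excluded so the
# A-X-A cleavage site is unambiguous), A-X-A cleavage. Returns seq + end.
make_signal_peptide <- function() {
  n_extra <- sample(0:2, 1)
  n_region <- c(sample(c("K", "R"), 1),
                if (n_extra > 0) sample(c("N", "Q", "E", "D", "P"), n_extra,
                                        replace = TRUE))
  h_region <- sample(c("L", "V", "I", "F"), sample(7:9, 1), replace = TRUE)
  cleave <- c("A", sample(c("S", "N", "Q"), 1), "A")
  sp <- c("M", n_region, h_region, cleave)
  list(seq = chars_str(sp), sp_end = length(sp))
}

# Optional furin-cleaved pro-region ending in R-X-K-R.
make_proregion <- function() {
  body <- sample(POOL_LINKER, sample(3:6, 1), replace = TRUE)
  chars_str(c(body, "R", sample(c("S", "N", "A"), 1), "K", "R"))
}

mutate_residues <- function(chars, rate, protect = rep(FALSE, length(chars))) {
  hit <- runif(length(chars)) < rate & !protect & chars %in% AA20
  for (i in which(hit)) {
    sub <- blosum_substitute(chars[i])
    chars[i] <- if (sub == "C") "S" else sub
  }
  chars
}

# Resize a spacer segment to `target` residues: insertions sample from the
# segment's own residues (fallback: linker pool), deletions are random.
# 'C' is never introduced.
resize_segment <- function(seg_chars, target) {
  pool <- seg_chars[seg_chars != "C"]
  if (length(pool) == 0) pool <- POOL_LINKER
  while (length(seg_chars) < target) {
    ins <- sample(pool, 1)
    pos <- sample(length(seg_chars) + 1L, 1)
    seg_chars <- append(seg_chars, ins, after = pos - 1L)
  }
  while (length(seg_chars) > target) {
    seg_chars <- seg_chars[-sample(length(seg_chars), 1)]
  }
  seg_chars
}

# Mature region of a seed record (after its signal peptide).
seed_mature <- function(rec_row) {
  sp <- predict_signal_peptide(rec_row$sequence)
  if (is.na(sp)) stop("seed sequence without detectable signal peptide: ", rec_row$id)
  substr(rec_row$sequence, sp + 1L, nchar(rec_row$sequence))
}

# Build a mature region carrying the motif: a seed's mature region with each
# inter-cysteine spacer redrawn uniformly within the motif's range (or
# overridden) and non-cysteine positions mutated at `rate`.
synth_motif_mature <- function(seed, motif, rate, spacer_override = NULL,
                               core_only = FALSE) {
  rec <- seed$records[sample(nrow(seed$records), 1), , drop = FALSE]
  mature <- seed_mature(rec)
  mm <- find_motif(mature, motif)
  if (length(mm) == 0) stop("seed mature region lacks its own motif")
  p <- mm[[1]]$positions
  mchars <- str_chars(mature)
  pre <- if (p[1] > 1) mchars[1:(p[1] - 1)] else character(0)
  post <- if (p[length(p)] < length(mchars)) mchars[(p[length(p)] + 1L):length(mchars)] else character(0)
  segs <- lapply(seq_len(length(p) - 1L), function(i) {
    if (p[i + 1L] - p[i] > 1L) mchars[(p[i] + 1L):(p[i + 1L] - 1L)] else character(0)
  })
  targets <- vapply(seq_along(segs), function(i) {
    if (!is.null(spacer_override) && !is.na(spacer_override[i])) {
      as.integer(spacer_override[i])
    } else {
      sample(motif$spacers[i, 1]:motif$spacers[i, 2], 1)
    }
  }, integer(1))
  segs <- Map(resize_segment, segs, targets)
  core <- character(0)
  for (i in seq_along(segs)) core <- c(core, "C", segs[[i]])
  core <- c(core, "C")
  out <- if (core_only) core else c(pre, core, post)
  protect <- out == "C"
  chars_str(mutate_residues(out, rate, protect))
}

# Glycine-rich mature region with glycine fraction drawn U(0.20, 0.60).
# GRSPs are repeat-structured, so glycines are laid down as GG/G blocks
# interleaved with hydrophilic spacer tokens (no spurious h-region, no
# cysteines) rather than scattered uniformly.
synth_grsp_mature <- function(len = NULL) {
  L <- if (is.null(len)) sample(40:120, 1) else len
  g <- runif(1, 0.20, 0.60)
  n_g <- max(round(g * L), ceiling(0.18 * L))
  blocks <- c(rep(list(c("G", "G")), floor(n_g / 2)),
              if (n_g %% 2 == 1) list("G"))
  n_other <- L - n_g
  others <- sample(POOL_GRSP_SPACER, n_other, replace = TRUE)
  # split the non-G residues into roughly as many spacer tokens as G blocks
  grp_idx <- sort(sample(seq_len(max(length(blocks), 1)), n_other, replace = TRUE))
  spacers <- unname(split(others, grp_idx))
  out <- character(0)
  for (i in seq_len(max(length(blocks), length(spacers)))) {
    if (i <= length(blocks)) out <- c(out, blocks[[i]])
    if (i <= length(spacers)) out <- c(out, spacers[[i]])
  }
  chars_str(out[seq_len(L)])
}

truth_row <- function(id, genome_id, group, subgroup = NA_character_,
                      n_dom = 0L, has_sp = FALSE, sp_end = 0L, gly = NA_real_,
                      length = NA_integer_) {
  data.frame(id = id, genome_id = genome_id, planted_group = group,
             planted_subgroup = subgroup, n_saposin_domains = as.integer(n_dom),
             has_signal_peptide = has_sp, sp_end = as.integer(sp_end),
             mature_glycine_pct = gly, length = as.integer(length),
             stringsAsFactors = FALSE)
}

#' Plant one synthetic AMP of a given group
#'
#' Composes a canonical signal peptide, an optional furin-cleaved pro-region,
#' and a mature region carrying the group's defining feature: Cecropin = a
#' BLOSUM62-mutated copy of a seed mature region; Diapausin/CSab/Nemapore =
#' the group's cysteine array with spacers drawn uniformly within the
#' configured ranges on a seed-derived scaffold; GRSP = a glycine-rich mature
#' region (glycine fraction U(0.20, 0.60)) with total length <= 200.
#'
#' Uses the caller's RNG stream; seed it for reproducibility.
#'
#' @param group One of the five AMP groups.
#' @param subgroup CSab subgroup (required for CSab).
#' @param seeds Seed-set list from \code{\link{load_seed_sets}}.
#' @param motifs Motif definitions from \code{\link{load_motifs}}.
#' @param cfg A \code{\link{sim_config}}.
#' @param id,genome_id Identifiers for the emitted record.
#' @param n_domains Number of Saposin B domains (Nemapore; default 1-3).
#' @param truncate Drop the signal peptide (incomplete gene model).
#' @return \code{list(record, truth, domains)}: a one-row protein record, a
#'   one-row truth table, and zero or more domain annotation rows.
#' @export
plant_amp <- function(group, subgroup = NA_character_, seeds, motifs, cfg,
                      id = "amp1", genome_id = "G1", n_domains = NULL,
                      truncate = FALSE) {
  group <- match.arg(group, AMP_GROUPS)
  sp <- make_signal_peptide()
  rate <- cfg$mutation_rate
  domains <- NULL
  if (group == "Cecropin") {
    rec <- seeds$cecropin$records[sample(nrow(seeds$cecropin$records), 1), , drop = FALSE]
    mature <- chars_str(mutate_residues(str_chars(seed_mature(rec)), rate))
    pro <- if (runif(1) < 0.5) make_proregion() else ""
    body <- paste0(pro, mature)
  } else if (group == "Diapausin") {
    body <- synth_motif_mature(seeds$diapausin, motifs$Diapausin, rate)
  } else if (group == "CSab") {
    subgroup <- match.arg(subgroup, CSAB_SUBGROUPS)
    set_name <- paste0("csab_", tolower(sub("_", "", subgroup)))
    set_name <- c(MND = "csab_mnd", TID = "csab_tid", Macin = "csab_macin",
                  Drosomycin = "csab_drosomycin", MND_6Cys = "csab_mnd6cys")[subgroup]
    body <- synth_motif_mature(seeds[[set_name]], motifs[[subgroup]], rate)
  } else if (group == "Nemapore") {
    nd <- if (is.null(n_domains)) sample(1:3, 1) else as.integer(n_domains)
    pre <- sample(POOL_LINKER, sample(3:6, 1), replace = TRUE)
    parts <- chars_str(pre)
    dom_spans <- list()
    for (k in seq_len(nd)) {
      dom <- synth_motif_mature(seeds$nemapore, motifs$SaposinB, rate,
                                core_only = TRUE)
      start <- nchar(parts) + 1L
      parts <- paste0(parts, dom)
      dom_spans[[k]] <- c(start, nchar(parts))
      if (k < nd) {
        parts <- paste0(parts, chars_str(sample(POOL_LINKER, sample(4:8, 1),
                                                replace = TRUE)))
      }
    }
    body <- parts
  } else { # GRSP
    body <- synth_grsp_mature()
  }
  seq <- if (truncate) body else paste0(sp$seq, body)
  sp_end <- if (truncate) 0L else sp$sp_end
  rec <- protein_records(id, seq, genome_id = genome_id)
  gly <- glycine_fraction(body)
  if (group == "Nemapore") {
    offset <- if (truncate) 0L else sp$sp_end
    domains <- do.call(rbind, lapply(dom_spans, function(s) {
      data.frame(id = id, domain = "SaposinB",
                 start = s[1] + offset, end = s[2] + offset,
                 stringsAsFactors = FALSE)
    }))
  }
  nd_out <- if (group == "Nemapore") length(dom_spans) else 0L
  list(record = rec,
       truth = truth_row(id, genome_id, group, subgroup, nd_out,
                         has_sp = !truncate, sp_end = sp_end, gly = gly,
                         length = nchar(seq)),
       domains = domains)
}

#' Construct a decoy protein of a named class
#'
#' \code{random} decoys are background-frequency sequences. Each hard-decoy
#' class violates exactly one acceptance rule and no other:
#' \code{glycine_rich_long} (GRSP-like but 250 aa), \code{glycine_rich_no_sp}
#' (GRSP-like, no signal peptide), \code{saplip_extra_domain} (one Saposin B
#' domain plus an annotated extra domain), \code{cys_rich_wrong_spacing}
#' (Diapausin-like with one spacer at range max + 3).
#'
#' Uses the caller's RNG stream; seed it for reproducibility.
#'
#' @param kind Decoy class.
#' @inheritParams plant_amp
#' @return As \code{\link{plant_amp}}.
#' @export
make_decoy <- function(kind = c("random", "glycine_rich_long",
                                "glycine_rich_no_sp", "saplip_extra_domain",
                                "cys_rich_wrong_spacing"),
                       seeds, motifs, cfg, id = "dec1", genome_id = "G1") {
  kind <- match.arg(kind)
  domains <- NULL
  if (kind == "random") {
    L <- sample(80:300, 1)
    seq <- chars_str(sample(AA20, L, replace = TRUE, prob = AA_BACKGROUND))
    if (!startsWith(seq, "M")) seq <- paste0("M", substr(seq, 2, L))
    rec <- protein_records(id, seq, genome_id = genome_id)
    return(list(record = rec,
                truth = truth_row(id, genome_id, "decoy", length = nchar(seq)),
                domains = NULL))
  }
  label <- "hard_decoy"
  if (kind == "glycine_rich_long") {
    sp <- make_signal_peptide()
    body <- synth_grsp_mature(len = 250L - sp$sp_end)
    seq <- paste0(sp$seq, body)
    truth <- truth_row(id, genome_id, label, kind, has_sp = TRUE,
                       sp_end = sp$sp_end, gly = glycine_fraction(body),
                       length = nchar(seq))
  } else if (kind == "glycine_rich_no_sp") {
    body <- synth_grsp_mature()
    seq <- paste0("M", body)
    truth <- truth_row(id, genome_id, label, kind, has_sp = FALSE,
                       gly = glycine_fraction(body), length = nchar(seq))
  } else if (kind == "saplip_extra_domain") {
    sp <- make_signal_peptide()
    dom <- synth_motif_mature(seeds$nemapore, motifs$SaposinB,
                              cfg$mutation_rate, core_only = TRUE)
    pre <- chars_str(sample(POOL_LINKER, 4, replace = TRUE))
    tail_len <- 80L
    tail_seq <- chars_str(sample(setdiff(AA20, "C"), tail_len, replace = TRUE))
    seq <- paste0(sp$seq, pre, dom, tail_seq)
    dstart <- sp$sp_end + nchar(pre) + 1L
    dend <- dstart + nchar(dom) - 1L
    domains <- data.frame(id = rep(id, 2),
                          domain = c("SaposinB", "PeptidaseM12"),
                          start = c(dstart, dend + 5L),
                          end = c(dend, dend + 70L),
                          stringsAsFactors = FALSE)
    truth <- truth_row(id, genome_id, label, kind, n_dom = 1L, has_sp = TRUE,
                       sp_end = sp$sp_end, length = nchar(seq))
  } else { # cys_rich_wrong_spacing
    sp <- make_signal_peptide()
    m <- motifs$Diapausin
    override <- rep(NA_integer_, m$n_cys - 1L)
    bad <- sample(m$n_cys - 1L, 1)
    override[bad] <- m$spacers[bad, 2] + 3L
    body <- synth_motif_mature(seeds$diapausin, m, cfg$mutation_rate,
                               spacer_override = override)
    seq <- paste0(sp$seq, body)
    truth <- truth_row(id, genome_id, label, kind, has_sp = TRUE,
                       sp_end = sp$sp_end, gly = glycine_fraction(body),
                       length = nchar(seq))
  }
  rec <- protein_records(id, seq, genome_id = genome_id)
  list(record = rec, truth = truth, domains = domains)
}

#' Generate the full synthetic study corpus
#'
#' Deterministic given \code{cfg$seed}: per-genome RNG streams are derived at
#' fixed offsets from the master seed. Produces per-genome proteomes with
#' planted AMPs of every group, decoys (including the four hard-decoy
#' classes), species metadata, ground truth, domain annotations, and a
#' life-stage TPM table in which an exact \code{expressed_fraction} of
#' planted genes has at least one stage at >= 2 TPM.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @param seeds,motifs Seed sets and motif definitions (defaults: shipped
#'   fixtures).
#' @param out_dir Optional directory; when given, writes
#'   \code{proteomes/<genome>.fasta}, \code{meta.tsv}, \code{truth.tsv},
#'   \code{domains.tsv} and \code{tpm.tsv}.
#' @return \code{list(proteins, meta, truth, domains, tpm)}.
#' @export
generate_study <- function(cfg = sim_config(), seeds = load_seed_sets(),
                           motifs = load_motifs(), out_dir = NULL) {
  clades <- rep(c("9/V", "10/IV", "2/I", "8/III", "12/IV", "9/V"),
                length.out = cfg$n_genomes)
  lifestyles <- rep(c("FLN", "APN", "PPN", "EPN", "FLN", "APN"),
                    length.out = cfg$n_genomes)
  all_rec <- list(); all_truth <- list(); all_dom <- list(); meta <- list()
  hard_counts <- round(cfg$hard_decoy_fractions * cfg$n_decoys_per_genome)
  for (gi in seq_len(cfg$n_genomes)) {
    gid <- paste0("G", gi)
    with_seed(child_seed(cfg$seed, gi), {
      # planted AMPs, cycling CSab subgroups
      for (grp in AMP_GROUPS) {
        for (j in seq_len(cfg$planted_per_group[[grp]])) {
          sub <- if (grp == "CSab") CSAB_SUBGROUPS[(j - 1L) %% 5L + 1L] else NA_character_
          trunc <- grp %in% c("Diapausin", "CSab", "Nemapore") &&
            runif(1) < cfg$truncate_fraction
          id <- sprintf("%s_AMP_%s_%03d", gid, tolower(grp), j)
          p <- plant_amp(grp, sub, seeds, motifs, cfg, id = id,
                         genome_id = gid, truncate = trunc)
          all_rec[[length(all_rec) + 1L]] <- p$record
          all_truth[[length(all_truth) + 1L]] <- p$truth
          if (!is.null(p$domains)) all_dom[[length(all_dom) + 1L]] <- p$domains
        }
      }
      # decoys: hard classes first, then random
      di <- 0L
      for (kind in names(hard_counts)) {
        for (j in seq_len(hard_counts[[kind]])) {
          di <- di + 1L
          d <- make_decoy(kind, seeds, motifs, cfg,
                          id = sprintf("%s_DEC_%04d", gid, di), genome_id = gid)
          all_rec[[length(all_rec) + 1L]] <- d$record
          all_truth[[length(all_truth) + 1L]] <- d$truth
          if (!is.null(d$domains)) all_dom[[length(all_dom) + 1L]] <- d$domains
        }
      }
      while (di < cfg$n_decoys_per_genome) {
        di <- di + 1L
        d <- make_decoy("random", seeds, motifs, cfg,
                        id = sprintf("%s_DEC_%04d", gid, di), genome_id = gid)
        all_rec[[length(all_rec) + 1L]] <- d$record
        all_truth[[length(all_truth) + 1L]] <- d$truth
      }
      n_prot <- sum(cfg$planted_per_group) + cfg$n_decoys_per_genome
      meta[[gi]] <- data.frame(
        genome_id = gid, species = paste0("Synthetica sp", gi),
        clade = clades[gi], lifestyle = lifestyles[gi],
        pcg_count = n_prot, busco_complete = round(runif(1, 85, 99.9), 1),
        stringsAsFactors = FALSE)
    })
  }
  proteins <- do.call(rbind, all_rec)
  truth <- do.call(rbind, all_truth)
  domains <- if (length(all_dom)) do.call(rbind, all_dom) else
    data.frame(id = character(0), domain = character(0),
               start = integer(0), end = integer(0))
  meta <- do.call(rbind, meta)
  proteins$species <- meta$species[match(proteins$genome_id, meta$genome_id)]
  tpm <- synth_tpm(truth, cfg)
  out <- list(proteins = proteins, meta = meta, truth = truth,
              domains = domains, tpm = tpm)
  if (!is.null(out_dir)) write_study(out, out_dir)
  out
}

# Life-stage TPM table for planted genes: an exact expressed_fraction gets
# one high stage (U(5, 500)); everything else stays below 2 TPM.
synth_tpm <- function(truth, cfg) {
  planted <- truth$id[truth$planted_group %in% AMP_GROUPS]
  n <- length(planted)
  ns <- length(cfg$stages)
  m <- matrix(0, nrow = n, ncol = ns, dimnames = list(planted, cfg$stages))
  with_seed(child_seed(cfg$seed, 999), {
    m[] <- round(runif(n * ns, 0, 1.9), 3)
    n_expr <- round(cfg$expressed_fraction * n)
    expressed <- sample(planted, n_expr)
    for (g in expressed) {
      m[g, sample(ns, 1)] <- round(runif(1, 5, 500), 3)
    }
  })
  m
}

write_study <- function(study, out_dir) {
  dir.create(file.path(out_dir, "proteomes"), recursive = TRUE, showWarnings = FALSE)
  for (gid in unique(study$proteins$genome_id)) {
    write_fasta(study$proteins[study$proteins$genome_id == gid, ],
                file.path(out_dir, "proteomes", paste0(gid, ".fasta")))
  }
  write_tsv_hashed(study$meta, file.path(out_dir, "meta.tsv"))
  write_tsv_hashed(study$truth, file.path(out_dir, "truth.tsv"))
  write_tsv_hashed(study$domains, file.path(out_dir, "domains.tsv"))
  tpm_df <- data.frame(gene_id = rownames(study$tpm), study$tpm,
                       check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_hashed(tpm_df, file.path(out_dir, "tpm.tsv"))
  invisible(out_dir)
}
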