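#' Read a protein FASTA file into a protein record table
#'
#' Parses a FASTA file of amino-acid sequences into a data frame of protein
#' records. The id is the header token before the first whitespace; sequences
#' are uppercased, a terminal stop codon \code{'*'} is stripped, and the
#' ambiguity codes \code{U}, \code{B} and \code{Z} are mapped to \code{'X'}
#' (with a warning), so the resulting alphabet is the 20 standard residues
#' plus \code{'X'}.
#'
#' @param path Path to a FASTA file.
#' @param species,genome_id Optional provenance labels attached to every
#'   record (defaults: \code{NA}).
#' @return A data frame with columns \code{id}, \code{species},
#'   \code{genome_id}, \code{sequence}, \code{length}.
#' @export
read_fasta <- function(path, species = NA_character_, genome_id = NA_character_) {
  stopifnot(file.exists(path))
  aa <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*$", "", seqs)
  protein_records(ids, seqs, species = species, genome_id = genome_id)
}

#' Construct a validated protein record table
#'
#' @param ids Character vector of unique ids.
#' @param sequences Character vector of amino-acid sequences (same length).
#' @param species,genome_id Provenance labels (scalars or vectors).
#' @return Data frame of protein records (see \code{\link{read_fasta}}).
#' @export
protein_records <- function(ids, sequences, species = NA_character_,
                            genome_id = NA_character_) {
  stopifnot(length(ids) == length(sequences))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sequences <- toupper(sequences)
  if (any(nchar(sequences) == 0)) {
    stop("empty sequence for id(s): ",
         paste(ids[nchar(sequences) == 0], collapse = ", "))
  }
  if (any(grepl("[UBZ]", sequences))) {
    warning("residues U/B/Z mapped to 'X'")
    sequences <- gsub("[UBZ]", "X", sequences)
  }
  bad <- grepl(sprintf("[^%sX]", paste(AA20, collapse = "")), sequences)
  if (any(bad)) {
    stop("invalid residues in sequence(s): ", paste(ids[bad], collapse = ", "))
  }
  data.frame(id = as.character(ids),
             species = rep_len(as.character(species), length(ids)),
             genome_id = rep_len(as.character(genome_id), length(ids)),
             sequence = sequences,
             length = nchar(sequences),
             stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records Protein record data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::BStringSet(records$sequence)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read the species metadata table
#'
#' Validated per-genome metadata: clade, lifestyle, protein-coding gene count
#' and BUSCO completeness, as carried alongside each proteome.
#'
#' @param path TSV with a '#'-prefixed header and columns \code{genome_id},
#'   \code{species}, \code{clade}, \code{lifestyle}, \code{pcg_count},
#'   \code{busco_complete}.
#' @return Validated data frame.
#' @export
read_species_meta <- function(path) {
  df <- read_tsv_hashed(path)
  validate_species_meta(df)
}

validate_species_meta <- function(df) {
  need <- c("genome_id", "species", "clade", "lifestyle",
            "pcg_count", "busco_complete")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("missing column(s): ", paste(missing, collapse = ", "))
  df$pcg_count <- suppressWarnings(as.numeric(df$pcg_count))
  df$busco_complete <- suppressWarnings(as.numeric(df$busco_complete))
  if (anyNA(df$pcg_count)) stop("non-numeric pcg_count")
  if (any(df$pcg_count < 1)) stop("pcg_count must be >= 1")
  bad <- !df$lifestyle %in% LIFESTYLES
  if (any(bad)) {
    stop("unknown lifestyle label(s): ",
         paste(unique(df$lifestyle[bad]), collapse = ", "))
  }
  if (anyNA(df$busco_complete) || any(df$busco_complete < 0 | df$busco_complete > 100)) {
    stop("busco_complete must be in [0, 100]")
  }
  df[need]
}

#' Read a gene-by-stage TPM expression table
#'
#' @param path TSV with a '#'-prefixed header: first column gene id, remaining
#'   columns numeric life-stage TPM values.
#' @return A numeric matrix (genes x stages) with gene ids as rownames and
#'   stage ids as colnames, preserving file order.
#' @export
read_tpm <- function(path) {
  df <- read_tsv_hashed(path)
  if (ncol(df) < 2) stop("TPM table needs a gene column plus >=1 stage column")
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) stop("non-numeric or missing TPM value")
  if (any(m < 0)) stop("negative TPM value")
  rownames(m) <- genes
  m
}

#' Write an AMP candidate table to TSV
#'
#' One row per candidate; motif coordinates are serialized 1-based inclusive
#' as \code{"start-end"}. Round-trips through \code{\link{read_candidates}}.
#'
#' @param cands Candidate data frame (as produced by \code{\link{run_pipeline}}).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_candidates <- function(cands, path) {
  cols <- candidate_columns()
  if (is.null(cands) || nrow(cands) == 0) {
    empty <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    return(write_tsv_hashed(empty, path))
  }
  out <- cands[, cols]
  write_tsv_hashed(out, path)
}

candidate_columns <- function() {
  c("id", "genome_id", "species", "group", "subgroup", "complete",
    "evalue", "bits", "coverage", "motif", "motif_span", "n_motifs",
    "n_saposin_domains", "sp_end", "furin_sites", "mature_seq",
    "mature_glycine_pct", "accepted_by", "stage")
}

#' Read an AMP candidate table written by \code{\link{write_candidates}}
#'
#' @param path Candidate TSV path.
#' @return Candidate data frame with numeric/logical columns restored.
#' @export
read_candidates <- function(path) {
  df <- read_tsv_hashed(path)
  if (nrow(df) == 0) {
    for (cl in c("complete")) df[[cl]] <- logical(0)
    for (cl in c("evalue", "bits", "coverage", "mature_glycine_pct"))
      df[[cl]] <- numeric(0)
    for (cl in c("n_motifs", "n_saposin_domains", "sp_end"))
      df[[cl]] <- integer(0)
    return(df[candidate_columns()])
  }
  df$complete <- as.logical(df$complete)
  for (cl in c("evalue", "bits", "coverage", "mature_glycine_pct"))
    df[[cl]] <- as.numeric(df[[cl]])
  for (cl in c("n_motifs", "n_saposin_domains", "sp_end"))
    df[[cl]] <- as.integer(df[[cl]])
  for (cl in c("subgroup", "motif", "motif_span", "furin_sites",
               "mature_seq", "accepted_by", "stage"))
    df[[cl]] <- as.character(df[[cl]])
  df[candidate_columns()]
}

#' Construct a seed set (curated queries plus their multiple alignment)
#'
#' @param group One of the five AMP groups.
#' @param records Protein record data frame of the seed sequences.
#' @param alignment Named character vector of equal-length gapped rows whose
#'   ungapped forms equal the seed sequences.
#' @param subgroup Optional subgroup label.
#' @return An object of class \code{"seed_set"}.
#' @export
seed_set <- function(group, records, alignment, subgroup = NA_character_) {
  group <- match.arg(group, AMP_GROUPS)
  if (length(unique(nchar(alignment))) != 1) {
    stop("alignment rows must have equal length")
  }
  ungapped <- gsub("-", "", alignment, fixed = TRUE)
  ord <- match(records$id, names(alignment))
  if (anyNA(ord)) stop("alignment is missing seed id(s)")
  if (!all(ungapped[ord] == records$sequence)) {
    stop("ungapped alignment rows must equal the seed sequences")
  }
  structure(list(group = group, subgroup = subgroup,
                 records = records, alignment = alignment),
            class = "seed_set")
}

#' Load the synthetic curated seed sets shipped with the package
#'
#' The seed fixtures are small synthetic stand-ins for curated AMP query
#' sets: one FASTA plus one aligned FASTA per seed set under
#' \code{inst/extdata/seeds/} (one set per group; one per subgroup for CSab).
#'
#' @param dir Directory of seed fixtures (default: the installed fixtures).
#' @return Named list of \code{\link{seed_set}} objects.
#' @export
load_seed_sets <- function(dir = system.file("extdata", "seeds", package = "nemamp")) {
  sets <- list(
    cecropin = list("Cecropin", NA_character_),
    diapausin = list("Diapausin", NA_character_),
    csab_mnd = list("CSab", "MND"),
    csab_tid = list("CSab", "TID"),
    csab_macin = list("CSab", "Macin"),
    csab_drosomycin = list("CSab", "Drosomycin"),
    csab_mnd6cys = list("CSab", "MND_6Cys"),
    nemapore = list("Nemapore", NA_character_),
    grsp = list("GRSP", NA_character_))
  out <- list()
  for (nm in names(sets)) {
    base <- file.path(dir, paste0(nm, "_synthetic"))
    rec <- read_fasta(paste0(base, ".fasta"))
    aln <- Biostrings::readBStringSet(paste0(base, "_aln.fasta"))
    aln <- setNames(toupper(as.character(aln)),
                    vapply(strsplit(names(aln), "\\s+"), `[`, character(1), 1L))
    out[[nm]] <- seed_set(sets[[nm]][[1]], rec, aln, subgroup = sets[[nm]][[2]])
  }
  out
}
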