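# Life-stage expression calls and heatmap matrices.

#' Call genes expressed at a TPM threshold
#'
#' A gene is expressed iff its maximum over life stages reaches the
#' threshold, inclusive (>= 2 TPM by default): a gene peaking at exactly
#' 2.00 is expressed, at 1.99 it is not.
#'
#' @param mat TPM matrix (genes x stages), e.g. from \code{\link{read_tpm}}.
#' @param threshold Expression cut-off in TPM (default 2).
#' @return Named logical vector, one flag per gene.
#' @export
call_expressed <- function(mat, threshold = 2) {
  apply(mat, 1, max) >= threshold
}

#' Row-standardized log TPM matrix with clustering order
#'
#' TPM values are transformed as log2(TPM + 1) and converted per row to Z
#' values using the sample standard deviation (n - 1); constant rows get
#' z = 0 and are flagged rather than dropped. Rows are ordered by
#' agglomerative average-linkage clustering on Euclidean distances of the z
#' rows (deterministic for a fixed input).
#'
#' @param mat TPM matrix with >= 2 genes and >= 2 stages.
#' @return \code{list(z, row_order, constant_rows, merge, height)}:
#'   the z matrix, the leaf-order permutation, flags for constant rows, and
#'   the linkage merge table with heights.
#' @export
heatmap_matrix <- function(mat) {
  if (nrow(mat) < 2) stop("need >= 2 genes")
  if (ncol(mat) < 2) stop("need >= 2 stages")
  x <- log2(mat + 1)
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  constant <- s < .Machine$double.eps^0.5
  z <- (x - mu) / ifelse(constant, 1, s)
  z[constant, ] <- 0
  hc <- hclust(dist(z), method = "average")
  list(z = z, row_order = hc$order, constant_rows = constant,
       merge = hc$merge, height = hc$height)
}

#' Per-species expression summaries of AMP genes
#'
#' Counts, per species, how many identified AMP genes have at least one life
#' stage at or above the threshold, plus the pooled fraction across species.
#' Candidate ids missing from a species' expression matrix are counted
#' unexpressed with a warning; species with zero AMP genes are excluded with
#' a note.
#'
#' @param mats Named list of TPM matrices, one per species.
#' @param candidates Candidate table; \code{species} selects the matrix.
#' @param threshold Expression cut-off in TPM (default 2).
#' @return \code{list(per_species, pooled_fraction)}; \code{per_species} has
#'   columns \code{species}, \code{n_amp_genes}, \code{n_expressed},
#'   \code{fraction_expressed}.
#' @export
summarize_expression <- function(mats, candidates, threshold = 2) {
  out <- list()
  n_expr_tot <- 0L
  n_tot <- 0L
  for (sp in names(mats)) {
    ids <- unique(candidates$id[candidates$species == sp])
    if (length(ids) == 0) {
      message("species with zero AMP genes excluded: ", sp)
      next
    }
    m <- mats[[sp]]
    known <- ids[ids %in% rownames(m)]
    if (length(known) < length(ids)) {
      warning(length(ids) - length(known),
              " candidate id(s) missing from expression matrix for ", sp,
              "; counted unexpressed")
    }
    n_expr <- if (length(known)) {
      sum(call_expressed(m[known, , drop = FALSE], threshold))
    } else 0L
    out[[length(out) + 1L]] <- data.frame(
      species = sp, n_amp_genes = length(ids), n_expressed = n_expr,
      fraction_expressed = n_expr / length(ids), stringsAsFactors = FALSE)
    n_expr_tot <- n_expr_tot + n_expr
    n_tot <- n_tot + length(ids)
  }
  list(per_species = if (length(out)) do.call(rbind, out) else NULL,
       pooled_fraction = if (n_tot > 0) n_expr_tot / n_tot else NA_real_)
}
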