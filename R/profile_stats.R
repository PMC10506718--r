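# Repertoire statistics: per-genome tallies, relative abundance,
# lifestyle/clade aggregation and the nonparametric tests.

#' Per-genome AMP repertoire tallies
#'
#' Counts complete and incomplete candidates per group for every genome in
#' the metadata (genomes with zero candidates get all-zero rows) and the
#' relative abundance as a percentage of AMP genes relative to total
#' protein-coding genes per genome.
#'
#' @param candidates Candidate table from \code{\link{run_pipeline}}.
#' @param meta Species metadata (\code{\link{read_species_meta}}).
#' @return Data frame: \code{genome_id}, one count column per group,
#'   \code{total_amp}, \code{pcg_count}, \code{rel_abundance}.
#' @export
tally <- function(candidates, meta) {
  unknown <- setdiff(candidates$genome_id, meta$genome_id)
  if (length(unknown)) {
    stop("candidate(s) with unknown genome_id: ", paste(unknown, collapse = ", "))
  }
  out <- data.frame(genome_id = meta$genome_id, stringsAsFactors = FALSE)
  for (g in AMP_GROUPS) {
    out[[g]] <- vapply(meta$genome_id, function(gid) {
      sum(candidates$genome_id == gid & candidates$group == g)
    }, numeric(1))
  }
  out$total_amp <- rowSums(out[AMP_GROUPS])
  out$pcg_count <- meta$pcg_count
  out$rel_abundance <- 100 * out$total_amp / out$pcg_count
  rownames(out) <- NULL
  out
}

#' Group summaries (mean +/- SEM) by lifestyle or clade
#'
#' SEM uses the sample standard deviation (n - 1); a group of a single
#' genome gets SEM 0 with an explicit \code{n1_flag} rather than being
#' dropped.
#'
#' @param profiles Output of \code{\link{tally}}.
#' @param meta Species metadata.
#' @param by \code{"lifestyle"} or \code{"clade"}.
#' @return Data frame: grouping label, \code{n}, \code{mean_amp},
#'   \code{sem_amp}, \code{mean_rel_abundance}, \code{sem_rel_abundance},
#'   \code{n1_flag}.
#' @export
summarize_profiles <- function(profiles, meta, by = c("lifestyle", "clade")) {
  by <- match.arg(by)
  lab <- meta[[by]][match(profiles$genome_id, meta$genome_id)]
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  out <- lapply(sort(unique(lab)), function(l) {
    tot <- profiles$total_amp[lab == l]
    rel <- profiles$rel_abundance[lab == l]
    data.frame(group = l, n = length(tot),
               mean_amp = mean(tot), sem_amp = sem(tot),
               mean_rel_abundance = mean(rel), sem_rel_abundance = sem(rel),
               n1_flag = length(tot) == 1, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Lilliefors statistic: one-sample KS distance against the normal with
# estimated mean/sd, computed on sorted data.
lilliefors_stat <- function(x) {
  n <- length(x)
  z <- pnorm(sort(x), mean = mean(x), sd = sd(x))
  i <- seq_len(n)
  max(pmax(i / n - z, z - (i - 1) / n))
}

.lilliefors_null_cache <- new.env(parent = emptyenv())

lilliefors_null <- function(n, mc_reps, seed) {
  key <- paste(n, mc_reps, seed, sep = "_")
  if (!is.null(.lilliefors_null_cache[[key]])) return(.lilliefors_null_cache[[key]])
  null <- with_seed(seed, {
    vapply(seq_len(mc_reps), function(i) lilliefors_stat(rnorm(n)), numeric(1))
  })
  .lilliefors_null_cache[[key]] <- null
  null
}

#' Normality test (Lilliefors-corrected Kolmogorov-Smirnov)
#'
#' One-sample KS against a normal with estimated mean and sd; because the
#' parameters are estimated, the p-value comes from a seeded Monte-Carlo
#' null of the same sample size (the null table is cached per (n, reps)).
#'
#' @param values Numeric vector, n >= 5.
#' @param mc_reps Monte-Carlo replicates (default 10000).
#' @param seed Seed for the null simulation.
#' @return \code{list(statistic, p_value, n)}.
#' @export
ks_normality <- function(values, mc_reps = 10000L, seed = 101L) {
  if (length(values) < 5) stop("need n >= 5")
  if (sd(values) < .Machine$double.eps^0.5) stop("zero variance")
  d <- lilliefors_stat(values)
  null <- lilliefors_null(length(values), mc_reps, seed)
  list(statistic = d, p_value = (1 + sum(null >= d)) / (mc_reps + 1),
       n = length(values))
}

#' Kruskal-Wallis test with Dunn's multiple comparisons
#'
#' Overall H (tie-corrected, via \code{stats::kruskal.test}) with chi-square
#' p on k - 1 df, followed by Dunn z-tests on pooled mean ranks for every
#' pair, with Bonferroni adjustment by default (configurable to Sidak or
#' none).
#'
#' @param groups List of >= 2 numeric vectors (each n >= 2).
#' @param adjust \code{"bonferroni"} (default), \code{"sidak"} or
#'   \code{"none"}.
#' @return \code{list(H, df, p_overall, pairwise, adjust)}; \code{pairwise}
#'   has columns \code{group1}, \code{group2}, \code{z}, \code{p_adjusted}.
#' @export
kruskal_dunn <- function(groups, adjust = c("bonferroni", "sidak", "none")) {
  adjust <- match.arg(adjust)
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  x <- unlist(groups, use.names = FALSE)
  if (sd(x) < .Machine$double.eps^0.5) stop("all values identical")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kw <- kruskal.test(x, g)
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n_i <- lengths(groups)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  labels <- names(groups) %||% paste0("g", seq_along(groups))
  if (is.null(names(groups)) || any(names(groups) == "")) {
    labels <- paste0("g", seq_along(groups))
  }
  pairs <- utils::combn(seq_along(groups), 2)
  n_pairs <- ncol(pairs)
  pw <- lapply(seq_len(n_pairs), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n_i[i] + 1 / n_i[j]))
    z <- (rbar[i] - rbar[j]) / se
    p <- 2 * pnorm(-abs(z))
    p_adj <- switch(adjust,
                    bonferroni = min(1, p * n_pairs),
                    sidak = 1 - (1 - p)^n_pairs,
                    none = p)
    data.frame(group1 = labels[i], group2 = labels[j],
               z = unname(z), p_adjusted = unname(p_adj),
               stringsAsFactors = FALSE)
  })
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p_overall = kw$p.value, pairwise = do.call(rbind, pw), adjust = adjust)
}

#' Percentage shares of total AMP genes per group
#'
#' @param counts Named (or ordered) vector of the five per-group gene totals.
#' @return \code{list(total, shares)}; shares as percentages to 2 decimals in
#'   the fixed group order.
#' @export
group_shares <- function(counts) {
  if (is.null(names(counts))) names(counts) <- AMP_GROUPS
  stopifnot(length(counts) == length(AMP_GROUPS))
  total <- sum(counts)
  if (total < 1) stop("all counts zero")
  list(total = total, shares = round(100 * counts / total, 2))
}
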