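# Rank-based enrichment of seed-predicted miRNA targets in gene-level score
# vectors: IC loads, per-gene correlations to a miRNA profile, or external
# log2 fold changes.  All tests are Wilcoxon rank-sum; multiple-testing
# control follows the few-tests/many-tests split (Bonferroni vs BH FDR).

#' Multiple-testing adjustment
#'
#' `bonferroni`: min(1, m * p).  `bh_fdr`: Benjamini-Hochberg step-up with
#' monotonicity enforcement.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @param method `"bonferroni"` or `"bh_fdr"`.
#' @param m Number of tests (defaults to `length(p)`; override when some
#'   hypotheses were skipped but still count toward the family).
#' @return Adjusted values, same order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh_fdr"),
                           m = length(p)) {
  method <- match.arg(method)
  if (!length(p)) return(numeric(0L))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("adjust_pvalues: p-values must lie in [0, 1]")
  }
  if (method == "bonferroni") return(pmin(1, m * p))
  n <- length(p)
  ord <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(m / seq(n, 1L) * p[ord]))
  q[order(ord)]
}

#' Wilcoxon rank-sum test
#'
#' The statistic W is the sum of the (mid)ranks of `x` in the pooled sample.
#' The exact null distribution is used when `n + m <= 12` and there are no
#' ties (full enumeration over all C(n+m, n) rank assignments); otherwise a
#' normal approximation with tie correction and continuity correction.
#'
#' @param x,y Non-empty numeric vectors.
#' @param alternative `"two_sided"`, `"less"` (x shifted below y) or
#'   `"greater"`.
#' @param mode `"auto"` (default), `"exact"` or `"normal"`.
#' @return List with `W`, `p`, `alternative`, and `mode_used`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two_sided", "less", "greater"),
                              mode = c("auto", "exact", "normal")) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("wilcoxon_rank_sum: empty vector")
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(n)])
  has_ties <- anyDuplicated(pooled) > 0L
  if (mode == "auto") {
    mode <- if (N <= 12L && !has_ties) "exact" else "normal"
  }
  if (mode == "exact") {
    if (has_ties) stop("wilcoxon_rank_sum: exact mode requires tie-free data")
    sums <- colSums(utils::combn(N, n))  # null rank-sum for every assignment
    p_less <- mean(sums <= W)
    p_greater <- mean(sums >= W)
  } else {
    mu <- n * (N + 1) / 2
    tie_tab <- table(pooled)
    sigma2 <- n * m * (N + 1) / 12 -
      n * m * sum(tie_tab^3 - tie_tab) / (12 * N * (N - 1))
    if (sigma2 <= 0) {
      # all observations identical: no evidence either way
      p_less <- p_greater <- 1
    } else {
      sigma <- sqrt(sigma2)
      p_less <- stats::pnorm((W - mu + 0.5) / sigma)
      p_greater <- stats::pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE)
    }
  }
  p <- switch(alternative,
              less = p_less,
              greater = p_greater,
              two_sided = min(1, 2 * min(p_less, p_greater)))
  list(W = W, p = p, alternative = alternative, mode_used = mode)
}

#' Test a target set for enrichment in a gene-level score vector
#'
#' Wilcoxon rank-sum of the targets' scores against the non-targets' scores.
#' The reported direction is the sign of the median difference
#' (targets minus non-targets).
#'
#' @param scores Named numeric vector (names = gene ids, the analysis
#'   universe).
#' @param target_set Character vector of gene ids, a strict non-empty subset
#'   of the universe.
#' @param alternative Sidedness passed to [wilcoxon_rank_sum()].
#' @param hypothesis Label recorded in the result row.
#' @return One-row data.frame: hypothesis, n_target, n_background, W,
#'   direction, p.
#' @export
score_enrichment <- function(scores, target_set,
                             alternative = c("two_sided", "less", "greater"),
                             hypothesis = "targets") {
  alternative <- match.arg(alternative)
  if (is.null(names(scores))) stop("score_enrichment: scores must be named")
  universe <- names(scores)
  extra <- setdiff(target_set, universe)
  if (length(extra)) {
    stop("score_enrichment: target gene(s) outside the score universe: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  }
  target_set <- unique(target_set)
  if (!length(target_set) || length(target_set) >= length(universe)) {
    stop("score_enrichment: degenerate hypothesis (target set empty or ",
         "equal to the universe)")
  }
  is_t <- universe %in% target_set
  wt <- wilcoxon_rank_sum(scores[is_t], scores[!is_t],
                          alternative = alternative)
  med_diff <- stats::median(scores[is_t]) - stats::median(scores[!is_t])
  data.frame(hypothesis = hypothesis,
             n_target = sum(is_t),
             n_background = sum(!is_t),
             W = wt$W,
             direction = if (med_diff < 0) "negative_shift" else "positive_shift",
             p = wt$p,
             stringsAsFactors = FALSE)
}

# Restrict a target_map's target sets to a gene universe.
restrict_targets <- function(targets, universe) {
  lapply(targets$targets, intersect, y = universe)
}

#' Enrichment of each miRNA's targets in each significant IC's loads
#'
#' For every (miRNA, significant IC) pair, tests the IC loads of the miRNA's
#' seed-predicted targets against all other genes (two-sided), applies BH FDR
#' over all pairs, and summarises each miRNA by its minimum adjusted q across
#' the significant ICs together with the IC achieving it.
#'
#' @param decomp An `ica_decomposition`.
#' @param targets A `target_map`.
#' @param significant_ics Character or integer indices of the significant
#'   components (from [rank_components()]).
#' @return data.frame of miRNA x IC results (mirna_id, component, n_target,
#'   n_background, W, direction, p, q) with attribute `"summary"`: one row
#'   per miRNA (mirna_id, best_ic, q_min).
#' @export
ic_target_enrichment <- function(decomp, targets, significant_ics) {
  if (!length(significant_ics)) {
    stop("ic_target_enrichment: no significant ICs supplied; run ",
         "rank_components() first")
  }
  if (is.numeric(significant_ics)) {
    significant_ics <- colnames(decomp$loads)[significant_ics]
  }
  universe <- intersect(rownames(decomp$loads), targets$gene_universe)
  if (length(universe) < length(targets$gene_universe)) {
    message("ic_target_enrichment: universe restricted to ",
            length(universe), " shared genes")
  }
  tsets <- restrict_targets(targets, universe)
  rows <- list()
  for (m in targets$mirna_ids) {
    tset <- tsets[[m]]
    if (!length(tset) || length(tset) >= length(universe)) {
      message("ic_target_enrichment: skipping ", m,
              " (degenerate target set of size ", length(tset), ")")
      next
    }
    for (ic in significant_ics) {
      scores <- decomp$loads[universe, ic]
      res <- score_enrichment(scores, tset, "two_sided",
                              hypothesis = paste(m, ic, sep = " x "))
      res <- cbind(data.frame(mirna_id = m, component = ic,
                              stringsAsFactors = FALSE),
                   res[, setdiff(names(res), "hypothesis")])
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (!length(rows)) stop("ic_target_enrichment: no testable miRNA x IC pair")
  tab <- do.call(rbind, rows)
  tab$q <- adjust_pvalues(tab$p, "bh_fdr")
  summary <- do.call(rbind, lapply(split(tab, tab$mirna_id), function(d) {
    i <- which.min(d$q)
    data.frame(mirna_id = d$mirna_id[i], best_ic = d$component[i],
               q_min = d$q[i], stringsAsFactors = FALSE)
  }))
  summary <- summary[order(summary$q_min, summary$mirna_id), , drop = FALSE]
  rownames(summary) <- NULL
  attr(tab, "summary") <- summary
  tab
}

#' Negative-correlation baseline target enrichment
#'
#' Computes the Pearson correlation of every gene's expression profile with
#' the miRNA profile and tests whether the targets' correlations are shifted
#' toward -1 (one-sided), the classical reciprocal-expression criterion.
#'
#' @param mrna Genes x samples log-ratio matrix.
#' @param mirna_profile Numeric vector over the same samples (named or in
#'   column order).
#' @param targets Character vector of target gene ids.
#' @param hypothesis Label for the result row.
#' @return One-row data.frame as from [score_enrichment()], computed on the
#'   correlation vector with `alternative = "less"`.
#' @export
correlation_enrichment <- function(mrna, mirna_profile, targets,
                                   hypothesis = "correlation") {
  if (!is.null(names(mirna_profile))) {
    if (!setequal(names(mirna_profile), colnames(mrna))) {
      stop("correlation_enrichment: sample mismatch between profile and matrix")
    }
    mirna_profile <- mirna_profile[colnames(mrna)]
  } else if (length(mirna_profile) != ncol(mrna)) {
    stop("correlation_enrichment: profile length != number of samples")
  }
  if (stats::sd(mirna_profile) == 0) {
    stop("correlation_enrichment: miRNA profile is constant; ",
         "correlations undefined")
  }
  sds <- apply(mrna, 1L, stats::sd)
  if (any(sds == 0)) {
    message("correlation_enrichment: dropping ", sum(sds == 0),
            " zero-variance gene row(s)")
    mrna <- mrna[sds > 0, , drop = FALSE]
  }
  r <- as.vector(stats::cor(t(mrna), mirna_profile))
  names(r) <- rownames(mrna)
  score_enrichment(r, intersect(targets, names(r)), "less",
                   hypothesis = hypothesis)
}

#' Pairwise miRNA cooperativity in one component's loads
#'
#' For every unordered miRNA pair, the common targets (intersection of the
#' two seed-predicted sets) are tested for enrichment in the chosen IC's
#' loads; Bonferroni correction over the number of pairs actually tested.
#' Pairs with an empty intersection are skipped with a message.
#'
#' @param decomp An `ica_decomposition`.
#' @param targets A `target_map`.
#' @param ic Component name or index to test in.
#' @return data.frame: mirna_a, mirna_b, component, n_target, n_background,
#'   W, direction, p, q (Bonferroni).
#' @export
pairwise_cooperativity <- function(decomp, targets, ic) {
  if (is.numeric(ic)) ic <- colnames(decomp$loads)[ic]
  if (!ic %in% colnames(decomp$loads)) {
    stop("pairwise_cooperativity: unknown component '", ic, "'")
  }
  universe <- intersect(rownames(decomp$loads), targets$gene_universe)
  tsets <- restrict_targets(targets, universe)
  ids <- targets$mirna_ids
  if (length(ids) < 2L) stop("pairwise_cooperativity: need >= 2 miRNAs")
  pairs <- utils::combn(ids, 2L)
  rows <- list()
  n_skipped <- 0L
  scores <- decomp$loads[universe, ic]
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    common <- intersect(tsets[[a]], tsets[[b]])
    if (!length(common) || length(common) >= length(universe)) {
      message("pairwise_cooperativity: skipping ", a, "/", b,
              " (common target set of size ", length(common), ")")
      n_skipped <- n_skipped + 1L
      next
    }
    res <- score_enrichment(scores, common, "two_sided",
                            hypothesis = paste(a, b, sep = "+"))
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(mirna_a = a, mirna_b = b, component = ic,
                       stringsAsFactors = FALSE),
            res[, setdiff(names(res), "hypothesis")])
  }
  if (!length(rows)) stop("pairwise_cooperativity: no testable pair")
  tab <- do.call(rbind, rows)
  tab$q <- adjust_pvalues(tab$p, "bonferroni")
  attr(tab, "n_pairs_skipped") <- n_skipped
  tab[order(tab$p), , drop = FALSE]
}

#' Pathway enrichment among miRNA targets in component loads
#'
#' The analysis universe is the union of all miRNA target sets (the genes the
#' method considers regulated); for each component and each pathway, the
#' loads of pathway-member targets are tested against the remaining targets
#' (Wilcoxon, two-sided).  The reported sign is positive when the pathway
#' members' median load is above zero and negative otherwise; member genes
#' with |load| > `load_threshold` are reported as the driver list.  BH FDR is
#' applied over all pathway x IC tests.
#'
#' @param decomp An `ica_decomposition`.
#' @param targets A `target_map`.
#' @param genesets Named list of gene-id vectors (from [read_gmt()]).
#' @param components Components to test (default: all).
#' @param load_threshold Absolute-load cut-off defining driver genes
#'   (default 2; affects reporting only, not p-values).
#' @param universe `"targets"` (default, union of miRNA targets) or `"all"`
#'   (every gene in the decomposition).
#' @param min_mapped Pathways with fewer mapped genes are skipped.
#' @return data.frame: pathway, component, sign, n_pathway, n_background, W,
#'   direction, p, q, drivers (comma-separated gene ids).
#' @export
pathway_enrichment <- function(decomp, targets, genesets,
                               components = colnames(decomp$loads),
                               load_threshold = 2, universe = c("targets", "all"),
                               min_mapped = 3L) {
  universe <- match.arg(universe)
  genes <- if (universe == "targets") {
    intersect(rownames(decomp$loads),
              unique(unlist(targets$targets, use.names = FALSE)))
  } else rownames(decomp$loads)
  if (!length(genes)) stop("pathway_enrichment: empty target universe")
  if (is.numeric(components)) components <- colnames(decomp$loads)[components]
  rows <- list()
  n_skipped <- 0L
  for (pw in names(genesets)) {
    members <- intersect(genesets[[pw]], genes)
    if (length(members) < min_mapped || length(members) >= length(genes)) {
      n_skipped <- n_skipped + 1L
      next
    }
    for (ic in components) {
      scores <- decomp$loads[genes, ic]
      res <- score_enrichment(scores, members, "two_sided", hypothesis = pw)
      med <- stats::median(scores[members])
      drivers <- members[abs(decomp$loads[members, ic]) > load_threshold]
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(pathway = pw, component = ic,
                         sign = if (med > 0) "positive" else "negative",
                         stringsAsFactors = FALSE),
              res[, setdiff(names(res), "hypothesis")],
              data.frame(drivers = paste(drivers, collapse = ","),
                         stringsAsFactors = FALSE))
    }
  }
  if (n_skipped) {
    message("pathway_enrichment: skipped ", n_skipped,
            " pathway(s) with < ", min_mapped, " mapped genes")
  }
  if (!length(rows)) stop("pathway_enrichment: no testable pathway")
  tab <- do.call(rbind, rows)
  tab$q <- adjust_pvalues(tab$p, "bh_fdr")
  tab[order(tab$p), , drop = FALSE]
}

#' Validate predicted targets against external fold changes
#'
#' Tests each miRNA's targets for a shift in an external log2 fold-change
#' vector (e.g. cytokine-treated vs untreated islets), two-sided with the
#' direction reported; BH FDR across miRNAs.
#'
#' @param fold_changes Named numeric vector of per-gene log2 fold changes.
#' @param targets A `target_map`.
#' @return data.frame: mirna_id, n_target, n_background, W, direction, p, q.
#' @export
foldchange_validation <- function(fold_changes, targets) {
  universe <- intersect(names(fold_changes), targets$gene_universe)
  if (length(universe) < 2L) {
    stop("foldchange_validation: degenerate universe of size ",
         length(universe))
  }
  fc <- fold_changes[universe]
  tsets <- restrict_targets(targets, universe)
  rows <- list()
  for (m in targets$mirna_ids) {
    tset <- tsets[[m]]
    if (!length(tset) || length(tset) >= length(universe)) {
      message("foldchange_validation: skipping ", m, " (degenerate target set)")
      next
    }
    res <- score_enrichment(fc, tset, "two_sided", hypothesis = m)
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(mirna_id = m, stringsAsFactors = FALSE),
            res[, setdiff(names(res), "hypothesis")])
  }
  if (!length(rows)) stop("foldchange_validation: no testable miRNA")
  tab <- do.call(rbind, rows)
  tab$q <- adjust_pvalues(tab$p, "bh_fdr")
  tab[order(tab$p), , drop = FALSE]
}
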