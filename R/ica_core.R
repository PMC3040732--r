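# Decomposition E = C %*% M of a genes x samples log-ratio matrix into
# independent transcriptional programs: columns of C are per-gene "loads"
# (standardized to mean 0 / variance 1), rows of M are per-sample "mixes".

# Run code under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Exponential contrast and its derivatives, G(u) = -exp(-u^2/2),
# g(u) = u exp(-u^2/2), g'(u) = (1 - u^2) exp(-u^2/2).
contrast_G <- function(u) -exp(-u^2 / 2)
contrast_g <- function(u) u * exp(-u^2 / 2)
contrast_gprime <- function(u) (1 - u^2) * exp(-u^2 / 2)

#' Negentropy of a standardized load vector
#'
#' Approximates negentropy as J(y) = (mean(G(y)) - E[G(v)])^2 with the
#' exponential contrast G(u) = -exp(-u^2/2) and v standard normal.  The
#' Gaussian reference E[G(v)] is the analytic value -1/sqrt(2) (the integral
#' of -exp(-u^2/2) under the standard normal density), not a Monte-Carlo
#' estimate, so J carries no reference-sample noise.
#'
#' @param y Numeric vector with mean approximately 0 and variance 1.
#' @param check Validate standardization (tolerance 0.05 on mean and
#'   variance); disable for inner-loop use.
#' @return Non-negative scalar negentropy.
#' @export
negentropy <- function(y, check = TRUE) {
  if (check) {
    if (abs(mean(y)) > 0.05 || abs(stats::var(y) - 1) > 0.05) {
      stop("negentropy: input must be standardized to mean 0, variance 1 ",
           "(got mean ", signif(mean(y), 3), ", var ",
           signif(stats::var(y), 3), ")")
    }
  }
  (mean(contrast_G(y)) - (-1 / sqrt(2)))^2
}

#' fastICA decomposition of an expression matrix
#'
#' Fixed-point fastICA with the exponential contrast: the genes x samples
#' matrix is column-centered and whitened in sample space, then an orthogonal
#' unmixing matrix is estimated by symmetric (parallel) fixed-point iteration
#' maximizing negentropy.  All `n_components = min(G, S)` components are
#' extracted directly -- no PCA pre-reduction, which can destroy
#' low-variance programs.  The best of `restarts` random initializations by
#' total negentropy is kept.  Component order is descending negentropy and
#' each component's sign is fixed so its largest-|load| gene is positive,
#' making outputs reproducible despite ICA's sign/permutation indeterminacy.
#'
#' @param E Numeric matrix, genes x samples, complete (no NA).
#' @param n_components Number of components, at most `min(G, S)`.
#' @param tol Convergence tolerance on the unmixing directions.
#' @param max_iter Maximum fixed-point iterations per restart.
#' @param restarts Number of random restarts.
#' @param rng_seed Integer seed; two runs with the same seed are identical.
#' @return Object of class `ica_decomposition`: `loads` (G x n, mean 0 /
#'   variance 1 per column), `mixes` (n x S), `n_components`, `negentropies`,
#'   `converged` (per component), `rng_seed`, `center` (column means removed).
#' @export
fast_ica <- function(E, n_components = min(dim(E)), tol = 1e-6,
                     max_iter = 2000L, restarts = 8L, rng_seed = 1L) {
  stopifnot(is.matrix(E), is.numeric(E))
  if (anyNA(E)) stop("fast_ica: matrix contains missing values")
  G <- nrow(E); S <- ncol(E)
  if (n_components > min(G, S)) {
    stop("fast_ica: n_components (", n_components, ") exceeds min(G, S) = ",
         min(G, S))
  }
  n <- as.integer(n_components)
  center <- colMeans(E)
  Xc <- sweep(E, 2L, center)
  cv <- crossprod(Xc) / (G - 1)
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[n] < 1e-12 * max(eg$values[1L], .Machine$double.eps)) {
    stop("fast_ica: whitening is rank-deficient at dimension ", n,
         " (eigenvalue ", signif(eg$values[n], 3), ")")
  }
  K <- eg$vectors[, seq_len(n), drop = FALSE] %*%
    diag(1 / sqrt(eg$values[seq_len(n)]), n)
  Z <- Xc %*% K  # G x n, cov(Z) = I

  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)), n) %*%
      t(e$vectors) %*% W
  }

  run_once <- function() {
    W <- qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
    W <- sym_decorrelate(W)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      Y <- Z %*% W
      ex <- exp(-Y^2 / 2)  # shared by g and g'
      W1 <- crossprod(Z, Y * ex) / G -
        sweep(W, 2L, colMeans((1 - Y^2) * ex), "*")
      W1 <- sym_decorrelate(W1)
      delta <- max(abs(1 - abs(colSums(W1 * W))))
      W <- W1
      if (delta < tol) { converged <- TRUE; break }
    }
    Ssrc <- Z %*% W
    J <- apply(Ssrc, 2L, function(y) {
      negentropy((y - mean(y)) / stats::sd(y), check = FALSE)
    })
    list(W = W, total_J = sum(J), converged = converged)
  }

  best <- with_seed(rng_seed, {
    runs <- lapply(seq_len(restarts), function(i) run_once())
    runs[[which.max(vapply(runs, `[[`, numeric(1L), "total_J"))]]
  })
  if (!best$converged) {
    warning("fast_ica: best restart did not converge within ", max_iter,
            " iterations")
  }

  loads <- Z %*% best$W
  loads <- scale(loads)  # enforce mean 0 / variance 1 exactly
  attr(loads, "scaled:center") <- NULL
  attr(loads, "scaled:scale") <- NULL
  J <- apply(loads, 2L, negentropy, check = FALSE)
  ord <- order(J, decreasing = TRUE)
  loads <- loads[, ord, drop = FALSE]
  J <- J[ord]
  for (j in seq_len(n)) {
    i_max <- which.max(abs(loads[, j]))
    if (loads[i_max, j] < 0) loads[, j] <- -loads[, j]
  }
  mixes <- qr.solve(loads, Xc)  # least-squares: loads %*% mixes ~ Xc
  comp_ids <- paste0("IC", seq_len(n))
  dimnames(loads) <- list(rownames(E), comp_ids)
  dimnames(mixes) <- list(comp_ids, colnames(E))
  structure(list(loads = loads, mixes = mixes, n_components = n,
                 negentropies = stats::setNames(J, comp_ids),
                 converged = stats::setNames(rep(best$converged, n), comp_ids),
                 rng_seed = rng_seed, center = center),
            class = "ica_decomposition")
}

#' @export
print.ica_decomposition <- function(x, ...) {
  cat("ica_decomposition:", nrow(x$loads), "genes x", x$n_components,
      "components x", ncol(x$mixes), "samples\n")
  cat("  negentropies:", paste(signif(x$negentropies, 3), collapse = " "), "\n")
  cat("  converged:", all(x$converged), " seed:", x$rng_seed, "\n")
  invisible(x)
}

#' Classical one-way ANOVA F-test
#'
#' @param values Numeric vector.
#' @param groups Vector or factor of group labels, same length.
#' @return List with `F`, `p`, `df1`, `df2` and a `degenerate` flag set when
#'   all within-group variance is zero but group means differ (F reported as
#'   `Inf`, p as 0).
#' @export
one_way_F <- function(values, groups) {
  groups <- as.factor(groups)
  sizes <- table(groups)
  if (any(sizes == 0L)) {
    stop("one_way_F: group(s) with zero observations: ",
         paste(names(sizes)[sizes == 0L], collapse = ", "))
  }
  k <- nlevels(groups)
  n <- length(values)
  if (k < 2L) stop("one_way_F: need at least 2 groups")
  if (n <= k) stop("one_way_F: need total n > number of groups")
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ssb <- sum(sizes * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  df1 <- k - 1L; df2 <- n - k
  if (ssw <= .Machine$double.eps * ssb) {
    if (ssb > 0) {
      return(list(F = Inf, p = 0, df1 = df1, df2 = df2, degenerate = TRUE))
    }
    return(list(F = 0, p = 1, df1 = df1, df2 = df2, degenerate = TRUE))
  }
  Fstat <- (ssb / df1) / (ssw / df2)
  list(F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, degenerate = FALSE)
}

# Full cross-classification of all design factors, for non-control samples
# in a given column order.
design_groups <- function(design, sample_ids) {
  factors <- attr(design, "factors")
  if (is.null(factors) || !length(factors)) {
    stop("design has no factor columns")
  }
  idx <- match(sample_ids, design$sample_id)
  if (anyNA(idx)) {
    stop("design is missing sample(s): ",
         paste(sample_ids[is.na(idx)], collapse = ", "))
  }
  interaction(design[idx, factors, drop = FALSE], drop = TRUE, sep = ":")
}

#' Rank independent components against the experimental design
#'
#' Each component's mix row is tested by one-way ANOVA across the full
#' cross-classification of the design factors (condition x time); p-values
#' are Bonferroni-corrected over the number of components and components
#' with corrected p below `alpha` are flagged significant.
#'
#' @param decomp An `ica_decomposition`.
#' @param design Design data.frame covering all sample columns of the mixes.
#' @param alpha Significance threshold on the Bonferroni-corrected p
#'   (default 1e-4).
#' @return data.frame (ordered by p): component, F, p, p_bonferroni,
#'   significant.
#' @export
rank_components <- function(decomp, design, alpha = 1e-4) {
  groups <- design_groups(design, colnames(decomp$mixes))
  if (all(table(groups) < 2L)) {
    stop("rank_components: fewer than 2 replicates in every design cell; ",
         "F-statistics are undefined")
  }
  tests <- apply(decomp$mixes, 1L, one_way_F, groups = groups)
  res <- data.frame(
    component = rownames(decomp$mixes),
    F = vapply(tests, `[[`, numeric(1L), "F"),
    p = vapply(tests, `[[`, numeric(1L), "p"),
    stringsAsFactors = FALSE
  )
  res$p_bonferroni <- adjust_pvalues(res$p, "bonferroni")
  res$significant <- res$p_bonferroni < alpha
  res[order(res$p, res$component), , drop = FALSE]
}

#' Select differentially expressed miRNAs by overall ANOVA
#'
#' Per-miRNA one-way F across the design's condition groups, Bonferroni
#' correction over the number of profiled miRNAs (the few-test regime), and
#' selection at corrected value < `q_threshold`.
#'
#' @param mirna_matrix miRNA x samples log-ratio matrix.
#' @param design Design data.frame covering the matrix columns.
#' @param q_threshold Threshold on the corrected value (default 0.1).
#' @return data.frame of all miRNAs (mirna_id, F, p, q, selected), ordered by
#'   p; the selected subset has q < q_threshold.
#' @export
select_significant_mirnas <- function(mirna_matrix, design, q_threshold = 0.1) {
  groups <- design_groups(design, colnames(mirna_matrix))
  tests <- apply(mirna_matrix, 1L, one_way_F, groups = groups)
  res <- data.frame(
    mirna_id = rownames(mirna_matrix),
    F = vapply(tests, `[[`, numeric(1L), "F"),
    p = vapply(tests, `[[`, numeric(1L), "p"),
    stringsAsFactors = FALSE
  )
  res$q <- adjust_pvalues(res$p, "bonferroni")
  res$selected <- res$q < q_threshold
  res[order(res$p, res$mirna_id), , drop = FALSE]
}
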