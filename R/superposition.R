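# miRNA profiles are too weakly modulated for a joint ICA, but they can be
# represented as linear superpositions of the mRNA-derived component mixes;
# the scaled coefficients say which transcriptional programs drive each
# miRNA and R^2 says how completely.

#' Fit one miRNA profile as a superposition of component mixes
#'
#' Ordinary least squares without intercept: profile ~ sum_t c_t * mix_t over
#' the chosen components.  Coefficients are rescaled to absolute sum 1 (the
#' raw solution is also returned); fit quality is the coefficient of
#' determination R^2 = 1 - SS_resid / SS_total with SS_total about the
#' profile mean, reported as percent variance explained.
#'
#' @param mirna_profile Numeric vector over samples (named or in mix column
#'   order).
#' @param mixes Components x samples matrix (rows = IC mixes).
#' @param ic_subset Component names or indices to fit against (default: all).
#' @param intercept Include an intercept term (for uncentred data; the
#'   intercept is not part of the scaled coefficients).
#' @return List of class `superposition_fit`: `coefficients` (abs-sum 1),
#'   `raw_coefficients`, `r_squared`, `variance_explained_pct`, `degenerate`
#'   (TRUE for an all-zero profile, where scaling is skipped and R^2 is NA).
#' @export
fit_superposition <- function(mirna_profile, mixes, ic_subset = NULL,
                              intercept = FALSE) {
  if (is.numeric(ic_subset)) ic_subset <- rownames(mixes)[ic_subset]
  if (!is.null(ic_subset)) mixes <- mixes[ic_subset, , drop = FALSE]
  if (!is.null(names(mirna_profile))) {
    if (!setequal(names(mirna_profile), colnames(mixes))) {
      stop("fit_superposition: sample mismatch; offenders: ",
           paste(union(setdiff(names(mirna_profile), colnames(mixes)),
                       setdiff(colnames(mixes), names(mirna_profile))),
                 collapse = ", "))
    }
    mirna_profile <- mirna_profile[colnames(mixes)]
  } else if (length(mirna_profile) != ncol(mixes)) {
    stop("fit_superposition: profile length != number of samples")
  }
  if (nrow(mixes) > ncol(mixes)) {
    stop("fit_superposition: more components than samples")
  }
  X <- t(mixes)
  if (intercept) X <- cbind(`(intercept)` = 1, X)
  if (all(mirna_profile == 0)) {
    cf <- stats::setNames(rep(0, nrow(mixes)), rownames(mixes))
    return(structure(list(coefficients = cf, raw_coefficients = cf,
                          r_squared = NA_real_,
                          variance_explained_pct = NA_real_,
                          degenerate = TRUE),
                     class = "superposition_fit"))
  }
  sv <- svd(X)
  pos <- sv$d > max(sv$d) * 1e-10
  if (!all(pos)) {
    warning("fit_superposition: collinear mix rows; ",
            "minimum-norm solution returned")
  }
  beta <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% mirna_profile) / sv$d[pos])
  beta <- stats::setNames(as.vector(beta), colnames(X))
  fitted <- as.vector(X %*% beta)
  ss_res <- sum((mirna_profile - fitted)^2)
  ss_tot <- sum((mirna_profile - mean(mirna_profile))^2)
  r2 <- if (ss_tot == 0) NA_real_ else max(0, min(1, 1 - ss_res / ss_tot))
  raw <- beta[rownames(mixes)]
  denom <- sum(abs(raw))
  cf <- if (denom > 0) raw / denom else raw
  structure(list(coefficients = cf, raw_coefficients = raw,
                 r_squared = r2,
                 variance_explained_pct = 100 * r2,
                 degenerate = FALSE),
            class = "superposition_fit")
}

#' @export
print.superposition_fit <- function(x, ...) {
  cat("superposition_fit: R^2 =", signif(x$r_squared, 4),
      "(", signif(x$variance_explained_pct, 4), "% variance explained )\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' Fit every miRNA profile as a superposition of IC mixes
#'
#' @param mirna_matrix miRNAs x samples log-ratio matrix.
#' @param decomp An `ica_decomposition` sharing the sample columns.
#' @param significant_only Fit against the significant components only
#'   (requires `ranking`); otherwise against all extracted components.
#' @param ranking Output of [rank_components()], needed when
#'   `significant_only = TRUE`.
#' @param intercept Passed to [fit_superposition()].
#' @return data.frame: mirna_id, one scaled-coefficient column per fitted IC,
#'   r_squared, variance_explained_pct.
#' @export
fit_all_mirnas <- function(mirna_matrix, decomp, significant_only = TRUE,
                           ranking = NULL, intercept = FALSE) {
  if (!setequal(colnames(mirna_matrix), colnames(decomp$mixes))) {
    stop("fit_all_mirnas: sample mismatch; offenders: ",
         paste(union(setdiff(colnames(mirna_matrix), colnames(decomp$mixes)),
                     setdiff(colnames(decomp$mixes), colnames(mirna_matrix))),
               collapse = ", "))
  }
  ics <- rownames(decomp$mixes)
  if (significant_only) {
    if (is.null(ranking)) {
      stop("fit_all_mirnas: significant_only = TRUE needs the ranking from ",
           "rank_components()")
    }
    ics <- ranking$component[ranking$significant]
    if (!length(ics)) stop("fit_all_mirnas: no significant components")
  }
  rows <- lapply(rownames(mirna_matrix), function(m) {
    fit <- fit_superposition(mirna_matrix[m, colnames(decomp$mixes)],
                             decomp$mixes, ic_subset = ics,
                             intercept = intercept)
    cf <- as.list(fit$coefficients)
    names(cf) <- ics
    cbind(data.frame(mirna_id = m, stringsAsFactors = FALSE),
          as.data.frame(cf, check.names = FALSE),
          data.frame(r_squared = fit$r_squared,
                     variance_explained_pct = fit$variance_explained_pct))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
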