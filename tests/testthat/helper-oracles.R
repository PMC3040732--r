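# Independent oracles used across the suite.  Each deliberately avoids the
# code path it checks.

# position-by-position sliding-window match count (overlapping)
brute_count <- function(utr, pattern) {
  n <- nchar(utr); k <- nchar(pattern)
  if (n < k) return(0L)
  hits <- 0L
  for (i in seq_len(n - k + 1L)) {
    if (substr(utr, i, i + k - 1L) == pattern) hits <- hits + 1L
  }
  hits
}

# reverse complement through Biostrings, not the package's chartr path
rc_oracle <- function(rna_seed) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    chartr("U", "T", rna_seed))))
}

# textbook ANOVA via R's linear-model machinery
anova_oracle <- function(values, groups) {
  fit <- stats::anova(stats::lm(values ~ factor(groups)))
  list(F = fit$`F value`[1L], p = fit$`Pr(>F)`[1L])
}

random_dna_str <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# small ica_decomposition stand-in for tests that only need loads/mixes
make_decomp <- function(loads, mixes) {
  structure(list(loads = loads, mixes = mixes, n_components = ncol(loads),
                 negentropies = rep(NA_real_, ncol(loads)),
                 converged = TRUE, rng_seed = NA_integer_, center = NULL),
            class = "ica_decomposition")
}

# target_map stand-in built directly from a planted-truth list
make_target_map <- function(targets, gene_universe) {
  structure(list(mirna_ids = names(targets), gene_universe = gene_universe,
                 seeds = NULL, targets = targets, site_counts = NULL),
            class = "target_map")
}

# default two-factor, 12-sample design for compact fixtures
small_design <- function() {
  sd <- expand.grid(pdx1 = c("off", "on"), il1b = c("no", "yes"),
                    replicate = 1:3, stringsAsFactors = FALSE)
  df <- data.frame(sample_id = sprintf("s%02d", seq_len(nrow(sd))),
                   pdx1 = sd$pdx1, il1b = sd$il1b,
                   replicate = sd$replicate, is_control = FALSE,
                   stringsAsFactors = FALSE)
  attr(df, "factors") <- c("pdx1", "il1b")
  df
}
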