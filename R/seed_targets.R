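#' Reverse complement of a nucleotide string
#'
#' @param x A single DNA or RNA string (uppercase).
#' @param out `"dna"` or `"rna"` output alphabet.
#' @return The reverse complement in the requested alphabet.
#' @export
reverse_complement <- function(x, out = c("dna", "rna")) {
  out <- match.arg(out)
  comp <- chartr("ACGTUN", "TGCAAN", x)
  rc <- paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
  if (out == "rna") chartr("T", "U", rc) else chartr("U", "T", rc)
}

#' Extract the seed from a mature miRNA sequence
#'
#' The seed is taken from mature-sequence positions 2-7 (1-based, the
#' field-standard 6mer); the match pattern searched for in 3'UTRs is its
#' reverse complement on the DNA alphabet.  Start and length are configurable
#' so 7mer or offset variants are expressible.
#'
#' @param mature_sequence RNA string, length >= seed_start + seed_len - 1.
#' @param seed_start 1-based start of the seed in the mature sequence.
#' @param seed_len Seed length in nucleotides.
#' @return List with `seed_rna` and `match_dna`.
#' @export
extract_seed <- function(mature_sequence, seed_start = 2L, seed_len = 6L) {
  mature_sequence <- toupper(chartr("T", "U", mature_sequence))
  if (grepl("[^ACGU]", mature_sequence)) {
    stop("extract_seed: sequence contains characters outside {A,C,G,U}")
  }
  need <- seed_start + seed_len - 1L
  if (nchar(mature_sequence) < need) {
    stop("extract_seed: mature sequence has ", nchar(mature_sequence),
         " nt, need at least ", need, " (no position ", need, ")")
  }
  seed_rna <- substr(mature_sequence, seed_start, need)
  list(seed_rna = seed_rna, match_dna = reverse_complement(seed_rna, "dna"))
}

#' Count (possibly overlapping) exact seed-match sites in a 3'UTR
#'
#' Matching is exact and case-insensitive after uppercasing; positions
#' containing N never match.  Overlapping occurrences are counted.
#'
#' @param utr DNA string (a 3'UTR, sense strand).
#' @param match_dna DNA match pattern (reverse complement of the seed).
#' @return Integer count of occurrences.
#' @export
scan_utr <- function(utr, match_dna) {
  if (!nzchar(utr)) stop("scan_utr: empty UTR")
  utr <- toupper(chartr("U", "T", utr))
  match_dna <- toupper(chartr("U", "T", match_dna))
  hits <- gregexpr(paste0("(?=", match_dna, ")"), utr, perl = TRUE)[[1L]]
  if (length(hits) == 1L && hits[1L] == -1L) 0L else length(hits)
}

#' Build the miRNA -> target-gene map by 6mer seed matching
#'
#' A gene is a target of a miRNA when its 3'UTR contains at least one exact
#' occurrence of the reverse complement of the miRNA seed.  Genes without a
#' UTR sequence are simply absent from the universe (not non-targets).
#'
#' @param mirnas Named character vector, miRNA id -> mature RNA sequence.
#' @param utrs Named character vector, gene id -> 3'UTR DNA string.
#' @param seed_start,seed_len Seed coordinates, see [extract_seed()].
#' @return Object of class `target_map`: list with `mirna_ids`,
#'   `gene_universe`, `seeds` (per-miRNA seed/pattern), `targets` (named list
#'   of gene-id vectors) and `site_counts` (data.frame mirna_id, gene_id,
#'   site_count).
#' @export
build_target_map <- function(mirnas, utrs, seed_start = 2L, seed_len = 6L) {
  if (!length(mirnas) || !length(utrs)) {
    stop("build_target_map: empty miRNA or UTR input")
  }
  seeds <- lapply(mirnas, extract_seed, seed_start = seed_start,
                  seed_len = seed_len)
  pat <- vapply(seeds, `[[`, character(1L), "match_dna")
  dup <- duplicated(pat)
  if (any(dup)) {
    warning("build_target_map: identical seed shared by miRNAs: ",
            paste(names(pat)[pat %in% pat[dup]], collapse = ", "),
            " (their target sets are identical)")
  }
  utrs <- toupper(chartr("U", "T", utrs))
  utr_set <- Biostrings::DNAStringSet(utrs)
  targets <- vector("list", length(mirnas))
  names(targets) <- names(mirnas)
  rows <- vector("list", length(mirnas))
  for (i in seq_along(mirnas)) {
    counts <- Biostrings::vcountPattern(pat[[i]], utr_set)
    hit <- counts >= 1L
    targets[[i]] <- names(utrs)[hit]
    rows[[i]] <- data.frame(mirna_id = names(mirnas)[i],
                            gene_id = names(utrs)[hit],
                            site_count = counts[hit],
                            stringsAsFactors = FALSE)
  }
  structure(list(mirna_ids = names(mirnas),
                 gene_universe = names(utrs),
                 seeds = seeds,
                 targets = targets,
                 site_counts = do.call(rbind, rows)),
            class = "target_map")
}

#' @export
print.target_map <- function(x, ...) {
  cat("target_map:", length(x$mirna_ids), "miRNAs,",
      length(x$gene_universe), "genes in universe\n")
  n <- lengths(x$targets)
  cat("  targets per miRNA:", paste(sprintf("%s=%d", names(n), n),
                                    collapse = ", "), "\n")
  invisible(x)
}

#' Write a target map as TSV (mirna_id, gene_id, site_count)
#' @param map A `target_map`.
#' @param path Output TSV path.
#' @param metadata Provenance metadata for the JSON sidecar.
#' @export
write_target_map <- function(map, path, metadata = list()) {
  write_results(map$site_counts, path, metadata)
}
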