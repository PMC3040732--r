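# Ground-truth-annotated synthetic data: sparse super-Gaussian
# transcriptional programs mixed into samples according to a factorial
# design, with miRNA repression planted into program loads, miRNA profiles
# built as linear superpositions of the program mixes, and sequence files
# (mature miRNAs, 3'UTRs) whose seed-match structure reproduces the planted
# target map exactly.

# Standard Laplace draws scaled to unit variance (Laplace is the canonical
# super-Gaussian source family; ICA is unidentifiable for Gaussian sources).
rlaplace_unit <- function(n) {
  u <- stats::runif(n) - 0.5
  (-sign(u) * log1p(-2 * abs(u))) / sqrt(2)
}

#' Simulate sparse super-Gaussian transcriptional programs
#'
#' Each program's load vector has a `sparsity` fraction of genes drawn from
#' a unit-variance Laplace distribution and the rest exactly zero, then the
#' column is standardized to mean 0 / variance 1.
#'
#' @param G Number of genes (>= 100).
#' @param T_programs Number of programs (<= 8).
#' @param sparsity Fraction of non-zero genes per program, in (0, 1].
#' @param rng_seed Integer seed.
#' @return G x T matrix `C_true` with rownames g0001.. and colnames P1..
#' @export
simulate_programs <- function(G, T_programs, sparsity = 0.1, rng_seed = 1L) {
  stopifnot(G >= 100L, T_programs >= 1L, T_programs <= 8L)
  if (sparsity <= 0 || sparsity > 1) {
    stop("simulate_programs: sparsity must lie in (0, 1]")
  }
  with_seed(rng_seed, {
    C <- matrix(0, G, T_programs)
    k <- max(2L, round(sparsity * G))
    for (t in seq_len(T_programs)) {
      idx <- sample.int(G, k)
      C[idx, t] <- rlaplace_unit(k)
    }
    C <- scale(C)
    attr(C, "scaled:center") <- NULL
    attr(C, "scaled:scale") <- NULL
    dimnames(C) <- list(sprintf("g%04d", seq_len(G)),
                        paste0("P", seq_len(T_programs)))
    C
  })
}

#' Simulate a factorial sample design and program mixes
#'
#' Samples are the full crossing of the supplied factors times `replicates`.
#' A program mapped to a factor gets mix = `effect_size` when the sample is
#' at that factor's second ("on") level plus Normal(0, sigma_mix) replicate
#' noise; unmapped programs get condition-independent Normal(0, 1) mixes
#' (active but uncorrelated with the design).
#'
#' @param T_programs Number of programs.
#' @param factors Named list of 2+ level label vectors
#'   (default: pdx1 on/off, il1b yes/no, time 2h/24h).
#' @param replicates Replicates per design cell (>= 2).
#' @param effect_map Named integer-ish mapping factor name -> program index;
#'   each program mapped to at most one factor.
#' @param effect_size Mix shift for the "on" level.
#' @param sigma_mix Replicate noise SD for mapped programs.
#' @param rng_seed Integer seed.
#' @return List: `design` (data.frame with sample_id, factor columns,
#'   replicate, is_control and a `"factors"` attribute) and `M_true`
#'   (T x samples matrix).
#' @export
simulate_design_and_mixes <- function(T_programs,
                                      factors = list(pdx1 = c("off", "on"),
                                                     il1b = c("no", "yes"),
                                                     time = c("2h", "24h")),
                                      replicates = 3L,
                                      effect_map = NULL,
                                      effect_size = 3,
                                      sigma_mix = 0.5,
                                      rng_seed = 1L) {
  if (replicates < 2L) {
    stop("simulate_design_and_mixes: need >= 2 replicates per cell")
  }
  if (is.null(effect_map)) {
    nm <- utils::head(names(factors), T_programs)
    effect_map <- stats::setNames(seq_along(nm), nm)
  }
  if (anyDuplicated(unlist(effect_map))) {
    stop("simulate_design_and_mixes: each program may be mapped to at most ",
         "one factor")
  }
  grid <- expand.grid(c(factors, list(replicate = seq_len(replicates))),
                      stringsAsFactors = FALSE)
  S <- nrow(grid)
  design <- data.frame(sample_id = sprintf("s%02d", seq_len(S)),
                       grid[names(factors)],
                       replicate = grid$replicate,
                       is_control = FALSE,
                       stringsAsFactors = FALSE)
  attr(design, "factors") <- names(factors)
  M <- with_seed(rng_seed, {
    M <- matrix(stats::rnorm(T_programs * S), T_programs, S)
    mapped <- integer(0)
    for (f in names(effect_map)) {
      t <- effect_map[[f]]
      on_level <- factors[[f]][2L]
      M[t, ] <- effect_size * (design[[f]] == on_level) +
        stats::rnorm(S, 0, sigma_mix)
      mapped <- c(mapped, t)
    }
    M
  })
  dimnames(M) <- list(paste0("P", seq_len(T_programs)), design$sample_id)
  list(design = design, M_true = M, effect_map = effect_map)
}

#' Plant miRNA repression (and optional pathway shifts) into program loads
#'
#' For each miRNA, a random gene subset becomes its target set; when the
#' miRNA is assigned a program, the targets' loads in that program are
#' shifted by `effect` (negative = repression).  miRNAs with assignment `NA`
#' are decoys: they get target sets but no load modification.  Optional
#' pathways are planted the same way with their own shift.  Columns are
#' re-standardized afterwards.
#'
#' @param C_true G x T program load matrix.
#' @param mirna_ids Character vector of miRNA ids.
#' @param program_assignment Integer vector (same length), program index per
#'   miRNA or NA for decoys.
#' @param target_fraction Fraction of genes targeted per miRNA
#'   (`target_fraction * G >= 20`).
#' @param effect Load shift applied to targets in the assigned program.
#' @param pathways Optional integer: number of pathways to plant.
#' @param pathway_size Genes per planted pathway (drawn from the miRNA target
#'   union).
#' @param pathway_effect Load shift for planted pathway members.
#' @param n_decoy_pathways Pathways drawn from the target union with no
#'   shift.
#' @param rng_seed Integer seed.
#' @return List: `C_modified` (re-standardized), `planted_targets` (named
#'   list of gene ids), `pathway_sets` (named list), `pathway_truth`
#'   (data.frame pathway, program, sign; decoys have program NA).
#' @export
plant_mirna_regulation <- function(C_true, mirna_ids, program_assignment,
                                   target_fraction = 0.1, effect = -1.5,
                                   pathways = 0L, pathway_size = 40L,
                                   pathway_effect = -3,
                                   n_decoy_pathways = pathways,
                                   rng_seed = 1L) {
  G <- nrow(C_true)
  if (round(target_fraction * G) < 20L) {
    stop("plant_mirna_regulation: target_fraction * G must be >= 20")
  }
  stopifnot(length(mirna_ids) == length(program_assignment))
  with_seed(rng_seed, {
    C <- C_true
    k <- round(target_fraction * G)
    planted <- stats::setNames(vector("list", length(mirna_ids)), mirna_ids)
    hits <- matrix(0L, G, ncol(C))
    for (i in seq_along(mirna_ids)) {
      idx <- sample.int(G, k)
      planted[[i]] <- rownames(C_true)[sort(idx)]
      t <- program_assignment[i]
      if (!is.na(t)) {
        C[idx, t] <- C[idx, t] + effect
        hits[idx, t] <- hits[idx, t] + 1L
      }
    }
    overlap <- sum(hits > 1L)
    if (overlap) {
      message("plant_mirna_regulation: ", overlap,
              " gene x program cell(s) received summed overlapping shifts")
    }
    pathway_sets <- list()
    pathway_truth <- NULL
    if (pathways > 0L) {
      target_union <- unique(unlist(planted, use.names = FALSE))
      progs <- rep_len(seq_len(ncol(C)), pathways)
      for (j in seq_len(pathways)) {
        members <- sample(target_union, min(pathway_size, length(target_union)))
        nm <- sprintf("PW_planted_%02d", j)
        pathway_sets[[nm]] <- sort(members)
        C[members, progs[j]] <- C[members, progs[j]] + pathway_effect
        pathway_truth <- rbind(pathway_truth, data.frame(
          pathway = nm, program = progs[j],
          sign = if (pathway_effect > 0) "positive" else "negative",
          stringsAsFactors = FALSE))
      }
      for (j in seq_len(n_decoy_pathways)) {
        nm <- sprintf("PW_decoy_%02d", j)
        pathway_sets[[nm]] <-
          sort(sample(target_union, min(pathway_size, length(target_union))))
        pathway_truth <- rbind(pathway_truth, data.frame(
          pathway = nm, program = NA_integer_, sign = NA_character_,
          stringsAsFactors = FALSE))
      }
    }
    C <- scale(C)
    attr(C, "scaled:center") <- NULL
    attr(C, "scaled:scale") <- NULL
    dimnames(C) <- dimnames(C_true)
    list(C_modified = C, planted_targets = planted,
         pathway_sets = pathway_sets, pathway_truth = pathway_truth)
  })
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Emit mature-miRNA and 3'UTR sequence sets realising a planted target map
#'
#' Mature miRNAs are random 22-mers with pairwise-distinct position-2-7
#' seeds.  Target UTRs carry >= 1 inserted match site per targeting miRNA;
#' non-target UTRs are rejection-sampled to contain 0 sites for every
#' simulated miRNA, so scanning the emitted files reproduces
#' `planted_targets` exactly.
#'
#' @param planted_targets Named list, miRNA id -> gene-id vector.
#' @param gene_ids Full gene universe (every gene gets a UTR).
#' @param utr_length UTR length in nt (>= 50).
#' @param rng_seed Integer seed.
#' @return List: `mirnas` (named RNA strings), `utrs` (named DNA strings).
#' @export
emit_sequences <- function(planted_targets, gene_ids, utr_length = 200L,
                           rng_seed = 1L) {
  if (utr_length < 50L) stop("emit_sequences: utr_length must be >= 50")
  mirna_ids <- names(planted_targets)
  with_seed(rng_seed, {
    seqs <- character(length(mirna_ids))
    seeds_seen <- character(0)
    for (i in seq_along(mirna_ids)) {
      repeat {
        s <- paste(sample(c("A", "C", "G", "U"), 22L, replace = TRUE),
                   collapse = "")
        sd6 <- substr(s, 2L, 7L)
        if (!sd6 %in% seeds_seen) { seeds_seen <- c(seeds_seen, sd6); break }
        message("emit_sequences: seed collision, regenerating miRNA ",
                mirna_ids[i])
      }
      seqs[i] <- s
    }
    names(seqs) <- mirna_ids
    patterns <- vapply(seqs, function(s) extract_seed(s)$match_dna,
                       character(1L))
    any_site <- function(utr) any(vapply(patterns, function(p) {
      grepl(p, utr, fixed = TRUE)
    }, logical(1L)))
    clean_utr <- function() {
      repeat {
        u <- random_dna(utr_length)
        if (!any_site(u)) return(u)
      }
    }
    targeting <- stats::setNames(
      lapply(gene_ids, function(g) {
        mirna_ids[vapply(planted_targets, function(tt) g %in% tt, logical(1L))]
      }), gene_ids)
    utrs <- character(length(gene_ids))
    names(utrs) <- gene_ids
    for (g in gene_ids) {
      who <- targeting[[g]]
      repeat {
        u <- clean_utr()
        if (length(who)) {
          # non-overlapping insertion slots, 6 nt apart
          n_slots <- utr_length %/% 6L
          slots <- (sample.int(n_slots, length(who)) - 1L) * 6L + 1L
          for (j in seq_along(who)) {
            substr(u, slots[j], slots[j] + 5L) <- patterns[[who[j]]]
          }
        }
        counts <- vapply(patterns, function(p) scan_utr(u, p), integer(1L))
        ok <- all(counts[who] >= 1L) &&
          all(counts[setdiff(mirna_ids, who)] == 0L)
        if (ok) break
      }
      utrs[g] <- u
    }
    list(mirnas = seqs, utrs = utrs)
  })
}

#' Mix programs into observed expression matrices
#'
#' mRNA = C_modified %*% M_true + Normal(0, noise_sd) entrywise; miRNA
#' profiles = mirna_coefficients %*% M_true + Normal(0, mirna_noise_sd).
#'
#' @param C_modified G x T load matrix (after planting).
#' @param M_true T x S mix matrix.
#' @param noise_sd Entrywise mRNA noise SD.
#' @param mirna_coefficients miRNA x T coefficient matrix.
#' @param mirna_noise_sd Entrywise miRNA noise SD.
#' @param rng_seed Integer seed.
#' @return List: `mrna` (G x S), `mirna` (miRNAs x S).
#' @export
emit_expression <- function(C_modified, M_true, noise_sd = 0.1,
                            mirna_coefficients, mirna_noise_sd = 0.05,
                            rng_seed = 1L) {
  stopifnot(ncol(C_modified) == nrow(M_true),
            ncol(mirna_coefficients) == nrow(M_true))
  with_seed(rng_seed, {
    mrna <- C_modified %*% M_true +
      matrix(stats::rnorm(nrow(C_modified) * ncol(M_true), 0, noise_sd),
             nrow(C_modified))
    mirna <- mirna_coefficients %*% M_true +
      matrix(stats::rnorm(nrow(mirna_coefficients) * ncol(M_true), 0,
                          mirna_noise_sd),
             nrow(mirna_coefficients))
    dimnames(mrna) <- list(rownames(C_modified), colnames(M_true))
    dimnames(mirna) <- list(rownames(mirna_coefficients), colnames(M_true))
    list(mrna = mrna, mirna = mirna)
  })
}

#' Generate the complete synthetic benchmark bundle
#'
#' The default fixture mirrors the shape of a small factorial
#' perturbation-and-time-course array study: 5 programs, 3 binary design
#' factors x 3 replicates (24 samples), ~2000 genes, 8 planted miRNAs plus
#' decoys.  Every planted miRNA is assigned one design-mapped program and
#' represses a random 10% of genes there (load shift -1.5); its expression
#' profile tracks its program's mix.  Decoy miRNAs have seed-matched target
#' sets but no planted regulation and noise-only profiles.
#'
#' @param G Genes.
#' @param T_programs Programs.
#' @param n_mirna Planted (regulating) miRNAs.
#' @param n_decoys Decoy miRNAs.
#' @param sparsity,target_fraction,effect See the stage generators.
#' @param factors,replicates,effect_size,sigma_mix Design parameters.
#' @param noise_sd,mirna_noise_sd Observation noise.
#' @param coef_spread Half-width of the uniform off-program superposition
#'   weights of each miRNA profile.
#' @param coef_main Superposition weight of each planted miRNA's assigned
#'   program (recycled over miRNAs; default 1).  Setting some entries to 0
#'   models miRNAs whose expression is decoupled from the program they
#'   repress -- such miRNAs defeat correlation-based prediction but not
#'   load-based prediction.
#' @param n_pathways Planted pathways (plus as many decoy pathways).
#' @param pathway_effect Load shift for planted pathway members.
#' @param utr_length UTR length; set `emit_seqs = FALSE` to skip sequence
#'   generation (the slowest stage) when only matrices are needed.
#' @param emit_seqs Generate FASTA-ready sequences.
#' @param rng_seed Master seed; all stage seeds derive from it.
#' @return List with `mrna`, `mirna`, `design`, `mirna_seqs`, `utrs`,
#'   `pathways` and a `truth` sub-list (C_modified, M_true, planted_targets,
#'   program_assignment, mirna_coefficients scaled to abs-sum 1,
#'   pathway_truth, effect sizes, rng_seed).
#' @export
simulate_dataset <- function(G = 2000L, T_programs = 5L, n_mirna = 8L,
                             n_decoys = 4L, sparsity = 0.1,
                             target_fraction = 0.1, effect = -1.5,
                             factors = list(pdx1 = c("off", "on"),
                                            il1b = c("no", "yes"),
                                            time = c("2h", "24h")),
                             replicates = 3L, effect_size = 3,
                             sigma_mix = 0.5, noise_sd = 0.1,
                             mirna_noise_sd = 0.05, coef_spread = 0.25,
                             coef_main = 1, n_pathways = 0L,
                             pathway_effect = -3, utr_length = 200L,
                             emit_seqs = TRUE, rng_seed = 1L) {
  sub <- with_seed(rng_seed, sample.int(2^31 - 1L, 6L))
  C_true <- simulate_programs(G, T_programs, sparsity, rng_seed = sub[1L])
  dm <- simulate_design_and_mixes(T_programs, factors, replicates,
                                  effect_size = effect_size,
                                  sigma_mix = sigma_mix, rng_seed = sub[2L])
  mirna_ids <- c(sprintf("mir%02d", seq_len(n_mirna)),
                 if (n_decoys > 0L) sprintf("decoy%02d", seq_len(n_decoys)))
  # regulating miRNAs live on design-mapped programs (condition-responsive);
  # unmapped programs stay as pure confounders
  mapped_programs <- unlist(dm$effect_map, use.names = FALSE)
  assignment <- c(rep_len(mapped_programs, n_mirna),
                  rep(NA_integer_, n_decoys))
  names(assignment) <- mirna_ids
  pl <- plant_mirna_regulation(C_true, mirna_ids, assignment,
                               target_fraction = target_fraction,
                               effect = effect, pathways = n_pathways,
                               pathway_effect = pathway_effect,
                               rng_seed = sub[3L])
  coef_main <- rep_len(coef_main, n_mirna)
  coef <- with_seed(sub[4L], {
    co <- matrix(stats::runif(length(mirna_ids) * T_programs, -coef_spread,
                              coef_spread),
                 length(mirna_ids), T_programs,
                 dimnames = list(mirna_ids, rownames(dm$M_true)))
    for (i in seq_len(n_mirna)) co[i, assignment[i]] <- coef_main[i]
    co
  })
  expr <- emit_expression(pl$C_modified, dm$M_true, noise_sd, coef,
                          mirna_noise_sd, rng_seed = sub[5L])
  seqs <- if (emit_seqs) {
    emit_sequences(pl$planted_targets, rownames(C_true),
                   utr_length = utr_length, rng_seed = sub[6L])
  } else list(mirnas = NULL, utrs = NULL)
  denom <- rowSums(abs(coef))
  coef_scaled <- coef / ifelse(denom > 0, denom, 1)
  list(mrna = expr$mrna, mirna = expr$mirna, design = dm$design,
       mirna_seqs = seqs$mirnas, utrs = seqs$utrs,
       pathways = pl$pathway_sets,
       truth = list(C_modified = pl$C_modified, M_true = dm$M_true,
                    planted_targets = pl$planted_targets,
                    program_assignment = assignment,
                    effect_map = dm$effect_map,
                    mirna_coefficients = coef_scaled,
                    pathway_truth = pl$pathway_truth,
                    effect = effect, noise_sd = noise_sd,
                    mirna_noise_sd = mirna_noise_sd, rng_seed = rng_seed))
}

#' Write a simulated bundle to disk
#'
#' Emits mrna.tsv, mirna.tsv, design.tsv, mirnas.fa, utrs.fa, pathways.gmt
#' and a truth.json manifest into `dir`.
#'
#' @param sim Output of [simulate_dataset()] (with sequences).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_table(sim$mrna, file.path(dir, "mrna.tsv"), "gene_id")
  write_expression_table(sim$mirna, file.path(dir, "mirna.tsv"), "mirna_id")
  utils::write.table(sim$design, file.path(dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_fasta_strings(sim$mirna_seqs, file.path(dir, "mirnas.fa"))
  write_fasta_strings(sim$utrs, file.path(dir, "utrs.fa"))
  if (length(sim$pathways)) {
    gmt <- vapply(names(sim$pathways), function(nm) {
      paste(c(nm, "simulated", sim$pathways[[nm]]), collapse = "\t")
    }, character(1L))
    writeLines(gmt, file.path(dir, "pathways.gmt"))
  }
  truth <- sim$truth
  truth$C_modified <- NULL  # large; reproducible from rng_seed
  truth$M_true <- apply(truth$M_true, 1L, identity, simplify = FALSE)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

write_fasta_strings <- function(seqs, path) {
  if (is.null(seqs)) stop("write_fasta_strings: no sequences to write")
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}
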