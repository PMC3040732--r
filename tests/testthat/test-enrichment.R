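test_that("wilcoxon_rank_sum exact mode matches hand enumeration", {
  # x occupies the 3 smallest of 6 ranks: unique minimum rank-sum, 1/20 per tail
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), "two_sided")
  expect_equal(r$p, 0.1)
  expect_equal(r$W, 6)
  expect_equal(r$mode_used, "exact")
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), "less")$p, 0.05)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), "greater")$p, 1)
  # identical multisets: no shift either way
  expect_gte(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3), "two_sided")$p, 0.9)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "empty")
})

test_that("exact p equals the pwilcox oracle for all tie-free splits", {
  for (N in 4:10) {
    worst <- 0
    for (n in 2:(N - 2)) {
      m <- N - n
      # every possible assignment of ranks 1..N to x
      combos <- utils::combn(N, n)
      for (j in seq_len(ncol(combos))) {
        x <- combos[, j]
        y <- setdiff(seq_len(N), x)
        U <- sum(x) - n * (n + 1) / 2
        p_less <- stats::pwilcox(U, n, m)
        p_greater <- 1 - stats::pwilcox(U - 1, n, m)
        d1 <- abs(wilcoxon_rank_sum(x, y, "less", mode = "exact")$p - p_less)
        d2 <- abs(wilcoxon_rank_sum(x, y, "two_sided", mode = "exact")$p -
                    min(1, 2 * min(p_less, p_greater)))
        worst <- max(worst, d1, d2)
      }
    }
    expect_lt(worst, 1e-12)
  }
})

test_that("normal mode agrees with wilcox.test (ties + continuity)", {
  set.seed(77)
  for (i in 1:40) {
    x <- sample(1:8, sample(5:15, 1), replace = TRUE)  # forces ties
    y <- sample(1:8, sample(5:15, 1), replace = TRUE)
    got <- wilcoxon_rank_sum(x, y, "two_sided", mode = "normal")
    want <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                correct = TRUE))
    expect_equal(got$p, want$p.value, tolerance = 1e-9)
    gl <- wilcoxon_rank_sum(x, y, "less", mode = "normal")
    wl <- suppressWarnings(stats::wilcox.test(x, y, alternative = "less",
                                              exact = FALSE, correct = TRUE))
    expect_equal(gl$p, wl$p.value, tolerance = 1e-9)
  }
})

test_that("score_enrichment detects a planted negative shift", {
  set.seed(5)
  scores <- c(rnorm(200, -1, 0.5), rnorm(1800, 0, 1))
  names(scores) <- sprintf("g%04d", seq_along(scores))
  targets <- names(scores)[1:200]
  res <- score_enrichment(scores, targets, "two_sided")
  expect_lt(res$p, 1e-10)
  expect_equal(res$direction, "negative_shift")
  expect_equal(res$n_target, 200)
  expect_equal(res$n_background, 1800)

  expect_error(score_enrichment(scores, names(scores)), "degenerate")
  expect_error(score_enrichment(scores, character(0)), "degenerate")
  expect_error(score_enrichment(scores, "nope"), "outside")
})

test_that("score_enrichment p is a rank statistic (monotone invariance)", {
  set.seed(6)
  scores <- setNames(rnorm(100), sprintf("g%03d", 1:100))
  targets <- sample(names(scores), 20)
  p1 <- score_enrichment(scores, targets)$p
  p2 <- score_enrichment(exp(3 * scores) + 5, targets)$p  # strictly monotone
  expect_equal(p1, p2)
  # swapping target/background flips the one-sided tail, keeps two-sided p
  rest <- setdiff(names(scores), targets)
  expect_equal(score_enrichment(scores, targets, "less")$p,
               score_enrichment(scores, rest, "greater")$p)
  expect_equal(score_enrichment(scores, targets)$p,
               score_enrichment(scores, rest)$p)
})

test_that("null score_enrichment p-values are uniform", {
  set.seed(9)
  ps <- vapply(1:400, function(i) {
    scores <- setNames(rnorm(300), sprintf("g%03d", 1:300))
    score_enrichment(scores, sample(names(scores), 40))$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  frac <- mean(ps < 0.05)
  expect_gt(frac, 0.02); expect_lt(frac, 0.08)
})

test_that("adjust_pvalues matches hand-worked values and p.adjust", {
  expect_equal(adjust_pvalues(0.01, "bonferroni", m = 5), 0.05)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bh_fdr"),
               c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(0.5, "bonferroni"), 0.5)
  expect_equal(adjust_pvalues(0.5, "bh_fdr"), 0.5)
  expect_error(adjust_pvalues(c(0.5, 1.2), "bonferroni"), "\\[0, 1\\]")
  expect_identical(adjust_pvalues(numeric(0), "bh_fdr"), numeric(0))

  set.seed(10)
  for (i in 1:30) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjust_pvalues(p, "bh_fdr"), p.adjust(p, "BH"))
    expect_equal(adjust_pvalues(p, "bonferroni"), p.adjust(p, "bonferroni"))
    # Bonferroni dominates BH; BH is monotone in p
    expect_true(all(adjust_pvalues(p, "bonferroni") >=
                      adjust_pvalues(p, "bh_fdr") - 1e-12))
    q <- adjust_pvalues(p, "bh_fdr")
    expect_true(!is.unsorted(q[order(p)]))
  }
})

test_that("ic_target_enrichment finds the planted miRNA and its IC", {
  set.seed(14)
  G <- 800
  genes <- sprintf("g%04d", 1:G)
  loads <- matrix(rnorm(G * 3), G, 3, dimnames = list(genes, paste0("IC", 1:3)))
  targets <- sample(genes, 80)
  loads[targets, 1] <- loads[targets, 1] - 1.5
  loads <- scale(loads)
  map <- make_target_map(list(m1 = targets, decoy = sample(genes, 80)), genes)
  tab <- ic_target_enrichment(make_decomp(loads, matrix(0, 3, 2)), map,
                              paste0("IC", 1:3))
  s <- attr(tab, "summary")
  expect_lt(s$q_min[s$mirna_id == "m1"], 0.1)
  expect_equal(s$best_ic[s$mirna_id == "m1"], "IC1")
  expect_equal(nrow(tab), 6)  # 2 miRNAs x 3 ICs
  expect_error(ic_target_enrichment(make_decomp(loads, matrix(0, 3, 2)), map,
                                    character(0)), "rank_components")
})

test_that("BH with a single test leaves p unchanged", {
  set.seed(15)
  genes <- sprintf("g%03d", 1:100)
  loads <- matrix(rnorm(100), 100, 1, dimnames = list(genes, "IC1"))
  map <- make_target_map(list(m1 = sample(genes, 20)), genes)
  tab <- ic_target_enrichment(make_decomp(loads, matrix(0, 1, 2)), map, "IC1")
  expect_equal(tab$q, tab$p)
})

test_that("correlation_enrichment flags anti-correlated targets", {
  set.seed(9)
  S <- 12
  profile <- rnorm(S, sd = 2)
  non_targets <- matrix(rnorm(950 * S), 950, S)
  targets <- matrix(rep(-profile, each = 50), 50, S) +
    matrix(rnorm(50 * S, 0, 0.05), 50, S)
  mrna <- rbind(targets, non_targets)
  dimnames(mrna) <- list(sprintf("g%04d", 1:1000), sprintf("s%02d", 1:S))
  res <- correlation_enrichment(mrna, profile, rownames(mrna)[1:50])
  expect_lt(res$p, 1e-8)
  expect_equal(res$direction, "negative_shift")
  expect_error(correlation_enrichment(mrna, rep(1, S), rownames(mrna)[1:50]),
               "constant")
  mrna[3, ] <- 7  # zero-variance row is dropped, not fatal
  expect_message(correlation_enrichment(mrna, profile, rownames(mrna)[1:2]),
                 "zero-variance")
})

test_that("pairwise_cooperativity tests pair intersections with Bonferroni", {
  set.seed(21)
  G <- 600
  genes <- sprintf("g%04d", 1:G)
  loads <- matrix(rnorm(G * 2), G, 2, dimnames = list(genes, c("IC1", "IC2")))
  common <- sample(genes, 40)
  loads[common, 1] <- loads[common, 1] - 2
  loads <- scale(loads)
  tmap <- list(
    mA = c(common, sample(setdiff(genes, common), 60)),
    mB = c(common, sample(setdiff(genes, common), 60)),
    mC = sample(genes, 80)
  )
  map <- make_target_map(tmap, genes)
  tab <- pairwise_cooperativity(make_decomp(loads, matrix(0, 2, 2)), map, "IC1")
  ab <- tab[tab$mirna_a == "mA" & tab$mirna_b == "mB", ]
  expect_lt(ab$q, 0.05)
  expect_equal(tab$q, pmin(1, tab$p * nrow(tab)))

  # 8 miRNAs with guaranteed overlap -> all 28 pairs tested
  tmap8 <- setNames(lapply(1:8, function(i) {
    c(genes[1:10], sample(genes[-(1:10)], 30))
  }), paste0("m", 1:8))
  tab8 <- pairwise_cooperativity(make_decomp(loads, matrix(0, 2, 2)),
                                 make_target_map(tmap8, genes), 1L)
  expect_equal(nrow(tab8), 28)

  # disjoint pair skipped
  tmap2 <- list(mA = genes[1:20], mB = genes[21:40])
  expect_message(
    expect_error(pairwise_cooperativity(make_decomp(loads, matrix(0, 2, 2)),
                                        make_target_map(tmap2, genes), "IC1"),
                 "no testable pair"),
    "skipping")
})

test_that("pathway_enrichment detects a planted low-load pathway", {
  set.seed(31)
  G <- 1000
  genes <- sprintf("g%04d", 1:G)
  loads <- matrix(rnorm(G * 2), G, 2, dimnames = list(genes, c("IC1", "IC2")))
  target_union <- sample(genes, 400)
  pw <- sample(target_union, 40)
  loads[pw, 2] <- -3
  map <- make_target_map(list(m1 = target_union[1:250],
                              m2 = target_union[151:400]), genes)
  gs <- list(PW_hit = pw, PW_null = sample(target_union, 40),
             PW_outside = setdiff(genes, target_union)[1:5])
  tab <- suppressMessages(
    pathway_enrichment(make_decomp(loads, matrix(0, 2, 2)), map, gs))
  hit <- tab[tab$pathway == "PW_hit" & tab$component == "IC2", ]
  expect_lt(hit$q, 0.05)
  expect_equal(hit$sign, "negative")
  # pathway disjoint from the target universe is skipped
  expect_false("PW_outside" %in% tab$pathway)
  # driver list = members beyond |load| threshold; threshold only affects it
  expect_true(all(strsplit(hit$drivers, ",")[[1]] %in% pw))
  tab_inf <- suppressMessages(
    pathway_enrichment(make_decomp(loads, matrix(0, 2, 2)), map, gs,
                       load_threshold = Inf))
  expect_equal(tab_inf$p, tab$p)
  expect_true(all(tab_inf$drivers == ""))
})

test_that("foldchange_validation reports per-miRNA shifts with FDR", {
  set.seed(41)
  genes <- sprintf("g%04d", 1:500)
  fc <- setNames(rnorm(500, 0, 0.3), genes)
  up <- sample(genes, 60)
  fc[up] <- fc[up] + 0.5
  map <- make_target_map(list(m_up = up, m_null = sample(genes, 60)), genes)
  tab <- foldchange_validation(fc, map)
  expect_lt(tab$q[tab$mirna_id == "m_up"], 0.05)
  expect_equal(tab$direction[tab$mirna_id == "m_up"], "positive_shift")
  expect_error(foldchange_validation(fc[1], map), "degenerate universe")
})
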