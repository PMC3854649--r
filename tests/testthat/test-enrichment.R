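test_that("hypergeometric tail matches exhaustive enumeration everywhere (N <= 12)", {
  expect_equal(hypergeom_tail(10, 5, 4, 2), 55 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_tail(4, 2, 2, 0), 1 - 1 / 6, tolerance = 1e-12)
  expect_equal(hypergeom_tail(10, 5, 4, 4), 0)  # tail beyond the support

  for (N in 1:12) {
    for (n in 0:N) {
      for (m in 0:N) {
        for (k in 0:min(m, n)) {
          expect_equal(hypergeom_tail(N, m, n, k),
                       enum_hyper_tail(N, m, n, k), tolerance = 1e-10)
        }
      }
    }
  }
  expect_error(hypergeom_tail(10, 11, 4, 2), "require")
  expect_error(hypergeom_tail(10, 5, 4, 5), "require")
})

test_that("chi-squared statistic matches hand values and chisq.test on a table panel", {
  ct <- chi2_statistic(50, 10, 950, 90)
  expect_equal(ct$statistic, 1100 * (50 * 90 - 10 * 950)^2 /
                 (60 * 1040 * 1000 * 100), tolerance = 1e-12)
  expect_equal(ct$statistic, 4.40705, tolerance = 1e-4)
  expect_identical(ct$df, 1L)
  # proportional rows give a zero statistic
  expect_equal(chi2_statistic(10, 20, 30, 60)$statistic, 0)

  panel <- list(c(50, 10, 950, 90), c(3, 7, 12, 8), c(1, 1, 1, 1),
                c(25, 5, 100, 400), c(8, 2, 2, 8))
  for (tb in panel) {
    got <- chi2_statistic(tb[1], tb[2], tb[3], tb[4])
    ref <- suppressWarnings(
      chisq.test(matrix(tb, 2, byrow = TRUE), correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(chi2_statistic(0, 0, 5, 5), "zero margin")
})

test_that("chi-squared statistic is invariant to simultaneous row/column swaps", {
  set.seed(5)
  for (i in 1:20) {
    tb <- rgamma(4, 3, 0.1) + 0.5
    s0 <- chi2_statistic(tb[1], tb[2], tb[3], tb[4])$statistic
    expect_equal(chi2_statistic(tb[3], tb[4], tb[1], tb[2])$statistic, s0)
    expect_equal(chi2_statistic(tb[2], tb[1], tb[4], tb[3])$statistic, s0)
    expect_equal(chi2_statistic(tb[4], tb[3], tb[2], tb[1])$statistic, s0)
  }
})

test_that("BH adjustment matches the hand step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(7)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    # adjusted values are non-decreasing in raw-p order
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("unweighted hypergeometric enrichment matches a brute-force count oracle", {
  st <- random_stats(200, frac_sig = 0.12, seed = 21)
  sets <- random_sets(st$gene_id, n_sets = 10, seed = 22)
  fit <- enrich(st, sets, method = "hypergeometric", alpha = 0.01)
  N <- nrow(st)
  m <- sum(st$p_value < 0.01)
  for (id in sets$ids) {
    members <- sets$members[[id]]
    n <- sum(members %in% st$gene_id)
    k <- sum(st$p_value[st$gene_id %in% members] < 0.01)
    row <- fit$table[fit$table$set_id == id, ]
    expect_equal(row$n_genes, n)
    expect_equal(row$pathway_score, k)
    expect_equal(row$p_value,
                 1 - sum(dhyper(0:k, m, N - m, n)), tolerance = 1e-10)
  }
})

test_that("m = 0 and whole-array pathways hit the tail's boundary cases", {
  st <- data.frame(gene_id = paste0("g", 1:30),
                   fold_change = rep(c(2, 0.5), 15),
                   p_value = rep(0.5, 30))  # nothing significant
  sets <- gene_set_collection(list(all = st$gene_id,
                                   some = st$gene_id[1:5]))
  fit <- enrich(st, sets, method = "hypergeometric")
  # with m = 0, X is identically 0, so P(X > 0) = 0 for every pathway
  expect_equal(fit$table$p_value, c(0, 0))

  st$p_value[1:3] <- 1e-4
  fit2 <- enrich(st, sets, method = "hypergeometric")
  # pathway = whole array: k = min(m, n), tail beyond the support
  expect_equal(fit2$table$p_value[fit2$table$set_id == "all"], 0)
})

test_that("weighted hypergeometric reproduces the worked pseudo-population example", {
  # 5 genes with rounded scores (2,1,0,1,0); pathway = first two genes.
  # Pseudo population 5*2 = 10, successes 4, draws 4, tail beyond k = 3:
  # P(X > 3) = C(4,4)C(6,0)/C(10,4) = 1/210.
  st <- data.frame(gene_id = paste0("g", 1:5),
                   fold_change = 2^c(2, 1, 0, 1, 0),
                   p_value = rep(0.5, 5))
  sets <- gene_set_collection(list(P = c("g1", "g2")))
  fit <- enrich(st, sets, method = "weighted_hypergeometric", a = 1)
  expect_equal(fit$table$p_value, 1 / 210, tolerance = 1e-12)
  expect_equal(fit$table$pathway_score, 3)

  # cross-check against exhaustive enumeration on the pseudo population
  expect_equal(fit$table$p_value, enum_hyper_tail(10, 4, 4, 3),
               tolerance = 1e-12)
})

test_that("indicator scores reduce the weighted hypergeometric test to the classic one", {
  for (seed in 1:5) {
    st <- random_stats(150, frac_sig = 0.15, seed = seed)
    sets <- random_sets(st$gene_id, n_sets = 8, seed = seed + 100)
    ind <- stats::setNames(as.numeric(st$p_value < 0.01), st$gene_id)
    classic <- enrich(st, sets, method = "hypergeometric", alpha = 0.01)
    weighted <- enrich(st, sets, method = "weighted_hypergeometric",
                       gene_scores = ind)
    mg <- merge(classic$table, weighted$table, by = "set_id")
    live <- mg$status.y != "degenerate"
    expect_true(any(live))
    expect_equal(mg$p_value.y[live], mg$p_value.x[live], tolerance = 1e-12)
    # degenerate pathways are exactly those with no significant member
    expect_equal(mg$pathway_score.x[!live], rep(0, sum(!live)))
  }
})

test_that("zero-score pathways are flagged degenerate with p = 1", {
  st <- data.frame(gene_id = paste0("g", 1:20),
                   fold_change = c(rep(1, 10), rep(4, 10)),
                   p_value = rep(0.5, 20))
  sets <- gene_set_collection(list(null = paste0("g", 1:6),
                                   hot = paste0("g", 11:16)))
  fit <- enrich(st, sets, method = "weighted_hypergeometric")
  nullrow <- fit$table[fit$table$set_id == "null", ]
  expect_identical(nullrow$status, "degenerate")
  expect_equal(nullrow$p_value, 1)
  expect_identical(fit$table$status[fit$table$set_id == "hot"], "ok")

  # all fold changes 1: weighted chi-squared has no score mass at all
  st$fold_change <- 1
  fitc <- enrich(st, sets, method = "weighted_chi2")
  expect_true(all(fitc$table$status == "degenerate"))
  expect_true(all(fitc$table$p_value == 1))
})

test_that("unweighted chi-squared enrichment equals the explicitly built table", {
  st <- random_stats(300, frac_sig = 0.1, seed = 31)
  sets <- random_sets(st$gene_id, n_sets = 10, seed = 32)
  fit <- enrich(st, sets, method = "chi2", alpha = 0.01)
  N <- nrow(st); m <- sum(st$p_value < 0.01)
  for (id in sets$ids) {
    members <- sets$members[[id]]
    n <- length(members)
    k <- sum(st$p_value[st$gene_id %in% members] < 0.01)
    ref <- chi2_statistic(n, k, N - n, m - k)
    expect_equal(fit$table$p_value[fit$table$set_id == id], ref$p_value,
                 tolerance = 1e-12)
  }
})

test_that("weighted chi-squared equals the score-filled table and respects score_margin", {
  st <- random_stats(250, frac_sig = 0.1, seed = 41)
  sets <- random_sets(st$gene_id, n_sets = 8, seed = 42)
  g <- stats::setNames(gene_score(st$fold_change, 1), st$gene_id)
  S <- sum(g)
  N <- nrow(st)
  for (margin in c("exclusive", "total")) {
    fit <- enrich(st, sets, method = "weighted_chi2", a = 1,
                  score_margin = margin)
    for (id in sets$ids) {
      members <- sets$members[[id]]
      n <- length(members)
      k <- sum(g[members])
      n22 <- if (margin == "exclusive") S - k else S
      ref <- chi2_statistic(n, k, N - n, n22)
      row <- fit$table[fit$table$set_id == id, ]
      expect_equal(row$p_value, ref$p_value, tolerance = 1e-12)
      expect_equal(row$pathway_score, k, tolerance = 1e-12)
    }
  }
})

test_that("uniform gene scores give proportional rows and a zero weighted chi-squared", {
  st <- data.frame(gene_id = paste0("g", 1:40),
                   fold_change = rep(4, 40),  # every gene scores 2
                   p_value = rep(0.5, 40))
  sets <- gene_set_collection(list(A = paste0("g", 1:10),
                                   B = paste0("g", 5:30)))
  fit <- enrich(st, sets, method = "weighted_chi2")
  expect_equal(fit$table$p_value, c(1, 1), tolerance = 1e-12)
})

test_that("null chi-squared enrichment rejects at roughly its nominal rate", {
  set.seed(61)
  ps <- numeric()
  for (r in 1:100) {
    n_genes <- 400
    st <- data.frame(gene_id = sprintf("g%03d", 1:n_genes),
                     fold_change = 2^rnorm(n_genes, 0, 0.5),
                     p_value = runif(n_genes))
    sets <- random_sets(st$gene_id, n_sets = 10, size_range = c(30, 120),
                        seed = r)
    fit <- enrich(st, sets, method = "chi2", alpha = 0.05)
    ps <- c(ps, fit$table$p_value[fit$table$status == "ok"])
  }
  rate <- mean(ps < 0.05)
  # Monte-Carlo bound at 1000 tests (tests within a dataset share m,
  # so allow a margin above the binomial sd)
  expect_lt(abs(rate - 0.05), 0.025)
})

test_that("results are ranked by p with deterministic score and id tie-breaking", {
  st <- data.frame(gene_id = paste0("g", 1:50),
                   fold_change = c(rep(8, 10), rep(1.1, 40)),
                   p_value = c(rep(0.001, 10), rep(0.8, 40)))
  sets <- gene_set_collection(list(
    b_hot = paste0("g", 1:8), a_hot = paste0("g", c(1:7, 9)),
    cold = paste0("g", 20:35)))
  fit <- enrich(st, sets, method = "hypergeometric")
  expect_identical(sort(fit$table$rank), 1:3)
  # equal p and equal score: lexicographic id order breaks the tie
  ph <- fit$table[fit$table$set_id %in% c("a_hot", "b_hot"), ]
  if (ph$p_value[1] == ph$p_value[2] &&
      ph$pathway_score[1] == ph$pathway_score[2]) {
    expect_identical(ph$set_id, c("a_hot", "b_hot"))
  }
  # identical fits rank identically across runs
  fit2 <- enrich(st, sets, method = "hypergeometric")
  expect_identical(fit$table, fit2$table)

  tp <- top_pathways(fit, k = 2)
  expect_identical(nrow(tp), 2L)
  expect_identical(top_pathways(fit, k = 99)$set_id, fit$table$set_id)
})

test_that("every fit reports valid probabilities, FDR and ranks", {
  st <- random_stats(120, frac_sig = 0.2, seed = 71)
  sets <- random_sets(st$gene_id, n_sets = 12, seed = 72)
  sets$members$P01 <- c("nope1", "nope2")  # force an untestable pathway
  for (meth in c("hypergeometric", "chi2", "weighted_hypergeometric",
                 "weighted_chi2")) {
    fit <- enrich(st, sets, method = meth)
    tab <- fit$table
    expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
    expect_true(all(tab$fdr >= tab$p_value - 1e-15))
    expect_identical(sort(tab$rank), seq_len(nrow(tab)))
    expect_identical(tab$status[tab$set_id == "P01"], "untestable")
    expect_equal(tab$p_value[tab$set_id == "P01"], 1)
  }
})

test_that("fold-change orientation cannot change the weighted results", {
  st <- random_stats(100, frac_sig = 0.1, seed = 81)
  sets <- random_sets(st$gene_id, n_sets = 6, seed = 82)
  flipped <- st
  flipped$fold_change <- 1 / st$fold_change
  for (meth in c("weighted_hypergeometric", "weighted_chi2")) {
    a <- enrich(st, sets, method = meth)
    b <- enrich(flipped, sets, method = meth)
    expect_equal(a$table$p_value, b$table$p_value, tolerance = 1e-12)
  }
})
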