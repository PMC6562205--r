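test_that("BH adjustment matches brute force and the reference implementation", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               bf_bh(c(0.01, 0.02, 0.03, 0.04)), tolerance = 1e-12)

  set.seed(3)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, bf_bh(p), tolerance = 1e-10)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    # permutation invariance after re-alignment
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm])[order(perm)], q, tolerance = 1e-15)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "erfrag_input_error")
})

test_that("differential expression behaves on exchangeable and planted inputs", {
  set.seed(10)
  base <- rnbinom(300, mu = exp(rnorm(300, 5, 1)), size = 10)
  counts <- tibble::tibble(gene_id = sprintf("G%03d", 1:300),
                           A_1 = base, A_2 = base, B_1 = base, B_2 = base)
  groups <- tibble::tibble(sample_id = c("A_1", "A_2", "B_1", "B_2"),
                           condition = c("A", "A", "B", "B"))
  de <- differential_expression(counts, groups, condition_a = "A")
  expect_true(all(de$log2_fold_change == 0))
  expect_true(all(de$direction == "ns"))

  # planted 2-fold up gene at high expression, n = 5 vs 5, low dispersion
  set.seed(77)
  null_mu <- exp(rnorm(399, 5, 1))
  mk <- function(mu2) vapply(mu2, function(m) rnbinom(1, mu = m, size = 200), numeric(1))
  counts2 <- tibble::tibble(gene_id = sprintf("G%03d", 1:400))
  for (s in sprintf("A_%d", 1:5)) counts2[[s]] <- mk(c(2000, null_mu))
  for (s in sprintf("B_%d", 1:5)) counts2[[s]] <- mk(c(1000, null_mu))
  groups2 <- tibble::tibble(sample_id = c(sprintf("A_%d", 1:5), sprintf("B_%d", 1:5)),
                            condition = rep(c("A", "B"), each = 5))
  de2 <- differential_expression(counts2, groups2, condition_a = "A")
  expect_equal(de2$direction[1], "up")
  expect_equal(de2$log2_fold_change[1], 1, tolerance = 0.3)

  # all-zero gene is retained but untestable
  counts$A_1[1] <- counts$A_2[1] <- counts$B_1[1] <- counts$B_2[1] <- 0L
  de3 <- differential_expression(counts, groups)
  expect_false(de3$testable[1])
  expect_true(is.na(de3$p_raw[1]))
  expect_equal(nrow(de3), 300)
})

test_that("null simulations keep the false-discovery rate controlled", {
  n_clean <- 0L
  fractions <- numeric(10)
  for (s in 1:10) {
    sim <- generate_omics(n_genes = 2000, n_up = 0, n_down = 0,
                          n_replicates = 10, seed = 4000 + s)
    de <- differential_expression(sim$counts, sim$groups, condition_a = "A")
    n_clean <- n_clean + (sum(de$direction != "ns") == 0L)
    fractions[s] <- mean(de$p_raw < 0.05, na.rm = TRUE)
  }
  expect_gte(n_clean, 9L)
  # raw p calibration: fraction below 0.05 within 3 binomial sd
  sd3 <- 3 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(mean(fractions) - 0.05), sd3)
})

test_that("exclusive sets follow the all-batches rule, symmetry, and brute force", {
  batch_tbl <- function(ids, m) {
    tibble::tibble(protein_id = ids, batch_1 = m[, 1], batch_2 = m[, 2],
                   batch_3 = m[, 3])
  }
  ids <- c("P1", "P2", "P3")
  a <- batch_tbl(ids, rbind(c(1, 1, 0), c(1, 1, 1), c(0, 0, 0)))
  b <- batch_tbl(ids, rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1)))
  excl <- exclusive_sets(a, b)
  expect_equal(excl$a_exclusive, "P2") # P1 present in only 2 of 3 batches
  expect_equal(excl$b_exclusive, "P3")

  swapped <- exclusive_sets(b, a)
  expect_equal(swapped$a_exclusive, excl$b_exclusive)
  expect_equal(swapped$b_exclusive, excl$a_exclusive)

  set.seed(12)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    ids <- sprintf("P%02d", seq_len(n))
    ma <- matrix(runif(n * 3) < 0.6, n); mb <- matrix(runif(n * 3) < 0.6, n)
    got <- exclusive_sets(batch_tbl(ids, ma * 1), batch_tbl(ids, mb * 1))
    bf_a <- ids[apply(ma, 1, all) & !apply(mb, 1, any)]
    bf_b <- ids[apply(mb, 1, all) & !apply(ma, 1, any)]
    expect_equal(got$a_exclusive, bf_a)
    expect_equal(got$b_exclusive, bf_b)
    expect_equal(sort(got$union), sort(c(bf_a, bf_b)))
  }

  expect_error(exclusive_sets(a, b[1:2, ]), class = "erfrag_alignment_error")
})

test_that("gene-protein integration applies the fold-change thresholds exactly", {
  de <- tibble::tibble(gene_id = c("G1", "G2", "G3"),
                       mean_expression = 100,
                       log2_fold_change = c(2.1, 1.9, -2.4),
                       p_raw = 0.001, q_bh = 0.01,
                       direction = c("up", "up", "down"), testable = TRUE)
  prot <- tibble::tibble(protein_id = c("G1", "G2", "G3"),
                         log2fc = c(2.5, 2.5, -2.6))
  res <- integrate_gene_protein(de, prot)
  expect_equal(res$up_candidates$gene_id, "G1")   # (2.1, 2.5) kept
  expect_false("G2" %in% res$up_candidates$gene_id) # (1.9, 2.5) dropped
  expect_equal(res$down_candidates$gene_id, "G3")

  expect_warning(empty <- integrate_gene_protein(de[0, ], prot))
  expect_equal(empty$counts$n_paired, 0L)

  set.seed(5)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    de_r <- tibble::tibble(gene_id = sprintf("G%03d", 1:n),
                           mean_expression = 1, log2_fold_change = rnorm(n, 0, 2),
                           p_raw = runif(n), q_bh = runif(n),
                           direction = "ns", testable = TRUE)
    pr_r <- tibble::tibble(protein_id = sample(de_r$gene_id, n %/% 2),
                           log2fc = rnorm(n %/% 2, 0, 2))
    res_r <- integrate_gene_protein(de_r, pr_r)
    joined <- merge(de_r, pr_r, by.x = "gene_id", by.y = "protein_id")
    expect_equal(res_r$counts$n_up,
                 sum(joined$log2_fold_change > 2 & joined$log2fc > 2))
    expect_equal(res_r$counts$n_down,
                 sum(joined$log2_fold_change < -2 & joined$log2fc < -2))
  }
})

test_that("expression tiers are balanced quartiles, rank-invariant, oracle-equal", {
  tbl <- tibble::tibble(gene_id = sprintf("G%d", 1:8), expression = c(8:1))
  tiers <- expression_tiers(tbl)
  expect_equal(as.integer(table(tiers$tier)), c(2L, 2L, 2L, 2L))
  expect_equal(as.character(tiers$tier[tiers$gene_id == "G1"]), "very_high")

  # monotone (positive) transformation leaves tiers unchanged
  transformed <- dplyr::mutate(tbl, expression = sqrt(expression))
  expect_equal(expression_tiers(transformed)$tier, tiers$tier)

  set.seed(9)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    tb <- tibble::tibble(gene_id = sprintf("G%03d", sample(1000, n)),
                         expression = exp(rnorm(n)))
    got <- expression_tiers(tb)
    # brute-force rank-and-split oracle
    o <- order(-tb$expression, tb$gene_id)
    sizes <- diff(floor(seq(0, n, length.out = 5)))
    oracle <- stats::setNames(
      rep(c("very_high", "high", "low", "very_low"), times = sizes),
      tb$gene_id[o]
    )
    expect_equal(as.character(got$tier), unname(oracle[got$gene_id]))
    expect_true(max(table(got$tier)) - min(table(got$tier)) <= 1)
  }

  expect_warning(small <- expression_tiers(tbl[1:3, ]))
  expect_equal(nrow(small), 3L)
})

test_that("top-n selection and overlaps match set arithmetic", {
  de <- tibble::tibble(gene_id = c("B", "A", "C", "D"),
                       p_raw = c(0.01, 0.01, 0.5, 0.2))
  # tie at the boundary broken by lexicographic gene id
  expect_equal(top_n_by_pvalue(de, 1), "A")
  expect_equal(top_n_by_pvalue(de, 3), c("A", "B", "D"))
  expect_error(top_n_by_pvalue(de, 5), class = "erfrag_input_error")
  expect_error(top_n_by_pvalue(dplyr::bind_rows(de, de), 2),
               class = "erfrag_input_error")

  expect_equal(cross_overlap(c("A", "B"), c("A", "B"))$n_shared, 2L)
  expect_equal(cross_overlap(c("A", "B"), c("C", "D"))$n_shared, 0L)
  set.seed(14)
  for (i in 1:20) {
    a <- sample(letters, sample(5:20, 1))
    b <- sample(letters, sample(5:20, 1))
    expect_equal(sort(cross_overlap(a, b)$shared), sort(intersect(a, b)))
  }
})

test_that("hypergeometric ORA equals exhaustive combinatorial enumeration", {
  universe <- sprintf("G%02d", 1:20)
  term <- universe[1:5]
  res <- ora(universe[1:5], list(T1 = term), universe)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p, 6.45e-5, tolerance = 1e-2)

  res_all <- ora(universe[1:5], list(T_all = universe), universe)
  expect_equal(res_all$p, 1)

  set.seed(21)
  for (i in 1:50) {
    N <- sample(8:25, 1)
    uni <- sprintf("U%02d", seq_len(N))
    K <- sample(1:N, 1); n <- sample(1:N, 1)
    term <- sample(uni, K); sel <- sample(uni, n)
    k <- length(intersect(term, sel))
    got <- ora(sel, list(T = term), uni)
    expect_equal(got$p, bf_hyper_tail(k, K, N, n), tolerance = 1e-10)
  }

  expect_error(ora(c("G01", "NOT_THERE"), list(T1 = term), universe),
               "NOT_THERE", class = "erfrag_input_error")
})

test_that("the planted enriched term ranks first in almost every seed", {
  wins <- 0L
  for (s in 1:10) {
    sim <- generate_omics(n_genes = 600, n_up = 60, n_down = 0,
                          n_replicates = 5, seed = 6000 + s)
    de <- differential_expression(sim$counts, sim$groups, condition_a = "A")
    up <- de$gene_id[de$direction == "up"]
    enr <- ora(up, sim$annotation, sim$universe)
    wins <- wins + (enr$term_id[1] == sim$enriched_term)
  }
  expect_gte(wins, 9L)
})

test_that("summary bookkeeping keeps up + down equal to the significant total", {
  set.seed(30)
  for (i in 1:10) {
    n <- 50
    de <- tibble::tibble(direction = sample(c("up", "down", "ns"), n, replace = TRUE))
    s <- de_summary(de)
    expect_equal(s$n_up + s$n_down, s$n_significant)
  }
})
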