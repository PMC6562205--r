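#' Benjamini-Hochberg step-up adjustment
#'
#' Computes BH q values: with ordered p values \eqn{p_{(1)} \le \dots \le
#' p_{(m)}}, \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1.
#' Order-preserving; `NA` p values propagate and do not count towards `m`.
#'
#' @param p_values Numeric vector of p values in \[0, 1\].
#' @return q values aligned with the input.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  p <- p_values[ok]
  if (any(p < 0 | p > 1)) {
    stop_erfrag("p values must lie in [0, 1].", "erfrag_input_error")
  }
  m <- length(p)
  q <- rep(NA_real_, length(p_values))
  if (m > 0) {
    o <- order(p)
    adj <- pmin(1, p[o] * m / seq_len(m))
    adj <- rev(cummin(rev(adj))) # enforce monotonicity (step-up)
    qq <- numeric(m)
    qq[o] <- adj
    q[ok] <- qq
  }
  q
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median across genes of
#' the ratio of a sample's count to the gene's geometric mean over all
#' samples, using only genes with positive counts in every sample.
#'
#' @param count_matrix Non-negative integer matrix, genes x samples.
#' @return Numeric vector of size factors, one per sample.
#' @export
size_factors <- function(count_matrix) {
  keep <- rowSums(count_matrix > 0) == ncol(count_matrix)
  if (!any(keep)) {
    rlang::warn("no gene has positive counts in all samples; size factors set to 1.")
    return(rep(1, ncol(count_matrix)))
  }
  logs <- log(count_matrix[keep, , drop = FALSE])
  geo <- rowMeans(logs)
  apply(logs, 2L, function(col) exp(stats::median(col - geo)))
}

counts_to_matrix <- function(counts) {
  stopifnot("gene_id" %in% names(counts))
  if (anyDuplicated(counts$gene_id)) {
    stop_erfrag("duplicate gene ids in count table.", "erfrag_input_error")
  }
  m <- as.matrix(counts[, setdiff(names(counts), "gene_id"), drop = FALSE])
  rownames(m) <- counts$gene_id
  storage.mode(m) <- "double"
  m
}

#' Two-condition differential expression on normalized log counts
#'
#' Normalizes counts by median-of-ratios size factors, then tests each gene
#' with a two-sample pooled-variance t test on `log2(normalized + 1)`,
#' adjusts p values by Benjamini-Hochberg, and reports the log2 fold change
#' of condition A over condition B computed from normalized means with a
#' pseudo-count of 1. Genes with all-zero counts are retained but flagged
#' untestable. Direction is `up` iff `q_bh < alpha` and the fold change is
#' positive (symmetrically `down`), otherwise `ns`.
#'
#' @param counts Tibble with `gene_id` plus one column per sample.
#' @param groups Tibble with `sample_id`, `condition` (exactly two levels).
#' @param condition_a Condition treated as the numerator (default the first
#'   level; in the disease design, the mutant genotype).
#' @param alpha FDR threshold for direction calls.
#' @return A `de_table` tibble: `gene_id`, `mean_expression`,
#'   `log2_fold_change`, `p_raw`, `q_bh`, `direction`, `testable`.
#' @export
differential_expression <- function(counts, groups, condition_a = NULL,
                                    alpha = 0.05) {
  m <- counts_to_matrix(counts)
  if (!all(c("sample_id", "condition") %in% names(groups))) {
    stop_erfrag("`groups` needs sample_id and condition columns.", "erfrag_input_error")
  }
  if (!setequal(colnames(m), groups$sample_id)) {
    stop_erfrag("count columns and group sample ids disagree.", "erfrag_input_error")
  }
  groups <- groups[match(colnames(m), groups$sample_id), ]
  levels <- unique(groups$condition)
  if (length(levels) != 2L) {
    stop_erfrag("exactly two conditions are required.", "erfrag_input_error")
  }
  if (is.null(condition_a)) condition_a <- levels[[1L]]
  cond_b <- setdiff(levels, condition_a)
  in_a <- groups$condition == condition_a
  if (sum(in_a) < 2L || sum(!in_a) < 2L) {
    stop_erfrag("at least 2 replicates per condition are required.",
                "erfrag_input_error")
  }

  sf <- size_factors(m)
  norm <- sweep(m, 2L, sf, "/")
  logn <- log2(norm + 1)
  mean_a <- rowMeans(norm[, in_a, drop = FALSE])
  mean_b <- rowMeans(norm[, !in_a, drop = FALSE])
  lfc <- log2((mean_a + 1) / (mean_b + 1))

  testable <- rowSums(m) > 0
  xa <- logn[, in_a, drop = FALSE]; xb <- logn[, !in_a, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  va <- apply(xa, 1L, stats::var); vb <- apply(xb, 1L, stats::var)
  dmean <- rowMeans(xa) - rowMeans(xb)
  pooled <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(pooled * (1 / na + 1 / nb))
  tstat <- dmean / se
  p <- 2 * stats::pt(abs(tstat), df = na + nb - 2, lower.tail = FALSE)
  # degenerate genes: zero variance in both arms
  p[se == 0 & dmean == 0] <- 1
  p[se == 0 & dmean != 0] <- 0
  p[!testable] <- NA_real_
  q <- bh_adjust(p)

  out <- tibble(
    gene_id = rownames(m),
    mean_expression = unname((mean_a + mean_b) / 2),
    log2_fold_change = unname(lfc),
    p_raw = unname(p), q_bh = unname(q),
    direction = dplyr::case_when(
      is.na(q) ~ "ns",
      q < alpha & lfc > 0 ~ "up",
      q < alpha & lfc < 0 ~ "down",
      TRUE ~ "ns"
    ),
    testable = testable
  )
  class(out) <- c("de_table", class(out))
  attr(out, "condition_a") <- condition_a
  attr(out, "condition_b") <- cond_b
  out
}

#' Summary counts of a differential-expression table
#'
#' @param de_table Output of [differential_expression()] (or any tibble with
#'   a `direction` column).
#' @return One-row tibble: `n_up`, `n_down`, `n_significant`, `n_genes`;
#'   `n_up + n_down == n_significant` by construction.
#' @export
de_summary <- function(de_table) {
  tibble(
    n_up = sum(de_table$direction == "up"),
    n_down = sum(de_table$direction == "down"),
    n_significant = sum(de_table$direction %in% c("up", "down")),
    n_genes = nrow(de_table)
  )
}

#' MA-style plot of a differential-expression table
#'
#' Log2 fold change against mean normalized expression, significant genes
#' highlighted.
#'
#' @param object A `de_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.de_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$mean_expression,
                               y = .data$log2_fold_change,
                               colour = .data$direction != "ns")) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "red"),
                                 labels = c("ns", "FDR < 0.05"), name = NULL) +
    ggplot2::labs(x = "mean of normalized counts", y = "log2 fold change") +
    ggplot2::theme_minimal()
}

#' Strict genotype-exclusive protein sets
#'
#' A protein is A-exclusive when it is present in every batch of genotype A
#' and absent from every batch of genotype B (and symmetrically for B).
#' Presence in only some batches does not qualify — the published rule
#' requires detection in all three batches of one genotype and none of the
#' other.
#'
#' @param presence_a,presence_b Tibbles with `protein_id` plus one 0/1 (or
#'   logical) column per batch; both genotypes must cover the same proteins
#'   and the same number of batches.
#' @return List with `a_exclusive`, `b_exclusive` (character vectors) and
#'   `union` (their disjoint union).
#' @export
exclusive_sets <- function(presence_a, presence_b) {
  pa <- presence_matrix(presence_a); pb <- presence_matrix(presence_b)
  if (!identical(sort(rownames(pa)), sort(rownames(pb)))) {
    stop_erfrag("protein universes of the two genotypes differ.",
                "erfrag_alignment_error")
  }
  if (ncol(pa) != ncol(pb)) {
    stop_erfrag("batch counts differ between genotypes.", "erfrag_alignment_error")
  }
  pb <- pb[rownames(pa), , drop = FALSE]
  a_excl <- rownames(pa)[rowSums(pa) == ncol(pa) & rowSums(pb) == 0]
  b_excl <- rownames(pa)[rowSums(pb) == ncol(pb) & rowSums(pa) == 0]
  list(a_exclusive = a_excl, b_exclusive = b_excl,
       union = c(a_excl, b_excl))
}

presence_matrix <- function(presence) {
  stopifnot("protein_id" %in% names(presence))
  m <- as.matrix(presence[, setdiff(names(presence), "protein_id"), drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!m %in% c(0, 1))) {
    stop_erfrag("presence values must be 0/1 or logical.", "erfrag_input_error")
  }
  rownames(m) <- presence$protein_id
  m
}

#' Integrate transcript and protein fold changes at a common threshold
#'
#' Inner-joins a differential-expression table with protein log2 fold
#' changes on the shared identifier and retains concordant candidates whose
#' fold changes exceed the threshold at both levels: up-candidates with both
#' log2 fold changes above `up_threshold` (default +2), down-candidates with
#' both below `down_threshold` (default -2).
#'
#' @param de_table Output of [differential_expression()].
#' @param protein_fc Tibble with `protein_id` and `log2fc`.
#' @param up_threshold,down_threshold Log2 fold-change cut-offs.
#' @param require_significant Additionally require `q_bh < 0.05` at the
#'   transcript level (the published criterion is ambiguous; both modes are
#'   exposed).
#' @return List with `paired` (joined tibble), `up_candidates`,
#'   `down_candidates` and `counts`.
#' @export
integrate_gene_protein <- function(de_table, protein_fc, up_threshold = 2,
                                   down_threshold = -2,
                                   require_significant = FALSE) {
  paired <- dplyr::inner_join(
    de_table, protein_fc,
    by = c(gene_id = "protein_id"), suffix = c("_gene", "_protein")
  ) |>
    dplyr::rename(log2fc_protein = "log2fc")
  if (nrow(paired) == 0L) {
    rlang::warn("no transcript-protein identifier overlap; empty integration.")
  }
  keep <- if (require_significant) !is.na(paired$q_bh) & paired$q_bh < 0.05 else TRUE
  up <- paired[keep & paired$log2_fold_change > up_threshold &
                 paired$log2fc_protein > up_threshold, , drop = FALSE]
  down <- paired[keep & paired$log2_fold_change < down_threshold &
                   paired$log2fc_protein < down_threshold, , drop = FALSE]
  list(
    paired = paired,
    up_candidates = up, down_candidates = down,
    counts = tibble(n_paired = nrow(paired), n_up = nrow(up), n_down = nrow(down))
  )
}

#' Assign expression tiers by within-subset quartiles
#'
#' Ranks the subset's genes by expression (descending, ties broken by gene
#' id) and splits the ranking into four contiguous tiers — very high, high,
#' low, very low — whose sizes differ by at most one. Tiers are rank-based,
#' so any monotone transformation of the expression values leaves them
#' unchanged. Subsets smaller than 4 are assigned from the top tier down
#' with a warning.
#'
#' @param expression Tibble with `gene_id` and `expression` (positive).
#' @param genes_subset Genes to tier (default: all rows).
#' @return Tibble `gene_id`, `expression`, `tier` (ordered factor).
#' @export
expression_tiers <- function(expression, genes_subset = NULL) {
  stopifnot(all(c("gene_id", "expression") %in% names(expression)))
  if (!is.null(genes_subset)) {
    expression <- dplyr::filter(expression, .data$gene_id %in% genes_subset)
  }
  if (any(expression$expression <= 0)) {
    stop_erfrag("expression values must be positive for tiering.",
                "erfrag_input_error")
  }
  lv <- c("very_high", "high", "low", "very_low")
  n <- nrow(expression)
  expression <- dplyr::arrange(expression, dplyr::desc(.data$expression),
                               .data$gene_id)
  if (n < 4L) {
    rlang::warn("fewer than 4 genes: tiers assigned by value from the top down.")
    tier <- lv[seq_len(n)]
  } else {
    sizes <- diff(floor(seq(0, n, length.out = 5L)))
    tier <- rep(lv, times = sizes)
  }
  dplyr::mutate(expression, tier = factor(tier, levels = lv))
}

#' Top-n genes by raw p value
#'
#' Ascending raw p value, ties at the boundary broken by lexicographic gene
#' id (the ranking the cross-study comparison consumes).
#'
#' @param de_table Tibble with `gene_id` and `p_raw`.
#' @param n List length.
#' @return Character vector of gene ids.
#' @export
top_n_by_pvalue <- function(de_table, n) {
  if (anyDuplicated(de_table$gene_id)) {
    stop_erfrag("duplicate gene ids.", "erfrag_input_error")
  }
  n <- assert_count(n, "n", min = 0L, class = "erfrag_input_error")
  if (n > nrow(de_table)) {
    stop_erfrag("n exceeds the table size.", "erfrag_input_error")
  }
  ranked <- dplyr::arrange(de_table, .data$p_raw, .data$gene_id)
  utils::head(ranked$gene_id, n)
}

#' Overlap between two gene lists
#'
#' @param list_a,list_b Character vectors.
#' @return List with `shared` (intersection, sorted) and `n_shared`.
#' @export
cross_overlap <- function(list_a, list_b) {
  shared <- sort(intersect(list_a, list_b))
  list(shared = shared, n_shared = length(shared))
}

#' Hypergeometric over-representation analysis
#'
#' For each annotation term, tests whether the selected genes overlap the
#' term more than expected under sampling without replacement from the
#' universe: the one-sided p value is the upper hypergeometric tail
#' P(overlap >= observed). P values are BH-adjusted across terms; terms with
#' no annotated gene in the universe are dropped; output is sorted by p.
#'
#' @param selected_genes Character vector, a subset of `universe`.
#' @param annotation_sets Named list of gene sets (term -> genes).
#' @param universe Character vector of all assayed genes.
#' @return Tibble: `term_id`, `term_size`, `n_selected`, `overlap`, `p`, `q`.
#' @export
ora <- function(selected_genes, annotation_sets, universe) {
  selected_genes <- unique(selected_genes)
  universe <- unique(universe)
  outside <- setdiff(selected_genes, universe)
  if (length(outside) > 0) {
    stop_erfrag(
      sprintf("selected gene(s) not in universe: %s",
              paste(utils::head(outside, 5L), collapse = ", ")),
      "erfrag_input_error"
    )
  }
  N <- length(universe); n_sel <- length(selected_genes)
  rows <- purrr::imap_dfr(annotation_sets, function(genes, term) {
    genes <- intersect(unique(genes), universe)
    K <- length(genes)
    if (K == 0L) return(NULL)
    k <- length(intersect(selected_genes, genes))
    p <- stats::phyper(k - 1, K, N - K, n_sel, lower.tail = FALSE)
    tibble(term_id = term, term_size = K, n_selected = n_sel, overlap = k, p = p)
  })
  if (nrow(rows) == 0L) return(dplyr::mutate(rows, q = numeric(0)))
  rows$q <- bh_adjust(rows$p)
  dplyr::arrange(rows, .data$p, .data$term_id)
}
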