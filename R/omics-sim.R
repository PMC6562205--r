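#' Simulate a two-condition transcriptome with matched proteome detection
#'
#' Generates the multi-omics design of the hepatocyte-model study: RNA counts
#' for two genotypes (condition A, the disease genotype, vs. condition B, its
#' isogenic control) from a negative-binomial model with planted log2 fold
#' changes on designated genes; per-batch protein presence/absence tables
#' (default 3 batches per genotype) in which detection probability increases
#' with expression; a configurable number of genotype-exclusive proteins
#' (default 14 A-exclusive and 3 B-exclusive, the published design); and a
#' GMT-style annotation with one term enriched among the up-regulated genes.
#'
#' Planted fold changes are applied symmetrically (half up in A, half down in
#' B on the log scale) so mean expression is comparable across conditions.
#' Gene and protein identifiers are shared, so transcript-protein integration
#' joins on the identifier directly.
#'
#' @param n_genes Total genes.
#' @param n_up,n_down Planted up-/down-regulated genes (up = higher in A).
#' @param log2fc_mean,log2fc_sd Planted |log2 fold change| distribution.
#' @param dispersion Negative-binomial dispersion (1/size).
#' @param n_replicates RNA replicates per condition.
#' @param n_batches Proteome batches per genotype.
#' @param n_proteins Proteins detected by mass spectrometry (first
#'   `n_proteins` genes).
#' @param n_a_exclusive,n_b_exclusive Genotype-exclusive protein counts.
#' @param detection_scale Mean expression at which per-batch detection
#'   probability reaches ~63%.
#' @param n_terms,term_size Annotation terms and genes per term.
#' @param seed Integer seed.
#' @return List with `counts` (tibble, `gene_id` + one column per sample),
#'   `groups` (sample/condition tibble), `truth` (planted per-gene effects),
#'   `presence_a`, `presence_b` (protein x batch 0/1 tibbles), `protein_fc`
#'   (protein-level log2 fold changes), `annotation` (named list of gene
#'   sets), `enriched_term`, `universe`.
#' @export
generate_omics <- function(n_genes = 2000L, n_up = 100L, n_down = 100L,
                           log2fc_mean = 2, log2fc_sd = 0.25,
                           dispersion = 0.1, n_replicates = 3L,
                           n_batches = 3L, n_proteins = 600L,
                           n_a_exclusive = 14L, n_b_exclusive = 3L,
                           detection_scale = 50, n_terms = 10L,
                           term_size = 50L, seed) {
  n_genes <- assert_count(n_genes, "n_genes", min = 1L, class = "erfrag_config_error")
  n_up <- assert_count(n_up, "n_up", class = "erfrag_config_error")
  n_down <- assert_count(n_down, "n_down", class = "erfrag_config_error")
  if (n_up + n_down > n_genes) {
    stop_erfrag("n_up + n_down must not exceed n_genes.", "erfrag_config_error")
  }
  n_replicates <- assert_count(n_replicates, "n_replicates", min = 2L,
                               class = "erfrag_config_error")
  n_batches <- assert_count(n_batches, "n_batches", min = 1L,
                            class = "erfrag_config_error")
  n_proteins <- min(assert_count(n_proteins, "n_proteins", min = 1L,
                                 class = "erfrag_config_error"), n_genes)
  if (missing(seed)) stop_erfrag("`seed` must be supplied.", "erfrag_config_error")
  set.seed(as.integer(seed))

  gene_id <- sprintf("G%05d", seq_len(n_genes))
  base_mu <- exp(stats::rnorm(n_genes, mean = 5, sd = 1.3))

  planted <- rep("ns", n_genes)
  idx <- sample.int(n_genes, n_up + n_down)
  up_idx <- idx[seq_len(n_up)]
  down_idx <- idx[n_up + seq_len(n_down)]
  planted[up_idx] <- "up"; planted[down_idx] <- "down"
  lfc <- numeric(n_genes)
  lfc[up_idx] <- abs(stats::rnorm(n_up, log2fc_mean, log2fc_sd))
  lfc[down_idx] <- -abs(stats::rnorm(n_down, log2fc_mean, log2fc_sd))

  mu_a <- base_mu * 2^(lfc / 2)
  mu_b <- base_mu * 2^(-lfc / 2)
  size <- 1 / dispersion
  draw <- function(mu) matrix(
    stats::rnbinom(n_genes * n_replicates, mu = rep(mu, n_replicates), size = size),
    nrow = n_genes
  )
  counts_a <- draw(mu_a); counts_b <- draw(mu_b)
  samples <- c(sprintf("A_%d", seq_len(n_replicates)),
               sprintf("B_%d", seq_len(n_replicates)))
  counts <- as_tibble(cbind(counts_a, counts_b), .name_repair = ~samples)
  counts <- dplyr::bind_cols(tibble(gene_id = gene_id), counts)
  groups <- tibble(sample_id = samples,
                   condition = rep(c("A", "B"), each = n_replicates))

  # proteome: detection probability saturates with mean expression
  prot_idx <- seq_len(n_proteins)
  protein_id <- gene_id[prot_idx]
  p_detect <- 1 - exp(-base_mu[prot_idx] / detection_scale)
  draw_presence <- function() {
    m <- matrix(stats::runif(n_proteins * n_batches) < p_detect, n_proteins)
    colnames(m) <- sprintf("batch_%d", seq_len(n_batches))
    m
  }
  pres_a <- draw_presence(); pres_b <- draw_presence()
  n_a_exclusive <- min(n_a_exclusive, n_proteins)
  n_b_exclusive <- min(n_b_exclusive, n_proteins - n_a_exclusive)
  # exclusive proteins preferentially among planted DE genes when available
  a_pool <- intersect(prot_idx, up_idx); b_pool <- intersect(prot_idx, down_idx)
  a_excl <- utils::head(c(a_pool, setdiff(prot_idx, c(a_pool, b_pool))), n_a_exclusive)
  b_pool <- setdiff(c(b_pool, setdiff(prot_idx, c(a_excl, b_pool))), a_excl)
  b_excl <- utils::head(b_pool, n_b_exclusive)
  pres_a[match(a_excl, prot_idx), ] <- TRUE
  pres_b[match(a_excl, prot_idx), ] <- FALSE
  pres_a[match(b_excl, prot_idx), ] <- FALSE
  pres_b[match(b_excl, prot_idx), ] <- TRUE
  # break exclusivity patterns that arose by chance so the matrices contain
  # exactly the configured exclusive sets
  designated <- c(match(a_excl, prot_idx), match(b_excl, prot_idx))
  acc_a <- setdiff(which(rowSums(pres_a) == n_batches & rowSums(pres_b) == 0),
                   designated)
  acc_b <- setdiff(which(rowSums(pres_b) == n_batches & rowSums(pres_a) == 0),
                   designated)
  pres_a[acc_a, 1L] <- FALSE
  pres_b[acc_b, 1L] <- FALSE

  presence_a <- dplyr::bind_cols(tibble(protein_id = protein_id),
                                 as_tibble(pres_a * 1L))
  presence_b <- dplyr::bind_cols(tibble(protein_id = protein_id),
                                 as_tibble(pres_b * 1L))
  protein_fc <- tibble(
    protein_id = protein_id,
    log2fc = lfc[prot_idx] + stats::rnorm(n_proteins, sd = 0.3)
  )

  # GMT-style annotation: one term enriched among the planted up genes
  term_size <- min(term_size, n_genes)
  annotation <- purrr::map(seq_len(max(n_terms, 1L)), function(i) {
    sample(gene_id, term_size)
  })
  names(annotation) <- sprintf("TERM_%03d", seq_len(max(n_terms, 1L)))
  enriched_term <- "TERM_001"
  if (n_up > 0) {
    n_from_up <- min(ceiling(0.6 * term_size), n_up)
    annotation[[enriched_term]] <- unique(c(
      sample(gene_id[up_idx], n_from_up),
      sample(gene_id, term_size - n_from_up)
    ))
  }

  list(
    counts = counts, groups = groups,
    truth = tibble(gene_id = gene_id, planted = planted, true_log2fc = lfc,
                   base_mean = base_mu),
    presence_a = presence_a, presence_b = presence_b,
    protein_fc = protein_fc,
    annotation = annotation, enriched_term = if (n_up > 0) enriched_term else NA,
    a_exclusive = gene_id[a_excl], b_exclusive = gene_id[b_excl],
    universe = gene_id
  )
}

#' Write gene sets in GMT format
#'
#' One line per term: term id, description, then member genes, tab-separated.
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional per-term description column.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- purrr::imap_chr(sets, function(genes, term) {
    paste(c(term, descriptions[[match(term, names(sets))]], genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return Named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(
    purrr::map(parts, function(x) unique(x[-(1:2)])),
    purrr::map_chr(parts, 1L)
  )
}
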