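ranked_list <- function(result, gene_type = c("seed", "interactor", "both")) {
  stopifnot(inherits(result, "cancer_result"))
  gene_type <- match.arg(gene_type)
  if (gene_type == "seed") return(result$seeds)
  if (gene_type == "interactor") return(result$interactors)
  df <- rbind(result$seeds, result$interactors)
  o <- order(-df$network_score, -df$mutated_interactors, df$gene)
  df <- df[o, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  row.names(df) <- NULL
  df
}

#' Top-scoring genes of one cancer
#'
#' First `n` genes of the requested ranked list; for `gene_type = "both"`
#' the seed and interactor lists are pooled and re-ranked by the same key
#' (score desc, mutated interactors desc, symbol asc) before truncation.
#' Lists shorter than `n` are returned whole.
#'
#' @param result a `cancer_result`.
#' @param n number of genes to keep.
#' @param gene_type `"seed"`, `"interactor"` or `"both"`.
#' @return character vector of gene symbols in rank order.
#' @export
top_hubs <- function(result, n = 50, gene_type = c("seed", "interactor", "both")) {
  stopifnot(n >= 1)
  df <- ranked_list(result, gene_type)
  utils::head(df$gene, n)
}

#' Genes recurring among the top hubs of several cancers
#'
#' Intersects the top-`n` lists of each cancer and keeps genes that are a
#' top-`n` hub in at least `k` cancers, sorted by number of cancers
#' descending then gene symbol.
#'
#' @param results list of `cancer_result` objects.
#' @param n top-list cutoff per cancer.
#' @param k minimum number of cancers.
#' @param gene_type which list(s) to intersect.
#' @return data.frame with columns `gene`, `n_cancers`, `cancers`
#'   (comma-joined, in input order).
#' @export
shared_hubs <- function(results, n = 50, k = 3,
                        gene_type = c("seed", "interactor", "both")) {
  stopifnot(k >= 1, n >= 1)
  if (length(results) == 0L) stop("shared_hubs: empty result list")
  gene_type <- match.arg(gene_type)
  cancers <- unname(vapply(results, function(r) r$cancer, character(1)))
  tops <- lapply(results, top_hubs, n = n, gene_type = gene_type)
  membership <- data.frame(
    gene = unlist(tops, use.names = FALSE),
    cancer = rep(cancers, lengths(tops)),
    stringsAsFactors = FALSE
  )
  counts <- table(membership$gene)
  keep <- names(counts)[counts >= k]
  if (length(keep) == 0L) {
    return(data.frame(gene = character(0), n_cancers = integer(0),
                      cancers = character(0), stringsAsFactors = FALSE))
  }
  joined <- vapply(keep, function(g) {
    paste(cancers[cancers %in% membership$cancer[membership$gene == g]],
          collapse = ",")
  }, character(1))
  out <- data.frame(gene = keep, n_cancers = as.integer(counts[keep]),
                    cancers = joined, stringsAsFactors = FALSE)
  out <- out[order(-out$n_cancers, out$gene), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Gene x cancer network-score matrix
#'
#' Assembles the network scores of several cancers into one matrix (genes
#' union over results; structural zeros where a gene is absent from a
#' cancer's lists). With `normalize = TRUE` every cancer column is min-max
#' scaled to `[0, 1]` so scores become comparable across cohorts with
#' different mutation rates; an all-equal column maps to all zeros.
#'
#' @param results list of `cancer_result` objects.
#' @param gene_type which list(s) to include.
#' @param normalize min-max scale each column.
#' @return numeric matrix, rownames genes, colnames cancer ids.
#' @export
build_score_matrix <- function(results,
                               gene_type = c("both", "seed", "interactor"),
                               normalize = TRUE) {
  if (length(results) == 0L) stop("build_score_matrix: empty result list")
  gene_type <- match.arg(gene_type)
  dfs <- lapply(results, ranked_list, gene_type = gene_type)
  cancers <- unname(vapply(results, function(r) r$cancer, character(1)))
  genes <- sort(unique(unlist(lapply(dfs, `[[`, "gene"), use.names = FALSE)))
  mat <- matrix(0, nrow = length(genes), ncol = length(cancers),
                dimnames = list(genes, cancers))
  for (j in seq_along(dfs)) {
    mat[dfs[[j]]$gene, j] <- dfs[[j]]$network_score
  }
  if (normalize) {
    mat <- apply(mat, 2L, function(x) {
      rng <- range(x)
      if (rng[1L] == rng[2L]) return(rep(0, length(x)))
      (x - rng[1L]) / (rng[2L] - rng[1L])
    })
    if (length(genes) == 1L) { # apply() drops to a vector for one row
      mat <- matrix(mat, nrow = 1L, dimnames = list(genes, cancers))
    }
  }
  mat
}

#' Correlations between mutation count, Meta-Z and network score
#'
#' Pairwise-complete correlation matrix of the three per-gene quantities
#' across one cancer's retained genes. Meta-Z enters only for seed genes
#' (interactors have no significant survival score). A zero-variance
#' quantity gets an undefined (`NA`) row and column, with a warning.
#'
#' @param result a `cancer_result`.
#' @param method `"pearson"` or `"spearman"` (scores are heavy-tailed; the
#'   rank-based option is more robust).
#' @return 3 x 3 symmetric numeric matrix with unit diagonal.
#' @export
score_correlations <- function(result, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  df <- rbind(result$seeds, result$interactors)
  vars <- data.frame(
    mutation_count = df$mutation_count,
    meta_z = ifelse(df$gene_type == "seed", df$meta_z, NA_real_),
    network_score = df$network_score
  )
  if (sum(stats::complete.cases(vars)) < 3L) {
    stop("score_correlations: need at least 3 genes with all three values")
  }
  degenerate <- vapply(vars, function(x) {
    s <- stats::sd(x, na.rm = TRUE)
    !is.finite(s) || s == 0
  }, logical(1))
  m <- suppressWarnings(
    stats::cor(vars, use = "pairwise.complete.obs", method = method)
  )
  if (any(degenerate)) {
    warning("score_correlations: zero variance in ",
            paste(names(vars)[degenerate], collapse = ", "),
            "; reporting NA")
    m[degenerate, ] <- NA_real_
    m[, degenerate] <- NA_real_
  }
  diag(m) <- 1
  m
}

#' Count genes scoring over a threshold
#'
#' Number of genes (seeds and interactors pooled) whose network score is
#' strictly greater than `threshold`.
#'
#' @param result a `cancer_result`.
#' @param threshold non-negative score cutoff.
#' @return integer count.
#' @export
count_high_scores <- function(result, threshold = 100) {
  stopifnot(threshold >= 0)
  df <- rbind(result$seeds, result$interactors)
  sum(df$network_score > threshold)
}

#' Detect outlier genes by network score
#'
#' Genes whose network score lies significantly above the mean of the
#' selected list's score distribution: `score > mean + k_sd * sd` with the
#' sample standard deviation. A degenerate (zero-variance) distribution
#' yields no outliers, with a warning.
#'
#' @param result a `cancer_result`.
#' @param k_sd number of standard deviations above the mean (1.96 mirrors a
#'   95\% one-sided normal cutoff).
#' @param gene_type which list(s) to consider.
#' @return sorted character vector of outlier genes.
#' @export
detect_outliers <- function(result, k_sd = 1.96,
                            gene_type = c("both", "seed", "interactor")) {
  gene_type <- match.arg(gene_type)
  df <- ranked_list(result, gene_type)
  if (nrow(df) < 2L) stop("detect_outliers: need at least 2 scored genes")
  s <- stats::sd(df$network_score)
  if (s == 0) {
    warning("detect_outliers: zero score variance, no outliers")
    return(character(0))
  }
  cutoff <- mean(df$network_score) + k_sd * s
  sort(df$gene[df$network_score > cutoff])
}

#' Overlap of hub genes with an external cancer-gene list
#'
#' @param hubs character vector of predicted hub genes.
#' @param external character vector of externally curated cancer genes.
#' @return list with `intersection` (sorted symbols) and `percentage`
#'   (share of the external list covered, 0-100).
#' @export
external_overlap <- function(hubs, external) {
  external <- unique(toupper(trimws(external)))
  external <- external[external != ""]
  if (length(external) == 0L) stop("external_overlap: empty external list")
  hubs <- unique(toupper(trimws(hubs)))
  inter <- sort(intersect(hubs, external))
  list(intersection = inter,
       percentage = 100 * length(inter) / length(external))
}
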