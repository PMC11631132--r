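#' Count a gene's interactors and mutated interactors
#'
#' For each gene, `total_interactors` is its degree in the interactome (0
#' when the gene is absent from the graph) and `mutated_interactors` is the
#' number of its neighbours belonging to the mutated reference set. The gene
#' itself never counts: self-loops were removed at ingest.
#'
#' @param genes character vector of symbols.
#' @param itm an [interactome()].
#' @param mutated_set character vector of mutated symbols.
#' @return data.frame with columns `gene`, `total_interactors`,
#'   `mutated_interactors`.
#' @export
neighbour_counts <- function(genes, itm, mutated_set) {
  stopifnot(inherits(itm, "interactome"))
  genes <- toupper(trimws(genes))
  mutated_set <- unique(toupper(trimws(mutated_set)))
  nb <- itm$adj[genes]
  data.frame(
    gene = genes,
    total_interactors = vapply(nb, length, integer(1), USE.NAMES = FALSE),
    mutated_interactors = vapply(nb, function(v) sum(v %in% mutated_set),
                                 integer(1), USE.NAMES = FALSE),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Network score of a gene
#'
#' The score multiplies the total number of interactors `T` by the fraction
#' of them that are mutated, `M / T`, which is algebraically the number of
#' mutated neighbours `M`. It is nevertheless evaluated as written, with `T`
#' and `M` reported separately in all outputs so downstream consumers can
#' form any variant without rescoring. Isolated genes (`T = 0`) score 0.
#'
#' @param total_interactors,mutated_interactors non-negative integer vectors
#'   with `mutated <= total` elementwise.
#' @return numeric vector of scores.
#' @export
network_score <- function(total_interactors, mutated_interactors) {
  t_ <- as.numeric(total_interactors)
  m_ <- as.numeric(mutated_interactors)
  if (any(m_ < 0) || any(t_ < 0)) stop("network_score: negative count")
  if (any(m_ > t_)) {
    stop("network_score: mutated_interactors exceeds total_interactors")
  }
  ifelse(t_ > 0, t_ * (m_ / t_), 0)
}

#' Score retained genes and build the ranked seed / interactor lists
#'
#' Computes every retained gene's network score against the interactome and
#' the mutated reference set, splits the genes by type, and ranks each list
#' by score descending with ties broken by mutated-interactor count
#' descending, then gene symbol ascending. Genes absent from the interactome
#' keep score 0 and rank at the bottom rather than being dropped.
#'
#' @param statuses data.frame of retained genes from [filter_genes()]
#'   (rows with `retained == TRUE`; passing non-retained rows is an error).
#' @param itm an [interactome()].
#' @param mutated_set mutated reference symbols; default is the mutated
#'   subset of `statuses` (the filtered reading). Pass the full mutated gene
#'   list of the cohort for the raw reading.
#' @param cancer cancer id; default taken from `statuses`.
#' @param thresholds optional [filter_thresholds()] to carry into outputs;
#'   default is the `"thresholds"` attribute of `statuses`.
#' @param mutated_reference label recorded in run metadata
#'   (`"filtered"` or `"raw"`).
#' @return an object of class `cancer_result`: list with `cancer`, ranked
#'   data.frames `seeds` and `interactors`, `thresholds`, `mutated_set` and
#'   `metadata`.
#' @export
score_and_rank <- function(statuses, itm, mutated_set = NULL,
                           cancer = NULL, thresholds = NULL,
                           mutated_reference = c("filtered", "raw")) {
  mutated_reference <- match.arg(mutated_reference)
  if (any(!statuses$retained)) {
    stop("score_and_rank: statuses contain non-retained genes")
  }
  if (anyDuplicated(statuses$gene)) {
    stop("score_and_rank: duplicate gene symbols: ",
         paste(unique(statuses$gene[duplicated(statuses$gene)]),
               collapse = ", "))
  }
  if (is.null(cancer)) {
    cancer <- if (nrow(statuses) > 0L) statuses$cancer[1L] else NA_character_
  }
  if (is.null(thresholds)) thresholds <- attr(statuses, "thresholds")
  if (is.null(mutated_set)) {
    mutated_set <- statuses$gene[statuses$total_count > 0]
  }
  mutated_set <- unique(toupper(trimws(mutated_set)))

  counts <- neighbour_counts(statuses$gene, itm, mutated_set)
  scored <- data.frame(
    gene = statuses$gene,
    gene_type = statuses$gene_type,
    cluster = statuses$cluster,
    precog_label = statuses$precog_label,
    meta_z = statuses$meta_z,
    mutation_count = statuses$total_count,
    location_class = statuses$location_class,
    total_interactors = counts$total_interactors,
    mutated_interactors = counts$mutated_interactors,
    network_score = network_score(counts$total_interactors,
                                  counts$mutated_interactors),
    stringsAsFactors = FALSE
  )
  rank_list <- function(df) {
    o <- order(-df$network_score, -df$mutated_interactors, df$gene)
    df <- df[o, , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    row.names(df) <- NULL
    df
  }
  structure(
    list(cancer = cancer,
         seeds = rank_list(scored[scored$gene_type == "seed", , drop = FALSE]),
         interactors = rank_list(scored[scored$gene_type == "interactor", ,
                                        drop = FALSE]),
         thresholds = thresholds,
         mutated_set = sort(mutated_set),
         metadata = list(mutated_reference = mutated_reference)),
    class = "cancer_result"
  )
}

#' @export
print.cancer_result <- function(x, ...) {
  cat(sprintf("<cancer_result> %s: %d seeds, %d interactors, %d mutated reference genes\n",
              x$cancer, nrow(x$seeds), nrow(x$interactors),
              length(x$mutated_set)))
  invisible(x)
}
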