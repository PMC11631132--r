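#' Configuration for a synthetic cohort
#'
#' Describes one simulated cancer cohort: a skewed (geometric) distribution
#' of per-gene mutation counts, a sparse set of genes with significant
#' survival Meta-Z scores, and an Erdos-Renyi background interactome into
#' which `n_hubs` hub genes are planted. Each planted hub is an unmutated
#' gene given a strong survival score (`|Z| >= 2.58`, so it survives
#' filtering as a seed) and wired to `hub_degree` distinct mutated genes,
#' making its expected network score far exceed the background.
#'
#' @param n_genes total number of genes.
#' @param n_mutated number of genes carrying at least one mutation.
#' @param mutation_count_p geometric success probability; per-gene counts
#'   are `1 + rgeom(p)` (right-skewed, minimum 1).
#' @param frac_orf probability that a mutation event falls in the ORF.
#' @param n_precog_sig number of non-hub genes given `|Z| >= 1.96` (half of
#'   them `>= 2.58`), signs random.
#' @param z_sd scale of the background Meta-Z scores (truncated normal kept
#'   inside the significance band so ground truth is exact).
#' @param background_degree mean degree of the background interactome.
#' @param n_hubs number of planted hub genes.
#' @param hub_degree planted edges from each hub to mutated genes.
#' @param cancer cancer id used in the emitted files.
#' @param seed integer RNG seed; one seed drives deterministic sub-streams
#'   per output file.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500, n_mutated = 250,
                       mutation_count_p = 0.3, frac_orf = 0.7,
                       n_precog_sig = 50, z_sd = 1,
                       background_degree = 3, n_hubs = 3, hub_degree = 25,
                       cancer = "SYNTH", seed = 1L) {
  stopifnot(n_genes >= 2, n_mutated >= 1, n_mutated <= n_genes,
            mutation_count_p > 0, mutation_count_p < 1,
            frac_orf > 0, frac_orf < 1,
            n_precog_sig >= 0, z_sd > 0, background_degree > 0,
            n_hubs >= 0, n_hubs <= n_genes - n_mutated,
            n_precog_sig <= n_genes - n_hubs)
  if (n_hubs > 0 && hub_degree < 1) stop("sim_config: hub_degree must be >= 1")
  if (hub_degree > n_mutated) {
    stop("sim_config: hub_degree exceeds the number of mutated genes")
  }
  structure(list(n_genes = n_genes, n_mutated = n_mutated,
                 mutation_count_p = mutation_count_p, frac_orf = frac_orf,
                 n_precog_sig = n_precog_sig, z_sd = z_sd,
                 background_degree = background_degree, n_hubs = n_hubs,
                 hub_degree = hub_degree, cancer = cancer,
                 seed = as.integer(seed)),
            class = "sim_config")
}

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", eol = "\n", fileEncoding = "UTF-8")
  close(con)
  path
}

#' Generate a complete synthetic cohort with known ground truth
#'
#' Emits a MAF-like mutation table, a Meta-Z table, a TAB3 interaction file
#' and a ground-truth JSON into `dir`. An identical `sim_config` (including
#' seed) produces byte-identical files; each file draws from its own
#' deterministic sub-stream so regenerating one does not perturb the others.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return list with `paths` (mutations, precog, interactions, truth),
#'   `truth` (list: `hub_genes`, per-gene data.frame `genes`,
#'   `mutated_genes`) and `config`.
#' @export
generate_cohort <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  sub_seed <- sample.int(2147483646L, 3L)
  genes <- sprintf("G%06d", seq_len(config$n_genes))

  # stream 1: mutation events
  set.seed(sub_seed[1L])
  mutated <- sort(sample(genes, config$n_mutated))
  counts <- 1L + stats::rgeom(config$n_mutated, config$mutation_count_p)
  n_events <- sum(counts)
  in_orf <- stats::runif(n_events) < config$frac_orf
  labels <- character(n_events)
  labels[in_orf] <- sample(default_orf_labels, sum(in_orf), replace = TRUE)
  labels[!in_orf] <- sample(default_non_orf_labels, sum(!in_orf),
                            replace = TRUE)
  mut_df <- data.frame(Hugo_Symbol = rep(mutated, counts),
                       Variant_Classification = labels,
                       check.names = FALSE, stringsAsFactors = FALSE)

  # stream 2: survival Meta-Z scores (background truncated inside the
  # non-significant band so the significant set is exactly the planted one)
  set.seed(sub_seed[2L])
  lo <- stats::pnorm(-1.96, sd = config$z_sd)
  hi <- stats::pnorm(1.96, sd = config$z_sd)
  z <- stats::qnorm(stats::runif(config$n_genes, lo, hi), sd = config$z_sd)
  names(z) <- genes
  hubs <- if (config$n_hubs > 0) {
    sort(sample(setdiff(genes, mutated), config$n_hubs))
  } else character(0)
  sig <- if (config$n_precog_sig > 0) {
    sample(setdiff(genes, hubs), config$n_precog_sig)
  } else character(0)
  n_strong <- ceiling(length(sig) / 2)
  strong <- sig[seq_len(n_strong)]
  weak <- setdiff(sig, strong)
  z[strong] <- sample(c(-1, 1), length(strong), replace = TRUE) *
    (2.58 + abs(stats::rnorm(length(strong), sd = 0.5)))
  z[weak] <- sample(c(-1, 1), length(weak), replace = TRUE) *
    stats::runif(length(weak), 1.96, 2.575)
  z[hubs] <- sample(c(-1, 1), length(hubs), replace = TRUE) *
    (2.58 + abs(stats::rnorm(length(hubs), sd = 0.5)))
  z <- round(z, 6)
  precog_df <- data.frame(Gene = genes, z = z, check.names = FALSE,
                          stringsAsFactors = FALSE, row.names = NULL)
  names(precog_df)[2L] <- config$cancer

  # stream 3: interactome = ER background + planted hub wiring
  set.seed(sub_seed[3L])
  p_edge <- min(1, config$background_degree / (config$n_genes - 1))
  g <- igraph::sample_gnp(config$n_genes, p_edge)
  bg_edges <- igraph::as_edgelist(g)
  edge_a <- genes[bg_edges[, 1L]]
  edge_b <- genes[bg_edges[, 2L]]
  for (h in hubs) {
    targets <- sample(setdiff(mutated, h), config$hub_degree)
    edge_a <- c(edge_a, rep(h, config$hub_degree))
    edge_b <- c(edge_b, targets)
  }
  itm <- interactome(cbind(edge_a, edge_b), nodes = genes)
  tab3_df <- data.frame(
    "#BioGRID Interaction ID" = seq_len(nrow(itm$edges)),
    "Official Symbol Interactor A" = itm$edges$a,
    "Official Symbol Interactor B" = itm$edges$b,
    "Experimental System Type" = "physical",
    check.names = FALSE, stringsAsFactors = FALSE
  )

  # ground truth, consistent with the emitted files by construction
  orf_events <- split(in_orf, rep(mutated, counts))
  orf_count <- integer(config$n_genes); names(orf_count) <- genes
  non_orf_count <- orf_count
  orf_count[mutated] <- vapply(orf_events[mutated], sum, integer(1))
  total <- orf_count
  total[mutated] <- counts
  non_orf_count[mutated] <- total[mutated] - orf_count[mutated]
  nc <- neighbour_counts(genes, itm, mutated)
  truth_genes <- data.frame(
    gene = genes,
    total_count = as.integer(total),
    orf_count = as.integer(orf_count),
    non_orf_count = as.integer(non_orf_count),
    location_class = classify_location(orf_count, non_orf_count),
    meta_z = as.numeric(z),
    total_interactors = nc$total_interactors,
    mutated_interactors = nc$mutated_interactors,
    stringsAsFactors = FALSE, row.names = NULL
  )
  truth <- list(cancer = config$cancer, hub_genes = hubs,
                mutated_genes = mutated, genes = truth_genes)

  paths <- list(
    mutations = write_tsv(mut_df, file.path(dir, "mutations.tsv")),
    precog = write_tsv(precog_df, file.path(dir, "precog.tsv")),
    interactions = write_tsv(tab3_df, file.path(dir, "interactions.tab3.tsv")),
    truth = file.path(dir, "truth.json")
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  list(paths = paths, truth = truth, config = config)
}

#' Recovery of planted hubs in a ranked result
#'
#' Fraction of the planted hub genes ranked within the top `top_k` of the
#' seed list, with each hub's rank reported. With no planted hubs the
#' recovery is vacuously 1.
#'
#' @param truth ground-truth list from [generate_cohort()].
#' @param result the `cancer_result` computed from the matching cohort.
#' @param top_k rank cutoff.
#' @return list with `recovery` (in `[0, 1]`) and `detail` (data.frame
#'   `gene`, `rank`, `in_top_k`).
#' @export
recovery_report <- function(truth, result, top_k) {
  hubs <- truth$hub_genes
  if (length(hubs) == 0L) {
    return(list(recovery = 1.0,
                detail = data.frame(gene = character(0), rank = integer(0),
                                    in_top_k = logical(0))))
  }
  all_genes <- c(result$seeds$gene, result$interactors$gene)
  if (!all(hubs %in% all_genes)) {
    stop("recovery_report: planted hub(s) absent from result: ",
         paste(setdiff(hubs, all_genes), collapse = ", "),
         " (gene-set mismatch between truth and result)")
  }
  rank <- result$seeds$rank[match(hubs, result$seeds$gene)]
  detail <- data.frame(gene = hubs, rank = rank,
                       in_top_k = !is.na(rank) & rank <= top_k,
                       stringsAsFactors = FALSE)
  list(recovery = mean(detail$in_top_k), detail = detail)
}
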