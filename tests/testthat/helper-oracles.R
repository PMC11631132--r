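# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's own code paths: the median is recomputed from order
# statistics, retention rules are transcribed one scalar case at a time, and
# graph quantities come from igraph.

write_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

oracle_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# scalar transcription of the five retention inequalities + the rescue rule
oracle_retained <- function(class, f, label, z, md, min_, z_strong = 2.58) {
  effect <- label != "none"
  if (class == "NON_ORF" && effect) return(f >= md + min_)
  if (class == "NON_ORF") return(f > 3 * md + min_)
  if (class == "ORF") return(f >= md - min_)
  if (class == "BOTH" && effect) return(f >= md - min_)
  if (class == "BOTH") return(f > 3 * md)
  if (class == "NONE") return(!is.na(z) && abs(z) >= z_strong)
  stop("oracle_retained: bad class ", class)
}

oracle_label <- function(z, z_sig = 1.96) {
  if (is.na(z)) return("none")
  if (z >= z_sig) return("oncogene")
  if (z <= -z_sig) return("tumour_suppressor")
  "none"
}

oracle_cluster <- function(f, label) {
  if (f > 0 && label == "none") return("MUT")
  if (f == 0) return("PRECOG")
  "MUT_PRECOG"
}

oracle_class <- function(orf, non) {
  if (orf > 0 && non > 0) return("BOTH")
  if (orf > 0) return("ORF")
  if (non > 0) return("NON_ORF")
  "NONE"
}

# random toy cohort for filter-rule equivalence checks
random_filter_cohort <- function(seed, max_genes = 50) {
  set.seed(seed)
  n <- sample(5:max_genes, 1)
  genes <- sprintf("T%03d", seq_len(n))
  orf <- stats::rgeom(n, 0.4)
  non <- stats::rgeom(n, 0.5)
  if (all(orf + non == 0)) orf[1] <- 1L
  has_z <- stats::runif(n) < 0.6
  z <- ifelse(has_z, stats::rnorm(n, sd = 1.5), NA_real_)
  profiles <- data.frame(
    gene = genes, cancer = "TOY", orf_count = orf, non_orf_count = non,
    total_count = orf + non,
    location_class = vapply(seq_len(n), function(i) oracle_class(orf[i], non[i]),
                            character(1)),
    stringsAsFactors = FALSE
  )
  precog <- data.frame(gene = genes[has_z], cancer = "TOY",
                       meta_z = z[has_z], stringsAsFactors = FALSE)
  list(profiles = profiles, precog = precog, z = z)
}

# gene-by-gene evaluation of the whole filter, independent of filter_genes()
oracle_filter <- function(cohort, z_sig = 1.96, z_strong = 2.58) {
  profiles <- cohort$profiles
  z <- cohort$z
  label <- vapply(z, oracle_label, character(1), z_sig = z_sig)
  keep <- profiles$total_count > 0 | label != "none"
  positive <- profiles$total_count[profiles$total_count > 0]
  md <- if (length(positive)) oracle_median(positive) else 0
  min_ <- if (length(positive)) min(positive) else 0
  out <- profiles[keep, , drop = FALSE]
  zk <- z[keep]; lk <- label[keep]
  out$meta_z <- zk
  out$precog_label <- lk
  out$retained <- vapply(seq_len(nrow(out)), function(i) {
    oracle_retained(out$location_class[i], out$total_count[i], lk[i], zk[i],
                    md, min_, z_strong)
  }, logical(1))
  out$cluster <- NA_character_
  out$gene_type <- NA_character_
  r <- which(out$retained)
  out$cluster[r] <- vapply(r, function(i) oracle_cluster(out$total_count[i], lk[i]),
                           character(1))
  out$gene_type[r] <- ifelse(out$cluster[r] == "MUT", "interactor", "seed")
  out[order(out$gene), , drop = FALSE]
}

# igraph as the independent route for degree / mutated-neighbour counts
oracle_neighbour_counts <- function(edges, nodes, gene, mutated) {
  ig <- igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE,
                                      vertices = nodes)
  ig <- igraph::simplify(ig)
  if (!gene %in% nodes) return(c(0L, 0L))
  nb <- names(igraph::neighbors(ig, gene))
  c(length(nb), sum(nb %in% mutated))
}

# a ranked cancer_result assembled by hand (sorting spelled out explicitly)
toy_result <- function(cancer, seed_genes = character(0), seed_scores = numeric(0),
                       int_genes = character(0), int_scores = numeric(0),
                       seed_M = NULL, int_M = NULL,
                       seed_mut = NULL, seed_z = NULL) {
  build <- function(genes, scores, M, type, mut = NULL, z = NULL) {
    n <- length(genes)
    if (is.null(M)) M <- round(scores)
    if (is.null(mut)) mut <- rep(0L, n)
    if (is.null(z)) z <- rep(NA_real_, n)
    df <- data.frame(
      gene = genes, gene_type = rep(type, n),
      cluster = rep(if (type == "seed") "PRECOG" else "MUT", n),
      precog_label = rep(if (type == "seed") "oncogene" else "none", n),
      meta_z = z, mutation_count = mut,
      location_class = rep(if (type == "seed") "NONE" else "ORF", n),
      total_interactors = pmax(as.integer(M), 1L) + 2L,
      mutated_interactors = as.integer(M),
      network_score = scores, stringsAsFactors = FALSE
    )
    df <- df[order(-df$network_score, -df$mutated_interactors, df$gene), ,
             drop = FALSE]
    df$rank <- seq_len(nrow(df))
    row.names(df) <- NULL
    df
  }
  structure(
    list(cancer = cancer,
         seeds = build(seed_genes, seed_scores, seed_M, "seed",
                       seed_mut, seed_z),
         interactors = build(int_genes, int_scores, int_M, "interactor"),
         thresholds = filter_thresholds(1, 1),
         mutated_set = character(0),
         metadata = list(mutated_reference = "filtered")),
    class = "cancer_result"
  )
}

# small synthetic cohort config used by slower end-to-end tests
small_sim <- function(seed, ...) {
  sim_config(n_genes = 200, n_mutated = 100, n_precog_sig = 20,
             n_hubs = 2, hub_degree = 15, seed = seed, ...)
}
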