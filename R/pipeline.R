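default_run_config <- function() {
  list(
    cancers = list(),            # named list: cancer id -> mutation path
    precog = NULL,               # path to the Meta-Z table
    precog_columns = NULL,       # named: cancer id -> column (default = id)
    interactions = NULL,         # path to the TAB3 file
    gene_column = "Gene",
    columns = c(gene = "Hugo_Symbol", variant = "Variant_Classification"),
    orf_labels = default_orf_labels,
    non_orf_labels = default_non_orf_labels,
    unknown_policy = "error",
    z_sig = 1.96,
    z_strong = 2.58,
    non_orf_noeffect_mult = 3,
    both_noeffect_mult = 3,
    mutated_reference = "filtered",
    formats = c("tsv", "json"),
    out_dir = NULL
  )
}

#' Load a pipeline configuration file
#'
#' Reads a YAML file and merges it over the package defaults. Recognised
#' keys mirror the arguments of [run_pipeline()]'s stages: input paths per
#' cancer, column names, the ORF / NON_ORF label map, significance
#' thresholds, the rule multipliers, `mutated_reference` and output options.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (k in names(user)) cfg[[k]] <- user[[k]]
  if (!is.null(user$columns)) cfg$columns <- unlist(user$columns)
  cfg
}

#' Run the full per-cancer pipeline
#'
#' Executes the stages in order for every configured cancer: read mutations,
#' aggregate per-gene profiles, integrate survival Meta-Z scores, apply the
#' md/min retention rules, score retained genes against the interactome and
#' write ranked seed / interactor lists. Gene counts at every stage boundary
#' are recorded in each result's metadata and a `run_metadata.json` is
#' written next to the outputs when `out_dir` is set.
#'
#' @param config configuration list (see [load_run_config()]) or the path
#'   to a YAML file.
#' @param quiet suppress per-stage messages.
#' @return named list of `cancer_result` objects, one per cancer.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- load_run_config(config)
  }
  cfg <- default_run_config()
  for (k in names(config)) cfg[[k]] <- config[[k]]
  if (length(cfg$cancers) == 0L) stop("run_pipeline: no cancers configured")
  if (is.null(cfg$precog)) stop("run_pipeline: no Meta-Z table configured")
  if (is.null(cfg$interactions)) {
    stop("run_pipeline: no interaction file configured")
  }
  say <- function(...) if (!quiet) message(...)
  vm <- variant_map(cfg$orf_labels, cfg$non_orf_labels, cfg$unknown_policy)
  itm <- read_biogrid_tab3(cfg$interactions)
  say("interactome: ", length(itm$nodes), " nodes, ", nrow(itm$edges),
      " edges")

  results <- list()
  for (cancer in names(cfg$cancers)) {
    mut_path <- cfg$cancers[[cancer]]
    precog_col <- cfg$precog_columns[[cancer]]
    if (is.null(precog_col)) precog_col <- cancer
    records <- read_mutation_table(mut_path, cancer, vm, cfg$columns)
    profiles <- build_gene_profiles(records, cancer = cancer)
    precog <- read_precog_table(cfg$precog, precog_col, cfg$gene_column)
    statuses <- filter_genes(profiles, precog,
                             z_sig = cfg$z_sig, z_strong = cfg$z_strong,
                             non_orf_noeffect_mult = cfg$non_orf_noeffect_mult,
                             both_noeffect_mult = cfg$both_noeffect_mult)
    retained <- statuses[statuses$retained, , drop = FALSE]
    attr(retained, "thresholds") <- attr(statuses, "thresholds")
    mutated_set <- switch(cfg$mutated_reference,
      filtered = retained$gene[retained$total_count > 0],
      raw = profiles$gene[profiles$total_count > 0],
      stop("run_pipeline: mutated_reference must be 'filtered' or 'raw'")
    )
    res <- score_and_rank(retained, itm, mutated_set, cancer = cancer,
                          mutated_reference = cfg$mutated_reference)
    stage_counts <- list(
      mutation_records = nrow(records),
      mutated_genes = sum(profiles$total_count > 0),
      evaluated_genes = nrow(statuses),
      retained_genes = nrow(retained),
      seeds = nrow(res$seeds),
      interactors = nrow(res$interactors)
    )
    # conservation across the score stage: nothing silently dropped
    stopifnot(stage_counts$seeds + stage_counts$interactors ==
                stage_counts$retained_genes)
    res$metadata <- c(res$metadata, list(
      stage_counts = stage_counts,
      input_checksums = list(
        mutations = unname(tools::md5sum(mut_path)),
        precog = unname(tools::md5sum(cfg$precog)),
        interactions = unname(tools::md5sum(cfg$interactions))
      )
    ))
    say(cancer, ": ", stage_counts$mutation_records, " records, ",
        stage_counts$mutated_genes, " mutated genes, ",
        stage_counts$retained_genes, " retained (",
        stage_counts$seeds, " seeds + ", stage_counts$interactors,
        " interactors); md=", res$thresholds$md,
        " min=", res$thresholds$min_)
    if (!is.null(cfg$out_dir)) {
      write_results(res, file.path(cfg$out_dir, cancer), cfg$formats)
    }
    results[[cancer]] <- res
  }
  if (!is.null(cfg$out_dir)) {
    meta <- list(
      tool = "hubscore",
      version = as.character(utils::packageVersion("hubscore")),
      mutated_reference = cfg$mutated_reference,
      z_sig = cfg$z_sig, z_strong = cfg$z_strong,
      non_orf_noeffect_mult = cfg$non_orf_noeffect_mult,
      both_noeffect_mult = cfg$both_noeffect_mult,
      cancers = lapply(results, function(r) {
        c(list(md = r$thresholds$md, min = r$thresholds$min_),
          r$metadata$stage_counts)
      })
    )
    jsonlite::write_json(meta, file.path(cfg$out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  results
}

#' Cross-cancer comparison of pipeline results
#'
#' Runs the Results-style analytics over several per-cancer results: the
#' shared top-hub table, the min-max normalised score matrix, and (when
#' external gene lists are given) the overlap of each cancer's outlier genes
#' with each list. Tables are written as TSV when `out_dir` is set.
#'
#' @param results named list of `cancer_result` objects.
#' @param n top-list cutoff (50 focuses on the strongest hubs).
#' @param k minimum number of cancers for a shared hub.
#' @param gene_type list(s) used for the shared-hub table.
#' @param external optional named list of external gene-list character
#'   vectors (or file paths, read via [read_gene_list()]).
#' @param k_sd outlier cutoff in standard deviations for the overlap step.
#' @param out_dir optional output directory.
#' @return list with `shared` (data.frame), `matrix` (numeric matrix) and
#'   `overlaps` (data.frame or `NULL`).
#' @export
compare_results <- function(results, n = 50, k = 3,
                            gene_type = c("seed", "interactor", "both"),
                            external = NULL, k_sd = 1.96, out_dir = NULL) {
  gene_type <- match.arg(gene_type)
  if (length(results) < 1L) stop("compare_results: no results given")
  shared <- shared_hubs(results, n = n, k = k, gene_type = gene_type)
  mat <- build_score_matrix(results, gene_type = "both", normalize = TRUE)
  overlaps <- NULL
  if (!is.null(external)) {
    if (is.null(names(external))) {
      names(external) <- paste0("list", seq_along(external))
    }
    rows <- list()
    for (lname in names(external)) {
      ext <- external[[lname]]
      if (is.character(ext) && length(ext) == 1L && file.exists(ext)) {
        ext <- read_gene_list(ext)
      }
      for (cancer in names(results)) {
        out <- detect_outliers(results[[cancer]], k_sd = k_sd,
                               gene_type = "both")
        ov <- external_overlap(out, ext)
        rows[[length(rows) + 1L]] <- data.frame(
          cancer = cancer, external = lname,
          n_external = length(unique(toupper(trimws(ext)))),
          n_overlap = length(ov$intersection),
          percentage = ov$percentage, stringsAsFactors = FALSE
        )
      }
    }
    overlaps <- do.call(rbind, rows)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(shared, file.path(out_dir, "shared_hubs.tsv"))
    mat_df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                         stringsAsFactors = FALSE)
    write_tsv(mat_df, file.path(out_dir, "score_matrix.tsv"))
    if (!is.null(overlaps)) {
      write_tsv(overlaps, file.path(out_dir, "external_overlap.tsv"))
    }
  }
  list(shared = shared, matrix = mat, overlaps = overlaps)
}
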