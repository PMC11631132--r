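#' Read a MAF-like mutation table
#'
#' Reads a tab-separated mutation table (one row per mutation event) keeping
#' the gene-symbol and variant-classification columns, and harmonises every
#' variant label into `ORF` / `NON_ORF` through a [variant_map()]. Gene
#' symbols are uppercased and whitespace-stripped; input row order is
#' preserved.
#'
#' @param path path to a tab-separated file with a header row.
#' @param cancer cancer-type identifier attached to every record.
#' @param map a [variant_map()]; its `unknown_policy` decides what happens to
#'   rows whose label is in neither set.
#' @param columns named character vector with entries `gene` and `variant`
#'   giving the column names to use.
#' @return data.frame with columns `gene`, `region`, `raw_label`, `cancer`.
#' @export
read_mutation_table <- function(path, cancer, map = variant_map(),
                                columns = c(gene = "Hugo_Symbol",
                                            variant = "Variant_Classification")) {
  if (!file.exists(path)) stop("mutation table not found: ", path)
  stopifnot(all(c("gene", "variant") %in% names(columns)))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  for (col in columns[c("gene", "variant")]) {
    if (!col %in% names(df)) {
      stop("mutation table ", path, ": required column '", col,
           "' absent from header")
    }
  }
  gene <- toupper(trimws(df[[columns[["gene"]]]]))
  raw_label <- df[[columns[["variant"]]]]
  if (nrow(df) > 0L && any(gene == "")) {
    stop("mutation table ", path, ": empty gene symbol at line ",
         which(gene == "")[1L] + 1L)
  }
  region <- resolve_region(raw_label, map)
  unknown <- is.na(region)
  if (any(unknown)) {
    if (map$unknown_policy == "error") {
      i <- which(unknown)[1L]
      stop("mutation table ", path, ": unknown variant label '",
           raw_label[i], "' at line ", i + 1L)
    } else if (map$unknown_policy == "non_orf") {
      region[unknown] <- "NON_ORF"
    } else { # skip
      keep <- !unknown
      gene <- gene[keep]; region <- region[keep]; raw_label <- raw_label[keep]
    }
  }
  data.frame(gene = gene, region = region, raw_label = raw_label,
             cancer = rep(cancer, length(gene)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read a Meta-Z survival-score table
#'
#' Loads one cancer column from a gene x cancer table of survival meta-Z
#' scores. Non-numeric or empty cells are skipped (a message reports how
#' many); duplicate gene symbols are resolved by keeping the record with the
#' largest absolute Z, preserving significance calls in either direction.
#'
#' @param path tab-separated file with a gene column and one numeric column
#'   per cancer type.
#' @param cancer_column name of the column to load.
#' @param gene_column name of the gene-symbol column.
#' @return data.frame with columns `gene`, `cancer`, `meta_z`.
#' @export
read_precog_table <- function(path, cancer_column, gene_column = "Gene") {
  if (!file.exists(path)) stop("meta-Z table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  for (col in c(gene_column, cancer_column)) {
    if (!col %in% names(df)) {
      stop("meta-Z table ", path, ": column '", col, "' absent from header")
    }
  }
  gene <- toupper(trimws(df[[gene_column]]))
  meta_z <- suppressWarnings(as.numeric(df[[cancer_column]]))
  bad <- !is.finite(meta_z) | gene == ""
  if (sum(bad) > 0L) {
    message("read_precog_table: skipped ", sum(bad),
            " unparsable cell(s) in column '", cancer_column, "'")
  }
  gene <- gene[!bad]
  meta_z <- meta_z[!bad]
  if (length(gene) == 0L) {
    stop("meta-Z table ", path, ": zero parsable rows for column '",
         cancer_column, "'")
  }
  first_seen <- unique(gene)
  # keep max |z| per gene; stable order() makes ties resolve to first input row
  o <- order(-abs(meta_z))
  keep <- o[!duplicated(gene[o])]
  keep <- keep[order(match(gene[keep], first_seen))]
  data.frame(gene = gene[keep], cancer = cancer_column,
             meta_z = meta_z[keep], stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Build an interactome from an edge list
#'
#' Constructs the undirected symbol-keyed interaction graph used for network
#' scoring. Symbols are uppercased and trimmed; self-loops are dropped;
#' duplicate pairs (in either order) collapse to a single edge.
#'
#' @param edges two-column matrix or data.frame of interactor symbols; may be
#'   `NULL` for an empty graph.
#' @param nodes optional additional node symbols (isolated nodes allowed).
#' @return an object of class `interactome` with elements `nodes` (sorted
#'   character), `edges` (data.frame `a`, `b` with `a < b`) and `adj`
#'   (named adjacency list).
#' @export
interactome <- function(edges = NULL, nodes = character()) {
  nodes <- toupper(trimws(as.character(nodes)))
  if (is.null(edges) || NROW(edges) == 0L) {
    a <- character(0); b <- character(0)
  } else {
    edges <- as.matrix(edges)
    stopifnot(ncol(edges) == 2L)
    a <- toupper(trimws(as.character(edges[, 1L])))
    b <- toupper(trimws(as.character(edges[, 2L])))
  }
  keep <- a != b & a != "" & b != ""
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  lo <- lo[!dup]; hi <- hi[!dup]
  all_nodes <- sort(unique(c(nodes[nodes != ""], lo, hi)))
  adj <- lapply(
    split(c(hi, lo), factor(c(lo, hi), levels = all_nodes)),
    function(v) sort(unique(v))
  )
  edf <- data.frame(a = lo, b = hi, stringsAsFactors = FALSE)
  edf <- edf[order(edf$a, edf$b), , drop = FALSE]
  row.names(edf) <- NULL
  structure(list(nodes = all_nodes, edges = edf, adj = adj),
            class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat("<interactome> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  invisible(x)
}

#' Read a BioGRID TAB3 interaction file
#'
#' Parses the tab-separated BioGRID TAB3 dialect into an undirected
#' [interactome()]. Only the two official-symbol columns are consumed;
#' evidence lines repeating the same unordered pair collapse to one edge and
#' self-interactions are removed.
#'
#' @param path path to the TAB3 file.
#' @param symbol_columns names of the two interactor-symbol columns.
#' @param row_filter optional function taking the raw data.frame and
#'   returning a logical keep-vector, e.g. to restrict to physical evidence.
#' @return an [interactome()].
#' @export
read_biogrid_tab3 <- function(path,
                              symbol_columns = c("Official Symbol Interactor A",
                                                 "Official Symbol Interactor B"),
                              row_filter = NULL) {
  if (!file.exists(path)) stop("interaction file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  missing <- setdiff(symbol_columns, names(df))
  if (length(missing) > 0L) {
    stop("interaction file ", path, ": column(s) ",
         paste(sprintf("'%s'", missing), collapse = ", "),
         " absent from header")
  }
  if (!is.null(row_filter)) df <- df[row_filter(df), , drop = FALSE]
  # "-" is TAB3's missing-symbol marker
  a <- df[[symbol_columns[[1L]]]]
  b <- df[[symbol_columns[[2L]]]]
  ok <- !(a %in% c("", "-")) & !(b %in% c("", "-"))
  itm <- interactome(cbind(a[ok], b[ok]))
  if (nrow(itm$edges) == 0L) {
    warning("interaction file ", path, ": no edges after filtering")
  }
  itm
}

#' Read a plain-text gene list
#'
#' One symbol per line; `#` starts a comment; blank lines ignored; symbols
#' uppercased; duplicates removed keeping first occurrence.
#'
#' @param path path to the list file.
#' @return character vector of symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- toupper(trimws(lines))
  unique(lines[lines != ""])
}

result_columns <- c("gene", "gene_type", "cluster", "precog_label", "meta_z",
                    "mutation_count", "location_class", "total_interactors",
                    "mutated_interactors", "network_score", "rank")

#' Write ranked per-cancer results
#'
#' Writes the seed and interactor lists of a [score_and_rank()] result, one
#' file per list and format. TSV files use a `.` decimal separator, UTF-8 and
#' LF line endings for reproducible diffs; the JSON file mirrors the records
#' and prepends a run-metadata header (thresholds, md/min, mutated-set size,
#' input checksums when known).
#'
#' @param result a `cancer_result` from [score_and_rank()].
#' @param out_dir output directory (created if needed).
#' @param formats subset of `c("tsv", "json")`.
#' @return invisibly, the character vector of written file paths.
#' @export
write_results <- function(result, out_dir, formats = c("tsv", "json")) {
  stopifnot(inherits(result, "cancer_result"))
  formats <- match.arg(formats, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  th <- result$thresholds
  if ("tsv" %in% formats) {
    for (lst in c("seeds", "interactors")) {
      p <- file.path(out_dir, sprintf("%s_%s.tsv", result$cancer, lst))
      con <- file(p, open = "wb") # LF endings on every platform
      utils::write.table(result[[lst]][, result_columns], con, sep = "\t",
                         quote = FALSE, row.names = FALSE, na = "NA",
                         eol = "\n", fileEncoding = "UTF-8")
      close(con)
      paths <- c(paths, p)
    }
  }
  if ("json" %in% formats) {
    p <- file.path(out_dir, sprintf("%s_results.json", result$cancer))
    payload <- list(
      metadata = c(list(cancer = result$cancer),
                   result$metadata,
                   list(thresholds = unclass(th),
                        n_mutated_reference = length(result$mutated_set))),
      seeds = result$seeds[, result_columns],
      interactors = result$interactors[, result_columns]
    )
    jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows")
    paths <- c(paths, p)
  }
  invisible(paths)
}
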