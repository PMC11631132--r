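#' Classify a gene's mutation location
#'
#' Four-way location class from the per-gene region counts: `ORF` when all
#' mutations fall in the coding sequence, `NON_ORF` when all fall outside it,
#' `BOTH` when both regions are hit, `NONE` when no mutation was detected.
#'
#' @param orf_count,non_orf_count non-negative integer vectors (recycled).
#' @return character vector of classes.
#' @examples
#' classify_location(c(3, 0, 1, 0), c(0, 0, 4, 0))
#' @export
classify_location <- function(orf_count, non_orf_count) {
  if (any(orf_count < 0) || any(non_orf_count < 0)) {
    stop("classify_location: counts must be non-negative")
  }
  n <- max(length(orf_count), length(non_orf_count))
  orf <- rep_len(orf_count, n)
  non <- rep_len(non_orf_count, n)
  out <- rep("NONE", n)
  out[orf > 0 & non == 0] <- "ORF"
  out[orf == 0 & non > 0] <- "NON_ORF"
  out[orf > 0 & non > 0] <- "BOTH"
  out
}

#' Aggregate mutation records into per-gene profiles
#'
#' Tallies ORF / NON_ORF event counts per gene and assigns the location
#' class. Genes listed in `universe` but absent from the records receive a
#' zero-count `NONE` profile, so survival-only genes can flow through the
#' same downstream path.
#'
#' @param records data.frame of mutation records from
#'   [read_mutation_table()]; all rows must share one cancer id.
#' @param universe optional character vector of symbols guaranteed a profile.
#' @param cancer cancer id to use when `records` is empty.
#' @return data.frame with columns `gene`, `cancer`, `orf_count`,
#'   `non_orf_count`, `total_count`, `location_class`, one row per gene,
#'   sorted by gene symbol.
#' @export
build_gene_profiles <- function(records, universe = NULL, cancer = NA_character_) {
  if (nrow(records) > 0L) {
    ids <- unique(records$cancer)
    if (length(ids) > 1L) {
      stop("build_gene_profiles: records mix cancer ids: ",
           paste(ids, collapse = ", "))
    }
    cancer <- ids
  }
  universe <- toupper(trimws(as.character(universe)))
  genes <- sort(unique(c(records$gene, universe[universe != ""])))
  region <- factor(records$region, levels = c("ORF", "NON_ORF"))
  tab <- table(factor(records$gene, levels = genes), region)
  orf <- as.integer(tab[, "ORF"])
  non <- as.integer(tab[, "NON_ORF"])
  data.frame(
    gene = genes, cancer = rep(cancer, length(genes)),
    orf_count = orf, non_orf_count = non, total_count = orf + non,
    location_class = classify_location(orf, non),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
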