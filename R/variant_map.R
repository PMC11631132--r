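#' Default ORF variant-classification labels
#'
#' MAF-dialect variant classes whose nucleotide change falls inside the
#' protein-coding sequence. Silent/synonymous changes are included: they can
#' affect transcript stability and are treated as potentially functional.
#' @keywords internal
default_orf_labels <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Silent", "Synonymous",
  "Frame_Shift_Ins", "Frame_Shift_Del", "In_Frame_Ins", "In_Frame_Del",
  "Nonstop_Mutation", "Translation_Start_Site"
)

#' Default NON_ORF variant-classification labels
#' @keywords internal
default_non_orf_labels <- c(
  "3'UTR", "5'UTR", "Intron", "5'Flank", "3'Flank", "IGR", "RNA",
  "Splice_Site", "Splice_Region"
)

#' Build a variant-classification map
#'
#' Maps raw MAF-style variant-classification labels onto the two harmonised
#' regions, `ORF` and `NON_ORF`. Matching is case-insensitive and ignores
#' surrounding whitespace. Labels seen in the data but present in neither set
#' are handled according to `unknown_policy`: `"error"` aborts the read,
#' `"skip"` drops the row, `"non_orf"` assigns the row to `NON_ORF`.
#'
#' @param orf_labels character vector of labels mapped to `ORF`.
#' @param non_orf_labels character vector of labels mapped to `NON_ORF`.
#' @param unknown_policy one of `"error"`, `"skip"`, `"non_orf"`.
#' @return an object of class `variant_map`.
#' @examples
#' vm <- variant_map()
#' resolve_region(c("Missense_Mutation", "Intron"), vm)
#' @export
variant_map <- function(orf_labels = default_orf_labels,
                        non_orf_labels = default_non_orf_labels,
                        unknown_policy = c("error", "skip", "non_orf")) {
  unknown_policy <- match.arg(unknown_policy)
  orf_key <- tolower(trimws(orf_labels))
  non_orf_key <- tolower(trimws(non_orf_labels))
  clash <- intersect(orf_key, non_orf_key)
  if (length(clash) > 0L) {
    stop("variant_map: labels mapped to both regions: ",
         paste(clash, collapse = ", "))
  }
  structure(
    list(orf_labels = orf_labels, non_orf_labels = non_orf_labels,
         unknown_policy = unknown_policy,
         orf_key = orf_key, non_orf_key = non_orf_key),
    class = "variant_map"
  )
}

#' Resolve raw variant labels to regions
#'
#' @param labels character vector of raw variant-classification labels.
#' @param map a [variant_map()].
#' @return character vector with entries `"ORF"`, `"NON_ORF"` or `NA` for
#'   labels not covered by the map (the caller applies the unknown policy).
#' @export
resolve_region <- function(labels, map) {
  stopifnot(inherits(map, "variant_map"))
  key <- tolower(trimws(labels))
  out <- rep(NA_character_, length(key))
  out[key %in% map$orf_key] <- "ORF"
  out[key %in% map$non_orf_key] <- "NON_ORF"
  out
}

#' @export
print.variant_map <- function(x, ...) {
  cat("<variant_map> ", length(x$orf_labels), " ORF labels, ",
      length(x$non_orf_labels), " NON_ORF labels, unknown_policy=",
      x$unknown_policy, "\n", sep = "")
  invisible(x)
}
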