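#' Filter thresholds for gene retention
#'
#' Bundles the per-cancer mutation-count anchors (`md`, the median, and
#' `min_`, the minimum, of per-gene mutation counts over mutated genes) with
#' the survival-significance levels and the multipliers of the retention
#' rules. Defaults follow the standard two-sided normal quantiles: 1.96
#' (95\% confidence) for calling a survival effect, 2.58 (99\%) for rescuing
#' unmutated genes.
#'
#' @param md median per-gene mutation count (real; non-integer for even n).
#' @param min_ minimum per-gene mutation count.
#' @param z_sig significance level for the oncogene / tumour-suppressor call.
#' @param z_strong stricter level rescuing unmutated genes.
#' @param non_orf_noeffect_mult multiplier in the `NON_ORF`, no-effect rule
#'   (`count > mult * md + min_`).
#' @param both_noeffect_mult multiplier in the `BOTH`, no-effect rule
#'   (`count > mult * md`).
#' @return an object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(md, min_, z_sig = 1.96, z_strong = 2.58,
                              non_orf_noeffect_mult = 3,
                              both_noeffect_mult = 3) {
  stopifnot(is.numeric(md), is.numeric(min_),
            z_sig > 0, z_strong >= z_sig,
            min_ >= 0, md >= min_)
  structure(list(md = md, min_ = min_, z_sig = z_sig, z_strong = z_strong,
                 non_orf_noeffect_mult = non_orf_noeffect_mult,
                 both_noeffect_mult = both_noeffect_mult),
            class = "filter_thresholds")
}

#' @export
print.filter_thresholds <- function(x, ...) {
  cat(sprintf("<filter_thresholds> md=%g min=%g z_sig=%g z_strong=%g\n",
              x$md, x$min_, x$z_sig, x$z_strong))
  invisible(x)
}

#' Label genes by survival Meta-Z score
#'
#' `oncogene` when `meta_z >= z_sig`, `tumour_suppressor` when
#' `meta_z <= -z_sig` (both boundaries inclusive), otherwise `none`. A
#' missing score (`NA`) means no survival evidence and yields `none`.
#'
#' @param meta_z numeric vector of Meta-Z scores; `NA` allowed.
#' @param z_sig positive significance threshold.
#' @return character vector of labels.
#' @export
precog_label <- function(meta_z, z_sig = 1.96) {
  stopifnot(z_sig > 0)
  if (any(!is.na(meta_z) & !is.finite(meta_z))) {
    stop("precog_label: non-finite meta_z")
  }
  out <- rep("none", length(meta_z))
  out[!is.na(meta_z) & meta_z >= z_sig] <- "oncogene"
  out[!is.na(meta_z) & meta_z <= -z_sig] <- "tumour_suppressor"
  out
}

#' Per-cancer mutation-count anchors
#'
#' Median and minimum of per-gene total mutation counts over the mutated
#' genes of a cohort (genes absent from the mutation data do not enter, so a
#' structural zero cannot collapse the thresholds). The median of an even
#' number of genes is the mean of the two middle order statistics and may be
#' non-integer.
#'
#' @param profiles data.frame from [build_gene_profiles()].
#' @return list with elements `md` and `min_`.
#' @export
mutation_stats <- function(profiles) {
  counts <- profiles$total_count[profiles$total_count > 0]
  if (length(counts) == 0L) {
    stop("mutation_stats: no mutated gene in profiles")
  }
  list(md = stats::median(counts), min_ = min(counts))
}

#' Decide gene retention
#'
#' Applies the class-specific retention rules anchored on `md` and `min_`
#' (`f` is the gene's total mutation count, an "effect" is a label other
#' than `none`):
#' \itemize{
#'   \item `NON_ORF`, effect: retained iff `f >= md + min_`
#'   \item `NON_ORF`, no effect: retained iff `f > 3 * md + min_`
#'   \item `ORF`, any label: retained iff `f >= md - min_`
#'   \item `BOTH`, effect: retained iff `f >= md - min_`
#'   \item `BOTH`, no effect: retained iff `f > 3 * md`
#'   \item `NONE`: retained iff `|meta_z| >= z_strong` (never when absent)
#' }
#' All inequalities are evaluated in real arithmetic; the multipliers are
#' configurable through [filter_thresholds()].
#'
#' @param location_class character vector of location classes.
#' @param total_count numeric vector of per-gene mutation counts.
#' @param label character vector of survival labels ([precog_label()]).
#' @param meta_z numeric vector of Meta-Z scores (`NA` = absent).
#' @param th a [filter_thresholds()].
#' @return logical vector of retention decisions.
#' @export
is_retained <- function(location_class, total_count, label, meta_z, th) {
  stopifnot(inherits(th, "filter_thresholds"))
  n <- length(location_class)
  f <- rep_len(as.numeric(total_count), n)
  label <- rep_len(label, n)
  meta_z <- rep_len(as.numeric(meta_z), n)
  effect <- label != "none"
  ret <- rep(NA, n)
  i <- location_class == "NON_ORF" & effect
  ret[i] <- f[i] >= th$md + th$min_
  i <- location_class == "NON_ORF" & !effect
  ret[i] <- f[i] > th$non_orf_noeffect_mult * th$md + th$min_
  i <- location_class == "ORF"
  ret[i] <- f[i] >= th$md - th$min_
  i <- location_class == "BOTH" & effect
  ret[i] <- f[i] >= th$md - th$min_
  i <- location_class == "BOTH" & !effect
  ret[i] <- f[i] > th$both_noeffect_mult * th$md
  i <- location_class == "NONE"
  ret[i] <- !is.na(meta_z[i]) & abs(meta_z[i]) >= th$z_strong
  if (anyNA(ret)) {
    stop("is_retained: unknown location class: ",
         paste(unique(location_class[is.na(ret)]), collapse = ", "))
  }
  ret
}

#' Assign the mutation / survival cluster
#'
#' Retained genes fall in exactly one of three clusters: `MUT` (mutated, no
#' survival effect), `PRECOG` (unmutated, significant survival score) or
#' `MUT_PRECOG` (both). An unmutated gene without a survival label has been
#' discarded upstream; encountering one here is a contract violation.
#'
#' @param total_count numeric vector of mutation counts.
#' @param label character vector of survival labels.
#' @return character vector of clusters.
#' @export
assign_cluster <- function(total_count, label) {
  mutated <- total_count > 0
  effect <- label != "none"
  if (any(!mutated & !effect)) {
    stop("assign_cluster: unmutated gene without survival label ",
         "should have been discarded upstream")
  }
  out <- character(length(total_count))
  out[mutated & !effect] <- "MUT"
  out[!mutated & effect] <- "PRECOG"
  out[mutated & effect] <- "MUT_PRECOG"
  out
}

#' Label, filter and cluster the genes of one cancer
#'
#' Evaluates the union of mutated genes and survival-scored genes: genes with
#' no mutation and no significant survival score are discarded before
#' evaluation; `md` / `min_` are computed once from the mutated subset; each
#' remaining gene gets a retention decision, a cluster and a gene type
#' (`seed` for `PRECOG` / `MUT_PRECOG`, `interactor` for `MUT`).
#'
#' @param profiles data.frame from [build_gene_profiles()].
#' @param precog data.frame from [read_precog_table()] (may have zero rows).
#' @param z_sig,z_strong significance thresholds, see [filter_thresholds()].
#' @param non_orf_noeffect_mult,both_noeffect_mult rule multipliers.
#' @return data.frame with one row per evaluated gene: the profile columns
#'   plus `meta_z`, `precog_label`, `retained`, `cluster` and `gene_type`
#'   (the last two `NA` for non-retained genes). The
#'   [filter_thresholds()] used are attached as attribute `"thresholds"`.
#' @export
filter_genes <- function(profiles, precog, z_sig = 1.96, z_strong = 2.58,
                         non_orf_noeffect_mult = 3, both_noeffect_mult = 3) {
  if (is.null(precog) || nrow(precog) == 0L) {
    precog <- data.frame(gene = character(0), meta_z = numeric(0),
                         stringsAsFactors = FALSE)
  }
  cancer <- if (nrow(profiles) > 0L) profiles$cancer[1L] else NA_character_
  extra <- setdiff(precog$gene, profiles$gene)
  if (length(extra) > 0L) {
    zero <- data.frame(
      gene = extra, cancer = cancer, orf_count = 0L, non_orf_count = 0L,
      total_count = 0L, location_class = "NONE", stringsAsFactors = FALSE
    )
    profiles <- rbind(profiles, zero)
  }
  profiles <- profiles[order(profiles$gene), , drop = FALSE]
  meta_z <- precog$meta_z[match(profiles$gene, precog$gene)]
  label <- precog_label(meta_z, z_sig)

  keep <- profiles$total_count > 0 | label != "none"
  profiles <- profiles[keep, , drop = FALSE]
  meta_z <- meta_z[keep]
  label <- label[keep]

  if (any(profiles$total_count > 0)) {
    ms <- mutation_stats(profiles)
  } else {
    ms <- list(md = 0, min_ = 0) # only the NONE rescue branch can fire
  }
  th <- filter_thresholds(ms$md, ms$min_, z_sig, z_strong,
                          non_orf_noeffect_mult, both_noeffect_mult)
  retained <- is_retained(profiles$location_class, profiles$total_count,
                          label, meta_z, th)
  cluster <- rep(NA_character_, nrow(profiles))
  cluster[retained] <- assign_cluster(profiles$total_count[retained],
                                      label[retained])
  gene_type <- rep(NA_character_, nrow(profiles))
  gene_type[retained] <- ifelse(cluster[retained] == "MUT",
                                "interactor", "seed")
  out <- cbind(profiles,
               data.frame(meta_z = meta_z, precog_label = label,
                          retained = retained, cluster = cluster,
                          gene_type = gene_type, stringsAsFactors = FALSE))
  row.names(out) <- NULL
  attr(out, "thresholds") <- th
  out
}
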