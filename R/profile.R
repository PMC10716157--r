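# From ZOTU counts + taxonomy assignments + a per-sample 16S genus fraction
# to composite species-level relative abundances; rarefaction for the
# diversity analyses.

UNCLASSIFIED_BIF <- "Bifidobacterium (unclassified)"

#' Rarefy a ZOTU count table
#'
#' Samples with fewer total reads than `depth` are dropped (with a message);
#' remaining samples are subsampled to exactly `depth` reads without
#' replacement (multivariate hypergeometric).
#'
#' @param table samples-by-ZOTUs matrix of non-negative integer counts.
#' @param depth target depth (default 2000).
#' @param seed RNG seed (set once for the whole subsampling).
#' @return rarefied count matrix (possibly fewer rows).
#' @export
rarefy <- function(table, depth = 2000L, seed = NULL) {
  stopifnot(is.matrix(table), all(table >= 0), depth >= 1L)
  totals <- rowSums(table)
  keep <- totals >= depth
  if (!any(keep)) stop("all samples fall below the rarefaction depth ", depth)
  if (any(!keep)) {
    message(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(utils::head(rownames(table)[!keep], 5L), collapse = ", "),
            if (sum(!keep) > 5L) ", ..." else "")
  }
  x <- table[keep, , drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  # vegan warns when every count exceeds the depth (a heuristic aimed at
  # relative abundances); counts here are validated integers
  out <- withCallingHandlers(
    vegan::rrarefy(x, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  storage.mode(out) <- "integer"
  out
}

#' Composite species-level relative abundances
#'
#' For each sample and species s: `abundance(s) = reads(s) / reads(genus) *
#' bif16s`, where `reads(genus)` counts reads in all ZOTUs assigned within
#' genus *Bifidobacterium* and `bif16s` is the genus's share of the whole
#' bacterial community from 16S sequencing. Genus-level-only assignments
#' pool into the `"Bifidobacterium (unclassified)"` feature; discarded and
#' non-*Bifidobacterium* ZOTUs enter neither numerator nor denominator.
#' Row sums therefore equal `bif16s` exactly (zero rows for samples with no
#' bifidobacterial reads).
#'
#' @param table samples-by-ZOTUs count matrix (non-rarefied).
#' @param assignments data.frame from [classify_table()].
#' @param bif16s named numeric vector, per-sample genus fraction in `[0,1]`.
#' @return object of class `bifido_profile`: list with `abundance`
#'   (samples-by-features fraction matrix), `bif_fraction_16s`,
#'   `feature_map` (ZOTU -> feature for the ZOTUs used).
#' @export
composite_abundance <- function(table, assignments, bif16s) {
  stopifnot(is.matrix(table))
  miss <- setdiff(rownames(table), names(bif16s))
  if (length(miss)) stop("no 16S genus fraction for sample(s): ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  if (any(bif16s < 0 | bif16s > 1)) stop("bif16s fractions must lie in [0,1]")
  unassigned <- setdiff(colnames(table), assignments$zotu_id)
  if (length(unassigned)) stop("assignments missing for ZOTU(s): ",
                               paste(utils::head(unassigned, 5L), collapse = ", "))
  a <- assignments[match(colnames(table), assignments$zotu_id), , drop = FALSE]
  in_genus <- a$status == "assigned" &
    vapply(a$taxonomy, function(t) tax_has_genus(t), TRUE)
  feat <- rep(NA_character_, nrow(a))
  sp <- vapply(a$taxonomy[in_genus], function(t) tax_species(t) %na% UNCLASSIFIED_BIF, "")
  feat[in_genus] <- sp
  features <- sort(unique(stats::na.omit(feat)))
  if (!length(features)) features <- UNCLASSIFIED_BIF
  ab <- matrix(0, nrow(table), length(features),
               dimnames = list(rownames(table), features))
  bt <- table[, in_genus, drop = FALSE]
  denom <- rowSums(bt)
  zero <- denom == 0
  if (any(zero)) {
    warning(sum(zero), " sample(s) with zero bifidobacterial reads; ",
            "their profile rows are zero")
  }
  for (f in features) {
    num <- rowSums(table[, which(in_genus & feat == f), drop = FALSE])
    ab[, f] <- ifelse(zero, 0, num / denom) * bif16s[rownames(table)]
  }
  structure(list(abundance = ab,
                 bif_fraction_16s = bif16s[rownames(table)],
                 feature_map = stats::setNames(feat[in_genus],
                                               colnames(table)[in_genus])),
            class = "bifido_profile")
}

#' @export
print.bifido_profile <- function(x, ...) {
  cat("composite Bifidobacterium species profile\n")
  cat("  samples:  ", nrow(x$abundance), "\n", sep = "")
  cat("  features: ", ncol(x$abundance), " (",
      paste(utils::head(colnames(x$abundance), 4L), collapse = ", "),
      if (ncol(x$abundance) > 4L) ", ..." else "", ")\n", sep = "")
  invisible(x)
}

#' Group means of a species profile
#'
#' Per-group arithmetic mean of each feature (as shown next to species names
#' in community overview figures). Samples with a missing group value are
#' excluded with a message.
#'
#' @param profile a `bifido_profile` or a plain abundance matrix.
#' @param metadata data.frame with rownames = sample ids.
#' @param group_var column of `metadata` to group by.
#' @return data.frame: one row per group, columns `group`, `n`, then one
#'   mean per feature.
#' @export
aggregate_by <- function(profile, metadata, group_var) {
  ab <- if (inherits(profile, "bifido_profile")) profile$abundance else profile
  if (!group_var %in% names(metadata)) {
    stop("group_var `", group_var, "` not in metadata")
  }
  g <- metadata[rownames(ab), group_var]
  ok <- !is.na(g)
  if (!all(ok)) message(sum(!ok), " sample(s) without `", group_var, "` excluded")
  ab <- ab[ok, , drop = FALSE]; g <- factor(g[ok])
  empty <- setdiff(levels(g), unique(as.character(g)))
  if (length(empty)) warning("empty group(s) excluded: ", paste(empty, collapse = ", "))
  g <- droplevels(g)
  means <- apply(ab, 2L, function(col) tapply(col, g, mean))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1L,
                                           dimnames = list(levels(g), colnames(ab)))
  data.frame(group = rownames(means), n = as.integer(table(g)[rownames(means)]),
             means, check.names = FALSE, row.names = NULL,
             stringsAsFactors = FALSE)
}
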