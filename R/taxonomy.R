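#' @keywords internal
"_PACKAGE"

# Ranked lineages are semicolon-separated strings of `rank__Name` fields,
# e.g. "d__Bacteria;p__Actinobacteria;g__Bifidobacterium;s__Bifidobacterium longum".
# Any suffix of ranks may be absent; ranks must appear in canonical order.

.TAX_RANKS <- c("d", "p", "c", "o", "f", "g", "s")

#' Split a lineage string into named rank fields
#'
#' @param lineage a single lineage string (`rank__Name` fields separated by
#'   `;`), or `NA`/`""` for an empty lineage.
#' @return named character vector of taxon names, names are rank letters in
#'   canonical order (`d p c o f g s`).
#' @export
tax_split <- function(lineage) {
  if (length(lineage) != 1L) stop("`lineage` must be a single string")
  if (is.na(lineage) || !nzchar(lineage)) {
    return(stats::setNames(character(0), character(0)))
  }
  fields <- strsplit(lineage, ";", fixed = TRUE)[[1L]]
  fields <- trimws(fields)
  fields <- fields[nzchar(fields)]
  m <- regmatches(fields, regexec("^([a-z])__(.*)$", fields))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed lineage field(s): ", paste(fields[bad], collapse = ", "))
  }
  ranks <- vapply(m, `[[`, "", 2L)
  names_ <- vapply(m, `[[`, "", 3L)
  idx <- match(ranks, .TAX_RANKS)
  if (anyNA(idx)) stop("unknown rank prefix in lineage: ", lineage)
  if (is.unsorted(idx, strictly = TRUE)) {
    stop("lineage ranks out of canonical order: ", lineage)
  }
  stats::setNames(names_, ranks)
}

#' Join named rank fields back into a lineage string
#'
#' @param fields named character vector as returned by [tax_split()].
#' @return lineage string (`""` for an empty lineage).
#' @export
tax_join <- function(fields) {
  if (length(fields) == 0L) return("")
  paste(paste0(names(fields), "__", unname(fields)), collapse = ";")
}

#' Finest rank present in a lineage
#'
#' @param lineage lineage string.
#' @return single rank letter, or `NA_character_` for an empty lineage.
#' @export
tax_rank <- function(lineage) {
  f <- tax_split(lineage)
  if (length(f) == 0L) return(NA_character_)
  names(f)[length(f)]
}

# Numeric depth of the finest rank (0 = empty, 7 = species); used to compare
# which of two lineages is the finer ("higher taxonomy level").
tax_depth <- function(lineage) {
  r <- tax_rank(lineage)
  if (is.na(r)) 0L else match(r, .TAX_RANKS)
}

#' Lowest common ancestor (longest common prefix) of lineages
#'
#' The LCA of a set of ranked lineages is the longest shared prefix of rank
#' fields; it is the finest taxon on which all lineages agree.
#'
#' @param lineages character vector of lineage strings.
#' @return single lineage string (`""` if the lineages share nothing or the
#'   input is empty).
#' @export
tax_lca <- function(lineages) {
  lineages <- lineages[!is.na(lineages)]
  if (length(lineages) == 0L) return("")
  splits <- lapply(lineages, tax_split)
  acc <- splits[[1L]]
  for (s in splits[-1L]) {
    k <- min(length(acc), length(s))
    if (k == 0L) return("")
    same <- names(acc)[seq_len(k)] == names(s)[seq_len(k)] &
      unname(acc[seq_len(k)]) == unname(s[seq_len(k)])
    keep <- if (all(same)) k else (which(!same)[1L] - 1L)
    if (keep == 0L) return("")
    acc <- acc[seq_len(keep)]
  }
  tax_join(acc)
}

#' Does a lineage contain a given genus?
#'
#' @param lineage lineage string.
#' @param genus genus name (default `"Bifidobacterium"`).
#' @return logical.
#' @export
tax_has_genus <- function(lineage, genus = "Bifidobacterium") {
  f <- tax_split(lineage)
  !is.na(f["g"]) && identical(unname(f["g"]), genus)
}

# Species name for profiling: the `s` field if present, else NA.
tax_species <- function(lineage) {
  f <- tax_split(lineage)
  if (is.na(f["s"])) NA_character_ else unname(f["s"])
}
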