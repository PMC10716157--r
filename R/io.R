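# Readers/writers for the plain-text dialects the pipeline consumes:
# FASTA (via Biostrings), Newick (via ape), BLAST tabular hits, metadata /
# count / distance-matrix TSVs. All readers are lossless for the fields the
# pipeline uses; none mutates its input on disk.

#' Read a FASTA file
#'
#' @param path FASTA path (wrapped lines and CRLF endings are handled).
#' @return named character vector of uppercase sequences; names are the full
#'   header lines (without `>`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (names become headers).
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a BLAST-style tabular hit file
#'
#' Expected dialect: 12 standard outfmt-6 columns plus two extensions,
#' `qcovhsp` (query coverage per HSP) and `slineage` (subject ranked
#' lineage): `qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore qcovhsp slineage`. No header row.
#'
#' @param path TSV path.
#' @param max_matches_per_read cap on parsed hits per query (excess rows are
#'   dropped with a message), mirroring a read-level parser cap.
#' @return data.frame with the 14 documented columns.
#' @export
read_blast_hits <- function(path, max_matches_per_read = 2000L) {
  if (!file.exists(path)) stop("hit file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(.HIT_COLS)), .HIT_COLS))
    num <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
             "sstart", "send", "evalue", "bitscore", "qcovhsp")
    for (cc in num) out[[cc]] <- numeric(0)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 14L)) {
    bad <- which(nf != 14L)[1L]
    stop("hit file ", path, " line ", bad, ": expected 14 tab-separated ",
         "columns, found ", nf[bad])
  }
  m <- do.call(rbind, parts)
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- .HIT_COLS
  num <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
           "sstart", "send", "evalue", "bitscore", "qcovhsp")
  for (cc in num) {
    v <- suppressWarnings(as.numeric(out[[cc]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("hit file ", path, " line ", bad, ": non-numeric value `",
           out[[cc]][bad], "` in column ", cc)
    }
    out[[cc]] <- v
  }
  if (any(out$pident < 0 | out$pident > 100)) stop("pident outside [0,100] in ", path)
  if (any(out$bitscore < 0)) stop("negative bit score in ", path)
  keep <- stats::ave(seq_len(nrow(out)), out$qseqid, FUN = seq_along) <=
    as.integer(max_matches_per_read)
  if (!all(keep)) {
    message(sum(!keep), " hits beyond the per-query parser cap dropped")
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Write a hit table in the package's BLAST tabular dialect
#' @param hits data.frame with the columns of [read_blast_hits()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blast_hits <- function(hits, path) {
  utils::write.table(hits[, .HIT_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a samples-by-features count table (TSV, samples as rows)
#'
#' First column holds sample ids; header row holds feature ids.
#'
#' @param path TSV path.
#' @return numeric matrix, rownames = sample ids.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count table needs an id column plus features: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "numeric"
  if (anyNA(m)) stop("missing values in count table ", path)
  if (any(m < 0)) stop("negative counts in ", path)
  rownames(m) <- ids
  m
}

#' Write a samples-by-features table as TSV (samples as rows)
#' @param m matrix with row and column names.
#' @param path output path.
#' @param id_col name for the sample-id column.
#' @param digits significant digits for fractional values.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(m, path, id_col = "sample_id", digits = 8L) {
  df <- data.frame(rownames(m), signif(m, digits), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column `sample_id<TAB>fraction` file
#' @param path TSV path (header optional; detected by a non-numeric second
#'   field on line 1).
#' @return named numeric vector of fractions in `[0, 1]`.
#' @export
read_bif16s <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected two columns in ", path)
  if (is.na(suppressWarnings(as.numeric(df[1L, 2L])))) df <- df[-1L, , drop = FALSE]
  v <- as.numeric(df[[2L]])
  if (anyNA(v) || any(v < 0 | v > 1)) stop("fractions outside [0,1] in ", path)
  stats::setNames(v, as.character(df[[1L]]))
}

#' Read a sample metadata table
#'
#' Empty cells and `"NA"` are read as missing; per-analysis complete-case
#' filtering is done downstream (each analysis reports its own n).
#'
#' @param path TSV path with header; first column = sample id.
#' @return data.frame, rownames = sample ids.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in ", path)
  df <- df[, -1L, drop = FALSE]
  rownames(df) <- ids
  df
}

#' Write/read a square distance matrix as TSV with header row and column
#' @param d `dist` object or square matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  write_count_table(m, path, id_col = "sample_id", digits = 10L)
}

#' @rdname write_distance_matrix
#' @return for the reader: a `dist` object.
#' @export
read_distance_matrix <- function(path) {
  m <- read_count_table(path)
  if (nrow(m) != ncol(m) || !all(rownames(m) == colnames(m))) {
    stop("not a square labelled distance matrix: ", path)
  }
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix not symmetric: ", path)
  stats::as.dist(m)
}

#' Read a Newick tree
#' @param path Newick file.
#' @return `ape::phylo` object.
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels in ", path)
  tr
}

#' Read a `genome_id<TAB>lineage` taxonomy sidecar
#' @param path TSV path (no header).
#' @return named character vector of lineage strings.
#' @export
read_taxonomy_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected `genome_id<TAB>lineage` in ", path)
  for (ln in df[[2L]]) tax_split(ln)  # validate
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}
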