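# Construction of the groEL amplicon reference database ("BIF"): in-silico
# PCR against genome sequences, primer trimming, exact deduplication, and a
# pairwise-identity QC summary.

#' Define a primer pair for in-silico PCR
#'
#' Both primers are given 5'->3'; the reverse primer is written on the
#' opposite strand, as on a primer order sheet. IUPAC degeneracy codes are
#' allowed and count as matches during comparison.
#'
#' @param forward,reverse IUPAC nucleotide strings.
#' @param max_mismatches mismatches tolerated per primer site (default 3,
#'   roughly 10% of a typical 25-nt primer).
#' @return object of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse, max_mismatches = 3L) {
  for (p in c(forward, reverse)) {
    if (!nzchar(p)) stop("primers must be non-empty")
    if (grepl("[^ACGTRYSWKMBDHVN]", toupper(p))) {
      stop("primer contains non-IUPAC characters: ", p)
    }
  }
  structure(list(forward = toupper(forward), reverse = toupper(reverse),
                 max_mismatches = as.integer(max_mismatches)),
            class = "primer_pair")
}

#' Placeholder groEL primer pair used by the synthetic generator
#'
#' The groEL primer sequences used in population studies are instrument
#' to the lab protocol and are supplied via configuration; this synthetic
#' pair (not a published primer set) is what the package's own genome
#' simulator plants around amplicons, so the whole refdb stage can be
#' exercised without external data.
#'
#' @return a [primer_pair()].
#' @export
default_primers <- function() {
  primer_pair("GGYGAYGGYACVACVACHGC", "CGCAYTTSACRTCSGCRTTC", max_mismatches = 3L)
}

#' In-silico PCR: extract primer-flanked amplicons from a genome
#'
#' Finds every region flanked by a forward-primer site and a downstream
#' reverse-primer site on either strand; reverse-strand products are
#' reverse-complemented so output is always in forward-primer orientation.
#' Primer bases are removed (trimming keeps the insert only). The leftmost
#' forward match takes the nearest downstream reverse match whose insert
#' falls inside the length window; scanning then resumes past that product.
#'
#' @param genome DNA string (A/C/G/T/N).
#' @param primers a [primer_pair()].
#' @param amplicon_min,amplicon_max accepted insert length window (defaults
#'   350-600 nt, centred on the ~460 bp groEL amplicon).
#' @return character vector of amplicon sequences (possibly empty).
#' @export
extract_amplicon <- function(genome, primers = default_primers(),
                             amplicon_min = 350L, amplicon_max = 600L) {
  if (!nzchar(genome)) stop("genome must be non-empty")
  genome <- toupper(genome)
  if (grepl("[^ACGTRYSWKMBDHVN]", genome)) {
    stop("genome contains non-IUPAC characters")
  }
  fwd <- .scan_strand(genome, primers, amplicon_min, amplicon_max)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(genome)))
  rev <- .scan_strand(rc, primers, amplicon_min, amplicon_max)
  out <- c(fwd, rev)
  unname(out)
}

# One-strand scan: forward primer, then nearest downstream revcomp(reverse).
.scan_strand <- function(s, primers, amplicon_min, amplicon_max) {
  subject <- Biostrings::DNAString(s)
  f_hits <- Biostrings::matchPattern(Biostrings::DNAString(primers$forward),
                                     subject, max.mismatch = primers$max_mismatches,
                                     fixed = FALSE)
  if (length(f_hits) == 0L) return(character(0))
  r_site <- Biostrings::reverseComplement(Biostrings::DNAString(primers$reverse))
  r_hits <- Biostrings::matchPattern(r_site, subject,
                                     max.mismatch = primers$max_mismatches,
                                     fixed = FALSE)
  if (length(r_hits) == 0L) return(character(0))
  f_start <- IRanges::start(f_hits); f_end <- IRanges::end(f_hits)
  r_start <- IRanges::start(r_hits); r_end <- IRanges::end(r_hits)
  out <- character(0)
  cursor <- 0L
  for (i in seq_along(f_start)) {
    if (f_start[i] <= cursor) next
    cand <- which(r_start > f_end[i])
    if (length(cand) == 0L) next
    ins_len <- r_start[cand] - f_end[i] - 1L
    ok <- cand[ins_len >= amplicon_min & ins_len <= amplicon_max]
    if (length(ok) == 0L) next
    j <- ok[1L]
    out <- c(out, substr(s, f_end[i] + 1L, r_start[j] - 1L))
    cursor <- r_end[j]
  }
  out
}

#' Deduplicate reference sequences
#'
#' Collapses exact sequence-string duplicates; the first record seen (input
#' order) is kept as the representative. Idempotent.
#'
#' @param records data.frame with columns `id`, `sequence`, `taxonomy`,
#'   `source_genome`, `is_outgroup`.
#' @return object of class `bifido_refdb`: list with `records` (the unique
#'   rows) and `dedup_map` (named character vector, original id ->
#'   representative id, total over all input ids).
#' @export
dedupe <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0L,
            all(c("id", "sequence") %in% names(records)))
  if (anyDuplicated(records$id)) stop("record ids must be unique")
  first <- !duplicated(records$sequence)
  rep_id <- records$id[first][match(records$sequence, records$sequence[first])]
  db <- structure(list(records = records[first, , drop = FALSE],
                       dedup_map = stats::setNames(rep_id, records$id)),
                  class = "bifido_refdb")
  rownames(db$records) <- NULL
  db
}

#' @export
print.bifido_refdb <- function(x, ...) {
  cat("groEL amplicon reference database\n")
  cat("  records:    ", nrow(x$records), " (",
      sum(x$records$is_outgroup), " outgroup)\n", sep = "")
  cat("  collapsed:  ", length(x$dedup_map) - nrow(x$records),
      " duplicate input sequence(s)\n", sep = "")
  invisible(x)
}

#' Build the reference database from genomes + taxonomy sidecar
#'
#' Extracts amplicons from every genome record, attaches the ranked lineage
#' from the sidecar map, flags outgroup records (lineages outside genus
#' *Bifidobacterium*), and deduplicates.
#'
#' @param genomes named character vector of genome sequences, or a FASTA
#'   path. Names (first whitespace-separated token) must appear in
#'   `taxonomy`.
#' @param taxonomy named character vector `genome_id -> lineage`, or a TSV
#'   path for [read_taxonomy_map()].
#' @param primers a [primer_pair()].
#' @param ... passed to [extract_amplicon()].
#' @return a `bifido_refdb`.
#' @export
build_refdb <- function(genomes, taxonomy, primers = default_primers(), ...) {
  if (is.character(genomes) && length(genomes) == 1L && file.exists(genomes)) {
    genomes <- read_fasta(genomes)
  }
  if (is.character(taxonomy) && length(taxonomy) == 1L && file.exists(taxonomy)) {
    taxonomy <- read_taxonomy_map(taxonomy)
  }
  ids <- vapply(strsplit(names(genomes), "\\s+"), `[[`, "", 1L)
  miss <- setdiff(ids, names(taxonomy))
  if (length(miss)) stop("no taxonomy for genome(s): ", paste(miss, collapse = ", "))
  rows <- list()
  for (i in seq_along(genomes)) {
    amps <- extract_amplicon(genomes[[i]], primers, ...)
    if (length(amps) == 0L) {
      message("no amplicon found in genome ", ids[i])
      next
    }
    lineage <- taxonomy[[ids[i]]]
    for (k in seq_along(amps)) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = if (length(amps) == 1L) ids[i] else paste0(ids[i], "_amp", k),
        sequence = amps[k], taxonomy = lineage, source_genome = ids[i],
        is_outgroup = !tax_has_genus(lineage), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no amplicons recovered from any genome")
  dedupe(do.call(rbind, rows))
}

#' Pairwise-identity QC summary of a reference database
#'
#' Aligns every record pair globally and reports identity = matching
#' columns / alignment length. Summarises the fraction of in-group
#' (non-outgroup) pairs above `threshold` and the maximum identity between
#' any in-group and outgroup record.
#'
#' @param db a `bifido_refdb` with at least 2 records.
#' @param threshold in-group identity threshold (default 0.75).
#' @return list: `frac_ingroup_above` (fraction of in-group pairs with
#'   identity > threshold), `max_outgroup_identity` (or `NA` if no outgroup),
#'   `identities` (data.frame of all pairs: `id1`, `id2`, `identity`,
#'   `pair_type`).
#' @export
identity_summary <- function(db, threshold = 0.75) {
  rec <- db$records
  if (nrow(rec) < 2L) stop("identity_summary needs at least 2 records")
  n <- nrow(rec)
  pairs <- utils::combn(n, 2L)
  ident <- numeric(ncol(pairs))
  seqs <- Biostrings::DNAStringSet(rec$sequence)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    aln <- Biostrings::pairwiseAlignment(seqs[[i]], seqs[[j]], type = "global")
    ident[k] <- Biostrings::nmatch(aln) / Biostrings::nchar(aln)
  }
  type <- ifelse(rec$is_outgroup[pairs[1L, ]] | rec$is_outgroup[pairs[2L, ]],
                 ifelse(rec$is_outgroup[pairs[1L, ]] & rec$is_outgroup[pairs[2L, ]],
                        "outgroup", "mixed"), "ingroup")
  idents <- data.frame(id1 = rec$id[pairs[1L, ]], id2 = rec$id[pairs[2L, ]],
                       identity = ident, pair_type = type,
                       stringsAsFactors = FALSE)
  ing <- idents$identity[idents$pair_type == "ingroup"]
  mix <- idents$identity[idents$pair_type == "mixed"]
  list(frac_ingroup_above = if (length(ing)) mean(ing > threshold) else NA_real_,
       max_outgroup_identity = if (length(mix)) max(mix) else NA_real_,
       identities = idents)
}

#' Write a reference database to disk
#'
#' Emits the reference FASTA (headers `>{id} taxonomy={lineage}
#' outgroup={0|1}`), the dedup map TSV and, optionally, the identity
#' summary TSV.
#'
#' @param db a `bifido_refdb`.
#' @param dir output directory (created if needed).
#' @param identity logical; also compute and write the identity summary.
#' @return named list of written paths, invisibly.
#' @export
write_refdb <- function(db, dir, identity = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- db$records
  headers <- sprintf("%s taxonomy=%s outgroup=%d", rec$id, rec$taxonomy,
                     as.integer(rec$is_outgroup))
  fasta <- file.path(dir, "refdb.fasta")
  write_fasta(stats::setNames(rec$sequence, headers), fasta)
  dm <- file.path(dir, "dedup_map.tsv")
  utils::write.table(data.frame(original_id = names(db$dedup_map),
                                representative_id = unname(db$dedup_map)),
                     dm, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- list(fasta = fasta, dedup_map = dm)
  if (identity) {
    qc <- identity_summary(db)
    ip <- file.path(dir, "identity_summary.tsv")
    utils::write.table(qc$identities, ip, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$identity <- ip
  }
  invisible(paths)
}

#' Read a reference database written by [write_refdb()]
#' @param dir directory holding `refdb.fasta` and `dedup_map.tsv`.
#' @return a `bifido_refdb`.
#' @export
read_refdb <- function(dir) {
  seqs <- read_fasta(file.path(dir, "refdb.fasta"))
  hdr <- names(seqs)
  id <- sub("\\s.*$", "", hdr)
  taxonomy <- sub("^.*taxonomy=(\\S+(?: \\S+)*?) outgroup=.*$", "\\1", hdr)
  outg <- sub("^.*outgroup=([01]).*$", "\\1", hdr) == "1"
  rec <- data.frame(id = id, sequence = unname(seqs), taxonomy = taxonomy,
                    source_genome = id, is_outgroup = outg,
                    stringsAsFactors = FALSE)
  dm <- utils::read.delim(file.path(dir, "dedup_map.tsv"),
                          stringsAsFactors = FALSE)
  structure(list(records = rec,
                 dedup_map = stats::setNames(dm$representative_id,
                                             dm$original_id)),
            class = "bifido_refdb")
}
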