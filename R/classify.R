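# Taxonomy assignment of ZOTUs from two BLAST-style hit tables (a general
# nucleotide database "NT" and the groEL amplicon database "BIF"), using
# top-percent LCA per database and a bit-score arbitration rule between them.

.HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
               "qstart", "qend", "sstart", "send", "evalue", "bitscore",
               "qcovhsp", "slineage")

#' Default hit-filtering thresholds
#'
#' Megablast-style screening thresholds: e-value at most `1e-10`, query
#' coverage per HSP at least 60, percent identity at least 75, and at most
#' 1000 targets per query (kept by descending bit score).
#'
#' @return named list of thresholds.
#' @export
hit_thresholds <- function() {
  list(evalue = 1e-10, qcov = 60, pident = 75, max_target_seqs = 1000L,
       max_matches_per_read = 2000L)
}

#' Filter BLAST-style hits
#'
#' Applies the screening thresholds to a hit table and caps the number of
#' retained hits per query at `max_target_seqs`, keeping the highest bit
#' scores. Coverage and identity bounds are inclusive.
#'
#' @param hits data.frame with at least columns `qseqid`, `pident`, `evalue`,
#'   `bitscore`, `qcovhsp`, `slineage`.
#' @param thresholds list as from [hit_thresholds()].
#' @return filtered data.frame (same columns, row order: by query then by
#'   descending bit score).
#' @export
filter_hits <- function(hits, thresholds = hit_thresholds()) {
  stopifnot(is.data.frame(hits))
  need <- c("qseqid", "pident", "evalue", "bitscore", "qcovhsp", "slineage")
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("hit table missing column(s): ", paste(miss, collapse = ", "))
  for (th in c("evalue", "qcov", "pident")) {
    if (!is.numeric(thresholds[[th]]) || thresholds[[th]] < 0) {
      stop("threshold `", th, "` must be a non-negative number")
    }
  }
  keep <- hits$evalue <= thresholds$evalue &
    hits$qcovhsp >= thresholds$qcov &
    hits$pident >= thresholds$pident
  out <- hits[keep, , drop = FALSE]
  if (nrow(out) == 0L) return(out)
  out <- out[order(out$qseqid, -out$bitscore), , drop = FALSE]
  cap <- as.integer(thresholds$max_target_seqs)
  idx <- stats::ave(seq_len(nrow(out)), out$qseqid, FUN = seq_along) <= cap
  out <- out[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-percent lowest common ancestor of one query's hits
#'
#' MEGAN-style LCA: hits with bit score below `min_score` are dropped; of the
#' rest, those within `top_percent` percent of the best bit score are
#' retained, and the assignment is the longest common lineage prefix of the
#' retained hits.
#'
#' @param hits data.frame of hits for a single query (`bitscore`,
#'   `slineage` columns used).
#' @param min_score minimum bit score (default 100).
#' @param top_percent retain hits with bit score at least
#'   `(1 - top_percent/100)` times the best (default 10).
#' @return list with `taxonomy` (lineage string or `NA` if no hit survives)
#'   and `max_bit` (best retained bit score, or `NA`).
#' @export
lca_top_percent <- function(hits, min_score = 100, top_percent = 10) {
  if (is.null(hits) || nrow(hits) == 0L) {
    return(list(taxonomy = NA_character_, max_bit = NA_real_))
  }
  hits <- hits[hits$bitscore >= min_score, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(list(taxonomy = NA_character_, max_bit = NA_real_))
  }
  top <- max(hits$bitscore)
  kept <- hits[hits$bitscore >= (1 - top_percent / 100) * top, , drop = FALSE]
  list(taxonomy = tax_lca(kept$slineage), max_bit = top)
}

#' Arbitrate between NT- and BIF-based assignments of one ZOTU
#'
#' Implements the dual-database decision tree. Writing `bNT`/`bBIF` for the
#' maximum bit scores (absent treated as 0), the rules are evaluated in
#' order:
#'
#' 1. no hits in either database: discarded (`no_hits`);
#' 2. NT taxonomy present, outside genus *Bifidobacterium*, and `bNT > bBIF`:
#'    discarded (`nonbif_nt_dominant`);
#' 3. identical NT and BIF taxonomies: assigned, source `agree`;
#' 4. `bBIF == bNT`, or `bBIF > bNT` with `0.9 * bBIF <= bNT`: assigned the
#'    finer-rank lineage of the two (rank tie goes to BIF), source
#'    `merged_finer`;
#' 5. `bBIF > bNT` and `0.9 * bBIF > bNT`: assigned the BIF taxonomy;
#' 6. `bBIF < bNT` (NT lineage within *Bifidobacterium*): assigned the NT
#'    taxonomy, with a warning — this branch is not expected to occur.
#'
#' @param nt_tax,bif_tax lineage strings or `NA`.
#' @param nt_bit,bif_bit maximum bit scores or `NA`.
#' @param zotu_id optional id recorded in the result.
#' @return one-row data.frame: `zotu_id`, `status`, `taxonomy`, `source`,
#'   `max_bit_nt`, `max_bit_bif`, `rule_fired`.
#' @export
arbitrate <- function(nt_tax, nt_bit, bif_tax, bif_bit, zotu_id = NA_character_) {
  nt_present <- !is.na(nt_tax) && nzchar(nt_tax)
  bif_present <- !is.na(bif_tax) && nzchar(bif_tax)
  bnt <- if (is.na(nt_bit)) 0 else nt_bit
  bbif <- if (is.na(bif_bit)) 0 else bif_bit

  res <- function(status, taxonomy, source, rule) {
    data.frame(zotu_id = zotu_id, status = status,
               taxonomy = taxonomy, source = source,
               max_bit_nt = nt_bit, max_bit_bif = bif_bit,
               rule_fired = rule, stringsAsFactors = FALSE)
  }

  if (!nt_present && !bif_present) {
    return(res("discarded_no_hits", NA_character_, NA_character_, "rule1_no_hits"))
  }
  if (nt_present && !tax_has_genus(nt_tax) && bnt > bbif) {
    return(res("discarded_nonbif_nt_dominant", NA_character_, NA_character_,
               "rule2_nonbif_nt_dominant"))
  }
  if (nt_present && bif_present && identical(nt_tax, bif_tax)) {
    return(res("assigned", nt_tax, "agree", "rule3_agree"))
  }
  if (bbif == bnt || (bbif > bnt && 0.9 * bbif <= bnt)) {
    finer <- if (tax_depth(bif_tax %na% "") >= tax_depth(nt_tax %na% "")) {
      bif_tax
    } else {
      nt_tax
    }
    return(res("assigned", finer, "merged_finer", "rule4_merge_finer"))
  }
  if (bbif > bnt) {
    return(res("assigned", bif_tax, "BIF", "rule5_bif_dominant"))
  }
  warning("NT bit score exceeds BIF for a Bifidobacterium-lineage ZOTU (",
          zotu_id, "); assigning the NT taxonomy")
  res("assigned", nt_tax, "NT", "rule6_nt_dominant")
}

`%na%` <- function(x, default) if (length(x) == 0L || is.na(x)) default else x

#' Classify a set of ZOTUs from NT and BIF hit tables
#'
#' Runs per-database hit filtering and top-percent LCA, then arbitrates the
#' two assignments for each ZOTU.
#'
#' @param zotu_ids character vector of all ZOTU ids (ZOTUs without hits are
#'   still reported, as discarded).
#' @param nt_hits,bif_hits data.frames in the BLAST tabular dialect of
#'   [read_blast_hits()] (or paths to such files).
#' @param thresholds list as from [hit_thresholds()].
#' @param min_score,top_percent LCA parameters, see [lca_top_percent()].
#' @return data.frame with one row per ZOTU (columns as in [arbitrate()]).
#' @export
classify_table <- function(zotu_ids, nt_hits, bif_hits,
                           thresholds = hit_thresholds(),
                           min_score = 100, top_percent = 10) {
  if (is.character(nt_hits)) nt_hits <- read_blast_hits(nt_hits)
  if (is.character(bif_hits)) bif_hits <- read_blast_hits(bif_hits)
  stopifnot(length(zotu_ids) > 0L, !anyDuplicated(zotu_ids))
  for (nm in c("nt_hits", "bif_hits")) {
    h <- get(nm)
    unknown <- setdiff(unique(h$qseqid), zotu_ids)
    if (length(unknown)) {
      warning(length(unknown), " ", nm, " quer",
              if (length(unknown) == 1L) "y" else "ies",
              " not in the ZOTU id set; skipped: ",
              paste(utils::head(unknown, 5L), collapse = ", "))
    }
  }
  nt_f <- filter_hits(nt_hits[nt_hits$qseqid %in% zotu_ids, , drop = FALSE], thresholds)
  bif_f <- filter_hits(bif_hits[bif_hits$qseqid %in% zotu_ids, , drop = FALSE], thresholds)
  nt_by <- split(nt_f, nt_f$qseqid)
  bif_by <- split(bif_f, bif_f$qseqid)
  out <- lapply(zotu_ids, function(z) {
    nt <- lca_top_percent(nt_by[[z]], min_score, top_percent)
    bif <- lca_top_percent(bif_by[[z]], min_score, top_percent)
    arbitrate(nt$taxonomy, nt$max_bit, bif$taxonomy, bif$max_bit, zotu_id = z)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  message("classified ", nrow(out), " ZOTUs; status counts: ",
          paste(names(table(out$status)), table(out$status),
                sep = "=", collapse = ", "))
  out
}
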