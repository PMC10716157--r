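# Orchestration: a validated plain-text configuration and a run function
# chaining classify -> profile -> diversity -> association stages, with a
# manifest recording seeds, input checksums and per-stage exclusion counts.

#' Pipeline configuration
#'
#' Collects input paths and thresholds. All thresholds default to the
#' package-wide screening conventions: e-value 1e-10, identity 75, coverage
#' 60, LCA min score 100 and top percent 10, BIF bit-score factor 0.9,
#' rarefaction depth 2000, 999 permutations, significance at p < 0.05 and
#' p.adj < 0.1.
#'
#' @param zotus path to the ZOTU FASTA (ids are taken from headers).
#' @param nt_hits,bif_hits paths to the two hit tables.
#' @param counts path to the samples-by-ZOTUs count TSV.
#' @param bif16s path to the `sample_id<TAB>fraction` TSV.
#' @param metadata path to the sample metadata TSV.
#' @param tree optional Newick tree over ZOTUs (enables Faith's PD).
#' @param covariates metadata columns to test with univariate dbRDA
#'   (default none).
#' @param rarefy_depth,n_perm,min_score,top_percent,bif_factor,alpha,alpha_adj
#'   numeric thresholds (see description).
#' @param seed integer seed driving all randomness in the run.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(zotus, nt_hits, bif_hits, counts, bif16s,
                            metadata, tree = NULL, covariates = character(0),
                            rarefy_depth = 2000L, n_perm = 999L,
                            min_score = 100, top_percent = 10,
                            bif_factor = 0.9, alpha = 0.05, alpha_adj = 0.1,
                            seed = 1L) {
  cfg <- list(zotus = zotus, nt_hits = nt_hits, bif_hits = bif_hits,
              counts = counts, bif16s = bif16s, metadata = metadata,
              tree = tree, covariates = covariates,
              rarefy_depth = as.integer(rarefy_depth),
              n_perm = as.integer(n_perm), min_score = min_score,
              top_percent = top_percent, bif_factor = bif_factor,
              alpha = alpha, alpha_adj = alpha_adj, seed = as.integer(seed))
  stopifnot(cfg$rarefy_depth >= 1L, cfg$n_perm >= 1L,
            cfg$top_percent >= 0, cfg$top_percent <= 100,
            cfg$bif_factor > 0, cfg$bif_factor <= 1,
            cfg$alpha > 0, cfg$alpha < 1, cfg$alpha_adj > 0, cfg$alpha_adj < 1)
  for (f in c("zotus", "nt_hits", "bif_hits", "counts", "bif16s", "metadata")) {
    if (!file.exists(cfg[[f]])) stop("input `", f, "` not found: ", cfg[[f]])
  }
  if (!is.null(tree) && !file.exists(tree)) stop("tree file not found: ", tree)
  structure(cfg, class = "pipeline_config")
}

#' Write/read a pipeline configuration as plain-text key=value lines
#' @param cfg a [pipeline_config()].
#' @param path file path.
#' @return `path` (writer) / a `pipeline_config` (reader).
#' @export
write_config <- function(cfg, path) {
  flat <- lapply(unclass(cfg), function(v) {
    if (is.null(v)) "" else paste(v, collapse = ",")
  })
  writeLines(paste0(names(flat), "=", unlist(flat)), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  vals <- stats::setNames(vapply(kv, `[[`, "", 3L), vapply(kv, `[[`, "", 2L))
  as_chr <- function(x) if (nzchar(x)) strsplit(x, ",")[[1L]] else character(0)
  pipeline_config(
    zotus = vals[["zotus"]], nt_hits = vals[["nt_hits"]],
    bif_hits = vals[["bif_hits"]], counts = vals[["counts"]],
    bif16s = vals[["bif16s"]], metadata = vals[["metadata"]],
    tree = if (nzchar(vals[["tree"]])) vals[["tree"]] else NULL,
    covariates = as_chr(vals[["covariates"]]),
    rarefy_depth = as.integer(vals[["rarefy_depth"]]),
    n_perm = as.integer(vals[["n_perm"]]),
    min_score = as.numeric(vals[["min_score"]]),
    top_percent = as.numeric(vals[["top_percent"]]),
    bif_factor = as.numeric(vals[["bif_factor"]]),
    alpha = as.numeric(vals[["alpha"]]),
    alpha_adj = as.numeric(vals[["alpha_adj"]]),
    seed = as.integer(vals[["seed"]]))
}

#' Run the full profiling pipeline
#'
#' Classification (dual-database LCA + arbitration), composite species
#' profiling, rarefied alpha/beta diversity and, if covariates are
#' configured, univariate dbRDA on Bray-Curtis distances of the species
#' profile. Results and a manifest (seed, input checksums, per-stage
#' exclusion counts) are written to `out_dir`.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a list with `assignments`, `profile`, `alpha`,
#'   `beta`, `dbrda`, `manifest`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  zotu_ids <- sub("\\s.*$", "", names(read_fasta(cfg$zotus)))
  counts <- read_count_table(cfg$counts)
  bif16s <- read_bif16s(cfg$bif16s)
  metadata <- read_metadata(cfg$metadata)
  tree <- if (!is.null(cfg$tree)) read_tree(cfg$tree) else NULL

  assignments <- classify_table(zotu_ids, cfg$nt_hits, cfg$bif_hits,
                                min_score = cfg$min_score,
                                top_percent = cfg$top_percent)
  utils::write.table(assignments, file.path(out_dir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  prof <- composite_abundance(counts, assignments, bif16s)
  write_count_table(prof$abundance, file.path(out_dir, "species_profile.tsv"))

  rare <- rarefy(counts, depth = cfg$rarefy_depth, seed = cfg$seed)
  alpha <- alpha_diversity(rare, tree)
  utils::write.table(cbind(sample_id = rownames(alpha), alpha),
                     file.path(out_dir, "alpha_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  beta <- beta_diversity(prof$abundance[rownames(rare), , drop = FALSE],
                         "bray_curtis")
  write_distance_matrix(beta, file.path(out_dir, "bray_curtis.tsv"))

  dbrda <- NULL
  if (length(cfg$covariates)) {
    miss <- setdiff(cfg$covariates, names(metadata))
    if (length(miss)) stop("covariate(s) not in metadata: ",
                           paste(miss, collapse = ", "))
    d_all <- beta_diversity(prof$abundance, "bray_curtis")
    rows <- lapply(cfg$covariates, function(cv) {
      dbrda_univariate(d_all, metadata[rownames(prof$abundance), cv],
                       n_perm = cfg$n_perm, seed = cfg$seed, term = cv)
    })
    dbrda <- do.call(rbind, rows)
    dbrda$p_adj <- bh_adjust(dbrda$p)
    utils::write.table(dbrda, file.path(out_dir, "dbrda_univariate.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  inputs <- c(cfg$zotus, cfg$nt_hits, cfg$bif_hits, cfg$counts, cfg$bif16s,
              cfg$metadata, cfg$tree)
  manifest <- c(
    list(seed = cfg$seed, n_zotus = length(zotu_ids),
         n_samples = nrow(counts),
         samples_dropped_at_rarefaction = nrow(counts) - nrow(rare),
         n_features = ncol(prof$abundance)),
    as.list(stats::setNames(
      as.integer(table(factor(assignments$rule_fired,
                              levels = sort(unique(assignments$rule_fired))))),
      paste0("zotus_", sort(unique(assignments$rule_fired))))),
    as.list(stats::setNames(unname(tools::md5sum(inputs)),
                            paste0("md5_", basename(inputs)))))
  writeLines(paste0(names(manifest), "=", unlist(manifest)),
             file.path(out_dir, "manifest.txt"))
  invisible(list(assignments = assignments, profile = prof, alpha = alpha,
                 beta = beta, dbrda = dbrda, manifest = manifest))
}
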