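# Independent oracle implementations used to check package results. These
# are deliberately written as direct, naive transcriptions of the
# definitions, sharing no code with the package internals.

# Longest common prefix of semicolon-separated lineages.
oracle_lca <- function(lineages) {
  parts <- lapply(lineages, function(l) strsplit(l, ";", fixed = TRUE)[[1]])
  k <- min(lengths(parts))
  if (k == 0) return("")
  keep <- 0
  for (i in seq_len(k)) {
    field <- vapply(parts, `[[`, "", i)
    if (length(unique(field)) == 1) keep <- i else break
  }
  if (keep == 0) "" else paste(parts[[1]][seq_len(keep)], collapse = ";")
}

# Dual-database arbitration, transcribed independently as a flat rule list:
# the discard rule, the agreement rule, and the three bit-score branches.
# Absent databases contribute bit score 0.
oracle_arbitrate <- function(nt_tax, nt_bit, bif_tax, bif_bit) {
  has <- function(t) !is.na(t) && nzchar(t)
  is_bif <- function(t) grepl("g__Bifidobacterium(;|$)", t)
  depth <- function(t) if (!has(t)) 0 else length(strsplit(t, ";", fixed = TRUE)[[1]])
  bnt <- if (is.na(nt_bit)) 0 else nt_bit
  bbif <- if (is.na(bif_bit)) 0 else bif_bit
  if (!has(nt_tax) && !has(bif_tax)) return("discarded_no_hits")
  if (has(nt_tax) && !is_bif(nt_tax) && bnt > bbif) {
    return("discarded_nonbif_nt_dominant")
  }
  if (has(nt_tax) && has(bif_tax) && nt_tax == bif_tax) return(nt_tax)
  if (bbif == bnt || (bbif > bnt && 0.9 * bbif <= bnt)) {
    return(if (depth(bif_tax) >= depth(nt_tax)) {
      if (has(bif_tax)) bif_tax else ""
    } else nt_tax)
  }
  if (bbif > bnt) return(bif_tax)
  nt_tax
}

# Faith's PD by brute force: union of edges on root-to-tip paths.
oracle_pd <- function(tree, tips) {
  root <- ape::Ntip(tree) + 1L
  edges <- integer(0)
  for (tip in match(tips, tree$tip.label)) {
    path_nodes <- ape::nodepath(tree, root, tip)
    for (i in seq_len(length(path_nodes) - 1L)) {
      e <- which(tree$edge[, 1] == path_nodes[i] &
                 tree$edge[, 2] == path_nodes[i + 1])
      edges <- union(edges, e)
    }
  }
  sum(tree$edge.length[edges])
}

# BH adjustment straight from the step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    adj[i] <- min(1, min(p[ord][seq(rank_i, m)] * m / seq(rank_i, m)))
  }
  adj
}

# Elementwise beta-diversity oracles.
oracle_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)
oracle_jsd <- function(x, y) {
  p <- x / sum(x); q <- y / sum(y); m <- (p + q) / 2
  term <- function(a) {
    i <- a > 0
    sum(a[i] * log(a[i] / m[i]))
  }
  0.5 * term(p) + 0.5 * term(q)
}

# Random lineage drawing on a small taxonomy for LCA fuzzing.
random_lineage <- function() {
  ranks <- c("d", "p", "c", "o", "f", "g", "s")
  depth <- sample(1:7, 1)
  paste(paste0(ranks[1:depth], "__t",
               cumsum(sample(1:2, depth, replace = TRUE))),
        collapse = ";")
}

make_hits <- function(zotu, lineages, bits) {
  data.frame(qseqid = zotu, sseqid = paste0("s", seq_along(bits)),
             pident = 98, length = 460, mismatch = 5, gapopen = 0,
             qstart = 1, qend = 460, sstart = 1, send = 460,
             evalue = 1e-100, bitscore = bits, qcovhsp = 100,
             slineage = lineages, stringsAsFactors = FALSE)
}
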