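# Synthetic inputs with the statistical structure the analysis assumes:
# groEL-bearing genomes for the refdb stage, hit tables engineered to
# exercise each arbitration rule, and a cohort generator with planted
# covariate effects (piecewise age trends with change points at 16 and 30,
# latitude gradients, ethnicity offsets, wheat-responder species, an
# urbanization shift) on an absolute-abundance log-linear scale.

.BIF_LINEAGE_PREFIX <- paste0("d__Bacteria;p__Actinobacteriota;",
                              "c__Actinomycetia;o__Bifidobacteriales;",
                              "f__Bifidobacteriaceae;g__Bifidobacterium")

bif_lineage <- function(species = NULL) {
  if (is.null(species) || is.na(species)) return(.BIF_LINEAGE_PREFIX)
  paste0(.BIF_LINEAGE_PREFIX, ";s__", species)
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate_dna <- function(s, rate) {
  if (rate <= 0) return(s)
  v <- strsplit(s, "")[[1L]]
  hit <- stats::runif(length(v)) < rate
  if (any(hit)) {
    v[hit] <- vapply(v[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, "")
  }
  paste(v, collapse = "")
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Simulate groEL-bearing genomes plus ground-truth taxonomy
#'
#' Each species gets a root amplicon; variants are point-mutated copies,
#' each embedded in a random genome flanked by the primer sites (a random
#' half of the genomes carry the locus on the reverse strand). Optional
#' outgroup genomes (genus *Lactobacillus*) use an unrelated amplicon.
#'
#' @param n_species number of *Bifidobacterium* species (>= 2).
#' @param n_variants_per_species amplicon variants per species.
#' @param primers a [primer_pair()] planted around each amplicon.
#' @param mutation_rate per-site substitution rate applied to each variant
#'   relative to its species root (default 0.02).
#' @param species_divergence per-site substitution rate of each species
#'   root relative to a shared family root (default 0.08), so in-group
#'   amplicons stay homologous — cross-species identities land near 0.83,
#'   nearly all above the 0.75 QC threshold — while the outgroup is
#'   unrelated.
#' @param amplicon_length insert length (default 460).
#' @param n_outgroup number of outgroup genomes (default 1).
#' @param seed RNG seed.
#' @return list: `genomes` (named character vector), `taxonomy` (named
#'   lineage vector, one entry per genome).
#' @export
simulate_refset <- function(n_species = 9L, n_variants_per_species = 3L,
                            primers = default_primers(), mutation_rate = 0.02,
                            species_divergence = 0.08,
                            amplicon_length = 460L, n_outgroup = 1L,
                            seed = 1L) {
  stopifnot(n_species >= 2L, n_variants_per_species >= 1L)
  set.seed(seed)
  genomes <- character(0); taxonomy <- character(0)
  # concrete per-site instantiation of a degenerate primer, as found in a
  # real template
  iupac <- strsplit(c(A = "A", C = "C", G = "G", T = "T", R = "AG",
                      Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                      B = "CGT", D = "AGT", H = "ACT", V = "ACG",
                      N = "ACGT"), "")
  concretize <- function(p) {
    paste(vapply(strsplit(p, "")[[1L]], function(b) {
      opts <- iupac[[b]]
      opts[sample.int(length(opts), 1L)]
    }, ""), collapse = "")
  }
  emit <- function(amp, id, lineage) {
    cassette <- paste0(concretize(primers$forward), amp,
                       .revcomp(concretize(primers$reverse)))
    g <- paste0(.rand_dna(sample(200:600, 1L)), cassette,
                .rand_dna(sample(200:600, 1L)))
    if (stats::runif(1) < 0.5) g <- .revcomp(g)
    genomes[[id]] <<- g
    taxonomy[[id]] <<- lineage
  }
  family_root <- .rand_dna(amplicon_length)
  for (s in seq_len(n_species)) {
    root <- .mutate_dna(family_root, species_divergence)
    lineage <- bif_lineage(sprintf("Bifidobacterium synthetica%02d", s))
    for (v in seq_len(n_variants_per_species)) {
      emit(.mutate_dna(root, mutation_rate),
           sprintf("genome_s%02d_v%02d", s, v), lineage)
    }
  }
  if (n_outgroup > 0L) {
    out_lineage <- paste0("d__Bacteria;p__Bacillota;c__Bacilli;",
                          "o__Lactobacillales;f__Lactobacillaceae;",
                          "g__Lactobacillus;s__Lactobacillus syntheticus")
    for (k in seq_len(n_outgroup)) {
      emit(.rand_dna(amplicon_length), sprintf("genome_out%02d", k),
           out_lineage)
    }
  }
  list(genomes = genomes, taxonomy = taxonomy)
}

#' Simulate NT/BIF hit tables that exercise named arbitration rules
#'
#' For each ZOTU in the plan, emits hit rows whose lineages and bit scores
#' force the requested decision-tree branch in [arbitrate()].
#'
#' @param rule_plan data.frame with columns `zotu_id` and `rule`, `rule`
#'   one of `rule1_no_hits`, `rule2_nonbif_nt_dominant`, `rule3_agree`,
#'   `rule4_merge_finer`, `rule5_bif_dominant`, `rule6_nt_dominant`.
#' @param seed RNG seed (hit cosmetics only; scores are deterministic).
#' @return list of data.frames `nt` and `bif` in the dialect of
#'   [read_blast_hits()].
#' @export
simulate_hit_tables <- function(rule_plan, seed = 1L) {
  stopifnot(is.data.frame(rule_plan),
            all(c("zotu_id", "rule") %in% names(rule_plan)))
  known <- c("rule1_no_hits", "rule2_nonbif_nt_dominant", "rule3_agree",
             "rule4_merge_finer", "rule5_bif_dominant", "rule6_nt_dominant")
  bad <- setdiff(rule_plan$rule, known)
  if (length(bad)) stop("unknown rule(s) in plan: ", paste(bad, collapse = ", "))
  set.seed(seed)
  sp_a <- bif_lineage("Bifidobacterium synthetica01")
  sp_b <- bif_lineage("Bifidobacterium synthetica02")
  nonbif <- paste0("d__Bacteria;p__Bacillota;c__Bacilli;o__Lactobacillales;",
                   "f__Lactobacillaceae;g__Lactobacillus;",
                   "s__Lactobacillus syntheticus")
  hit <- function(z, subj, bit, lineage) {
    data.frame(qseqid = z, sseqid = subj, pident = 98, length = 460,
               mismatch = 9, gapopen = 0, qstart = 1, qend = 460,
               sstart = 1, send = 460, evalue = 1e-120, bitscore = bit,
               qcovhsp = 100, slineage = lineage, stringsAsFactors = FALSE)
  }
  nt <- list(); bif <- list()
  for (i in seq_len(nrow(rule_plan))) {
    z <- rule_plan$zotu_id[i]
    switch(rule_plan$rule[i],
      rule1_no_hits = NULL,
      rule2_nonbif_nt_dominant = {
        nt[[length(nt) + 1L]] <- hit(z, "nt_nonbif", 300, nonbif)
        bif[[length(bif) + 1L]] <- hit(z, "bif_spA", 250, sp_a)
      },
      rule3_agree = {
        nt[[length(nt) + 1L]] <- hit(z, "nt_spA", 210, sp_a)
        bif[[length(bif) + 1L]] <- hit(z, "bif_spA", 205, sp_a)
      },
      rule4_merge_finer = {
        nt[[length(nt) + 1L]] <- hit(z, "nt_genus", 190, bif_lineage())
        bif[[length(bif) + 1L]] <- hit(z, "bif_spA", 200, sp_a)
      },
      rule5_bif_dominant = {
        nt[[length(nt) + 1L]] <- hit(z, "nt_genus", 150, bif_lineage())
        bif[[length(bif) + 1L]] <- hit(z, "bif_spA", 200, sp_a)
      },
      rule6_nt_dominant = {
        nt[[length(nt) + 1L]] <- hit(z, "nt_spB", 250, sp_b)
        bif[[length(bif) + 1L]] <- hit(z, "bif_spA", 200, sp_a)
      })
  }
  empty <- utils::head(hit("x", "y", 1, sp_a), 0L)
  list(nt = if (length(nt)) do.call(rbind, nt) else empty,
       bif = if (length(bif)) do.call(rbind, bif) else empty)
}

#' Specification of a synthetic cohort
#'
#' Defaults describe the emulated study conditions: 600 samples across 12
#' sites spanning latitudes 23-50 degN, longitudes 75-130 degE and two
#' high-altitude sites; eight named *Bifidobacterium* species plus one
#' genus-level-only taxon over 40 ZOTUs; piecewise-linear age trends with
#' change points at ages 16 and 30; a +0.8 log-unit wheat effect on
#' *B. adolescentis* and *B. longum*; latitude/longitude/altitude
#' gradients; Tibetan/Uygur ethnicity offsets; an urbanization shift; and
#' negative-binomial sequencing depths (mean 15000, floored at the 2000-
#' read rarefaction depth).
#'
#' @param n_samples cohort size (default 600).
#' @param n_zotus number of ZOTUs (default 40; every species keeps at
#'   least one).
#' @param noise_sd per-species log-abundance noise SD (default 1).
#' @param depth_mean,depth_size negative-binomial depth parameters.
#' @param min_depth floor applied to depths (default 2000).
#' @param seed RNG seed.
#' @param effects optional replacement for the planted covariate effect
#'   map: named list, term -> named numeric vector of per-species
#'   log-effects. Continuous terms (`latitude`, `longitude`, `altitude`)
#'   act per SD; `term=level` entries are categorical offsets.
#' @param age_slopes optional replacement for the species-by-segment
#'   matrix of per-year log slopes (segments: 0-16, 16-30, 30+).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 600L, n_zotus = 40L, noise_sd = 1,
                        depth_mean = 15000, depth_size = 3, min_depth = 2000L,
                        seed = 1L, effects = NULL, age_slopes = NULL) {
  species <- c("Bifidobacterium longum", "Bifidobacterium pseudocatenulatum",
               "Bifidobacterium adolescentis", "Bifidobacterium breve",
               "Bifidobacterium bifidum", "Bifidobacterium animalis",
               "Bifidobacterium dentium", "Bifidobacterium angulatum",
               NA_character_)  # NA = genus-level-only taxon
  baselines <- c(2.0, 1.7, 1.5, 0.3, 0.2, -0.3, -1.0, -1.1, -1.6)
  feature <- ifelse(is.na(species), UNCLASSIFIED_BIF, species)
  names(baselines) <- feature
  sites <- data.frame(
    site = sprintf("S%02d", 1:12),
    lat = c(23.1, 26.6, 30.7, 31.2, 34.3, 36.1, 39.9, 41.8, 43.8, 45.8, 29.7, 36.6),
    lon = c(113.3, 106.6, 104.1, 121.5, 108.9, 103.8, 116.4, 123.4, 87.6,
            126.5, 91.1, 101.8),
    alt = c(20, 1100, 500, 10, 400, 1500, 50, 200, 900, 150, 3650, 2300),
    zone = c("I1", "II1", "II2", "I2", "II3", "III1", "I3", "I4", "III2",
             "I5", "IV2", "IV1"),
    ethnicity_main = c("Han", "Miao", "Han", "Han", "Han", "Hui", "Han",
                       "Han", "Uygur", "Mongolian", "Tibetan", "Tibetan"),
    stringsAsFactors = FALSE)
  if (is.null(effects)) {
    effects <- list(
      latitude = c("Bifidobacterium adolescentis" = 0.3, "Bifidobacterium angulatum" = -0.3,
                   "Bifidobacterium dentium" = -0.2),
      longitude = c("Bifidobacterium longum" = -0.15, "Bifidobacterium adolescentis" = -0.15,
                    "Bifidobacterium animalis" = 0.2),
      altitude = c("Bifidobacterium longum" = 0.2, "Bifidobacterium pseudocatenulatum" = 0.2,
                   "Bifidobacterium adolescentis" = 0.2, "Bifidobacterium angulatum" = 0.3),
      "staple=wheat" = c("Bifidobacterium adolescentis" = 0.8, "Bifidobacterium longum" = 0.8),
      "staple=rice&wheat" = c("Bifidobacterium adolescentis" = 0.4, "Bifidobacterium longum" = 0.4),
      "ethnicity=Tibetan" = stats::setNames(c(1.5, 1.0),
                                            c(UNCLASSIFIED_BIF, "Bifidobacterium angulatum")),
      "ethnicity=Uygur" = c("Bifidobacterium angulatum" = 1.2),
      "residence=urban" = c("Bifidobacterium dentium" = -0.5, "Bifidobacterium angulatum" = -0.4,
                            "Bifidobacterium animalis" = 0.3),
      "residence=pastoral" = stats::setNames(c(0.5, 0.4),
                                             c(UNCLASSIFIED_BIF, "Bifidobacterium angulatum")))
  }
  if (is.null(age_slopes)) {
    age_slopes <- rbind(
      "Bifidobacterium longum"             = c(-0.02, -0.02, -0.02),
      "Bifidobacterium pseudocatenulatum"  = c(0.08, 0.00, 0.00),
      "Bifidobacterium adolescentis"       = c(0.15, -0.03, -0.03),
      "Bifidobacterium breve"              = c(-0.08, -0.08, 0.00),
      "Bifidobacterium bifidum"            = c(-0.03, -0.03, -0.03),
      "Bifidobacterium animalis"           = c(-0.12, -0.01, -0.01),
      "Bifidobacterium dentium"            = c(-0.06, -0.06, 0.02),
      "Bifidobacterium angulatum"          = c(0.05, 0.00, 0.00))
    age_slopes <- rbind(age_slopes,
                        matrix(0, 1, 3, dimnames = list(UNCLASSIFIED_BIF)))
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_zotus = as.integer(n_zotus), species = species,
                 feature = feature, baselines = baselines,
                 noise_sd = noise_sd, change_points = c(16, 30),
                 age_slopes = age_slopes, effects = effects, sites = sites,
                 depth_mean = depth_mean, depth_size = depth_size,
                 min_depth = as.integer(min_depth),
                 background_logmean = log(sum(exp(baselines)) * 15),
                 background_logsd = 0.7, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Piecewise-linear age basis with breaks at the change points; returns the
# per-species log contribution for a vector of ages.
.age_effect <- function(ages, slopes, breaks) {
  b1 <- pmin(ages, breaks[1L])
  b2 <- pmin(pmax(ages - breaks[1L], 0), breaks[2L] - breaks[1L])
  b3 <- pmax(ages - breaks[2L], 0)
  cbind(b1, b2, b3) %*% t(slopes)
}

#' Simulate a cohort: ZOTU counts, 16S genus fraction, metadata, truth
#'
#' Per sample: covariates are drawn from the site layout; species
#' log-abundances are `baseline + piecewise age trend + planted covariate
#' effects + N(0, noise_sd)` on an absolute scale; an independent
#' log-normal background community sets the genus's 16S fraction
#' `bif16s = T / (T + background)` with `T` the summed bifidobacterial
#' abundance; sequencing depth is negative binomial (floored) and ZOTU
#' counts are multinomial over the within-genus composition, with fixed
#' per-species ZOTU weights (every species keeps at least one ZOTU).
#'
#' @param spec a [cohort_spec()].
#' @return list: `counts` (samples x ZOTUs), `bif16s`, `metadata`,
#'   `assignments` (ground-truth ZOTU taxonomy in [classify_table()]
#'   layout), `composition` (true composite species fractions),
#'   `truth` (data.frame of planted effects: `term`, `feature`, `effect`),
#'   `tree` (random coalescent over the ZOTUs, for Faith's PD), `spec`.
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  ns <- length(spec$species)
  site_i <- sample.int(nrow(spec$sites), n, replace = TRUE)
  sites <- spec$sites[site_i, , drop = FALSE]
  age <- round(stats::runif(n, 0.1, 90), 1)
  sex <- sample(c("female", "male"), n, replace = TRUE)
  month <- sample(c("April", "June", "August", "October"), n, replace = TRUE)
  # staple follows latitude (wheat in the north), with noise
  p_wheat <- stats::plogis((sites$lat - 36) / 5)
  staple <- vapply(p_wheat, function(pw) {
    sample(c("wheat", "rice", "rice&wheat"),
           1L, prob = c(pw, (1 - pw), 0.4))
  }, "")
  ethnicity <- vapply(seq_len(n), function(i) {
    main <- sites$ethnicity_main[i]
    sample(c(main, "Han"), 1L, prob = c(if (main == "Han") 1 else 0.7,
                                        if (main == "Han") 0 else 0.3))
  }, "")
  residence <- vapply(sites$alt, function(a) {
    if (a > 2000) sample(c("pastoral", "rural"), 1L, prob = c(0.6, 0.4))
    else sample(c("urban", "rural"), 1L, prob = c(0.4, 0.6))
  }, "")
  metadata <- data.frame(
    site = sites$site, lat = sites$lat, lon = sites$lon, alt = sites$alt,
    zone = sites$zone, age = age, sex = sex, ethnicity = ethnicity,
    staple = staple, residence = residence, month = month,
    row.names = sprintf("sample%04d", seq_len(n)), stringsAsFactors = FALSE)

  eta <- matrix(rep(spec$baselines, each = n), n, ns,
                dimnames = list(rownames(metadata), spec$feature))
  eta <- eta + .age_effect(age, spec$age_slopes[spec$feature, , drop = FALSE],
                           spec$change_points)
  truth <- list()
  zscore <- function(v) (v - mean(v)) / stats::sd(v)
  cont <- c(latitude = "lat", longitude = "lon", altitude = "alt")
  for (term in names(spec$effects)) {
    eff <- spec$effects[[term]]
    bad <- setdiff(names(eff), spec$feature)
    if (length(bad)) stop("effect on unknown feature(s): ",
                          paste(bad, collapse = ", "))
    if (term %in% names(cont)) {
      x <- zscore(metadata[[cont[[term]]]])
    } else {
      kv <- strsplit(term, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L || !kv[1L] %in% names(metadata)) {
        stop("unknown effect term: ", term)
      }
      x <- as.numeric(metadata[[kv[1L]]] == kv[2L])
    }
    eta[, names(eff)] <- eta[, names(eff), drop = FALSE] +
      outer(x, unname(eff))
    truth[[length(truth) + 1L]] <- data.frame(
      term = term, feature = names(eff), effect = unname(eff),
      stringsAsFactors = FALSE)
  }
  eta <- eta + matrix(stats::rnorm(n * ns, 0, spec$noise_sd), n, ns)
  abund <- exp(eta)
  total_bif <- rowSums(abund)
  background <- exp(stats::rnorm(n, spec$background_logmean,
                                 spec$background_logsd))
  bif16s <- total_bif / (total_bif + background)
  composition <- abund / (total_bif + background)

  # ZOTU layout: every species keeps one ZOTU, the rest are spread randomly
  zotu_species <- c(seq_len(ns),
                    sample.int(ns, spec$n_zotus - ns, replace = TRUE))
  zotu_w <- stats::rgamma(spec$n_zotus, shape = 2)
  zotu_ids <- sprintf("ZOTU%03d", seq_len(spec$n_zotus))
  within <- abund / total_bif
  pz <- within[, zotu_species, drop = FALSE] *
    rep(zotu_w / stats::ave(zotu_w, zotu_species, FUN = sum), each = n)
  colnames(pz) <- zotu_ids
  depth <- pmax(stats::rnbinom(n, mu = spec$depth_mean, size = spec$depth_size),
                spec$min_depth)
  counts <- t(vapply(seq_len(n), function(i) {
    stats::rmultinom(1L, depth[i], pz[i, ])[, 1L]
  }, integer(spec$n_zotus)))
  dimnames(counts) <- list(rownames(metadata), zotu_ids)

  assignments <- data.frame(
    zotu_id = zotu_ids, status = "assigned",
    taxonomy = vapply(spec$species[zotu_species],
                      function(s) bif_lineage(if (is.na(s)) NULL else s), ""),
    source = "agree", max_bit_nt = NA_real_, max_bit_bif = NA_real_,
    rule_fired = "rule3_agree", stringsAsFactors = FALSE)
  tree <- ape::rcoal(spec$n_zotus, tip.label = sample(zotu_ids))

  list(counts = counts, bif16s = stats::setNames(bif16s, rownames(metadata)),
       metadata = metadata, assignments = assignments,
       composition = composition,
       truth = do.call(rbind, truth), tree = tree, spec = spec)
}
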