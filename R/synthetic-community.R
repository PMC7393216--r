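#' Specification for a synthetic lake community
#'
#' Describes the study conditions a simulated dataset should emulate: a
#' two-habitat pond survey (brine and sediment samples along a salinity
#' gradient), a community of a few dominant and many rare taxa with
#' log-normal abundances, planted strongly correlated MAG pairs (the
#' symbiont signal), gene catalogs whose read counts follow taxon
#' abundance times gene length, homology hits consistent with a known
#' taxonomy, and KO inventories drawn from metabolic archetype templates.
#'
#' @param n_taxa Number of taxa (= MAGs; default 40).
#' @param n_samples Number of samples (default 18: 9 brine + 9 sediment).
#' @param sample_groups Named character vector sample -> group; default
#'   `B1..B9` brine and `S1..S9` sediment.
#' @param n_dominant Number of dominant taxa (default 5).  Dominance is
#'   modelled in tiers: per sample one of them is the top taxon at
#'   `dominant_factor` (default 100) times a lognorm(0, `sdlog_top`)
#'   factor over the rare mass (`meanlog_rare` 0, `sdlog_rare` 1); each
#'   other dominant taxon is co-abundant (relative level drawn uniformly
#'   from `abundant_band`, default 0.6-1.0 of the top) with probability
#'   `co_abundant_prob` (default 0.3), otherwise sub-dominant
#'   (`subdominant_band`, default 0.02-0.4).  The tiers keep the
#'   ground-truth abundant/not-abundant labels well separated from the
#'   50%-of-maximum decision boundary, so they remain stable under
#'   multiplicative observation noise.
#' @param meanlog_rare,sdlog_rare,dominant_factor,sdlog_top,co_abundant_prob,abundant_band,subdominant_band
#'   Abundance model parameters (see `n_dominant`).
#' @param planted_pairs Data frame (`taxon_a`, `taxon_b`, `rho`) of pairs
#'   whose abundance vectors are constructed to reach exactly the target
#'   Pearson correlation before observation noise; defaults to one
#'   perfect (rho 1) and one strong (rho 0.98) pair on the last four
#'   taxa.  `|rho| <= 1` required.
#' @param genes_per_taxon,gene_length_bp Integer ranges (min, max) for
#'   catalog genes per taxon and gene length in bp.
#' @param depth_per_sample Reads per sample for the gene catalog
#'   (default 1e5).
#' @param count_model `"multinomial"` (sampled integer counts) or
#'   `"expected"` (exact real-valued expected counts; the zero-noise
#'   validation mode, since multinomial sampling is itself noise).
#' @param decoy_prob Probability that a gene also hits a sister species
#'   within the top-bitscore band (exercises the LCA fallback; default 0).
#' @param contigs_per_taxon,contig_length_bp Integer ranges for MAG
#'   contig structure.
#' @param coverage_scale Mean-coverage scale factor linking taxon
#'   abundance to contig coverage (default 30).
#' @param coverage_noise_sd Standard deviation of multiplicative
#'   log-normal coverage noise (0 = noise-free; 0.05 is the 5% regime).
#' @param seed Integer seed; every random draw flows from it.
#' @return A validated `community_spec` list.
#' @export
community_spec <- function(n_taxa = 40,
                           n_samples = 18,
                           sample_groups = NULL,
                           n_dominant = 5,
                           meanlog_rare = 0,
                           sdlog_rare = 1,
                           dominant_factor = 100,
                           sdlog_top = 0.3,
                           co_abundant_prob = 0.3,
                           abundant_band = c(0.6, 1.0),
                           subdominant_band = c(0.02, 0.4),
                           planted_pairs = NULL,
                           genes_per_taxon = c(5L, 12L),
                           gene_length_bp = c(300L, 1500L),
                           depth_per_sample = 1e5,
                           count_model = c("multinomial", "expected"),
                           decoy_prob = 0,
                           contigs_per_taxon = c(3L, 6L),
                           contig_length_bp = c(20000L, 200000L),
                           coverage_scale = 30,
                           coverage_noise_sd = 0,
                           seed = 1L) {
  count_model <- match.arg(count_model)
  if (n_taxa < 1 || n_samples < 2) {
    stop_sodamag("need n_taxa >= 1 and n_samples >= 2",
                 class = "sodamag_parameter_error")
  }
  if (is.null(sample_groups)) {
    half <- ceiling(n_samples / 2)
    ids <- c(paste0("B", seq_len(half)),
             paste0("S", seq_len(n_samples - half)))
    sample_groups <- setNames(
      rep(c("brine", "sediment"), c(half, n_samples - half)), ids)
  }
  if (length(sample_groups) != n_samples) {
    stop_sodamag("sample_groups must name all ", n_samples, " samples",
                 class = "sodamag_parameter_error")
  }
  taxa <- sprintf("T%02d", seq_len(n_taxa))
  if (is.null(planted_pairs)) {
    planted_pairs <- if (n_taxa >= 4 && n_taxa > n_dominant + 4) {
      tibble::tibble(
        taxon_a = taxa[c(n_taxa - 3L, n_taxa - 1L)],
        taxon_b = taxa[c(n_taxa - 2L, n_taxa)],
        rho = c(1.0, 0.98))
    } else {
      tibble::tibble(taxon_a = character(), taxon_b = character(),
                     rho = numeric())
    }
  }
  planted_pairs <- as_tibble(planted_pairs)
  if (nrow(planted_pairs) > 0) {
    if (any(abs(planted_pairs$rho) > 1)) {
      stop_sodamag("planted correlation target |rho| must be <= 1",
                   class = "sodamag_parameter_error")
    }
    bad <- setdiff(c(planted_pairs$taxon_a, planted_pairs$taxon_b), taxa)
    if (length(bad) > 0L) {
      stop_sodamag("planted pair references unknown taxa: ",
                   paste(bad, collapse = ", "),
                   class = "sodamag_parameter_error")
    }
  }
  if (depth_per_sample <= 0) {
    stop_sodamag("depth_per_sample must be positive",
                 class = "sodamag_parameter_error")
  }
  structure(list(
    n_taxa = as.integer(n_taxa), n_samples = as.integer(n_samples),
    sample_groups = sample_groups, taxa = taxa,
    n_dominant = as.integer(n_dominant),
    meanlog_rare = meanlog_rare, sdlog_rare = sdlog_rare,
    dominant_factor = dominant_factor, sdlog_top = sdlog_top,
    co_abundant_prob = co_abundant_prob,
    abundant_band = abundant_band,
    subdominant_band = subdominant_band,
    planted_pairs = planted_pairs,
    genes_per_taxon = as.integer(genes_per_taxon),
    gene_length_bp = as.integer(gene_length_bp),
    depth_per_sample = depth_per_sample, count_model = count_model,
    decoy_prob = decoy_prob,
    contigs_per_taxon = as.integer(contigs_per_taxon),
    contig_length_bp = as.integer(contig_length_bp),
    coverage_scale = coverage_scale,
    coverage_noise_sd = coverage_noise_sd,
    seed = as.integer(seed)), class = "community_spec")
}

#' Metabolic archetype marker templates
#'
#' Named marker inventories mirroring recurring soda-lake genome types:
#' an autotrophic sulfur oxidiser (CBB cycle plus sqr/fccB, the oxidative
#' rDsrAB context and soeABC), a chemolithotrophic sulfate reducer
#' (reductive dsrABD, polysulfide/thiosulfate respiration, mvhADG and the
#' Wood-Ljungdahl markers), a nanohaloarchaeon with the phosphorolytic
#' glucan route and complete glycolysis but no amylase, a woesearchaeon
#' with amylase but neither phosphoglucomutase nor phosphofructokinase
#' (incomplete glycolysis), and a minimal sqr-only heterotroph.
#'
#' @return Named list of marker character vectors.
#' @export
ko_profile_templates <- function() {
  glycolysis <- c("gpi", "pfk", "fba", "tpi", "gap", "pgk", "gpm",
                  "eno", "pk")
  list(
    sulfur_oxidizer_autotroph = c(
      "prk", "rbcL", "rbcS", "sqr", "fccB",
      "dsrA", "dsrB", "dsrE", "dsrF", "dsrH",
      "soeA", "soeB", "soeC"),
    sulfate_reducer = c(
      "dsrA", "dsrB", "dsrD", "psrA_phsA",
      "mvhA", "mvhD", "mvhG",
      "cooS", "acsB", "cdhD", "cdhE"),
    nanohaloarchaeon_NHA1 = c("pyg", "pgm", glycolysis),
    woesearchaeon = c("pyg", "amy", "glk",
                      setdiff(glycolysis, "pfk")),
    heterotroph_sqr = "sqr")
}

sample_range <- function(range, n) {
  if (range[[1L]] == range[[2L]]) rep(range[[1L]], n)
  else sample(seq(range[[1L]], range[[2L]]), n, replace = TRUE)
}

# affine-free construction of a positive vector with exact sample Pearson
# correlation rho against `a` (n >= 3; a must be non-constant)
planted_vector <- function(a, rho, scale = mean(a)) {
  n <- length(a)
  z <- as.vector(scale(a))
  repeat {
    e <- stats::rnorm(n)
    e <- stats::residuals(stats::lm(e ~ z))
    if (stats::sd(e) > 1e-12) break
  }
  e <- as.vector(scale(e))
  b <- rho * z + sqrt(max(0, 1 - rho^2)) * e
  shrink <- 0.9 / max(abs(b))
  scale * (1 + shrink * b)
}

#' Generate a synthetic community with full ground truth
#'
#' Builds, deterministically from `spec$seed`, a taxonomy (5 ranks:
#' root, superkingdom, phylum, genus, species), per-sample taxon
#' abundances from the dominant/rare log-normal model with planted
#' exact-correlation pairs, MAG contig sets with coverage proportional to
#' taxon abundance (optionally with multiplicative noise), a gene catalog
#' with counts proportional to taxon abundance times gene length, a hit
#' table pointing every gene at its taxon's species taxid (plus optional
#' sister-species decoys in the top-bitscore band), and per-MAG marker
#' inventories cycled over [ko_profile_templates()].
#'
#' @param spec A [community_spec()].
#' @return A `community_truth` list: `spec`, `taxonomy`
#'   ([taxonomy_tree()]), `taxa` tibble (taxon_id, species/genus/phylum
#'   taxids, template), `abundance` (taxa x samples truth matrix, raw
#'   positive scale), `mags` ([mag_set()]), `genes` ([gene_catalog()]),
#'   `gene_taxon` (gene -> taxon map), `hits` (hit tibble), `markers`
#'   (long tibble mag_id/marker), `groups`, `expected_abundant` (tibble
#'   of truth abundant calls), and `expected_modules` (module partition
#'   of the noise-free truth abundance matrix; it contains the planted
#'   pairs plus any chance super-threshold correlation in the sampled
#'   profiles).
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  withr::with_seed(spec$seed, generate_community_impl(spec))
}

generate_community_impl <- function(spec) {
  n <- spec$n_taxa
  samples <- names(spec$sample_groups)

  # taxonomy: root(1) -> 2 superkingdoms -> phyla -> genera -> species.
  # two species per genus so sister-species decoy hits are well defined.
  n_genus <- ceiling(n / 2)
  n_phyla <- max(2L, ceiling(n_genus / 3))
  species_tax <- 1000L + seq_len(n)
  genus_of_taxon <- rep(seq_len(n_genus), each = 2L)[seq_len(n)]
  genus_tax <- 500L + seq_len(n_genus)
  phylum_of_genus <- rep(seq_len(n_phyla), length.out = n_genus)
  phylum_tax <- 100L + seq_len(n_phyla)
  sk_of_phylum <- rep(c(1L, 2L), length.out = n_phyla)
  sk_tax <- c(10L, 11L)
  taxonomy <- taxonomy_tree(
    taxid = c(1L, sk_tax, phylum_tax, genus_tax, species_tax),
    parent = c(1L, 1L, 1L, sk_tax[sk_of_phylum],
               phylum_tax[phylum_of_genus], genus_tax[genus_of_taxon]),
    rank = c("root", rep("superkingdom", 2L),
             rep("phylum", n_phyla), rep("genus", n_genus),
             rep("species", n)),
    name = c("root", "Bacteria", "Archaea",
             paste0("Phylum_", seq_len(n_phyla)),
             paste0("Genus_", seq_len(n_genus)),
             paste0("Species_", spec$taxa)))

  templates <- ko_profile_templates()
  taxa <- tibble::tibble(
    taxon_id = spec$taxa,
    species_taxid = species_tax,
    genus_taxid = genus_tax[genus_of_taxon],
    phylum_taxid = phylum_tax[phylum_of_genus][genus_of_taxon],
    template = names(templates)[rep(seq_along(templates),
                                    length.out = n)])

  # abundance truth: a few dominant taxa over many rare ones
  abund <- matrix(
    stats::rlnorm(n * length(samples), spec$meanlog_rare,
                  spec$sdlog_rare),
    nrow = n, dimnames = list(spec$taxa, samples))
  if (spec$n_dominant > 0) {
    dom <- seq_len(min(spec$n_dominant, n))
    for (s in seq_along(samples)) {
      top <- spec$dominant_factor * stats::rlnorm(1, 0, spec$sdlog_top)
      level <- numeric(length(dom))
      level[[sample(seq_along(dom), 1L)]] <- 1
      open <- level == 0
      co <- open & stats::runif(length(dom)) < spec$co_abundant_prob
      level[co] <- stats::runif(sum(co), spec$abundant_band[[1L]],
                                spec$abundant_band[[2L]])
      sub <- open & !co
      level[sub] <- stats::runif(sum(sub), spec$subdominant_band[[1L]],
                                 spec$subdominant_band[[2L]])
      abund[dom, s] <- top * level
    }
  }
  if (length(samples) >= 3) {
    for (i in seq_len(nrow(spec$planted_pairs))) {
      pp <- spec$planted_pairs[i, ]
      abund[pp$taxon_b, ] <- planted_vector(
        abund[pp$taxon_a, ], pp$rho,
        scale = mean(abund[pp$taxon_b, ]))
    }
  }

  # MAGs: one per taxon; coverage proportional to abundance
  n_contigs <- sample_range(spec$contigs_per_taxon, n)
  contigs <- tibble::tibble(
    contig_id = unlist(lapply(seq_len(n), function(i) {
      sprintf("%s_c%02d", spec$taxa[[i]], seq_len(n_contigs[[i]]))
    })),
    mag_id = rep(spec$taxa, n_contigs),
    length_bp = sample_range(spec$contig_length_bp, sum(n_contigs)))
  coverage <- spec$coverage_scale *
    abund[contigs$mag_id, , drop = FALSE]
  if (spec$coverage_noise_sd > 0) {
    coverage <- coverage * matrix(
      stats::rlnorm(length(coverage), 0, spec$coverage_noise_sd),
      nrow = nrow(coverage))
  }
  rownames(coverage) <- contigs$contig_id
  quality <- tibble::tibble(
    mag_id = spec$taxa,
    completeness = round(stats::runif(n, 92, 99), 2),
    contamination = round(stats::runif(n, 0, 3), 2),
    taxonomy_label = unname(taxonomy$name[as.character(taxa$species_taxid)]))
  mags <- mag_set(contigs, coverage, quality)

  # gene catalog: counts ~ taxon abundance x gene length
  n_genes <- sample_range(spec$genes_per_taxon, n)
  gene_taxon <- rep(spec$taxa, n_genes)
  taxon_idx <- match(gene_taxon, spec$taxa)
  gene_id <- unlist(lapply(seq_len(n), function(i) {
    sprintf("%s_g%03d", spec$taxa[[i]], seq_len(n_genes[[i]]))
  }))
  gene_len <- sample_range(spec$gene_length_bp, length(gene_id))
  # each taxon's read mass is proportional to its abundance and is split
  # over its genes proportionally to gene length, so the mOTU-style sum
  # of length-normalised gene abundances recovers the taxon profile
  # exactly in the noise-free regime
  weight <- abund[gene_taxon, , drop = FALSE] *
    (gene_len / n_genes[taxon_idx])
  prob <- sweep(weight, 2, colSums(weight), "/")
  counts <- if (spec$count_model == "expected") {
    prob * spec$depth_per_sample
  } else {
    vapply(seq_along(samples), function(s) {
      stats::rmultinom(1L, size = spec$depth_per_sample,
                       prob = prob[, s])[, 1L]
    }, numeric(length(gene_id)))
  }
  dimnames(counts) <- list(gene_id, samples)
  genes <- gene_catalog(gene_id, gene_len, counts)

  # hit table: own species, plus optional sister-species decoy in the
  # top-bitscore band (sister = the other species of the same genus)
  own <- tibble::tibble(
    query_id = gene_id,
    subject_id = paste0("ref_", taxa$species_taxid[taxon_idx]),
    pident = 98, align_len = as.integer(round(gene_len / 3)),
    mismatch = 2L, gapopen = 0L, qstart = 1L,
    qend = as.integer(round(gene_len / 3)), sstart = 1L,
    send = as.integer(round(gene_len / 3)),
    evalue = 1e-50, bitscore = 200,
    taxid = taxa$species_taxid[taxon_idx])
  hits <- own
  if (spec$decoy_prob > 0) {
    sister_genus <- genus_of_taxon
    sister <- vapply(seq_len(n), function(i) {
      others <- which(sister_genus == sister_genus[[i]])
      others <- setdiff(others, i)
      if (length(others) == 0L) NA_integer_
      else taxa$species_taxid[[others[[1L]]]]
    }, integer(1))
    decoy_tax <- sister[taxon_idx]
    pick <- stats::rbinom(length(gene_id), 1L, spec$decoy_prob) == 1L &
      !is.na(decoy_tax)
    if (any(pick)) {
      decoys <- own[pick, ]
      decoys$subject_id <- paste0("ref_", decoy_tax[pick])
      decoys$pident <- 95
      decoys$bitscore <- 190   # within the 10% top-bitscore band
      decoys$taxid <- decoy_tax[pick]
      hits <- rbind(own, decoys)
    }
  }

  markers <- tibble::tibble(
    mag_id = rep(taxa$taxon_id,
                 lengths(templates[taxa$template])),
    marker = unlist(templates[taxa$template], use.names = FALSE))

  # truth-side expectations, from the noise-free abundance
  scaled <- sweep(abund, 2, apply(abund, 2, max) / 100, "/")
  expected_abundant <- tibble::tibble(
    mag_id = rep(rownames(scaled), times = ncol(scaled)),
    sample_id = rep(colnames(scaled), each = nrow(scaled)),
    is_abundant = as.vector(scaled) > 50)
  # co-occurrence is a deterministic functional of the abundances, so
  # the truth modules are the thresholded-correlation components of the
  # noise-free truth matrix itself; the planted pairs guarantee their
  # own edges, and any chance super-threshold correlation between other
  # sampled profiles is genuine truth-level structure
  expected_modules <- if (length(samples) >= 3 && n >= 2) {
    extract_modules(
      build_network(pairwise_correlation(
        abundance_matrix(abund, "raw"))),
      nodes = spec$taxa)
  } else {
    strong <- spec$planted_pairs[spec$planted_pairs$rho > 0.9, ,
                                 drop = FALSE]
    extract_modules(
      tibble::tibble(mag_a = strong$taxon_a, mag_b = strong$taxon_b),
      nodes = spec$taxa)
  }

  structure(list(
    spec = spec, taxonomy = taxonomy, taxa = taxa, abundance = abund,
    mags = mags, genes = genes,
    gene_taxon = setNames(gene_taxon, gene_id), hits = hits,
    markers = markers, groups = spec$sample_groups,
    expected_abundant = expected_abundant,
    expected_modules = expected_modules), class = "community_truth")
}

#' @export
print.community_truth <- function(x, ...) {
  cat(sprintf(paste0("synthetic community: %d taxa x %d samples, ",
                     "%d genes, %d planted pair(s), seed %d\n"),
              x$spec$n_taxa, x$spec$n_samples, nrow(x$genes$genes),
              nrow(x$spec$planted_pairs), x$spec$seed))
  invisible(x)
}

#' Write a synthetic community's observable files
#'
#' Emits every file a real pipeline run would consume, in the package's
#' I/O dialects: gene catalog FASTA (random sequences of the recorded
#' lengths) and count TSV, a 13-column hit table, the taxonomy as
#' 4-column TSV, contig coverage and MAG quality TSVs, the gene-to-KO
#' long table realised from the marker templates, and the sample-group
#' map.  Output is byte-deterministic for a given spec seed.
#'
#' @param truth A `community_truth` from [generate_community()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
emit_observables <- function(truth, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop_sodamag("cannot create output directory: ", out_dir,
                 class = "sodamag_io_error")
  }
  paths <- c(
    genes_fasta = file.path(out_dir, "genes.fasta"),
    gene_counts = file.path(out_dir, "gene_counts.tsv"),
    hits = file.path(out_dir, "hits.tsv"),
    taxonomy = file.path(out_dir, "taxonomy.tsv"),
    contig_coverage = file.path(out_dir, "contig_coverage.tsv"),
    mag_quality = file.path(out_dir, "mag_quality.tsv"),
    gene_ko = file.path(out_dir, "gene_ko.tsv"),
    sample_groups = file.path(out_dir, "sample_groups.tsv"))

  withr::with_seed(truth$spec$seed + 1L, {
    seqs <- vapply(truth$genes$genes$length_bp, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = "")
    }, "")
  })
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- truth$genes$genes$gene_id
  Biostrings::writeXStringSet(dna, paths[["genes_fasta"]])

  write_gene_counts(truth$genes, paths[["gene_counts"]])
  write_blast_tab(truth$hits, paths[["hits"]])
  write_taxonomy(truth$taxonomy, paths[["taxonomy"]])
  write_mag_set(truth$mags, paths[["contig_coverage"]],
                paths[["mag_quality"]])

  map <- marker_ko_map()
  gene_ko <- tibble::tibble(
    gene_id = sprintf("%s_mk%02d", truth$markers$mag_id,
                      stats::ave(seq_len(nrow(truth$markers)),
                                 truth$markers$mag_id,
                                 FUN = seq_along)),
    mag_id = truth$markers$mag_id,
    ko = map$ko[match(truth$markers$marker, map$marker)])
  utils::write.table(as.data.frame(gene_ko), paths[["gene_ko"]],
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")

  utils::write.table(
    data.frame(sample_id = names(truth$groups), group = truth$groups),
    paths[["sample_groups"]], sep = "\t", quote = FALSE,
    row.names = FALSE, fileEncoding = "UTF-8")
  invisible(paths)
}
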