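#' Configuration for a synthetic metagenomic community
#'
#' Study conditions for the synthetic-community generator: a gene catalog
#' of a few hundred genes observed in tens of samples spanning two filter
#' size fractions (particle-associated = 1, free-living = 0) and a depth
#' gradient, with a known size-fraction effect and a saturating depth
#' trend injected into the coverage-weighted GC and N-ARSC, ten
#' single-copy marker genes, marker gene-cluster families per domain, and
#' multiplicative lognormal coverage noise.
#'
#' Defaults mirror the scale of the study system: a fraction effect of
#' +0.05 on weighted GC and +0.013 atoms/residue on weighted N-ARSC in
#' the particle fraction, and a depth trend that rises from the surface
#' and plateaus near 150 m.
#'
#' @param n_genes Catalog size (default 400).
#' @param n_samples Number of metagenomes (default 48; must be even).
#' @param depths Unique sampling depths in meters, recycled over samples.
#' @param base_gc,base_narsc Free-living surface values of the weighted
#'   GC fraction and N-ARSC (atoms/residue).
#' @param delta_gc,delta_narsc Injected particle-minus-free-living
#'   differences in weighted GC and N-ARSC.
#' @param depth_amplitude_gc,depth_amplitude_narsc Plateau heights of the
#'   saturating depth trend added to GC and N-ARSC.
#' @param depth_scale_m e-folding scale of the depth trend
#'   (`amp * (1 - exp(-depth/scale))`), default 50 m.
#' @param coverage_noise_sd Lognormal sigma of the multiplicative
#'   coverage noise (default 0.3).
#' @param n_single_copy Number of single-copy marker genes (default 10).
#' @param marker_cluster_counts Named vector: gene clusters per marker
#'   family (bacteria rpoZ, archaea ftsZ, virus Gp23).
#' @param mean_gene_length_aa Mean protein length of simulated genes.
#' @param seed Integer seed; the whole community is a deterministic
#'   function of the configuration.
#' @return A list of class `community_config`.
#' @export
community_config <- function(n_genes = 400,
                             n_samples = 48,
                             depths = c(15, 30, 50, 75, 90, 100, 112, 125,
                                        150, 200, 300, 500),
                             base_gc = 0.48, base_narsc = 0.31,
                             delta_gc = 0.05, delta_narsc = 0.013,
                             depth_amplitude_gc = 0.02,
                             depth_amplitude_narsc = 0.005,
                             depth_scale_m = 50,
                             coverage_noise_sd = 0.3,
                             n_single_copy = 10,
                             marker_cluster_counts = c(bacteria = 24,
                                                       archaea = 18,
                                                       virus = 18),
                             mean_gene_length_aa = 150,
                             seed = 1L) {
  stopifnot(n_genes >= 50, n_samples %% 2 == 0, n_samples >= 8,
            n_single_copy <= n_genes, coverage_noise_sd >= 0,
            base_gc + delta_gc + depth_amplitude_gc < 1,
            base_narsc + delta_narsc + depth_amplitude_narsc < 3)
  structure(as.list(environment()), class = "community_config")
}

#' Simulate one gene with controlled amino-acid usage and GC bias
#'
#' Draws a protein of the requested length from the given amino-acid
#' weights, then back-translates it choosing synonymous codons with
#' probabilities tilted toward G/C-rich codons by `gc_bias` (0.5 is
#' neutral); the CDS translates exactly back to the sampled protein and
#' contains no stop codon.
#'
#' @param length_aa Protein length in residues.
#' @param aa_weights Named 20-vector of amino-acid sampling weights
#'   (normalized internally).
#' @param gc_bias Codon G/C preference in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A one-row tibble: `cds`, `protein`.
#' @export
simulate_gene <- function(length_aa, aa_weights, gc_bias = 0.5, seed = NULL) {
  stopifnot(length_aa >= 1, gc_bias >= 0, gc_bias <= 1)
  if (is.null(names(aa_weights)) || !all(.aa_codes %in% names(aa_weights))) {
    stop("aa_weights must be named with the 20 standard codes", call. = FALSE)
  }
  aa_weights <- aa_weights[.aa_codes]
  if (any(aa_weights < 0) || sum(aa_weights) <= 0) {
    stop("invalid amino-acid weights", call. = FALSE)
  }
  gen <- function() {
    prot <- sample(.aa_codes, length_aa, replace = TRUE,
                   prob = aa_weights / sum(aa_weights))
    codons <- character(length_aa)
    for (a in unique(prot)) {
      fam <- names(.genetic_code)[.genetic_code == a]
      gcn <- stringr::str_count(fam, "[GC]")
      p <- gc_bias^gcn * (1 - gc_bias)^(3 - gcn)
      if (sum(p) == 0) p <- rep(1, length(fam))
      pos <- which(prot == a)
      codons[pos] <- sample(fam, length(pos), replace = TRUE, prob = p / sum(p))
    }
    tibble::tibble(cds = paste(codons, collapse = ""),
                   protein = paste(prot, collapse = ""))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# saturating depth trend: flat near surface value, plateau near 150 m
.depth_trend <- function(depth, amplitude, scale_m) {
  amplitude * (1 - exp(-depth / scale_m))
}

# amino-acid sampling weights for the generator's gene pools; gc_tilt
# favors residues whose codon families are AT-rich (-1) or GC-rich (+1)
# without touching side-chain nitrogen (both tilt sets are N-free)
.pool_aa_weights <- function(n_rich_scale, gc_tilt = 0) {
  w <- stats::setNames(rep(1, 20), .aa_codes)
  w[c("R", "K", "H", "N", "Q", "W")] <- n_rich_scale
  if (gc_tilt < 0) w[c("F", "I", "L", "Y", "M")] <- 2.5
  if (gc_tilt > 0) w[c("A", "G", "P", "V")] <- 2.5
  w
}

#' Simulate a synthetic community with known stoichiogenomic structure
#'
#' Builds a gene catalog (CDS + protein + annotations), per-sample
#' expected and noisy observed coverage tables, sample metadata, and a
#' ground-truth record. Genes are drawn from three pools differing in GC
#' bias and side-chain nitrogen richness; per sample the pool mixing
#' proportions are solved (per domain) so that the *expected*
#' coverage-weighted GC and N-ARSC hit
#' `base + delta * fraction + trend(depth)` exactly. Ten single-copy
#' marker genes share one common expected coverage per sample (one copy
#' per average genome), and small marker gene-cluster families (rpoZ /
#' ftsZ / Gp23 analogs) with varying arginine content are appended for
#' the amino-acid driver analysis. Observed coverage multiplies the
#' expectation by mean-one lognormal noise.
#'
#' @param config A [community_config()].
#' @return A list of class `stoich_community`: `catalog` (gene tibble with
#'   `gene_id`, `cds`, `protein`, `domain_label`, `ko_label`,
#'   `is_single_copy_cog`), `coverage` and `expected_coverage` (long
#'   tibbles), `metadata` (`sample_id`, `station`, `depth`, `fraction`,
#'   `total_reads`), and `ground_truth` (true per-sample weighted GC /
#'   N-ARSC per domain, injected effect sizes, expected genes per genome).
#' @export
simulate_community <- function(config = community_config()) {
  stopifnot(inherits(config, "community_config"))
  withr::with_seed(config$seed, .simulate_community_impl(config))
}

.simulate_community_impl <- function(cfg) {
  domains <- c(bacteria = 0.70, archaea = 0.18, virus = 0.12)
  n_dom <- pmax(round(cfg$n_genes * domains), 30)
  pool_bias <- c(0.10, 0.95, 0.50)
  pool_nscale <- c(0.4, 0.4, 1.5)
  pool_tilt <- c(-1, 1, 0)

  # --- catalog ------------------------------------------------------------
  catalog <- purrr::map_dfr(names(n_dom), function(d) {
    n <- n_dom[[d]]
    pool <- rep_len(1:3, n)
    lens <- pmax(50, stats::rpois(n, cfg$mean_gene_length_aa))
    g <- purrr::map_dfr(seq_len(n), function(i) {
      simulate_gene(lens[i],
                    .pool_aa_weights(pool_nscale[pool[i]], pool_tilt[pool[i]]),
                    gc_bias = pool_bias[pool[i]])
    })
    g$domain_label <- d
    g$pool <- pool
    g
  })
  catalog$gene_id <- sprintf("g%04d", seq_len(nrow(catalog)))
  catalog$is_single_copy_cog <- FALSE
  sc_idx <- which(catalog$domain_label == "bacteria" & catalog$pool == 2)
  sc_idx <- sc_idx[seq_len(cfg$n_single_copy)]
  catalog$is_single_copy_cog[sc_idx] <- TRUE
  catalog$ko_label <- ""
  bact <- which(catalog$domain_label == "bacteria" & !catalog$is_single_copy_cog)
  kos <- c("sdhC", sprintf("K%05d", seq_len(max(1, length(bact) %/% 5))))
  catalog$ko_label[bact] <- rep_len(kos, length(bact))

  # marker gene-cluster families, distinguished mainly by arginine content
  marker_names <- c(bacteria = "rpoZ", archaea = "ftsZ", virus = "Gp23")
  markers <- purrr::map_dfr(names(cfg$marker_cluster_counts), function(d) {
    k <- cfg$marker_cluster_counts[[d]]
    purrr::map_dfr(seq_len(k), function(i) {
      w <- stats::setNames(rep(1, 20), .aa_codes)
      w["R"] <- 0.5 + 3.5 * (i - 1) / max(k - 1, 1)
      w[setdiff(.aa_codes, "R")] <- w[setdiff(.aa_codes, "R")] *
        exp(stats::rnorm(19, 0, 0.1))
      g <- simulate_gene(120, w, gc_bias = 0.5)
      g$domain_label <- d
      g$pool <- NA_integer_
      g$is_single_copy_cog <- FALSE
      g$ko_label <- marker_names[[d]]
      g
    })
  })
  markers$gene_id <- sprintf("mk%03d", seq_len(nrow(markers)))
  catalog <- dplyr::bind_rows(catalog, markers)

  props <- gene_properties(
    catalog[, c("gene_id", "cds", "protein", "domain_label", "ko_label",
                "is_single_copy_cog")])

  # --- samples ------------------------------------------------------------
  grid <- tidyr::expand_grid(depth = cfg$depths, fraction = c(0, 1))
  grid <- grid[rep_len(seq_len(nrow(grid)), cfg$n_samples), ]
  metadata <- tibble::tibble(
    sample_id = sprintf("s%03d", seq_len(cfg$n_samples)),
    station = rep_len(paste0("st", 1:4), cfg$n_samples),
    depth = grid$depth,
    fraction = grid$fraction,
    total_reads = round(1e7 * exp(stats::rnorm(cfg$n_samples, 0, 0.3)))
  )

  # --- expected coverage: solve pool mixing per domain and sample ---------
  base_w <- exp(stats::rnorm(nrow(catalog), 0, 1))  # within-pool gene weights
  base_w[catalog$is_single_copy_cog] <-
    mean(base_w[catalog$is_single_copy_cog])  # one copy per average genome
  dom_scale <- c(bacteria = 200, archaea = 40, virus = 60)

  target_gc <- function(fr, dp) cfg$base_gc + cfg$delta_gc * fr +
    .depth_trend(dp, cfg$depth_amplitude_gc, cfg$depth_scale_m)
  target_n <- function(fr, dp) cfg$base_narsc + cfg$delta_narsc * fr +
    .depth_trend(dp, cfg$depth_amplitude_narsc, cfg$depth_scale_m)

  expected <- purrr::map_dfr(names(n_dom), function(d) {
    in_dom <- catalog$domain_label == d & !is.na(catalog$pool)
    pm <- vapply(1:3, function(p) {
      i <- in_dom & catalog$pool == p
      c(gc = stats::weighted.mean(props$gc[i], base_w[i]),
        n = stats::weighted.mean(props$n_arsc[i], base_w[i]))
    }, numeric(2))
    A <- rbind(rep(1, 3), pm["gc", ], pm["n", ])
    purrr::map_dfr(seq_len(nrow(metadata)), function(s) {
      b <- c(1, target_gc(metadata$fraction[s], metadata$depth[s]),
             target_n(metadata$fraction[s], metadata$depth[s]))
      a <- solve(A, b)
      if (any(a < -1e-10)) {
        stop("injected deltas infeasible for the generator's gene pools",
             call. = FALSE)
      }
      a <- pmax(a, 0)
      scale_s <- dom_scale[[d]] * metadata$total_reads[s] / 1e7
      w <- numeric(sum(in_dom))
      genes_d <- which(in_dom)
      for (p in 1:3) {
        i <- catalog$pool[genes_d] == p
        w[i] <- a[p] * base_w[genes_d][i] / sum(base_w[genes_d][i])
      }
      tibble::tibble(sample_id = metadata$sample_id[s],
                     gene_id = catalog$gene_id[genes_d],
                     coverage = scale_s * w)
    })
  })

  # marker clusters: ~1% of domain coverage, arginine-rich clusters favored
  # in the particle fraction and at depth
  marker_cov <- purrr::map_dfr(names(cfg$marker_cluster_counts), function(d) {
    mk <- which(catalog$domain_label == d & is.na(catalog$pool))
    z <- scale(props$aa_R[mk])[, 1]
    purrr::map_dfr(seq_len(nrow(metadata)), function(s) {
      drive <- 0.8 * metadata$fraction[s] +
        0.8 * (1 - exp(-metadata$depth[s] / cfg$depth_scale_m))
      w <- exp(z * drive + stats::rnorm(length(mk), 0, 0.2))
      scale_s <- 0.01 * dom_scale[[d]] * metadata$total_reads[s] / 1e7
      tibble::tibble(sample_id = metadata$sample_id[s],
                     gene_id = catalog$gene_id[mk],
                     coverage = scale_s * w / sum(w))
    })
  })
  expected <- dplyr::bind_rows(expected, marker_cov) |>
    dplyr::arrange(.data$sample_id, .data$gene_id)

  noise <- exp(stats::rnorm(nrow(expected), 0, cfg$coverage_noise_sd) -
                 cfg$coverage_noise_sd^2 / 2)
  observed <- dplyr::mutate(expected, coverage = .data$coverage * noise)

  # --- ground truth (independent matrix arithmetic, not sample_profiles) --
  gt_profiles <- expected |>
    dplyr::left_join(props[, c("gene_id", "domain_label", "gc", "n_arsc")],
                     by = "gene_id") |>
    dplyr::group_by(.data$sample_id, .data$domain_label) |>
    dplyr::summarise(
      gc = sum(.data$gc * .data$coverage) / sum(.data$coverage),
      n_arsc = sum(.data$n_arsc * .data$coverage) / sum(.data$coverage),
      .groups = "drop")
  sc_ids <- catalog$gene_id[catalog$is_single_copy_cog]
  gt_gpg <- expected |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      genes_per_genome = sum(.data$coverage) /
        mean(.data$coverage[.data$gene_id %in% sc_ids]),
      .groups = "drop")

  structure(list(
    catalog = dplyr::select(catalog, "gene_id", "cds", "protein",
                            "domain_label", "ko_label", "is_single_copy_cog"),
    properties = props,
    coverage = observed,
    expected_coverage = expected,
    metadata = metadata,
    single_copy_ids = sc_ids,
    marker_ids = stats::setNames(
      lapply(names(marker_names), function(d)
        catalog$gene_id[catalog$ko_label == marker_names[[d]]]),
      marker_names),
    ground_truth = list(
      profiles = gt_profiles,
      genes_per_genome = gt_gpg,
      delta_gc = cfg$delta_gc,
      delta_narsc = cfg$delta_narsc,
      depth_trend = c(amplitude_gc = cfg$depth_amplitude_gc,
                      amplitude_narsc = cfg$depth_amplitude_narsc,
                      scale_m = cfg$depth_scale_m)),
    config = cfg), class = "stoich_community")
}

#' @exportS3Method base::print
print.stoich_community <- function(x, ...) {
  cat("Synthetic community:", nrow(x$catalog), "genes,",
      nrow(x$metadata), "samples,",
      length(x$single_copy_ids), "single-copy markers\n")
  invisible(x)
}

#' Simulate alignment records reproducing a target coverage
#'
#' Emits per-read alignment summaries (sample, gene, alignment length,
#' mismatches, mapped bases) whose recomputed coverage matches the target
#' coverage row: for each gene, `round(coverage * length / read_length)`
#' reads of `min(read_length, gene_length)` bases with binomial
#' mismatches at the given per-base error rate.
#'
#' @param coverage_row Named numeric vector (or tibble with `gene_id`,
#'   `coverage`) of target coverages for one sample.
#' @param gene_lengths As in [gene_coverage()].
#' @param sample_id Sample identifier stamped on the records.
#' @param read_length Read length in bp (default 150); reads are
#'   truncated to the gene length for short genes.
#' @param error_rate Per-base mismatch probability.
#' @param seed Optional integer seed.
#' @return An alignment tibble suitable for [filter_alignments()].
#' @export
simulate_alignments <- function(coverage_row, gene_lengths,
                                sample_id = "s001", read_length = 150,
                                error_rate = 0.005, seed = NULL) {
  if (is.data.frame(coverage_row)) {
    coverage_row <- stats::setNames(coverage_row$coverage, coverage_row$gene_id)
  }
  len <- .as_length_vector(gene_lengths)
  stopifnot(all(names(coverage_row) %in% names(len)), all(coverage_row >= 0))
  gen <- function() {
    purrr::map_dfr(names(coverage_row), function(g) {
      alen <- min(read_length, len[[g]])
      n_reads <- round(coverage_row[[g]] * len[[g]] / alen)
      if (n_reads == 0) return(NULL)
      tibble::tibble(
        sample_id = sample_id, gene_id = g,
        alignment_length = rep(alen, n_reads),
        mismatches = stats::rbinom(n_reads, alen, error_rate),
        mapped_bases = rep(alen, n_reads))
    })
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  if (is.null(out) || nrow(out) == 0) {
    return(tibble::tibble(sample_id = character(), gene_id = character(),
                          alignment_length = integer(),
                          mismatches = integer(), mapped_bases = integer()))
  }
  out
}
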