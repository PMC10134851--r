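#' Read a FASTA file into a tibble
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @return A tibble with columns `gene_id` (first word of the header) and
#'   `seq`. An empty file yields an empty tibble with a warning.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(tibble::tibble(gene_id = character(), seq = character()))
  }
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids in ", path, ": ",
         paste(utils::head(unique(ids[duplicated(ids)]), 3), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(gene_id = ids, seq = unname(as.character(x)))
}

#' Write sequences to a FASTA file
#'
#' @param x Tibble with `gene_id` and a sequence column (`seq`, `cds` or
#'   `protein`).
#' @param path Output path.
#' @param seq_col Which column holds the sequence (default the first of
#'   `seq`, `cds`, `protein` present).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, seq_col = NULL) {
  if (is.null(seq_col)) {
    seq_col <- intersect(c("seq", "cds", "protein"), names(x))[1]
  }
  stopifnot(!is.na(seq_col), "gene_id" %in% names(x))
  if (anyDuplicated(x$gene_id)) stop("duplicate gene ids", call. = FALSE)
  s <- Biostrings::BStringSet(stats::setNames(x[[seq_col]], x$gene_id))
  Biostrings::writeXStringSet(s, path, width = 70)
  invisible(path)
}

#' Read a gene catalog from FASTA plus an annotation table
#'
#' @param nt_path Nucleotide FASTA of the CDS sequences.
#' @param aa_path Optional protein FASTA (ids must match); translated from
#'   the CDS when absent.
#' @param annotation_path Optional TSV with `gene_id` and annotation
#'   columns (`domain_label`, `ko_label`, `is_single_copy_cog`).
#' @return A gene tibble ready for [gene_properties()].
#' @export
read_gene_catalog <- function(nt_path, aa_path = NULL, annotation_path = NULL) {
  nt <- dplyr::rename(read_fasta(nt_path), cds = "seq")
  if (!is.null(aa_path)) {
    aa <- dplyr::rename(read_fasta(aa_path), protein = "seq")
    if (!setequal(nt$gene_id, aa$gene_id)) {
      stop("nucleotide and protein FASTA ids do not match", call. = FALSE)
    }
    nt <- dplyr::inner_join(nt, aa, by = "gene_id")
  }
  if (!is.null(annotation_path)) {
    ann <- readr::read_tsv(annotation_path, show_col_types = FALSE, na = "NA")
    stopifnot("gene_id" %in% names(ann))
    nt <- dplyr::left_join(nt, ann, by = "gene_id")
  }
  nt
}

#' Write a result table as TSV
#'
#' Tab-separated, UTF-8, `.` decimal separator, `NA` for undefined values
#' (e.g. side-chain N:C of poly-glycine genes).
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(x, path, na = "NA")
  invisible(path)
}

#' Run the full stoichiogenomic pipeline on a synthetic or supplied
#' community
#'
#' Chains every stage — per-gene properties, coverage weighting, sample
#' profiles, genome-size estimation, conditioned ordination with
#' permutational variance partitioning, depth mixed models with
#' likelihood-ratio tests, marker amino-acid driver models, and baseline
#' log-ratio functional enrichment — writing one TSV per stage plus a
#' JSON run log to `outdir`. All randomness flows from `config$seed`, so
#' two runs with the same configuration are byte-identical.
#'
#' @param config Either a [community_config()] (a community is simulated)
#'   or a list with elements `community` (a `stoich_community`) and/or
#'   overrides `n_perm`, `q`, `seed`, `stages`. A path to a YAML file with
#'   `community_config` fields is also accepted.
#' @param outdir Output directory (created if needed).
#' @param stages Character vector of stages to run; default all of
#'   `properties`, `profiles`, `ags`, `ordination`, `lmm`, `drivers`,
#'   `enrichment`.
#' @param n_perm Permutations for the variance partitioning (default 999).
#' @param q FDR level for enrichment (default 0.10).
#' @return Invisibly, a named list of the per-stage result objects.
#' @export
run_pipeline <- function(config = community_config(), outdir,
                         stages = c("properties", "profiles", "ags",
                                    "ordination", "lmm", "drivers",
                                    "enrichment"),
                         n_perm = 999, q = 0.10) {
  if (is.character(config) && length(config) == 1) {
    config <- do.call(community_config, yaml::read_yaml(config))
  }
  if (inherits(config, "community_config")) {
    community <- simulate_community(config)
  } else if (inherits(config, "stoich_community")) {
    community <- config
  } else stop("config must be a community_config, a stoich_community, ",
              "or a YAML path", call. = FALSE)
  seed <- community$config$seed
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  md <- community$metadata
  props <- community$properties

  if ("properties" %in% stages) {
    write_table(props, file.path(outdir, "gene_properties.tsv"))
    out$properties <- props
  }
  profiles <- step("profiles",
    sample_profiles(community$coverage, props))
  if ("profiles" %in% stages) {
    write_table(profiles, file.path(outdir, "sample_profiles.tsv"))
    out$profiles <- profiles
  }
  if ("ags" %in% stages) {
    ags <- step("ags", genome_size(community$coverage,
                                   community$single_copy_ids,
                                   props[, c("gene_id", "nt_length")]))
    write_table(ags, file.path(outdir, "genome_size.tsv"))
    out$genome_size <- ags
  }
  if ("ordination" %in% stages) {
    out$ordination <- step("ordination", {
      purrr::map(split(profiles, profiles$domain_label), function(pr) {
        d <- dplyr::inner_join(pr, md, by = "sample_id")
        ord <- ordinate_profiles(
          d, condition = "total_reads",
          properties = setdiff(names(pr)[vapply(pr, is.numeric, logical(1))],
                               "total_reads"))
        vp <- dplyr::bind_rows(
          permanova_r2(ord$scores[-1], d$fraction, n_perm = n_perm,
                       seed = seed, name = "fraction"),
          permanova_r2(ord$scores[-1], asinh(d$depth), n_perm = n_perm,
                       seed = seed + 1L, name = "asinh_depth"))
        list(ordination = ord, variance_partition = vp)
      })
    })
    scores <- purrr::imap_dfr(out$ordination, function(o, d)
      dplyr::mutate(o$ordination$scores[, 1:3], domain_label = d))
    write_table(scores, file.path(outdir, "ordination_scores.tsv"))
    write_table(
      purrr::imap_dfr(out$ordination, function(o, d)
        dplyr::mutate(o$variance_partition, domain_label = d)),
      file.path(outdir, "variance_partition.tsv"))
  }
  if ("lmm" %in% stages) {
    out$lmm <- step("lmm", {
      purrr::map_dfr(unique(profiles$domain_label), function(dom) {
        pr <- dplyr::inner_join(
          dplyr::filter(profiles, .data$domain_label == dom), md,
          by = "sample_id")
        purrr::map_dfr(c("gc", "n_arsc", "nc_ratio"), function(resp) {
          full <- fit_depth_lmm(pr, resp)
          null <- fit_fixed_only(pr, resp)
          lrt <- likelihood_ratio_test(full, null)
          sp <- blup_depth_correlation(full)
          dplyr::mutate(tidy(full), response = resp, domain_label = dom,
                        aic = full$aic, loglik = full$loglik,
                        lrt_p = lrt$p_value, delta_aic = lrt$delta_aic,
                        blup_spearman = sp$rho_spearman)
        })
      })
    })
    write_table(out$lmm, file.path(outdir, "lmm_fits.tsv"))
  }
  if ("drivers" %in% stages) {
    out$drivers <- step("drivers", {
      purrr::imap(community$marker_ids, function(ids, mk) {
        cov_mk <- dplyr::filter(community$coverage, .data$gene_id %in% ids)
        aa_cols <- paste0("aa_", .aa_codes)
        prof <- marker_weighted_profile(
          cov_mk, props[, c("gene_id", aa_cols)])
        vals <- marker_weighted_profile(
          cov_mk, props[, c("gene_id", "n_arsc", "nc_ratio")])
        data <- prof |>
          dplyr::inner_join(vals, by = "sample_id") |>
          dplyr::inner_join(md[, c("sample_id", "fraction")], by = "sample_id")
        fit <- fit_aa_drivers(data, seed = seed)
        list(fit = fit, ranking = rank_drivers(fit$model))
      })
    })
    write_table(
      purrr::imap_dfr(out$drivers, function(d, mk)
        dplyr::mutate(tidy(d$fit$model), marker = mk)),
      file.path(outdir, "driver_coefficients.tsv"))
    write_table(
      purrr::imap_dfr(out$drivers, function(d, mk)
        dplyr::mutate(d$fit$evaluation, marker = mk)),
      file.path(outdir, "driver_evaluation.tsv"))
  }
  if ("enrichment" %in% stages) {
    out$enrichment <- step("enrichment", {
      ko_cov <- community$coverage |>
        dplyr::left_join(props[, c("gene_id", "ko_label")], by = "gene_id") |>
        dplyr::filter(.data$ko_label != "") |>
        dplyr::group_by(.data$sample_id, ko = .data$ko_label) |>
        dplyr::summarise(coverage = sum(.data$coverage), .groups = "drop")
      lr <- build_logratios(ko_cov, baseline_id = "sdhC")
      ko_enrichment(lr, md, q = q)
    })
    write_table(out$enrichment, file.path(outdir, "enrichment.tsv"))
  }
  log <- list(
    package_version = as.character(utils::packageVersion("stoichiomics")),
    seed = seed, n_perm = n_perm, q = q, stages = stages,
    n_genes = nrow(community$catalog), n_samples = nrow(md),
    config = unclass(community$config))
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
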