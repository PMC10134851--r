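#' Alignment identity
#'
#' Identity of an alignment computed as `1 - mismatches / alignment_length`.
#'
#' @param mismatches Integer vector of mismatch counts.
#' @param alignment_length Integer vector of alignment lengths (bp), > 0.
#' @return Numeric vector of identities.
#' @export
#' @examples
#' alignment_identity(5, 100)
alignment_identity <- function(mismatches, alignment_length) {
  if (any(alignment_length <= 0)) stop("alignment_length must be > 0", call. = FALSE)
  if (any(mismatches < 0 | mismatches > alignment_length)) {
    stop("mismatches must lie in [0, alignment_length]", call. = FALSE)
  }
  1 - mismatches / alignment_length
}

#' Filter alignment records for coverage computation
#'
#' Keeps alignments with identity of at least 95% (inclusive) and an
#' alignment length strictly greater than 60 bp, the standard filter for
#' competitive mapping against a gene catalog.
#'
#' @param alignments Data frame with columns `sample_id`, `gene_id`,
#'   `alignment_length`, `mismatches`, `mapped_bases`.
#' @param min_identity Identity threshold (inclusive). Default 0.95.
#' @param min_length Alignment length threshold (exclusive). Default 60.
#' @return The filtered tibble (possibly zero rows).
#' @export
filter_alignments <- function(alignments, min_identity = 0.95, min_length = 60) {
  stopifnot(is.data.frame(alignments),
            all(c("alignment_length", "mismatches") %in% names(alignments)))
  alignments <- tibble::as_tibble(alignments)
  id <- alignment_identity(alignments$mismatches, alignments$alignment_length)
  alignments[id >= min_identity & alignments$alignment_length > min_length, ]
}

#' Per-gene coverage from filtered alignments
#'
#' Coverage of a gene in a sample is the total number of base pairs mapped
#' to it divided by the gene length (mean per-base depth).
#'
#' @param alignments Filtered alignment tibble (see [filter_alignments()])
#'   with columns `sample_id`, `gene_id`, `mapped_bases`.
#' @param gene_lengths Data frame with `gene_id` and `nt_length` (bp), or a
#'   named numeric vector of lengths. Defines the full gene universe:
#'   genes without alignments get coverage 0.
#' @return A tibble `sample_id`, `gene_id`, `coverage` covering the full
#'   sample-by-gene grid.
#' @export
gene_coverage <- function(alignments, gene_lengths) {
  len <- .as_length_vector(gene_lengths)
  stopifnot(all(c("sample_id", "gene_id", "mapped_bases") %in% names(alignments)))
  unknown <- setdiff(unique(alignments$gene_id), names(len))
  if (length(unknown) > 0) {
    stop("alignments reference unknown gene(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  samples <- unique(alignments$sample_id)
  alignments |>
    dplyr::group_by(.data$sample_id, .data$gene_id) |>
    dplyr::summarise(coverage = sum(.data$mapped_bases), .groups = "drop") |>
    tidyr::complete(sample_id = samples, gene_id = names(len),
                    fill = list(coverage = 0)) |>
    dplyr::mutate(coverage = unname(.data$coverage / len[.data$gene_id])) |>
    dplyr::arrange(.data$sample_id, .data$gene_id)
}

.as_length_vector <- function(gene_lengths) {
  if (is.data.frame(gene_lengths)) {
    stopifnot(all(c("gene_id", "nt_length") %in% names(gene_lengths)))
    len <- stats::setNames(gene_lengths$nt_length, gene_lengths$gene_id)
  } else {
    stopifnot(is.numeric(gene_lengths), !is.null(names(gene_lengths)))
    len <- gene_lengths
  }
  if (any(len <= 0)) stop("gene lengths must be positive", call. = FALSE)
  if (anyDuplicated(names(len))) stop("duplicate gene ids in lengths", call. = FALSE)
  len
}

#' Per-gene copy numbers normalized to single-copy marker genes
#'
#' Divides each gene's coverage by the arithmetic mean coverage of the
#' single-copy marker genes (the 10 single-copy COGs) within the same
#' sample, yielding an average per-genome copy number. Zeros among the
#' marker coverages are included in the mean as long as at least one marker
#' has positive coverage.
#'
#' @param coverage Long coverage tibble (`sample_id`, `gene_id`,
#'   `coverage`) as produced by [gene_coverage()]; must contain a row for
#'   every single-copy marker in every sample.
#' @param single_copy_ids Character vector of marker gene ids.
#' @return The coverage tibble with an added `copy_number` column.
#' @export
copy_numbers <- function(coverage, single_copy_ids) {
  stopifnot(length(single_copy_ids) >= 1)
  missing_sc <- setdiff(single_copy_ids, unique(coverage$gene_id))
  if (length(missing_sc) > 0) {
    stop("single-copy marker(s) absent from coverage table: ",
         paste(missing_sc, collapse = ", "), call. = FALSE)
  }
  out <- coverage |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(
      .sc_mean = mean(.data$coverage[.data$gene_id %in% single_copy_ids])
    ) |>
    dplyr::ungroup()
  if (any(out$.sc_mean <= 0)) {
    bad <- unique(out$sample_id[out$.sc_mean <= 0])
    stop("all single-copy marker coverages are zero in sample(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  out |>
    dplyr::mutate(copy_number = .data$coverage / .data$.sc_mean) |>
    dplyr::select(-".sc_mean")
}

#' Average number of genes per genome
#'
#' Sum of per-gene copy numbers per sample.
#'
#' @param cn Tibble with `sample_id` and `copy_number` (see
#'   [copy_numbers()]).
#' @return A tibble `sample_id`, `genes_per_genome`.
#' @export
genes_per_genome <- function(cn) {
  cn |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(genes_per_genome = sum(.data$copy_number), .groups = "drop")
}

#' Average genome length from gene copy numbers
#'
#' Sum over genes of copy number times gene length. Counts cataloged gene
#' lengths only, so it is a lower bound that ignores intergenic DNA.
#'
#' @param cn Tibble with `sample_id`, `gene_id`, `copy_number`.
#' @param gene_lengths As in [gene_coverage()].
#' @return A tibble `sample_id`, `genome_length` (bp).
#' @export
average_genome_length <- function(cn, gene_lengths) {
  len <- .as_length_vector(gene_lengths)
  cn |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      genome_length = unname(sum(.data$copy_number * len[.data$gene_id])),
      .groups = "drop")
}

#' Genome size summary per sample
#'
#' Convenience wrapper chaining [copy_numbers()], [genes_per_genome()] and
#' [average_genome_length()].
#'
#' @inheritParams copy_numbers
#' @inheritParams average_genome_length
#' @return A tibble `sample_id`, `genes_per_genome`, `genome_length`.
#' @export
genome_size <- function(coverage, single_copy_ids, gene_lengths) {
  cn <- copy_numbers(coverage, single_copy_ids)
  dplyr::left_join(genes_per_genome(cn),
                   average_genome_length(cn, gene_lengths),
                   by = "sample_id")
}

#' Weighted gene coverages within a sample
#'
#' Divides each gene's coverage by the summed coverage of all genes in that
#' sample, removing differences in sequencing depth; the weights sum to 1
#' per sample.
#'
#' @param coverage Long coverage tibble (`sample_id`, `gene_id`, `coverage`).
#' @return The tibble with an added `weight` column.
#' @export
weighted_coverages <- function(coverage) {
  out <- coverage |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(.total = sum(.data$coverage)) |>
    dplyr::ungroup()
  if (any(out$.total <= 0)) {
    bad <- unique(out$sample_id[out$.total <= 0])
    stop("sample(s) with zero total coverage: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  out |>
    dplyr::mutate(weight = .data$coverage / .data$.total) |>
    dplyr::select(-".total")
}

#' Coverage-weighted stoichiogenomic sample profiles
#'
#' Multiplies each gene's properties by its weighted coverage and sums,
#' producing one gene-property profile per sample and taxonomic domain.
#' Weights are renormalized within each domain so that a profile is a
#' convex combination of the properties of that domain's genes; genes with
#' an undefined side-chain N:C ratio are excluded (weights renormalized)
#' from the `nc_ratio` average only. Genes labeled `"other"` are dropped.
#'
#' @param coverage Long coverage tibble (`sample_id`, `gene_id`,
#'   `coverage`).
#' @param properties Per-gene property tibble from [gene_properties()];
#'   must include `domain_label` unless `by_domain = FALSE`.
#' @param by_domain Compute one profile per sample and domain (default).
#' @return A tibble keyed by `sample_id` (and `domain_label`), with the
#'   coverage-weighted mean of every numeric property.
#' @export
sample_profiles <- function(coverage, properties, by_domain = TRUE) {
  stopifnot(all(c("sample_id", "gene_id", "coverage") %in% names(coverage)))
  prop_cols <- setdiff(names(properties)[vapply(properties, is.numeric, logical(1))],
                       "nt_length")
  joined <- dplyr::inner_join(coverage, properties, by = "gene_id")
  if (by_domain) {
    if (!"domain_label" %in% names(properties)) {
      stop("properties must carry domain_label when by_domain = TRUE", call. = FALSE)
    }
    joined <- dplyr::filter(joined, .data$domain_label != "other")
    grp <- dplyr::group_by(joined, .data$sample_id, .data$domain_label)
  } else {
    grp <- dplyr::group_by(joined, .data$sample_id)
  }
  out <- grp |>
    dplyr::summarise(
      .total = sum(.data$coverage),
      dplyr::across(dplyr::all_of(setdiff(prop_cols, "nc_ratio")),
                    ~ sum(.x * coverage) / sum(coverage)),
      nc_ratio = {
        ok <- !is.na(.data$nc_ratio)
        if (any(ok & .data$coverage > 0)) {
          sum(.data$nc_ratio[ok] * .data$coverage[ok]) / sum(.data$coverage[ok])
        } else NA_real_
      },
      .groups = "drop"
    )
  if (any(out$.total <= 0)) {
    stop("sample/domain group with zero total coverage; cannot form profile",
         call. = FALSE)
  }
  out <- dplyr::select(out, -".total")
  if ("c_arsc" %in% names(out)) {
    out <- dplyr::relocate(out, "nc_ratio", .after = "c_arsc")
  }
  out
}

#' Coverage-weighted marker-gene profile per sample
#'
#' Weighted average of per-cluster values of a marker gene family (e.g.
#' the amino-acid frequency vectors or N:C ratios of rpoZ / ftsZ / Gp23
#' gene clusters), using each cluster's coverage in the sample as weight.
#' Samples where the marker is absent (zero total coverage) are returned
#' with `NA` values and flagged with a warning.
#'
#' @param coverage Long tibble (`sample_id`, `gene_id`, `coverage`)
#'   restricted to the marker's gene clusters.
#' @param cluster_values Tibble with `gene_id` and one or more numeric
#'   columns (a 20-column amino-acid frequency table, a scalar `nc_ratio`,
#'   ...).
#' @return A tibble with one row per sample and the coverage-weighted mean
#'   of each numeric column.
#' @export
marker_weighted_profile <- function(coverage, cluster_values) {
  val_cols <- names(cluster_values)[vapply(cluster_values, is.numeric, logical(1))]
  stopifnot(length(val_cols) >= 1, "gene_id" %in% names(cluster_values))
  joined <- dplyr::inner_join(coverage, cluster_values, by = "gene_id")
  out <- joined |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      .total = sum(.data$coverage),
      dplyr::across(dplyr::all_of(val_cols),
                    ~ if (sum(coverage) > 0) sum(.x * coverage) / sum(coverage)
                      else NA_real_),
      .groups = "drop")
  if (any(out$.total <= 0)) {
    warning("marker absent (zero coverage) in ", sum(out$.total <= 0),
            " sample(s); profile set to NA", call. = FALSE)
  }
  dplyr::select(out, -".total")
}
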