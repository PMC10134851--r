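#' Log-ratios of orthologue coverages to a baseline gene
#'
#' Compositional log-ratio transform for functional comparison: each KEGG
#' orthologue's summed coverage is divided by the coverage of a baseline
#' orthologue in the same sample (default `sdhC`, a ubiquitous
#' TCA-cycle component) and the natural log is taken. Only orthologues
#' with positive coverage in every sample are retained, so all entries are
#' finite; per-sample total-coverage scaling cancels exactly.
#'
#' @param ko_coverage Long tibble `sample_id`, `ko`, `coverage` (one row
#'   per sample and orthologue).
#' @param baseline_id Orthologue used as the denominator (default
#'   `"sdhC"`); must have positive coverage in every sample.
#' @return A tibble `sample_id`, `ko`, `log_ratio` excluding the baseline
#'   itself, with attributes `baseline_id` and `n_orthologues`.
#' @export
build_logratios <- function(ko_coverage, baseline_id = "sdhC") {
  stopifnot(all(c("sample_id", "ko", "coverage") %in% names(ko_coverage)))
  base <- dplyr::filter(ko_coverage, .data$ko == baseline_id)
  if (nrow(base) == 0) stop("baseline orthologue not found: ", baseline_id,
                            call. = FALSE)
  zero_base <- base$sample_id[base$coverage <= 0]
  if (length(zero_base) > 0) {
    stop("baseline '", baseline_id, "' has zero coverage in sample(s): ",
         paste(utils::head(zero_base, 5), collapse = ", "), call. = FALSE)
  }
  n_samples <- dplyr::n_distinct(ko_coverage$sample_id)
  keep <- ko_coverage |>
    dplyr::group_by(.data$ko) |>
    dplyr::summarise(ok = dplyr::n() == n_samples && all(.data$coverage > 0),
                     .groups = "drop") |>
    dplyr::filter(.data$ok, .data$ko != baseline_id)
  out <- ko_coverage |>
    dplyr::filter(.data$ko %in% keep$ko) |>
    dplyr::left_join(dplyr::select(base, "sample_id", base_cov = "coverage"),
                     by = "sample_id") |>
    dplyr::mutate(log_ratio = log(.data$coverage / .data$base_cov)) |>
    dplyr::select("sample_id", "ko", "log_ratio")
  attr(out, "baseline_id") <- baseline_id
  attr(out, "n_orthologues") <- nrow(keep)
  out
}

#' Per-orthologue linear models of log-ratio abundance
#'
#' For each orthologue, regresses the log-ratio on size fraction, depth
#' and their interaction, and pools the p-values of those three
#' parameters across all orthologues for Benjamini-Hochberg control at
#' rate `q` (default 10%). Depth enters untransformed here.
#'
#' @param logratios Output of [build_logratios()].
#' @param metadata Tibble with `sample_id`, `fraction` (0/1) and `depth`.
#' @param q Target false discovery rate (default 0.10).
#' @return A tibble with one row per orthologue and parameter: `ko`,
#'   `term` (fraction, depth, fraction:depth), `estimate`, `p_value`,
#'   `significant` (BH at rate `q` over the pooled p-values).
#' @export
ko_enrichment <- function(logratios, metadata, q = 0.10) {
  stopifnot(all(c("sample_id", "fraction", "depth") %in% names(metadata)),
            q > 0, q < 1)
  df <- dplyr::inner_join(logratios, metadata, by = "sample_id")
  n_per <- dplyr::count(df, .data$ko)
  if (any(n_per$n <= 4)) stop("need more than 4 samples per orthologue",
                              call. = FALSE)
  if (dplyr::n_distinct(df$fraction) < 2) {
    stop("only one size fraction present; fraction effect inestimable",
         call. = FALSE)
  }
  res <- df |>
    dplyr::group_by(.data$ko) |>
    dplyr::group_modify(~ {
      fit <- stats::lm(log_ratio ~ fraction * depth, data = .x)
      sm <- summary(fit)$coefficients
      terms <- c("fraction", "depth", "fraction:depth")
      tibble::tibble(term = terms,
                     estimate = unname(sm[terms, "Estimate"]),
                     p_value = unname(sm[terms, "Pr(>|t|)"]))
    }) |>
    dplyr::ungroup()
  res$significant <- bh_fdr(res$p_value, q = q)
  res
}

#' Benjamini-Hochberg rejection flags
#'
#' Step-up FDR control: flags the p-values rejected at rate `q`.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param q Target false discovery rate (default 0.10).
#' @return Logical vector of rejection flags, same length as `pvals`.
#' @export
#' @examples
#' bh_fdr(c(0.001, 0.02, 0.04, 0.9), q = 0.1)
bh_fdr <- function(pvals, q = 0.10) {
  stopifnot(q > 0, q < 1)
  if (length(pvals) == 0) return(logical(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH") <= q
}
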