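# Independent reference data and brute-force oracles used across tests.

# Molecular formulas (heavy atoms) of the 20 free amino acids, from the
# standard chemical formulas; the side chain is the free amino acid minus
# the glycine-like backbone (2 C, 1 N, no S).
free_aa_formula <- tibble::tribble(
  ~residue, ~C, ~N, ~S,
  "A", 3L, 1L, 0L,
  "R", 6L, 4L, 0L,
  "N", 4L, 2L, 0L,
  "D", 4L, 1L, 0L,
  "C", 3L, 1L, 1L,
  "E", 5L, 1L, 0L,
  "Q", 5L, 2L, 0L,
  "G", 2L, 1L, 0L,
  "H", 6L, 3L, 0L,
  "I", 6L, 1L, 0L,
  "L", 6L, 1L, 0L,
  "K", 6L, 2L, 0L,
  "M", 5L, 1L, 1L,
  "F", 9L, 1L, 0L,
  "P", 5L, 1L, 0L,
  "S", 3L, 1L, 0L,
  "T", 4L, 1L, 0L,
  "V", 5L, 1L, 0L,
  "W", 11L, 2L, 0L,
  "Y", 9L, 1L, 0L
)

aa_codes20 <- free_aa_formula$residue

# brute-force per-residue atom counting from the free-amino-acid formulas
brute_force_arsc <- function(protein) {
  res <- strsplit(protein, "")[[1]]
  f <- free_aa_formula[match(res, free_aa_formula$residue), ]
  list(n_sum = sum(f$N - 1L), c_sum = sum(f$C - 2L), len = length(res))
}

random_protein <- function(len) {
  paste(sample(aa_codes20, len, replace = TRUE), collapse = "")
}

# small deterministic catalog for coverage tests
tiny_catalog <- function() {
  tibble::tibble(
    gene_id = c("sc1", "sc2", "gA", "gB", "gPolyG"),
    cds = c("ATGAAACGTCGT", "ATGCATCATAAA", "ATGCGTCGTCGT",
            "ATGGCAGCTGCC", "GGAGGTGGAGGC"),
    domain_label = c("bacteria", "bacteria", "bacteria", "bacteria",
                     "bacteria"),
    ko_label = c("", "", "K00001", "K00002", ""),
    is_single_copy_cog = c(TRUE, TRUE, FALSE, FALSE, FALSE)
  )
}

# two-sample coverage table over the tiny catalog
tiny_coverage <- function() {
  tidyr::expand_grid(sample_id = c("s1", "s2"),
                     gene_id = tiny_catalog()$gene_id) |>
    dplyr::mutate(coverage = c(10, 10, 20, 5, 5,
                               4, 8, 6, 6, 0))
}
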