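#' Amino-acid residue atom table
#'
#' Heavy-atom composition of the side chain of each of the 20 standard
#' amino acids (the residue minus the N--C-alpha--C(=O) backbone, hydrogens
#' excluded), together with the average isotopic mass of the free amino
#' acid in Daltons. This table defines N-ARSC, C-ARSC and the side-chain
#' N:C ratio: arginine is the only residue contributing three side-chain
#' nitrogen atoms, histidine contributes two, and methionine none.
#'
#' @return A tibble with 20 rows and columns `residue` (one-letter code),
#'   `name`, `side_chain_c`, `side_chain_n`, `side_chain_s` (integer heavy
#'   atom counts) and `free_aa_mass` (Da).
#' @export
#' @examples
#' residue_atoms()
residue_atoms <- function() {
  tibble::tibble(
    residue      = .aa_codes,
    name         = .aa_names,
    side_chain_c = unname(.side_c[.aa_codes]),
    side_chain_n = unname(.side_n[.aa_codes]),
    side_chain_s = unname(.side_s[.aa_codes]),
    free_aa_mass = unname(.aa_mass[.aa_codes])
  )
}

.aa_codes <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.aa_names <- c("alanine", "cysteine", "aspartate", "glutamate",
               "phenylalanine", "glycine", "histidine", "isoleucine",
               "lysine", "leucine", "methionine", "asparagine", "proline",
               "glutamine", "arginine", "serine", "threonine", "valine",
               "tryptophan", "tyrosine")

.side_c <- c(A = 1L, C = 1L, D = 2L, E = 3L, F = 7L, G = 0L, H = 4L,
             I = 4L, K = 4L, L = 4L, M = 3L, N = 2L, P = 3L, Q = 3L,
             R = 4L, S = 1L, T = 2L, V = 3L, W = 9L, Y = 7L)

.side_n <- c(A = 0L, C = 0L, D = 0L, E = 0L, F = 0L, G = 0L, H = 2L,
             I = 0L, K = 1L, L = 0L, M = 0L, N = 1L, P = 0L, Q = 1L,
             R = 3L, S = 0L, T = 0L, V = 0L, W = 1L, Y = 0L)

.side_s <- c(A = 0L, C = 1L, D = 0L, E = 0L, F = 0L, G = 0L, H = 0L,
             I = 0L, K = 0L, L = 0L, M = 1L, N = 0L, P = 0L, Q = 0L,
             R = 0L, S = 0L, T = 0L, V = 0L, W = 0L, Y = 0L)

# average isotopic masses of the free amino acids, Da
.aa_mass <- c(A = 89.09, C = 121.16, D = 133.10, E = 147.13, F = 165.19,
              G = 75.07, H = 155.15, I = 131.17, K = 146.19, L = 131.17,
              M = 149.21, N = 132.12, P = 115.13, Q = 146.15, R = 174.20,
              S = 105.09, T = 119.12, V = 117.15, W = 204.23, Y = 181.19)

# genetic code (translation table 11; sense-codon assignments as standard)
.genetic_code <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  # outer nesting above gives first base fastest; rebuild in canonical order
  codons <- paste0(rep(b, each = 16), rep(rep(b, each = 4), 4), rep(b, 16))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
})

# synonymous family sizes per amino acid under table 11 (61 sense codons)
.codon_family_size <- local({
  aa <- .genetic_code[.genetic_code != "*"]
  tab <- table(aa)
  stats::setNames(as.integer(tab), names(tab))
})

.iupac_nt <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

.check_nt <- function(seq, arg = "seq") {
  seq <- toupper(seq)
  bad <- stringr::str_detect(seq, paste0("[^", paste(.iupac_nt, collapse = ""), "]"))
  if (any(bad, na.rm = TRUE)) {
    stop(sprintf("invalid nucleotide characters in %s (IUPAC DNA codes only)", arg),
         call. = FALSE)
  }
  seq
}

.aa_count_matrix <- function(protein, arg = "protein") {
  protein <- toupper(protein)
  m <- vapply(.aa_codes,
              function(a) stringr::str_count(protein, stringr::fixed(a)),
              numeric(length(protein)))
  if (length(protein) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, .aa_codes))
  n <- nchar(protein)
  if (any(n == 0L)) stop(sprintf("empty %s sequence", arg), call. = FALSE)
  if (any(rowSums(m) != n)) {
    stop(sprintf("%s contains characters outside the 20 standard amino-acid codes", arg),
         call. = FALSE)
  }
  m
}

#' GC content of a nucleotide sequence
#'
#' Fraction of unambiguous bases that are G or C. IUPAC ambiguity codes are
#' excluded from both the numerator and the denominator, so a run of `N`s
#' does not bias the estimate.
#'
#' @param seq Character vector of nucleotide sequences (case-insensitive,
#'   IUPAC DNA alphabet).
#' @return Numeric vector of GC fractions in `[0, 1]`.
#' @export
#' @examples
#' gc_content(c("ATGC", "GGCC", "ATATNNGC"))
gc_content <- function(seq) {
  seq <- .check_nt(seq)
  gc <- stringr::str_count(seq, "[GC]")
  acgt <- stringr::str_count(seq, "[ACGT]")
  if (any(acgt == 0L)) {
    stop("sequence empty or all-ambiguous: GC content undefined", call. = FALSE)
  }
  gc / acgt
}

#' Translate a coding sequence (translation table 11)
#'
#' Translates an in-frame bacterial/archaeal CDS to protein, dropping a
#' terminal stop codon if present. Internal stop codons, ambiguous codons
#' and lengths not divisible by three are errors: the gene catalog is
#' assumed to hold complete, unambiguous genes.
#'
#' @param cds Character vector of coding sequences.
#' @return Character vector of protein sequences.
#' @export
#' @examples
#' translate_cds("ATGAAA")
#' translate_cds("ATGTAA")
translate_cds <- function(cds) {
  cds <- .check_nt(cds, "cds")
  cds <- chartr("U", "T", cds)
  vapply(cds, function(s) {
    if (nchar(s) %% 3 != 0 || nchar(s) == 0) {
      stop("CDS length must be a positive multiple of 3", call. = FALSE)
    }
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    aa <- .genetic_code[codons]
    if (anyNA(aa)) stop("ambiguous codon cannot be translated", call. = FALSE)
    n <- length(aa)
    if (aa[n] == "*") aa <- aa[-n]
    if (any(aa == "*")) stop("internal stop codon in CDS", call. = FALSE)
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Side-chain heavy-atom counts for amino-acid residues
#'
#' @param residue Character vector of one-letter amino-acid codes.
#' @return A tibble with columns `residue`, `side_chain_c`, `side_chain_n`,
#'   `side_chain_s`.
#' @export
#' @examples
#' side_chain_atoms(c("R", "H", "M", "G"))
side_chain_atoms <- function(residue) {
  residue <- toupper(residue)
  if (!all(residue %in% .aa_codes)) {
    stop("residue must be one of the 20 standard one-letter codes", call. = FALSE)
  }
  tibble::tibble(
    residue = residue,
    side_chain_c = unname(.side_c[residue]),
    side_chain_n = unname(.side_n[residue]),
    side_chain_s = unname(.side_s[residue])
  )
}

#' Nitrogen atoms per residue side chain (N-ARSC)
#'
#' Mean number of nitrogen atoms in amino-acid residue side chains over all
#' residues of a protein. Ranges from 0 (e.g. poly-glycine) to 3
#' (poly-arginine).
#'
#' @param protein Character vector of protein sequences (standard 20 codes).
#' @return Numeric vector.
#' @export
#' @examples
#' n_arsc(c("RRRR", "GGGG", "RK"))
n_arsc <- function(protein) {
  m <- .aa_count_matrix(protein)
  as.vector(m %*% .side_n[.aa_codes]) / rowSums(m)
}

#' Carbon atoms per residue side chain (C-ARSC)
#'
#' @inheritParams n_arsc
#' @return Numeric vector.
#' @export
#' @examples
#' c_arsc(c("AAAA", "FW"))
c_arsc <- function(protein) {
  m <- .aa_count_matrix(protein)
  as.vector(m %*% .side_c[.aa_codes]) / rowSums(m)
}

#' Aggregate side-chain N:C ratio of a protein
#'
#' Total side-chain nitrogen atoms divided by total side-chain carbon atoms
#' over all residues (an aggregate ratio, not the mean of per-residue
#' ratios, which would be undefined for glycine). Proteins with zero
#' side-chain carbon return `NA` with a warning and are excluded from
#' coverage-weighted averages downstream.
#'
#' @inheritParams n_arsc
#' @return Numeric vector; `NA` where the ratio is undefined.
#' @export
#' @examples
#' side_chain_nc_ratio(c("R", "A"))
side_chain_nc_ratio <- function(protein) {
  m <- .aa_count_matrix(protein)
  n_tot <- as.vector(m %*% .side_n[.aa_codes])
  c_tot <- as.vector(m %*% .side_c[.aa_codes])
  out <- ifelse(c_tot > 0, n_tot / c_tot, NA_real_)
  if (anyNA(out)) {
    warning("side-chain N:C undefined (zero side-chain carbon) for ",
            sum(is.na(out)), " sequence(s); returning NA", call. = FALSE)
  }
  out
}

#' Amino-acid frequencies of a protein
#'
#' @inheritParams n_arsc
#' @return A tibble with one row per input protein and one column per
#'   amino-acid code (alphabetical); each row sums to 1.
#' @export
#' @examples
#' aa_frequencies("AR")
aa_frequencies <- function(protein) {
  m <- .aa_count_matrix(protein)
  tibble::as_tibble(m / rowSums(m))
}

#' Molecular weight of the summed amino acids of a protein
#'
#' Sum of the average masses of the free amino acids coded by the gene
#' (no water subtraction for peptide bonds).
#'
#' @inheritParams n_arsc
#' @return Numeric vector, Daltons.
#' @export
#' @examples
#' protein_mw("GG")
protein_mw <- function(protein) {
  m <- .aa_count_matrix(protein)
  as.vector(m %*% .aa_mass[.aa_codes])
}

.split_codons <- function(cds) {
  cds <- .check_nt(cds, "cds")[[1]]
  if (nchar(cds) %% 3 != 0 || nchar(cds) == 0) {
    stop("CDS length must be a positive multiple of 3", call. = FALSE)
  }
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- .genetic_code[codons]
  if (anyNA(aa)) stop("ambiguous codon in CDS", call. = FALSE)
  n <- length(aa)
  if (aa[n] == "*") { codons <- codons[-n]; aa <- aa[-n] }
  if (any(aa == "*")) stop("internal stop codon in CDS", call. = FALSE)
  list(codons = codons, aa = unname(aa))
}

#' Codon usage diversity of a gene
#'
#' For each amino acid occurring at least once in the gene, the fraction of
#' its synonymous codons (under translation table 11) actually used; the
#' statistic is the unweighted mean of these fractions. 1 means every
#' encoded amino acid uses its full synonymous repertoire.
#'
#' @param cds Character vector of coding sequences.
#' @return Numeric vector in `(0, 1]`.
#' @export
#' @examples
#' codon_diversity("ATGTGG")   # Met + Trp, single-codon families
#' codon_diversity("CTGCTA")   # Leu via 2 of its 6 codons
codon_diversity <- function(cds) {
  vapply(cds, function(s) {
    cod <- .split_codons(s)
    if (length(cod$aa) == 0) stop("no sense codons in CDS", call. = FALSE)
    per_aa <- tapply(cod$codons, cod$aa, function(x) length(unique(x)))
    mean(per_aa / .codon_family_size[names(per_aa)])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Effective number of codons (ENC) of a gene
#'
#' Wright-style codon-bias statistic on `[20, 61]`: 61 indicates uniform
#' synonymous codon usage, 20 maximal bias (a single codon per family).
#' Family homozygosity is estimated as `F = (n * sum(p^2) - 1) / (n - 1)`
#' per amino acid; families observed fewer than twice are skipped. The
#' threefold (isoleucine) class falls back to the mean of the two- and
#' fourfold estimates when missing; if a whole two-, four- or sixfold class
#' cannot be estimated the statistic is undefined and `NA` is returned.
#'
#' @param cds Character vector of coding sequences.
#' @return Numeric vector; `NA` where too few codons are available.
#' @export
effective_number_of_codons <- function(cds) {
  vapply(cds, function(s) {
    cod <- .split_codons(s)
    fam <- split(cod$codons, cod$aa)
    f_hat <- vapply(fam, function(x) {
      n <- length(x)
      if (n < 2) return(NA_real_)
      p <- as.vector(table(x)) / n
      (n * sum(p^2) - 1) / (n - 1)
    }, numeric(1))
    size <- .codon_family_size[names(f_hat)]
    cls_mean <- function(k) {
      v <- f_hat[size == k & !is.na(f_hat) & f_hat > 0]
      if (length(v) == 0) NA_real_ else mean(v)
    }
    f2 <- cls_mean(2); f3 <- cls_mean(3); f4 <- cls_mean(4); f6 <- cls_mean(6)
    if (is.na(f3)) f3 <- mean(c(f2, f4), na.rm = TRUE)
    if (is.na(f2) || is.na(f4) || is.na(f6) || is.nan(f3)) return(NA_real_)
    enc <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
    min(max(enc, 20), 61)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Per-gene stoichiogenomic properties
#'
#' Computes the full per-gene metric vector for a gene catalog: nucleotide
#' length, GC content, N-ARSC, C-ARSC, aggregate side-chain N:C ratio,
#' summed amino-acid molecular weight, codon diversity, effective number of
#' codons, and the 20 amino-acid frequencies. Proteins are translated from
#' the CDS (table 11) when not supplied.
#'
#' @param genes A data frame with columns `gene_id`, `cds`, and optionally
#'   `protein` plus annotation columns (`domain_label`, `ko_label`,
#'   `is_single_copy_cog`), which are carried through.
#' @return A tibble, one row per gene: `gene_id`, annotations, `nt_length`,
#'   `gc`, `n_arsc`, `c_arsc`, `nc_ratio` (`NA` when undefined), `mw`,
#'   `codon_diversity`, `codon_bias_enc`, and `aa_A` ... `aa_Y`.
#' @export
#' @examples
#' gene_properties(data.frame(gene_id = "g1", cds = "ATGAAA"))
gene_properties <- function(genes) {
  stopifnot(is.data.frame(genes), all(c("gene_id", "cds") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids", call. = FALSE)
  genes <- tibble::as_tibble(genes)
  if (!"protein" %in% names(genes)) {
    genes$protein <- translate_cds(genes$cds)
  } else {
    plen <- nchar(genes$protein)
    ok <- nchar(genes$cds) == 3 * plen | nchar(genes$cds) == 3 * (plen + 1)
    if (!all(ok)) stop("cds and protein lengths inconsistent", call. = FALSE)
  }
  freq <- aa_frequencies(genes$protein)
  names(freq) <- paste0("aa_", names(freq))
  ann <- intersect(c("domain_label", "ko_label", "is_single_copy_cog"), names(genes))
  out <- dplyr::bind_cols(
    genes[, c("gene_id", ann), drop = FALSE],
    tibble::tibble(
      nt_length = nchar(genes$cds),
      gc = gc_content(genes$cds),
      n_arsc = n_arsc(genes$protein),
      c_arsc = c_arsc(genes$protein),
      nc_ratio = suppressWarnings(side_chain_nc_ratio(genes$protein)),
      mw = protein_mw(genes$protein),
      codon_diversity = codon_diversity(genes$cds),
      codon_bias_enc = effective_number_of_codons(genes$cds)
    ),
    freq
  )
  out
}
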