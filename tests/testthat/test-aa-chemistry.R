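test_that("residue atom table has the canonical side-chain composition", {
  at <- residue_atoms()
  expect_equal(nrow(at), 20)
  expect_true(all(at$side_chain_c >= 0 & at$side_chain_n >= 0 &
                    at$side_chain_s >= 0))
  n <- setNames(at$side_chain_n, at$residue)
  expect_equal(unname(n["R"]), 3L)
  expect_equal(sum(n == max(n)), 1L)  # arginine is the unique maximum
  expect_equal(unname(n["H"]), 2L)
  expect_equal(unname(n["M"]), 0L)
  expect_equal(unname(n["G"]), 0L)
  g <- at[at$residue == "G", ]
  expect_equal(g$side_chain_c, 0L)
})

test_that("side_chain_atoms matches known residue structures and rejects junk", {
  sc <- side_chain_atoms(c("R", "H", "M", "G"))
  expect_equal(sc$side_chain_c, c(4L, 4L, 3L, 0L))
  expect_equal(sc$side_chain_n, c(3L, 2L, 0L, 0L))
  expect_equal(sc$side_chain_s, c(0L, 0L, 1L, 0L))
  expect_error(side_chain_atoms("B"), "standard")
  expect_error(side_chain_atoms("U"), "standard")
})

test_that("gc_content counts unambiguous bases only", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATATNNGC"), 2 / 6)
  expect_equal(gc_content("atgc"), 0.5)  # case-insensitive
  expect_error(gc_content("NNNN"), "all-ambiguous")
  expect_error(gc_content(""), "invalid|all-ambiguous")
  expect_error(gc_content("ATXG"), "invalid")
})

test_that("gc_content is invariant under reversal and rev-comp augmentation", {
  set.seed(1)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(gc_content(s), gc_content(rev_s))
    rc <- chartr("ACGT", "TGCA", rev_s)
    expect_equal(gc_content(paste0(s, rc)), gc_content(s))
  }
})

test_that("translate_cds follows table 11 and handles stops", {
  expect_equal(translate_cds("ATGAAA"), "MK")
  expect_equal(translate_cds("ATGTAA"), "M")  # terminal stop dropped
  expect_error(translate_cds("ATGTAAAAA"), "internal stop")
  expect_error(translate_cds("ATGAA"), "multiple of 3")
  expect_error(translate_cds("ATGNNN"), "ambiguous")
})

test_that("n_arsc / c_arsc match hand counts", {
  expect_equal(n_arsc("RRRR"), 3.0)
  expect_equal(n_arsc("GGGG"), 0.0)
  expect_equal(n_arsc("RK"), 2.0)
  expect_equal(c_arsc("AAAA"), 1.0)
  expect_equal(c_arsc("GG"), 0.0)
  expect_equal(c_arsc("FW"), 8.0)
  expect_error(n_arsc(""), "empty")
  expect_error(n_arsc("AXZ"), "standard")
})

test_that("n_arsc / c_arsc equal brute-force atom counting on random proteins", {
  set.seed(42)
  for (i in 1:1000) {
    p <- random_protein(sample(5:80, 1))
    bf <- brute_force_arsc(p)
    # integer atom totals before division
    expect_identical(round(n_arsc(p) * bf$len), as.numeric(bf$n_sum))
    expect_identical(round(c_arsc(p) * bf$len), as.numeric(bf$c_sum))
    expect_equal(n_arsc(p), bf$n_sum / bf$len)
    expect_equal(c_arsc(p), bf$c_sum / bf$len)
  }
})

test_that("side-chain N:C is the aggregate ratio, NA when carbon-free", {
  expect_equal(side_chain_nc_ratio("R"), 0.75)
  expect_equal(side_chain_nc_ratio("A"), 0.0)
  expect_warning(out <- side_chain_nc_ratio("G"), "undefined")
  expect_true(is.na(out))
  set.seed(7)
  for (i in 1:50) {
    p <- random_protein(30)
    if (c_arsc(p) > 0) {
      expect_equal(side_chain_nc_ratio(p), n_arsc(p) / c_arsc(p))
    }
  }
})

test_that("n_arsc concatenation is the length-weighted mean", {
  set.seed(3)
  for (i in 1:20) {
    p1 <- random_protein(sample(5:40, 1))
    p2 <- random_protein(sample(5:40, 1))
    l1 <- nchar(p1); l2 <- nchar(p2)
    expect_equal(n_arsc(paste0(p1, p2)),
                 (l1 * n_arsc(p1) + l2 * n_arsc(p2)) / (l1 + l2))
  }
})

test_that("aa_frequencies sums to one and errors on empty input", {
  f <- aa_frequencies("AAAA")
  expect_equal(f$A, 1.0)
  expect_equal(sum(f), 1.0)
  f2 <- aa_frequencies("AR")
  expect_equal(c(f2$A, f2$R), c(0.5, 0.5))
  expect_error(aa_frequencies(""), "empty")
  set.seed(11)
  for (i in 1:50) {
    expect_equal(sum(aa_frequencies(random_protein(sample(1:100, 1)))), 1,
                 tolerance = 1e-9)
  }
})

test_that("protein_mw sums free amino-acid average masses", {
  expect_equal(protein_mw("G"), 75.07)
  expect_equal(protein_mw("GG"), 150.14)
  p1 <- "ARNDC"; p2 <- "WYV"
  expect_equal(protein_mw(paste0(p1, p2)), protein_mw(p1) + protein_mw(p2))
  expect_error(protein_mw("AB"), "standard")
})

test_that("codon_diversity is the mean used/available synonymous fraction", {
  expect_equal(codon_diversity("ATGTGG"), 1.0)        # Met + Trp
  expect_equal(codon_diversity("CTGCTA"), 1 / 3)      # 2 of 6 Leu codons
  # every synonymous codon of every encoded amino acid -> 1
  expect_equal(codon_diversity("GCTGCCGCAGCGATG"), 1.0)  # all 4 Ala + Met
  expect_error(codon_diversity("AT"), "multiple of 3")
})

test_that("effective number of codons hits both asymptotes", {
  # uniform synonymous usage, every family well sampled
  code <- stoichiomics:::.genetic_code
  sense <- names(code)[code != "*" & !code %in% c("M", "W")]
  uniform <- paste(rep(c(sense, "ATG", "TGG"), 60), collapse = "")
  expect_equal(effective_number_of_codons(uniform), 61, tolerance = 0.01)
  # one codon per family = maximal bias
  aa <- unique(code[code != "*"])
  one_each <- vapply(aa, function(a) names(code)[code == a][1], character(1))
  biased <- paste(rep(one_each, 30), collapse = "")
  expect_equal(effective_number_of_codons(biased), 20)
  # concentrating leucine usage on one codon lowers ENC
  base <- rep(names(code)[code != "*"], 5)
  leu <- names(code)[code == "L"]
  spread <- paste(c(base, rep(leu, 20)), collapse = "")
  conc <- paste(c(base, rep(leu[1], 120)), collapse = "")
  expect_lt(effective_number_of_codons(conc),
            effective_number_of_codons(spread))
})

test_that("gene_properties bundles the per-gene metrics deterministically", {
  g <- data.frame(gene_id = "g1", cds = "ATGAAA")
  p <- gene_properties(g)
  expect_equal(p$gc, 1 / 6)  # one G among six unambiguous bases
  expect_equal(p$n_arsc, 0.5)   # M (0) + K (1)
  expect_equal(p$nt_length, 6L)
  polyg <- data.frame(gene_id = "g2", cds = "GGAGGTGGC")
  p2 <- gene_properties(polyg)
  expect_equal(p2$n_arsc, 0)
  expect_true(is.na(p2$nc_ratio))
  # determinism
  expect_identical(gene_properties(g), gene_properties(g))
  expect_error(gene_properties(data.frame(gene_id = c("a", "a"),
                                          cds = c("ATG", "ATG"))),
               "duplicate")
})
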