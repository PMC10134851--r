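test_that("alignment identity follows 1 - mismatches/length", {
  expect_equal(alignment_identity(5, 100), 0.95)
  expect_equal(alignment_identity(0, 80), 1.0)
  expect_equal(alignment_identity(50, 100), 0.5)
  expect_error(alignment_identity(0, 0), "> 0")
  expect_error(alignment_identity(5, 4), "\\[0, alignment_length\\]")
})

test_that("alignment filter is inclusive on identity, strict on length", {
  recs <- tibble::tibble(
    sample_id = "s1", gene_id = c("a", "b", "c"),
    alignment_length = c(100L, 60L, 100L),
    mismatches = c(5L, 0L, 6L),
    mapped_bases = c(100L, 60L, 100L))
  kept <- filter_alignments(recs)
  expect_equal(kept$gene_id, "a")   # 95% kept; len 60 dropped; 94% dropped
})

test_that("gene coverage is mapped bases over gene length on the full grid", {
  len <- c(gA = 100, gB = 50, gC = 200)
  recs <- tibble::tibble(
    sample_id = c("s1", "s1", "s1"),
    gene_id = c("gA", "gB", "gB"),
    alignment_length = 100L, mismatches = 0L,
    mapped_bases = c(500, 100, 150))
  cov <- gene_coverage(recs, len)
  cv <- setNames(cov$coverage, cov$gene_id)
  expect_equal(unname(cv["gA"]), 5.0)
  expect_equal(unname(cv["gB"]), 5.0)   # (100 + 150) / 50
  expect_equal(unname(cv["gC"]), 0.0)   # no records
  bad <- dplyr::mutate(recs, gene_id = "ghost")
  expect_error(gene_coverage(bad, len), "unknown gene")
})

test_that("coverage recomputed from deterministic alignments is exact", {
  len <- c(g1 = 300, g2 = 600, g3 = 450)
  target <- c(g1 = 5, g2 = 12, g3 = 0)
  recs <- simulate_alignments(target, len, error_rate = 0, seed = 1)
  cov <- gene_coverage(filter_alignments(recs), len)
  placed <- recs |> dplyr::group_by(gene_id) |>
    dplyr::summarise(bases = sum(mapped_bases))
  for (g in placed$gene_id) {
    expect_identical(cov$coverage[cov$gene_id == g],
                     placed$bases[placed$gene_id == g] / len[[g]])
  }
  expect_equal(cov$coverage[cov$gene_id == "g3"], 0)
})

test_that("copy numbers normalize to the mean single-copy coverage", {
  cov <- tibble::tibble(sample_id = "s1",
                        gene_id = c("sc1", "sc2", "g1", "g2"),
                        coverage = c(5, 15, 5, 20))
  cn <- copy_numbers(cov, c("sc1", "sc2"))
  expect_equal(cn$copy_number, c(0.5, 1.5, 0.5, 2.0))  # SC mean = 10
  allzero <- dplyr::mutate(cov, coverage = c(0, 0, 5, 5))
  expect_error(copy_numbers(allzero, c("sc1", "sc2")), "zero")
  expect_error(copy_numbers(cov, "nope"), "absent")
})

test_that("genes per genome and genome length follow the copy numbers", {
  cn <- tibble::tibble(sample_id = "s1", gene_id = c("a", "b"),
                       copy_number = c(2, 0.5))
  expect_equal(genes_per_genome(cn)$genes_per_genome, 2.5)
  gl <- average_genome_length(cn, c(a = 500, b = 1000))
  expect_equal(gl$genome_length, 2 * 500 + 0.5 * 1000)
  # equal lengths L -> genes_per_genome * L
  gl2 <- average_genome_length(cn, c(a = 700, b = 700))
  expect_equal(gl2$genome_length, 2.5 * 700)
})

test_that("copy numbers, genes/genome and profiles are scale invariant", {
  cov <- tiny_coverage()
  props <- gene_properties(tiny_catalog())
  sc <- c("sc1", "sc2")
  lens <- props[, c("gene_id", "nt_length")]
  scaled <- cov |>
    dplyr::mutate(coverage = coverage * ifelse(sample_id == "s1", 7, 0.3))
  for (f in list(
    function(x) copy_numbers(x, sc)$copy_number,
    function(x) genome_size(x, sc, lens),
    function(x) sample_profiles(x, props))) {
    expect_equal(f(cov), f(scaled))
  }
})

test_that("weighted coverages sum to one and reject empty samples", {
  cov <- tibble::tibble(sample_id = "s1", gene_id = c("a", "b", "c"),
                        coverage = c(1, 1, 2))
  w <- weighted_coverages(cov)
  expect_equal(w$weight, c(0.25, 0.25, 0.5))
  w10 <- weighted_coverages(dplyr::mutate(cov, coverage = coverage * 10))
  expect_equal(w10$weight, w$weight)
  single <- tibble::tibble(sample_id = "s1", gene_id = c("a", "b"),
                           coverage = c(3, 0))
  expect_equal(weighted_coverages(single)$weight, c(1, 0))
  zero <- dplyr::mutate(cov, coverage = 0)
  expect_error(weighted_coverages(zero), "zero total coverage")
})

test_that("sample profiles are coverage-weighted means within domain", {
  props <- gene_properties(tiny_catalog())
  # two genes, weights 0.25/0.75 on gc 0.4/0.6 -> 0.55
  p2 <- tibble::tibble(gene_id = c("x", "y"), domain_label = "bacteria",
                       gc = c(0.4, 0.6), n_arsc = c(0.1, 0.3),
                       nc_ratio = c(0.2, 0.4))
  cov2 <- tibble::tibble(sample_id = "s1", gene_id = c("x", "y"),
                         coverage = c(1, 3))
  prof <- sample_profiles(cov2, p2)
  expect_equal(prof$gc, 0.55)
  expect_equal(prof$nc_ratio, 0.35)
  # single gene -> its own property vector
  one <- sample_profiles(cov2[2, ], p2)
  expect_equal(one$gc, 0.6)
  # profile of the tiny catalog stays within per-gene property range
  cov <- tiny_coverage()
  prof_all <- sample_profiles(cov, props)
  for (col in c("gc", "n_arsc", "c_arsc", "mw")) {
    expect_true(all(prof_all[[col]] >= min(props[[col]]) - 1e-12))
    expect_true(all(prof_all[[col]] <= max(props[[col]]) + 1e-12))
  }
  # weighted aa frequencies still sum to 1
  aa_cols <- grep("^aa_", names(prof_all), value = TRUE)
  expect_equal(unname(rowSums(prof_all[, aa_cols])), rep(1, nrow(prof_all)),
               tolerance = 1e-6)
})

test_that("undefined N:C genes are excluded from the nc_ratio average only", {
  props <- gene_properties(tiny_catalog())
  expect_true(is.na(props$nc_ratio[props$gene_id == "gPolyG"]))
  cov <- tiny_coverage()
  prof <- sample_profiles(cov, props)
  ok <- !is.na(props$nc_ratio)
  s1 <- cov[cov$sample_id == "s1", ]
  manual <- sum(props$nc_ratio[ok] * s1$coverage[match(props$gene_id[ok],
                                                       s1$gene_id)]) /
    sum(s1$coverage[match(props$gene_id[ok], s1$gene_id)])
  expect_equal(prof$nc_ratio[prof$sample_id == "s1"], manual)
})

test_that("marker profiles are coverage-weighted and flag absent markers", {
  vals <- tibble::tibble(gene_id = c("m1", "m2"), nc_ratio = c(0.2, 0.4))
  cov <- tibble::tibble(sample_id = c("s1", "s1", "s2", "s2"),
                        gene_id = c("m1", "m2", "m1", "m2"),
                        coverage = c(1, 3, 0, 0))
  expect_warning(out <- marker_weighted_profile(cov, vals), "absent")
  expect_equal(out$nc_ratio[out$sample_id == "s1"], 0.35)
  expect_true(is.na(out$nc_ratio[out$sample_id == "s2"]))
  # single cluster -> its value; equal coverages -> arithmetic mean
  one <- marker_weighted_profile(cov[1, ], vals)
  expect_equal(one$nc_ratio, 0.2)
  eq <- marker_weighted_profile(dplyr::mutate(cov[1:2, ], coverage = 5), vals)
  expect_equal(eq$nc_ratio, 0.3)
})
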