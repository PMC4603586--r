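profile_of <- function(zipper, ...) {
  zipper_profile(make_domain(zipper, ...))
}

test_that("composition reports planted register frequencies", {
  # 10 zippers of 3 heptads; 5 plant Asn at a of heptad 2 (position +12)
  profs <- c(
    lapply(1:5, function(i) profile_of(make_zipper(3, list(`12` = "N")))),
    lapply(1:5, function(i) profile_of(make_zipper(3)))
  )
  comp <- composition(profs)
  expect_equal(unname(comp$asn_at_a_by_heptad["2"]), 0.5)
  expect_equal(comp$leu_at_d, 1.0)          # canonical zippers
  pf <- comp$pair_freq_by_heptad
  expect_true(all(abs(pf$complete + pf$incomplete + pf$uncharged - 1) < 1e-12))
  for (r in c("g", "e", "a", "d")) {
    expect_equal(sum(comp$register_freq[[r]]), 1.0)
  }
})

test_that("the restricted denominator never lowers the Asn-at-a frequency", {
  fam <- generate_family(synthetic_spec(n_proteins = 40, seed = 23))
  profs <- lapply(seq_len(40), function(i) {
    zipper_profile(find_bzip_domain(fam$proteins[i, ]))
  })
  all_m <- composition(profs, "all_members")$asn_at_a_by_heptad
  with_h <- composition(profs, "members_with_heptad")$asn_at_a_by_heptad
  ok <- !is.na(all_m) & !is.na(with_h)
  expect_true(all(with_h[ok] >= all_m[ok] - 1e-12))
})

toy_models <- function(starts, chrom = "chr1", ids = NULL) {
  ids <- ids %||% paste0("g", seq_along(starts))
  mapply(function(s, id) {
    gene_model(id, paste0("p_", id), chrom, "+", cbind(s, s + 299))
  }, starts, ids, SIMPLIFY = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("tandem clusters chain adjacent family genes", {
  m <- toy_models(c(1000, 3000, 900000))
  cl <- detect_tandem_clusters(m, max_gap_bp = 100000)
  expect_equal(length(cl), 1L)
  expect_equal(cl[[1]]$members, c("g1", "g2"))
  expect_equal(cl[[1]]$span, c(1000, 3299))

  # different chromosomes never cluster
  m2 <- c(toy_models(1000, "chr1", "a"), toy_models(2000, "chr2", "b"))
  expect_equal(length(detect_tandem_clusters(m2, max_gap_bp = 1e6)), 0L)
})

test_that("an intervening non-family gene is tolerated up to the limit", {
  fam <- toy_models(c(1000, 9000), ids = c("A", "C"))
  census <- data.frame(gene_id = c("A", "B", "C"), chromosome = "chr1",
                       start = c(1000, 5000, 9000),
                       end = c(1299, 5299, 9299))
  cl1 <- detect_tandem_clusters(fam, family_ids = c("A", "C"),
                                max_intervening = 1, all_genes = census)
  expect_equal(length(cl1), 1L)
  expect_equal(cl1[[1]]$members, c("A", "C"))
  cl0 <- detect_tandem_clusters(fam, family_ids = c("A", "C"),
                                max_intervening = 0, all_genes = census)
  expect_equal(length(cl0), 0L)
  # brute-force chaining oracle on permuted toy layouts
  set.seed(5)
  for (rep in 1:10) {
    starts <- sort(sample(seq(1000, 2e6, by = 400), 6))
    fam_ids <- paste0("f", 1:6)
    m <- toy_models(starts, ids = fam_ids)
    got <- detect_tandem_clusters(m, max_gap_bp = 50000)
    linked <- diff(starts) - 300 <= 50000
    grp <- cumsum(c(0, !linked))
    want <- Filter(function(g) length(g) >= 2,
                   split(fam_ids, grp))
    expect_equal(lapply(got, `[[`, "members"), unname(want))
  }
})

test_that("cluster membership survives relabeling and translation", {
  m <- toy_models(c(1000, 3000, 900000))
  base <- detect_tandem_clusters(m)
  shifted <- toy_models(c(1000, 3000, 900000) + 1e6,
                        ids = c("x", "y", "z"))
  tr <- detect_tandem_clusters(shifted)
  expect_equal(length(tr), length(base))
  expect_equal(tr[[1]]$members, c("x", "y"))
})

test_that("genes map into external duplication blocks by overlap", {
  m <- toy_models(c(1000, 50000))
  blocks <- data.frame(block_id = c("B1", "B2"), chromosome = "chr1",
                       start = c(500, 100000), end = c(2000, 200000))
  bm <- map_genes_to_blocks(m, blocks)
  expect_equal(bm$block_ids, c("B1", ""))
})

test_that("the joined report keeps one row per protein with NA markers", {
  fam <- generate_family(synthetic_spec(n_proteins = 12, seed = 31))
  doms <- lapply(seq_len(12), function(i) find_bzip_domain(fam$proteins[i, ]))
  calls <- lapply(doms, classify_binding_group)
  profs <- lapply(doms, zipper_profile)
  sf <- assign_subfamilies(profs)
  # drop some gene models: rows must survive with missing markers
  models <- fam$models[1:8]
  pattern_calls <- lapply(seq_along(models), function(i) {
    classify_intron_pattern(models[[i]], doms[[i]],
                            introns_from_model(models[[i]],
                                               fam$proteins$sequence[i]))
  })
  expect_warning(
    rep_ <- join_report(fam$proteins, calls, sf, profs, pattern_calls,
                        models, detect_tandem_clusters(models)),
    "without a gene model")
  expect_equal(nrow(rep_), 12L)
  expect_true(all(is.na(rep_$gene_id[9:12])))
  expect_true(all(is.na(rep_$intron_pattern[9:12])))
  expect_false(anyNA(rep_$group))
  # random subsets: row count always equals the protein count
  set.seed(7)
  for (k in 1:5) {
    keep <- sample(12, sample(3:12, 1))
    expect_warning(
      r <- join_report(fam$proteins, calls, sf, profs,
                       pattern_calls[seq_len(min(length(keep), 8))],
                       models[seq_len(min(max(keep), 8))], list()),
      regexp = NULL)
    expect_equal(nrow(r), nrow(fam$proteins))
  }
})
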