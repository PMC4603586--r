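# A model/domain/introns bundle with introns planted at given signed
# positions and phases inside the basic/hinge window of a 5-leader protein.
plant_gene <- function(paper_pos = integer(0), phase = integer(0),
                       residues = list(), leader = 5L) {
  plant <- list()
  zip <- make_zipper(3)
  seq <- make_bzip_seq(zip, leader = leader)
  for (nm in names(residues)) {
    at <- leader + as.integer(nm) + 18L + 1L
    substr(seq, at, at) <- residues[[nm]]
  }
  len <- nchar(seq)
  cum <- 3L * (leader + sort(paper_pos) + 18L) + phase[order(paper_pos)]
  exon_lens <- diff(c(0L, sort(cum), 3L * len))
  seg <- matrix(0L, length(exon_lens), 2L)
  pos <- 1L
  for (k in seq_along(exon_lens)) {
    seg[k, ] <- c(pos, pos + exon_lens[k] - 1L)
    pos <- pos + exon_lens[k] + 100L
  }
  m <- gene_model("g1", NA_character_, "chr1", "+", seg)
  m$protein_id <- "test"
  d <- find_bzip_domain(data.frame(id = "test", sequence = seq,
                                   description = ""))
  list(model = m, domain = d, introns = introns_from_model(m, seq))
}

test_that("window patterns a-f are recognized from position and phase", {
  f0 <- plant_gene()
  call_f <- classify_intron_pattern(f0$model, f0$domain, f0$introns)
  expect_equal(call_f$pattern, "f")
  expect_true(call_f$intronless_gene)

  a <- plant_gene(paper_pos = -14L, phase = 0L)
  expect_equal(classify_intron_pattern(a$model, a$domain, a$introns)$pattern,
               "a")
  b <- plant_gene(paper_pos = -4L, phase = 0L)
  expect_equal(classify_intron_pattern(b$model, b$domain, b$introns)$pattern,
               "b")
  cc <- plant_gene(paper_pos = c(-15L, -3L), phase = c(0L, 0L))
  expect_equal(classify_intron_pattern(cc$model, cc$domain, cc$introns)$pattern,
               "c")
  d <- plant_gene(paper_pos = -5L, phase = 2L, residues = list(`-5` = "Q"))
  expect_equal(classify_intron_pattern(d$model, d$domain, d$introns)$pattern,
               "d")
  e <- plant_gene(paper_pos = -5L, phase = 2L, residues = list(`-5` = "R"))
  expect_equal(classify_intron_pattern(e$model, e$domain, e$introns)$pattern,
               "e")
})

test_that("a P1 window intron is unclassified with a reason", {
  g <- plant_gene(paper_pos = -5L, phase = 1L)
  call <- classify_intron_pattern(g$model, g$domain, g$introns)
  expect_equal(call$pattern, "unclassified")
  expect_match(call$reasons, "P1")
})

test_that("introns outside the window only affect the intronless flag", {
  # an intron in the leader: pattern f, but the gene is not intronless
  g <- plant_gene()
  len <- nchar(g$domain$sequence)
  seg <- matrix(c(1L, 6L, 200L, 200L + 3L * len - 6L - 1L), 2L, 2L,
                byrow = TRUE)
  m <- gene_model("g1", "test", "chr1", "+", seg)
  call <- classify_intron_pattern(m, g$domain, introns_from_model(m))
  expect_equal(call$pattern, "f")
  expect_false(call$intronless_gene)

  # adding an outside (leader) intron to a pattern-a gene changes nothing
  a2 <- plant_gene(paper_pos = -14L, phase = 0L)
  lens <- a2$model$cds_segments[, "end"] - a2$model$cds_segments[, "start"] + 1L
  lead_cut <- 3L * 2L  # P0 split after the second leader codon
  new_lens <- c(lead_cut, lens[1L] - lead_cut, lens[-1L])
  seg2 <- matrix(0L, length(new_lens), 2L)
  pos <- 1L
  for (k in seq_along(new_lens)) {
    seg2[k, ] <- c(pos, pos + new_lens[k] - 1L)
    pos <- pos + new_lens[k] + 100L
  }
  m2 <- gene_model("g1", "test", "chr1", "+", seg2)
  call2 <- classify_intron_pattern(m2, a2$domain,
                                   introns_from_model(m2,
                                                      a2$domain$sequence))
  expect_equal(call2$pattern, "a")
  expect_equal(nrow(call2$window_introns), 1L)
})

test_that("gene/domain protein mismatch is rejected", {
  g <- plant_gene(paper_pos = -4L, phase = 0L)
  g$model$protein_id <- "someone_else"
  expect_error(classify_intron_pattern(g$model, g$domain, g$introns),
               "someone_else")
})

test_that("the census sums to the gene count, intronless kept apart", {
  g1 <- plant_gene(); g2 <- plant_gene()
  g3 <- plant_gene(paper_pos = -14L, phase = 0L)
  calls <- list(classify_intron_pattern(g1$model, g1$domain, g1$introns),
                classify_intron_pattern(g2$model, g2$domain, g2$introns),
                classify_intron_pattern(g3$model, g3$domain, g3$introns))
  cen <- pattern_census(calls)
  expect_equal(cen$counts, c(a = 1L, f = 2L))
  expect_equal(sum(cen$counts), 3L)
  expect_equal(cen$intronless, 2L)
  expect_error(pattern_census(list()), "at least one")
})

test_that("a planted family census equals the planted histogram", {
  fam <- generate_family(synthetic_spec(n_proteins = 60, seed = 17))
  calls <- lapply(seq_len(60), function(i) {
    d <- find_bzip_domain(fam$proteins[i, ])
    classify_intron_pattern(fam$models[[i]], d,
                            introns_from_model(fam$models[[i]],
                                               fam$proteins$sequence[i]))
  })
  cen <- pattern_census(calls)
  truth_tab <- table(fam$truth$proteins$pattern)
  expect_equal(cen$counts[names(truth_tab)],
               setNames(as.integer(truth_tab), names(truth_tab)))
  expect_equal(cen$intronless, sum(fam$truth$proteins$intronless))
  expect_equal(cen$n_genes, 60L)
})
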