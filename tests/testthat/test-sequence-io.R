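test_that("FASTA reading tokenizes headers and normalizes sequences", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">SlbZIP01 desc words", "mknr", "aalz*",
               ">SlbZIP02", "MMMM"), fa)
  rec <- read_fasta(fa)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$id, c("SlbZIP01", "SlbZIP02"))
  expect_equal(rec$description[1], "desc words")
  expect_equal(rec$description[2], "")
  # uppercasing agrees with an independent character-map oracle; the
  # non-canonical Z becomes X and the trailing stop is stripped
  expect_equal(rec$sequence[1], chartr("Z", "X", toupper("mknraalz")))
})

test_that("FASTA reading rejects empty files and duplicate ids", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  file.create(fa)
  expect_error(read_fasta(fa), "empty")
  writeLines(c(">a", "MK", ">a", "ML"), fa)
  expect_error(read_fasta(fa), "a")
})

test_that("FASTA write/read round-trips records identically", {
  rec <- data.frame(id = c("p1", "p2"),
                    sequence = c(strclp(rep("MKL", 50)), "MA"),
                    description = c("first", ""))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(rec, fa)
  expect_equal(read_fasta(fa), rec)
})

test_that("gene models order CDS segments in transcript orientation", {
  plus <- gene_model("g1", "p1", "chr1", "+", cbind(1, 300))
  expect_equal(nrow(plus$cds_segments), 1L)
  expect_equal(plus$cds_length, 300L)
  minus <- gene_model("g2", "p2", "chr1", "-",
                      cbind(c(100, 500), c(160, 559)))
  # 5'->3' of a minus-strand transcript runs down the genomic axis
  expect_equal(minus$cds_segments[, "start"], c(500L, 100L))
  expect_equal(minus$cds_length, 121L)
  expect_false(minus$cds_ok)
  expect_error(gene_model("g3", "p3", "chr1", "+",
                          cbind(c(1, 50), c(60, 90))), "overlap")
})

test_that("GFF3 reading builds models and flags defects", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1\t1000\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t1\t1000\t.\t+\t.\tID=mA;Parent=gA",
    "chr1\tsrc\tCDS\t1\t300\t.\t+\t0\tID=cA;Parent=mA;protein_id=pA",
    "chr1\tsrc\tgene\t2000\t3000\t.\t-\t.\tID=gB",
    "chr1\tsrc\tmRNA\t2000\t3000\t.\t-\t.\tID=mB;Parent=gB",
    "chr1\tsrc\tCDS\t2000\t2099\t.\t-\t0\tID=cB1;Parent=mB;protein_id=pB",
    "chr1\tsrc\tCDS\t2500\t2599\t.\t-\t2\tID=cB2;Parent=mB;protein_id=pB",
    "chr1\tsrc\tgene\t5000\t5100\t.\t+\t.\tID=gC",
    "chr1\tsrc\tmRNA\t5000\t5100\t.\t+\t.\tID=mC;Parent=gC"
  ), gff)
  expect_message(models <- read_gff3(gff), "mC")
  expect_equal(sort(names(models)), c("gA", "gB"))
  expect_equal(models[["gA"]]$cds_length, 300L)
  expect_true(models[["gA"]]$cds_ok)
  # minus strand: descending genomic coordinates; concatenated length oracle
  mb <- models[["gB"]]
  expect_equal(mb$cds_segments[, "start"], c(2500L, 2000L))
  expect_equal(mb$cds_length, sum(c(2099 - 2000, 2599 - 2500) + 1))
  expect_false(mb$cds_ok)  # 200 nt, flagged not fixed
})

test_that("GFF3 reading rejects CDS rows without Parent", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=mA",
    "chr1\tsrc\tCDS\t1\t300\t.\t+\t0\tID=cA"
  ), gff)
  expect_error(read_gff3(gff), "Parent")
})

test_that("GFF3 write/read round-trips synthetic gene models", {
  fam <- generate_family(synthetic_spec(n_proteins = 8, seed = 3))
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(fam$models, gff)
  back <- read_gff3(gff)
  expect_equal(length(back), length(fam$models))
  for (m in fam$models) {
    b <- back[[m$gene_id]]
    expect_equal(unname(b$cds_segments), unname(m$cds_segments))
    expect_equal(b$strand, m$strand)
    expect_equal(b$chromosome, m$chromosome)
  }
})

test_that("intron phases follow the cumulative-codon rule", {
  m <- gene_model("g", "p", "chr1", "+", cbind(c(1, 200), c(30, 259)))
  intr <- introns_from_model(m)  # exon CDS lengths 30, 60
  expect_equal(intr$phase, "P0")
  expect_equal(intr$protein_position, 11L)
  expect_true(is.na(intr$interrupted_residue))

  # 32 coding bases before the splice: the cut falls between the second
  # and third nucleotide of codon 11
  prot <- strclp(c(rep("A", 10), "W", rep("A", 19)))
  m2 <- gene_model("g", "p", "chr1", "+", cbind(c(1, 200), c(32, 257)))
  intr2 <- introns_from_model(m2, prot)
  expect_equal(intr2$phase, "P2")
  expect_equal(intr2$protein_position, 11L)
  expect_equal(intr2$interrupted_residue, "W")

  m3 <- gene_model("g", "p", "chr1", "+",
                   cbind(c(1, 100, 200), c(10, 119, 229)))
  intr3 <- introns_from_model(m3)  # lengths 10, 20, 30
  expect_equal(intr3$phase, c("P1", "P0"))

  single <- gene_model("g", "p", "chr1", "+", cbind(1, 300))
  expect_equal(nrow(introns_from_model(single)), 0L)
})

test_that("intron phases match a base-by-base codon-walk oracle", {
  set.seed(11)
  for (i in 1:200) {
    m <- random_gene_model(i)
    prot <- strclp(sample(LETTERS[LETTERS %in% c("A", "Q", "R", "W")],
                          m$cds_length / 3, replace = TRUE))
    got <- introns_from_model(m, prot)
    expect_equal(got, codon_walk_oracle(m, prot))
    expect_equal(nrow(got), nrow(m$cds_segments) - 1L)
  }
})
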