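# Sequence construction helpers. Fill residues are drawn from letters that
# carry no structural meaning for the scanner or the charge classifier.
FILL <- c("A", "S", "T", "G", "V", "F", "W", "Y", "H", "C")

fill <- function(n, letter = "A") strclp(rep(letter, n))
strclp <- function(x) paste(x, collapse = "")

# leader + basic/hinge (-18..-1) + zipper (+1..) + optional breaker tail
make_bzip_seq <- function(zipper, leader = 5L, n18 = "N", n10 = "R",
                          key6 = "S", tail = "") {
  basic <- rep("A", 18L)
  basic[1L] <- n18    # -18
  basic[9L] <- n10    # -10
  basic[13L] <- key6  # -6
  paste0(fill(leader), strclp(basic), zipper, tail)
}

# a canonical zipper: h heptads in d..c order, L at d, fill elsewhere,
# with optional planted residues given as list(paper_pos = residue)
make_zipper <- function(h, plant = list()) {
  z <- rep("A", 7L * h)
  z[seq(1L, 7L * h, by = 7L)] <- "L"
  for (nm in names(plant)) z[as.integer(nm)] <- plant[[nm]]
  strclp(z)
}

make_domain <- function(zipper, ...) {
  seq <- make_bzip_seq(zipper, ...)
  d <- find_bzip_domain(data.frame(id = "test", sequence = seq,
                                   description = ""))
  stopifnot(inherits(d, "bzip_domain"))
  d
}

# random multi-exon gene models for phase-oracle checks
random_gene_model <- function(i, max_exons = 6L) {
  n_exons <- sample(1:max_exons, 1L)
  # exon lengths with total divisible by 3
  lens <- sample(5:120, n_exons, replace = TRUE)
  lens[n_exons] <- lens[n_exons] + (3L - sum(lens) %% 3L) %% 3L
  introns <- if (n_exons > 1L) sample(30:200, n_exons - 1L, replace = TRUE)
    else integer(0)
  pos <- sample(1:10000, 1L)
  seg <- matrix(0L, n_exons, 2L)
  for (k in seq_len(n_exons)) {
    seg[k, ] <- c(pos, pos + lens[k] - 1L)
    pos <- pos + lens[k] + if (k < n_exons) introns[k] else 0L
  }
  strand <- sample(c("+", "-"), 1L)
  if (strand == "-") {
    total <- max(seg) - min(seg) + 1L
    seg <- cbind(min(seg) + max(seg) - seg[, 2L],
                 min(seg) + max(seg) - seg[, 1L])
  }
  gene_model(paste0("g", i), paste0("p", i), "chr1", strand, seg)
}
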