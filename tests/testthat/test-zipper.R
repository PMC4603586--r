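test_that("register assignment puts +1 on d and walks the heptads", {
  d <- make_domain(make_zipper(3), tail = paste0("P", fill(4)))
  reg <- assign_registers(d)
  expect_equal(nrow(reg), 21L)
  expect_equal(max(reg$heptad), 3L)
  expect_equal(reg$paper_pos[reg$register == "d"], c(1L, 8L, 15L))
  expect_equal(reg$register[1:7], c("d", "e", "f", "g", "a", "b", "c"))
  # canonical zipper: every d residue is a leucine
  expect_true(all(reg$residue[reg$register == "d"] == "L"))
})

test_that("a truncated final heptad keeps only the registers it contains", {
  zip10 <- substr(make_zipper(2), 1, 10)
  d <- make_domain(zip10, tail = paste0("P", fill(4)))
  reg <- assign_registers(d)
  expect_equal(max(reg$heptad), 2L)
  expect_equal(sort(reg$register[reg$heptad == 2]), c("d", "e", "f"))
  # position-walk oracle: register letter cycles d,e,f,g,a,b,c from +1
  cycle <- rep(c("d", "e", "f", "g", "a", "b", "c"), 2)
  expect_equal(reg$register, cycle[1:10])
})

test_that("the register offset shifts the phase and downstream pairs", {
  d <- make_domain(make_zipper(3))
  reg <- assign_registers(d, offset = 1L)
  expect_equal(reg$register[1], "e")
  expect_equal(reg$register[7], "d")
})

test_that("g-e' pair classification matches the charge definitions", {
  ek <- classify_ge_pair("E", "K")
  expect_equal(ek$completeness, "complete")
  expect_equal(ek$pair_class, "attract_ge")
  as_ <- classify_ge_pair("A", "S")
  expect_equal(as_$completeness, "uncharged")
  expect_equal(as_$pair_class, "none")
  expect_equal(classify_ge_pair("D", "E")$pair_class, "acidic_repulsive")
  expect_equal(classify_ge_pair("R", "K")$pair_class, "basic_repulsive")
  expect_equal(classify_ge_pair("K", "D")$pair_class, "attract_eg")
  expect_equal(classify_ge_pair("E", "A")$completeness, "incomplete")
  # X never matches a charge class
  expect_equal(classify_ge_pair("X", "E")$completeness, "incomplete")
})

test_that("all 441 ordered pairs agree with the exhaustive truth table", {
  letters21 <- c(bzipr:::AA_LETTERS, "X")
  for (h_basic in c(FALSE, TRUE)) {
    cl <- residue_classes(histidine_basic = h_basic)
    for (g in letters21) for (e in letters21) {
      got <- classify_ge_pair(g, e, cl)
      exp <- ge_truth_oracle(g, e, cl$acidic, cl$basic)
      expect_identical(got, exp)
    }
  }
})

test_that("pair classification is symmetric under acidic/basic swap", {
  swap <- c(D = "K", E = "R", K = "D", R = "E")
  mirror <- c(acidic_repulsive = "basic_repulsive",
              basic_repulsive = "acidic_repulsive",
              attract_ge = "attract_eg", attract_eg = "attract_ge",
              none = "none")
  for (g in c("D", "E", "K", "R")) for (e in c("D", "E", "K", "R")) {
    a <- classify_ge_pair(g, e)$pair_class
    b <- classify_ge_pair(swap[[g]], swap[[e]])$pair_class
    expect_equal(b, unname(mirror[a]))
  }
})

test_that("pairs form between a g and the following heptad's e", {
  d <- make_domain(make_zipper(3))
  pairs <- extract_ge_pairs(assign_registers(d))
  expect_equal(nrow(pairs), 2L)           # 3 full heptads -> 2 pairs
  expect_equal(pairs$heptad, c(1L, 2L))

  d1 <- make_domain(make_zipper(1))
  expect_equal(nrow(extract_ge_pairs(assign_registers(d1))), 0L)

  # planted D at g of heptad 1 and K at e of heptad 2 (positions +4, +9)
  dp <- make_domain(make_zipper(3, plant = list(`4` = "D", `9` = "K")))
  pp <- extract_ge_pairs(assign_registers(dp))
  expect_equal(pp$pair_class[pp$heptad == 1], "attract_ge")
})

test_that("completeness categories conserve the pair total", {
  fam <- generate_family(synthetic_spec(n_proteins = 40, seed = 9))
  total <- 0L; by_cat <- c(complete = 0L, incomplete = 0L, uncharged = 0L)
  for (i in seq_len(nrow(fam$proteins))) {
    zp <- zipper_profile(find_bzip_domain(fam$proteins[i, ]))
    total <- total + nrow(zp$pairs)
    tab <- table(factor(zp$pairs$completeness,
                        levels = c("complete", "incomplete", "uncharged")))
    by_cat <- by_cat + as.integer(tab)
    expect_equal(sum(tab), nrow(zp$pairs))
  }
  expect_equal(sum(by_cat), total)
  expect_gt(total, 0L)
})

test_that("register assignment is shift-equivariant over whole heptads", {
  core <- make_zipper(3, plant = list(`4` = "D", `9` = "K", `18` = "E"))
  d0 <- make_domain(core)
  shifted <- make_domain(paste0(make_zipper(1), core))
  p0 <- extract_ge_pairs(assign_registers(d0))
  p1 <- extract_ge_pairs(assign_registers(shifted))
  p1 <- p1[p1$heptad > 1L, ]
  expect_equal(p1$heptad, p0$heptad + 1L)
  expect_equal(p1$pair_class, p0$pair_class)
  expect_equal(p1$g_residue, p0$g_residue)
})
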