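#' Assign coiled-coil heptad registers across the leucine zipper
#'
#' With the default register offset the first zipper leucine (+1) occupies
#' register d, so positions +1..+7 carry registers d,e,f,g,a,b,c, repeating
#' every seven residues — the canonical phase in which zipper leucines sit
#' at d and the g residue of heptad n faces the e residue of heptad n+1
#' (the i, i+5 spacing). Heptad n covers positions 7(n-1)+1 .. 7n; a
#' truncated final heptad is retained with only the registers it contains.
#'
#' @param domain a [build_domain()] result with `zipper_length >= 1`.
#' @param offset integer register offset; `offset = 1` shifts +1 to
#'   register e, etc. All downstream statistics honour the offset.
#' @return a data.frame with columns `heptad`, `register` (a-g),
#'   `paper_pos`, `seq_pos`, `residue` — one row per zipper residue.
#' @export
assign_registers <- function(domain, offset = 0L) {
  stopifnot(inherits(domain, "bzip_domain"), domain$zipper_length >= 1L)
  p <- seq_len(domain$zipper_length)            # paper positions +1..
  regs <- c("d", "e", "f", "g", "a", "b", "c")
  data.frame(
    heptad = (p - 1L) %/% 7L + 1L,
    register = regs[((p - 1L + as.integer(offset)) %% 7L) + 1L],
    paper_pos = p,
    seq_pos = domain$first_leu_pos + p - 1L,
    residue = substring(domain$sequence, domain$first_leu_pos + p - 1L,
                        domain$first_leu_pos + p - 1L),
    stringsAsFactors = FALSE
  )
}

#' Classify one inter-helical g-e' residue pair
#'
#' A g-e' pair is complete when both residues are charged, incomplete when
#' exactly one is, and uncharged otherwise. Complete pairs fall into four
#' classes by the charges at g and e': acidic repulsive (both acidic),
#' basic repulsive (both basic), +/- attractive (acidic g, basic e') and
#' -/+ attractive (basic g, acidic e'). Incomplete and uncharged pairs have
#' class `"none"`.
#'
#' @param g_residue,e_residue single residue letters (canonical or `X`).
#' @param classes a [residue_classes()] object supplying the charge sets.
#' @return list with `completeness` (`"complete"`, `"incomplete"`,
#'   `"uncharged"`) and `pair_class` (`"acidic_repulsive"`,
#'   `"basic_repulsive"`, `"attract_ge"`, `"attract_eg"`, `"none"`).
#' @examples
#' classify_ge_pair("E", "K")  # +/- attractive
#' @export
classify_ge_pair <- function(g_residue, e_residue,
                             classes = residue_classes()) {
  g_acid <- g_residue %in% classes$acidic
  g_base <- g_residue %in% classes$basic
  e_acid <- e_residue %in% classes$acidic
  e_base <- e_residue %in% classes$basic
  n_charged <- (g_acid || g_base) + (e_acid || e_base)
  completeness <- c("uncharged", "incomplete", "complete")[n_charged + 1L]
  pair_class <- "none"
  if (n_charged == 2L) {
    pair_class <- if (g_acid && e_acid) "acidic_repulsive"
      else if (g_base && e_base) "basic_repulsive"
      else if (g_acid && e_base) "attract_ge"
      else "attract_eg"
  }
  list(completeness = completeness, pair_class = pair_class)
}

#' Extract and classify all g-e' pairs of a zipper
#'
#' One pair is formed for every heptad n that carries a g residue and whose
#' successor heptad n+1 carries an e residue; a trailing g with no
#' following e contributes no pair. Pairs are ordered by heptad index (the
#' g side).
#'
#' @param registers output of [assign_registers()].
#' @param classes a [residue_classes()] object.
#' @return a data.frame with columns `heptad`, `g_residue`, `e_residue`,
#'   `completeness`, `pair_class`.
#' @export
extract_ge_pairs <- function(registers, classes = residue_classes()) {
  g <- registers[registers$register == "g", c("heptad", "residue")]
  e <- registers[registers$register == "e", c("heptad", "residue")]
  m <- merge(g, data.frame(heptad = e$heptad - 1L, e_residue = e$residue),
             by = "heptad")
  names(m)[names(m) == "residue"] <- "g_residue"
  m <- m[order(m$heptad), , drop = FALSE]
  cls <- lapply(seq_len(nrow(m)), function(i) {
    classify_ge_pair(m$g_residue[i], m$e_residue[i], classes)
  })
  m$completeness <- vapply(cls, `[[`, "", "completeness")
  m$pair_class <- vapply(cls, `[[`, "", "pair_class")
  rownames(m) <- NULL
  m
}

#' Profile a leucine zipper
#'
#' Bundles the per-protein zipper features used for dimerization
#' prediction: heptad registers, Asn-at-a heptads, the Leu-at-d fraction,
#' classified g-e' pairs, the dimerization call and the canonical signature
#' used for subfamily partitioning.
#'
#' @param domain a [build_domain()] result.
#' @param classes a [residue_classes()] object.
#' @param offset register offset passed to [assign_registers()].
#' @return an object of class `zipper_profile` with components
#'   `protein_id`, `registers`, `n_heptads`, `asn_at_a` (heptad indices),
#'   `leu_at_d_fraction`, `pairs`, `dimer_call`, `signature`.
#' @export
zipper_profile <- function(domain, classes = residue_classes(),
                           offset = 0L) {
  reg <- assign_registers(domain, offset)
  pairs <- extract_ge_pairs(reg, classes)
  a <- reg[reg$register == "a", ]
  d <- reg[reg$register == "d", ]
  n_heptads <- max(reg$heptad)
  call <- call_dimerization(pairs)
  structure(list(
    protein_id = domain$protein_id,
    registers = reg,
    n_heptads = n_heptads,
    asn_at_a = a$heptad[a$residue == "N"],
    leu_at_d_fraction = if (nrow(d)) mean(d$residue == "L") else NA_real_,
    pairs = pairs,
    dimer_call = call,
    signature = pair_signature(pairs, n_heptads)
  ), class = "zipper_profile")
}

#' @export
print.zipper_profile <- function(x, ...) {
  cat(sprintf("<zipper_profile> %s: %d heptad(s), %d g-e' pair(s), %s\n",
              x$protein_id, x$n_heptads, nrow(x$pairs), x$dimer_call))
  invisible(x)
}
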