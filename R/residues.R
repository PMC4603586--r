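#' Residue class sets used throughout the pipeline
#'
#' Builds the named residue sets that parameterize domain scanning, register
#' profiling and pair classification: acidic/basic charge sets, the bulky
#' hydrophobic set, the helix-breaker set that terminates the zipper, the
#' zipper-initiator set at position +1, and the substitute sets tolerated at
#' the -18 and -10 anchor positions (Lys at -18 for group IX members, Ile at
#' -10 for group XI members).
#'
#' Histidine is treated as uncharged by default; set `histidine_basic = TRUE`
#' to move it into the basic set. The unknown residue `X` never belongs to
#' any class.
#'
#' @param breakers helix-breaker residues ending the zipper (default `"P"`;
#'   `c("P", "G")` is a common stricter choice).
#' @param initiators residues accepted at zipper position +1 (default `"L"`;
#'   widen to `c("L","I","V","F","M")` for degenerate zippers).
#' @param sub18 substitute residues tolerated at position -18 besides Asn.
#' @param sub10 substitute residues tolerated at position -10 besides Arg/Lys.
#' @param histidine_basic logical; count His as basic.
#' @return a list of class `residue_classes` with components `acidic`,
#'   `basic`, `charged`, `hydrophobic`, `breakers`, `initiators`, `sub18`,
#'   `sub10`.
#' @examples
#' cl <- residue_classes()
#' cl$charged
#' @export
residue_classes <- function(breakers = "P", initiators = "L",
                            sub18 = "K", sub10 = "I",
                            histidine_basic = FALSE) {
  acidic <- c("D", "E")
  basic <- c("K", "R")
  if (isTRUE(histidine_basic)) basic <- c(basic, "H")
  cl <- list(
    acidic = acidic,
    basic = basic,
    charged = c(acidic, basic),
    hydrophobic = c("L", "I", "V", "F", "M"),
    breakers = breakers,
    initiators = initiators,
    sub18 = sub18,
    sub10 = sub10
  )
  stopifnot(all(lengths(cl) >= 1L))
  bad <- setdiff(unlist(cl), AA_LETTERS)
  if (length(bad)) stop("unknown residue letters: ", paste(bad, collapse = ", "))
  class(cl) <- "residue_classes"
  cl
}

# 20 canonical amino acids; X marks unknowns and matches no class
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
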