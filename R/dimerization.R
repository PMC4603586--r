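#' Call dimerization propensity from classified g-e' pairs
#'
#' A zipper is called `homodimer` when an attractive pair sits in the first
#' heptad and no repulsive pair occurs anywhere; `heterodimer` when at
#' least one complete pair exists and every complete pair is repulsive;
#' otherwise `both`. Incomplete pairs are neutral for the call — they
#' contribute little to homodimer stability but can complete attractively
#' in a heterodimer.
#'
#' @param pairs data.frame from [extract_ge_pairs()].
#' @return one of `"homodimer"`, `"heterodimer"`, `"both"`.
#' @examples
#' p <- data.frame(heptad = 1:2, g_residue = c("E", "A"),
#'                 e_residue = c("K", "S"),
#'                 completeness = c("complete", "uncharged"),
#'                 pair_class = c("attract_ge", "none"))
#' call_dimerization(p)
#' @export
call_dimerization <- function(pairs) {
  attractive <- pairs$pair_class %in% c("attract_ge", "attract_eg")
  repulsive <- pairs$pair_class %in% c("acidic_repulsive", "basic_repulsive")
  complete <- pairs$completeness == "complete"
  if (any(attractive & pairs$heptad == 1L) && !any(repulsive)) {
    return("homodimer")
  }
  if (any(complete) && all(repulsive[complete])) return("heterodimer")
  "both"
}

#' Canonical signature of a zipper's pair-class profile
#'
#' Encodes the heptad count and the ordered per-heptad pair classes as a
#' deterministic string; proteins sharing a signature share a dimerization
#' subfamily.
#'
#' @param pairs data.frame from [extract_ge_pairs()].
#' @param n_heptads total heptad count (including a partial final heptad).
#' @return a character scalar, e.g. `"H4|1:+/-,3:AR"`.
#' @export
pair_signature <- function(pairs, n_heptads) {
  abbr <- c(acidic_repulsive = "AR", basic_repulsive = "BR",
            attract_ge = "+/-", attract_eg = "-/+")
  keep <- order(pairs$heptad)
  parts <- vapply(keep, function(i) {
    cls <- pairs$pair_class[i]
    tag <- if (cls == "none") {
      if (pairs$completeness[i] == "incomplete") "i" else "u"
    } else abbr[[cls]]
    paste0(pairs$heptad[i], ":", tag)
  }, character(1))
  paste0("H", n_heptads, "|", paste(parts, collapse = ","))
}

#' Partition zipper profiles into dimerization subfamilies
#'
#' Proteins with identical signatures (heptad count plus ordered pair-class
#' profile) form one subfamily. Labels `BZ1`, `BZ2`, ... are assigned to
#' the distinct signatures in lexicographic order, so the labelling is
#' deterministic across runs and independent of input order.
#'
#' @param profiles list of [zipper_profile()] objects.
#' @return a data.frame with columns `protein_id`, `signature`,
#'   `dimer_call`, `subfamily`.
#' @export
assign_subfamilies <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  sig <- vapply(profiles, `[[`, "", "signature")
  lv <- sort(unique(sig))
  data.frame(
    protein_id = vapply(profiles, `[[`, "", "protein_id"),
    signature = sig,
    dimer_call = vapply(profiles, `[[`, "", "dimer_call"),
    subfamily = paste0("BZ", match(sig, lv)),
    stringsAsFactors = FALSE
  )
}
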