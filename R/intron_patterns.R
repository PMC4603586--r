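#' Default intron pattern table
#'
#' The six conserved intron patterns (a-f) within the basic/hinge window
#' (-18..-1) are keyed on intron number, position and splicing phase:
#' a and b carry a single P0 intron (a in the basic sub-window, b in the
#' hinge sub-window — the positional split is configurable because the
#' published figure defining it is not machine-readable); c carries two P0
#' introns; d and e carry one P2 intron interrupting Gln and Arg,
#' respectively; f has no intron within the window.
#'
#' @param a_window,b_window signed position ranges (inclusive) splitting
#'   single-P0 introns between patterns a and b.
#' @param d_residue,e_residue interrupted residues defining patterns d/e.
#' @return a list used by [classify_intron_pattern()].
#' @export
default_pattern_table <- function(a_window = c(-18L, -11L),
                                  b_window = c(-10L, -1L),
                                  d_residue = "Q", e_residue = "R") {
  list(a_window = as.integer(a_window), b_window = as.integer(b_window),
       d_residue = d_residue, e_residue = e_residue)
}

#' Classify a gene's intron pattern within the basic/hinge window
#'
#' Introns are first restricted to those affecting the signed window
#' -18..-1 of the anchored domain (a P2 intron whose split codon straddles
#' the window boundary counts as inside when the interrupted residue's
#' signed position is within the window). The restricted set is then
#' matched: no window introns -> f; two P0 introns -> c; one P2 intron
#' interrupting Gln -> d, or Arg -> e; one P0 intron -> a or b by the
#' positional sub-window. Any other configuration is `"unclassified"` with
#' reasons (no published pattern carries a P1 window intron).
#'
#' @param model the [gene_model()] (used for identity and the
#'   intronless flag).
#' @param domain the protein's [build_domain()] result.
#' @param introns data.frame from [introns_from_model()]; must carry
#'   `interrupted_residue` (pass the protein to `introns_from_model`).
#' @param pattern_table a [default_pattern_table()].
#' @return a list of class `intron_pattern_call`: `gene_id`, `pattern`
#'   (`"a"`..`"f"` or `"unclassified"`), `window_introns`,
#'   `intronless_gene`, `reasons`.
#' @export
classify_intron_pattern <- function(model, domain, introns,
                                    pattern_table = default_pattern_table()) {
  stopifnot(inherits(domain, "bzip_domain"))
  if (!is.null(model$protein_id) && !is.na(model$protein_id) &&
      !is.na(domain$protein_id) && model$protein_id != domain$protein_id) {
    stop("gene ", model$gene_id, " references protein ", model$protein_id,
         " but domain is for ", domain$protein_id)
  }
  pos <- seq_to_paper(domain, introns$protein_position)
  in_window <- !is.na(pos) & pos >= -18L & pos <= -1L
  w <- introns[in_window, , drop = FALSE]
  w$paper_pos <- pos[in_window]
  reasons <- character(0)
  pattern <- if (nrow(w) == 0L) {
    "f"
  } else if (nrow(w) == 2L && all(w$phase == "P0")) {
    "c"
  } else if (nrow(w) == 1L && w$phase == "P2") {
    if (identical(w$interrupted_residue, pattern_table$d_residue)) "d"
    else if (identical(w$interrupted_residue, pattern_table$e_residue)) "e"
    else {
      reasons <- paste0("P2 intron interrupts ", w$interrupted_residue,
                        ", not ", pattern_table$d_residue, "/",
                        pattern_table$e_residue)
      "unclassified"
    }
  } else if (nrow(w) == 1L && w$phase == "P0") {
    if (w$paper_pos >= pattern_table$a_window[1L] &&
        w$paper_pos <= pattern_table$a_window[2L]) "a"
    else if (w$paper_pos >= pattern_table$b_window[1L] &&
             w$paper_pos <= pattern_table$b_window[2L]) "b"
    else {
      reasons <- paste0("P0 intron at position ", w$paper_pos,
                        " outside the a/b sub-windows")
      "unclassified"
    }
  } else {
    reasons <- if (any(w$phase == "P1")) {
      "phase P1 not in pattern table"
    } else {
      paste0(nrow(w), " window introns with phases ",
             paste(w$phase, collapse = ","), " match no pattern")
    }
    "unclassified"
  }
  structure(list(gene_id = model$gene_id, pattern = pattern,
                 window_introns = w,
                 intronless_gene = (nrow(introns) == 0L),
                 reasons = reasons),
            class = "intron_pattern_call")
}

#' @export
print.intron_pattern_call <- function(x, ...) {
  cat(sprintf("<intron_pattern_call> %s: pattern %s (%d window intron(s)%s)\n",
              x$gene_id, x$pattern, nrow(x$window_introns),
              if (x$intronless_gene) ", intronless" else ""))
  invisible(x)
}

#' Census of intron patterns across a family
#'
#' Counts genes per pattern; the intronless count is reported separately
#' from pattern f, because f also contains genes whose introns all lie
#' outside the basic/hinge window.
#'
#' @param calls list of [classify_intron_pattern()] results.
#' @return list with `counts` (named integer vector over observed
#'   patterns), `intronless` and `n_genes`.
#' @export
pattern_census <- function(calls) {
  if (length(calls) == 0L) stop("pattern_census needs at least one call")
  pat <- vapply(calls, `[[`, "", "pattern")
  counts <- table(pat)
  list(counts = setNames(as.integer(counts), names(counts)),
       intronless = sum(vapply(calls, `[[`, logical(1), "intronless_gene")),
       n_genes = length(calls))
}
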