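#' Scan a protein for the bZIP basic-region anchor
#'
#' The basic region of a bZIP domain carries the invariant motif
#' N-x7-R/K-x9 followed by the first zipper leucine. The scan reports every
#' position triple (Asn anchor, basic residue 8 positions downstream, zipper
#' initiator 18 positions downstream of the anchor) compatible with that
#' spacing, in left-to-right order. Substitute residues configured in the
#' residue classes are honoured: Lys at the -18 position (group IX) and a
#' hydrophobic Ile at -10 (group XI).
#'
#' @param protein a single-row data.frame from [read_fasta()], or a plain
#'   character sequence.
#' @param classes a [residue_classes()] object.
#' @return a data.frame with columns `asn_pos`, `basic_pos`, `leu_pos`
#'   (1-based sequence positions); zero rows when no anchor is present.
#' @examples
#' scan_basic_anchor("MNAAAAAAARAAAAAAAAALLLLLLLA")
#' @export
scan_basic_anchor <- function(protein, classes = residue_classes()) {
  seq <- protein_sequence(protein)
  n <- nchar(seq)
  if (n < 19L) {
    return(data.frame(asn_pos = integer(0), basic_pos = integer(0),
                      leu_pos = integer(0)))
  }
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  set18 <- c("N", classes$sub18)
  set10 <- c("R", "K", classes$sub10)
  cand <- which(ch %in% set18)
  cand <- cand[cand + 18L <= n]
  cand <- cand[ch[cand + 8L] %in% set10 & ch[cand + 18L] %in% classes$initiators]
  data.frame(asn_pos = cand, basic_pos = cand + 8L, leu_pos = cand + 18L)
}

#' Build a numbered bZIP domain from an anchor candidate
#'
#' Establishes the conventional signed numbering: the 18 residues starting
#' at the Asn anchor are -18..-1 (basic region -18..-10, hinge -9..-1),
#' the first zipper leucine is +1, and numbering continues +2, +3, ...
#' (position 0 does not exist). The zipper ends at the last residue before
#' the first helix-breaker residue at or after +1, or at the sequence end.
#'
#' @param protein sequence or single-row protein data.frame.
#' @param candidate one row of [scan_basic_anchor()] output (or a numeric
#'   vector `c(asn_pos, basic_pos, leu_pos)`).
#' @param classes a [residue_classes()] object; `classes$breakers` bounds
#'   the zipper.
#' @return an object of class `bzip_domain` with components `protein_id`,
#'   `sequence`, `asn_pos`, `basic_pos`, `first_leu_pos`, `zipper_end`,
#'   `zipper_length`.
#' @export
build_domain <- function(protein, candidate, classes = residue_classes()) {
  seq <- protein_sequence(protein)
  id <- protein_id(protein)
  cand <- unlist(candidate)[1:3]
  asn <- as.integer(cand[[1L]]); basic <- as.integer(cand[[2L]])
  leu <- as.integer(cand[[3L]])
  n <- nchar(seq)
  if (asn < 1L || leu > n) stop("anchor candidate out of sequence range")
  if (basic - asn != 8L || leu - basic != 10L) {
    stop("candidate does not satisfy the N-x7-R/K-x9 spacing")
  }
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  after <- which(ch %in% classes$breakers & seq_along(ch) >= leu)
  zipper_end <- if (length(after)) min(after) - 1L else n
  structure(list(protein_id = id, sequence = seq,
                 asn_pos = asn, basic_pos = basic, first_leu_pos = leu,
                 zipper_end = zipper_end,
                 zipper_length = zipper_end - leu + 1L),
            class = "bzip_domain")
}

#' @export
print.bzip_domain <- function(x, ...) {
  cat(sprintf(paste0("<bzip_domain> %s: Asn(-18) at %d, basic(-10) at %d, ",
                     "zipper +1..+%d (residues %d..%d)\n"),
              x$protein_id, x$asn_pos, x$basic_pos, x$zipper_length,
              x$first_leu_pos, x$zipper_end))
  invisible(x)
}

#' Convert between sequence positions and signed domain numbering
#'
#' `seq_to_paper()` maps a 1-based sequence index covered by the domain to
#' the signed position (-18..-1 for basic/hinge, +1.. for the zipper);
#' `paper_to_seq()` is its inverse. Position 0 is never produced or
#' accepted.
#'
#' @param domain a [build_domain()] result.
#' @param i 1-based sequence position(s).
#' @param p signed domain position(s).
#' @return integer vector; `NA` where outside the covered span.
#' @export
seq_to_paper <- function(domain, i) {
  i <- as.integer(i)
  out <- ifelse(i < domain$first_leu_pos,
                i - domain$asn_pos - 18L,
                i - domain$first_leu_pos + 1L)
  out[i < domain$asn_pos | i > domain$zipper_end] <- NA_integer_
  as.integer(out)
}

#' @rdname seq_to_paper
#' @export
paper_to_seq <- function(domain, p) {
  p <- as.integer(p)
  if (any(p == 0L, na.rm = TRUE)) stop("position 0 does not exist")
  out <- ifelse(p < 0L, domain$asn_pos + p + 18L, domain$first_leu_pos + p - 1L)
  out[p < -18L | out > domain$zipper_end] <- NA_integer_
  as.integer(out)
}

#' Pick one domain among several candidates
#'
#' When several anchor candidates exist the one with the longest zipper is
#' kept (the zipper is the defining C-terminal feature); ties go to the
#' leftmost anchor. An empty candidate list yields a `bzip_no_domain`
#' marker, not an error.
#'
#' @param candidates list of `bzip_domain` objects.
#' @return one `bzip_domain`, or an object of class `bzip_no_domain`.
#' @export
select_domain <- function(candidates) {
  candidates <- Filter(function(d) inherits(d, "bzip_domain"), candidates)
  if (length(candidates) == 0L) {
    return(structure(list(), class = "bzip_no_domain"))
  }
  lens <- vapply(candidates, `[[`, integer(1), "zipper_length")
  anchors <- vapply(candidates, `[[`, integer(1), "asn_pos")
  candidates[[order(-lens, anchors)[1L]]]
}

#' @export
print.bzip_no_domain <- function(x, ...) {
  cat("<bzip_no_domain> no bZIP domain found\n")
  invisible(x)
}

#' Locate the bZIP domain of a protein
#'
#' Convenience wrapper: scans for anchors, builds a numbered domain for
#' each, and selects one via [select_domain()].
#'
#' @inheritParams scan_basic_anchor
#' @return a `bzip_domain`, or `bzip_no_domain` when the protein carries no
#'   anchor motif.
#' @export
find_bzip_domain <- function(protein, classes = residue_classes()) {
  cand <- scan_basic_anchor(protein, classes)
  if (nrow(cand) == 0L) return(structure(list(), class = "bzip_no_domain"))
  doms <- lapply(seq_len(nrow(cand)), function(i) {
    build_domain(protein, cand[i, ], classes)
  })
  select_domain(doms)
}

# accept either a plain sequence string or a protein record row
protein_sequence <- function(protein) {
  if (is.character(protein) && length(protein) == 1L) return(protein)
  if (!is.null(protein$sequence)) return(protein$sequence[1L])
  stop("cannot extract a sequence from 'protein'")
}

protein_id <- function(protein) {
  if (is.character(protein) && length(protein) == 1L) return(NA_character_)
  if (!is.null(protein$id)) return(protein$id[1L])
  NA_character_
}
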