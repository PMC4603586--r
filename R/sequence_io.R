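#' Read protein sequences from FASTA
#'
#' Sequences are uppercased, a trailing stop symbol (`*`) is stripped from
#' the 3' end only, and any letter outside the 20 canonical amino acids is
#' normalized to `X`. Gzip-compressed files are accepted.
#'
#' @param path path to a FASTA file.
#' @return a data.frame with columns `id`, `sequence`, `description`
#'   (one row per record).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 a bZIP", "MKNAAAAAAARAAAAAAAAAL"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA ids: ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*$", "", seqs)
  seqs <- gsub(sprintf("[^%s]", paste(AA_LETTERS, collapse = "")), "X", seqs)
  if (any(nchar(seqs) == 0L)) {
    stop("zero-length sequence for: ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  data.frame(id = ids, sequence = unname(seqs), description = unname(desc),
             stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param proteins data.frame with `id`, `sequence` and optionally
#'   `description` columns, as returned by [read_fasta()].
#' @param path output path.
#' @param width line width for wrapped sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  desc <- if ("description" %in% names(proteins)) proteins$description else ""
  hdr <- ifelse(nzchar(desc), paste(proteins$id, desc), proteins$id)
  lines <- unlist(lapply(seq_len(nrow(proteins)), function(i) {
    s <- proteins$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", hdr[i]), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a gene model
#'
#' CDS segments are stored 1-based inclusive in genomic coordinates, ordered
#' 5'->3' in transcript orientation (descending genomic coordinates on the
#' minus strand). The total CDS length must be divisible by 3; if not, the
#' model is flagged via `cds_ok = FALSE` rather than silently repaired.
#'
#' @param gene_id,protein_id,chromosome,strand identifiers; `strand` is
#'   `"+"` or `"-"`.
#' @param cds_segments two-column matrix or data.frame of (start, end).
#' @return a list of class `gene_model`.
#' @export
gene_model <- function(gene_id, protein_id, chromosome, strand, cds_segments) {
  cds <- as.matrix(cds_segments)
  storage.mode(cds) <- "integer"
  colnames(cds) <- c("start", "end")
  if (nrow(cds) == 0L) stop("gene model needs at least one CDS segment")
  if (any(cds[, "end"] < cds[, "start"])) stop("CDS segment with end < start")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  # transcript orientation: ascending genomic on +, descending on -
  ord <- order(cds[, "start"], decreasing = (strand == "-"))
  cds <- cds[ord, , drop = FALSE]
  g <- cds[order(cds[, "start"]), , drop = FALSE]
  if (nrow(g) > 1L && any(g[-1L, "start"] <= g[-nrow(g), "end"])) {
    stop("overlapping CDS segments in gene ", gene_id)
  }
  len <- sum(cds[, "end"] - cds[, "start"] + 1L)
  structure(list(gene_id = gene_id, protein_id = protein_id,
                 chromosome = chromosome, strand = strand,
                 cds_segments = cds, cds_length = len,
                 cds_ok = (len %% 3L == 0L)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%s, %d CDS segment(s), %d nt%s\n",
              x$gene_id, x$protein_id, x$chromosome, x$strand,
              nrow(x$cds_segments), x$cds_length,
              if (x$cds_ok) "" else " [length not divisible by 3]"))
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Expects gene/mRNA/CDS features with `Parent` attributes on CDS rows.
#' One model is built per mRNA; when a gene carries several mRNAs and
#' `collapse = "longest"` (the default), the transcript with the longest
#' total CDS is kept and flagged with attribute `collapsed = TRUE`.
#' mRNAs lacking CDS features are excluded with a message. Models whose CDS
#' length is not divisible by 3 are flagged (`cds_ok = FALSE`), not dropped.
#'
#' @param path path to a GFF3 file (gzip accepted).
#' @param collapse `"longest"` keeps one model per gene (longest CDS);
#'   `"none"` returns one model per mRNA.
#' @return a list of [gene_model()] objects, named by `gene_id`.
#' @export
read_gff3 <- function(path, collapse = c("longest", "none")) {
  collapse <- match.arg(collapse)
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g)
  mrna <- g[g$type %in% c("mRNA", "transcript"), , drop = FALSE]
  cds <- g[g$type == "CDS", , drop = FALSE]
  if (nrow(cds)) {
    if (is.null(cds$Parent)) {
      stop("CDS feature(s) without Parent attribute in ", path)
    }
    parent <- vapply(cds$Parent, function(p) {
      if (length(p) == 0L || is.na(p[1L]) || !nzchar(p[1L])) NA_character_ else p[1L]
    }, character(1))
    if (anyNA(parent)) stop("CDS feature(s) without Parent attribute in ", path)
    cds$parent_id <- parent
  }
  models <- list()
  for (i in seq_len(nrow(mrna))) {
    mid <- as.character(mrna$ID[i])
    gid <- if (is.null(mrna$Parent)) NA_character_ else {
      as.character(unlist(mrna$Parent[i]))[1L]
    }
    if (is.na(gid) || !nzchar(gid)) gid <- mid
    seg <- cds[cds$parent_id == mid, , drop = FALSE]
    if (nrow(seg) == 0L) {
      message("mRNA ", mid, " has no CDS features; excluded")
      next
    }
    pid <- if ("protein_id" %in% names(seg) && !is.na(seg$protein_id[1L])) {
      as.character(seg$protein_id[1L])
    } else mid
    models[[length(models) + 1L]] <- gene_model(
      gene_id = gid, protein_id = pid,
      chromosome = as.character(seg$seqid[1L]),
      strand = as.character(seg$strand[1L]),
      cds_segments = cbind(seg$start, seg$end)
    )
  }
  if (collapse == "longest" && length(models)) {
    gids <- vapply(models, `[[`, "", "gene_id")
    keep <- unlist(lapply(split(seq_along(models), gids), function(ix) {
      if (length(ix) == 1L) return(ix)
      lens <- vapply(models[ix], `[[`, integer(1), "cds_length")
      sel <- ix[which.max(lens)]
      attr(models[[sel]], "collapsed") <<- TRUE
      sel
    }))
    models <- models[sort(keep)]
  }
  names(models) <- vapply(models, `[[`, "", "gene_id")
  models
}

#' Write gene models to GFF3
#'
#' Emits gene/mRNA/CDS rows for each model; the inverse of [read_gff3()]
#' on the models the package produces.
#'
#' @param models list of [gene_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    cds <- m$cds_segments
    span <- c(min(cds[, "start"]), max(cds[, "end"]))
    mid <- paste0(m$gene_id, ".1")
    lines <- c(lines,
      sprintf("%s\tbzipr\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              m$chromosome, span[1L], span[2L], m$strand, m$gene_id),
      sprintf("%s\tbzipr\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              m$chromosome, span[1L], span[2L], m$strand, mid, m$gene_id))
    gord <- cds[order(cds[, "start"]), , drop = FALSE]
    lines <- c(lines, sprintf(
      "%s\tbzipr\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s;protein_id=%s",
      m$chromosome, gord[, "start"], gord[, "end"], m$strand, mid, mid,
      m$protein_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Derive introns and splicing phases from a gene model
#'
#' Each junction between consecutive CDS segments (in transcript
#' orientation) yields one intron. With `c` the cumulative number of coding
#' nucleotides 5' of the junction, the splicing phase is `c mod 3`: P0 falls
#' between codons, P1 after the first nucleotide of a codon, and P2 between
#' the second and third nucleotides of a codon. The affected protein
#' position is the codon containing (P1/P2) or following (P0) the splice,
#' and for P1/P2 the interrupted residue is reported when the protein
#' sequence is supplied.
#'
#' @param model a [gene_model()].
#' @param protein optional protein sequence (character scalar) used to fill
#'   `interrupted_residue`.
#' @return a data.frame with columns `intron_index`, `protein_position`,
#'   `phase` (`"P0"`, `"P1"`, `"P2"`) and `interrupted_residue`
#'   (`NA` for P0). Zero-row for single-segment models.
#' @examples
#' m <- gene_model("g1", "p1", "chr1", "+",
#'                 cbind(c(1, 201), c(32, 258)))
#' introns_from_model(m)
#' @export
introns_from_model <- function(model, protein = NULL) {
  stopifnot(inherits(model, "gene_model"))
  if (!model$cds_ok) {
    warning("CDS length of ", model$gene_id, " not divisible by 3; ",
            "phases downstream of the defect are unreliable")
  }
  seg_len <- model$cds_segments[, "end"] - model$cds_segments[, "start"] + 1L
  n_introns <- length(seg_len) - 1L
  if (n_introns <= 0L) {
    return(data.frame(intron_index = integer(0), protein_position = integer(0),
                      phase = character(0), interrupted_residue = character(0),
                      stringsAsFactors = FALSE))
  }
  cum <- cumsum(seg_len)[seq_len(n_introns)]
  phase_num <- cum %% 3L
  phase <- paste0("P", phase_num)
  protein_position <- cum %/% 3L + 1L  # == ceiling((cum + 1) / 3)
  interrupted <- rep(NA_character_, n_introns)
  if (!is.null(protein)) {
    seq <- if (is.list(protein) || is.data.frame(protein)) protein$sequence[1L] else protein
    hit <- which(phase_num != 0L & protein_position <= nchar(seq))
    if (length(hit)) {
      interrupted[hit] <- substring(seq, protein_position[hit],
                                    protein_position[hit])
    }
  }
  data.frame(intron_index = seq_len(n_introns),
             protein_position = protein_position,
             phase = phase, interrupted_residue = interrupted,
             stringsAsFactors = FALSE)
}
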