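#' Family-level register and pair composition
#'
#' Aggregates zipper profiles into the histogram-style statistics a family
#' survey reports: residue frequencies at the interface registers g, e, a,
#' d (normalized over observed residues per register), the per-heptad
#' Asn-at-a frequency, the overall Leu-at-d and hydrophobic-at-a/d
#' fractions, and per-heptad g-e' pair fractions
#' (complete/incomplete/uncharged, plus attractive/repulsive within the
#' complete pairs).
#'
#' Under `denominator_mode = "all_members"` (default) every protein counts
#' in the denominator of heptad n's Asn-at-a frequency, whether or not its
#' zipper reaches heptad n; `"members_with_heptad"` restricts the
#' denominator to proteins whose zipper has an a residue in that heptad.
#'
#' @param profiles list of [zipper_profile()] objects.
#' @param denominator_mode `"all_members"` or `"members_with_heptad"`.
#' @param classes a [residue_classes()] object.
#' @return a list of class `composition_table` with `register_freq`,
#'   `asn_at_a_by_heptad`, `leu_at_d`, `hydrophobic_ad`,
#'   `pair_freq_by_heptad`, `n_proteins`, `denominator_mode`.
#' @export
composition <- function(profiles,
                        denominator_mode = c("all_members",
                                             "members_with_heptad"),
                        classes = residue_classes()) {
  denominator_mode <- match.arg(denominator_mode)
  stopifnot(length(profiles) >= 1L)
  reg_all <- do.call(rbind, lapply(profiles, `[[`, "registers"))
  pair_all <- do.call(rbind, lapply(profiles, function(p) {
    if (nrow(p$pairs)) cbind(p$pairs, protein_id = p$protein_id) else NULL
  }))
  register_freq <- lapply(setNames(nm = c("g", "e", "a", "d")), function(r) {
    res <- reg_all$residue[reg_all$register == r]
    if (!length(res)) return(numeric(0))
    tab <- table(res)
    setNames(as.numeric(tab) / sum(tab), names(tab))
  })
  max_hept <- max(reg_all$heptad)
  a_rows <- reg_all[reg_all$register == "a", ]
  asn_at_a <- vapply(seq_len(max_hept), function(h) {
    hits <- sum(vapply(profiles, function(p) h %in% p$asn_at_a, logical(1)))
    denom <- if (denominator_mode == "all_members") length(profiles) else {
      sum(vapply(profiles, function(p) {
        any(p$registers$register == "a" & p$registers$heptad == h)
      }, logical(1)))
    }
    if (denom == 0L) NA_real_ else hits / denom
  }, numeric(1))
  d_res <- reg_all$residue[reg_all$register == "d"]
  a_res <- a_rows$residue
  pair_freq <- if (is.null(pair_all)) {
    data.frame(heptad = integer(0))
  } else {
    do.call(rbind, lapply(sort(unique(pair_all$heptad)), function(h) {
      p <- pair_all[pair_all$heptad == h, ]
      n <- nrow(p)
      data.frame(heptad = h, n_pairs = n,
                 complete = mean(p$completeness == "complete"),
                 incomplete = mean(p$completeness == "incomplete"),
                 uncharged = mean(p$completeness == "uncharged"),
                 attractive = mean(p$pair_class %in%
                                     c("attract_ge", "attract_eg")),
                 repulsive = mean(p$pair_class %in%
                                    c("acidic_repulsive", "basic_repulsive")))
    }))
  }
  structure(list(
    register_freq = register_freq,
    asn_at_a_by_heptad = setNames(asn_at_a, seq_len(max_hept)),
    leu_at_d = if (length(d_res)) mean(d_res == "L") else NA_real_,
    hydrophobic_ad = if (length(c(a_res, d_res))) {
      mean(c(a_res, d_res) %in% classes$hydrophobic)
    } else NA_real_,
    pair_freq_by_heptad = pair_freq,
    n_proteins = length(profiles),
    denominator_mode = denominator_mode
  ), class = "composition_table")
}

#' Detect tandem gene clusters
#'
#' Chains family genes on the same chromosome into maximal clusters. When a
#' full gene census (`all_genes`) is supplied, two family genes chain if at
#' most `max_intervening` annotated non-family genes lie between them;
#' otherwise they chain if the genomic gap between their spans is at most
#' `max_gap_bp`. Both thresholds are stand-ins for a rule the literature
#' leaves informal, and are exposed for that reason.
#'
#' @param models list of [gene_model()] objects (family genes).
#' @param family_ids character vector of family gene ids (defaults to all
#'   model ids).
#' @param max_intervening maximum intervening non-family genes.
#' @param max_gap_bp maximum genomic gap when no census is given.
#' @param all_genes optional data.frame census with columns `gene_id`,
#'   `chromosome`, `start`, `end` covering family and non-family genes.
#' @return list of clusters, each a list with `chromosome`, `members`
#'   (gene ids ordered by coordinate) and `span` (c(start, end)).
#' @export
detect_tandem_clusters <- function(models, family_ids = NULL,
                                   max_intervening = 1L,
                                   max_gap_bp = 100000L,
                                   all_genes = NULL) {
  spans <- gene_spans(models)
  if (is.null(family_ids)) family_ids <- spans$gene_id
  fam <- spans[spans$gene_id %in% family_ids, , drop = FALSE]
  if (anyNA(fam$start) || anyNA(fam$chromosome)) {
    stop("missing coordinates for: ",
         paste(fam$gene_id[is.na(fam$start) | is.na(fam$chromosome)],
               collapse = ", "))
  }
  clusters <- list()
  for (chr in unique(fam$chromosome)) {
    f <- fam[fam$chromosome == chr, , drop = FALSE]
    f <- f[order(f$start), , drop = FALSE]
    if (nrow(f) < 2L) next
    linked <- vapply(seq_len(nrow(f) - 1L), function(i) {
      if (!is.null(all_genes)) {
        between <- all_genes[all_genes$chromosome == chr &
                               all_genes$start > f$start[i] &
                               all_genes$start < f$start[i + 1L] &
                               !(all_genes$gene_id %in% family_ids), ,
                             drop = FALSE]
        nrow(between) <= max_intervening
      } else {
        gap <- f$start[i + 1L] - f$end[i] - 1L
        gap <= max_gap_bp
      }
    }, logical(1))
    grp <- cumsum(c(0L, !linked))
    for (g in split(seq_len(nrow(f)), grp)) {
      if (length(g) < 2L) next
      clusters[[length(clusters) + 1L]] <- list(
        chromosome = chr,
        members = f$gene_id[g],
        span = c(min(f$start[g]), max(f$end[g]))
      )
    }
  }
  clusters
}

gene_spans <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    data.frame(gene_id = m$gene_id, protein_id = m$protein_id,
               chromosome = m$chromosome,
               start = min(m$cds_segments[, "start"]),
               end = max(m$cds_segments[, "end"]),
               stringsAsFactors = FALSE)
  }))
}

#' Map genes into externally supplied duplication blocks
#'
#' Segmental-duplication (synteny) blocks are consumed as a 4-column
#' interval table produced by external synteny tools; membership only is
#' computed, never synteny itself.
#'
#' @param models list of [gene_model()] objects.
#' @param blocks data.frame with columns `block_id`, `chromosome`,
#'   `start`, `end`.
#' @return data.frame `gene_id`, `block_ids` (comma-joined, `""` if none).
#' @export
map_genes_to_blocks <- function(models, blocks) {
  stopifnot(all(c("block_id", "chromosome", "start", "end") %in%
                  names(blocks)))
  spans <- gene_spans(models)
  spans$block_ids <- vapply(seq_len(nrow(spans)), function(i) {
    hit <- blocks$chromosome == spans$chromosome[i] &
      blocks$start <= spans$end[i] & blocks$end >= spans$start[i]
    paste(blocks$block_id[hit], collapse = ",")
  }, character(1))
  spans[, c("gene_id", "block_ids")]
}

#' Join all per-protein and per-gene calls into one family report
#'
#' One row per protein; calls missing for a protein (no gene model, no
#' pattern call, ...) are emitted with `NA` markers and a warning rather
#' than dropping the row.
#'
#' @param proteins data.frame from [read_fasta()].
#' @param binding_calls list of [classify_binding_group()] results.
#' @param subfamilies data.frame from [assign_subfamilies()].
#' @param profiles list of [zipper_profile()] objects.
#' @param pattern_calls list of [classify_intron_pattern()] results.
#' @param models list of [gene_model()] objects.
#' @param clusters list from [detect_tandem_clusters()].
#' @param blocks optional block table for [map_genes_to_blocks()].
#' @return a data.frame with one row per protein.
#' @export
join_report <- function(proteins, binding_calls = list(),
                        subfamilies = NULL, profiles = list(),
                        pattern_calls = list(), models = list(),
                        clusters = list(), blocks = NULL) {
  pick <- function(lst, field, ids, key = "protein_id") {
    nm <- vapply(lst, `[[`, "", key)
    vals <- vapply(lst, function(x) {
      v <- x[[field]]
      if (is.null(v) || length(v) == 0L) NA else v[[1L]]
    }, vector(mode = "character", 1L))
    vals[match(ids, nm)]
  }
  ids <- proteins$id
  out <- data.frame(protein_id = ids, stringsAsFactors = FALSE)
  out$group <- if (length(binding_calls)) {
    pick(binding_calls, "group", ids)
  } else NA_character_
  if (!is.null(subfamilies)) {
    m <- match(ids, subfamilies$protein_id)
    out$dimer_call <- subfamilies$dimer_call[m]
    out$subfamily <- subfamilies$subfamily[m]
  } else {
    out$dimer_call <- out$subfamily <- NA_character_
  }
  out$zipper_heptads <- if (length(profiles)) {
    nm <- vapply(profiles, `[[`, "", "protein_id")
    vapply(ids, function(i) {
      k <- match(i, nm)
      if (is.na(k)) NA_integer_ else profiles[[k]]$n_heptads
    }, integer(1))
  } else NA_integer_
  gene_of <- if (length(models)) {
    setNames(vapply(models, `[[`, "", "gene_id"),
             vapply(models, `[[`, "", "protein_id"))
  } else character(0)
  out$gene_id <- unname(gene_of[ids])
  out$intron_pattern <- if (length(pattern_calls)) {
    pick(pattern_calls, "pattern", out$gene_id, key = "gene_id")
  } else NA_character_
  cl_of <- character(0)
  for (k in seq_along(clusters)) {
    cl_of[clusters[[k]]$members] <- paste0("cluster", k)
  }
  out$tandem_cluster <- unname(cl_of[out$gene_id])
  if (!is.null(blocks) && length(models)) {
    bm <- map_genes_to_blocks(models, blocks)
    out$block_ids <- bm$block_ids[match(out$gene_id, bm$gene_id)]
  }
  n_missing <- sum(is.na(out$gene_id))
  if (n_missing > 0L) {
    warning(n_missing, " protein(s) without a gene model; ",
            "gene-level fields set to NA")
  }
  out
}
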