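# Independent oracles kept deliberately naive; they never share code with
# the implementation paths they check.

# base-by-base codon walk: assign every coding nucleotide (in transcript
# order) to a codon slot, then read off the fill state at each junction
codon_walk_oracle <- function(model, protein = NULL) {
  seg_len <- model$cds_segments[, "end"] - model$cds_segments[, "start"] + 1L
  slot <- 0L; codon <- 1L
  out <- list()
  for (k in seq_along(seg_len)) {
    for (b in seq_len(seg_len[k])) {
      slot <- slot + 1L
      if (slot == 3L) { slot <- 0L; codon <- codon + 1L }
    }
    if (k < length(seg_len)) {
      phase <- paste0("P", slot)
      pp <- codon  # codon being filled (slot>0) or the next codon (slot==0)
      res <- if (slot == 0L || is.null(protein)) NA_character_ else {
        substr(protein, pp, pp)
      }
      out[[k]] <- data.frame(intron_index = k, protein_position = pp,
                             phase = phase, interrupted_residue = res,
                             stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(intron_index = integer(0), protein_position = integer(0),
                      phase = character(0), interrupted_residue = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# exhaustive truth table for g-e' pair classification, built from charge
# signs rather than set logic
ge_truth_oracle <- function(g, e, acidic, basic) {
  sign_of <- function(r) if (r %in% basic) 1L else if (r %in% acidic) -1L else 0L
  sg <- sign_of(g); se <- sign_of(e)
  n <- sum(sg != 0L, se != 0L)
  completeness <- switch(n + 1L, "uncharged", "incomplete", "complete")
  pair_class <- "none"
  if (n == 2L) {
    pair_class <- if (sg < 0L && se < 0L) "acidic_repulsive"
      else if (sg > 0L && se > 0L) "basic_repulsive"
      else if (sg < 0L) "attract_ge" else "attract_eg"
  }
  list(completeness = completeness, pair_class = pair_class)
}

# dimerization rule restated directly from the propensity definitions
dimer_oracle <- function(classes_by_heptad) {
  att <- c("attract_ge", "attract_eg")
  rep_ <- c("acidic_repulsive", "basic_repulsive")
  cls <- classes_by_heptad
  h <- as.integer(names(cls))
  if (any(cls[h == 1L] %in% att) && !any(cls %in% rep_)) return("homodimer")
  complete <- cls %in% c(att, rep_)
  if (any(complete) && all(cls[complete] %in% rep_)) return("heterodimer")
  "both"
}

# O(n^3) average-linkage agglomeration over a precomputed distance matrix;
# returns merge heights and the cophenetic distance matrix
naive_upgma <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  dm <- d
  coph <- matrix(0, n, n)
  heights <- numeric(0)
  while (sum(active) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    idx <- which(active)
    for (a in idx) for (b in idx) {
      if (a < b && dm[a, b] < best_d) { best_d <- dm[a, b]; best <- c(a, b) }
    }
    a <- best[1L]; b <- best[2L]
    heights <- c(heights, best_d)
    for (x in clusters[[a]]) for (y in clusters[[b]]) {
      coph[x, y] <- coph[y, x] <- best_d
    }
    na <- length(clusters[[a]]); nb <- length(clusters[[b]])
    for (x in idx) {
      if (x == a || x == b) next
      dm[a, x] <- dm[x, a] <- (na * dm[a, x] + nb * dm[b, x]) / (na + nb)
    }
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    active[b] <- FALSE
  }
  dimnames(coph) <- dimnames(d)
  list(heights = sort(heights), cophenetic = coph)
}

# plain re-evaluation of the ddCt arithmetic, spreadsheet style
ddct_oracle <- function(ct, ref, cal) {
  genes <- setdiff(unique(ct$gene_id), ref)
  samples <- unique(ct$sample_id)
  mean_ct <- function(g, s) mean(ct$ct[ct$gene_id == g & ct$sample_id == s])
  out <- expand.grid(gene_id = genes, sample_id = samples,
                     stringsAsFactors = FALSE)
  out$fold <- NA_real_
  for (i in seq_len(nrow(out))) {
    g <- out$gene_id[i]; s <- out$sample_id[i]
    dct <- mean_ct(g, s) - mean_ct(ref, s)
    dct0 <- mean_ct(g, cal) - mean_ct(ref, cal)
    out$fold[i] <- 2^(-(dct - dct0))
  }
  out
}
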