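#' Specification for a synthetic bZIP family
#'
#' Describes the study conditions a generated family emulates: proteins
#' carrying exactly one planted N-x7-R/K-x9 anchor followed by a
#' heptad-periodic leucine zipper of 3-9 heptads with planted register
#' residues and g-e' pair classes, matched gene models with introns at
#' planted positions/phases realizing the conserved window patterns a-f,
#' a tandem-cluster chromosome layout, and a qRT-PCR Ct table with planted
#' log2 fold-change effects and Gaussian replicate noise.
#'
#' @param n_proteins family size.
#' @param seed integer seed; the seed fully determines every generated
#'   byte.
#' @param heptad_range inclusive range of zipper heptad counts.
#' @param asn_a_prob probability that any given heptad plants Asn at
#'   register a.
#' @param pair_class_probs named probabilities for the per-junction g-e'
#'   pair plan (classes `acidic_repulsive`, `basic_repulsive`,
#'   `attract_ge`, `attract_eg`, `incomplete`, `uncharged`).
#' @param tandem_fraction fraction of genes placed in tandem clusters of
#'   2-3 members.
#' @param n_expr_genes number of genes receiving Ct rows.
#' @param n_samples number of samples including the calibrator.
#' @param n_replicates biological replicates per (gene, sample).
#' @param effect_sd standard deviation of planted log2 fold effects.
#' @param ct_noise_sd Gaussian replicate noise on the Ct scale.
#' @param signature_templates optional list of `list(n_heptads,
#'   pair_classes)` templates cycled over the proteins, for planting a
#'   known number of distinct dimerization signatures.
#' @param plans optional explicit per-protein plan list overriding the
#'   sampled plans (validated before any output is produced).
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 200L, seed = 1L,
                           heptad_range = c(3L, 9L),
                           asn_a_prob = 0.3,
                           pair_class_probs = c(acidic_repulsive = 0.08,
                                                basic_repulsive = 0.08,
                                                attract_ge = 0.12,
                                                attract_eg = 0.12,
                                                incomplete = 0.35,
                                                uncharged = 0.25),
                           tandem_fraction = 0.3,
                           n_expr_genes = 20L, n_samples = 6L,
                           n_replicates = 3L, effect_sd = 2,
                           ct_noise_sd = 0.2,
                           signature_templates = NULL,
                           plans = NULL) {
  structure(as.list(environment()), class = "synthetic_spec")
}

# residues free of structural meaning: uncharged, not the anchor Asn, not
# the -10 substitute Ile, not the initiator/d-register Leu, not breaker Pro
FILL_SET <- c("A", "S", "T", "G", "Q", "V", "M", "F", "W", "Y", "H", "C")

PAIR_PLAN_CLASSES <- c("acidic_repulsive", "basic_repulsive",
                       "attract_ge", "attract_eg", "incomplete", "uncharged")

GROUP_KEYS <- c(X = "Q", VIII = "M", VII = "C", VI = "W", V = "Y",
                IV = "A", III = "G", II = "T")

PATTERNS <- c("a", "b", "c", "d", "e", "f_outside", "f_intronless")

rfill <- function(n) sample(FILL_SET, n, replace = TRUE)

sample_plan <- function(i, spec) {
  group <- sample(c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
                    "IX", "X", "XI"), 1L)
  if (!is.null(spec$signature_templates)) {
    tpl <- spec$signature_templates[[((i - 1L) %%
                                        length(spec$signature_templates)) + 1L]]
    n_heptads <- tpl$n_heptads
    pair_classes <- tpl$pair_classes
  } else {
    n_heptads <- sample(seq(spec$heptad_range[1L], spec$heptad_range[2L]), 1L)
    pair_classes <- sample(PAIR_PLAN_CLASSES, n_heptads - 1L, replace = TRUE,
                           prob = spec$pair_class_probs[PAIR_PLAN_CLASSES])
  }
  pattern <- sample(PATTERNS, 1L)
  leader_len <- sample(6:30, 1L)
  intron <- switch(pattern,
    a = list(paper_pos = sample(-18:-11, 1L), phase = 0L),
    b = list(paper_pos = sample(-10:-1, 1L), phase = 0L),
    c = list(paper_pos = c(sample(-18:-10, 1L), sample(-8:-1, 1L)),
             phase = c(0L, 0L)),
    d = list(paper_pos = sample(setdiff(-9:-1, -6L), 1L), phase = 2L,
             interrupted = "Q"),
    e = list(paper_pos = sample(setdiff(-9:-1, -6L), 1L), phase = 2L,
             interrupted = "R"),
    f_outside = NULL, f_intronless = NULL)
  list(
    id = sprintf("SYNbZIP%03d", i),
    group = group,
    leader_len = leader_len,
    n_heptads = n_heptads,
    asn_a_heptads = which(runif(n_heptads) < spec$asn_a_prob),
    pair_classes = pair_classes,
    incomplete_side = sample(c("g", "e"), max(n_heptads - 1L, 0L),
                             replace = TRUE),
    has_tail = runif(1) < 0.8,
    pattern = pattern,
    intron = intron,
    n_leader_introns = if (pattern == "f_outside") sample(1:2, 1L)
      else if (pattern == "f_intronless") 0L
      else sample(0:1, 1L),
    strand = sample(c("+", "-"), 1L)
  )
}

validate_plan <- function(plan) {
  if (!plan$group %in% c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
                         "IX", "X", "XI")) {
    stop("plan ", plan$id, ": unknown group ", plan$group)
  }
  if (plan$n_heptads < 1L) stop("plan ", plan$id, ": n_heptads must be >= 1")
  if (length(plan$pair_classes) != max(plan$n_heptads - 1L, 0L) ||
      !all(plan$pair_classes %in% PAIR_PLAN_CLASSES)) {
    stop("plan ", plan$id, ": invalid pair-class plan")
  }
  intr <- plan$intron
  if (!is.null(intr)) {
    if (any(intr$paper_pos < -18L | intr$paper_pos > -1L)) {
      stop("plan ", plan$id, ": window intron outside -18..-1")
    }
    if (!is.null(intr$interrupted)) {
      if (all(intr$phase == 0L)) {
        stop("plan ", plan$id, ": P0 intron cannot interrupt a residue")
      }
      # the planted basic/hinge residue must agree with the intron plan
      planted <- planted_basic_residue(plan, intr$paper_pos[1L])
      if (!is.null(planted) && planted != intr$interrupted) {
        stop("plan ", plan$id, ": intron interrupts ", intr$interrupted,
             " but position ", intr$paper_pos[1L], " is planted as ", planted)
      }
    }
  }
  invisible(plan)
}

# residue forced at a signed basic/hinge position by the plan, or NULL
planted_basic_residue <- function(plan, p) {
  if (p == -18L) return(if (plan$group == "IX") "K" else "N")
  if (p == -10L) return(if (plan$group == "XI") "I" else NULL)
  if (p == -6L) {
    return(if (plan$group %in% names(GROUP_KEYS)) GROUP_KEYS[[plan$group]]
           else "S")
  }
  NULL
}

build_protein_sequence <- function(plan) {
  basic <- rfill(18L)                      # signed positions -18..-1
  names(basic) <- as.character(-18:-1)
  basic["-18"] <- if (plan$group == "IX") "K" else "N"
  basic["-10"] <- if (plan$group == "XI") "I" else sample(c("R", "K"), 1L)
  basic["-6"] <- if (plan$group %in% names(GROUP_KEYS)) {
    GROUP_KEYS[[plan$group]]
  } else "S"
  intr <- plan$intron
  if (!is.null(intr) && !is.null(intr$interrupted)) {
    basic[as.character(intr$paper_pos[1L])] <- intr$interrupted
  }
  h <- plan$n_heptads
  zip <- rfill(7L * h)                     # positions +1..+7h
  reg_of <- rep(c("d", "e", "f", "g", "a", "b", "c"), h)
  zip[reg_of == "d"] <- "L"
  a_idx <- which(reg_of == "a")
  zip[a_idx] <- rfill(length(a_idx))
  heptad_of <- rep(seq_len(h), each = 7L)
  for (k in a_idx) {
    zip[k] <- if (heptad_of[k] %in% plan$asn_a_heptads) "N" else {
      sample(setdiff(FILL_SET, "N"), 1L)
    }
  }
  acid <- c("D", "E"); base <- c("K", "R")
  for (j in seq_len(max(h - 1L, 0L))) {
    g_pos <- 7L * (j - 1L) + 4L            # register g of heptad j
    e_pos <- 7L * j + 2L                   # register e of heptad j+1
    cls <- plan$pair_classes[j]
    gr <- switch(cls,
                 acidic_repulsive = sample(acid, 1L),
                 basic_repulsive = sample(base, 1L),
                 attract_ge = sample(acid, 1L),
                 attract_eg = sample(base, 1L),
                 incomplete = if (plan$incomplete_side[j] == "g") {
                   sample(c(acid, base), 1L)
                 } else sample(FILL_SET, 1L),
                 uncharged = sample(FILL_SET, 1L))
    er <- switch(cls,
                 acidic_repulsive = sample(acid, 1L),
                 basic_repulsive = sample(base, 1L),
                 attract_ge = sample(base, 1L),
                 attract_eg = sample(acid, 1L),
                 incomplete = if (plan$incomplete_side[j] == "e") {
                   sample(c(acid, base), 1L)
                 } else sample(FILL_SET, 1L),
                 uncharged = sample(FILL_SET, 1L))
    zip[g_pos] <- gr
    zip[e_pos] <- er
  }
  # unpaired boundary g/e registers stay uncharged fill
  tail_part <- if (plan$has_tail) c("P", rfill(sample(5:15, 1L))) else character(0)
  paste(c(rfill(plan$leader_len), basic, zip, tail_part), collapse = "")
}

build_gene_plan <- function(plan, prot_len) {
  asn_seq <- plan$leader_len + 1L
  cum <- integer(0)
  if (!is.null(plan$intron)) {
    seqpos <- asn_seq + plan$intron$paper_pos + 18L
    cum <- c(cum, 3L * (seqpos - 1L) + plan$intron$phase)
  }
  if (plan$n_leader_introns > 0L && plan$leader_len >= 4L) {
    at <- sample(2:(plan$leader_len - 1L), plan$n_leader_introns)
    cum <- c(cum, 3L * (at - 1L))          # P0 introns in the leader
  }
  cum <- sort(unique(cum))
  cds_total <- 3L * prot_len
  stopifnot(all(cum > 0L & cum < cds_total))
  exon_lens <- diff(c(0L, cum, cds_total))
  intron_lens <- if (length(cum)) sample(80:300, length(cum), replace = TRUE)
    else integer(0)
  list(exon_lens = exon_lens, intron_lens = intron_lens)
}

place_gene <- function(gstart, exon_lens, intron_lens, strand) {
  total <- sum(exon_lens) + sum(intron_lens)
  if (strand == "+") {
    pos <- gstart
    seg <- matrix(0L, length(exon_lens), 2L)
    for (k in seq_along(exon_lens)) {
      seg[k, ] <- c(pos, pos + exon_lens[k] - 1L)
      pos <- pos + exon_lens[k]
      if (k <= length(intron_lens)) pos <- pos + intron_lens[k]
    }
  } else {
    pos <- gstart + total - 1L
    seg <- matrix(0L, length(exon_lens), 2L)
    for (k in seq_along(exon_lens)) {
      seg[k, ] <- c(pos - exon_lens[k] + 1L, pos)
      pos <- pos - exon_lens[k]
      if (k <= length(intron_lens)) pos <- pos - intron_lens[k]
    }
  }
  list(segments = seg, span = total)
}

#' Generate a synthetic bZIP family with planted ground truth
#'
#' Emits protein records, matched gene models, a Ct table and a truth
#' object whose labels (anchor positions, binding group, per-junction g-e'
#' pair classes, dimerization call, intron pattern, tandem-cluster
#' membership, true log2 folds) describe exactly what was planted, so
#' pipeline recovery can be scored. All randomness flows from
#' `spec$seed`; the same seed reproduces byte-identical output files.
#'
#' Every plan is validated before any output is produced; an internally
#' inconsistent plan (for example a P2 intron said to interrupt Arg at a
#' position planted with another residue) aborts generation.
#'
#' @param spec a [synthetic_spec()].
#' @param dir optional output directory; when given, writes
#'   `family.fasta`, `family.gff3`, `ct_table.tsv` and `truth.tsv`.
#' @return list with `proteins` (data.frame), `models` (list of
#'   [gene_model()]), `ct` (data.frame), `truth` (list), `plans`, and
#'   `paths` when `dir` was given.
#' @export
generate_family <- function(spec = synthetic_spec(), dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)
  n <- spec$n_proteins
  plans <- if (!is.null(spec$plans)) spec$plans
    else lapply(seq_len(n), sample_plan, spec = spec)
  lapply(plans, validate_plan)
  n <- length(plans)

  proteins <- vector("list", n)
  for (i in seq_len(n)) {
    plan <- plans[[i]]
    for (try in 1:20) {
      s <- build_protein_sequence(plan)
      if (nrow(scan_basic_anchor(s)) == 1L) break
      if (try == 20L) stop("could not realize a single-anchor sequence for ",
                           plan$id)
    }
    proteins[[i]] <- data.frame(id = plan$id, sequence = s,
                                description = paste0("synthetic bZIP group ",
                                                     plan$group))
  }
  proteins <- do.call(rbind, proteins)

  # chromosome layout: clusters of 2-3 adjacent genes, singletons far apart
  idx <- seq_len(n)
  n_clustered <- floor(spec$tandem_fraction * n)
  cluster_sizes <- integer(0)
  while (sum(cluster_sizes) < n_clustered - 1L) {
    cluster_sizes <- c(cluster_sizes, sample(2:3, 1L))
  }
  cluster_of <- rep(NA_integer_, n)
  k <- 1L
  for (ci in seq_along(cluster_sizes)) {
    take <- k:min(k + cluster_sizes[ci] - 1L, n)
    cluster_of[take] <- ci
    k <- k + length(take)
  }
  chroms <- sprintf("chr%02d", ((idx - 1L) %% 12L) + 1L)
  # keep cluster members on one chromosome
  for (ci in unique(cluster_of[!is.na(cluster_of)])) {
    members <- which(cluster_of == ci)
    chroms[members] <- chroms[members[1L]]
  }
  chrom_cursor <- setNames(rep(1L, 12L), sprintf("chr%02d", 1:12))

  models <- vector("list", n)
  truth_rows <- vector("list", n)
  truth_pairs <- vector("list", n)
  for (i in seq_len(n)) {
    plan <- plans[[i]]
    prot_len <- nchar(proteins$sequence[i])
    gp <- build_gene_plan(plan, prot_len)
    chr <- chroms[i]
    prev_same_cluster <- i > 1L && !is.na(cluster_of[i]) &&
      identical(cluster_of[i], cluster_of[i - 1L])
    gap <- if (prev_same_cluster) sample(2000:20000, 1L)
      else sample(300000:600000, 1L)
    gstart <- chrom_cursor[[chr]] + gap
    placed <- place_gene(gstart, gp$exon_lens, gp$intron_lens, plan$strand)
    chrom_cursor[[chr]] <- gstart + placed$span
    gid <- sub("SYNbZIP", "SYNgene", plan$id)
    models[[i]] <- gene_model(gid, plan$id, chr, plan$strand,
                              placed$segments)
    asn_seq <- plan$leader_len + 1L
    truth_rows[[i]] <- data.frame(
      protein_id = plan$id, gene_id = gid,
      asn_pos = asn_seq, basic_pos = asn_seq + 8L,
      first_leu_pos = asn_seq + 18L,
      group = plan$group, n_heptads = plan$n_heptads,
      dimer_call = plan_dimer_call(plan$pair_classes),
      signature = plan_signature(plan),
      pattern = sub("_.*$", "", plan$pattern),
      intronless = (plan$pattern == "f_intronless"),
      intron_phases = paste(if (is.null(plan$intron)) character(0)
                            else paste0("P", plan$intron$phase),
                            collapse = ","),
      cluster = ifelse(is.na(cluster_of[i]), NA_character_,
                       paste0("cluster", cluster_of[i])),
      stringsAsFactors = FALSE
    )
    if (plan$n_heptads > 1L) {
      truth_pairs[[i]] <- data.frame(
        protein_id = plan$id,
        heptad = seq_len(plan$n_heptads - 1L),
        planted_class = plan$pair_classes,
        stringsAsFactors = FALSE
      )
    }
  }
  truth <- list(proteins = do.call(rbind, truth_rows),
                pairs = do.call(rbind, truth_pairs))

  # Ct table with planted log2 fold effects
  n_expr <- min(spec$n_expr_genes, n)
  expr_genes <- truth$proteins$gene_id[seq_len(n_expr)]
  samples <- c("S0", sprintf("S%d", seq_len(spec$n_samples - 1L)))
  l2f <- matrix(rnorm(n_expr * spec$n_samples, 0, spec$effect_sd),
                n_expr, spec$n_samples,
                dimnames = list(expr_genes, samples))
  l2f[, "S0"] <- 0
  baseline <- runif(n_expr, 22, 28)
  ct_rows <- list()
  for (gi in seq_len(n_expr)) {
    for (s in samples) {
      ct_rows[[length(ct_rows) + 1L]] <- data.frame(
        gene_id = expr_genes[gi], sample_id = s,
        replicate = seq_len(spec$n_replicates),
        ct = baseline[gi] - l2f[gi, s] +
          rnorm(spec$n_replicates, 0, spec$ct_noise_sd))
    }
  }
  for (s in samples) {
    ct_rows[[length(ct_rows) + 1L]] <- data.frame(
      gene_id = "REF1", sample_id = s, replicate = seq_len(spec$n_replicates),
      ct = 20 + rnorm(spec$n_replicates, 0, spec$ct_noise_sd))
  }
  ct <- do.call(rbind, ct_rows)
  rownames(ct) <- NULL
  truth$log2_fold <- l2f

  out <- list(proteins = proteins, models = models, ct = ct, truth = truth,
              plans = plans)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    p <- list(
      fasta = file.path(dir, "family.fasta"),
      gff3 = file.path(dir, "family.gff3"),
      ct = file.path(dir, "ct_table.tsv"),
      truth = file.path(dir, "truth.tsv")
    )
    write_fasta(proteins, p$fasta)
    write_gff3(models, p$gff3)
    write.table(ct, p$ct, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(truth$proteins, p$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$paths <- p
  }
  out
}

# truth-side dimer call from the planted per-junction classes
plan_dimer_call <- function(pair_classes) {
  attr1 <- length(pair_classes) >= 1L &&
    pair_classes[1L] %in% c("attract_ge", "attract_eg")
  any_rep <- any(pair_classes %in% c("acidic_repulsive", "basic_repulsive"))
  any_attr <- any(pair_classes %in% c("attract_ge", "attract_eg"))
  if (attr1 && !any_rep) return("homodimer")
  if (any_rep && !any_attr) return("heterodimer")
  "both"
}

plan_signature <- function(plan) {
  abbr <- c(acidic_repulsive = "AR", basic_repulsive = "BR",
            attract_ge = "+/-", attract_eg = "-/+",
            incomplete = "i", uncharged = "u")
  parts <- if (plan$n_heptads > 1L) {
    paste0(seq_len(plan$n_heptads - 1L), ":", abbr[plan$pair_classes])
  } else character(0)
  paste0("H", plan$n_heptads, "|", paste(parts, collapse = ","))
}

#' Generate decoy proteins without the bZIP anchor motif
#'
#' Decoy sequences are drawn from an alphabet excluding Asn and Lys, so no
#' N-x7-R/K-x9 anchor (including the tolerated -18 Lys substitute) can
#' occur; each sequence is additionally post-checked with
#' [scan_basic_anchor()] under widened substitute/initiator sets.
#'
#' @param n number of decoys.
#' @param seed integer seed.
#' @param length_range inclusive sequence length range.
#' @return a data.frame of protein records (possibly zero-row).
#' @export
generate_decoys <- function(n, seed = 1L, length_range = c(100L, 300L)) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  if (n == 0L) {
    return(data.frame(id = character(0), sequence = character(0),
                      description = character(0)))
  }
  alphabet <- setdiff(AA_LETTERS, c("N", "K"))
  wide <- residue_classes(initiators = c("L", "I", "V", "F", "M"))
  seqs <- vapply(seq_len(n), function(i) {
    repeat {
      len <- sample(length_range[1L]:length_range[2L], 1L)
      s <- paste(sample(alphabet, len, replace = TRUE), collapse = "")
      if (nrow(scan_basic_anchor(s, wide)) == 0L) return(s)
    }
  }, character(1))
  data.frame(id = sprintf("DECOY%03d", seq_len(n)), sequence = seqs,
             description = "synthetic non-bZIP decoy")
}
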