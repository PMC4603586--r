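#' Load and validate a pipeline run configuration
#'
#' A run configuration names the input paths (`fasta` required; `gff3`,
#' `rules`, `ct_table`, `blocks` optional) and analysis parameters
#' (`breakers`, `initiators`, `register_offset`, `denominator_mode`,
#' `max_intervening`, `max_gap_bp`, `histidine_basic`, `reference_gene`,
#' `calibrator_sample`, `out_dir`). Referenced paths must exist at
#' validation time; validation failures abort before any stage runs.
#'
#' @param config a YAML file path or a named list.
#' @return a validated list of class `run_config`.
#' @export
load_run_config <- function(config) {
  cfg <- if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else as.list(config)
  defaults <- list(gff3 = NULL, rules = NULL, ct_table = NULL, blocks = NULL,
                   breakers = "P", initiators = "L",
                   register_offset = 0L,
                   denominator_mode = "all_members",
                   max_intervening = 1L, max_gap_bp = 100000L,
                   histidine_basic = FALSE,
                   reference_gene = "REF1", calibrator_sample = "S0",
                   out_dir = "bzipr_out")
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (is.null(cfg$fasta)) stop("config must name a 'fasta' input")
  for (nm in c("fasta", "gff3", "rules", "ct_table", "blocks")) {
    if (!is.null(cfg[[nm]]) && !file.exists(cfg[[nm]])) {
      stop("config path for '", nm, "' does not exist: ", cfg[[nm]])
    }
  }
  if (!cfg$denominator_mode %in% c("all_members", "members_with_heptad")) {
    stop("invalid denominator_mode: ", cfg$denominator_mode)
  }
  cfg$breakers <- as_residues(cfg$breakers)
  cfg$initiators <- as_residues(cfg$initiators)
  structure(cfg, class = "run_config")
}

#' Run the full characterization pipeline
#'
#' Executes scan -> classify -> zipper -> dimer -> introns -> summarize in
#' order on the configured inputs and writes TSV reports plus a JSON run
#' manifest (config hash, package and R versions, input checksums) into
#' `out_dir`. Stage outputs are pure functions of the inputs and
#' configuration; rerunning with an identical configuration reproduces
#' identical reports. When a `ct_table` is configured, relative expression
#' and the clustering tree are written as well.
#'
#' @param config a `run_config`, YAML path or named list (see
#'   [load_run_config()]).
#' @return invisibly, a list with the in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else load_run_config(config)
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  tsv <- function(df, f) {
    write.table(df, out(f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rules <- if (!is.null(cfg$rules)) load_rule_table(cfg$rules) else {
    default_rule_table(residue_classes(breakers = cfg$breakers,
                                       initiators = cfg$initiators,
                                       histidine_basic = cfg$histidine_basic))
  }
  classes <- rules$classes

  # stage: scan
  proteins <- read_fasta(cfg$fasta)
  domains <- lapply(seq_len(nrow(proteins)), function(i) {
    find_bzip_domain(proteins[i, ], classes)
  })
  found <- vapply(domains, inherits, logical(1), "bzip_domain")
  tsv(data.frame(
    protein_id = proteins$id,
    asn_pos = vapply(domains, function(d) {
      if (inherits(d, "bzip_domain")) d$asn_pos else NA_integer_
    }, integer(1)),
    first_leu_pos = vapply(domains, function(d) {
      if (inherits(d, "bzip_domain")) d$first_leu_pos else NA_integer_
    }, integer(1)),
    zipper_length = vapply(domains, function(d) {
      if (inherits(d, "bzip_domain")) d$zipper_length else NA_integer_
    }, integer(1)),
    status = ifelse(found, "ok", "no_domain")
  ), "domains.tsv")
  doms <- domains[found]
  prots_found <- proteins[found, , drop = FALSE]

  # stage: classify
  calls <- lapply(doms, classify_binding_group, rules = rules)
  tsv(data.frame(
    protein_id = vapply(calls, `[[`, "", "protein_id"),
    group = vapply(calls, `[[`, "", "group"),
    anomalies = vapply(calls, function(x) {
      if (nrow(x$anomalies) == 0L) "" else {
        paste(sprintf("%d:%s", x$anomalies$position, x$anomalies$observed),
              collapse = ",")
      }
    }, character(1))
  ), "binding_groups.tsv")

  # stage: zipper + dimer
  profiles <- lapply(doms, zipper_profile, classes = classes,
                     offset = cfg$register_offset)
  pair_rows <- do.call(rbind, lapply(profiles, function(p) {
    if (nrow(p$pairs) == 0L) return(NULL)
    cbind(protein_id = p$protein_id, p$pairs)
  }))
  if (!is.null(pair_rows)) tsv(pair_rows, "zipper_pairs.tsv")
  subfam <- assign_subfamilies(profiles)
  tsv(subfam, "dimerization.tsv")

  # stage: introns
  models <- list(); pattern_calls <- list()
  if (!is.null(cfg$gff3)) {
    models <- read_gff3(cfg$gff3)
    dom_of <- setNames(doms, vapply(doms, `[[`, "", "protein_id"))
    seq_of <- setNames(prots_found$sequence, prots_found$id)
    for (m in models) {
      d <- dom_of[[m$protein_id]]
      if (is.null(d)) next
      intr <- introns_from_model(m, seq_of[[m$protein_id]])
      pattern_calls[[length(pattern_calls) + 1L]] <-
        classify_intron_pattern(m, d, intr)
    }
    tsv(data.frame(
      gene_id = vapply(pattern_calls, `[[`, "", "gene_id"),
      pattern = vapply(pattern_calls, `[[`, "", "pattern"),
      n_window_introns = vapply(pattern_calls, function(x) {
        nrow(x$window_introns)
      }, integer(1)),
      phases = vapply(pattern_calls, function(x) {
        paste(x$window_introns$phase, collapse = ",")
      }, character(1)),
      intronless = vapply(pattern_calls, `[[`, logical(1), "intronless_gene")
    ), "intron_patterns.tsv")
    cen <- pattern_census(pattern_calls)
    tsv(data.frame(pattern = c(names(cen$counts), "intronless"),
                   count = c(cen$counts, cen$intronless)),
        "intron_census.tsv")
  }

  # stage: summarize
  clusters <- if (length(models) >= 2L) {
    detect_tandem_clusters(models, max_intervening = cfg$max_intervening,
                           max_gap_bp = cfg$max_gap_bp)
  } else list()
  if (length(clusters)) {
    tsv(do.call(rbind, lapply(seq_along(clusters), function(k) {
      cl <- clusters[[k]]
      data.frame(cluster = paste0("cluster", k), chromosome = cl$chromosome,
                 members = paste(cl$members, collapse = ","),
                 start = cl$span[1L], end = cl$span[2L])
    })), "clusters.tsv")
  }
  comp <- composition(profiles, denominator_mode = cfg$denominator_mode,
                      classes = classes)
  tsv(do.call(rbind, lapply(names(comp$register_freq), function(r) {
    f <- comp$register_freq[[r]]
    if (!length(f)) return(NULL)
    data.frame(register = r, residue = names(f), frequency = as.numeric(f))
  })), "composition_registers.tsv")
  tsv(data.frame(heptad = as.integer(names(comp$asn_at_a_by_heptad)),
                 asn_at_a = as.numeric(comp$asn_at_a_by_heptad)),
      "composition_asn_at_a.tsv")
  tsv(comp$pair_freq_by_heptad, "composition_pairs.tsv")
  blocks <- if (!is.null(cfg$blocks)) {
    read.delim(cfg$blocks, stringsAsFactors = FALSE)
  } else NULL
  report <- suppressWarnings(join_report(
    proteins, calls, subfam, profiles, pattern_calls, models, clusters,
    blocks))
  tsv(report, "family_report.tsv")

  # stage: expression
  expression <- NULL
  if (!is.null(cfg$ct_table)) {
    ct <- read.delim(cfg$ct_table, stringsAsFactors = FALSE)
    folds <- ddct(ct, cfg$reference_gene, cfg$calibrator_sample)
    tsv(folds, "expression_folds.tsv")
    mat <- fold_matrix(folds)
    if (nrow(mat) >= 2L) {
      cl <- cluster_genes(mat)
      writeLines(merge_tree_newick(cl$hclust), out("expression_tree.nwk"))
      writeLines(cl$order, out("expression_leaf_order.txt"))
      expression <- list(folds = folds, clustering = cl)
    } else expression <- list(folds = folds, clustering = NULL)
  }

  manifest <- list(
    config_hash = config_hash(cfg),
    package_version = as.character(utils::packageVersion("bzipr")),
    r_version = R.version.string,
    inputs = input_checksums(cfg)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(proteins = proteins, domains = domains,
                 binding_calls = calls, profiles = profiles,
                 subfamilies = subfam, models = models,
                 pattern_calls = pattern_calls, clusters = clusters,
                 composition = comp, report = report,
                 expression = expression, out_dir = cfg$out_dir))
}

#' Reshape ddct output into a genes-by-samples log2 fold matrix
#'
#' @param folds data.frame from [ddct()].
#' @param value `"log2_fold"` (default) or `"fold"`.
#' @return numeric matrix with gene ids as rownames.
#' @export
fold_matrix <- function(folds, value = "log2_fold") {
  genes <- sort(unique(folds$gene_id))
  samples <- sort(unique(folds$sample_id))
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(folds$gene_id, genes), match(folds$sample_id, samples))] <-
    folds[[value]]
  m
}

config_hash <- function(cfg) {
  keep <- cfg[sort(setdiff(names(cfg), "out_dir"))]
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(keep), tf)
  unname(tools::md5sum(tf))
}

input_checksums <- function(cfg) {
  paths <- Filter(Negate(is.null),
                  cfg[c("fasta", "gff3", "rules", "ct_table", "blocks")])
  lapply(paths, function(p) unname(tools::md5sum(p)))
}
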