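#' Default DNA-binding specificity rule table
#'
#' bZIP DNA-binding specificity groups are defined by characteristic
#' residues in the basic and hinge regions (signed positions -18..-1).
#' The two substitutions stated for the tomato family are encoded directly:
#' group XI carries a hydrophobic Ile at -10 instead of Arg/Lys, and group
#' IX carries a Lys at the -18 anchor. The complete per-group residue table
#' is not public, so groups II-VIII and X ship with synthetic
#' single-position placeholder rules (a distinguishing residue at -6) and
#' group I acts as the generic N(-18)/R|K(-10) fallback, last in
#' precedence. The table is data: edit or replace it via
#' [load_rule_table()] without touching code.
#'
#' @param classes a [residue_classes()] object stored alongside the rules.
#' @return an object of class `rule_table`: list with `groups` (ordered
#'   list of `label` + named position rules) and `classes`.
#' @export
default_rule_table <- function(classes = residue_classes()) {
  grp <- function(label, ...) list(label = label, rules = list(...))
  groups <- list(
    grp("XI", `-18` = "N", `-10` = "I"),
    grp("IX", `-18` = "K", `-10` = c("R", "K")),
    grp("X",  `-18` = "N", `-10` = c("R", "K"), `-6` = "Q"),
    grp("VIII", `-18` = "N", `-10` = c("R", "K"), `-6` = "M"),
    grp("VII",  `-18` = "N", `-10` = c("R", "K"), `-6` = "C"),
    grp("VI",   `-18` = "N", `-10` = c("R", "K"), `-6` = "W"),
    grp("V",    `-18` = "N", `-10` = c("R", "K"), `-6` = "Y"),
    grp("IV",   `-18` = "N", `-10` = c("R", "K"), `-6` = "A"),
    grp("III",  `-18` = "N", `-10` = c("R", "K"), `-6` = "G"),
    grp("II",   `-18` = "N", `-10` = c("R", "K"), `-6` = "T"),
    grp("I",    `-18` = "N", `-10` = c("R", "K"))
  )
  validate_rule_table(structure(list(groups = groups, classes = classes),
                                class = "rule_table"))
}

validate_rule_table <- function(rt) {
  labels <- vapply(rt$groups, `[[`, "", "label")
  if (anyDuplicated(labels)) {
    stop("duplicate group labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  for (g in rt$groups) {
    pos <- as.integer(names(g$rules))
    if (any(is.na(pos)) || any(pos < -18L | pos > -1L)) {
      stop("group ", g$label, ": rule positions must lie in -18..-1, got ",
           paste(names(g$rules), collapse = ", "))
    }
    bad <- setdiff(unlist(g$rules), AA_LETTERS)
    if (length(bad)) {
      stop("group ", g$label, ": unknown residue letters ",
           paste(bad, collapse = ", "))
    }
  }
  rt
}

#' Load a binding-group rule table from a YAML config
#'
#' The config carries an ordered `groups` list (each entry: `label` plus a
#' `rules` mapping from signed position to allowed residues) and optional
#' `classes` overrides for [residue_classes()]. The shipped default lives
#' at `system.file("extdata", "binding_group_rules.yaml", package =
#' "bzipr")`.
#'
#' @param path YAML file path.
#' @return a validated `rule_table`.
#' @export
load_rule_table <- function(path) {
  if (!file.exists(path)) stop("rule table config not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$groups)) stop("rule table config lacks a 'groups' entry")
  cl_args <- y$classes %||% list()
  cl_args <- cl_args[names(cl_args) %in% names(formals(residue_classes))]
  cl_args <- lapply(cl_args, function(v) if (is.list(v)) unlist(v) else v)
  if (!is.null(cl_args$histidine_basic)) {
    cl_args$histidine_basic <- as.logical(cl_args$histidine_basic)
  }
  for (nm in setdiff(names(cl_args), "histidine_basic")) {
    cl_args[[nm]] <- as_residues(cl_args[[nm]])
  }
  classes <- do.call(residue_classes, cl_args)
  groups <- lapply(y$groups, function(g) {
    list(label = as.character(g$label),
         rules = lapply(g$rules, as_residues))
  })
  validate_rule_table(structure(list(groups = groups, classes = classes),
                                class = "rule_table"))
}

#' Write a rule table back to YAML
#'
#' Inverse of [load_rule_table()]; reloading the written file reproduces
#' the same rules.
#'
#' @param rules a `rule_table`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_rule_table <- function(rules, path) {
  y <- list(
    groups = lapply(rules$groups, function(g) {
      list(label = g$label, rules = lapply(g$rules, as.list))
    }),
    classes = list(breakers = as.list(rules$classes$breakers),
                   initiators = as.list(rules$classes$initiators),
                   sub18 = as.list(rules$classes$sub18),
                   sub10 = as.list(rules$classes$sub10),
                   histidine_basic = "H" %in% rules$classes$basic)
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Classify a domain into a DNA-binding specificity group
#'
#' Rules are evaluated in table order and the first group whose every
#' (position, allowed-residue-set) constraint is satisfied wins; specific
#' groups therefore precede the generic fallback. Deviations of the -18
#' residue from Asn or of the -10 residue from Arg/Lys are always reported
#' as anomalies, whatever group matches.
#'
#' @param domain a [build_domain()] result.
#' @param protein sequence or protein record (defaults to the sequence
#'   stored in the domain).
#' @param rules a `rule_table`.
#' @return a list of class `binding_call` with `protein_id`, `group`
#'   (label or `"unassigned"`), `matched_rule` (index into the table or
#'   `NA`), and `anomalies` (data.frame of position/expected/observed).
#' @export
classify_binding_group <- function(domain, protein = NULL,
                                   rules = default_rule_table()) {
  stopifnot(inherits(domain, "bzip_domain"))
  seq <- if (is.null(protein)) domain$sequence else protein_sequence(protein)
  res_at <- function(p) substring(seq, paper_to_seq(domain, p),
                                  paper_to_seq(domain, p))
  group <- "unassigned"; matched <- NA_integer_
  for (k in seq_along(rules$groups)) {
    g <- rules$groups[[k]]
    ok <- all(vapply(names(g$rules), function(pn) {
      res_at(as.integer(pn)) %in% g$rules[[pn]]
    }, logical(1)))
    if (ok) { group <- g$label; matched <- k; break }
  }
  anomalies <- data.frame(position = integer(0), expected = character(0),
                          observed = character(0), stringsAsFactors = FALSE)
  r18 <- res_at(-18L); r10 <- res_at(-10L)
  if (!r18 %in% "N") {
    anomalies <- rbind(anomalies, data.frame(position = -18L, expected = "N",
                                             observed = r18))
  }
  if (!r10 %in% c("R", "K")) {
    anomalies <- rbind(anomalies, data.frame(position = -10L,
                                             expected = "R/K", observed = r10))
  }
  structure(list(protein_id = domain$protein_id, group = group,
                 matched_rule = matched, anomalies = anomalies),
            class = "binding_call")
}

#' @export
print.binding_call <- function(x, ...) {
  cat(sprintf("<binding_call> %s -> group %s (%d anomalies)\n",
              x$protein_id, x$group, nrow(x$anomalies)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# YAML 1.1 resolves bare Y/N as booleans; residue vectors written without
# quoting come back logical, so undo that before treating them as letters
as_residues <- function(x) {
  if (is.list(x)) x <- unlist(x)
  if (is.logical(x)) x <- ifelse(x, "Y", "N")
  as.character(x)
}
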