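# Classification of amino-acid variants by their effect on sumoylation.
#
# Types:
#   I(+) / I(-) : the substitution itself creates / removes a sumoylated
#                 lysine (the variant position is the site);
#   II(+) / II(-): a substitution within +/- flank of a lysine switches that
#                 lysine's sumoylation status on / off;
#   III         : a within-window substitution at a non-lysine position
#                 while the lysine stays sumoylated - interpreted as a
#                 change of the recognition context (e.g. which E3 ligase
#                 recognises the site) rather than of the site itself;
#   none        : no lysine whose window overlaps the variant changes
#                 status.
#
# Rule order is fixed: the variant position is examined first (Type I),
# then neighbouring lysines.  When several neighbouring lysines are
# affected, the call with the largest |mut - wt| probability shift is
# reported and all candidates are kept for audit.  Experimentally annotated
# evidence (site tables, curated per-variant effects) takes precedence over
# model predictions for the same lysine.

AMVR_TYPES <- c("I+", "I-", "II+", "II-", "III", "IV", "none")

resolve_level <- function(ensemble, level) {
  if (is.null(ensemble)) return(list(name = as.character(level), cutoff = NA_real_))
  nm <- if (is.numeric(level)) format(level) else as.character(level)
  if (!nm %in% names(ensemble$thresholds)) {
    stop(sprintf("unknown specificity level '%s'", nm), call. = FALSE)
  }
  list(name = nm, cutoff = ensemble$thresholds[[nm]])
}

# probabilities for lysine positions of a sequence under the ensemble
predict_positions <- function(ensemble, id, sequence, positions, flank) {
  if (!length(positions)) return(numeric(0))
  frags <- data.frame(protein_id = id, center_pos = positions,
                      residues = vapply(positions, function(p)
                        extract_fragment(sequence, p, flank), ""),
                      stringsAsFactors = FALSE)
  enc <- ensemble$encoding
  fm <- assemble_features(frags, encoders = enc$encoders, k_set = enc$k_set,
                          flank = enc$flank)
  predict(ensemble, fm$x)$probability
}

#' Classify a single variant by its effect on sumoylation
#'
#' Status of each lysine whose window overlaps the variant is determined
#' before and after the substitution, either from annotation (a site table
#' plus an optional curated per-variant `effect` of `"removed"`,
#' `"created"` or `"retained"` at `variant$site_pos`) or from the trained
#' ensemble at the chosen specificity level.  See the rule summary at the
#' top of this file.
#'
#' @param record one protein record (row of a protein-record data.frame).
#' @param variant list/row with `position`, `wt_aa`, `mut_aa` and optionally
#'   `site_pos`, `effect`, `class_label`.
#' @param sites optional site table (annotated evidence).
#' @param ensemble optional trained `sumo_ensemble` (predicted evidence).
#' @param flank window flank (10).
#' @param level specificity level name (`"default"`, `"0.9"`, ...) or number.
#' @return One-row data.frame: `protein_id, position, wt_aa, mut_aa, type,
#'   affected_site, wt_probability, mut_probability, level, evidence,
#'   class_label`, with the full candidate list in
#'   `attr(, "candidates")`.
#' @export
classify_variant <- function(record, variant, sites = NULL, ensemble = NULL,
                             flank = 10L, level = "default") {
  lv <- resolve_level(ensemble, level)
  mut_record <- apply_variant(record, variant)
  pos <- as.integer(variant$position)
  wt_seq <- record$sequence; mut_seq <- mut_record$sequence
  wt_res <- strsplit(wt_seq, "")[[1]]; mut_res <- strsplit(mut_seq, "")[[1]]
  ann <- if (is.null(sites)) integer(0) else
    sites$position[sites$protein_id == record$id]
  eff <- NULL; target <- NA_integer_
  if (!is.null(variant$effect) && !is.na(variant$effect) &&
      nzchar(variant$effect)) {
    eff <- as.character(variant$effect)
    target <- as.integer(variant$site_pos)
  }

  cand <- sort(unique(c(which(wt_res == "K"), which(mut_res == "K"))))
  cand <- cand[abs(cand - pos) <= flank]

  p_wt <- p_mut <- rep(NA_real_, length(cand))
  if (!is.null(ensemble)) {
    wt_k <- cand[wt_res[cand] == "K"]
    mut_k <- cand[mut_res[cand] == "K"]
    p_wt[match(wt_k, cand)] <-
      predict_positions(ensemble, record$id, wt_seq, wt_k, flank)
    p_mut[match(mut_k, cand)] <-
      predict_positions(ensemble, record$id, mut_seq, mut_k, flank)
  }

  status <- function(l, i, side) {
    res <- if (side == "wt") wt_res else mut_res
    if (res[l] != "K") return(list(on = FALSE, annotated = FALSE))
    if (!is.na(target) && l == target && !is.null(eff)) {
      on <- if (side == "wt") eff %in% c("removed", "retained") else
        eff %in% c("created", "retained")
      return(list(on = on, annotated = TRUE))
    }
    if (side == "wt" && l %in% ann) return(list(on = TRUE, annotated = TRUE))
    p <- if (side == "wt") p_wt[i] else p_mut[i]
    if (!is.na(p)) return(list(on = p >= lv$cutoff, annotated = FALSE))
    # annotation-only route: no information implies unchanged/off
    if (side == "mut" && l %in% ann) return(list(on = TRUE, annotated = TRUE))
    list(on = FALSE, annotated = FALSE)
  }

  rows <- list(); k <- 0L
  for (i in seq_along(cand)) {
    l <- cand[i]
    swt <- status(l, i, "wt"); smut <- status(l, i, "mut")
    type <- "none"
    if (l == pos) {
      if (variant$wt_aa == "K" && swt$on && variant$mut_aa != "K") {
        type <- "I-"
      } else if (variant$mut_aa == "K" && smut$on) {
        type <- "I+"
      }
    } else {
      if (!swt$on && smut$on) type <- "II+"
      else if (swt$on && !smut$on) type <- "II-"
      else if (swt$on && smut$on) type <- "III"
    }
    if (type != "none") {
      k <- k + 1L
      rows[[k]] <- data.frame(
        affected_site = l, type = type,
        wt_probability = p_wt[i], mut_probability = p_mut[i],
        annotated = swt$annotated || smut$annotated,
        stringsAsFactors = FALSE)
    }
  }

  base <- data.frame(
    protein_id = record$id, position = pos,
    wt_aa = variant$wt_aa, mut_aa = variant$mut_aa,
    type = "none", affected_site = NA_integer_,
    wt_probability = NA_real_, mut_probability = NA_real_,
    level = lv$name, evidence = NA_character_,
    class_label = if (!is.null(variant$class_label) &&
                      !is.na(variant$class_label))
      as.character(variant$class_label) else "unclassified",
    stringsAsFactors = FALSE)
  if (k == 0L) return(structure(base, candidates = NULL))

  cands <- do.call(rbind, rows)
  delta <- abs(cands$mut_probability - cands$wt_probability)
  pick <- if (any(cands$type %in% c("I-", "I+"))) {
    # rule order: the variant position itself takes precedence
    which(cands$type %in% c("I-", "I+"))[1]
  } else if (all(is.na(delta))) {
    if (!is.na(target) && target %in% cands$affected_site)
      which(cands$affected_site == target)[1] else 1L
  } else which.max(ifelse(is.na(delta), -Inf, delta))
  base$type <- cands$type[pick]
  base$affected_site <- cands$affected_site[pick]
  base$wt_probability <- cands$wt_probability[pick]
  base$mut_probability <- cands$mut_probability[pick]
  base$evidence <- if (cands$annotated[pick]) "annotated" else "predicted"
  structure(base, candidates = cands)
}

#' Classify a table of variants
#'
#' Applies [classify_variant()] to every variant at each requested
#' specificity level.  Variants referencing unknown protein ids are skipped
#' with a warning.
#'
#' @param records protein-record data.frame.
#' @param variants variant table (see [read_variant_table()]).
#' @param sites optional site table.
#' @param ensemble optional trained ensemble.
#' @param levels character/numeric vector of levels.
#' @param flank window flank.
#' @return `list(calls, sweep)`: `calls` has one row per variant x level;
#'   `sweep` is the per-level type-count table from [sweep_report()].
#' @export
classify_batch <- function(records, variants, sites = NULL, ensemble = NULL,
                           levels = "default", flank = 10L) {
  unknown <- setdiff(unique(variants$protein_id), records$id)
  if (length(unknown)) {
    warning(sprintf("skipping variants of unknown protein(s): %s",
                    paste(unknown, collapse = ",")), call. = FALSE)
    variants <- variants[!variants$protein_id %in% unknown, , drop = FALSE]
  }
  out <- list(); k <- 0L
  for (lv in levels) {
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, , drop = FALSE]
      rec <- records[records$id == v$protein_id, , drop = FALSE][1, ]
      k <- k + 1L
      out[[k]] <- classify_variant(rec, v, sites = sites,
                                   ensemble = ensemble, flank = flank,
                                   level = lv)
    }
  }
  calls <- if (k == 0L) {
    data.frame(protein_id = character(), position = integer(),
               wt_aa = character(), mut_aa = character(), type = character(),
               affected_site = integer(), wt_probability = numeric(),
               mut_probability = numeric(), level = character(),
               evidence = character(), class_label = character(),
               stringsAsFactors = FALSE)
  } else do.call(rbind, out)
  rownames(calls) <- NULL
  list(calls = calls, sweep = sweep_report(calls, levels = as.character(levels)))
}

#' Per-level type counts (threshold sweep report)
#'
#' @param calls a calls data.frame from [classify_batch()].
#' @param levels levels to report (default: those present in `calls`).
#' @return One row per level with counts of each type, the Type I and
#'   Type II subtotals and the overall total.
#' @export
sweep_report <- function(calls, levels = unique(calls$level)) {
  rows <- lapply(levels, function(lv) {
    cc <- calls[calls$level == lv, , drop = FALSE]
    n <- function(t) sum(cc$type == t)
    data.frame(level = lv,
               type_I_plus = n("I+"), type_I_minus = n("I-"),
               type_I_all = n("I+") + n("I-"),
               type_II_plus = n("II+"), type_II_minus = n("II-"),
               type_II_all = n("II+") + n("II-"),
               type_III = n("III"),
               total = sum(cc$type != "none"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Percentage of a count over a denominator, two decimals
#'
#' @param count,denominator non-negative numbers (`denominator > 0`).
#' @return `round(100 * count / denominator, 2)`.
#' @export
pct <- function(count, denominator) {
  stopifnot(denominator > 0)
  round(100 * count / denominator, 2)
}

#' Per-class summary of variant calls with enrichment tests
#'
#' Counts calls of each type within the disease / polymorphism /
#' unclassified classes, reports each count as a percentage of its class
#' denominator (two decimals), and tests disease vs polymorphism enrichment
#' per type with a 2 x 2 contingency test.
#'
#' @param calls calls data.frame (one level), or a pre-counted data.frame
#'   with columns `type`, `disease`, `polymorphism`, `unclassified`.
#' @param denominators named numeric vector with elements `disease`,
#'   `polymorphism`, `unclassified` (total variants per class).
#' @param test `"fisher"` (default) or `"chi2"`.
#' @return Data.frame with one row per type plus an `All` row: counts,
#'   percentages and the per-type p-value; the test used is recorded in
#'   `attr(, "method")`.
#' @export
summarize_by_class <- function(calls, denominators,
                               test = c("fisher", "chi2")) {
  test <- match.arg(test)
  stopifnot(all(c("disease", "polymorphism", "unclassified") %in%
                  names(denominators)))
  types <- c("I+", "I-", "II+", "II-", "III")
  if (all(c("disease", "polymorphism") %in% names(calls))) {
    counts <- calls                      # pre-counted table
    counts <- counts[match(types, counts$type), , drop = FALSE]
    counts$type <- types
    counts[is.na(counts)] <- 0
  } else {
    lab <- ifelse(calls$class_label %in% c("disease", "polymorphism"),
                  calls$class_label, "unclassified")
    counts <- data.frame(type = types,
                         disease = vapply(types, function(t)
                           sum(calls$type == t & lab == "disease"), 0),
                         polymorphism = vapply(types, function(t)
                           sum(calls$type == t & lab == "polymorphism"), 0),
                         unclassified = vapply(types, function(t)
                           sum(calls$type == t & lab == "unclassified"), 0),
                         stringsAsFactors = FALSE)
  }
  all_row <- data.frame(type = "All",
                        disease = sum(counts$disease),
                        polymorphism = sum(counts$polymorphism),
                        unclassified = sum(counts$unclassified),
                        stringsAsFactors = FALSE)
  tab <- rbind(counts[, c("type", "disease", "polymorphism", "unclassified")],
               all_row)
  tab$disease_pct <- pct(tab$disease, denominators[["disease"]])
  tab$polymorphism_pct <- pct(tab$polymorphism, denominators[["polymorphism"]])
  tab$unclassified_pct <- pct(tab$unclassified, denominators[["unclassified"]])
  tab$p.value <- vapply(seq_len(nrow(tab)), function(i) {
    d <- tab$disease[i]; p <- tab$polymorphism[i]
    m <- matrix(c(d, denominators[["disease"]] - d,
                  p, denominators[["polymorphism"]] - p),
                nrow = 2, byrow = TRUE)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(NA_real_)
    if (test == "fisher") fisher_exact_2x2(m)$p.value else
      pearson_chi2(m)$p.value
  }, 0)
  attr(tab, "method") <- test
  tab
}

#' Curated literature examples of sumoylation-affecting variants
#'
#' Loads the package's curated table of published substitutions with known
#' effects on specific sumoylation sites (site removed, created or retained
#' with an altered recognition context), and builds synthetic scaffold
#' sequences around the published local peptides so the variants can be run
#' through [classify_variant()].  Scaffolds are padded with `'X'` outside
#' the published window; they are stand-ins for the full-length proteins,
#' which are not shipped.
#'
#' @return `list(records, sites, variants)`; `variants` carries the curated
#'   `effect` and `site_pos` columns plus the group reported in the source
#'   literature (`reported_type`, not used by the classifier).
#' @export
curated_variant_set <- function() {
  path <- system.file("extdata", "curated_sumoamvr_variants.tsv",
                      package = "sumovar")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  flank <- 10L
  ids <- sprintf("%s.%d", tab$protein_id, seq_len(nrow(tab)))
  seqs <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    parsed <- parse_variant_token(tab$token[i])
    len <- max(tab$site_pos[i], parsed$position) + flank
    chars <- rep("X", len)
    pep <- strsplit(tab$peptide[i], "")[[1]]
    start <- max(1L, tab$site_pos[i] - flank)
    idx <- start + seq_along(pep) - 1L
    ok <- idx <= len
    chars[idx[ok]] <- pep[ok]
    chars[tab$site_pos[i]] <- "K"        # annotated site is a lysine
    chars[parsed$position] <- parsed$wt_aa  # token is authoritative
    seqs[i] <- paste(chars, collapse = "")
  }
  records <- data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
  sites <- data.frame(protein_id = ids, position = tab$site_pos,
                      evidence = "annotated", stringsAsFactors = FALSE)
  # for created sites the lysine exists only post-mutation: not a wild-type
  # annotation
  sites <- sites[tab$effect != "created", , drop = FALSE]
  parsed <- lapply(tab$token, parse_variant_token)
  variants <- data.frame(
    protein_id = ids,
    accession = tab$protein_id,
    token = tab$token,
    position = vapply(parsed, `[[`, 1L, "position"),
    wt_aa = vapply(parsed, `[[`, "", "wt_aa"),
    mut_aa = vapply(parsed, `[[`, "", "mut_aa"),
    site_pos = tab$site_pos,
    effect = tab$effect,
    reported_type = tab$reported_type,
    class_label = "unclassified",
    stringsAsFactors = FALSE)
  list(records = records, sites = sites, variants = variants)
}
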