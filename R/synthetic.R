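# Synthetic proteomes, site annotations, variant sets and profile files
# with known ground truth, so every pipeline stage is testable offline.

#' Configuration of the synthetic proteome generator
#'
#' The generator emulates a proteome in which planted sumoylated lysines
#' carry the PsiKxE consensus (large hydrophobic residue at -1, glutamate
#' at +2) with probability `motif_q`, against background fragments drawn
#' from `background` residue frequencies.  Defaults: 100 proteins of
#' uniform length 100-400 (roughly 1500 lysine fragments in total), 200
#' planted sites, and `motif_q = 0.8` - a realistic consensus fidelity,
#' since a substantial minority of experimentally mapped sumoylation sites
#' deviate from the consensus.
#'
#' @param n_proteins number of proteins.
#' @param length_range `c(min, max)` uniform protein length.
#' @param n_positive_sites number of planted sumoylation sites.
#' @param motif_q probability that a planted site carries the full
#'   consensus context.
#' @param background named residue frequency vector (default uniform over
#'   the 20 canonical residues).
#' @param variant_counts named counts of variants to construct per intended
#'   type (`I_minus`, `I_plus`, `II_minus`, `II_plus`, `III`).
#' @param class_mix named mixing proportions for the
#'   disease/polymorphism/unclassified class labels.
#' @param flank window flank.
#' @param seed integer seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_proteins = 100L, length_range = c(100L, 400L),
                         n_positive_sites = 200L, motif_q = 0.8,
                         background = NULL,
                         variant_counts = c(I_minus = 20L, I_plus = 20L,
                                            II_minus = 20L, II_plus = 20L,
                                            III = 20L),
                         class_mix = c(disease = 0.35, polymorphism = 0.55,
                                       unclassified = 0.10),
                         flank = 10L, seed = 1L) {
  stopifnot(motif_q >= 0, motif_q <= 1, n_positive_sites >= 0)
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  stopifnot(all(names(background) %in% AA_ALPHABET))
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 n_positive_sites = as.integer(n_positive_sites),
                 motif_q = motif_q, background = background,
                 variant_counts = variant_counts, class_mix = class_mix,
                 flank = as.integer(flank), seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic proteome with planted sumoylation sites
#'
#' @param config a [synth_config()].
#' @return `list(records, sites, truth, config)`: `truth` records every
#'   planted site and whether it carries the full consensus context.
#' @export
generate_proteome <- function(config = synth_config()) {
  set.seed(config$seed)
  lo <- max(config$length_range[1], 2L * config$flank + 1L)  # length floor
  hi <- max(config$length_range[2], lo)
  lens <- sample(lo:hi, config$n_proteins, replace = TRUE)
  ids <- sprintf("SYN%04d", seq_len(config$n_proteins))
  res <- lapply(lens, function(n)
    sample(names(config$background), n, replace = TRUE,
           prob = config$background))

  # choose planted positions: full windows inside the sequence, >= 5 apart
  pool <- do.call(rbind, lapply(seq_along(lens), function(i) {
    p <- (config$flank + 1L):(lens[i] - config$flank)
    data.frame(protein = i, pos = p)
  }))
  pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
  chosen <- list(); k <- 0L
  taken <- vector("list", config$n_proteins)
  for (r in seq_len(nrow(pool))) {
    if (k >= config$n_positive_sites) break
    i <- pool$protein[r]; p <- pool$pos[r]
    if (any(abs(taken[[i]] - p) < 5L)) next
    taken[[i]] <- c(taken[[i]], p)
    k <- k + 1L
    chosen[[k]] <- c(i, p)
  }
  if (k < config$n_positive_sites) {
    warning(sprintf("only %d of %d sites could be planted", k,
                    config$n_positive_sites), call. = FALSE)
  }
  truth <- data.frame(protein_id = character(k), position = integer(k),
                      has_motif = logical(k), stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    i <- chosen[[j]][1]; p <- chosen[[j]][2]
    res[[i]][p] <- "K"
    with_motif <- stats::runif(1) < config$motif_q
    if (with_motif) {
      res[[i]][p - 1L] <- sample(PSI_RESIDUES, 1L)
      res[[i]][p + 2L] <- "E"
    }
    truth$protein_id[j] <- ids[i]
    truth$position[j] <- p
    truth$has_motif[j] <- with_motif
  }
  records <- data.frame(id = ids,
                        sequence = vapply(res, paste, "", collapse = ""),
                        stringsAsFactors = FALSE)
  sites <- data.frame(protein_id = truth$protein_id,
                      position = truth$position,
                      evidence = rep("annotated", k), stringsAsFactors = FALSE)
  list(records = records, sites = sites, truth = truth, config = config)
}

one_to_three <- function(aa) {
  names(AA_THREE_TO_ONE)[match(aa, AA_THREE_TO_ONE)]
}

#' Construct variants with known ground-truth effect types
#'
#' Builds, by direct construction on the generated proteome, variants whose
#' intended classification is known: site-removing substitutions at planted
#' lysines (`I_minus`), site-creating substitutions inside consensus
#' contexts (`I_plus`), consensus-destroying substitutions next to planted
#' sites (`II_minus`), consensus-completing substitutions next to
#' background lysines (`II_plus`) and consensus-preserving within-window
#' substitutions (`III`).  A shortfall in any category is reported with a
#' warning, never silently.
#'
#' @param proteome output of [generate_proteome()].
#' @param config the same [synth_config()] (for counts, labels, seed).
#' @return `list(variants, truth)`: `variants` is a variant table with
#'   `token` and `class_label`; `truth` adds `intended_type` and `site_pos`.
#' @export
generate_variants <- function(proteome, config = proteome$config) {
  set.seed(config$seed + 1L)
  records <- proteome$records; truth <- proteome$truth
  flank <- config$flank
  chars <- lapply(records$sequence, function(s) strsplit(s, "")[[1]])
  names(chars) <- records$id
  planted_key <- paste(truth$protein_id, truth$position)
  rows <- list(); k <- 0L
  add <- function(id, pos, wt, mut, type, site) {
    k <<- k + 1L
    rows[[k]] <<- data.frame(protein_id = id, position = pos, wt_aa = wt,
                             mut_aa = mut,
                             token = paste0(one_to_three(wt), pos,
                                            one_to_three(mut)),
                             intended_type = type, site_pos = site,
                             stringsAsFactors = FALSE)
  }
  want <- config$variant_counts
  short <- c()

  # I(-): K -> R at planted sites
  idx <- sample(seq_len(nrow(truth)))
  n <- min(want[["I_minus"]], length(idx))
  for (j in utils::head(idx, n)) {
    add(truth$protein_id[j], truth$position[j], "K", "R", "I-",
        truth$position[j])
  }
  if (n < want[["I_minus"]]) short <- c(short, I_minus = want[["I_minus"]] - n)

  # II(-): destroy the E(+2) (or Psi(-1)) of a planted consensus site
  idx <- sample(which(truth$has_motif))
  n <- min(want[["II_minus"]], length(idx))
  for (j in utils::head(idx, n)) {
    id <- truth$protein_id[j]; p <- truth$position[j]
    wt <- chars[[id]][p + 2L]
    if (wt == "E") add(id, p + 2L, "E", "G", "II-", p)
    else add(id, p - 1L, chars[[id]][p - 1L], "A", "II-", p)
  }
  if (n < want[["II_minus"]]) short <- c(short, II_minus = want[["II_minus"]] - n)

  # III: within-window substitution preserving K, Psi(-1) and E(+2)
  idx <- sample(which(truth$has_motif))
  n <- 0L
  for (j in idx) {
    if (n >= want[["III"]]) break
    id <- truth$protein_id[j]; p <- truth$position[j]
    offs <- setdiff(-flank:flank, c(-1L, 0L, 2L))
    offs <- sample(offs)
    done <- FALSE
    for (o in offs) {
      q <- p + o
      wt <- chars[[id]][q]
      if (wt %in% c("K", "X")) next
      mut <- sample(setdiff(AA_ALPHABET, c(wt, "K")), 1L)
      add(id, q, wt, mut, "III", p)
      done <- TRUE
      break
    }
    if (done) n <- n + 1L
  }
  if (n < want[["III"]]) short <- c(short, III = want[["III"]] - n)

  # candidate scan over all proteins for I(+) and II(+) contexts
  near_planted <- function(id, pos) {
    any(truth$protein_id == id & abs(truth$position - pos) <= flank)
  }
  iplus <- list(); iiplus <- list()
  for (i in seq_len(nrow(records))) {
    id <- records$id[i]; cc <- chars[[id]]; L <- length(cc)
    for (p in (flank + 1L):(L - flank)) {
      if (near_planted(id, p)) next
      psi <- cc[p - 1L] %in% PSI_RESIDUES
      if (cc[p] != "K" && psi && cc[p + 2L] == "E") {
        iplus[[length(iplus) + 1L]] <- c(i, p)
      }
      if (cc[p] == "K" && psi && !cc[p + 2L] %in% c("E", "K")) {
        iiplus[[length(iiplus) + 1L]] <- c(i, p)
      }
    }
  }
  # I(+): mutate the centre of a consensus context to K
  if (length(iplus)) iplus <- iplus[sample.int(length(iplus))]
  n <- min(want[["I_plus"]], length(iplus))
  for (v in utils::head(iplus, n)) {
    id <- records$id[v[1]]; p <- v[2]
    add(id, p, chars[[id]][p], "K", "I+", p)
  }
  if (n < want[["I_plus"]]) short <- c(short, I_plus = want[["I_plus"]] - n)

  # II(+): complete a near-miss consensus next to a background lysine
  if (length(iiplus)) iiplus <- iiplus[sample.int(length(iiplus))]
  n <- min(want[["II_plus"]], length(iiplus))
  for (v in utils::head(iiplus, n)) {
    id <- records$id[v[1]]; p <- v[2]
    add(id, p + 2L, chars[[id]][p + 2L], "E", "II+", p)
  }
  if (n < want[["II_plus"]]) short <- c(short, II_plus = want[["II_plus"]] - n)

  if (length(short)) {
    warning(sprintf("variant count shortfall: %s",
                    paste(names(short), short, sep = "=", collapse = ", ")),
            call. = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$class_label <- sample(names(config$class_mix), nrow(tab),
                            replace = TRUE, prob = config$class_mix)
  tab$annotation <- ""
  variants <- tab[, c("protein_id", "token", "position", "wt_aa", "mut_aa",
                      "class_label", "annotation")]
  truth_out <- tab[, c("protein_id", "token", "position", "intended_type",
                       "site_pos", "class_label")]
  list(variants = variants, truth = truth_out)
}

#' Attach ground-truth site effects to a generated variant table
#'
#' Adds the `site_pos` and `effect` columns (`removed`/`created`/`retained`)
#' implied by each variant's intended type, so the table can be classified
#' annotation-driven exactly like a curated literature set.
#'
#' @param variants,truth the two tables returned by [generate_variants()].
#' @return The variant table with `site_pos` and `effect` columns.
#' @export
annotate_variants_with_truth <- function(variants, truth) {
  key <- paste(variants$protein_id, variants$token)
  tkey <- paste(truth$protein_id, truth$token)
  m <- match(key, tkey)
  variants$site_pos <- truth$site_pos[m]
  variants$effect <- c("I-" = "removed", "II-" = "removed",
                       "I+" = "created", "II+" = "created",
                       "III" = "retained")[truth$intended_type[m]]
  variants
}

#' Fabricate profile and structure files for a set of records
#'
#' Writes one ASCII position-specific scoring matrix (PSI-BLAST dialect,
#' alphabetical residue column order) and one per-residue structure TSV
#' (`position`, `asa`, `ss`) per protein.  Scores favour the observed
#' residue, so the profiles are format-valid stand-ins, not real
#' alignments.
#'
#' @param records protein-record data.frame.
#' @param dir output directory.
#' @param seed integer seed.
#' @return `data.frame(id, pssm, structure)` of written paths.
#' @export
fabricate_profiles <- function(records, dir, seed = 1L) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- data.frame(id = records$id, pssm = "", structure = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(records))) {
    id <- records$id[i]
    res <- strsplit(records$sequence[i], "")[[1]]
    n <- length(res)
    m <- matrix(sample(-4:3, n * 20L, replace = TRUE), n, 20L)
    colnames(m) <- AA_ALPHABET
    own <- match(res, AA_ALPHABET)
    ok <- !is.na(own)
    m[cbind(which(ok), own[ok])] <- sample(4:9, sum(ok), replace = TRUE)
    pssm_path <- file.path(dir, paste0(id, ".pssm"))
    lines <- c("", "Last position-specific scoring matrix computed",
               paste0("     ", paste(sprintf("%3s", AA_ALPHABET),
                                     collapse = " ")))
    body <- vapply(seq_len(n), function(p) {
      paste0(sprintf("%5d %s ", p, res[p]),
             paste(sprintf("%3d", m[p, ]), collapse = " "))
    }, "")
    writeLines(c(lines, body), pssm_path)

    st <- data.frame(position = seq_len(n),
                     asa = round(stats::runif(n, 0, 200), 1),
                     ss = sample(c("H", "E", "C"), n, replace = TRUE,
                                 prob = c(0.35, 0.2, 0.45)))
    st_path <- file.path(dir, paste0(id, ".struct.tsv"))
    utils::write.table(st, st_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$pssm[i] <- pssm_path
    out$structure[i] <- st_path
  }
  out
}
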