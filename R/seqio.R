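# Sequence, site-annotation and variant-table input/output, plus fragment
# dataset construction.
#
# Conventions used throughout the package:
#   * protein records  : data.frame(id, sequence), one row per protein;
#   * site tables      : data.frame(protein_id, position, evidence) with
#                        1-based positions indexing lysines;
#   * variant tables   : data.frame(protein_id, position, wt_aa, mut_aa,
#                        class_label, annotation, ...);
#   * fragments        : data.frame(protein_id, center_pos, residues, label)
#                        where residues is a (2*flank+1)-mer padded with 'X'.

#' Construct a set of protein records
#'
#' @param id character vector of accessions.
#' @param sequence character vector of uppercase amino-acid sequences
#'   (canonical residues or `'X'`).
#' @return A `data.frame` with columns `id` and `sequence`.
#' @export
protein_records <- function(id, sequence) {
  stopifnot(length(id) == length(sequence))
  sequence <- toupper(gsub("*", "", sequence, fixed = TRUE))
  bad <- grepl(sprintf("[^%sX]", paste(AA_ALPHABET, collapse = "")), sequence)
  if (any(bad)) {
    stop(sprintf("non-canonical residues in sequence(s): %s",
                 paste(id[bad], collapse = ", ")), call. = FALSE)
  }
  if (any(!nzchar(sequence))) stop("empty sequence(s)", call. = FALSE)
  data.frame(id = as.character(unname(id)), sequence = unname(sequence),
             stringsAsFactors = FALSE)
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and trailing stop characters (`'*'`) stripped.
#' The header word up to the first whitespace becomes the record id.
#'
#' @param path path to a FASTA file.
#' @return A protein-record `data.frame` (columns `id`, `sequence`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  first <- which(nzchar(trimws(lines)))[1]
  if (is.na(first) || !startsWith(trimws(lines[first]), ">")) {
    stop(sprintf("malformed FASTA header at line %d of %s",
                 if (is.na(first)) 1L else first, path), call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  protein_records(ids, as.character(set))
}

#' Write protein records to a FASTA file
#' @param records protein-record data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a sumoylation-site table
#'
#' Expects a TSV with header columns `protein_id`, `position` and optionally
#' `evidence` (default `"annotated"`).
#'
#' @param path path to a tab-separated file.
#' @return `data.frame(protein_id, position, evidence)`.
#' @export
read_site_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position")
  if (!all(need %in% names(tab))) {
    stop("site table must have columns protein_id and position", call. = FALSE)
  }
  if (is.null(tab$evidence)) tab$evidence <- "annotated"
  data.frame(protein_id = as.character(tab$protein_id),
             position = as.integer(tab$position),
             evidence = as.character(tab$evidence),
             stringsAsFactors = FALSE)
}

#' Write a site table as TSV
#' @param sites site-table data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse an amino-acid substitution token
#'
#' Tokens follow the `"Lys386Asn"` convention: wild-type residue, 1-based
#' position, mutant residue.  Either side may use a one-letter code
#' (`"Lys477T"`, `"K386N"`); embedded whitespace is ignored.
#'
#' @param token character scalar.
#' @return `list(wt_aa, position, mut_aa)` with one-letter residue codes.
#' @export
#' @examples
#' parse_variant_token("Lys386Asn")
parse_variant_token <- function(token) {
  tok <- gsub("\\s+", "", token)
  m <- regmatches(tok, regexec("^([A-Za-z]{1,3})([0-9]+)([A-Za-z]{1,3})$",
                               tok))[[1]]
  if (length(m) != 4L) {
    stop(sprintf("cannot parse variant token '%s'", token), call. = FALSE)
  }
  list(wt_aa = aa_one_letter(m[2], token),
       position = as.integer(m[3]),
       mut_aa = aa_one_letter(m[4], token))
}

#' Read a variant table
#'
#' Accepts either a `token` column (`"Lys386Asn"` style) or explicit
#' `wt_aa`/`position`/`mut_aa` columns.  Missing `class_label` values are
#' treated as `"unclassified"`.
#'
#' @param path path to a tab-separated file with header.
#' @return `data.frame(protein_id, position, wt_aa, mut_aa, class_label,
#'   annotation)`; wild-type and mutant residues must differ.
#' @export
read_variant_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"protein_id" %in% names(tab)) {
    stop("variant table must have a protein_id column", call. = FALSE)
  }
  if ("token" %in% names(tab)) {
    parsed <- lapply(tab$token, parse_variant_token)
    tab$wt_aa <- vapply(parsed, `[[`, "", "wt_aa")
    tab$position <- vapply(parsed, `[[`, 1L, "position")
    tab$mut_aa <- vapply(parsed, `[[`, "", "mut_aa")
  }
  need <- c("position", "wt_aa", "mut_aa")
  if (!all(need %in% names(tab))) {
    stop("variant table needs a token column or wt_aa/position/mut_aa columns",
         call. = FALSE)
  }
  if (is.null(tab$class_label)) tab$class_label <- "unclassified"
  tab$class_label[is.na(tab$class_label) | !nzchar(tab$class_label)] <-
    "unclassified"
  if (is.null(tab$annotation)) tab$annotation <- ""
  if (any(tab$wt_aa == tab$mut_aa)) {
    stop("variant with identical wild-type and mutant residue", call. = FALSE)
  }
  tab$position <- as.integer(tab$position)
  tab
}

#' Apply an amino-acid substitution to a protein record
#'
#' @param record a single protein record (one-row data.frame or
#'   `list(id, sequence)`).
#' @param variant a list/row with `position`, `wt_aa`, `mut_aa`.
#' @return The record with the substituted sequence.
#' @export
apply_variant <- function(record, variant) {
  seqs <- record$sequence
  pos <- as.integer(variant$position)
  if (pos < 1L || pos > nchar(seqs)) {
    stop(sprintf("variant position %d outside sequence of length %d",
                 pos, nchar(seqs)), call. = FALSE)
  }
  obs <- substr(seqs, pos, pos)
  if (obs != variant$wt_aa) {
    stop(sprintf("wild-type mismatch at %s:%d: expected %s, observed %s",
                 record$id, pos, variant$wt_aa, obs), call. = FALSE)
  }
  substr(seqs, pos, pos) <- variant$mut_aa
  record$sequence <- seqs
  record
}

#' Extract a lysine-centred sequence window
#'
#' Returns the `2*flank+1`-mer centred at `pos`; positions beyond the
#' sequence ends are padded with `'X'`.
#'
#' @param sequence character scalar amino-acid sequence.
#' @param pos 1-based centre position.
#' @param flank number of residues on each side (default 10, covering the
#'   downstream NDSM region of the PsiKxE consensus).
#' @return A character scalar of length `2*flank+1`.
#' @export
extract_fragment <- function(sequence, pos, flank = 10L) {
  n <- nchar(sequence)
  if (pos < 1L || pos > n) {
    stop(sprintf("position %d out of range [1, %d]", pos, n), call. = FALSE)
  }
  padded <- paste0(strrep("X", flank), sequence, strrep("X", flank))
  substr(padded, pos, pos + 2L * flank)
}

#' Build a labelled fragment dataset from records and a site table
#'
#' Only proteins that appear in the site table (i.e. experimentally
#' investigated substrates) contribute fragments.  Annotated positions
#' become positives; every other lysine in the same proteins becomes a
#' negative.  Annotated positions that do not hold a lysine are skipped
#' with a warning.
#'
#' @param records protein-record data.frame.
#' @param site_table site-table data.frame.
#' @param flank window flank size.
#' @return `data.frame(protein_id, center_pos, residues, label)` with
#'   `label` in `{"positive", "negative"}`.
#' @export
build_dataset <- function(records, site_table, flank = 10L) {
  keep <- records$id %in% unique(site_table$protein_id)
  out <- vector("list", sum(keep))
  idx <- 0L
  for (i in which(keep)) {
    id <- records$id[i]
    seqs <- records$sequence[i]
    res <- strsplit(seqs, "", fixed = TRUE)[[1]]
    lys <- which(res == "K")
    ann <- site_table$position[site_table$protein_id == id]
    bad <- setdiff(ann, lys)
    if (length(bad)) {
      warning(sprintf("skipping non-lysine annotated position(s) %s in %s",
                      paste(bad, collapse = ","), id), call. = FALSE)
      ann <- setdiff(ann, bad)
    }
    if (!length(lys)) next
    frag <- vapply(lys, function(p) extract_fragment(seqs, p, flank), "")
    idx <- idx + 1L
    out[[idx]] <- data.frame(
      protein_id = id, center_pos = lys, residues = frag,
      label = ifelse(lys %in% ann, "positive", "negative"),
      stringsAsFactors = FALSE)
  }
  if (idx == 0L) {
    return(data.frame(protein_id = character(), center_pos = integer(),
                      residues = character(), label = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out[seq_len(idx)])
  rownames(res) <- NULL
  res
}

#' Greedy redundancy reduction of equal-length fragments
#'
#' A fragment is dropped when its pairwise identity (matching positions over
#' total length, with `'X'` never matching) to any previously retained
#' fragment exceeds `max_identity`.  The filter is deterministic in the
#' input order.  This is a stand-in for whole-database clustering tools; the
#' commonly used sensitive cutoff 0.3 is the default.
#'
#' @param fragments fragment data.frame (or character vector of fragments).
#' @param max_identity maximum allowed pairwise identity.
#' @return The retained subset, same type as the input.
#' @export
reduce_redundancy <- function(fragments, max_identity = 0.3) {
  seqs <- if (is.data.frame(fragments)) fragments$residues else fragments
  n <- length(seqs)
  if (n <= 1L) return(fragments)
  chars <- fragment_char_matrix(seqs)
  L <- ncol(chars)
  kept <- integer(0)
  for (i in seq_len(n)) {
    drop <- FALSE
    for (j in kept) {
      ident <- sum(chars[i, ] == chars[j, ] & chars[i, ] != "X") / L
      if (ident > max_identity) { drop <- TRUE; break }
    }
    if (!drop) kept <- c(kept, i)
  }
  if (is.data.frame(fragments)) fragments[kept, , drop = FALSE] else seqs[kept]
}
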