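# Fragment feature encodings, F-score ranking and forward wrapper selection.

#' Encode fragments by per-position physicochemical properties
#'
#' Each of the 21 window positions contributes the property vector of the
#' residue it holds; the padding character `'X'` contributes zeros.
#'
#' @param fragments character vector of equal-length fragments (or a fragment
#'   data.frame).
#' @param table property matrix from [aa_properties()] (residues x
#'   properties; must include an `'X'` row).
#' @return A numeric matrix, one row per fragment, `L * ncol(table)`
#'   columns named `physchem_<property>_p<offset>`.
#' @export
encode_physchem <- function(fragments, table = aa_properties()) {
  seqs <- if (is.data.frame(fragments)) fragments$residues else fragments
  chars <- fragment_char_matrix(seqs)
  L <- ncol(chars)
  miss <- setdiff(unique(as.vector(chars)), rownames(table))
  if (length(miss)) {
    stop(sprintf("residue(s) missing from property table: %s",
                 paste(miss, collapse = ",")), call. = FALSE)
  }
  offs <- seq_len(L) - (L + 1L) %/% 2L
  blocks <- lapply(colnames(table), function(p) {
    v <- table[, p]
    m <- matrix(v[chars], nrow = nrow(chars))
    colnames(m) <- sprintf("physchem_%s_p%+d", p, offs)
    m
  })
  do.call(cbind, blocks)
}

#' Composition of k-spaced amino-acid pairs (CKSAAP)
#'
#' For each spacing `k`, counts ordered residue pairs separated by `k`
#' intervening positions, normalised by the number of such pairs in the
#' window (`L - k - 1`).  Pairs involving the padding character `'X'` are
#' ignored (counted as zero).
#'
#' @param fragments character vector of equal-length fragments (or fragment
#'   data.frame).
#' @param k_set integer vector of spacings (default `0:4`).
#' @return Numeric matrix with `400 * length(k_set)` columns named
#'   `cksaap_<pair>_k<k>`.
#' @export
encode_cksaap <- function(fragments, k_set = 0:4) {
  seqs <- if (is.data.frame(fragments)) fragments$residues else fragments
  chars <- fragment_char_matrix(seqs)
  n <- nrow(chars); L <- ncol(chars)
  if (any(k_set >= L - 1L) || any(k_set < 0L)) {
    stop(sprintf("spacings must lie in [0, %d]", L - 2L), call. = FALSE)
  }
  pairs <- as.vector(outer(AA_ALPHABET, AA_ALPHABET,
                           function(a, b) paste0(a, b)))
  blocks <- lapply(k_set, function(k) {
    i1 <- seq_len(L - k - 1L)
    i2 <- i1 + k + 1L
    a <- chars[, i1, drop = FALSE]
    b <- chars[, i2, drop = FALSE]
    valid <- a != "X" & b != "X"
    pair <- paste0(a, b)
    code <- match(pair, pairs)          # NA for pairs involving 'X'
    row <- rep(seq_len(n), times = length(i1))
    ok <- valid & !is.na(code)
    counts <- matrix(tabulate((row[ok] - 1L) * 400L + code[ok], n * 400L),
                     nrow = n, byrow = TRUE)
    colnames(counts) <- sprintf("cksaap_%s_k%d", pairs, k)
    counts / (L - k - 1L)
  })
  do.call(cbind, blocks)
}

#' Read a per-residue structure annotation table
#'
#' Expects a TSV with header columns `position`, `asa` (accessible surface
#' area, non-negative) and `ss` (secondary-structure class `H`/`E`/`C`).
#'
#' @param path path to the TSV file.
#' @return `data.frame(position, asa, ss)`.
#' @export
read_structure_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "asa", "ss")
  if (!all(need %in% names(tab))) {
    stop("structure table must have columns position, asa, ss", call. = FALSE)
  }
  if (!all(tab$ss %in% c("H", "E", "C"))) {
    stop("secondary-structure class must be H, E or C", call. = FALSE)
  }
  tab[, need]
}

#' Read an ASCII position-specific scoring matrix (PSSM)
#'
#' Parses the classic PSI-BLAST ASCII profile dialect: two header lines,
#' then one row per residue starting with the position index and the query
#' residue, followed by at least 20 integer substitution scores.
#'
#' @param path path to the profile file.
#' @return Numeric matrix, one row per sequence position, 20 named columns.
#' @export
read_pssm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rows <- grep("^\\s*[0-9]+\\s+[A-Z]\\s", lines, value = TRUE)
  if (!length(rows)) stop(sprintf("no profile rows found in %s", path),
                          call. = FALSE)
  parsed <- lapply(strsplit(trimws(rows), "\\s+"), function(f) {
    as.numeric(f[3:22])
  })
  m <- do.call(rbind, parsed)
  colnames(m) <- AA_ALPHABET
  m
}

window_positions <- function(center, flank, len) {
  pos <- (center - flank):(center + flank)
  pos[pos < 1L | pos > len] <- NA_integer_
  pos
}

#' One-hot secondary-structure encoding of fragment windows
#'
#' Each window position contributes a 3-vector indicating helix (`H`),
#' strand (`E`) or coil (`C`); padding positions and positions without
#' annotation are all-zero.
#'
#' @param fragments fragment data.frame with `protein_id` and `center_pos`.
#' @param annotations named list (by protein id) of structure tables as
#'   returned by [read_structure_table()].
#' @param records protein-record data.frame (for sequence lengths).
#' @param flank window flank size.
#' @return Numeric matrix with `3 * (2*flank+1)` columns.
#' @export
encode_ss <- function(fragments, annotations, records, flank = 10L) {
  n <- nrow(fragments)
  L <- 2L * flank + 1L
  offs <- -flank:flank
  out <- matrix(0, n, 3L * L)
  colnames(out) <- as.vector(outer(c("H", "E", "C"), offs,
                                   function(s, o) sprintf("ss_%s_p%+d", s, o)))
  lens <- stats::setNames(nchar(records$sequence), records$id)
  for (i in seq_len(n)) {
    id <- fragments$protein_id[i]
    ann <- annotations[[id]]
    if (is.null(ann)) next
    pos <- window_positions(fragments$center_pos[i], flank, lens[[id]])
    ss <- ann$ss[match(pos, ann$position)]
    for (j in seq_len(L)) {
      if (!is.na(ss[j])) {
        ch <- match(ss[j], c("H", "E", "C"))
        out[i, (j - 1L) * 3L + ch] <- 1
      }
    }
  }
  out
}

#' Accessible-surface-area encoding of fragment windows
#'
#' Per-position ASA values (zero at padding) plus the mean ASA over the
#' in-sequence window positions.
#'
#' @inheritParams encode_ss
#' @return Numeric matrix with `2*flank+2` columns.
#' @export
encode_aasa <- function(fragments, annotations, records, flank = 10L) {
  n <- nrow(fragments)
  L <- 2L * flank + 1L
  offs <- -flank:flank
  out <- matrix(0, n, L + 1L)
  colnames(out) <- c(sprintf("aasa_p%+d", offs), "aasa_mean")
  lens <- stats::setNames(nchar(records$sequence), records$id)
  for (i in seq_len(n)) {
    id <- fragments$protein_id[i]
    ann <- annotations[[id]]
    if (is.null(ann)) next
    pos <- window_positions(fragments$center_pos[i], flank, lens[[id]])
    asa <- ann$asa[match(pos, ann$position)]
    vals <- ifelse(is.na(asa), 0, asa)
    out[i, seq_len(L)] <- vals
    inseq <- !is.na(asa)
    out[i, L + 1L] <- if (any(inseq)) mean(asa[inseq]) else 0
  }
  out
}

#' Evolutionary-profile (PSSM) encoding of fragment windows
#'
#' The 21 x 20 block of profile scores covering the window, flattened
#' row-major; padding positions contribute zeros.
#'
#' @param fragments fragment data.frame.
#' @param profiles named list (by protein id) of PSSM matrices as returned
#'   by [read_pssm()].
#' @param flank window flank size.
#' @return Numeric matrix with `20 * (2*flank+1)` columns.
#' @export
encode_pssm <- function(fragments, profiles, flank = 10L) {
  n <- nrow(fragments)
  L <- 2L * flank + 1L
  offs <- -flank:flank
  out <- matrix(0, n, 20L * L)
  colnames(out) <- as.vector(t(outer(offs, AA_ALPHABET,
                                     function(o, a) sprintf("pssm_%s_p%+d", a, o))))
  for (i in seq_len(n)) {
    id <- fragments$protein_id[i]
    prof <- profiles[[id]]
    if (is.null(prof)) next
    pos <- window_positions(fragments$center_pos[i], flank, nrow(prof))
    for (j in seq_len(L)) {
      if (!is.na(pos[j])) {
        out[i, ((j - 1L) * 20L + 1L):(j * 20L)] <- prof[pos[j], ]
      }
    }
  }
  out
}

#' Assemble a labelled feature matrix from fragments
#'
#' Concatenates the requested encoder blocks in a fixed registry order
#' (physchem, cksaap, ss, aasa, pssm) and records per-column provenance.
#' Encoders that need missing optional inputs (structure annotations,
#' profiles) are skipped with a warning, or raise when `strict = TRUE`.
#'
#' @param fragments fragment data.frame with a `label` column
#'   (`"positive"`/`"negative"`) or pre-assigned `y`.
#' @param encoders character subset of
#'   `c("physchem", "cksaap", "ss", "aasa", "pssm")`.
#' @param records protein records (needed by structure encoders).
#' @param property_table see [encode_physchem()].
#' @param k_set see [encode_cksaap()].
#' @param structure named list of structure tables, or `NULL`.
#' @param profiles named list of PSSM matrices, or `NULL`.
#' @param flank window flank size.
#' @param strict raise instead of skipping encoders with missing inputs.
#' @return An object of class `feature_matrix`: `list(x, y, fragments,
#'   blocks, encoding)` where `y` is `+1`/`-1` (or `NA` for unlabelled
#'   fragments) and `encoding` records everything needed to re-encode new
#'   fragments consistently.
#' @export
assemble_features <- function(fragments,
                              encoders = c("physchem", "cksaap"),
                              records = NULL,
                              property_table = aa_properties(),
                              k_set = 0:4,
                              structure = NULL,
                              profiles = NULL,
                              flank = 10L,
                              strict = FALSE) {
  registry <- c("physchem", "cksaap", "ss", "aasa", "pssm")
  encoders <- registry[registry %in% encoders]
  if (!length(encoders)) stop("no known encoders requested", call. = FALSE)
  blocks <- list()
  for (e in encoders) {
    block <- switch(e,
      physchem = encode_physchem(fragments, property_table),
      cksaap = encode_cksaap(fragments, k_set),
      ss = {
        if (is.null(structure) || is.null(records)) {
          msg <- "secondary-structure encoder skipped: no annotations"
          if (strict) stop(msg, call. = FALSE) else { warning(msg, call. = FALSE); NULL }
        } else encode_ss(fragments, structure, records, flank)
      },
      aasa = {
        if (is.null(structure) || is.null(records)) {
          msg <- "ASA encoder skipped: no annotations"
          if (strict) stop(msg, call. = FALSE) else { warning(msg, call. = FALSE); NULL }
        } else encode_aasa(fragments, structure, records, flank)
      },
      pssm = {
        if (is.null(profiles)) {
          msg <- "PSSM encoder skipped: no profiles"
          if (strict) stop(msg, call. = FALSE) else { warning(msg, call. = FALSE); NULL }
        } else encode_pssm(fragments, profiles, flank)
      })
    if (!is.null(block)) blocks[[e]] <- block
  }
  x <- do.call(cbind, blocks)
  y <- if ("label" %in% names(fragments)) {
    ifelse(fragments$label == "positive", 1L,
           ifelse(fragments$label == "negative", -1L, NA_integer_))
  } else rep(NA_integer_, nrow(fragments))
  structure(list(
    x = x, y = y, fragments = fragments,
    blocks = stats::setNames(vapply(blocks, ncol, 0L), names(blocks)),
    encoding = list(encoders = names(blocks), k_set = k_set, flank = flank,
                    properties = colnames(property_table))),
    class = "feature_matrix")
}

#' F-score of each feature for two-class separation
#'
#' For feature i with whole-sample mean `xbar`, class means `xbar+`/`xbar-`
#' and class sizes `n+`/`n-`:
#' \deqn{F_i = \frac{(\bar x_i^+ - \bar x_i)^2 + (\bar x_i^- - \bar x_i)^2}{
#'   \frac{1}{n^+-1}\sum_k (x_{k,i}^+ - \bar x_i^+)^2 +
#'   \frac{1}{n^--1}\sum_k (x_{k,i}^- - \bar x_i^-)^2}}
#' A feature with zero within-class variance in both classes gets `F = 0`
#' when the numerator is also zero, and `+Inf` otherwise (a perfect
#' separator, ranked first).
#'
#' @param x numeric feature matrix (or a `feature_matrix`).
#' @param y class labels `+1`/`-1` (ignored when `x` is a `feature_matrix`).
#' @return Named numeric vector of F-scores.
#' @export
fscore <- function(x, y = NULL) {
  if (inherits(x, "feature_matrix")) { y <- x$y; x <- x$x }
  stopifnot(nrow(x) == length(y))
  pos <- x[y == 1L, , drop = FALSE]
  neg <- x[y == -1L, , drop = FALSE]
  if (nrow(pos) < 2L || nrow(neg) < 2L) {
    stop("each class needs at least two instances", call. = FALSE)
  }
  mall <- colMeans(x[y %in% c(1L, -1L), , drop = FALSE])
  mp <- colMeans(pos); mn <- colMeans(neg)
  num <- (mp - mall)^2 + (mn - mall)^2
  den <- colSums(sweep(pos, 2L, mp)^2) / (nrow(pos) - 1L) +
    colSums(sweep(neg, 2L, mn)^2) / (nrow(neg) - 1L)
  f <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  names(f) <- colnames(x)
  f
}

#' Average F-scores over several balanced training sets
#'
#' @param matrices list of `feature_matrix` objects (or `list(x, y)` pairs)
#'   sharing the same columns.
#' @return Named numeric vector of per-feature mean F-scores.
#' @export
fscore_averaged <- function(matrices) {
  scores <- lapply(matrices, function(m) {
    if (inherits(m, "feature_matrix")) fscore(m) else fscore(m$x, m$y)
  })
  rowMeans(do.call(cbind, scores))
}

rank_features <- function(scores) {
  # stable order by decreasing score, ties broken by column name
  names(scores)[order(-scores, names(scores), method = "radix")]
}

make_folds <- function(y, folds, seed) {
  # stratified fold ids, deterministic in seed
  set.seed(seed)
  id <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  id
}

cv_accuracy <- function(x, y, trainer, fold_id) {
  acc <- vapply(sort(unique(fold_id)), function(f) {
    te <- fold_id == f
    pred <- trainer(x[!te, , drop = FALSE], y[!te], x[te, , drop = FALSE])
    mean(pred == y[te])
  }, 0)
  mean(acc)
}

#' Forward best-first wrapper feature selection
#'
#' Features are examined in decreasing order of their (averaged) F-score;
#' a feature is retained iff adding it strictly improves the mean accuracy
#' over the cross-validation test folds (absolute tolerance `1e-9`).  The
#' baseline for the empty set is the majority-class rate.
#'
#' When `x` is a list of training sets (the usual case in the pipeline: the
#' ten balanced negative draws, all sharing the same columns), the wrapper
#' accuracy of a candidate set is the mean cross-validation accuracy over
#' the training sets and the ranking comes from the averaged F-scores.
#' Averaging over independent sets is what makes the acceptance decision
#' stable: on a single noisy evaluation a pure-noise feature is accepted
#' far too often.
#'
#' @param x feature matrix, `feature_matrix`, or a list of either.
#' @param y labels `+1`/`-1`, or a list of label vectors matching `x`
#'   (ignored for `feature_matrix` input).
#' @param trainer classifier factory: `function(xtr, ytr, xte)` returning
#'   predicted labels for `xte`.  Defaults to the package's RBF-kernel
#'   classifier.
#' @param folds number of cross-validation folds.
#' @param seed fold-assignment seed.
#' @param ranking optional pre-computed feature ranking (character vector);
#'   by default features are ranked by (averaged) [fscore()].
#' @param max_features examine only the top-ranked `max_features` features.
#' @return `list(ranking, scores, retained, trace)`; `trace` is a data.frame
#'   with the candidate feature, the accuracy achieved when it was tried and
#'   whether it was kept.
#' @export
forward_select <- function(x, y = NULL, trainer = svm_trainer(),
                           folds = 10L, seed = 1L,
                           ranking = NULL, max_features = Inf) {
  if (inherits(x, "feature_matrix")) { y <- x$y; x <- x$x }
  if (!is.list(x)) { x <- list(x); y <- list(y) }
  x <- lapply(x, function(xx) if (inherits(xx, "feature_matrix")) xx$x else xx)
  if (is.null(y)) stop("labels required", call. = FALSE)
  if (!is.list(y)) y <- list(y)
  stopifnot(length(x) == length(y))
  scores <- fscore_averaged(Map(function(xx, yy) list(x = xx, y = yy), x, y))
  if (is.null(ranking)) ranking <- rank_features(scores)
  if (is.finite(max_features)) ranking <- utils::head(ranking, max_features)
  fold_ids <- lapply(seq_along(x), function(m)
    make_folds(y[[m]], folds, seed + 7907L * m))
  base_rates <- vapply(y, function(yy)
    max(mean(yy == 1L), mean(yy == -1L)), 0)
  best <- mean(base_rates)               # majority-class baseline
  retained <- character(0)
  trace <- data.frame(feature = character(0), accuracy = numeric(0),
                      kept = logical(0), stringsAsFactors = FALSE)
  for (f in ranking) {
    cand <- c(retained, f)
    acc <- mean(vapply(seq_along(x), function(m)
      cv_accuracy(x[[m]][, cand, drop = FALSE], y[[m]], trainer,
                  fold_ids[[m]]), 0))
    keep <- acc > best + 1e-9
    if (keep) { retained <- cand; best <- acc }
    trace <- rbind(trace, data.frame(feature = f, accuracy = acc, kept = keep,
                                     stringsAsFactors = FALSE))
  }
  list(ranking = ranking, scores = scores, retained = retained,
       trace = trace, accuracy = best)
}
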