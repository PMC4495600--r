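# Contingency-table tests and motif statistics.

#' Pearson's chi-square test of independence
#'
#' Computes `sum((obs - exp)^2 / exp)` with `df = (r-1)(c-1)` and an
#' upper-tail p-value.  No continuity correction by default.
#'
#' @param table r x c matrix of non-negative counts.
#' @param correct apply the Yates continuity correction (2 x 2 only).
#' @return `list(statistic, df, p.value, method)`.
#' @export
pearson_chi2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  rs <- rowSums(table); cs <- colSums(table); n <- sum(table)
  if (any(rs == 0) || any(cs == 0)) {
    stop("zero row/column marginal", call. = FALSE)
  }
  expd <- outer(rs, cs) / n
  dev <- abs(table - expd)
  if (correct && all(dim(table) == 2L)) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expd)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE),
       method = if (correct) "pearson-chi2-yates" else "pearson-chi2")
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Exact hypergeometric test with fixed margins.  The two-sided p-value sums
#' the probabilities of all tables at least as extreme (probability not
#' larger than the observed one, with a small relative tolerance).
#'
#' @param table 2 x 2 matrix of non-negative counts.
#' @param two_sided two-sided (default) or upper-tail one-sided.
#' @return `list(statistic (odds ratio estimate), p.value, method)`.
#' @export
fisher_exact_2x2 <- function(table, two_sided = TRUE) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("table must be 2 x 2", call. = FALSE)
  a <- table[1, 1]
  m <- sum(table[1, ])            # white balls drawn margin
  k <- sum(table[, 1])            # draws
  n <- sum(table)
  supp <- max(0L, k - (n - m)):min(k, m)
  dens <- stats::dhyper(supp, m, n - m, k)
  pobs <- stats::dhyper(a, m, n - m, k)
  p <- if (two_sided) {
    sum(dens[dens <= pobs * (1 + 1e-7)])
  } else {
    sum(dens[supp >= a])
  }
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  list(statistic = or, p.value = min(1, p),
       method = if (two_sided) "fisher-exact-two-sided" else
         "fisher-exact-upper")
}

position_offsets <- function(L) seq_len(L) - (L + 1L) %/% 2L

#' Two-sample logo: per-position residue enrichment and depletion
#'
#' For every (window position, residue) pair, compares the occurrence
#' frequency between foreground and background fragments with a pooled
#' two-proportion z-test; cells with `p < alpha` are reported with their
#' direction.  The centre position and padding (`'X'`) are excluded.  A
#' continuity correction is applied by default: the uncorrected z-test is
#' anti-conservative for the rare residue counts typical of a 20-letter
#' alphabet, flooding null comparisons with spurious cells.
#'
#' @param pos_fragments,neg_fragments character vectors (or fragment
#'   data.frames) of equal-length fragments.
#' @param alpha significance cutoff.
#' @param correct apply the continuity correction (default `TRUE`).
#' @return `data.frame(position, residue, fg_freq, bg_freq, statistic,
#'   p.value, direction)` sorted by p-value.
#' @export
two_sample_logo <- function(pos_fragments, neg_fragments, alpha = 0.05,
                            correct = TRUE) {
  fg <- fragment_char_matrix(
    if (is.data.frame(pos_fragments)) pos_fragments$residues else pos_fragments)
  bg <- fragment_char_matrix(
    if (is.data.frame(neg_fragments)) neg_fragments$residues else neg_fragments)
  if (ncol(fg) != ncol(bg)) stop("fragment lengths differ", call. = FALSE)
  L <- ncol(fg)
  offs <- position_offsets(L)
  out <- list(); k <- 0L
  for (j in seq_len(L)) {
    if (offs[j] == 0L) next
    f <- fg[, j][fg[, j] != "X"]
    b <- bg[, j][bg[, j] != "X"]
    n1 <- length(f); n2 <- length(b)
    if (n1 == 0L || n2 == 0L) next
    for (aa in AA_ALPHABET) {
      x1 <- sum(f == aa); x2 <- sum(b == aa)
      if (x1 + x2 == 0L) next
      p1 <- x1 / n1; p2 <- x2 / n2
      pp <- (x1 + x2) / (n1 + n2)
      se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
      if (se == 0) next
      num <- abs(p1 - p2)
      if (correct) num <- max(0, num - (1 / n1 + 1 / n2) / 2)
      z <- sign(p1 - p2) * num / se
      pval <- 2 * stats::pnorm(-abs(z))
      if (pval < alpha) {
        k <- k + 1L
        out[[k]] <- data.frame(position = offs[j], residue = aa,
                               fg_freq = p1, bg_freq = p2, statistic = z,
                               p.value = pval,
                               direction = if (z > 0) "enriched" else "depleted",
                               stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) {
    return(data.frame(position = integer(), residue = character(),
                      fg_freq = numeric(), bg_freq = numeric(),
                      statistic = numeric(), p.value = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$p.value), , drop = FALSE]
}

#' Iterative motif extraction against a background set
#'
#' A simplified motif-x style procedure on centre-anchored fragments: at
#' each step the most significant (position, residue) pair by exact
#' binomial enrichment against the background is fixed, both sets are
#' reduced to the matching fragments, and the recursion continues until no
#' pair reaches `p_threshold` with at least `min_count` foreground
#' occurrences.  Completed motifs remove their matching foreground
#' fragments, and extraction restarts on the remainder.
#'
#' @param pos_fragments foreground fragments (centre residue anchored,
#'   typically `K`).
#' @param background_fragments background fragments of the same length.
#' @param p_threshold binomial significance threshold per fixed pair.
#' @param min_count minimum foreground support for a fixed pair.
#' @return `data.frame(pattern, support, positions)` where `pattern` uses
#'   `.` for unconstrained positions; zero rows when no motif is found.
#' @export
motifx <- function(pos_fragments, background_fragments,
                   p_threshold = 1e-6, min_count = 20L) {
  fg <- if (is.data.frame(pos_fragments)) pos_fragments$residues else
    pos_fragments
  bg <- if (is.data.frame(background_fragments))
    background_fragments$residues else background_fragments
  L <- unique(nchar(c(fg, bg)))
  if (length(L) != 1L) stop("fragments must share one length", call. = FALSE)
  center <- (L + 1L) %/% 2L
  motifs <- list(); mi <- 0L
  repeat {
    if (length(fg) < min_count) break
    cur_fg <- fg; cur_bg <- bg
    fixed <- character(L); fixed[] <- "."
    fixed[center] <- substr(cur_fg[1], center, center)
    found_any <- FALSE
    repeat {
      fgm <- fragment_char_matrix(cur_fg)
      bgm <- fragment_char_matrix(cur_bg)
      best <- NULL
      for (j in seq_len(L)) {
        if (fixed[j] != ".") next
        bcol <- bgm[, j][bgm[, j] != "X"]
        if (!length(bcol)) next
        for (aa in AA_ALPHABET) {
          kk <- sum(fgm[, j] == aa)
          if (kk < min_count) next
          p0 <- max(sum(bcol == aa) / length(bcol), 1e-12)
          pv <- stats::pbinom(kk - 1L, nrow(fgm), p0, lower.tail = FALSE)
          if (pv < p_threshold && (is.null(best) || pv < best$p)) {
            best <- list(j = j, aa = aa, p = pv, k = kk)
          }
        }
      }
      if (is.null(best)) break
      found_any <- TRUE
      fixed[best$j] <- best$aa
      keep_fg <- substr(cur_fg, best$j, best$j) == best$aa
      keep_bg <- substr(cur_bg, best$j, best$j) == best$aa
      cur_fg <- cur_fg[keep_fg]
      cur_bg <- cur_bg[keep_bg]
      if (length(cur_bg) < 2L) break
    }
    if (!found_any) break
    mi <- mi + 1L
    motifs[[mi]] <- data.frame(
      pattern = paste(fixed, collapse = ""),
      support = length(cur_fg),
      positions = paste(position_offsets(L)[fixed != "."], collapse = ","),
      stringsAsFactors = FALSE)
    # remove matched foreground fragments and look for the next motif
    pat <- fixed
    match_idx <- rep(TRUE, length(fg))
    for (j in which(pat != ".")) {
      match_idx <- match_idx & substr(fg, j, j) == pat[j]
    }
    fg <- fg[!match_idx]
  }
  if (mi == 0L) {
    return(data.frame(pattern = character(), support = integer(),
                      positions = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, motifs)
}
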