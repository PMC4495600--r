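# Balanced-negative ensemble of RBF-kernel soft-margin classifiers,
# cross-validation, probability scoring and specificity calibration.
#
# No SVM binding is assumed to be available at run time: the dual problem is
# solved by the package's own SMO routine (src/smo.cpp) and probabilities
# come from a sigmoid (Platt) fit on decision values.

#' Training configuration for the sumoylation-site ensemble
#'
#' Defaults are the shipped optimum of the predictor: penalty `C = 8` and
#' kernel width `gamma = 0.001953` (about 1/512, i.e. the usual 1/n_features
#' scale for a ~500-2000 dimensional encoding), ten balanced negative sets,
#' ten-fold cross-validation repeated ten times, and probability thresholds
#' calibrated at the 70/80/90/95% specificity levels (plus the 0.5 default).
#'
#' @param C soft-margin penalty (> 0).
#' @param gamma RBF kernel width (> 0).
#' @param n_negative_sets number of balanced negative draws / ensemble
#'   members.
#' @param folds cross-validation folds (>= 2).
#' @param repeats number of times the cross-validation is repeated.
#' @param seed integer root seed for every random draw.
#' @param specificity_levels numeric vector of target specificities.
#' @return A list of class `sumo_config`.
#' @export
sumo_config <- function(C = 8, gamma = 0.001953, n_negative_sets = 10L,
                        folds = 10L, repeats = 10L, seed = 1L,
                        specificity_levels = c(0.70, 0.80, 0.90, 0.95)) {
  stopifnot(C > 0, gamma > 0, folds >= 2L, n_negative_sets >= 1L)
  structure(list(C = C, gamma = gamma,
                 n_negative_sets = as.integer(n_negative_sets),
                 folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed),
                 specificity_levels = specificity_levels),
            class = "sumo_config")
}

scale_fit <- function(x) {
  lo <- apply(x, 2L, min); hi <- apply(x, 2L, max)
  rng <- hi - lo
  rng[rng == 0] <- 1
  list(lo = lo, rng = rng)
}

scale_apply <- function(x, s) {
  sweep(sweep(x, 2L, s$lo), 2L, s$rng, "/")
}

# Platt's sigmoid fit: P(y = +1 | f) = 1 / (1 + exp(A f + B)),
# Newton iteration with backtracking (Lin, Weng & Keerthi 2007).
platt_fit <- function(f, y, max_iter = 100L) {
  prior1 <- sum(y == 1L); prior0 <- sum(y == -1L)
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  t <- ifelse(y == 1L, hi, lo)
  A <- 0; B <- log((prior0 + 1) / (prior1 + 1))
  sigma <- 1e-12
  fval_of <- function(A, B) {
    fApB <- A * f + B
    sum(ifelse(fApB >= 0,
               t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  fval <- fval_of(A, B)
  for (it in seq_len(max_iter)) {
    fApB <- A * f + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(f * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(f * f * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(f * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {
      newA <- A + step * dA; newB <- B + step * dB
      newf <- fval_of(newA, newB)
      if (newf < fval + 1e-4 * step * gd) {
        A <- newA; B <- newB; fval <- newf; break
      }
      step <- step / 2
      if (step < 1e-10) return(list(A = A, B = B))
    }
  }
  list(A = A, B = B)
}

platt_prob <- function(f, A, B) {
  fApB <- A * f + B
  ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
}

#' Fit a single RBF-kernel soft-margin classifier
#'
#' @param x numeric feature matrix.
#' @param y labels `+1`/`-1` (integer, factor or numeric).
#' @param C soft-margin penalty.
#' @param gamma kernel width.
#' @param scale min-max scale features to `[0, 1]` using training ranges
#'   (recommended: keeps the default `gamma` on a sensible scale).
#' @param probability fit a sigmoid on the training decision values so the
#'   model can emit probabilities in `[0, 1]`.
#' @param eps SMO stopping tolerance.
#' @return An object of class `rbf_svm`.
#' @export
svm_fit <- function(x, y, C = 8, gamma = 0.001953, scale = TRUE,
                    probability = TRUE, eps = 1e-3) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L))) stop("labels must be +1/-1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("training data contains a single class", call. = FALSE)
  }
  scl <- NULL
  if (scale) { scl <- scale_fit(x); x <- scale_apply(x, scl) }
  K <- rbf_kernel_cpp(x, x, gamma)
  sol <- smo_solve(K, y, C, eps)
  sv <- which(sol$alpha > 1e-8)
  model <- structure(list(
    sv = x[sv, , drop = FALSE],
    coef = sol$alpha[sv] * y[sv],
    b = sol$b, gamma = gamma, C = C, scale = scl,
    decision_train = sol$decision, y_train = y,
    converged = sol$converged,
    features = colnames(x)), class = "rbf_svm")
  if (probability) {
    pl <- platt_fit(sol$decision, y)
    model$platt <- pl
  }
  model
}

#' Predict with a fitted RBF-kernel classifier
#'
#' @param object an `rbf_svm` model.
#' @param newx feature matrix with the training columns.
#' @param type `"probability"` (default), `"decision"` or `"class"`.
#' @param ... unused.
#' @return Numeric vector (probability/decision) or `+1`/`-1` labels.
#' @export
predict.rbf_svm <- function(object, newx,
                            type = c("probability", "decision", "class"),
                            ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  if (!is.null(object$features) && !is.null(colnames(newx))) {
    newx <- newx[, object$features, drop = FALSE]
  }
  if (!is.null(object$scale)) newx <- scale_apply(newx, object$scale)
  K <- rbf_kernel_cpp(newx, object$sv, object$gamma)
  f <- drop(K %*% object$coef) + object$b
  switch(type,
         decision = f,
         class = ifelse(f >= 0, 1L, -1L),
         probability = {
           if (is.null(object$platt)) stop("model fitted without probability")
           platt_prob(f, object$platt$A, object$platt$B)
         })
}

#' Classifier factory for wrapper selection and cross-validation
#'
#' Returns a `function(xtr, ytr, xte)` that fits the package's RBF-kernel
#' classifier and predicts hard labels, honouring the trainer contract of
#' [forward_select()].
#'
#' @param C,gamma,scale passed to [svm_fit()].
#' @return A trainer function.
#' @export
svm_trainer <- function(C = 8, gamma = 0.001953, scale = TRUE) {
  function(xtr, ytr, xte) {
    m <- svm_fit(xtr, ytr, C = C, gamma = gamma, scale = scale,
                 probability = FALSE)
    predict(m, xte, type = "class")
  }
}

#' Grid search for the kernel hyper-parameters
#'
#' Cross-validated accuracy over a (C, gamma) grid.  Provided for
#' completeness but not run by default anywhere: the shipped defaults
#' (C = 8, gamma = 0.001953) are the published optimum.
#'
#' @param x feature matrix.
#' @param y labels `+1`/`-1`.
#' @param C_grid,gamma_grid candidate values.
#' @param folds cross-validation folds.
#' @param seed fold-assignment seed.
#' @return `list(best, results)`: `best` holds the winning `C`/`gamma`
#'   (ties broken towards the first grid entry), `results` the full
#'   accuracy table.
#' @export
svm_grid_search <- function(x, y, C_grid = 2^(1:4),
                            gamma_grid = 2^(-11:-7), folds = 5L,
                            seed = 1L) {
  fid <- make_folds(y, folds, seed)
  grid <- expand.grid(C = C_grid, gamma = gamma_grid)
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(i) {
    cv_accuracy(x, y, svm_trainer(grid$C[i], grid$gamma[i]), fid)
  }, 0)
  best <- grid[which.max(grid$accuracy), ]
  list(best = list(C = best$C, gamma = best$gamma,
                   accuracy = best$accuracy),
       results = grid)
}

#' Draw balanced negative sets
#'
#' Each of `n_sets` sets holds `n_pos` negatives sampled without replacement
#' (within a set) from the negative pool; different sets are drawn
#' independently and may overlap.  Reproducible from `seed`.
#'
#' @param negatives integer vector of negative indices (or anything
#'   subsettable; its `seq_along` is sampled).
#' @param n_pos number of positives to match.
#' @param n_sets number of sets.
#' @param seed integer seed.
#' @return List of `n_sets` index vectors into `negatives`.
#' @export
sample_balanced_negatives <- function(negatives, n_pos, n_sets = 10L,
                                      seed = 1L) {
  n <- length(negatives)
  if (n < n_pos) {
    stop(sprintf("need at least %d negatives, have %d", n_pos, n),
         call. = FALSE)
  }
  set.seed(seed)
  lapply(seq_len(n_sets), function(m) sort(sample.int(n, n_pos)))
}

#' Train the balanced-negative classifier ensemble
#'
#' Draws `config$n_negative_sets` balanced negative sets, fits one
#' RBF-kernel classifier per set, and (optionally) calibrates
#' specificity-based probability cutoffs from the out-of-fold negative
#' scores of a per-member cross-validation.
#'
#' @param x_pos feature matrix of positive fragments.
#' @param x_neg feature matrix of the full negative pool.
#' @param config a [sumo_config()].
#' @param features optional character vector of selected feature names
#'   (columns of `x_pos`/`x_neg`) to train on.
#' @param calibrate run the per-member cross-validation needed for the
#'   specificity threshold table.
#' @param encoding optional encoding descriptor (stored for re-encoding at
#'   prediction time; see [assemble_features()]).
#' @return An object of class `sumo_ensemble`.
#' @export
train_ensemble <- function(x_pos, x_neg, config = sumo_config(),
                           features = NULL, calibrate = TRUE,
                           encoding = NULL) {
  x_pos <- as.matrix(x_pos); x_neg <- as.matrix(x_neg)
  if (!is.null(features)) {
    x_pos <- x_pos[, features, drop = FALSE]
    x_neg <- x_neg[, features, drop = FALSE]
  }
  n_pos <- nrow(x_pos)
  sets <- sample_balanced_negatives(seq_len(nrow(x_neg)), n_pos,
                                    config$n_negative_sets, config$seed)
  members <- vector("list", length(sets))
  for (m in seq_along(sets)) {
    xm <- rbind(x_pos, x_neg[sets[[m]], , drop = FALSE])
    ym <- c(rep(1L, n_pos), rep(-1L, n_pos))
    members[[m]] <- svm_fit(xm, ym, C = config$C, gamma = config$gamma)
  }
  oof_neg <- NULL
  if (calibrate) {
    # out-of-bag calibration: each pool negative is scored by the mean of
    # the members whose balanced set did not contain it, so the score
    # distribution matches that of fresh negatives under the full ensemble
    P <- matrix(NA_real_, nrow(x_neg), length(members))
    for (m in seq_along(members)) {
      P[, m] <- predict(members[[m]], x_neg, type = "probability")
      P[sets[[m]], m] <- NA_real_
    }
    oof_neg <- rowMeans(P, na.rm = TRUE)
    oof_neg <- oof_neg[!is.nan(oof_neg)]
    if (!length(oof_neg)) {
      # every negative was in every member's training set (tiny pools):
      # fall back to in-bag ensemble scores
      warning("no out-of-bag negatives; calibrating on in-bag scores",
              call. = FALSE)
      oof_neg <- rowMeans(vapply(members, function(m)
        predict(m, x_neg, type = "probability"), numeric(nrow(x_neg))))
    }
  }
  thresholds <- if (calibrate) {
    calibrate_thresholds(oof_neg, config$specificity_levels)
  } else {
    c(default = 0.5)
  }
  structure(list(members = members,
                 features = if (is.null(features)) colnames(x_pos) else features,
                 thresholds = thresholds,
                 config = config,
                 encoding = encoding,
                 oof_negative_scores = if (calibrate) oof_neg else NULL),
            class = "sumo_ensemble")
}

#' Specificity-calibrated probability cutoffs
#'
#' The cutoff for specificity level `s` is the empirical `s`-quantile
#' (nearest rank) of held-out negative probabilities, so that the fraction
#' of negatives called positive is at most `1 - s`.  The `default` level is
#' fixed at probability 0.5.
#'
#' @param neg_scores out-of-fold probabilities of negative fragments.
#' @param levels numeric specificity levels in (0, 1).
#' @return Named numeric vector of cutoffs (`default` first).
#' @export
calibrate_thresholds <- function(neg_scores, levels = c(0.70, 0.80, 0.90, 0.95)) {
  if (!length(neg_scores)) stop("no negative scores to calibrate on",
                                call. = FALSE)
  cuts <- stats::quantile(neg_scores, probs = levels, type = 1L, names = FALSE)
  out <- c(0.5, cuts)
  names(out) <- c("default", format(levels))
  out
}

#' Cross-validate the balanced-negative ensemble
#'
#' For each balanced set and each repeat, positives and negatives are split
#' into stratified folds in a 9:1 train:test ratio (for ten folds); a
#' classifier is fitted on the training part and evaluated on the held-out
#' fold.
#'
#' @param x_pos positive feature matrix.
#' @param x_neg_sets list of negative feature matrices, one per member
#'   (each with `nrow(x_pos)` rows), e.g. built with
#'   [sample_balanced_negatives()].
#' @param config a [sumo_config()].
#' @return `list(metrics, scores)`: `metrics` has one row per
#'   member x repeat x fold with `Ac`, `Sn`, `Sp`, `MCC` (percent, except
#'   MCC) and `AUC`; `scores` holds the out-of-fold probabilities with
#'   labels.
#' @export
cross_validate <- function(x_pos, x_neg_sets, config = sumo_config()) {
  n_pos <- nrow(x_pos)
  if (config$folds > n_pos) stop("more folds than positives", call. = FALSE)
  met <- list(); sco <- list(); k <- 0L
  for (m in seq_along(x_neg_sets)) {
    xm <- rbind(x_pos, as.matrix(x_neg_sets[[m]]))
    ym <- c(rep(1L, n_pos), rep(-1L, nrow(x_neg_sets[[m]])))
    for (r in seq_len(config$repeats)) {
      fid <- make_folds(ym, config$folds,
                        config$seed + 104729L * m + 1299709L * r)
      for (f in seq_len(config$folds)) {
        te <- fid == f
        fit <- svm_fit(xm[!te, , drop = FALSE], ym[!te],
                       C = config$C, gamma = config$gamma)
        p <- predict(fit, xm[te, , drop = FALSE], type = "probability")
        cls <- ifelse(p >= 0.5, 1L, -1L)
        cc <- confusion_counts(cls, ym[te])
        k <- k + 1L
        met[[k]] <- data.frame(
          member = m, rep = r, fold = f,
          Ac = accuracy(cc), Sn = sensitivity(cc), Sp = specificity(cc),
          MCC = mcc(cc), AUC = auc(roc_curve(p, ym[te])))
        sco[[k]] <- data.frame(member = m, rep = r, fold = f,
                               probability = p, label = ym[te])
      }
    }
  }
  list(metrics = do.call(rbind, met), scores = do.call(rbind, sco))
}

#' Ensemble probability and threshold calls for encoded fragments
#'
#' The ensemble probability is the unweighted mean of the member
#' probabilities; the call at specificity level `s` is positive iff the
#' probability reaches the calibrated cutoff for `s`, so calls are monotone
#' across levels.
#'
#' @param object a `sumo_ensemble`.
#' @param newx feature matrix (training columns).
#' @param ... unused.
#' @return A data.frame with `probability` and one logical `call_<level>`
#'   column per threshold level.
#' @export
predict.sumo_ensemble <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  if (!is.null(colnames(newx))) {
    newx <- newx[, object$features, drop = FALSE]
  }
  probs <- vapply(object$members, function(m) predict(m, newx),
                  numeric(nrow(newx)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = nrow(newx))
  p <- rowMeans(probs)
  out <- data.frame(probability = p)
  for (lv in names(object$thresholds)) {
    out[[paste0("call_", lv)]] <- p >= object$thresholds[[lv]]
  }
  out
}

#' Score lysine-centred fragments with a trained ensemble
#'
#' Re-encodes the fragments with the encoding stored in the ensemble and
#' returns per-fragment probabilities and calls.
#'
#' @param ensemble a `sumo_ensemble` carrying an `encoding` descriptor.
#' @param fragments fragment data.frame.
#' @param records protein records (needed only for structure encoders).
#' @param structure,profiles optional annotation inputs; if the ensemble was
#'   trained sequence-only they are not required.
#' @return `cbind(fragments, predictions)`.
#' @export
predict_fragments <- function(ensemble, fragments, records = NULL,
                              structure = NULL, profiles = NULL) {
  enc <- ensemble$encoding
  if (is.null(enc)) stop("ensemble carries no encoding descriptor",
                         call. = FALSE)
  fm <- assemble_features(fragments, encoders = enc$encoders,
                          records = records, k_set = enc$k_set,
                          structure = structure, profiles = profiles,
                          flank = enc$flank, strict = FALSE)
  cbind(fragments, predict(ensemble, fm$x))
}

#' Fit the full pipeline from records and a site table
#'
#' Builds the labelled fragment dataset, encodes it, optionally reduces
#' redundancy and performs feature selection, then trains the
#' balanced-negative ensemble.
#'
#' @param records protein records.
#' @param sites site table.
#' @param config a [sumo_config()].
#' @param encoders encoder subset (see [assemble_features()]).
#' @param reduce apply [reduce_redundancy()] to the fragments first.
#' @param select run [forward_select()] on the averaged F-score ranking and
#'   train on the retained features only (can be slow for wide encodings).
#' @param max_features cap on the number of ranked features examined by the
#'   wrapper when `select = TRUE`.
#' @param structure,profiles optional annotation inputs.
#' @param calibrate see [train_ensemble()].
#' @return A `sumo_ensemble`.
#' @export
sumovar_fit <- function(records, sites, config = sumo_config(),
                        encoders = c("physchem", "cksaap"),
                        reduce = FALSE, select = FALSE, max_features = 50L,
                        structure = NULL, profiles = NULL, calibrate = TRUE) {
  frags <- build_dataset(records, sites, flank = 10L)
  if (reduce) frags <- reduce_redundancy(frags)
  fm <- assemble_features(frags, encoders = encoders, records = records,
                          structure = structure, profiles = profiles)
  pos <- fm$x[fm$y == 1L, , drop = FALSE]
  neg <- fm$x[fm$y == -1L, , drop = FALSE]
  feats <- NULL
  if (select) {
    sets <- sample_balanced_negatives(seq_len(nrow(neg)), nrow(pos),
                                      config$n_negative_sets, config$seed)
    xs <- lapply(sets, function(s) rbind(pos, neg[s, , drop = FALSE]))
    ys <- lapply(sets, function(s) c(rep(1L, nrow(pos)),
                                     rep(-1L, length(s))))
    sel <- forward_select(xs, ys,
                          trainer = svm_trainer(config$C, config$gamma),
                          folds = config$folds, seed = config$seed,
                          max_features = max_features)
    feats <- sel$retained
    if (!length(feats)) feats <- utils::head(sel$ranking, 1L)
  }
  train_ensemble(pos, neg, config, features = feats, calibrate = calibrate,
                 encoding = fm$encoding)
}

#' Save a trained ensemble as plain-text files
#'
#' Writes a JSON manifest (configuration, thresholds, selected features,
#' per-member intercepts and sigmoid parameters) plus one CSV of support
#' vectors and coefficients per member.  No binary serialisation is used.
#'
#' @param ensemble a `sumo_ensemble`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "sumovar",
    config = unclass(ensemble$config),
    thresholds = as.list(ensemble$thresholds),
    features = ensemble$features,
    encoding = ensemble$encoding,
    n_members = length(ensemble$members),
    members = lapply(ensemble$members, function(m) {
      list(b = m$b, gamma = m$gamma, C = m$C,
           platt = m$platt,
           scale_lo = unname(m$scale$lo), scale_rng = unname(m$scale$rng))
    }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_along(ensemble$members)) {
    m <- ensemble$members[[i]]
    tab <- data.frame(coef = m$coef)
    tab <- cbind(tab, as.data.frame(m$sv))
    utils::write.csv(tab, file.path(dir, sprintf("member_%02d.csv", i)),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Load an ensemble saved by [save_ensemble()]
#' @param dir directory containing `manifest.json`.
#' @return A `sumo_ensemble`.
#' @export
load_ensemble <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  cfg <- do.call(sumo_config, man$config[c("C", "gamma", "n_negative_sets",
                                           "folds", "repeats", "seed",
                                           "specificity_levels")])
  members <- lapply(seq_len(man$n_members), function(i) {
    tab <- utils::read.csv(file.path(dir, sprintf("member_%02d.csv", i)),
                           check.names = FALSE)
    sv <- as.matrix(tab[, -1, drop = FALSE])
    mm <- if (is.data.frame(man$members)) as.list(man$members[i, ]) else
      man$members[[i]]
    scl <- list(lo = stats::setNames(unlist(mm$scale_lo), colnames(sv)),
                rng = stats::setNames(unlist(mm$scale_rng), colnames(sv)))
    structure(list(sv = sv, coef = tab$coef, b = unlist(mm$b)[[1]],
                   gamma = unlist(mm$gamma)[[1]], C = unlist(mm$C)[[1]],
                   scale = scl,
                   platt = list(A = unlist(mm$platt$A)[[1]],
                                B = unlist(mm$platt$B)[[1]]),
                   features = colnames(sv)),
              class = "rbf_svm")
  })
  thresholds <- unlist(man$thresholds)
  encoding <- man$encoding
  if (!is.null(encoding)) encoding <- lapply(encoding, unlist)
  structure(list(members = members, features = man$features,
                 thresholds = thresholds, config = cfg, encoding = encoding),
            class = "sumo_ensemble")
}
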