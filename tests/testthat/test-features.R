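test_that("encode_physchem matches per-position table lookup", {
  tab <- aa_properties()
  z <- encode_physchem(strrep("X", 21), tab)
  expect_true(all(z == 0))
  expect_equal(ncol(z), 21 * ncol(tab))

  one <- matrix(c(A = 3, C = -1, rep(0, 18)), ncol = 1,
                dimnames = list(AA_ALPHABET, "p"))
  one <- rbind(one, X = 0)
  expect_equal(unname(encode_physchem(strrep("A", 21), one))[1, ],
               rep(3, 21))

  frag <- random_fragments(5, seed = 2)
  enc <- encode_physchem(frag, tab)
  chars <- do.call(rbind, strsplit(frag, ""))
  for (i in 1:5) for (j in sample(21, 4)) for (p in colnames(tab)) {
    expect_equal(unname(enc[i, sprintf("physchem_%s_p%+d", p, j - 11)]),
                 unname(tab[chars[i, j], p]))
  }
})

test_that("encode_cksaap counts equal brute-force enumeration", {
  e <- encode_cksaap(strrep("A", 21), k_set = 0)
  expect_equal(unname(e[1, "cksaap_AA_k0"]), 1)   # 20/20
  expect_equal(sum(e), 1)

  lone <- paste0(strrep("X", 10), "K", strrep("X", 10))
  expect_true(all(encode_cksaap(lone, k_set = 0:4) == 0))

  expect_error(encode_cksaap(strrep("A", 21), k_set = 20), "spacings")

  frags <- random_fragments(10, seed = 4)
  for (k in 0:2) {
    enc <- encode_cksaap(frags, k_set = k)
    for (i in seq_along(frags)) {
      ch <- strsplit(frags[i], "")[[1]]
      counts <- table(vapply(seq_len(21 - k - 1), function(j)
        paste0(ch[j], ch[j + k + 1]), ""))
      for (pr in names(counts)) {
        expect_equal(unname(enc[i, sprintf("cksaap_%s_k%d", pr, k)]),
                     unname(counts[[pr]]) / (21 - k - 1))
      }
    }
  }
})

test_that("structure and profile encoders reproduce their inputs", {
  prot <- small_proteome(seed = 8, n_proteins = 3, n_sites = 5)
  dir <- tempfile()
  paths <- fabricate_profiles(prot$records, dir, seed = 3)
  structure_ann <- lapply(seq_len(nrow(paths)), function(i)
    read_structure_table(paths$structure[i]))
  names(structure_ann) <- paths$id
  profiles <- lapply(seq_len(nrow(paths)), function(i)
    read_pssm(paths$pssm[i]))
  names(profiles) <- paths$id

  frags <- build_dataset(prot$records, prot$sites)
  # all-helix annotation -> H channel all ones inside the sequence
  ann1 <- structure_ann
  ann1[[frags$protein_id[1]]]$ss <- "H"
  e <- encode_ss(frags[1, , drop = FALSE], ann1, prot$records)
  pos <- (frags$center_pos[1] - 10):(frags$center_pos[1] + 10)
  inseq <- pos >= 1 & pos <= nchar(prot$records$sequence[
    prot$records$id == frags$protein_id[1]])
  expect_equal(unname(e[1, sprintf("ss_H_p%+d", -10:10)]), as.numeric(inseq))

  # constant ASA a -> window mean a
  ann2 <- structure_ann
  ann2[[frags$protein_id[1]]]$asa <- 7.5
  a <- encode_aasa(frags[1, , drop = FALSE], ann2, prot$records)
  expect_equal(unname(a[1, "aasa_mean"]), 7.5)

  # ASA round trip: encoded per-position values equal the file contents
  a2 <- encode_aasa(frags[1, , drop = FALSE], structure_ann, prot$records)
  st <- structure_ann[[frags$protein_id[1]]]
  expect_equal(unname(a2[1, sprintf("aasa_p%+d", 0)]),
               st$asa[st$position == frags$center_pos[1]])

  # PSSM window fully inside the sequence equals a direct slice
  id <- frags$protein_id[1]
  prof <- profiles[[id]]
  inner <- frags[frags$center_pos > 10 &
                 frags$center_pos <= nrow(prof) - 10, , drop = FALSE]
  inner <- inner[inner$protein_id == id, , drop = FALSE][1, , drop = FALSE]
  pe <- encode_pssm(inner, profiles)
  sl <- as.vector(t(prof[(inner$center_pos - 10):(inner$center_pos + 10), ]))
  expect_equal(unname(pe[1, ]), sl)

  # centre at position 1 -> first ten 20-blocks zero
  first <- data.frame(protein_id = id, center_pos = 1,
                      residues = extract_fragment(
                        prot$records$sequence[prot$records$id == id], 1))
  pf <- encode_pssm(first, profiles)
  expect_true(all(pf[1, 1:200] == 0))

  # zero profile -> zero vector
  zp <- profiles
  zp[[id]][] <- 0
  expect_true(all(encode_pssm(first, zp) == 0))
})

test_that("assemble_features concatenates blocks in registry order", {
  frags <- data.frame(protein_id = "P", center_pos = 11,
                      residues = random_fragments(4, seed = 6),
                      label = c("positive", "positive", "negative",
                                "negative"))
  expect_warning(fm <- assemble_features(frags,
                                         encoders = c("cksaap", "pssm",
                                                      "physchem")),
                 "PSSM encoder skipped")
  expect_equal(names(fm$blocks), c("physchem", "cksaap"))
  expect_equal(ncol(fm$x), sum(fm$blocks))
  expect_equal(fm$y, c(1L, 1L, -1L, -1L))
  expect_error(assemble_features(frags, encoders = "pssm", strict = TRUE),
               "no profiles")
})

test_that("fscore implements the printed formula", {
  x <- cbind(const = rep(2, 8), sep = c(1, 1, 1, 1, 0, 0, 0, 0))
  y <- c(1L, 1L, 1L, 1L, -1L, -1L, -1L, -1L)
  f <- fscore(x, y)
  expect_equal(unname(f["const"]), 0)     # 0/0 convention
  expect_equal(unname(f["sep"]), Inf)     # perfect separator sentinel

  expect_error(fscore(x[c(1, 5:8), ], y[c(1, 5:8)]), "at least two")

  # independent direct evaluation of the formula on Gaussian data
  set.seed(13)
  xg <- matrix(rnorm(200 * 6), 200, 6,
               dimnames = list(NULL, paste0("f", 1:6)))
  yg <- rep(c(1L, -1L), each = 100)
  xg[yg == 1L, 1:2] <- xg[yg == 1L, 1:2] + 1
  oracle <- vapply(seq_len(6), function(i) {
    v <- xg[, i]; vp <- v[yg == 1L]; vn <- v[yg == -1L]
    num <- (mean(vp) - mean(v))^2 + (mean(vn) - mean(v))^2
    den <- sum((vp - mean(vp))^2) / (length(vp) - 1) +
      sum((vn - mean(vn))^2) / (length(vn) - 1)
    num / den
  }, 0)
  expect_equal(unname(fscore(xg, yg)), oracle, tolerance = 1e-12)

  # invariance under instance order, scaling behaviour under affine maps
  ord <- sample(200)
  expect_equal(fscore(xg[ord, ], yg[ord]), fscore(xg, yg))
  xs <- xg; xs[, 3] <- 5 * xs[, 3] + 2
  expect_equal(fscore(xs, yg)[3], fscore(xg, yg)[3], tolerance = 1e-12)
})

test_that("forward_select keeps one copy of duplicated features, none without signal", {
  set.seed(17)
  n <- 80
  y <- rep(c(1L, -1L), each = n / 2)
  inf <- y + rnorm(n, sd = 0.5)
  x <- cbind(a = inf, b = inf, c = inf)
  sel <- forward_select(x, y, folds = 5)
  expect_length(sel$retained, 1)

  # no signal anywhere: shuffled labels over ten independent sets
  xs <- lapply(1:10, function(m) cbind(n1 = rnorm(n), n2 = rnorm(n)))
  ys <- lapply(1:10, function(m) sample(y))
  sel2 <- forward_select(xs, ys, folds = 5)
  expect_lte(length(sel2$retained), 1)
  # accuracy trace is non-decreasing at accepted steps
  expect_true(all(diff(c(0, sel2$trace$accuracy[sel2$trace$kept])) >= 0))
})

test_that("top F-score features on consensus-planted data involve -1 and +2", {
  prot <- small_proteome(seed = 21, n_proteins = 30, n_sites = 60)
  ds <- build_dataset(prot$records, prot$sites)
  fm <- assemble_features(ds)
  f <- fscore(fm)
  top <- names(sort(f, decreasing = TRUE))[1:10]
  expect_true(any(grepl("_p[+]2$", top) | grepl("_p-1$", top) |
                    grepl("cksaap_.E_k0", top)))
})
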