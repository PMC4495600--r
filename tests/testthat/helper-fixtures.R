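# Shared fixtures: small deterministic inputs built in code.

random_sequence <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(sumovar::AA_ALPHABET, n, replace = TRUE), collapse = "")
}

random_fragments <- function(n, L = 21L, seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(sumovar::AA_ALPHABET, L, replace = TRUE), collapse = ""), "")
}

# a small proteome with planted consensus sites, shared across tests
small_proteome <- function(seed = 42L, n_proteins = 20L, n_sites = 40L,
                           motif_q = 1) {
  generate_proteome(synth_config(n_proteins = n_proteins,
                                 length_range = c(80L, 160L),
                                 n_positive_sites = n_sites,
                                 motif_q = motif_q, seed = seed))
}

write_temp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

# fragments of every lysine in a proteome that has no planted sites:
# a pool of genuine negatives from the background distribution
fresh_negative_fragments <- function(n_proteins = 400L, seed = 99L) {
  prot <- generate_proteome(synth_config(n_proteins = n_proteins,
                                         n_positive_sites = 0L, seed = seed))
  res <- strsplit(prot$records$sequence, "")
  do.call(rbind, lapply(seq_along(res), function(i) {
    lys <- which(res[[i]] == "K")
    data.frame(protein_id = prot$records$id[i], center_pos = lys,
               residues = vapply(lys, function(p)
                 extract_fragment(prot$records$sequence[i], p, 10L), ""),
               stringsAsFactors = FALSE)
  }))
}
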