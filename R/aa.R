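# Amino-acid alphabets and residue code conversion.

#' Residue alphabets
#'
#' `AA_ALPHABET` holds the twenty canonical amino acids (one-letter codes,
#' alphabetical); `PSI_RESIDUES` the large aliphatic/branched hydrophobic
#' residues accepted at the -1 position of the PsiKxE sumoylation
#' consensus.
#'
#' @format Character vectors.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname AA_ALPHABET
#' @export
PSI_RESIDUES <- c("L", "V", "I", "M", "F")

AA_THREE_TO_ONE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
  Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
  Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
  Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V"
)

#' Convert a residue code to a one-letter amino acid
#'
#' Accepts either a one-letter code (`"K"`) or a three-letter code
#' (`"Lys"`, case-insensitive).  Used when parsing substitution tokens such
#' as `"Lys386Asn"` that may mix the two conventions.
#'
#' @param code character scalar residue code.
#' @param context optional string (e.g. the full token) used in error
#'   messages.
#' @return A one-letter residue code.
#' @keywords internal
aa_one_letter <- function(code, context = code) {
  stopifnot(is.character(code), length(code) == 1L)
  if (nchar(code) == 1L) {
    up <- toupper(code)
    if (!up %in% AA_ALPHABET) {
      stop(sprintf("unknown residue code '%s' in '%s'", code, context),
           call. = FALSE)
    }
    return(up)
  }
  if (nchar(code) == 3L) {
    key <- paste0(toupper(substr(code, 1, 1)), tolower(substr(code, 2, 3)))
    if (!key %in% names(AA_THREE_TO_ONE)) {
      stop(sprintf("unknown residue code '%s' in '%s'", code, context),
           call. = FALSE)
    }
    return(unname(AA_THREE_TO_ONE[key]))
  }
  stop(sprintf("unknown residue code '%s' in '%s'", code, context),
       call. = FALSE)
}

#' Physicochemical property table for the canonical amino acids
#'
#' Literature reference values for eight widely used residue properties:
#' hydropathy (Kyte-Doolittle), hydrophilicity (Hopp-Woods), side-chain
#' volume, polarity (Grantham), isoelectric point, residue mass, and the
#' Chou-Fasman helix and sheet propensities.  The padding character `'X'`
#' maps to an all-zero row so windows that run off a sequence end contribute
#' nothing to the encoding.
#'
#' @return A numeric matrix with 21 rows (20 residues plus `'X'`) and one
#'   column per property.
#' @export
#' @examples
#' aa_properties()["K", ]
aa_properties <- function() {
  path <- system.file("extdata", "aa_properties.csv", package = "sumovar")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m <- rbind(m, X = 0)
  m
}

# Split fragment strings into an n x L character matrix.
fragment_char_matrix <- function(residues) {
  L <- unique(nchar(residues))
  if (length(L) != 1L) stop("fragments must all have equal length")
  matrix(unlist(strsplit(residues, "", fixed = TRUE), use.names = FALSE),
         ncol = L, byrow = TRUE)
}
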