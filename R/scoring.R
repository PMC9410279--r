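# Canonical BLOSUM62 (half-bit integer scores), embedded as a constant so
# scoring is bit-exact and needs no file parsing. Row/column order follows
# AA_ALPHABET (alphabetical).
BLOSUM62_SCORES <- matrix(c(
   4,  0, -2, -1, -2,  0, -2, -1, -1, -1, -1, -2, -1, -1, -1,  1,  0,  0, -3, -2,
   0,  9, -3, -4, -2, -3, -3, -1, -3, -1, -1, -3, -3, -3, -3, -1, -1, -1, -2, -2,
  -2, -3,  6,  2, -3, -1, -1, -3, -1, -4, -3,  1, -1,  0, -2,  0, -1, -3, -4, -3,
  -1, -4,  2,  5, -3, -2,  0, -3,  1, -3, -2,  0, -1,  2,  0,  0, -1, -2, -3, -2,
  -2, -2, -3, -3,  6, -3, -1,  0, -3,  0,  0, -3, -4, -3, -3, -2, -2, -1,  1,  3,
   0, -3, -1, -2, -3,  6, -2, -4, -2, -4, -3,  0, -2, -2, -2,  0, -2, -3, -2, -3,
  -2, -3, -1,  0, -1, -2,  8, -3, -1, -3, -2,  1, -2,  0,  0, -1, -2, -3, -2,  2,
  -1, -1, -3, -3,  0, -4, -3,  4, -3,  2,  1, -3, -3, -3, -3, -2, -1,  3, -3, -1,
  -1, -3, -1,  1, -3, -2, -1, -3,  5, -2, -1,  0, -1,  1,  2,  0, -1, -2, -3, -2,
  -1, -1, -4, -3,  0, -4, -3,  2, -2,  4,  2, -3, -3, -2, -2, -2, -1,  1, -2, -1,
  -1, -1, -3, -2,  0, -3, -2,  1, -1,  2,  5, -2, -2,  0, -1, -1, -1,  1, -1, -1,
  -2, -3,  1,  0, -3,  0,  1, -3,  0, -3, -2,  6, -2,  0,  0,  1,  0, -3, -4, -2,
  -1, -3, -1, -1, -4, -2, -2, -3, -1, -3, -2, -2,  7, -1, -2, -1, -1, -2, -4, -3,
  -1, -3,  0,  2, -3, -2,  0, -3,  1, -2,  0,  0, -1,  5,  1,  0, -1, -2, -2, -1,
  -1, -3, -2,  0, -3, -2,  0, -3,  2, -2, -1,  0, -2,  1,  5, -1, -1, -3, -3, -2,
   1, -1,  0,  0, -2,  0, -1, -2,  0, -2, -1,  1, -1,  0, -1,  4,  1, -2, -3, -2,
   0, -1, -1, -1, -2, -2, -2, -1, -1, -1, -1,  0, -1, -1, -1,  1,  5,  0, -2, -2,
   0, -1, -3, -2, -1, -3, -3,  3, -2,  1,  1, -3, -2, -2, -3, -2,  0,  4, -3, -1,
  -3, -2, -4, -3,  1, -2, -2, -3, -3, -2, -1, -4, -4, -2, -3, -3, -2, -3, 11,  2,
  -2, -2, -3, -2,  3, -3,  2, -1, -2, -1, -1, -2, -3, -1, -2, -2, -2, -1,  2,  7),
  nrow = 20, byrow = TRUE,
  dimnames = list(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))

new_substitution_matrix <- function(scores, name) {
  structure(scores, name = name,
            class = c("substitution_matrix", class(scores)))
}

#' Canonical BLOSUM62 substitution matrix
#'
#' Returns the standard BLOSUM62 half-bit integer matrix over the 20
#' amino acids, embedded as a package constant for bit-exact reproducibility.
#'
#' @return A symmetric 20x20 integer matrix of class `substitution_matrix`.
#' @examples
#' blosum62()["W", "W"] # 11
#' @export
blosum62 <- function() {
  new_substitution_matrix(BLOSUM62_SCORES, "BLOSUM62")
}

#' Cysteine-anchored BLOSUM62 variant
#'
#' BLOSUM62 with the cysteine row and column overwritten: C/C scores
#' `cys_match` (default 99) and C against any other residue scores
#' `cys_mismatch` (default -4). The huge C/C reward and flat C/x penalty
#' force alignments to pin homologous cysteines of the LU-domain scaffold
#' into the same columns, which is what makes progressive alignment of
#' three-finger proteins respect the disulfide framework.
#'
#' @param cys_match Score for a C/C pair.
#' @param cys_mismatch Score for C against any non-C residue.
#' @return A symmetric 20x20 matrix of class `substitution_matrix`.
#' @examples
#' m <- cysteine_anchored_matrix()
#' m["C", "C"] # 99
#' m["C", "A"] # -4
#' @export
cysteine_anchored_matrix <- function(cys_match = 99, cys_mismatch = -4) {
  m <- BLOSUM62_SCORES
  m["C", ] <- cys_mismatch
  m[, "C"] <- cys_mismatch
  m["C", "C"] <- cys_match
  new_substitution_matrix(m, "BLOSUM62-cys-anchored")
}

# Expansions used for ambiguity codes; a code scores as the minimum over its
# expansion, and X scores a flat -4 against everything (conservative: an
# unknown residue can never inflate an alignment score).
AMBIGUITY_EXPANSION <- list(B = c("D", "N"), Z = c("E", "Q"),
                            J = c("I", "L"), U = "C", O = "K")
X_SCORE <- -4

# Extend a 20x20 matrix with ambiguity rows/columns so the DP core can index
# any accepted symbol directly.
extend_matrix <- function(matrix) {
  ext <- c(AA_ALPHABET, AA_AMBIGUITY)
  out <- matrix(X_SCORE, nrow = length(ext), ncol = length(ext),
                dimnames = list(ext, ext))
  out[AA_ALPHABET, AA_ALPHABET] <- matrix[AA_ALPHABET, AA_ALPHABET]
  for (code in names(AMBIGUITY_EXPANSION)) {
    exp <- AMBIGUITY_EXPANSION[[code]]
    for (a in AA_ALPHABET) {
      v <- min(matrix[exp, a])
      out[code, a] <- v
      out[a, code] <- v
    }
    for (code2 in names(AMBIGUITY_EXPANSION)) {
      out[code, code2] <- min(matrix[AMBIGUITY_EXPANSION[[code]],
                                     AMBIGUITY_EXPANSION[[code2]]])
    }
  }
  out["X", ] <- X_SCORE
  out[, "X"] <- X_SCORE
  out
}

#' Score one residue pair under a substitution matrix
#'
#' Plain table lookup for the 20 standard residues. Ambiguity codes score as
#' the minimum over their expansion (`B` = D/N, `Z` = E/Q, `J` = I/L,
#' `U` = C, `O` = K); `X` scores a flat -4 against everything.
#'
#' @param matrix A `substitution_matrix`.
#' @param a,b Single residue characters.
#' @return The integer score.
#' @examples
#' score_pair(cysteine_anchored_matrix(), "C", "C") # 99
#' score_pair(blosum62(), "D", "E") # 2
#' @export
score_pair <- function(matrix, a, b) {
  ext <- extend_matrix(matrix)
  ok <- rownames(ext)
  if (!(is.character(a) && nchar(a) == 1 && a %in% ok)) {
    stop("not a residue or ambiguity code: '", a, "'", call. = FALSE)
  }
  if (!(is.character(b) && nchar(b) == 1 && b %in% ok)) {
    stop("not a residue or ambiguity code: '", b, "'", call. = FALSE)
  }
  unname(ext[a, b])
}

#' Write / read a substitution matrix in NCBI square-matrix text format
#'
#' Optional plain-text round-trip for interoperability with external tools;
#' the package's own matrices are embedded constants.
#'
#' @param matrix A `substitution_matrix`.
#' @param path File path.
#' @return `write_matrix` returns `matrix` invisibly; `read_matrix` returns
#'   a `substitution_matrix`.
#' @export
write_matrix <- function(matrix, path) {
  aa <- rownames(matrix)
  lines <- c(paste0("# ", attr(matrix, "name")),
             paste(" ", paste(aa, collapse = "  ")),
             vapply(aa, function(r) {
               paste(r, paste(sprintf("%2d", matrix[r, ]), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(matrix)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- do.call(rbind, lapply(lines[-1], function(l) {
    strsplit(trimws(l), "\\s+")[[1]]
  }))
  scores <- apply(body[, -1, drop = FALSE], 2, as.numeric)
  dimnames(scores) <- list(body[, 1], cols)
  new_substitution_matrix(scores[cols, cols], "from-file")
}
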