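# The five physicochemical residue groups used by the similarity statistic.
RESIDUE_GROUPS <- c(
  A = "hydrophobic", F = "hydrophobic", H = "hydrophobic", I = "hydrophobic",
  L = "hydrophobic", M = "hydrophobic", P = "hydrophobic", V = "hydrophobic",
  W = "hydrophobic",
  C = "cysteine",
  G = "polar", N = "polar", Q = "polar", S = "polar", T = "polar", Y = "polar",
  K = "positive", R = "positive",
  D = "negative", E = "negative")

#' Physicochemical group of a residue
#'
#' The 20 amino acids partition into five groups: hydrophobic
#' (A,F,H,I,L,M,P,V,W), cysteine (C), polar (G,N,Q,S,T,Y), positively
#' charged (K,R) and negatively charged (D,E). Ambiguity codes and gaps are
#' errors here; callers handle gaps before asking for a group.
#'
#' @param r A vector of single residue characters.
#' @return A character vector of group labels.
#' @examples
#' residue_group(c("H", "C", "E"))
#' @export
residue_group <- function(r) {
  out <- RESIDUE_GROUPS[r]
  if (anyNA(out)) {
    stop("not a standard residue: '", r[which(is.na(out))[1]], "'",
         call. = FALSE)
  }
  unname(out)
}

#' Residue-group scheme as a tibble
#'
#' @return A tibble with columns `residue` and `group`.
#' @export
residue_group_scheme <- function() {
  tibble::tibble(residue = names(RESIDUE_GROUPS),
                 group = unname(RESIDUE_GROUPS))
}

#' Grouped-residue percent similarity of two aligned rows
#'
#' The statistic scores each alignment column as a coincidence when both
#' rows hold residues of the same physicochemical group. The result is
#' `100 x coincidences / columns with at least one residue`: gap-gap
#' columns are excluded from the denominator and a residue opposite a gap
#' counts as a non-coincidence. Identity implies group coincidence, so the
#' value is never below plain percent identity.
#'
#' @param row_a,row_b Equal-length gapped strings from one alignment (or
#'   from a pairwise alignment).
#' @return A percentage in `[0, 100]`.
#' @examples
#' grouped_similarity("ACD", "GCE") # 100 * 2/3
#' @export
grouped_similarity <- function(row_a, row_b) {
  if (nchar(row_a) != nchar(row_b)) {
    stop("aligned rows must have equal length", call. = FALSE)
  }
  ca <- strsplit(row_a, "")[[1]]
  cb <- strsplit(row_b, "")[[1]]
  some_residue <- !(ca == "-" & cb == "-")
  if (!any(some_residue)) {
    stop("all-gap row pair: similarity undefined", call. = FALSE)
  }
  both <- ca != "-" & cb != "-"
  coincide <- both & residue_group_safe(ca) == residue_group_safe(cb)
  100 * sum(coincide, na.rm = TRUE) / sum(some_residue)
}

# Group lookup tolerating gaps (NA for '-'), erroring on anything else.
residue_group_safe <- function(chars) {
  out <- RESIDUE_GROUPS[chars]
  bad <- is.na(out) & chars != "-"
  if (any(bad)) {
    stop("not a standard residue: '", chars[which(bad)[1]], "'",
         call. = FALSE)
  }
  unname(out)
}

#' Pairwise grouped-similarity matrix of an alignment
#'
#' Scores every unordered row pair of a multiple alignment with
#' [grouped_similarity()].
#'
#' @param alignment An `lu_alignment` tibble (>= 2 rows), or any tibble with
#'   `id` and `aligned` columns.
#' @return A labeled symmetric matrix of class `lu_similarity` with
#'   percentages in `[0, 100]` and a diagonal of exactly 100.
#' @export
similarity_matrix <- function(alignment) {
  stopifnot(is.data.frame(alignment), nrow(alignment) >= 2,
            all(c("id", "aligned") %in% names(alignment)))
  labels <- alignment$id
  n <- length(labels)
  m <- matrix(100, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- grouped_similarity(alignment$aligned[i], alignment$aligned[j])
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  structure(m, class = c("lu_similarity", class(m)))
}

#' Grouped-similarity matrix from fresh pairwise alignments
#'
#' Instead of reading rows off one multiple alignment, aligns every pair of
#' domains globally under `matrix` and scores the pairwise alignment. Both
#' entry points are provided because a published percentage can come from
#' either convention.
#'
#' @param domains A domain tibble with unique labels.
#' @param matrix A `substitution_matrix`.
#' @param config A [search_config()] supplying gap penalties.
#' @return A labeled symmetric `lu_similarity` matrix.
#' @export
pairwise_similarity_matrix <- function(domains,
                                       matrix = cysteine_anchored_matrix(),
                                       config = search_config()) {
  labels <- domain_labels(domains)
  n <- length(labels)
  stopifnot(n >= 2)
  m <- matrix(100, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- needleman_wunsch(domains$residues[i], domains$residues[j],
                              matrix, config$gap_open, config$gap_extend)
      v <- grouped_similarity(aln$a, aln$b)
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  structure(m, class = c("lu_similarity", class(m)))
}

#' @describeIn similarity_matrix Tidy a similarity matrix into a long tibble
#'   (`id_a`, `id_b`, `similarity`, percentages to one decimal place).
#' @param x An `lu_similarity` matrix.
#' @param ... Unused.
#' @method tidy lu_similarity
#' @export
tidy.lu_similarity <- function(x, ...) {
  labels <- rownames(x)
  tidyr::expand_grid(id_a = labels, id_b = labels) |>
    dplyr::mutate(similarity = round(as.vector(t(unclass(x))), 1))
}

#' Write a similarity matrix as labeled square TSV
#'
#' Percentages are reported to one decimal place.
#'
#' @param sim An `lu_similarity` matrix.
#' @param path Output path.
#' @return `sim`, invisibly.
#' @export
write_similarity_tsv <- function(sim, path) {
  out <- tibble::as_tibble(round(unclass(sim), 1), rownames = "id")
  write_tsv_output(out, path)
  invisible(sim)
}
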