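# Global (Needleman-Wunsch) alignment of two residue strings; terminal gaps
# are penalized like internal ones. Returns the gapped strings and score.
needleman_wunsch <- function(a, b, matrix = cysteine_anchored_matrix(),
                             gap_open = 11, gap_extend = 1) {
  ext <- extend_matrix(matrix)
  S <- pair_score_matrix(ext, a, b)
  res <- align_affine_cpp(S, gap_open, gap_extend, local = FALSE)
  aligned <- gapped_from_moves(a, b, res)
  list(score = res$score, a = aligned$query, b = aligned$subject)
}

#' Alignment-based distance between two LU-domains
#'
#' Globally aligns the two sequences under the given matrix and returns
#' `1 - identity`, where identity is the fraction of identical residue pairs
#' among aligned residue-residue columns (gap columns are not counted).
#'
#' @param a,b Protein strings or one-row domain/record tibbles.
#' @param matrix A `substitution_matrix`.
#' @param config A [search_config()] supplying the gap penalties.
#' @return A number in `[0, 1]`; 0 for identical sequences.
#' @examples
#' pairwise_distance("CAC", "CGC") # 1 - 2/3
#' @export
pairwise_distance <- function(a, b, matrix = cysteine_anchored_matrix(),
                              config = search_config()) {
  a <- record_residues(a)
  b <- record_residues(b)
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  aln <- needleman_wunsch(a, b, matrix, config$gap_open, config$gap_extend)
  ca <- strsplit(aln$a, "")[[1]]
  cb <- strsplit(aln$b, "")[[1]]
  both <- ca != "-" & cb != "-"
  if (!any(both)) return(1)
  1 - sum(ca[both] == cb[both]) / sum(both)
}

#' All-pairs distance matrix for a set of domains
#'
#' @param domains A domain tibble (labels from `parent_id` or `id`).
#' @param matrix A `substitution_matrix`.
#' @param config A [search_config()] supplying gap penalties.
#' @return A labeled symmetric matrix with zero diagonal, values in `[0, 1]`.
#' @export
distance_matrix <- function(domains, matrix = cysteine_anchored_matrix(),
                            config = search_config()) {
  labels <- domain_labels(domains)
  n <- length(labels)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        v <- pairwise_distance(domains$residues[i], domains$residues[j],
                               matrix, config)
        d[i, j] <- v
        d[j, i] <- v
      }
    }
  }
  d
}

#' Neighbor-joining guide tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration (via [ape::nj()]); negative branch
#' lengths, an artifact of NJ on non-additive distances, are clamped to
#' zero. One- and two-label inputs are handled as degenerate trees (a
#' single leaf; a single edge split evenly).
#'
#' @param d A labeled symmetric matrix (zero diagonal) or `dist` object.
#' @return An unrooted `phylo` tree whose leaf labels are the input labels.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (!isSymmetric(unname(d), tol = 1e-12)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  n <- nrow(d)
  if (n == 1) {
    tree <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                           edge.length = 0, tip.label = labels,
                           Nnode = 1L), class = "phylo")
    return(tree)
  }
  if (n == 2) {
    tree <- structure(list(edge = rbind(c(3L, 1L), c(3L, 2L)),
                           edge.length = rep(d[1, 2] / 2, 2),
                           tip.label = labels, Nnode = 1L),
                      class = "phylo")
    return(tree)
  }
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

# Midpoint-rooted copy used for display and for ordering profile merges;
# the unrooted topology is what Newick export preserves.
rooted_for_display <- function(tree) {
  if (length(tree$tip.label) <= 2) return(tree)
  phangorn::midpoint(tree)
}

#' Progressive multiple alignment along a guide tree
#'
#' Aligns leaves pairwise and merges profiles in post-order over the
#' (midpoint-rooted) guide tree. Profile-profile column scores are the mean
#' of all cross-pair residue scores under `matrix` (pairs involving an
#' existing gap contribute zero); new gaps cost `gap_open + gap_extend` on
#' the first column and `gap_extend` thereafter, for terminal and internal
#' gaps alike. With the cysteine-anchored matrix the 99/-4 coefficients make
#' cysteine-cysteine pairing dominate every other consideration, so scaffold
#' cysteines of homologous LU-domains end up in shared columns.
#'
#' @param domains A domain tibble; labels from `parent_id` or `id` must be
#'   unique.
#' @param tree Optional guide tree (`phylo`, leaf labels matching the domain
#'   labels); defaults to neighbor-joining on [distance_matrix()].
#' @param matrix A `substitution_matrix`.
#' @param gap_open,gap_extend Gap penalties for the progressive stage
#'   (ClustalW-like scale by default).
#' @return An alignment tibble of class `lu_alignment` with columns `id` and
#'   `aligned` (equal-length gapped strings, rows in input order).
#' @export
progressive_align <- function(domains, tree = NULL,
                              matrix = cysteine_anchored_matrix(),
                              gap_open = 10, gap_extend = 0.2) {
  labels <- domain_labels(domains)
  if (anyDuplicated(labels)) {
    stop("domain labels must be unique for alignment", call. = FALSE)
  }
  seqs <- stats::setNames(domains$residues, labels)
  if (length(seqs) == 1) {
    return(new_alignment(tibble::tibble(id = labels, aligned = unname(seqs))))
  }
  if (is.null(tree)) {
    tree <- neighbor_joining(distance_matrix(domains, matrix))
  }
  if (!setequal(tree$tip.label, labels)) {
    stop("guide tree leaves do not match the domain labels", call. = FALSE)
  }
  ext <- extend_matrix(matrix)
  rooted <- rooted_for_display(tree)
  prof <- merge_node(root_node(rooted), rooted, seqs, ext, gap_open, gap_extend)
  aligned <- apply(prof$mat, 1, paste, collapse = "")
  out <- tibble::tibble(id = labels,
                        aligned = unname(aligned[match(labels, prof$labels)]))
  new_alignment(out)
}

root_node <- function(tree) length(tree$tip.label) + 1L

# Post-order profile merge at one node of the rooted guide tree. A profile
# is a character matrix (rows = sequences, one column per alignment column)
# plus its row labels. Multifurcations are folded left to right.
merge_node <- function(node, tree, seqs, ext, gap_open, gap_extend) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) {
    label <- tree$tip.label[node]
    return(list(mat = matrix(strsplit(seqs[[label]], "")[[1]], nrow = 1),
                labels = label))
  }
  children <- tree$edge[tree$edge[, 1] == node, 2]
  profs <- lapply(children, merge_node, tree = tree, seqs = seqs, ext = ext,
                  gap_open = gap_open, gap_extend = gap_extend)
  Reduce(function(a, b) merge_profiles(a, b, ext, gap_open, gap_extend), profs)
}

# Column symbol-count matrix of a profile over the extended alphabet;
# gaps are excluded (they contribute zero to cross-pair sums).
profile_counts <- function(mat, symbols) {
  counts <- matrix(0, nrow = length(symbols), ncol = ncol(mat),
                   dimnames = list(symbols, NULL))
  for (s in symbols) counts[s, ] <- colSums(mat == s)
  counts
}

merge_profiles <- function(a, b, ext, gap_open, gap_extend) {
  symbols <- rownames(ext)
  ca <- profile_counts(a$mat, symbols)
  cb <- profile_counts(b$mat, symbols)
  cs <- crossprod(ca, ext %*% cb) / (nrow(a$mat) * nrow(b$mat))
  res <- align_affine_cpp(cs, gap_open, gap_extend, local = FALSE)
  moves <- res$moves
  out <- matrix("-", nrow = nrow(a$mat) + nrow(b$mat), ncol = length(moves))
  ia <- 0L
  ib <- 0L
  ra <- seq_len(nrow(a$mat))
  rb <- nrow(a$mat) + seq_len(nrow(b$mat))
  for (k in seq_along(moves)) {
    if (moves[k] != 3L) { ia <- ia + 1L; out[ra, k] <- a$mat[, ia] }
    if (moves[k] != 2L) { ib <- ib + 1L; out[rb, k] <- b$mat[, ib] }
  }
  list(mat = out, labels = c(a$labels, b$labels))
}

new_alignment <- function(tbl) {
  widths <- nchar(tbl$aligned)
  stopifnot(length(unique(widths)) == 1)
  structure(tbl, class = c("lu_alignment", class(tbl)))
}

#' Write an alignment as gapped FASTA
#'
#' @param alignment An `lu_alignment` tibble.
#' @param path Output path.
#' @return `alignment`, invisibly.
#' @export
write_alignment_fasta <- function(alignment, path) {
  write_fasta(tibble::tibble(id = alignment$id,
                             residues = alignment$aligned), path)
  invisible(alignment)
}

#' Read a gapped FASTA file as an alignment
#'
#' Counterpart of [write_alignment_fasta()]: accepts `-` gap characters,
#' requires all rows to have equal length.
#'
#' @param path Path to an aligned (gapped) FASTA file.
#' @return An `lu_alignment` tibble with columns `id` and `aligned`.
#' @export
read_alignment_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  rows <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  bad <- grepl("[^-ACDEFGHIKLMNPQRSTVWYXBZJUO]", rows)
  if (any(bad)) {
    stop("illegal symbol in alignment row '", ids[which(bad)[1]], "'",
         call. = FALSE)
  }
  if (length(unique(nchar(rows))) > 1) {
    stop("alignment rows differ in length", call. = FALSE)
  }
  new_alignment(tibble::tibble(id = unname(ids), aligned = unname(rows)))
}

#' Serialize a tree to Newick text
#'
#' Branch lengths are written with six decimal places and a trailing `;`;
#' labels containing spaces or Newick metacharacters are single-quoted.
#'
#' @param tree A `phylo` object.
#' @return A single Newick string.
#' @examples
#' d <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
#' to_newick(neighbor_joining(d))
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  quote_label <- function(x) {
    ifelse(grepl("[][ ():;,']", x),
           paste0("'", gsub("'", "''", x), "'"), x)
  }
  child_rows <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  serialize <- function(node) {
    rows <- child_rows[[as.character(node)]]
    if (is.null(rows)) return(quote_label(tree$tip.label[node]))
    parts <- vapply(rows, function(r) {
      paste0(serialize(tree$edge[r, 2]),
             sprintf(":%.6f", tree$edge.length[r]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(serialize(ntip + 1L), ";")
}

domain_labels <- function(domains) {
  stopifnot(is.data.frame(domains), nrow(domains) > 0)
  if ("parent_id" %in% names(domains)) return(domains$parent_id)
  if ("id" %in% names(domains)) return(domains$id)
  stop("domains need a 'parent_id' or 'id' column", call. = FALSE)
}
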