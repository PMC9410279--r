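#' Specification of a synthetic LU-domain scaffold
#'
#' Describes the cysteine framework of a synthetic family ancestor:
#' `n_cys` cysteines separated by loop spacers, optionally ending in the
#' family's C-terminal signature (`CC`, four spacer residues, the final
#' cysteine, then `N`). When `loop_lengths` is `NULL` the free spacers are
#' drawn at generation time (deterministically from the seed) within a
#' range that keeps the domain in the 60-190-residue band.
#'
#' @param n_cys Cysteine count, 8-10.
#' @param loop_lengths Optional integer vector of free spacer lengths
#'   (`n_cys - 3` values when `terminal_motif`, else `n_cys - 1`).
#' @param terminal_motif Emit the C-terminal `CC-x(4)-C-N` signature
#'   (default `TRUE`; without it the scaffold detector will not accept the
#'   family, which is useful for negative controls).
#' @return A list of class `scaffold_spec`.
#' @export
scaffold_spec <- function(n_cys = 10L, loop_lengths = NULL,
                          terminal_motif = TRUE) {
  stopifnot(n_cys >= 8, n_cys <= 10)
  n_free <- if (terminal_motif) n_cys - 3L else n_cys - 1L
  if (!is.null(loop_lengths)) {
    stopifnot(length(loop_lengths) == n_free, all(loop_lengths >= 1))
    total <- n_cys + sum(loop_lengths) + if (terminal_motif) 5L else 0L
    if (total < 60 || total > 190) {
      stop("scaffold length ", total, " outside the 60-190 residue band",
           call. = FALSE)
    }
  }
  structure(list(n_cys = as.integer(n_cys),
                 loop_lengths = loop_lengths,
                 terminal_motif = terminal_motif),
            class = "scaffold_spec")
}

NON_CYS <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "C")

# Draw free spacer lengths that keep the whole domain >= 60 residues.
draw_loop_lengths <- function(spec) {
  n_free <- if (spec$terminal_motif) spec$n_cys - 3L else spec$n_cys - 1L
  lo <- max(3L, ceiling((60 - spec$n_cys - 7) / n_free))
  sample(lo:(lo + 8L), n_free, replace = TRUE)
}

# Build one random ancestor honoring the spec. Loops avoid cysteine so the
# planted scaffold is the only cysteine structure in the sequence.
build_ancestor <- function(spec) {
  loops <- spec$loop_lengths %||% draw_loop_lengths(spec)
  rand <- function(k) paste(sample(NON_CYS, k, replace = TRUE), collapse = "")
  prefix <- rand(2L)
  if (spec$terminal_motif) {
    body <- paste0(paste0(vapply(loops, function(k) paste0("C", rand(k)),
                                 character(1)), collapse = ""),
                   "CC", rand(4L), "C", "N")
  } else {
    inner <- paste0(vapply(loops[-length(loops)], function(k)
      paste0("C", rand(k)), character(1)), collapse = "")
    body <- paste0(inner, "C", rand(loops[length(loops)]), "C")
  }
  paste0(prefix, body)
}

# Mutate one sequence at non-cysteine positions. A `cross_group_fraction`
# of mutations jump to a different physicochemical group; the rest stay
# within group. Cysteine is never a source or a target, so the scaffold is
# invariant and no spurious scaffolds appear.
mutate_sequence <- function(residues, rate, cross_group_fraction) {
  chars <- strsplit(residues, "")[[1]]
  mutable <- which(chars != "C")
  hit <- mutable[stats::runif(length(mutable)) < rate]
  for (pos in hit) {
    grp <- RESIDUE_GROUPS[chars[pos]]
    cross <- stats::runif(1) < cross_group_fraction
    pool <- if (cross) {
      setdiff(names(RESIDUE_GROUPS)[RESIDUE_GROUPS != grp], "C")
    } else {
      setdiff(names(RESIDUE_GROUPS)[RESIDUE_GROUPS == grp], c("C", chars[pos]))
    }
    chars[pos] <- sample(pool, 1)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic LU-domain family
#'
#' Builds one random ancestor honoring `spec` and derives `n_members`
#' sequences by point mutation at non-cysteine positions. All members keep
#' cysteines at the ancestral scaffold positions, mirroring the invariant
#' disulfide core that the cysteine-anchored matrix exploits. Deterministic
#' given `seed`.
#'
#' @param spec A [scaffold_spec()].
#' @param n_members Number of family members to emit.
#' @param mutation_rate Per-position mutation probability in `[0, 0.5]`.
#' @param cross_group_fraction Fraction of mutations that change the
#'   residue's physicochemical group; at 0 all mutations are invisible to
#'   the grouped-similarity statistic.
#' @param seed Integer seed.
#' @param family_id Label prefix for member ids.
#' @return A list with `records` (a tibble usable with every pipeline
#'   stage) and `truth` (per member: `parent_id`, `start`, `end`,
#'   `cys_positions` list-column, `family_id`, `mutation_rate`).
#' @export
generate_family <- function(spec = scaffold_spec(), n_members = 10L,
                            mutation_rate = 0.2, cross_group_fraction = 0.5,
                            seed = 1L, family_id = "fam1") {
  stopifnot(n_members >= 1, mutation_rate >= 0, mutation_rate <= 0.5,
            cross_group_fraction >= 0, cross_group_fraction <= 1)
  withr::with_seed(seed, {
    ancestor <- build_ancestor(spec)
    members <- vapply(seq_len(n_members), function(i) {
      mutate_sequence(ancestor, mutation_rate, cross_group_fraction)
    }, character(1))
  })
  ids <- sprintf("%s_m%02d", family_id, seq_len(n_members))
  cys <- which(strsplit(ancestor, "")[[1]] == "C")
  records <- tibble::tibble(id = ids,
                            description = sprintf("synthetic LU-domain family %s", family_id),
                            residues = members,
                            has_ambiguity = FALSE)
  truth <- tibble::tibble(parent_id = ids,
                          start = cys[1], end = cys[length(cys)],
                          cys_positions = rep(list(cys), n_members),
                          family_id = family_id,
                          mutation_rate = mutation_rate,
                          ancestor = ancestor)
  list(records = records, truth = truth)
}

#' Generate a decoy proteome with planted homologs
#'
#' Emits `n_decoys` background proteins with residues drawn i.i.d. from
#' `background` (uniform over the 20 amino acids by default) plus the
#' `planted` records embedded between random flanks, in shuffled order.
#' Flanks avoid cysteine so a planted record's scaffold stays its only
#' cysteine structure. Deterministic given `seed`.
#'
#' @param n_decoys Number of decoy proteins (>= 0).
#' @param length_range Length-2 integer range for decoy lengths.
#' @param planted Optional record tibble (e.g. from [generate_family()]) to
#'   embed; `NULL` for a pure decoy set.
#' @param seed Integer seed.
#' @param background Optional named probability vector over the 20 residues.
#' @param flank_range Length-2 integer range for each flank.
#' @return A list with `records` (shuffled tibble) and `truth` (planted
#'   records only: `parent_id`, domain `start`/`end` on the emitted record,
#'   `cys_positions` list-column, `is_planted`).
#' @export
generate_proteome <- function(n_decoys = 1000L, length_range = c(100L, 500L),
                              planted = NULL, seed = 1L, background = NULL,
                              flank_range = c(10L, 50L)) {
  stopifnot(n_decoys >= 0, length(length_range) == 2,
            length_range[1] <= length_range[2])
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  }
  stopifnot(setequal(names(background), AA_ALPHABET))
  n_planted <- if (is.null(planted)) 0L else nrow(planted)
  withr::with_seed(seed, {
    decoys <- tibble::tibble(
      id = sprintf("decoy_%04d", seq_len(n_decoys)),
      description = "synthetic decoy protein",
      residues = vapply(seq_len(n_decoys), function(i) {
        len <- sample(length_range[1]:length_range[2], 1)
        paste(sample(AA_ALPHABET, len, replace = TRUE,
                     prob = background[AA_ALPHABET]), collapse = "")
      }, character(1)),
      has_ambiguity = FALSE)
    truth <- tibble::tibble(parent_id = character(), start = integer(),
                            end = integer(), cys_positions = list(),
                            is_planted = logical())
    embedded <- NULL
    if (n_planted > 0) {
      rows <- purrr::pmap(planted, function(id, residues, ...) {
        left <- paste(sample(NON_CYS, sample(flank_range[1]:flank_range[2], 1),
                             replace = TRUE), collapse = "")
        right <- paste(sample(NON_CYS, sample(flank_range[1]:flank_range[2], 1),
                              replace = TRUE), collapse = "")
        full <- paste0(left, residues, right)
        cys <- which(strsplit(full, "")[[1]] == "C")
        list(record = tibble::tibble(id = id,
                                     description = "synthetic planted LU-domain protein",
                                     residues = full, has_ambiguity = FALSE),
             truth = tibble::tibble(parent_id = id,
                                    start = cys[1], end = cys[length(cys)],
                                    cys_positions = list(cys),
                                    is_planted = TRUE))
      })
      embedded <- dplyr::bind_rows(purrr::map(rows, "record"))
      truth <- dplyr::bind_rows(purrr::map(rows, "truth"))
    }
    records <- dplyr::bind_rows(decoys, embedded)
    records <- records[sample.int(nrow(records)), ]
  })
  list(records = records, truth = truth)
}

#' Primer pairs used for transcript-expression qPCR
#'
#' The two primer pairs designed against the starfish transcript
#' XM_033772626.1 (theoretical products of 184 and 200 bp on that
#' template).
#'
#' @return A tibble with columns `pair`, `forward`, `reverse`,
#'   `product_length`.
#' @export
qpcr_primer_pairs <- function() {
  tibble::tibble(
    pair = c(1L, 2L),
    forward = c("CGGTGGGGAAAACAAACTGAC", "GCTCCGGTTCTCAAGACGTG"),
    reverse = c("ACGCTGTTCGAAAGCAGACT", "GTATCGCAGCACTCGACACA"),
    product_length = c(184L, 200L))
}

#' Synthetic transcript emulating the primers' native template
#'
#' The native transcript (XM_033772626.1) cannot be bundled, so this builds
#' a synthetic stand-in: random nucleotide background with the two real
#' primer pairs' binding sites embedded at spacings that give the same
#' theoretical product lengths (184 and 200 bp). Each primer site is
#' verified unique on the emitted template. Deterministic given `seed`.
#'
#' @param seed Integer seed.
#' @return A one-row nucleotide record tibble.
#' @export
synthetic_lu_transcript <- function(seed = 1L) {
  primers <- qpcr_primer_pairs()
  for (attempt in 0:20) {
    template <- withr::with_seed(seed + attempt, {
      rand <- function(k) paste(sample(NT_ALPHABET, k, replace = TRUE),
                                collapse = "")
      s1 <- primers$product_length[1] - nchar(primers$forward[1]) -
        nchar(primers$reverse[1])
      s2 <- primers$product_length[2] - nchar(primers$forward[2]) -
        nchar(primers$reverse[2])
      paste0(rand(25), primers$forward[1], rand(s1),
             reverse_complement(primers$reverse[1]), rand(30),
             primers$forward[2], rand(s2),
             reverse_complement(primers$reverse[2]), rand(30))
    })
    sites <- c(primers$forward, vapply(primers$reverse, reverse_complement,
                                       character(1)))
    counts <- vapply(sites, function(p) {
      Biostrings::countPattern(Biostrings::DNAString(p),
                               Biostrings::DNAString(template))
    }, integer(1))
    if (all(counts == 1L)) {
      return(tibble::tibble(id = "synthetic_lu_transcript",
                            description = "synthetic stand-in for the qPCR template",
                            residues = template, has_ambiguity = FALSE))
    }
  }
  stop("could not build a template with unique primer sites", call. = FALSE)
}
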