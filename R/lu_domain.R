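#' Curation settings for LU-domain reference sets
#'
#' Bundles the tunable parameters of scaffold detection and reference
#' curation. The defaults encode the family's invariant disulfide core: an
#' accepted scaffold has 8-10 cysteines inside a window of at most
#' `window` residues whose last four cysteines carry the Ly6/uPAR C-terminal
#' signature -- an adjacent `CC` doublet, then a short spacer
#' (`motif_spacer` residues, canonically 4), then the final cysteine, with a
#' following `N` preferred but not required. Reference proteins longer than
#' `max_length` residues (default 190) are dropped to exclude multi-domain
#' proteins.
#'
#' @param max_length Maximum reference protein length kept by curation.
#' @param min_cys,max_cys Accepted cysteine count of a scaffold.
#' @param window Maximum span (residues, first to last cysteine) of a scaffold.
#' @param motif_spacer Length-2 integer range for the residues between the
#'   `CC` doublet and the final cysteine.
#' @param max_doublet_gap Maximum residues between the cysteine preceding the
#'   doublet and the doublet itself.
#' @param require_cn If `TRUE`, the terminal `CN` motif is mandatory instead
#'   of merely preferred.
#' @param check_multi_scaffold If `TRUE` (default), records with two or more
#'   disjoint scaffolds are dropped by curation in addition to the length
#'   cut; disable to recover a pure length-based rule.
#' @param min_domain_length Minimal plausible LU-domain length.
#' @param margin Residues added on each side when extracting a domain.
#' @return A list of class `curation_config`.
#' @export
curation_config <- function(max_length = 190L, min_cys = 8L, max_cys = 10L,
                            window = 170L, motif_spacer = c(3L, 5L),
                            max_doublet_gap = 30L, require_cn = FALSE,
                            check_multi_scaffold = TRUE,
                            min_domain_length = 60L, margin = 2L) {
  stopifnot(min_cys <= max_cys, max_length > 0, window > 0,
            length(motif_spacer) == 2, motif_spacer[1] <= motif_spacer[2],
            margin >= 0)
  structure(list(max_length = as.integer(max_length),
                 min_cys = as.integer(min_cys),
                 max_cys = as.integer(max_cys),
                 window = as.integer(window),
                 motif_spacer = as.integer(motif_spacer),
                 max_doublet_gap = as.integer(max_doublet_gap),
                 require_cn = require_cn,
                 check_multi_scaffold = check_multi_scaffold,
                 min_domain_length = as.integer(min_domain_length),
                 margin = as.integer(margin)),
            class = "curation_config")
}

# All candidate scaffolds of one sequence: consecutive runs of cysteine
# positions satisfying count, span and terminal-signature constraints.
# Returns a tibble (one row per candidate) with a list-column of positions.
scaffold_candidates <- function(residues, config) {
  cys <- which(strsplit(residues, "")[[1]] == "C")
  n <- length(cys)
  len <- nchar(residues)
  out <- list()
  if (n >= config$min_cys) {
    for (i in seq_len(n)) {
      for (m in config$min_cys:config$max_cys) {
        j <- i + m - 1L
        if (j > n) break
        q <- cys[i:j]
        if (q[m] - q[1] + 1L > config$window) next
        # terminal signature on the last four cysteines:
        # C ...(<= max_doublet_gap)... CC x(spacer) C [N]
        doublet <- q[m - 1L] == q[m - 2L] + 1L
        spacer <- q[m] - q[m - 1L] - 1L
        gap_ok <- (q[m - 2L] - q[m - 3L] - 1L) <= config$max_doublet_gap
        if (!doublet || spacer < config$motif_spacer[1] ||
            spacer > config$motif_spacer[2] || !gap_ok) next
        cn <- q[m] < len && substr(residues, q[m] + 1L, q[m] + 1L) == "N"
        if (config$require_cn && !cn) next
        out[[length(out) + 1L]] <- tibble::tibble(
          start = q[1], end = q[m], n_cys = m, cn_motif = cn,
          positions = list(q))
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          n_cys = integer(), cn_motif = logical(),
                          positions = list()))
  }
  dplyr::bind_rows(out)
}

#' Detect the LU-domain cysteine scaffold in a protein sequence
#'
#' Scans for 8-10 consecutive cysteines within a bounded window whose final
#' four match the Ly6/uPAR C-terminal signature (see [curation_config()]).
#' Among candidate windows the best-scoring one is returned: windows with
#' the terminal `CN` motif outrank those without, then more cysteines, then
#' the leftmost start.
#'
#' @param record A one-row record tibble (with `residues`) or a plain
#'   protein string.
#' @param config A [curation_config()].
#' @return A list of class `cysteine_scaffold` with `cys_positions` (1-based)
#'   and `n_cys`, or `NULL` when no scaffold is present (a valid result,
#'   not an error).
#' @examples
#' detect_scaffold(strrep("A", 100)) # NULL: no cysteines
#' @export
detect_scaffold <- function(record, config = curation_config()) {
  residues <- record_residues(record)
  cand <- scaffold_candidates(residues, config)
  if (nrow(cand) == 0) return(NULL)
  cand <- dplyr::arrange(cand, dplyr::desc(.data$cn_motif),
                         dplyr::desc(.data$n_cys), .data$start)
  q <- cand$positions[[1]]
  structure(list(cys_positions = q, n_cys = length(q)),
            class = "cysteine_scaffold")
}

# Number of pairwise-disjoint accepted scaffolds (greedy interval scheduling
# by end position); >= 2 flags a multi-domain protein.
count_disjoint_scaffolds <- function(residues, config) {
  cand <- scaffold_candidates(residues, config)
  if (nrow(cand) == 0) return(0L)
  cand <- dplyr::arrange(cand, .data$end)
  n <- 0L
  last_end <- 0L
  for (k in seq_len(nrow(cand))) {
    if (cand$start[k] > last_end) {
      n <- n + 1L
      last_end <- cand$end[k]
    }
  }
  n
}

#' Extract an LU-domain around a detected scaffold
#'
#' The domain spans from `margin` residues before the first scaffold
#' cysteine to `margin` residues after the last one, clipped to the sequence
#' bounds. All coordinates are 1-based inclusive.
#'
#' @param record A one-row record tibble or a plain protein string.
#' @param scaffold A `cysteine_scaffold` detected on this record.
#' @param margin Non-negative flank width (default from [curation_config()]).
#' @return A one-row tibble with `parent_id`, `start`, `end`, `n_cys`,
#'   `cys_positions` (list-column, parent coordinates) and `residues`.
#' @export
extract_lu_domain <- function(record, scaffold, margin = 2L) {
  residues <- record_residues(record)
  parent_id <- record_id(record)
  stopifnot(inherits(scaffold, "cysteine_scaffold"), margin >= 0)
  q <- scaffold$cys_positions
  if (any(substring(residues, q, q) != "C")) {
    stop("scaffold positions do not hold 'C' on this record", call. = FALSE)
  }
  start <- max(1L, q[1] - as.integer(margin))
  end <- min(nchar(residues), q[length(q)] + as.integer(margin))
  if (end - start + 1L < 60L) {
    stop("extracted domain is shorter than 60 residues (", end - start + 1L,
         ")", call. = FALSE)
  }
  tibble::tibble(parent_id = parent_id, start = start, end = end,
                 n_cys = scaffold$n_cys, cys_positions = list(q),
                 residues = substr(residues, start, end))
}

#' Curate a reference set of single-LU-domain proteins
#'
#' Keeps records no longer than `config$max_length` residues that carry
#' exactly one detected scaffold, and returns their extracted LU-domains in
#' input order. The length cut is the primary multi-domain exclusion; the
#' disjoint-scaffold check is a stricter superset that can be disabled via
#' `check_multi_scaffold = FALSE` in the config.
#'
#' @param records A record tibble from [read_fasta()].
#' @param config A [curation_config()].
#' @return A domain tibble (`parent_id`, `start`, `end`, `n_cys`,
#'   `cys_positions`, `residues`), one row per kept record.
#' @export
curate_reference_set <- function(records, config = curation_config()) {
  check_records(records)
  empty <- tibble::tibble(parent_id = character(), start = integer(),
                          end = integer(), n_cys = integer(),
                          cys_positions = list(), residues = character())
  if (nrow(records) == 0) return(empty)
  kept <- purrr::pmap(records, function(id, residues, ...) {
    if (nchar(residues) > config$max_length) return(NULL)
    scaffold <- detect_scaffold(residues, config)
    if (is.null(scaffold)) return(NULL)
    if (config$check_multi_scaffold &&
        count_disjoint_scaffolds(residues, config) >= 2L) {
      return(NULL)
    }
    dom <- tryCatch(
      extract_lu_domain(residues, scaffold, margin = config$margin),
      error = function(e) NULL)
    if (is.null(dom)) return(NULL)
    dom$parent_id <- id
    dom
  })
  kept <- purrr::compact(kept)
  if (length(kept) == 0) return(empty)
  dplyr::bind_rows(kept)
}

#' Serialize a domain table to TSV
#'
#' Writes `parent_id`, `start`, `end`, `n_cys` and `sequence` columns;
#' coordinates are 1-based inclusive.
#'
#' @param domains A domain tibble from [curate_reference_set()].
#' @param path Output path.
#' @return `domains`, invisibly.
#' @export
write_domain_table <- function(domains, path) {
  out <- tibble::tibble(parent_id = domains$parent_id,
                        start = domains$start, end = domains$end,
                        n_cys = domains$n_cys, sequence = domains$residues)
  write_tsv_output(out, path)
  invisible(domains)
}

record_residues <- function(record) {
  if (is.character(record) && length(record) == 1) return(record)
  if (is.data.frame(record) && nrow(record) == 1 && "residues" %in% names(record)) {
    return(record$residues)
  }
  stop("expected a single protein string or a one-row record tibble",
       call. = FALSE)
}

record_id <- function(record) {
  if (is.data.frame(record) && "id" %in% names(record)) return(record$id)
  NA_character_
}
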