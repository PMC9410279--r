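HYDROGEN_MASS <- 1.00794
WATER_MASS <- 18.01528

#' Disulfide-corrected average protein mass
#'
#' Average (not monoisotopic) molecular mass of a protein chain, minus two
#' hydrogen masses per closed disulfide bond -- the quantity an ESI/MALDI
#' deconvolution of an oxidatively folded protein reports. Chain masses use
#' the standard average residue mass table.
#'
#' @param sequence A protein string over the 20 standard residues (or a
#'   one-row record tibble).
#' @param n_disulfides Number of closed disulfide bonds; requires
#'   `2 * n_disulfides` cysteines in the sequence.
#' @return A one-row tibble: `average_mass` (Da), `n_disulfides`,
#'   `n_residues`.
#' @examples
#' average_mass("G")$average_mass  # 75.07
#' @export
average_mass <- function(sequence, n_disulfides = 0L) {
  sequence <- record_residues(sequence)
  chars <- strsplit(sequence, "")[[1]]
  if (!all(chars %in% AA_ALPHABET)) {
    stop("mass is defined only over the 20 standard residues", call. = FALSE)
  }
  stopifnot(n_disulfides >= 0)
  n_cys <- sum(chars == "C")
  if (2 * n_disulfides > n_cys) {
    stop("sequence has ", n_cys, " cysteines; cannot close ", n_disulfides,
         " disulfide bonds", call. = FALSE)
  }
  mass <- seqinr::pmw(chars) - n_disulfides * 2 * HYDROGEN_MASS
  tibble::tibble(average_mass = unname(mass),
                 n_disulfides = as.integer(n_disulfides),
                 n_residues = length(chars))
}

#' Reverse complement of a nucleotide string
#'
#' @param x A nucleotide string over ACGT(N).
#' @return The reverse-complemented string.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' In-silico PCR on a transcript template
#'
#' Locates exact binding sites of the forward primer and of the reverse
#' complement of the reverse primer on the given strand of the template,
#' and returns the unique delimited product. Matching is exact (no
#' mismatches): the use case is verifying that designed primers delimit the
#' expected amplicon on their own template.
#'
#' @param template A nucleotide record (one-row tibble from
#'   [read_fasta()]) or a plain nucleotide string.
#' @param forward,reverse Primer strings, each at least 15 nt.
#' @return A one-row amplicon tibble (`start`, `end` 1-based inclusive on
#'   the template, `length`, `sequence`, `predicted_tm` at 50 mM Na+ when
#'   the product is at least 50 bp, else `NA`). If either primer has no
#'   site, a zero-row tibble ("no product") is returned; multiple candidate
#'   products are an error listing all coordinate pairs.
#' @export
insilico_pcr <- function(template, forward, reverse) {
  template <- record_residues(template)
  stopifnot(nchar(forward) >= 15, nchar(reverse) >= 15)
  subj <- Biostrings::DNAString(template)
  f_hits <- Biostrings::matchPattern(Biostrings::DNAString(forward), subj)
  r_site <- Biostrings::reverseComplement(Biostrings::DNAString(reverse))
  r_hits <- Biostrings::matchPattern(r_site, subj)
  no_product <- tibble::tibble(start = integer(), end = integer(),
                               length = integer(), sequence = character(),
                               predicted_tm = numeric())
  if (length(f_hits) == 0 || length(r_hits) == 0) return(no_product)
  idx <- tidyr::expand_grid(fi = seq_along(f_hits), ri = seq_along(r_hits))
  cand <- tibble::tibble(
    f_start = Biostrings::start(f_hits)[idx$fi],
    f_end = Biostrings::end(f_hits)[idx$fi],
    r_start = Biostrings::start(r_hits)[idx$ri],
    r_end = Biostrings::end(r_hits)[idx$ri]) |>
    dplyr::filter(.data$r_start >= .data$f_start, .data$r_end >= .data$f_end)
  if (nrow(cand) == 0) return(no_product)
  if (nrow(cand) > 1) {
    coords <- paste(sprintf("[%d..%d]", cand$f_start, cand$r_end),
                    collapse = ", ")
    stop("multiple candidate products: ", coords, call. = FALSE)
  }
  start <- cand$f_start
  end <- cand$r_end
  seq <- substr(template, start, end)
  len <- end - start + 1L
  tm <- if (len >= 50) product_tm(seq) else NA_real_
  tibble::tibble(start = start, end = end, length = len, sequence = seq,
                 predicted_tm = tm)
}

#' Predicted melting temperature of a PCR product
#'
#' Empirical duplex formula for products of 50 bp and longer:
#' `Tm = 81.5 + 0.41 * %GC - 675 / length + 16.6 * log10([Na+])`.
#' Not valid for primer-scale oligos, hence the length floor.
#'
#' @param amplicon A nucleotide string, or a one-row amplicon tibble from
#'   [insilico_pcr()] (its `sequence` is used).
#' @param na_molar Monovalent cation concentration in mol/L (default 0.05).
#' @return Predicted Tm in degrees Celsius.
#' @export
product_tm <- function(amplicon, na_molar = 0.05) {
  seq <- if (is.data.frame(amplicon)) amplicon$sequence else amplicon
  stopifnot(is.character(seq), length(seq) == 1, na_molar > 0)
  len <- nchar(seq)
  if (len < 50) {
    stop("Tm formula requires a product of at least 50 bp (got ", len, ")",
         call. = FALSE)
  }
  chars <- strsplit(seq, "")[[1]]
  pct_gc <- 100 * sum(chars %in% c("G", "C")) / len
  81.5 + 0.41 * pct_gc - 675 / len + 16.6 * log10(na_molar)
}
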