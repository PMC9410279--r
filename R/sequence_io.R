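#' Read a FASTA file into a tibble of sequence records
#'
#' Parses a multi-record FASTA file and returns one row per record. Residues
#' are uppercased on read; the record identifier is the first whitespace
#' token of the header, the remainder is kept as the description. Gap (`-`)
#' and stop (`*`) characters are rejected: gaps exist only inside alignment
#' objects. Ambiguity codes (`X B Z J U O` for protein, `N` for nucleotide)
#' are accepted but flagged in the `has_ambiguity` column; scoring functions
#' apply a conservative minimum-over-expansion fallback to them.
#'
#' @param path Path to a FASTA file. An empty file yields a zero-row tibble.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return A tibble with columns `id`, `description`, `residues`,
#'   `has_ambiguity`, in file order.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a first", "acdef", ">b", "GGH"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) {
    stop("FASTA file does not exist: ", path, call. = FALSE)
  }
  if (file.size(path) == 0 || length(readLines(path, n = 1L, warn = FALSE)) == 0) {
    return(empty_records())
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("Malformed FASTA at line ", first_bad_fasta_line(path), " of ",
           path, ": ", conditionMessage(e), call. = FALSE)
    }
  )
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  residues <- toupper(as.character(set))
  bad <- residue_violations(residues, alphabet)
  if (!is.null(bad)) {
    stop("Illegal ", alphabet, " symbol '", bad$symbol, "' in record '",
         id[bad$record], "' (line ", symbol_line(path, bad$symbol, id[bad$record]),
         " of ", path, ")", call. = FALSE)
  }
  if (any(nchar(residues) == 0)) {
    stop("Record '", id[which(nchar(residues) == 0)[1]],
         "' has an empty sequence", call. = FALSE)
  }
  tibble::tibble(
    id = unname(id),
    description = unname(description),
    residues = unname(residues),
    has_ambiguity = has_ambiguity(residues, alphabet)
  )
}

#' Write sequence records to a FASTA file
#'
#' @param records A tibble with at least `id` and `residues` columns (an
#'   optional `description` is appended to the header).
#' @param path Output path.
#' @param width Line-wrap width for the sequence body (default 60).
#' @return `records`, invisibly, so calls can be piped through.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.numeric(width), width >= 1)
  check_records(records)
  if (nrow(records) == 0) {
    file.create(path)
    return(invisible(records))
  }
  desc <- if ("description" %in% names(records)) records$description
          else rep("", nrow(records))
  desc[is.na(desc)] <- ""
  headers <- ifelse(desc == "", records$id, paste(records$id, desc))
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(width))
  invisible(records)
}

#' Write a tibble as a tab-separated table
#'
#' All tabular pipeline outputs are UTF-8 TSV with a header row.
#' @param x A data frame.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_tsv_output <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

empty_records <- function() {
  tibble::tibble(id = character(), description = character(),
                 residues = character(), has_ambiguity = logical())
}

check_records <- function(records) {
  if (!is.data.frame(records) || !all(c("id", "residues") %in% names(records))) {
    stop("records must be a data frame with 'id' and 'residues' columns",
         call. = FALSE)
  }
  if (nrow(records) > 0) {
    if (anyNA(records$id) || anyNA(records$residues)) {
      stop("record ids and residues must not be NA", call. = FALSE)
    }
    if (any(grepl("\\s", records$id))) {
      stop("record ids must not contain whitespace", call. = FALSE)
    }
    if (any(nchar(records$residues) == 0)) {
      stop("records must have non-empty residues", call. = FALSE)
    }
  }
  invisible(records)
}

alphabet_symbols <- function(alphabet, with_ambiguity = TRUE) {
  base <- if (alphabet == "protein") AA_ALPHABET else NT_ALPHABET
  amb <- if (alphabet == "protein") AA_AMBIGUITY else NT_AMBIGUITY
  if (with_ambiguity) c(base, amb) else base
}

residue_violations <- function(residues, alphabet) {
  allowed <- alphabet_symbols(alphabet)
  pattern <- paste0("[^", paste(allowed, collapse = ""), "]")
  hit <- regexpr(pattern, residues)
  idx <- which(hit > 0)
  if (length(idx) == 0) return(NULL)
  list(record = idx[1],
       symbol = substr(residues[idx[1]], hit[idx[1]], hit[idx[1]]))
}

has_ambiguity <- function(residues, alphabet) {
  amb <- if (alphabet == "protein") AA_AMBIGUITY else NT_AMBIGUITY
  grepl(paste0("[", paste(amb, collapse = ""), "]"), residues)
}

# Locate the line of the first offending symbol for an error message; only
# called on the failure path, so a plain line scan is fine.
symbol_line <- function(path, symbol, id) {
  lines <- readLines(path, warn = FALSE)
  in_record <- FALSE
  for (k in seq_along(lines)) {
    if (startsWith(lines[k], ">")) {
      in_record <- sub("\\s.*$", "", sub("^>", "", lines[k])) == id
    } else if (in_record && grepl(symbol, toupper(lines[k]), fixed = TRUE)) {
      return(k)
    }
  }
  NA_integer_
}

first_bad_fasta_line <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seen_header <- FALSE
  for (k in seq_along(lines)) {
    if (startsWith(lines[k], ">")) seen_header <- TRUE
    else if (!seen_header && nzchar(trimws(lines[k]))) return(k)
  }
  1L
}
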