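#' Configuration of a full discovery run
#'
#' Collects every knob of the curate - search - extract - align - tree -
#' similarity pipeline into one object that [run_pipeline()] consumes and
#' that the run manifest echoes, so a run can be reproduced bit-identically
#' from its manifest.
#'
#' @param reference_path Protein FASTA of reference single-LU-domain
#'   proteins.
#' @param proteome_path Protein FASTA of the target proteome.
#' @param output_dir Directory for the report bundle (created if absent).
#' @param curation A [curation_config()].
#' @param search A [search_config()].
#' @param matrix Matrix for the distance/MSA/similarity stages:
#'   `"modified"` (cysteine-anchored, the default) or `"blosum62"`. The
#'   search stage always scores with plain BLOSUM62, whose Karlin-Altschul
#'   statistics are valid; the anchored matrix is an alignment device, not
#'   a search statistic.
#' @param msa_gap_open,msa_gap_extend Gap penalties of the progressive
#'   alignment stage.
#' @param similarity_mode `"msa"` (score MSA rows) or `"pairwise"` (score
#'   fresh pairwise alignments).
#' @param seed Integer seed echoed into the manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(reference_path, proteome_path, output_dir,
                            curation = curation_config(),
                            search = search_config(),
                            matrix = c("modified", "blosum62"),
                            msa_gap_open = 10, msa_gap_extend = 0.2,
                            similarity_mode = c("msa", "pairwise"),
                            seed = 1L) {
  structure(list(reference_path = reference_path,
                 proteome_path = proteome_path,
                 output_dir = output_dir,
                 curation = curation, search = search,
                 matrix = match.arg(matrix),
                 msa_gap_open = msa_gap_open,
                 msa_gap_extend = msa_gap_extend,
                 similarity_mode = match.arg(similarity_mode),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Check a pipeline configuration without running it
#'
#' @param config A [pipeline_config()].
#' @return A character vector of problems, each naming the offending field;
#'   empty when the configuration is runnable.
#' @export
validate_config <- function(config) {
  problems <- character()
  note <- function(p) problems <<- c(problems, p)
  if (!is.character(config$reference_path) || !file.exists(config$reference_path)) {
    note("reference_path: file does not exist")
  }
  if (!is.character(config$proteome_path) || !file.exists(config$proteome_path)) {
    note("proteome_path: file does not exist")
  }
  if (!is.numeric(config$search$evalue_threshold) ||
      config$search$evalue_threshold <= 0) {
    note("search$evalue_threshold: must be > 0")
  }
  if (!config$matrix %in% c("modified", "blosum62")) {
    note("matrix: must be 'modified' or 'blosum62'")
  }
  if (!is.numeric(config$msa_gap_open) || config$msa_gap_open <= 0) {
    note("msa_gap_open: must be > 0")
  }
  if (!is.numeric(config$msa_gap_extend) || config$msa_gap_extend <= 0) {
    note("msa_gap_extend: must be > 0")
  }
  problems
}

#' Load a pipeline configuration from a YAML file
#'
#' Flat keys mirror the [pipeline_config()] arguments; nested `curation:`
#' and `search:` blocks override individual fields of those configs.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cur <- do.call(curation_config, y$curation %||% list())
  srch <- do.call(search_config, y$search %||% list())
  pipeline_config(reference_path = y$reference_path,
                  proteome_path = y$proteome_path,
                  output_dir = y$output_dir,
                  curation = cur, search = srch,
                  matrix = y$matrix %||% "modified",
                  msa_gap_open = y$msa_gap_open %||% 10,
                  msa_gap_extend = y$msa_gap_extend %||% 0.2,
                  similarity_mode = y$similarity_mode %||% "msa",
                  seed = y$seed %||% 1L)
}

#' Run the full LU-domain discovery pipeline
#'
#' Executes, in order: reference curation, proteome search, candidate
#' LU-domain extraction, pooling of candidates with references, guide-tree
#' construction, progressive multiple alignment, and grouped-residue
#' similarity. Writes the report bundle (`hits.tsv`, `hit_matrix.tsv`,
#' `candidates.fasta`, `msa.fasta`, `tree.nwk`, `similarity.tsv`,
#' `run_manifest.yml`, `run.log`) into `config$output_dir`. Candidate
#' domains are the hit subjects' detected scaffolds; when no scaffold is
#' found on a hit subject the best hit's subject span is used instead, with
#' a warning. Every stage logs its record count; any stage error aborts the
#' run, names the stage, and removes partial outputs.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `lu_run`: the per-stage objects (`references`,
#'   `ref_domains`, `proteome`, `hits`, `candidates`, `pool`, `tree`,
#'   `msa`, `similarity`), the bundle file paths (`files`) and the stage
#'   `counts`.
#' @export
run_pipeline <- function(config) {
  problems <- validate_config(config)
  if (length(problems) > 0) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(config$output_dir,
                     c(hits = "hits.tsv", hit_matrix = "hit_matrix.tsv",
                       candidates = "candidates.fasta", msa = "msa.fasta",
                       tree = "tree.nwk", similarity = "similarity.tsv",
                       manifest = "run_manifest.yml", log = "run.log"))
  names(files) <- c("hits", "hit_matrix", "candidates", "msa", "tree",
                    "similarity", "manifest", "log")
  log_lines <- character()
  log_stage <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- "setup"
  result <- tryCatch({
    align_matrix <- if (config$matrix == "modified") cysteine_anchored_matrix()
                    else blosum62()
    search_matrix <- blosum62()

    stage <- "curate"
    references <- read_fasta(config$reference_path, "protein")
    ref_domains <- curate_reference_set(references, config$curation)
    if (nrow(ref_domains) == 0) stop("no reference LU-domains survived curation")
    log_stage("curate: ", nrow(references), " reference records -> ",
              nrow(ref_domains), " LU-domains")

    stage <- "search"
    proteome <- read_fasta(config$proteome_path, "protein")
    hits <- search_proteome(ref_domains, proteome, search_matrix, config$search)
    log_stage("search: ", nrow(proteome), " proteome records -> ",
              nrow(hits), " hits below e = ",
              format(config$search$evalue_threshold))

    stage <- "extract"
    subject_ids <- unique(hits$subject_id)
    candidates <- extract_candidates(hits, proteome, config$curation)
    log_stage("extract: ", length(subject_ids), " hit subjects -> ",
              nrow(candidates), " candidate domains")

    stage <- "align"
    pool <- dplyr::bind_rows(ref_domains, candidates)
    dm <- distance_matrix(pool, align_matrix, config$search)
    tree <- neighbor_joining(dm)
    msa <- progressive_align(pool, tree, align_matrix,
                             config$msa_gap_open, config$msa_gap_extend)
    log_stage("align: ", nrow(pool), " pooled domains, ",
              nchar(msa$aligned[1]), " alignment columns")

    stage <- "similarity"
    sim <- if (nrow(pool) < 2) {
      structure(matrix(100, 1, 1, dimnames = list(pool$parent_id,
                                                  pool$parent_id)),
                class = c("lu_similarity", "matrix", "array"))
    } else if (config$similarity_mode == "msa") {
      similarity_matrix(msa)
    } else {
      pairwise_similarity_matrix(pool, align_matrix, config$search)
    }
    log_stage("similarity: ", nrow(sim), " x ", ncol(sim), " matrix (",
              config$similarity_mode, " mode)")

    stage <- "write"
    write_tsv_output(dplyr::select(hits, "query_id", "subject_id",
                                   "raw_score", "bit_score", "evalue",
                                   "q_start", "q_end", "s_start", "s_end"),
                     files[["hits"]])
    write_tsv_output(hit_matrix(hits), files[["hit_matrix"]])
    write_fasta(tibble::tibble(id = candidates$parent_id,
                               description = sprintf("LU-domain %d..%d (1-based inclusive)",
                                                     candidates$start,
                                                     candidates$end),
                               residues = candidates$residues),
                files[["candidates"]])
    write_alignment_fasta(msa, files[["msa"]])
    writeLines(to_newick(tree), files[["tree"]])
    write_similarity_tsv(sim, files[["similarity"]])
    yaml::write_yaml(manifest_of(config), files[["manifest"]])
    writeLines(log_lines, files[["log"]])

    structure(list(references = references, ref_domains = ref_domains,
                   proteome = proteome, hits = hits,
                   candidates = candidates, pool = pool, tree = tree,
                   msa = msa, similarity = sim, files = files,
                   counts = c(references = nrow(references),
                              ref_domains = nrow(ref_domains),
                              proteome = nrow(proteome),
                              hits = nrow(hits),
                              candidates = nrow(candidates),
                              pool = nrow(pool))),
              class = "lu_run")
  }, error = function(e) {
    unlink(files[file.exists(files)])
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  result
}

# Candidate LU-domains of hit subjects: detected scaffold when present,
# else the best hit's subject span (with a warning).
extract_candidates <- function(hits, proteome, curation) {
  empty <- tibble::tibble(parent_id = character(), start = integer(),
                          end = integer(), n_cys = integer(),
                          cys_positions = list(), residues = character())
  if (nrow(hits) == 0) return(empty)
  out <- lapply(unique(hits$subject_id), function(sid) {
    rec <- proteome[proteome$id == sid, ]
    scaffold <- detect_scaffold(rec$residues, curation)
    if (!is.null(scaffold)) {
      dom <- tryCatch(extract_lu_domain(rec$residues, scaffold,
                                        margin = curation$margin),
                      error = function(e) NULL)
      if (!is.null(dom)) {
        dom$parent_id <- sid
        return(dom)
      }
    }
    warning("no scaffold detected on hit subject '", sid,
            "'; falling back to the best hit span", call. = FALSE)
    best <- hits[hits$subject_id == sid, ][1, ]
    span <- substr(rec$residues, best$s_start, best$s_end)
    tibble::tibble(parent_id = sid, start = best$s_start, end = best$s_end,
                   n_cys = sum(strsplit(span, "")[[1]] == "C"),
                   cys_positions = list(best$s_start - 1L +
                                          which(strsplit(span, "")[[1]] == "C")),
                   residues = span)
  })
  dplyr::bind_rows(out)
}

# Manifest: everything needed to re-run bit-identically. Output location is
# deliberately not part of the manifest so that two runs of one manifest
# into different directories compare byte-identical.
manifest_of <- function(config) {
  list(tool = "lustar",
       version = as.character(utils::packageVersion("lustar")),
       seed = config$seed,
       inputs = list(reference_path = config$reference_path,
                     reference_md5 = unname(tools::md5sum(config$reference_path)),
                     proteome_path = config$proteome_path,
                     proteome_md5 = unname(tools::md5sum(config$proteome_path))),
       matrix = config$matrix,
       curation = unclass(config$curation),
       search = unclass(config$search),
       msa = list(gap_open = config$msa_gap_open,
                  gap_extend = config$msa_gap_extend),
       similarity_mode = config$similarity_mode)
}

#' @export
print.lu_run <- function(x, ...) {
  cat("<lustar pipeline run>\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-12s %d\n", nm, x$counts[[nm]]))
  }
  cat("  bundle:     ", dirname(x$files[[1]]), "\n")
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x An `lu_run` object.
#' @param ... Unused.
#' @return A one-row tibble of per-stage record counts.
#' @method glance lu_run
#' @export
glance.lu_run <- function(x, ...) {
  tibble::as_tibble(as.list(x$counts))
}
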