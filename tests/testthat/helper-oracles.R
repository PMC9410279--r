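# Independent brute-force oracle for affine-gap local alignment.
#
# A local alignment is a pairing of an index subsequence of `a` with an
# equal-length index subsequence of `b`; internal skips form gap runs, each
# costing gap_open + len * gap_extend. Enumerating every pairing (there are
# sum_k C(n,k) C(m,k) of them, tiny for the lengths used here) and taking
# the best score is exact and shares no code with the DP implementation.
oracle_local_score <- function(a, b, scores, gap_open = 11, gap_extend = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca)
  m <- length(cb)
  best <- 0
  for (k in seq_len(min(n, m))) {
    ia_all <- utils::combn(n, k)
    ib_all <- utils::combn(m, k)
    for (p in seq_len(ncol(ia_all))) {
      ia <- ia_all[, p]
      pair_a <- scores[ca[ia], , drop = FALSE]
      gaps_a <- gap_run_cost(ia, gap_open, gap_extend)
      for (q in seq_len(ncol(ib_all))) {
        ib <- ib_all[, q]
        s <- sum(pair_a[cbind(seq_len(k), match(cb[ib], colnames(scores)))]) -
          gaps_a - gap_run_cost(ib, gap_open, gap_extend)
        if (s > best) best <- s
      }
    }
  }
  best
}

gap_run_cost <- function(idx, gap_open, gap_extend) {
  if (length(idx) < 2) return(0)
  runs <- diff(idx) - 1
  runs <- runs[runs > 0]
  if (length(runs) == 0) return(0)
  sum(gap_open + runs * gap_extend)
}

# All sequences of the given lengths over an alphabet (for exhaustive cases).
all_sequences <- function(alphabet, lengths) {
  unlist(lapply(lengths, function(l) {
    apply(do.call(expand.grid, rep(list(alphabet), l)), 1, paste0,
          collapse = "")
  }), use.names = FALSE)
}

random_protein <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# A small curated-style record set with known composition: `n_good`
# single-scaffold records, `n_double` two-scaffold records, `n_long`
# oversized records (> 190 residues).
mixed_record_set <- function(n_good = 20, n_double = 5, n_long = 5, seed = 1) {
  fam <- generate_family(scaffold_spec(10), n_members = n_good + n_double + n_long,
                         mutation_rate = 0.2, seed = seed)
  rec <- fam$records
  non_cys <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "C")
  withr::with_seed(seed + 1, {
    for (i in seq_len(n_double)) {
      k <- n_good + i
      rec$residues[k] <- paste0(rec$residues[k],
                                paste(sample(non_cys, 15, replace = TRUE),
                                      collapse = ""),
                                rec$residues[k])
    }
    for (i in seq_len(n_long)) {
      k <- n_good + n_double + i
      pad <- 191 - nchar(rec$residues[k])
      rec$residues[k] <- paste0(rec$residues[k],
                                paste(sample(non_cys, pad, replace = TRUE),
                                      collapse = ""))
    }
  })
  rec$id <- sprintf("rec_%02d", seq_len(nrow(rec)))
  rec
}
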