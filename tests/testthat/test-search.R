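test_that("hand-checkable local alignments score as expected", {
  h <- smith_waterman("CASSC", "CASSC", cysteine_anchored_matrix())
  expect_equal(h$raw_score, 210) # 99 + 4 + 4 + 4 + 99, no gaps
  expect_equal(c(h$q_start, h$q_end, h$s_start, h$s_end), c(1, 5, 1, 5))
  expect_equal(h$aligned_query, "CASSC")
  # A/G scores 0 in BLOSUM62: no positive cell, empty alignment
  h0 <- smith_waterman("AAAA", "GGGG", blosum62())
  expect_equal(h0$raw_score, 0)
  expect_equal(h0$aligned_query, "")
  expect_equal(c(h0$q_start, h0$q_end), c(0, 0))
})

test_that("DP equals the brute-force oracle on exhaustive short pairs", {
  alphabet <- c("A", "C", "D", "W")
  seqs <- all_sequences(alphabet, 1:3)
  cfg <- search_config()
  for (m in list(blosum62(), cysteine_anchored_matrix())) {
    scores <- unclass(m)
    withr::with_seed(7, {
      pairs <- expand.grid(a = seqs, b = seqs, stringsAsFactors = FALSE)
      pairs <- pairs[sample(nrow(pairs), 400), ]
    })
    got <- mapply(function(a, b) {
      smith_waterman(a, b, m, cfg)$raw_score
    }, pairs$a, pairs$b)
    want <- mapply(function(a, b) {
      oracle_local_score(a, b, scores, cfg$gap_open, cfg$gap_extend)
    }, pairs$a, pairs$b)
    expect_equal(unname(got), unname(want))
  }
})

test_that("DP equals the brute-force oracle on random length-6 pairs", {
  alphabet <- c("A", "C", "D", "W")
  cfg <- search_config()
  scores <- unclass(cysteine_anchored_matrix())
  withr::with_seed(11, {
    for (trial in 1:150) {
      a <- random_protein(sample(3:6, 1), alphabet)
      b <- random_protein(sample(3:6, 1), alphabet)
      expect_equal(smith_waterman(a, b, cysteine_anchored_matrix(), cfg)$raw_score,
                   oracle_local_score(a, b, scores, cfg$gap_open, cfg$gap_extend))
    }
  })
})

test_that("local score agrees with an independent aligner on realistic pairs", {
  ref <- get(data("BLOSUM62", package = "Biostrings", envir = environment()))
  withr::with_seed(13, {
    for (trial in 1:25) {
      motif <- random_protein(10)
      a <- paste0(random_protein(15), motif, random_protein(15))
      b <- paste0(random_protein(10), motif, random_protein(20))
      ours <- smith_waterman(a, b, blosum62())$raw_score
      theirs <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(a), Biostrings::AAString(b),
        substitutionMatrix = ref, gapOpening = 11, gapExtension = 1,
        type = "local", scoreOnly = TRUE)
      expect_equal(ours, theirs)
    }
  })
})

test_that("alignment score is symmetric and spans re-slice the inputs", {
  withr::with_seed(17, {
    for (trial in 1:20) {
      a <- random_protein(sample(20:60, 1))
      b <- random_protein(sample(20:60, 1))
      ha <- smith_waterman(a, b)
      hb <- smith_waterman(b, a)
      expect_equal(ha$raw_score, hb$raw_score)
      if (ha$raw_score > 0) {
        expect_equal(gsub("-", "", ha$aligned_query),
                     substr(a, ha$q_start, ha$q_end))
        expect_equal(gsub("-", "", ha$aligned_subject),
                     substr(b, ha$s_start, ha$s_end))
      }
    }
  })
})

test_that("Karlin-Altschul scaling behaves as the closed form dictates", {
  cfg <- search_config()
  z <- evalue_of(0, 100, 200, cfg)
  expect_equal(z$bit_score, -log(0.041) / log(2), tolerance = 1e-12)
  expect_equal(z$evalue, 100 * 200 * 2^(-z$bit_score), tolerance = 1e-12)
  # doubling the subject length doubles E exactly
  expect_equal(evalue_of(50, 100, 400, cfg)$evalue,
               2 * evalue_of(50, 100, 200, cfg)$evalue)
  # bit score strictly increasing in the raw score
  bits <- evalue_of(0:100, 50, 50, cfg)$bit_score
  expect_true(all(diff(bits) > 0))
  # hit invariants: bit and E recompute from the reported raw score
  h <- smith_waterman("CASSC", "CASSCA", cysteine_anchored_matrix())
  expect_equal(h$bit_score,
               (cfg$lambda * h$raw_score - log(cfg$k_param)) / log(2),
               tolerance = 1e-9)
  expect_equal(h$evalue, 5 * 6 * 2^(-h$bit_score), tolerance = 1e-9)
})

test_that("proteome search recovers an exact planted copy as the top hit", {
  fam <- generate_family(scaffold_spec(9), n_members = 1, mutation_rate = 0,
                         seed = 23)
  refs <- curate_reference_set(fam$records)
  prot <- generate_proteome(n_decoys = 100, length_range = c(80L, 200L),
                            planted = fam$records, seed = 24)
  hits <- search_proteome(refs, prot$records)
  expect_true(fam$records$id[1] %in% hits$subject_id)
  top <- hits[which.min(hits$evalue), ]
  expect_equal(top$subject_id, fam$records$id[1])
  expect_equal(nrow(search_proteome(refs, prot$records[0, ])), 0)
})

test_that("the E-value filter is strict and monotone in the threshold", {
  fam <- generate_family(scaffold_spec(10), n_members = 3,
                         mutation_rate = 0.3, seed = 31)
  refs <- curate_reference_set(fam$records[1, ])
  prot <- generate_proteome(n_decoys = 30, planted = fam$records[2:3, ],
                            seed = 32)
  lenient <- search_proteome(refs, prot$records,
                             config = search_config(evalue_threshold = 1))
  expect_gt(nrow(lenient), 0)
  pivot <- max(lenient$evalue)
  at_pivot <- search_proteome(refs, prot$records,
                              config = search_config(evalue_threshold = pivot))
  above <- search_proteome(refs, prot$records,
                           config = search_config(evalue_threshold = pivot * 1.01))
  # strict inequality: a hit exactly at the threshold is excluded
  expect_false(pivot %in% at_pivot$evalue)
  expect_true(pivot %in% above$evalue)
  # monotonicity: tightening the threshold never adds hits
  keys <- function(h) paste(h$query_id, h$subject_id)
  for (thr in c(1e-8, 1e-5, 1e-2)) {
    sub <- search_proteome(refs, prot$records,
                           config = search_config(evalue_threshold = thr))
    expect_true(all(keys(sub) %in% keys(lenient)))
    expect_true(all(sub$evalue < thr))
  }
})

test_that("hit tables keep the best hit per pair and mark absences", {
  h1 <- tibble::tibble(query_id = "q1", subject_id = "s1", raw_score = 50,
                       bit_score = 20, evalue = 1e-6)
  h2 <- dplyr::mutate(h1, evalue = 5e-7, bit_score = 21)
  h3 <- tibble::tibble(query_id = "q2", subject_id = "s2", raw_score = 40,
                       bit_score = 15, evalue = 1e-5)
  tab <- hit_matrix(dplyr::bind_rows(h1, h2, h3))
  expect_equal(nrow(tab), 4) # 2 subjects x 2 references
  expect_equal(tab$evalue[tab$subject_id == "s1" & tab$query_id == "q1"], 5e-7)
  expect_equal(sum(is.na(tab$evalue)), 2)
  expect_equal(nrow(hit_matrix(h1[0, ])), 0)
})
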