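test_that("pairwise distance matches hand-aligned cases and is symmetric", {
  expect_equal(pairwise_distance("CAC", "CAC"), 0)
  expect_equal(pairwise_distance("CAC", "CGC"), 1 - 2 / 3)
  withr::with_seed(3, {
    for (trial in 1:25) {
      a <- random_protein(sample(10:40, 1))
      b <- random_protein(sample(10:40, 1))
      expect_equal(pairwise_distance(a, b), pairwise_distance(b, a))
      d <- pairwise_distance(a, b)
      expect_gte(d, 0)
      expect_lte(d, 1)
    }
  })
})

test_that("global alignment scores agree with an independent aligner", {
  ref <- get(data("BLOSUM62", package = "Biostrings", envir = environment()))
  withr::with_seed(5, {
    for (trial in 1:20) {
      a <- random_protein(sample(10:30, 1))
      b <- random_protein(sample(10:30, 1))
      ours <- lustar:::needleman_wunsch(a, b, blosum62(), 11, 1)$score
      theirs <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(a), Biostrings::AAString(b),
        substitutionMatrix = ref, gapOpening = 11, gapExtension = 1,
        type = "global", scoreOnly = TRUE)
      expect_equal(ours, theirs)
    }
  })
})

test_that("neighbor joining reproduces closed-form small cases", {
  d3 <- matrix(c(0, .2, .4, .2, 0, .4, .4, .4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d3)
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(lens, c(A = 0.1, B = 0.1, C = 0.3))
  d2 <- matrix(c(0, .5, .5, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(to_newick(neighbor_joining(d2)), "(A:0.250000,B:0.250000);")
  t1 <- neighbor_joining(matrix(0, 1, 1, dimnames = list("solo", "solo")))
  expect_equal(t1$tip.label, "solo")
  bad <- d2
  bad[1, 2] <- 0.7
  expect_error(neighbor_joining(bad), "symmetric")
})

test_that("NJ recovers the generating topology from additive distances", {
  withr::with_seed(19, {
    for (trial in 1:20) {
      true_tree <- ape::rtree(6)
      d <- ape::cophenetic.phylo(true_tree)
      got <- neighbor_joining(d[order(rownames(d)), order(colnames(d))])
      expect_equal(phangorn::RF.dist(ape::unroot(true_tree), got), 0)
    }
  })
})

test_that("negative NJ branch lengths are clamped to zero", {
  withr::with_seed(21, {
    for (trial in 1:10) {
      n <- 6
      d <- matrix(stats::runif(n * n, 0.05, 1), n, n)
      d <- (d + t(d)) / 2
      diag(d) <- 0
      dimnames(d) <- list(letters[1:n], letters[1:n])
      tr <- neighbor_joining(d)
      expect_true(all(tr$edge.length >= 0))
    }
  })
})

test_that("progressive alignment degaps back to its inputs", {
  fam <- generate_family(scaffold_spec(10), n_members = 8,
                         mutation_rate = 0.3, seed = 27)
  doms <- curate_reference_set(fam$records)
  msa <- progressive_align(doms)
  expect_s3_class(msa, "lu_alignment")
  expect_equal(length(unique(nchar(msa$aligned))), 1)
  expect_equal(gsub("-", "", msa$aligned),
               doms$residues[match(msa$id, doms$parent_id)])
  cols <- do.call(rbind, strsplit(msa$aligned, ""))
  expect_false(any(apply(cols, 2, function(x) all(x == "-"))))
})

test_that("degenerate alignments behave: one sequence, identical copies", {
  one <- tibble::tibble(id = "a", residues = "CASSCASSCA")
  m1 <- progressive_align(one)
  expect_equal(m1$aligned, "CASSCASSCA")
  two <- tibble::tibble(id = c("a", "b"),
                        residues = rep(strrep("CASSW", 15), 2))
  m2 <- progressive_align(two)
  expect_equal(m2$aligned[1], m2$aligned[2])
  expect_false(grepl("-", m2$aligned[1]))
})

test_that("cysteine anchoring pins scaffold cysteines into shared columns", {
  fam <- generate_family(scaffold_spec(10), n_members = 6,
                         mutation_rate = 0.3, seed = 29)
  doms <- curate_reference_set(fam$records)
  msa <- progressive_align(doms, matrix = cysteine_anchored_matrix())
  cols <- do.call(rbind, strsplit(msa$aligned, ""))
  all_cys_cols <- sum(apply(cols, 2, function(x) all(x == "C")))
  expect_gte(all_cys_cols, 10) # every scaffold cysteine in a full column
})

test_that("newick serialization round-trips through an independent parser", {
  withr::with_seed(33, {
    for (trial in 1:10) {
      tr <- ape::rtree(10)
      tr$edge.length <- round(tr$edge.length, 6)
      back <- ape::read.tree(text = to_newick(tr))
      expect_equal(phangorn::RF.dist(tr, back), 0)
      expect_equal(sort(back$edge.length), sort(tr$edge.length),
                   tolerance = 1e-9)
    }
  })
  # labels with spaces are quoted
  d2 <- matrix(c(0, .5, .5, 0), 2, 2,
               dimnames = list(c("tip one", "B"), c("tip one", "B")))
  nwk <- to_newick(neighbor_joining(d2))
  expect_match(nwk, "'tip one'", fixed = TRUE)
  back_labels <- gsub("^'|'$", "", ape::read.tree(text = nwk)$tip.label)
  expect_equal(sort(back_labels), sort(c("tip one", "B")))
})

test_that("a guide tree whose leaves mismatch the domains is refused", {
  doms <- tibble::tibble(id = c("a", "b"), residues = c("CASSW", "CASSW"))
  d2 <- matrix(c(0, .5, .5, 0), 2, 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  expect_error(progressive_align(doms, tree = neighbor_joining(d2)),
               "do not match")
})
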