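test_that("the residue groups partition the 20-letter alphabet", {
  scheme <- residue_group_scheme()
  expect_setequal(scheme$residue, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  expect_equal(nrow(scheme), 20)
  expect_equal(anyDuplicated(scheme$residue), 0)
  expect_setequal(unique(scheme$group),
                  c("hydrophobic", "cysteine", "polar", "positive", "negative"))
  expect_equal(sort(scheme$residue[scheme$group == "hydrophobic"]),
               strsplit("AFHILMPVW", "")[[1]])
  expect_equal(scheme$residue[scheme$group == "cysteine"], "C")
  expect_equal(sort(scheme$residue[scheme$group == "polar"]),
               strsplit("GNQSTY", "")[[1]])
  expect_equal(sort(scheme$residue[scheme$group == "positive"]), c("K", "R"))
  expect_equal(sort(scheme$residue[scheme$group == "negative"]), c("D", "E"))
  expect_equal(residue_group(c("H", "C")), c("hydrophobic", "cysteine"))
  expect_error(residue_group("X"), "not a standard residue")
  expect_error(residue_group("-"), "not a standard residue")
})

test_that("grouped similarity follows the column rules", {
  # A|G differ (hydrophobic vs polar), C|C coincide, D|E coincide (negative)
  expect_equal(grouped_similarity("ACD", "GCE"), 100 * 2 / 3)
  expect_equal(grouped_similarity("KDEL", "KDEL"), 100)
  # residue against gap is a non-coincidence that stays in the denominator
  expect_equal(grouped_similarity("AC-", "ACD"), 100 * 2 / 3)
  # gap-gap columns are excluded from the denominator entirely
  expect_equal(grouped_similarity("AC--", "ACD-"), 100 * 2 / 3)
  expect_error(grouped_similarity("AC", "ACD"), "equal length")
  expect_error(grouped_similarity("--", "--"), "all-gap")
})

test_that("grouped similarity is symmetric and bounded below by identity", {
  withr::with_seed(41, {
    for (trial in 1:30) {
      n <- sample(10:60, 1)
      a <- random_protein(n)
      b <- random_protein(n)
      s_ab <- grouped_similarity(a, b)
      expect_equal(s_ab, grouped_similarity(b, a))
      ca <- strsplit(a, "")[[1]]
      cb <- strsplit(b, "")[[1]]
      identity <- 100 * sum(ca == cb) / n
      expect_gte(s_ab + 1e-9, identity)
    }
  })
})

test_that("within-group mutation is invisible to the statistic", {
  for (rate in c(0.1, 0.3, 0.5)) {
    fam <- generate_family(scaffold_spec(10), n_members = 5,
                           mutation_rate = rate, cross_group_fraction = 0,
                           seed = 50 + round(100 * rate))
    anc <- fam$truth$ancestor[1]
    for (m in fam$records$residues) {
      expect_equal(grouped_similarity(anc, m), 100)
    }
  }
})

test_that("cross-group mutation pressure never raises mean similarity", {
  rates <- seq(0, 0.5, by = 0.1)
  means <- vapply(rates, function(rate) {
    sims <- vapply(1:20, function(s) {
      fam <- generate_family(scaffold_spec(9), n_members = 2,
                             mutation_rate = rate, cross_group_fraction = 1,
                             seed = 900 + s)
      grouped_similarity(fam$truth$ancestor[1], fam$records$residues[1])
    }, numeric(1))
    mean(sims)
  }, numeric(1))
  expect_true(all(diff(means) <= 1e-9))
})

test_that("similarity matrices are symmetric with a 100 diagonal", {
  fam <- generate_family(scaffold_spec(10), n_members = 5,
                         mutation_rate = 0.25, seed = 61)
  doms <- curate_reference_set(fam$records)
  msa <- progressive_align(doms)
  sim <- similarity_matrix(msa)
  expect_true(isSymmetric(unclass(unname(sim))))
  expect_equal(unname(diag(sim)), rep(100, nrow(sim)))
  expect_true(all(sim >= 0 & sim <= 100))
  # a 2-row alignment reduces to the pairwise statistic
  two <- msa[1:2, ]
  expect_equal(unname(similarity_matrix(two)[1, 2]),
               grouped_similarity(two$aligned[1], two$aligned[2]))
  # identical rows give all-100 matrices
  same <- tibble::tibble(id = c("a", "b", "c"), aligned = rep("CASSW", 3))
  expect_true(all(similarity_matrix(same) == 100))
})

test_that("pairwise-alignment similarity mode works and stays in range", {
  fam <- generate_family(scaffold_spec(10), n_members = 4,
                         mutation_rate = 0.3, seed = 63)
  doms <- curate_reference_set(fam$records)
  sim <- pairwise_similarity_matrix(doms)
  expect_true(isSymmetric(unclass(unname(sim))))
  expect_true(all(sim >= 0 & sim <= 100))
})

test_that("tidy() flattens a similarity matrix to one row per pair", {
  same <- tibble::tibble(id = c("a", "b"), aligned = c("CASSW", "CASSW"))
  td <- tidy(similarity_matrix(same))
  expect_equal(nrow(td), 4)
  expect_equal(td$similarity, rep(100, 4))
})
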