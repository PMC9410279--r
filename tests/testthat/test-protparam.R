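test_that("average mass matches standard residue-table values", {
  expect_equal(average_mass("G")$average_mass, 75.07, tolerance = 0.0002)
  expect_equal(average_mass("GG")$average_mass, 132.12, tolerance = 0.0002)
})

test_that("each disulfide removes exactly two hydrogens", {
  seq <- strrep("CASSC", 4) # 8 cysteines
  reduced <- average_mass(seq, 0)$average_mass
  for (n in 1:4) {
    expect_equal(average_mass(seq, n)$average_mass,
                 reduced - n * 2 * 1.00794, tolerance = 1e-9)
  }
  expect_error(average_mass(seq, 5), "cannot close")
  expect_error(average_mass("GXG"), "standard residues")
})

test_that("chain mass is additive up to one condensation water", {
  withr::with_seed(71, {
    for (trial in 1:10) {
      a <- random_protein(sample(5:40, 1))
      b <- random_protein(sample(5:40, 1))
      expect_equal(average_mass(paste0(a, b))$average_mass,
                   average_mass(a)$average_mass +
                     average_mass(b)$average_mass - 18.01528,
                   tolerance = 1e-6)
    }
  })
})

test_that("a folded LU-domain-scale protein lands in the 10 kDa range", {
  fam <- generate_family(scaffold_spec(10), n_members = 1,
                         mutation_rate = 0, seed = 73)
  dom <- curate_reference_set(fam$records)
  res <- average_mass(paste0("M", dom$residues[1]), 5)
  expect_gt(res$average_mass, 6000)
  expect_lt(res$average_mass, 13000)
})

test_that("in-silico PCR finds a constructed product with exact coordinates", {
  withr::with_seed(77, {
    fwd <- random_protein(20, c("A", "C", "G", "T"))
    rev <- random_protein(18, c("A", "C", "G", "T"))
    spacer <- random_protein(50, c("A", "C", "G", "T"))
    template <- paste0(fwd, spacer, reverse_complement(rev))
  })
  amp <- insilico_pcr(template, fwd, rev)
  expect_equal(amp$length, 20 + 50 + 18)
  expect_equal(amp$start, 1)
  expect_equal(amp$sequence, template)
  expect_equal(substr(template, amp$start, amp$end), amp$sequence)
  # degenerate full-length case: primers span the whole template
  amp2 <- insilico_pcr(template, template, reverse_complement(template))
  expect_equal(amp2$sequence, template)
})

test_that("missing sites give no product; ambiguous sites are an error", {
  template <- paste0(strrep("AT", 40), "GGGCCCGGGCCCGGGC", strrep("TA", 40))
  expect_equal(nrow(insilico_pcr(template, strrep("ACGT", 5),
                                 strrep("TGCA", 5))), 0)
  dup <- paste0(strrep("ACGTA", 4), strrep("G", 30), strrep("ACGTA", 4),
                strrep("G", 30), reverse_complement(strrep("TTACG", 4)))
  expect_error(insilico_pcr(dup, strrep("ACGTA", 4), strrep("TTACG", 4)),
               "multiple candidate products")
  expect_error(insilico_pcr(template, "ACGT", strrep("TGCA", 5)))
})

test_that("product Tm follows the duplex formula", {
  half_gc <- paste0(strrep("G", 46), strrep("A", 46), strrep("C", 46),
                    strrep("T", 46)) # 184 bp, 50% GC
  expect_equal(product_tm(half_gc, na_molar = 0.05),
               81.5 + 0.41 * 50 - 675 / 184 + 16.6 * log10(0.05),
               tolerance = 1e-9)
  expect_equal(product_tm(half_gc, na_molar = 0.05), 76.7, tolerance = 0.1)
  # strictly increasing in GC content at fixed length and salt
  low_gc <- paste0(strrep("G", 30), strrep("A", 62), strrep("C", 30),
                   strrep("T", 62))
  expect_lt(product_tm(low_gc), product_tm(half_gc))
  expect_error(product_tm("ACGT"), "at least 50")
})

test_that("the printed primer pairs delimit 184 and 200 bp on the synthetic template", {
  tx <- synthetic_lu_transcript()
  primers <- qpcr_primer_pairs()
  for (k in 1:2) {
    amp <- insilico_pcr(tx, primers$forward[k], primers$reverse[k])
    expect_equal(amp$length, primers$product_length[k])
    expect_true(startsWith(amp$sequence, primers$forward[k]))
    expect_true(endsWith(amp$sequence,
                         reverse_complement(primers$reverse[k])))
  }
})
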