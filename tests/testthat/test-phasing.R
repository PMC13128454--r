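test_that("variant sites validate and parse from strings", {
  s <- variant_site(659, "A", "G")
  expect_equal(s$position, 659L)
  expect_error(variant_site(659, "A", "A"))
  expect_error(variant_site(0, "A", "G"))
  expect_error(variant_site(10, "A", "N"))
  p <- parse_site("817:C>T")
  expect_equal(p$position, 817L)
  expect_equal(p$alt_base, "T")
  expect_error(parse_site("817C>T"), "cannot parse")
})

test_that("pair alleles classify coverage, quality and mate disagreement", {
  s1 <- variant_site(10, "A", "G")
  s2 <- variant_site(20, "C", "T")
  tsv <- data.frame(
    pair_id = c("p1", "p1", "p2", "p2", "p2", "p3", "p4", "p4"),
    site = c(10, 20, 10, 10, 20, 10, 10, 20),
    base = c("G", "C", "G", "A", "C", "G", "G", "T"),
    qual = c(30, 30, 30, 30, 30, 30, 30, 10),
    stringsAsFactors = FALSE)
  obs <- extract_pair_alleles(tsv, s1, s2)
  obs <- obs[order(obs$pair_id), ]
  # p1: clean alt/ref
  expect_equal(obs$allele_site1[1], "alt")
  expect_equal(obs$allele_site2[1], "ref")
  expect_true(obs$informative[1])
  # p2: mates disagree at site1 -> other, non-informative
  expect_equal(obs$allele_site1[2], "other")
  expect_false(obs$informative[2])
  # p3: covers only site1
  expect_equal(obs$allele_site2[3], "uncovered")
  expect_false(obs$informative[3])
  # p4: low-quality base at site2 filtered out -> uncovered
  expect_equal(obs$allele_site2[4], "uncovered")
  expect_error(extract_pair_alleles(tsv, s1, s1), "distinct")
})

test_that("generated reads round-trip to the ground-truth allele table", {
  g <- gen_read_pairs("trans", n_pairs = 60, error_rate = 0, seed = 101)
  obs <- extract_pair_alleles(g$alignments, g$sites$site1, g$sites$site2)
  obs <- obs[match(g$truth$pair_id, obs$pair_id), ]
  expect_equal(obs$allele_site1, g$truth$allele_site1)
  expect_equal(obs$allele_site2, g$truth$allele_site2)
  expect_true(all(obs$informative))
})

test_that("phase decision rule covers cis, trans, ambiguous, insufficient", {
  expect_equal(phase(obs_from_counts(n_aa = 10))$call, "cis")
  # the compound-heterozygous pattern: discordant pairs only, no alt-alt
  tr <- phase(obs_from_counts(n_ar = 6, n_ra = 6))
  expect_equal(tr$call, "trans")
  expect_equal(tr$n_trans_support, 12L)
  expect_equal(tr$conflict_fraction, 0)
  expect_equal(phase(obs_from_counts(n_aa = 2, n_ar = 1))$call,
               "insufficient")
  expect_equal(phase(obs_from_counts(n_aa = 5, n_ar = 5))$call, "ambiguous")
  # all ref-ref pairs: coverage without alt evidence
  rr <- phase(obs_from_counts(n_rr = 8))
  expect_equal(rr$call, "ambiguous")
  expect_true(is.na(rr$conflict_fraction))
  # counts table sums to informative pairs
  mix <- phase(obs_from_counts(n_aa = 1, n_ar = 9, n_ra = 8, n_rr = 3))
  expect_equal(sum(mix$counts), 21)
  expect_equal(mix$call, "trans") # 1/18 alt-alt below the 0.1 conflict cap
  expect_equal(mix$conflict_fraction, 1 / 18)
})

test_that("decision rule is site-swap symmetric for all tables up to 10", {
  # enumerate every (aa, ar, ra, rr) with at most 10 informative pairs
  grid <- expand.grid(aa = 0:10, ar = 0:10, ra = 0:10, rr = 0:10)
  grid <- grid[rowSums(grid) <= 10L, ]
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    a <- phase(obs_from_counts(g$aa, g$ar, g$ra, g$rr))
    b <- phase(obs_from_counts(g$aa, g$ra, g$ar, g$rr)) # swap the sites
    expect_identical(a$call, b$call)
    expect_identical(a$conflict_fraction, b$conflict_fraction)
  }
})

test_that("non-informative pairs never change the call", {
  base <- obs_from_counts(n_ar = 7, n_ra = 5)
  extra <- data.frame(
    pair_id = sprintf("x%02d", 1:6),
    allele_site1 = c("other", "uncovered", "alt", "ref", "other", "alt"),
    allele_site2 = c("alt", "ref", "uncovered", "other", "other",
                     "uncovered"),
    min_base_quality = 30, stringsAsFactors = FALSE)
  with_noise <- obs_from_counts(n_ar = 7, n_ra = 5, extra = extra)
  expect_identical(phase(base)$call, phase(with_noise)$call)
  expect_identical(phase(base)$counts, phase(with_noise)$counts)
})

test_that("calls are correct at realistic error rates, both phases", {
  for (ph in c("trans", "cis")) {
    correct <- 0L
    for (s in 1:25) {
      g <- gen_read_pairs(ph, n_pairs = 100, error_rate = 0.01,
                          seed = 1000 + s)
      obs <- extract_pair_alleles(g$alignments, g$sites$site1,
                                  g$sites$site2)
      correct <- correct + (phase(obs)$call == ph)
    }
    expect_equal(correct, 25L)
  }
})

test_that("SAM output is read back identically by the standard reader", {
  skip_if_not_installed("Rsamtools")
  sam <- withr::local_tempfile(fileext = ".sam")
  g <- gen_read_pairs("trans", n_pairs = 25, error_rate = 0.01, seed = 77,
                      sam_path = sam)
  rec <- read_sam_alignments(sam)
  obs_file <- extract_pair_alleles(rec, g$sites$site1, g$sites$site2)
  obs_mem <- extract_pair_alleles(g$alignments, g$sites$site1,
                                  g$sites$site2)
  obs_file <- obs_file[match(obs_mem$pair_id, obs_file$pair_id), ]
  expect_equal(obs_file$allele_site1, obs_mem$allele_site1)
  expect_equal(obs_file$allele_site2, obs_mem$allele_site2)
  expect_identical(phase(obs_file)$call, "trans")
})

test_that("gapped and clipped alignments are walked correctly", {
  s1 <- variant_site(10, "A", "G")
  s2 <- variant_site(20, "C", "T")
  # 3S: first three query bases soft-clipped; 2D skips ref 12-13;
  # site 10 -> query 10, site 20 -> query 18
  rec <- data.frame(
    qname = "p1", flag = 0L, pos = 4L, cigar = "3S8M2D9M",
    seq = "NNNCCCCCCGCCCCCCCTCC",
    qual = paste(rep("I", 20), collapse = ""),
    stringsAsFactors = FALSE)
  obs <- extract_pair_alleles(rec, s1, s2)
  expect_equal(obs$allele_site1, "alt")
  expect_equal(obs$allele_site2, "alt")
  # a site inside the deletion is uncovered
  s_del <- variant_site(12, "A", "G")
  obs2 <- extract_pair_alleles(rec, s1, s_del)
  expect_equal(obs2$allele_site2, "uncovered")
  # malformed records are skipped with a message
  bad <- rbind(rec, data.frame(qname = "p2", flag = 0L, pos = NA_integer_,
                               cigar = "17M", seq = rec$seq,
                               qual = rec$qual))
  expect_message(extract_pair_alleles(bad, s1, s2), "malformed")
})
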