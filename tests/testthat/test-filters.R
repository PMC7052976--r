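test_that("p-distance counts mismatches over comparable columns only", {
  expect_equal(p_distance("MKV", "MKV"), 0)
  expect_equal(p_distance("AAAA", "AAAT"), 0.25)
  # pairwise deletion: the gapped column is excluded, 4 comparable, 0 diffs
  expect_equal(p_distance("AA-CG", "AATCG"), 0)
  # ambiguity X excluded from the denominator
  expect_equal(p_distance("AXAA", "AAAT"), 1 / 3, tolerance = 1e-12)
  expect_error(p_distance("AB", "ABC"), "equal length")
  expect_error(p_distance("--", "AA"), "comparable")
})

test_that("p-distance is symmetric, bounded, and column-removal monotone", {
  set.seed(61)
  aa <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")
  for (i in 1:30) {
    n <- sample(10:60, 1)
    a <- paste(sample(aa, n, replace = TRUE), collapse = "")
    b <- paste(sample(aa, n, replace = TRUE), collapse = "")
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    comparable <- av != "-" & bv != "-"
    if (!any(comparable)) next
    d <- p_distance(a, b)
    expect_equal(d, p_distance(b, a))
    expect_gte(d, 0); expect_lte(d, 1)
    # dropping identical columns never decreases the distance
    ident <- comparable & av == bv
    if (any(ident) && !all(comparable == ident)) {
      keep <- !ident
      d2 <- p_distance(paste(av[keep], collapse = ""),
                       paste(bv[keep], collapse = ""))
      expect_gte(d2, d)
    }
  }
})

test_that("decontamination call uses top hits and a strict 60% rule", {
  mk_hits <- function(n, n_bact) {
    data.frame(subject = sprintf("s%03d", 1:n),
               class = c(rep("bacterial", n_bact),
                         rep("eukaryotic", n - n_bact)),
               bitscore = seq(500, by = -2, length.out = n),
               evalue = 10^-seq(50, by = -1, length.out = n))
  }
  r <- classify_contaminant(mk_hits(20, 13))
  expect_identical(r$decision, "exclude")   # 0.65 > 0.6
  expect_equal(r$fraction, 0.65)
  r2 <- classify_contaminant(mk_hits(20, 12))
  expect_identical(r2$decision, "keep")     # 0.60 not > 0.6
  r3 <- classify_contaminant(mk_hits(5, 4)) # denominator = available hits
  expect_identical(r3$decision, "exclude")
  expect_equal(r3$n_used, 5L)
  r4 <- classify_contaminant(mk_hits(25, 13))  # only top 20 used
  expect_equal(r4$n_used, 20L)
  r0 <- classify_contaminant(mk_hits(5, 0)[0, ])
  expect_identical(r0$decision, "keep")
  expect_equal(r0$n_used, 0L)
})

test_that("decontamination is invariant to hit-row order", {
  set.seed(67)
  hits <- data.frame(subject = sprintf("s%03d", 1:30),
                     class = sample(c("bacterial", "eukaryotic", "other"),
                                    30, replace = TRUE),
                     bitscore = sample(seq(100, 400, by = 10), 30),
                     evalue = runif(30, 0, 1e-10))
  base <- classify_contaminant(hits)
  for (i in 1:10) {
    shuffled <- hits[sample(nrow(hits)), ]
    expect_identical(classify_contaminant(shuffled), base)
  }
})

test_that("splice-leader scan anchors SL suffixes near the 5' end", {
  sl <- "AACTAACGCTATTATTAGAACAGTTTCTGTACTATATTG"
  suffix12 <- substr(sl, nchar(sl) - 11, nchar(sl))
  tx <- paste0(suffix12, paste(rep("A", 60), collapse = ""))
  hit <- sl_scan(tx, sl)
  expect_true(hit$found)
  expect_equal(hit$length, 12L)
  expect_equal(hit$position, 1L)

  tx11 <- paste0(substr(sl, nchar(sl) - 10, nchar(sl)),
                 paste(rep("A", 60), collapse = ""))
  expect_false(sl_scan(tx11, sl)$found)

  # suffix starting at position 40: outside window 30, inside window 50
  # (pad with A: the SL residue preceding the 12-mer is C, so the padding
  # cannot extend the match)
  tx40 <- paste0(paste(rep("A", 39), collapse = ""), suffix12, "CCCC")
  expect_false(sl_scan(tx40, sl, window = 30)$found)
  hit40 <- sl_scan(tx40, sl, window = 50)
  expect_true(hit40$found)
  expect_equal(hit40$position, 40L)

  # reverse-complement strand is also checked
  rc <- sl_scan(gcdollo:::revcomp(tx), sl)
  expect_true(rc$found)
  expect_identical(rc$strand, "-")

  expect_error(sl_scan(tx, "ACGT", min_len = 12), "exceeds SL length")
})

test_that("homolog filters enforce profile thresholds with per-rule reporting", {
  presets <- filter_presets()
  # trypanothione-style: BLAST 1e-20, p-distance 0.7
  ok <- filter_homolog_hit(list(evalue = 1e-25, search_type = "blast",
                                pdist = 0.3), presets$trypanothione)
  expect_identical(ok$decision, "accept")
  expect_true(all(ok$rules))

  # KKT-style: HMM 1e-5, p-distance 0.8, domain extension required
  kkt_bad <- filter_homolog_hit(
    list(evalue = 1e-6, search_type = "hmm", pdist = 0.85,
         hit_start = 5, hit_end = 400, domain_start = 100,
         domain_end = 300), presets$kkt)
  expect_identical(kkt_bad$decision, "reject")
  expect_false(kkt_bad$rules[["pdist"]])
  expect_true(kkt_bad$rules[["evalue"]])
  expect_true(kkt_bad$rules[["domain_extension"]])

  # KKIP7-style: E <= 1e-100 is not met by 1e-90
  kkip <- filter_homolog_hit(list(evalue = 1e-90, search_type = "blast",
                                  pdist = 0.5), presets$kkip7)
  expect_identical(kkip$decision, "reject")
  expect_false(kkip$rules[["evalue"]])

  # missing fields are reported by rule name
  expect_error(filter_homolog_hit(list(evalue = 1e-30,
                                       search_type = "hmm"), presets$kkt),
               "pdist")
  expect_error(filter_homolog_hit(list(evalue = 1e-30,
                                       search_type = "hmm",
                                       pdist = 0.1), presets$kkt),
               "domain_extension")
  expect_error(filter_homolog_hit(list(evalue = 1e-30,
                                       search_type = "blast",
                                       pdist = 0.1), presets$kkt),
               "no E-value threshold")
})

test_that("tightening thresholds never converts a reject into an accept", {
  set.seed(71)
  for (i in 1:50) {
    cand <- list(evalue = 10^-runif(1, 1, 120), search_type = "blast",
                 pdist = runif(1), sl_found = runif(1) < 0.5,
                 hit_start = sample(1:50, 1), hit_end = sample(200:400, 1),
                 domain_start = sample(20:80, 1),
                 domain_end = sample(250:380, 1))
    loose <- filter_profile("loose", blast_evalue_max = 10^-runif(1, 1, 40),
                            pdist_max = runif(1, 0.5, 1),
                            require_sl = FALSE,
                            require_domain_extension = FALSE)
    tight <- filter_profile("tight",
                            blast_evalue_max = loose$blast_evalue_max *
                              10^-runif(1, 0, 30),
                            pdist_max = loose$pdist_max * runif(1),
                            require_sl = TRUE,
                            require_domain_extension = TRUE)
    d_loose <- filter_homolog_hit(cand, loose)$decision
    d_tight <- filter_homolog_hit(cand, tight)$decision
    if (d_loose == "reject") expect_identical(d_tight, "reject")
  }
})
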