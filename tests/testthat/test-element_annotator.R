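toy <- make_toy_profiles(seed = 31)

test_that("frameshift-split fragments chain into one assembled domain", {
  rt <- toy$profiles[[3]]
  h1 <- make_hit("l", 1000, 1300, frame = 1L, profile_start = 0L,
                 profile_end = 100L, bit_score = 80)
  h2 <- make_hit("l", 1302, 1608, frame = 0L, profile_start = 98L,
                 profile_end = 200L, bit_score = 90, e_value = 1e-12)
  dom <- chain_fragments(rbind(h1, h2), toy$profiles)
  expect_identical(nrow(dom), 1L)
  expect_true(dom$interrupted)
  expect_identical(dom$n_parts, 2L)
  expect_equal(dom$genomic_start, 1000)
  expect_equal(dom$genomic_end, 1608)
  expect_equal(dom$combined_bits, 170)
  expect_equal(dom$best_evalue, 1e-12)
  expect_equal(dom$profile_coverage, 200 / rt$length)

  # a single hit is its own assembled domain
  single <- chain_fragments(h1, toy$profiles)
  expect_identical(nrow(single), 1L)
  expect_false(single$interrupted)
  expect_equal(single$genomic_start, 1000)
  expect_equal(single$genomic_end, 1300)

  # two full-profile copies far apart stay separate (profile overlap 150)
  far <- rbind(make_hit("l", 1000, 1450, profile_start = 0L,
                        profile_end = 150L),
               make_hit("l", 2450, 2900, profile_start = 0L,
                        profile_end = 150L))
  expect_identical(nrow(chain_fragments(far, toy$profiles)), 2L)
})

test_that("greedy chaining matches the exhaustive partition oracle", {
  set.seed(12)
  for (rep in 1:40) {
    n <- sample(2:5, 1)
    strand <- sample(c("+", "-"), 1)
    pos <- sort(sample(seq(0, 6000, by = 3), n))
    hits <- do.call(rbind, lapply(seq_len(n), function(i) {
      ps <- sample(0:150, 1)
      pe <- ps + sample(10:60, 1)
      make_hit("l", pos[i], pos[i] + 3 * (pe - ps), strand = strand,
               profile_start = as.integer(ps), profile_end = as.integer(pe))
    }))
    got <- chain_fragments(hits, toy$profiles)
    expect_identical(nrow(got), min_chain_partition(hits))
    # every reported chain is internally valid
    for (i in seq_len(nrow(got))) {
      parts <- got$parts[[i]]
      if (nrow(parts) > 1)
        for (j in seq_len(nrow(parts) - 1))
          expect_true(chainable(parts[j, ], parts[j + 1, ]))
    }
  }
})

test_that("tandem cores split a locus into separate elements", {
  locus <- data.frame(locus_id = "L1", sequence_id = "chr", start = 0,
                      stringsAsFactors = FALSE)
  mk <- function(pid, gs, ge) make_hit("L1", gs, ge, profile_id = pid,
                                       profile_end = 60L)
  hits <- rbind(mk("toy_GAG", 500, 740), mk("toy_gRT", 1000, 1360),
                mk("toy_INT", 1700, 1940),
                mk("toy_GAG", 9500, 9740), mk("toy_gRT", 10000, 10360),
                mk("toy_INT", 10700, 10940))
  dom <- chain_fragments(hits, toy$profiles)
  del <- delineate_elements(locus, dom, "gRT")
  expect_identical(length(del$elements), 2L)
  expect_identical(del$elements[[1]]$structure, "GAG.gRT.INT")
  expect_identical(del$elements[[2]]$structure, "GAG.gRT.INT")
  expect_lte(max(del$elements[[1]]$domains$genomic_end), 2000)
  expect_gte(min(del$elements[[2]]$domains$genomic_start), 9000)

  # one core, nothing else
  lone <- delineate_elements(locus, chain_fragments(mk("toy_gRT", 100, 460),
                                                    toy$profiles), "gRT")
  expect_identical(length(lone$elements), 1L)
  expect_identical(lone$elements[[1]]$structure, "gRT")

  # no core: nothing, with a logged reason
  nocore <- delineate_elements(locus,
                               chain_fragments(mk("toy_GAG", 100, 340),
                                               toy$profiles), "gRT")
  expect_identical(length(nocore$elements), 0L)
  expect_identical(nocore$dropped$reason, "no core domain in locus")

  # the additional-domain filter drops core-only elements with a reason
  filtered <- delineate_elements(locus,
                                 chain_fragments(mk("toy_gRT", 100, 460),
                                                 toy$profiles), "gRT",
                                 require_additional_domains = 1)
  expect_identical(length(filtered$elements), 0L)
  expect_match(filtered$dropped$reason, "additional domains")
})

test_that("minus-strand structure strings read 5' to 3' of the element", {
  locus <- data.frame(locus_id = "L1", sequence_id = "chr", start = 0,
                      stringsAsFactors = FALSE)
  mk <- function(pid, gs, ge) make_hit("L1", gs, ge, strand = "-",
                                       profile_id = pid, profile_end = 60L)
  # genomic order INT, gRH, gRT, Pro, GAG on the minus strand
  hits <- rbind(mk("toy_INT", 500, 740), mk("toy_gRH", 1000, 1240),
                mk("toy_gRT", 1500, 1860), mk("toy_Pro", 2100, 2340),
                mk("toy_GAG", 2600, 2840))
  del <- delineate_elements(locus, chain_fragments(hits, toy$profiles),
                            "gRT")
  expect_identical(length(del$elements), 1L)
  expect_identical(del$elements[[1]]$structure, "GAG.Pro.gRT.gRH.INT")
})

test_that("ORF intactness reflects stops and frameshift chaining", {
  locus <- data.frame(locus_id = "L1", sequence_id = "chr", start = 0,
                      stringsAsFactors = FALSE)
  clean <- make_hit("L1", 300, 660, profile_id = "toy_gRT",
                    profile_end = 120L,
                    aligned_aa = paste(rep("K", 120), collapse = ""))
  el <- delineate_elements(locus, chain_fragments(clean, toy$profiles),
                           "gRT")$elements[[1]]
  el <- detect_orf_intactness(el)
  expect_true(el$orf_intact)

  # one internal stop flips the flag
  aa_stop <- paste0(paste(rep("K", 60), collapse = ""), "*",
                    paste(rep("K", 59), collapse = ""))
  stopped <- make_hit("L1", 300, 660, profile_id = "toy_gRT",
                      profile_end = 120L, aligned_aa = aa_stop)
  el2 <- delineate_elements(locus, chain_fragments(stopped, toy$profiles),
                            "gRT")$elements[[1]]
  el2 <- detect_orf_intactness(el2)
  expect_false(el2$orf_intact)

  # a chained (interrupted) domain is never intact
  h1 <- make_hit("L1", 300, 600, profile_end = 100L)
  h2 <- make_hit("L1", 601, 901, profile_start = 100L, profile_end = 200L,
                 frame = 1L)
  el3 <- delineate_elements(locus, chain_fragments(rbind(h1, h2),
                                                   toy$profiles),
                            "gRT")$elements[[1]]
  el3 <- detect_orf_intactness(el3)
  expect_false(el3$orf_intact)
  expect_true(el3$domains$interrupted[1])
})

test_that("domain peptides splice chained fragments at the overlap", {
  locus <- data.frame(locus_id = "L1", sequence_id = "chr", start = 0,
                      stringsAsFactors = FALSE)
  aa1 <- paste(sample(aa_order, 100, TRUE), collapse = "")
  aa2 <- paste(sample(aa_order, 102, TRUE), collapse = "")
  h1 <- make_hit("L1", 0, 300, profile_start = 0L, profile_end = 100L,
                 aligned_aa = aa1)
  h2 <- make_hit("L1", 301, 607, profile_start = 98L, profile_end = 200L,
                 frame = 1L, aligned_aa = aa2)
  el <- delineate_elements(locus, chain_fragments(rbind(h1, h2),
                                                  toy$profiles),
                           "gRT")$elements[[1]]
  el <- detect_orf_intactness(el)
  el$element_id <- "E1"
  peps <- extract_domain_peptides(list(el))
  expect_identical(names(peps), "gRT")
  # 100 + 102 aa with a 2-aa profile overlap trimmed from the downstream part
  expect_identical(nchar(peps$gRT[["E1"]]), 200L)
  expect_identical(peps$gRT[["E1"]], paste0(aa1, substring(aa2, 3)))

  # an uninterrupted domain's peptide is the translation of its envelope
  peps1 <- extract_domain_peptides(list({
    e <- delineate_elements(locus, chain_fragments(h1, toy$profiles),
                            "gRT")$elements[[1]]
    e$element_id <- "E2"; e
  }))
  expect_identical(peps1$gRT[["E2"]], aa1)
  expect_identical(extract_domain_peptides(list()), list())
})
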