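test_that("a planted consensus yields one hit at the planted interval", {
  tp <- make_toy_profiles(seed = 21)
  core <- tp$profiles[[3]]
  cds <- tp$consensus_dna[["gRT"]]
  set.seed(7)
  for (case in list(list(strand = "+", offset = 10001),
                    list(strand = "-", offset = 12000))) {
    insert <- if (case$strand == "+") cds else revcomp(cds)
    genome <- c(chr = paste0(rand_dna(case$offset), insert, rand_dna(8000)))
    hits <- scan_profiles(genome, list(core))
    expect_identical(nrow(hits), 1L)
    expect_identical(hits$strand, case$strand)
    # hit covers the planted interval (boundary wobble only from chance
    # matching residues in the flanking sequence)
    expect_lte(abs(hits$genomic_start - case$offset), 9)
    expect_lte(abs(hits$genomic_end - (case$offset + nchar(cds))), 9)
    expect_equal(hits$frame,
                 if (case$strand == "+") case$offset %% 3
                 else (nchar(genome[[1]]) - case$offset - nchar(cds)) %% 3,
                 ignore_attr = TRUE)
  }
  expect_identical(nrow(scan_profiles(character(0), list(core))), 0L)
})

test_that("scanning the reverse complement mirrors every hit", {
  tp <- make_toy_profiles(seed = 22)
  set.seed(8)
  genome <- c(chr = paste0(rand_dna(3000), tp$consensus_dna[["gRT"]],
                           rand_dna(2000), revcomp(tp$consensus_dna[["GAG"]]),
                           rand_dna(3000)))
  profs <- tp$profiles[c(1, 3)]
  profs[[1]]$role <- "core"
  fwd <- scan_profiles(genome, profs)
  rev <- scan_profiles(setNames(revcomp(genome), "chr"), profs)
  L <- nchar(genome)
  expect_identical(nrow(fwd), nrow(rev))
  fwd <- fwd[order(fwd$profile_id), ]; rev <- rev[order(rev$profile_id), ]
  expect_equal(sort(L - rev$genomic_end), sort(fwd$genomic_start))
  expect_equal(sort(L - rev$genomic_start), sort(fwd$genomic_end))
  expect_setequal(paste(fwd$profile_id, chartr("+-", "-+", fwd$strand)),
                  paste(rev$profile_id, rev$strand))
})

test_that("pre-filter applies the inclusive e-value and length rules", {
  tp <- make_toy_profiles(seed = 23)
  core <- tp$profiles[[3]]
  ev <- c(1e-5, 9e-4, 1e-3, 2e-3, 0.5)
  hits <- do.call(rbind, lapply(ev, function(e)
    make_hit(e_value = e, profile_end = core$length)))
  kept <- prefilter_hits(hits, list(core))
  expect_identical(nrow(kept), 3L)
  expect_true(all(kept$e_value <= 1e-3))
  # order preserved and idempotent
  expect_identical(kept, prefilter_hits(kept, list(core)))
  # tightening the threshold never adds hits
  tighter <- prefilter_hits(hits, list(core), max_evalue = 1e-4)
  expect_true(all(tighter$e_value %in% kept$e_value))
  # short matches are dropped by the fraction rule
  short <- make_hit(e_value = 1e-9, profile_start = 0L,
                    profile_end = as.integer(0.2 * core$length))
  expect_identical(nrow(prefilter_hits(short, list(core))), 0L)
  expect_identical(nrow(prefilter_hits(retromine:::empty_hits(), list(core))), 0L)
})

test_that("external tabular output parses to the internal hit structure", {
  tp <- make_toy_profiles(seed = 24)
  core <- tp$profiles[[3]]
  set.seed(9)
  genome <- c(chr = paste0(rand_dna(5000), tp$consensus_dna[["gRT"]],
                           rand_dna(3000), revcomp(tp$consensus_dna[["gRT"]]),
                           rand_dna(5000)))
  internal <- scan_profiles(genome, list(core))
  expect_identical(nrow(internal), 2L)
  # serialize the internal hits as the external tool's 1-based tabular rows
  tab <- withr::local_tempfile(fileext = ".tsv")
  rows <- vapply(seq_len(nrow(internal)), function(i) {
    h <- internal[i, ]
    qframe <- (h$frame + 1L) * ifelse(h$strand == "-", -1L, 1L)
    qs <- if (h$strand == "+") h$genomic_start + 1 else h$genomic_end
    qe <- if (h$strand == "+") h$genomic_end else h$genomic_start + 1
    sprintf("%s\t%s\t%d\t%d\t%d\t%d\t%.3g\t%.2f\t%d\t%s", h$sequence_id,
            h$profile_id, qs, qe, h$profile_start + 1L, h$profile_end,
            h$e_value, h$bit_score, qframe, h$aligned_aa)
  }, character(1))
  writeLines(rows, tab)
  parsed <- parse_rpsblast_hits(tab)
  expect_identical(names(parsed), names(retromine:::empty_hits()))
  for (col in c("sequence_id", "genomic_start", "genomic_end", "strand",
                "profile_id", "profile_start", "profile_end", "aligned_aa"))
    expect_equal(parsed[[col]], internal[[col]], ignore_attr = TRUE)
  expect_equal(parsed$bit_score, internal$bit_score, tolerance = 0.01)
})
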