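rand_pep <- function(n) paste(sample(aa_order, n, TRUE), collapse = "")

# mutate a peptide at an exact number of positions
mutate_pep <- function(pep, n_mut) {
  s <- strsplit(pep, "")[[1]]
  pos <- sample(length(s), n_mut)
  s[pos] <- vapply(s[pos], function(a) sample(setdiff(aa_order, a), 1),
                   character(1))
  paste(s, collapse = "")
}

test_that("identical and dissimilar peptides cluster as expected", {
  set.seed(19)
  p <- rand_pep(120)
  same <- setNames(c(p, p, p), c("e1", "e2", "e3"))
  cl <- cluster_core_domains(same)
  expect_identical(length(unique(cl$cluster_id)), 1L)
  expect_setequal(cl$member_id, names(same))

  # ~50% identity: two singletons
  q <- mutate_pep(p, 60)
  two <- cluster_core_domains(setNames(c(p, q), c("a", "b")))
  expect_identical(length(unique(two$cluster_id)), 2L)

  expect_error(cluster_core_domains(setNames(c(p, q), c("a", "a"))),
               "duplicate")
})

test_that("greedy clustering equals brute-force transitive clustering", {
  set.seed(20)
  for (rep in 1:8) {
    # families of near-identical members plus unrelated singletons
    n_fam <- sample(2:3, 1)
    peptides <- character(0)
    for (f in seq_len(n_fam)) {
      base <- rand_pep(sample(90:140, 1))
      for (m in seq_len(sample(2:3, 1)))
        peptides <- c(peptides, mutate_pep(base, sample(0:4, 1)))
    }
    peptides <- c(peptides, replicate(sample(1:3, 1),
                                      rand_pep(sample(90:140, 1))))
    names(peptides) <- sprintf("e%02d", seq_along(peptides))
    got <- cluster_core_domains(peptides)
    want <- bruteforce_clusters(peptides)
    expect_identical(
      canonical_partition(split(got$member_id, got$cluster_id)),
      canonical_partition(want))
  }
})

test_that("representatives follow the structure-then-score-then-id order", {
  clusters <- data.frame(cluster_id = c(1L, 1L, 2L),
                         member_id = c("A", "B", "C"),
                         representative_id = c("A", "A", "C"),
                         stringsAsFactors = FALSE)
  elements <- data.frame(
    element_id = c("A", "B", "C"),
    structure = c("GAG.Pro.gRT.gRH.INT", "GAG.gRT.INT", "gRT"),
    score = c(80, 95, 50), stringsAsFactors = FALSE)
  # five domains beat three despite the lower score
  sel <- select_representatives(clusters, elements)
  expect_identical(unique(sel$representative_id[sel$cluster_id == 1]), "A")
  # a singleton represents itself
  expect_identical(sel$representative_id[sel$cluster_id == 2], "C")
  # equal structure and score: lexicographically smaller id wins
  tie_el <- data.frame(element_id = c("B", "A"),
                       structure = c("GAG.gRT", "GAG.gRT"),
                       score = c(70, 70), stringsAsFactors = FALSE)
  tie_cl <- data.frame(cluster_id = c(1L, 1L), member_id = c("B", "A"),
                       representative_id = c("B", "B"),
                       stringsAsFactors = FALSE)
  expect_identical(unique(select_representatives(tie_cl,
                                                 tie_el)$representative_id),
                   "A")
})

test_that("the cluster table round-trips through TSV", {
  set.seed(21)
  p <- rand_pep(100)
  peptides <- setNames(c(p, mutate_pep(p, 2), rand_pep(100), rand_pep(80)),
                       c("w", "x", "y", "z"))
  elements <- data.frame(element_id = names(peptides),
                         structure = c("GAG.gRT", "gRT", "gRT", "gRT"),
                         score = c(70, 60, 50, 40), stringsAsFactors = FALSE)
  cl <- select_representatives(cluster_core_domains(peptides), elements)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_table(cl, elements, path)
  back <- read_cluster_table(path)
  expect_identical(nrow(back), 4L)
  expect_identical(sort(back$member_id), c("w", "x", "y", "z"))
  expect_identical(
    canonical_partition(split(back$member_id, back$cluster_id)),
    canonical_partition(split(cl$member_id, cl$cluster_id)))

  # empty cluster set writes a header-only file
  empty <- cl[0, ]
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_table(empty, elements, path2)
  expect_identical(length(readLines(path2)), 1L)
})

test_that("raising the identity threshold only refines the partition", {
  set.seed(22)
  peptides <- character(0)
  for (f in 1:3) {
    base <- rand_pep(100)
    for (m in 1:3) peptides <- c(peptides, mutate_pep(base, sample(5:12, 1)))
  }
  names(peptides) <- sprintf("p%02d", seq_along(peptides))
  loose <- cluster_core_domains(peptides, min_seq_id = 0.8)
  tight <- cluster_core_domains(peptides, min_seq_id = 0.95)
  loose_of <- setNames(loose$cluster_id, loose$member_id)
  # every tight cluster lies inside one loose cluster
  for (cid in unique(tight$cluster_id)) {
    members <- tight$member_id[tight$cluster_id == cid]
    expect_identical(length(unique(loose_of[members])), 1L)
  }
})

test_that("clustering partitions a large random peptide set quickly", {
  set.seed(23)
  peptides <- setNames(vapply(1:1000, function(i)
    rand_pep(sample(80:150, 1)), character(1)),
    sprintf("e%04d", 1:1000))
  t0 <- Sys.time()
  cl <- cluster_core_domains(peptides)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_lt(elapsed, 60)
  # partition property: every peptide in exactly one cluster
  expect_identical(sort(cl$member_id), sort(names(peptides)))
  expect_identical(anyDuplicated(cl$member_id), 0L)
  # representatives are members of their own cluster
  ok <- vapply(unique(cl$cluster_id), function(cid) {
    rows <- cl[cl$cluster_id == cid, ]
    all(rows$representative_id %in% rows$member_id)
  }, logical(1))
  expect_true(all(ok))
})
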