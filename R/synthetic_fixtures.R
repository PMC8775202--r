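# Deterministic synthetic genomes with planted retroelements and truth
# tables, plus toy PSSM profiles, so every stage is testable without
# external databases.

# one deterministic sense codon per amino acid for back-translation
CODON_OF <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

random_dna <- function(n, gc = 0.4) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# substitute n_mut positions to a different base
mutate_dna <- function(seq, n_mut) {
  if (n_mut <= 0) return(seq)
  s <- strsplit(seq, "")[[1]]
  pos <- sample(length(s), n_mut)
  s[pos] <- vapply(s[pos],
                   function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                   character(1), USE.NAMES = FALSE)
  paste(s, collapse = "")
}

#' Build toy protein-domain profiles with matching consensus sequences
#'
#' One random consensus peptide is drawn per label and turned into a sharply
#' discriminative PSSM (consensus residue `match_score`, all others
#' `mismatch_score`) plus a back-translated consensus coding sequence.
#' Deterministic for a fixed seed.
#'
#' @param labels domain labels, 5'->3' (default the canonical Ty3/gypsy
#'   layout `GAG`, `Pro`, `gRT`, `gRH`, `INT`).
#' @param lengths peptide lengths per label (each >= 50 aa).
#' @param core_label which label plays the core role (default `"gRT"`).
#' @param seed RNG seed.
#' @param match_score,mismatch_score PSSM scores (defaults 7 / -4).
#' @return list with `profiles` (list of [domain_profile()]), `consensus_aa`
#'   and `consensus_dna` (named character vectors).
#' @export
make_toy_profiles <- function(labels = c("GAG", "Pro", "gRT", "gRH", "INT"),
                              lengths = c(90, 70, 120, 80, 100),
                              core_label = "gRT", seed = 1,
                              match_score = 7, mismatch_score = -4) {
  stopifnot(length(labels) == length(lengths), all(lengths >= 50),
            core_label %in% labels)
  withr::with_seed(seed, {
    consensus_aa <- setNames(vapply(lengths, function(L)
      paste(sample(AA_ORDER, L, TRUE), collapse = ""), character(1)), labels)
  })
  profiles <- lapply(seq_along(labels), function(i) {
    aa <- strsplit(consensus_aa[[i]], "")[[1]]
    m <- matrix(mismatch_score, length(aa), 20L)
    m[cbind(seq_along(aa), match(aa, AA_ORDER))] <- match_score
    domain_profile(paste0("toy_", labels[i]), labels[i],
                   if (labels[i] == core_label) "core" else "additional", m)
  })
  consensus_dna <- vapply(consensus_aa, function(s)
    paste(CODON_OF[strsplit(s, "")[[1]]], collapse = ""), character(1))
  list(profiles = profiles, consensus_aa = consensus_aa,
       consensus_dna = consensus_dna)
}

#' Specification of a synthetic planted genome
#'
#' Defines the study conditions of a fixture run: how many elements to
#' plant, their domain layout, LTR geometry and identity, frameshift
#' damage, tandem placement, and the background.
#'
#' @param element_count number of planted elements (default 10).
#' @param domain_labels,domain_lengths domain layout (defaults as in
#'   [make_toy_profiles()]).
#' @param core_label core domain label.
#' @param ltr_length LTR length in bases (default 300).
#' @param ltr_identity LTR pair identity as a fraction (default 0.95).
#' @param ltr_elements how many elements carry LTRs (default all).
#' @param frameshift_insertions number of domains per element disrupted by a
#'   1-2 bp insertion (default 0).
#' @param tandem place elements in close pairs (< 2 flanks apart) so their
#'   loci merge (default FALSE).
#' @param background_length i.i.d. background length in bases (default 1e6).
#' @param gc_content background GC fraction (default 0.4).
#' @param min_spacing minimum distance between planted elements outside
#'   tandem pairs (default 20000, keeping flanked loci from merging).
#' @param tandem_gap distance between the two elements of a tandem pair
#'   (default 3000).
#' @param seed RNG seed; the same spec yields byte-identical output.
#' @return a `plant_spec` list.
#' @export
plant_spec <- function(element_count = 10,
                       domain_labels = c("GAG", "Pro", "gRT", "gRH", "INT"),
                       domain_lengths = c(90, 70, 120, 80, 100),
                       core_label = "gRT", ltr_length = 300,
                       ltr_identity = 0.95, ltr_elements = element_count,
                       frameshift_insertions = 0, tandem = FALSE,
                       background_length = 1e6, gc_content = 0.4,
                       min_spacing = 20000, tandem_gap = 3000, seed = 1) {
  stopifnot(element_count >= 0, ltr_length >= 0,
            ltr_identity > 0, ltr_identity <= 1,
            ltr_elements <= element_count,
            background_length > 0)
  structure(list(element_count = element_count,
                 domain_labels = domain_labels,
                 domain_lengths = domain_lengths, core_label = core_label,
                 ltr_length = ltr_length, ltr_identity = ltr_identity,
                 ltr_elements = ltr_elements,
                 frameshift_insertions = frameshift_insertions,
                 tandem = tandem, background_length = background_length,
                 gc_content = gc_content, min_spacing = min_spacing,
                 tandem_gap = tandem_gap, seed = seed),
            class = "plant_spec")
}

# build one element in local coordinates; returns list(seq, domains, ltr)
build_element <- function(spec, fixtures, strand, with_ltr) {
  parts <- character(0)
  cur <- 0
  dom <- list()
  emit <- function(piece) {
    parts[[length(parts) + 1L]] <<- piece
    cur <<- cur + nchar(piece)
  }
  llen <- if (with_ltr) spec$ltr_length else 0
  ltr_seq <- if (with_ltr) random_dna(spec$ltr_length, spec$gc_content) else ""
  if (with_ltr) emit(ltr_seq)
  emit(random_dna(150, spec$gc_content))
  fs_labels <- if (spec$frameshift_insertions > 0)
    sample(spec$domain_labels, min(spec$frameshift_insertions,
                                   length(spec$domain_labels)))
  else character(0)
  for (lbl in spec$domain_labels) {
    cds <- fixtures$consensus_dna[[lbl]]
    d_start <- cur
    if (lbl %in% fs_labels) {
      n_aa <- nchar(cds) / 3
      cut_aa <- round(n_aa * runif(1, 0.4, 0.6))
      ins <- random_dna(sample(1:2, 1), spec$gc_content)
      emit(substring(cds, 1, 3 * cut_aa))
      emit(ins)
      emit(substring(cds, 3 * cut_aa + 1))
      interrupted <- TRUE
    } else {
      emit(cds)
      interrupted <- FALSE
    }
    dom[[lbl]] <- data.frame(label = lbl, start = d_start, end = cur,
                             interrupted = interrupted,
                             stringsAsFactors = FALSE)
    emit(random_dna(30, spec$gc_content))
  }
  emit(random_dna(150, spec$gc_content))
  ltr <- NULL
  if (with_ltr) {
    right_start <- cur
    n_mut <- round((1 - spec$ltr_identity) * spec$ltr_length)
    emit(mutate_dna(ltr_seq, n_mut))
    ltr <- list(left_start = 0, left_end = llen,
                right_start = right_start, right_end = cur)
  }
  seq <- paste(parts, collapse = "")
  domains <- do.call(rbind, dom)
  domains$strand <- strand
  total <- nchar(seq)
  if (strand == "-") {
    seq <- revcomp(seq)
    new_start <- total - domains$end
    domains$end <- total - domains$start
    domains$start <- new_start
    domains <- domains[order(domains$start), ]
    if (!is.null(ltr)) {
      ltr <- list(left_start = total - ltr$right_end,
                  left_end = total - ltr$right_start,
                  right_start = total - ltr$left_end,
                  right_end = total - ltr$left_start)
    }
  }
  rownames(domains) <- NULL
  list(seq = seq, domains = domains, ltr = ltr, length = total)
}

#' Generate a synthetic genome with planted elements and a truth table
#'
#' Elements are embedded at non-overlapping positions in i.i.d. background
#' sequence.  Optional frameshifts (1-2 bp insertions inside chosen
#' domains), mutated LTR copies at a stated identity, and tandem placement
#' (two elements within one prospective locus) exercise every annotation
#' stage.  Fully deterministic for a fixed spec.
#'
#' @param spec a [plant_spec()].
#' @param fixtures toy profiles from [make_toy_profiles()]; generated from
#'   the spec's layout and seed when omitted.
#' @return list with `genome` (named character vector, one chromosome
#'   `chr1`), `truth` (one row per element: coordinates, strand, structure,
#'   domain-block envelope, LTR geometry and expected identity),
#'   `truth_domains` (per-domain coordinates), `profiles`, `fixtures`.
#' @export
plant_genome <- function(spec, fixtures = NULL) {
  stopifnot(inherits(spec, "plant_spec"))
  if (is.null(fixtures))
    fixtures <- make_toy_profiles(spec$domain_labels, spec$domain_lengths,
                                  spec$core_label, seed = spec$seed)
  withr::with_seed(spec$seed + 1L, {
    bg <- random_dna(spec$background_length, spec$gc_content)
    n <- spec$element_count
    if (n == 0L) {
      list(genome = c(chr1 = bg),
           truth = empty_truth(), truth_domains = empty_truth_domains(),
           profiles = fixtures$profiles, fixtures = fixtures)
    } else {
    with_ltr <- seq_len(n) %in% sample(n, spec$ltr_elements)
    strands <- sample(c("+", "-"), n, TRUE)
    els <- lapply(seq_len(n), function(i)
      build_element(spec, fixtures, strands[i], with_ltr[i]))
    # background offsets: evenly slotted with jitter, respecting spacing
    edge <- 8000
    if (spec$tandem) {
      npair <- ceiling(n / 2)
      slot <- (spec$background_length - 2 * edge) / npair
      if (slot < spec$min_spacing + spec$tandem_gap)
        stop("background too short to host the planted elements")
      base <- edge + (seq_len(npair) - 1) * slot +
        runif(npair, 0, slot - spec$min_spacing - spec$tandem_gap)
      offsets <- as.numeric(rbind(base, base + spec$tandem_gap))[seq_len(n)]
    } else {
      slot <- (spec$background_length - 2 * edge) / n
      if (slot < spec$min_spacing)
        stop("background too short to host the planted elements")
      offsets <- edge + (seq_len(n) - 1) * slot +
        runif(n, 0, slot - spec$min_spacing)
    }
    offsets <- floor(offsets)
    # splice elements into the background
    pieces <- character(0)
    prev <- 0
    shift <- 0
    starts <- numeric(n)
    for (i in seq_len(n)) {
      pieces <- c(pieces, substring(bg, prev + 1, offsets[i]), els[[i]]$seq)
      starts[i] <- offsets[i] + shift
      shift <- shift + els[[i]]$length
      prev <- offsets[i]
    }
    pieces <- c(pieces, substring(bg, prev + 1))
    genome <- c(chr1 = paste(pieces, collapse = ""))
    truth <- do.call(rbind, lapply(seq_len(n), function(i) {
      e <- els[[i]]
      g <- starts[i]
      data.frame(element_index = i, sequence_id = "chr1",
                 start = g, end = g + e$length, strand = strands[i],
                 structure = paste(spec$domain_labels, collapse = "."),
                 block_start = g + min(e$domains$start),
                 block_end = g + max(e$domains$end),
                 has_ltr = with_ltr[i],
                 ltr_identity = if (with_ltr[i]) 100 * spec$ltr_identity
                                else NA_real_,
                 ltr_length = if (with_ltr[i]) spec$ltr_length
                              else NA_integer_,
                 ltr_left_start = if (with_ltr[i]) g + e$ltr$left_start
                                  else NA_real_,
                 ltr_left_end = if (with_ltr[i]) g + e$ltr$left_end
                                else NA_real_,
                 ltr_right_start = if (with_ltr[i]) g + e$ltr$right_start
                                   else NA_real_,
                 ltr_right_end = if (with_ltr[i]) g + e$ltr$right_end
                                 else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    truth_domains <- do.call(rbind, lapply(seq_len(n), function(i) {
      d <- els[[i]]$domains
      data.frame(element_index = i, label = d$label,
                 start = starts[i] + d$start, end = starts[i] + d$end,
                 strand = d$strand, interrupted = d$interrupted,
                 stringsAsFactors = FALSE)
    }))
    list(genome = genome, truth = truth, truth_domains = truth_domains,
         profiles = fixtures$profiles, fixtures = fixtures)
    }
  })
}

empty_truth <- function() {
  data.frame(element_index = integer(), sequence_id = character(),
             start = numeric(), end = numeric(), strand = character(),
             structure = character(), block_start = numeric(),
             block_end = numeric(), has_ltr = logical(),
             ltr_identity = numeric(), ltr_length = integer(),
             ltr_left_start = numeric(), ltr_left_end = numeric(),
             ltr_right_start = numeric(), ltr_right_end = numeric(),
             stringsAsFactors = FALSE)
}

empty_truth_domains <- function() {
  data.frame(element_index = integer(), label = character(),
             start = numeric(), end = numeric(), strand = character(),
             interrupted = logical(), stringsAsFactors = FALSE)
}

#' Write a planted fixture set to disk
#'
#' Emits `genome.fasta`, `truth.tsv`, `truth_domains.tsv` and
#' `profiles.pssm` under `out_dir`.
#'
#' @param planted result of [plant_genome()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_fixtures <- function(planted, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(planted$genome, file.path(out_dir, "genome.fasta"))
  write.table(planted$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(planted$truth_domains, file.path(out_dir, "truth_domains.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_profiles(planted$profiles, file.path(out_dir, "profiles.pssm"))
  invisible(out_dir)
}
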