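# End-to-end orchestration: batching -> round-1 core search -> locus
# building -> round-2 annotation -> LTR detection -> scoring/naming ->
# clustering, with per-stage artifacts and a run summary.

#' Default run configuration
#'
#' Every filtering and threshold value of the pipeline, defaulting to the
#' published value where one exists (e-value 1e-3, 7500 bp flanks, LTR
#' identity > 80 percent and length 100-3000 bp, clustering 0.8/0.8, 1 Gbp
#' assembly split with 100 Mbp batches).
#'
#' @param project run name used in element identifiers.
#' @param fasta input assembly FASTA path (optional when an in-memory
#'   assembly is passed to [run_pipeline()]).
#' @param profiles profile set: a path readable by [read_profiles()] or a
#'   list of [domain_profile()] objects.
#' @param out_dir output directory.
#' @param max_evalue,min_match_fraction round-1/2 hit pre-filter.
#' @param flank locus flank length (bases).
#' @param max_genomic_gap,max_profile_overlap fragment-chaining bounds.
#' @param ltr_window,ltr_min_identity,ltr_min_length,ltr_max_length LTR
#'   search window and strict thresholds.
#' @param min_seq_id,min_coverage clustering parameters.
#' @param split_threshold,batch_ceiling assembly batching sizes.
#' @param require_additional_domains element filter: minimum non-core
#'   domains (0 keeps every element with a core domain).
#' @param expected_domains complete-element domain count used by the score.
#' @param weights a [score_weights()] object.
#' @param seed RNG seed recorded with the run (the pipeline itself is
#'   deterministic).
#' @return a validated `run_config` list.
#' @export
default_config <- function(project = "run", fasta = NULL, profiles = NULL,
                           out_dir = tempfile("retromine_"),
                           max_evalue = 1e-3, min_match_fraction = 0.3,
                           flank = 7500, max_genomic_gap = 600,
                           max_profile_overlap = 15, ltr_window = 7500,
                           ltr_min_identity = 80, ltr_min_length = 100,
                           ltr_max_length = 3000, min_seq_id = 0.8,
                           min_coverage = 0.8, split_threshold = 1e9,
                           batch_ceiling = 1e8,
                           require_additional_domains = 0,
                           expected_domains = 5, weights = score_weights(),
                           seed = 1) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [default_config()]
#' values.
#'
#' @param path YAML file.
#' @return a `run_config` list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg <- defaults
  cfg[names(user)] <- user
  if (is.list(cfg$weights) && !inherits(cfg$weights, "score_weights"))
    cfg$weights <- do.call(score_weights, cfg$weights)
  structure(cfg, class = "run_config")
}

#' Run the full mining pipeline
#'
#' Executes, in order: batch planning, round-1 core-domain search, hit
#' pre-filtering, locus expansion/merging and sequence extraction, round-2
#' annotation with the full profile set (fragment chaining, tandem
#' delineation, ORF assessment), LTR detection, scoring and naming, domain
#' peptide extraction, and core-domain clustering with representative
#' selection.  Per-stage artifacts (batch manifest, hit TSVs, locus
#' FASTA/BED, element GFF3 and FASTA, per-domain peptide FASTAs, cluster
#' TSV, representatives FASTA, summary JSON) are written under
#' `config$out_dir`.
#'
#' @param config a `run_config` from [default_config()] / [load_config()].
#' @param assembly optional in-memory assembly (named character vector);
#'   read from `config$fasta` when omitted.
#' @return invisibly, a list with `summary` (per-stage counts and the
#'   thresholds in effect), `elements` (annotated `retro_element` list),
#'   `element_table`, `clusters`, `loci`, `plan`, `out_dir`.
#' @export
run_pipeline <- function(config, assembly = NULL) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    message("[retromine] ", msg)
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(assembly)) {
    if (is.null(config$fasta)) stop("config$fasta or assembly required")
    assembly <- stage("read_assembly", read_fasta(config$fasta))
  }
  profiles <- config$profiles
  if (is.character(profiles)) profiles <- read_profiles(profiles)
  validate_profile_set(profiles)
  core <- core_label(profiles)
  core_profiles <- profiles[vapply(profiles, `[[`, character(1),
                                   "role") == "core"]
  thr <- config[c("max_evalue", "min_match_fraction", "flank",
                  "max_genomic_gap", "max_profile_overlap", "ltr_window",
                  "ltr_min_identity", "ltr_min_length", "ltr_max_length",
                  "min_seq_id", "min_coverage", "split_threshold",
                  "batch_ceiling", "require_additional_domains",
                  "expected_domains")]
  for (k in names(thr)) say("threshold %s = %s", k, format(thr[[k]]))

  ## stage 1: batching
  plan <- stage("plan_batches",
                plan_batches(assembly, config$split_threshold,
                             config$batch_ceiling))
  write_batch_manifest(plan, file.path(out, "batch_manifest.tsv"))
  say("batches: %d", length(unique(plan$batch_index)))

  ## stage 2: round-1 core-domain search, per batch segment, coordinates
  ## mapped back to the original assembly
  hits1 <- stage("round1_search", {
    if (nrow(plan) == 0L) empty_hits() else {
      res <- lapply(seq_len(nrow(plan)), function(i) {
        seg <- plan[i, ]
        seq <- substring(assembly[[seg$source_id]], seg$start + 1, seg$end)
        h <- scan_profiles(setNames(seq, seg$source_id), core_profiles,
                           min_evalue = config$max_evalue)
        h$genomic_start <- h$genomic_start + seg$start
        h$genomic_end <- h$genomic_end + seg$start
        h
      })
      do.call(rbind, res)
    }
  })
  write_hits_tsv(hits1, file.path(out, "hits_round1.tsv"))
  hits1 <- prefilter_hits(hits1, core_profiles, config$max_evalue,
                          config$min_match_fraction)
  say("round-1 core hits after pre-filter: %d", nrow(hits1))

  ## stage 3: loci
  loci <- stage("locus_building", {
    l <- expand_and_merge(hits1, nchar(assembly), config$flank)
    extract_sequences(l, assembly)
  })
  if (nrow(loci)) {
    write_fasta(setNames(loci$sequence, loci$locus_id),
                file.path(out, "loci.fasta"))
    write_loci_bed(loci, file.path(out, "loci.bed"))
  }
  say("loci: %d", nrow(loci))

  ## stage 4: round-2 annotation
  hits2 <- stage("round2_search", {
    if (nrow(loci) == 0L) empty_hits()
    else prefilter_hits(
      scan_profiles(setNames(loci$sequence, loci$locus_id), profiles,
                    min_evalue = config$max_evalue),
      profiles, config$max_evalue, config$min_match_fraction)
  })
  write_hits_tsv(hits2, file.path(out, "hits_round2.tsv"))

  elements <- list()
  dropped <- list()
  stage("annotation", for (i in seq_len(nrow(loci))) {
    lh <- hits2[hits2$sequence_id == loci$locus_id[i], , drop = FALSE]
    dom <- chain_fragments(lh, profiles, config$max_genomic_gap,
                           config$max_profile_overlap)
    del <- delineate_elements(loci[i, ], dom, core,
                              config$require_additional_domains)
    dropped[[length(dropped) + 1L]] <- del$dropped
    for (el in del$elements) {
      el <- detect_orf_intactness(el)
      el$ltr <- find_ltr_pair(el, loci$sequence[i], config$ltr_window,
                              config$ltr_min_identity, config$ltr_min_length,
                              config$ltr_max_length)
      elements[[length(elements) + 1L]] <- el
    }
  })
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(locus_id = character(), structure = character(),
               reason = character(), stringsAsFactors = FALSE)
  write.table(dropped, file.path(out, "dropped_elements.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ## stage 5: scoring and naming; element numbering is per batch in order
  ## of genomic position
  stage("scoring_naming", {
    counters <- new.env(parent = emptyenv())
    weights <- config$weights
    weights$expected_domains <- config$expected_domains
    for (i in seq_along(elements)) {
      el <- elements[[i]]
      el$score <- compute_score(el, do.call(score_weights, weights))
      gstart <- el$locus_start + min(el$domains$genomic_start)
      b <- plan$batch_index[plan$source_id == el$sequence_id &
                            plan$start <= gstart & gstart < plan$end][1]
      key <- as.character(b)
      n <- (get0(key, counters) %||% 0L) + 1L
      assign(key, n, counters)
      el$element_id <- format_element_id(config$project, b, n, el)
      elements[[i]] <- el
    }
  })
  say("elements: %d (with LTR: %d)", length(elements),
      sum(vapply(elements, function(e) !is.null(e$ltr), logical(1))))

  element_table <- elements_table(elements)
  core_only <- report_core_only_fraction(element_table$structure, core)
  say("core-only fraction: %s",
      if (is.na(core_only)) "n/a" else sprintf("%.1f%%", core_only))

  ## stage 6: outputs per element
  if (length(elements)) {
    write_elements_gff3(elements, loci, file.path(out, "elements.gff3"))
    write_fasta(element_sequences(elements, assembly, loci),
                file.path(out, "elements.fasta"))
    peptides <- extract_domain_peptides(elements)
    for (lbl in names(peptides))
      write_fasta(peptides[[lbl]], file.path(out, sprintf("peptides_%s.faa",
                                                          lbl)))
  } else peptides <- list()

  ## stage 7: clustering of the core-domain peptides
  clusters <- NULL
  if (length(elements) && core %in% names(peptides)) {
    clusters <- stage("clustering", {
      cl <- cluster_core_domains(peptides[[core]], config$min_seq_id,
                                 config$min_coverage)
      select_representatives(cl, element_table)
    })
    write_cluster_table(clusters, element_table,
                        file.path(out, "clusters.tsv"))
    reps <- unique(clusters$representative_id)
    write_fasta(element_sequences(
      elements[match(reps, element_table$element_id)], assembly, loci),
      file.path(out, "representatives.fasta"))
    say("clusters: %d", length(unique(clusters$cluster_id)))
  }

  summary <- list(
    project = config$project, seed = config$seed,
    batches = length(unique(plan$batch_index)),
    round1_hits = nrow(hits1), loci = nrow(loci),
    round2_hits = nrow(hits2),
    elements = length(elements),
    with_ltr = sum(vapply(elements, function(e) !is.null(e$ltr),
                          logical(1))),
    dropped = nrow(dropped),
    core_only_fraction = core_only,
    clusters = if (is.null(clusters)) 0L
               else length(unique(clusters$cluster_id)),
    thresholds = thr)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out, "run_log.txt"))
  invisible(list(summary = summary, elements = elements,
                 element_table = element_table, clusters = clusters,
                 loci = loci, plan = plan, out_dir = out))
}

#' Fraction of elements containing only the core domain
#'
#' An estimated stringent upper bound on the false-positive rate: elements
#' whose structure is exactly the core label carry no corroborating
#' additional domain.
#'
#' @param structures character vector of element structure strings.
#' @param core_label the core domain label.
#' @return percent (0-100), or `NA` for an empty element set.
#' @export
report_core_only_fraction <- function(structures, core_label) {
  if (length(structures) == 0L) return(NA_real_)
  100 * mean(structures == core_label)
}

#' Summarise annotated elements as a data frame
#' @param elements list of `retro_element` objects.
#' @return data frame with id, locus, strand, structure, coordinates, ORF
#'   flag, LTR fields and score.
#' @export
elements_table <- function(elements) {
  if (length(elements) == 0L)
    return(data.frame(element_id = character(), locus_id = character(),
                      sequence_id = character(), strand = character(),
                      structure = character(), block_start = numeric(),
                      block_end = numeric(), n_domains = integer(),
                      orf_intact = logical(), ltr_identity = numeric(),
                      ltr_length = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(elements, function(e) data.frame(
    element_id = e$element_id, locus_id = e$locus_id,
    sequence_id = e$sequence_id, strand = e$strand, structure = e$structure,
    block_start = e$locus_start + min(e$domains$genomic_start),
    block_end = e$locus_start + max(e$domains$genomic_end),
    n_domains = nrow(e$domains), orf_intact = e$orf_intact,
    ltr_identity = if (is.null(e$ltr)) NA_real_ else e$ltr$identity,
    ltr_length = if (is.null(e$ltr)) NA_integer_ else e$ltr$length,
    score = e$score, stringsAsFactors = FALSE)))
}

write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# element nucleotide span: LTR-to-LTR when a pair is present, otherwise the
# domain block
element_sequences <- function(elements, assembly, loci) {
  seqs <- vapply(elements, function(e) {
    if (!is.null(e$ltr)) {
      s <- e$locus_start + e$ltr$left_start
      t <- e$locus_start + e$ltr$right_end
    } else {
      s <- e$locus_start + min(e$domains$genomic_start)
      t <- e$locus_start + max(e$domains$genomic_end)
    }
    substring(assembly[[e$sequence_id]], s + 1, t)
  }, character(1))
  setNames(seqs, vapply(elements, `[[`, character(1), "element_id"))
}

# GFF3 output (1-based inclusive): element features with domain and LTR
# children.  Attribute values carrying reserved characters are
# percent-escaped per the GFF3 spec.
write_elements_gff3 <- function(elements, loci, path) {
  esc <- function(x) {
    x <- gsub("%", "%25", x, fixed = TRUE)
    x <- gsub(";", "%3B", x, fixed = TRUE)
    x <- gsub("=", "%3D", x, fixed = TRUE)
    x <- gsub(",", "%2C", x, fixed = TRUE)
    x
  }
  rows <- character(0)
  for (i in seq_along(elements)) {
    e <- elements[[i]]
    eid <- sprintf("element%04d", i)
    if (!is.null(e$ltr)) {
      s <- e$locus_start + e$ltr$left_start
      t <- e$locus_start + e$ltr$right_end
    } else {
      s <- e$locus_start + min(e$domains$genomic_start)
      t <- e$locus_start + max(e$domains$genomic_end)
    }
    rows <- c(rows, sprintf(
      "%s\tretromine\tmobile_element\t%d\t%d\t%s\t%s\t.\tID=%s;Name=%s;structure=%s;orf_intact=%s",
      e$sequence_id, s + 1, t, format(e$score, nsmall = 1), e$strand, eid,
      esc(e$element_id), esc(e$structure), tolower(e$orf_intact)))
    for (j in seq_len(nrow(e$domains))) {
      d <- e$domains[j, ]
      rows <- c(rows, sprintf(
        "%s\tretromine\tprotein_match\t%d\t%d\t%.2f\t%s\t.\tID=%s.d%d;Parent=%s;Name=%s;interrupted=%s",
        e$sequence_id, e$locus_start + d$genomic_start + 1,
        e$locus_start + d$genomic_end, d$combined_bits, d$strand, eid, j,
        eid, esc(d$domain_label), tolower(d$interrupted)))
    }
    if (!is.null(e$ltr)) {
      for (side in c("left", "right")) {
        ls <- e$locus_start + e$ltr[[paste0(side, "_start")]]
        le <- e$locus_start + e$ltr[[paste0(side, "_end")]]
        rows <- c(rows, sprintf(
          "%s\tretromine\tlong_terminal_repeat\t%d\t%d\t.\t%s\t.\tID=%s.ltr_%s;Parent=%s;identity=%.3f",
          e$sequence_id, ls + 1, le, e$strand, eid, side, eid,
          e$ltr$identity))
      }
    }
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Parse an MMseqs2 easy-cluster membership TSV
#'
#' Adapter for externally produced clustering: a two-column
#' representative/member TSV as written by `mmseqs easy-cluster`.
#'
#' @param path TSV path.
#' @return cluster table in the format of [cluster_core_domains()].
#' @export
parse_mmseqs_clusters <- function(path) {
  tb <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("representative_id", "member_id"),
                   stringsAsFactors = FALSE)
  reps <- unique(tb$representative_id)
  data.frame(cluster_id = match(tb$representative_id, reps),
             member_id = tb$member_id,
             representative_id = tb$representative_id,
             stringsAsFactors = FALSE)
}
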