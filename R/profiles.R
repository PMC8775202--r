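#' Construct a protein-domain profile (PSSM)
#'
#' A profile is a position-specific scoring matrix over the 20 standard amino
#' acids, tagged with a domain label and a role: exactly one profile in a set
#' plays the `core` role (the round-1 search seed, reverse transcriptase for
#' LTR retrotransposons); the rest are `additional`.
#'
#' @param profile_id unique accession-like identifier.
#' @param label domain label used in structure strings (e.g. `"gRT"`).
#' @param role `"core"` or `"additional"`.
#' @param matrix numeric matrix, positions x 20, columns in the package's
#'   fixed amino-acid order `ACDEFGHIKLMNPQRSTVWY`.
#' @return an object of class `domain_profile`.
#' @export
domain_profile <- function(profile_id, label, role, matrix) {
  stopifnot(is.matrix(matrix), ncol(matrix) == 20L,
            role %in% c("core", "additional"))
  colnames(matrix) <- AA_ORDER
  structure(list(profile_id = profile_id, label = label, role = role,
                 matrix = matrix, length = nrow(matrix)),
            class = "domain_profile")
}

#' @export
print.domain_profile <- function(x, ...) {
  cat(sprintf("<domain_profile %s label=%s role=%s length=%d>\n",
              x$profile_id, x$label, x$role, x$length))
  invisible(x)
}

validate_profile_set <- function(profiles) {
  stopifnot(length(profiles) > 0)
  labels <- vapply(profiles, `[[`, character(1), "label")
  roles <- vapply(profiles, `[[`, character(1), "role")
  if (anyDuplicated(labels))
    stop("duplicate domain_label in profile set: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (sum(roles == "core") < 1L)
    stop("profile set must contain at least one core profile")
  invisible(profiles)
}

core_label <- function(profiles) {
  roles <- vapply(profiles, `[[`, character(1), "role")
  vapply(profiles, `[[`, character(1), "label")[roles == "core"][1]
}

#' Write profiles in the plain-text PSSM format
#'
#' One block per profile: a header line
#' `>profile_id <TAB> label <TAB> role <TAB> length` followed by `length`
#' lines of 20 whitespace-separated scores in amino-acid order
#' `ACDEFGHIKLMNPQRSTVWY`.
#'
#' @param profiles list of [domain_profile()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("# columns: ", paste(AA_ORDER, collapse = " ")), con)
  for (p in profiles) {
    writeLines(sprintf(">%s\t%s\t%s\t%d", p$profile_id, p$label, p$role,
                       p$length), con)
    writeLines(apply(p$matrix, 1L,
                     function(r) paste(format(r, trim = TRUE), collapse = " ")),
               con)
  }
  invisible(path)
}

#' Read profiles from the plain-text PSSM format
#' @param path path written by [write_profiles()].
#' @return list of [domain_profile()] objects.
#' @export
read_profiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  hdr <- which(startsWith(lines, ">"))
  if (length(hdr) == 0L) stop("no profiles in ", path)
  bounds <- c(hdr, length(lines) + 1L)
  profiles <- lapply(seq_along(hdr), function(i) {
    f <- strsplit(sub("^>", "", lines[hdr[i]]), "\t")[[1]]
    if (length(f) != 4L)
      stop("malformed profile header at line ", hdr[i], ": ", lines[hdr[i]])
    L <- as.integer(f[4])
    rows <- lines[seq(bounds[i] + 1L, bounds[i + 1L] - 1L)]
    rows <- rows[nzchar(rows)]
    if (length(rows) != L)
      stop("profile ", f[1], ": expected ", L, " matrix rows, found ",
           length(rows))
    m <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    if (ncol(m) != 20L) stop("profile ", f[1], ": matrix must have 20 columns")
    domain_profile(f[1], f[2], f[3], m)
  })
  validate_profile_set(profiles)
}
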