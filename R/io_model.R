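# Readers, writers and confidence filtering for the tabular evidence model.
# All files are UTF-8, tab-separated, single header row; the column names
# below are part of the public contract (see README).

GO_ASPECTS <- c("biological_process", "molecular_function", "cellular_component")
.GO_PATTERN <- "^GO:[0-9]{7}$"

.require_cols <- function(tab, cols, what, path) {
  miss <- setdiff(cols, names(tab))
  if (length(miss)) {
    stop(what, " file '", path, "' is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
}

.bad_rows <- function(idx, path, msg) {
  if (length(idx)) {
    stop("malformed ", msg, " in '", path, "' at data line(s): ",
         paste(head(idx, 10L), collapse = ", "))
  }
}

#' Read a peptide-evidence table
#'
#' Expected columns: `peptide`, `evalue`, `ms1_area`, `spectral_count`,
#' `sample_id`. One row per confidently identified peptide; `spectral_count`
#' carries the redundant occurrence count, `ms1_area` the MS1 extracted-ion
#' chromatogram area (the quantitative evidence weight).
#'
#' @param path TSV path
#' @return data.frame of validated peptide evidence.
#' @export
read_peptides <- function(path) {
  tab <- fread(path, sep = "\t", data.table = FALSE)
  .require_cols(tab, c("peptide", "evalue", "ms1_area", "spectral_count",
                       "sample_id"), "peptide", path)
  tab$peptide <- as.character(tab$peptide)
  tab$sample_id <- as.character(tab$sample_id)
  tab$evalue <- as.numeric(tab$evalue)
  tab$ms1_area <- as.numeric(tab$ms1_area)
  tab$spectral_count <- as.integer(tab$spectral_count)
  .bad_rows(which(!is.finite(tab$evalue) | tab$evalue <= 0), path,
            "E-value (must be > 0)")
  .bad_rows(which(!is.finite(tab$ms1_area) | tab$ms1_area < 0), path,
            "ms1_area (must be >= 0)")
  .bad_rows(which(is.na(tab$spectral_count) | tab$spectral_count < 1L), path,
            "spectral_count (must be >= 1)")
  tab
}

#' Write a peptide-evidence table
#' @param peptides data.frame as returned by [read_peptides()]
#' @param path destination
#' @return `path`, invisibly.
#' @export
write_peptides <- function(peptides, path) {
  fwrite(peptides[, c("peptide", "evalue", "ms1_area", "spectral_count",
                      "sample_id")], path, sep = "\t")
  invisible(path)
}

#' Read a protein-record table
#'
#' Expected columns: `accession`, `taxon_id`, `evalue`, `peptides`
#' (semicolon-joined identified-peptide sequences). Returns the table with
#' `peptides` expanded into a list-column of character vectors.
#'
#' @param path TSV path
#' @return data.frame with list-column `peptides`.
#' @export
read_proteins <- function(path) {
  tab <- fread(path, sep = "\t", data.table = FALSE)
  .require_cols(tab, c("accession", "taxon_id", "evalue", "peptides"),
                "protein", path)
  tab$accession <- as.character(tab$accession)
  tab$taxon_id <- as.character(tab$taxon_id)
  tab$evalue <- as.numeric(tab$evalue)
  .bad_rows(which(!is.finite(tab$evalue) | tab$evalue <= 0), path,
            "E-value (must be > 0)")
  peps <- strsplit(as.character(tab$peptides), ";", fixed = TRUE)
  .bad_rows(which(lengths(peps) == 0L | vapply(peps, function(p)
    any(!nzchar(p)), logical(1))), path, "peptide list (must be nonempty)")
  tab$peptides <- peps
  tab
}

#' Write a protein-record table
#' @param proteins data.frame with list-column `peptides`
#' @param path destination
#' @return `path`, invisibly.
#' @export
write_proteins <- function(proteins, path) {
  out <- proteins[, c("accession", "taxon_id", "evalue")]
  out$peptides <- vapply(proteins$peptides, paste, "", collapse = ";")
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read protein-to-GO annotations
#'
#' Two dialects:
#' * `"flat"`: TSV with header `accession`, `go_id`, `aspect` (aspect spelled
#'   out as `biological_process` / `molecular_function` /
#'   `cellular_component`).
#' * `"gaf"`: GAF 2.2 subset; `!`-prefixed comment lines skipped, no header;
#'   column 2 = object id, column 5 = GO id, column 9 = aspect code
#'   (`P`/`F`/`C`).
#'
#' @param path file path
#' @param dialect `"flat"` or `"gaf"`
#' @return data.frame with columns `accession`, `go_id`, `aspect`.
#' @export
read_annotations <- function(path, dialect = c("flat", "gaf")) {
  dialect <- match.arg(dialect)
  if (dialect == "flat") {
    tab <- fread(path, sep = "\t", colClasses = "character",
                 data.table = FALSE)
    .require_cols(tab, c("accession", "go_id", "aspect"), "annotation", path)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(fields) < 9L)
    .bad_rows(short, path, "GAF line (needs >= 9 columns)")
    code <- vapply(fields, `[[`, "", 9L)
    aspect <- c(P = "biological_process", F = "molecular_function",
                C = "cellular_component")[code]
    .bad_rows(which(is.na(aspect)), path, "GAF aspect code (P/F/C)")
    tab <- data.frame(accession = vapply(fields, `[[`, "", 2L),
                      go_id = vapply(fields, `[[`, "", 5L),
                      aspect = unname(aspect), stringsAsFactors = FALSE)
  }
  .bad_rows(which(!grepl(.GO_PATTERN, tab$go_id)), path,
            "GO id (expect GO: followed by 7 digits)")
  .bad_rows(which(!tab$aspect %in% GO_ASPECTS), path, "GO aspect")
  tab[, c("accession", "go_id", "aspect")]
}

#' Write a flat annotation table
#' @param annotations data.frame with `accession`, `go_id`, `aspect`
#' @param path destination
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  fwrite(annotations[, c("accession", "go_id", "aspect")], path, sep = "\t")
  invisible(path)
}

#' Retain the largest low-E-value prefix meeting a PFD target
#'
#' E-values are read as expected false-positive counts at their score, so the
#' estimated proportion of false discoveries among the `r` best-scoring items
#' is `E_r / r`. Items are ranked by ascending E-value and the largest prefix
#' whose estimated PFD is at or below `pfd_target` is kept.
#'
#' @param items data.frame with an `evalue` column
#' @param pfd_target fraction in (0, 1), e.g. 0.01
#' @return list with `retained` (rows of `items`, original order preserved)
#'   and `cutoff` (last retained E-value, or `NA` if nothing is retained).
#' @export
filter_by_pfd <- function(items, pfd_target) {
  stopifnot(is.data.frame(items), "evalue" %in% names(items),
            pfd_target > 0, pfd_target < 1)
  if (!nrow(items)) return(list(retained = items, cutoff = NA_real_))
  ord <- order(items$evalue)
  e_sorted <- items$evalue[ord]
  ok <- e_sorted / seq_along(e_sorted) <= pfd_target
  r <- if (any(ok)) max(which(ok)) else 0L
  if (r == 0L) {
    return(list(retained = items[0L, , drop = FALSE], cutoff = NA_real_))
  }
  keep <- sort(ord[seq_len(r)])
  list(retained = items[keep, , drop = FALSE], cutoff = e_sorted[r])
}

#' Retain items at or below an E-value cutoff
#'
#' @param items data.frame with an `evalue` column
#' @param cutoff positive E-value threshold (inclusive)
#' @return Rows of `items` with `evalue <= cutoff`, order preserved.
#' @export
apply_evalue_cutoff <- function(items, cutoff) {
  stopifnot(cutoff > 0)
  items[items$evalue <= cutoff, , drop = FALSE]
}

#' Write a biomass table
#' @param biomass data.frame (sample_id, level, taxon_id, biomass)
#' @param path destination
#' @return `path`, invisibly.
#' @export
write_biomass_tsv <- function(biomass, path) {
  fwrite(biomass, path, sep = "\t")
  invisible(path)
}

#' Write a function-abundance table
#' @param abundance data.frame
#'   (sample_id, level, taxon_id, taxon_name, aspect, go_id, abundance)
#' @param path destination
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(abundance, path) {
  fwrite(abundance, path, sep = "\t")
  invisible(path)
}
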