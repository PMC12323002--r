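# Lowest-common-ancestor baseline: per-peptide taxon assignment plus the
# normalized taxon abundance (NTA) and biological-function abundance (BA)
# statistics computed from redundant peptide counts, and the 0.5%
# taxon-specific-peptide filter used with Unipept-style outputs.

#' Assign each peptide to the LCA of its compatible taxa
#'
#' @param peptides peptide evidence data.frame
#' @param compat a `compatibility_map` (peptides absent from it are dropped
#'   with a warning)
#' @param tree taxonomy_tree
#' @return data.frame (`peptide`, `assigned_taxon`, `rank`), one row per
#'   unique peptide sequence.
#' @export
assign_lca <- function(peptides, compat, tree) {
  seqs <- sort(unique(peptides$peptide))
  known <- seqs %in% names(compat$taxon_sets)
  if (!all(known)) {
    warning(sum(!known), " peptide(s) absent from the compatibility map ",
            "were dropped")
    seqs <- seqs[known]
  }
  assigned <- vapply(seqs, function(p) lca(tree, compat$taxon_sets[[p]]),
                     character(1))
  data.frame(peptide = seqs, assigned_taxon = unname(assigned),
             rank = unname(tree$rank[assigned]), stringsAsFactors = FALSE)
}

#' Taxon abundances from LCA assignments
#'
#' `TA(t)` is the total spectral count (redundancy included) of peptides
#' whose assigned LCA is exactly `t`; `NTA(t) = TA(t) / sum_b TA(b)`.
#'
#' @param assignment data.frame from [assign_lca()]
#' @param peptides peptide evidence data.frame (spectral counts are summed
#'   per peptide sequence)
#' @return list with `ta` and `nta`, both named numeric vectors.
#' @export
compute_nta <- function(assignment, peptides) {
  counts <- vapply(split(peptides$spectral_count, peptides$peptide), sum,
                   numeric(1))
  hit <- match(assignment$peptide, names(counts))
  ta_raw <- counts[hit]
  ta_raw[is.na(ta_raw)] <- 0
  ta <- vapply(split(ta_raw, assignment$assigned_taxon), sum, numeric(1))
  ta <- ta[order(names(ta))]
  if (sum(ta) == 0) {
    warning("all taxon abundances are zero")
    return(list(ta = ta, nta = numeric(0)))
  }
  list(ta = ta, nta = ta / sum(ta))
}

#' Biological-function abundances from peptide counts
#'
#' `BA(g)` sums spectral counts of every peptide mapping to GO term `g`; a
#' peptide mapping to several terms contributes its full count to each.
#' Peptides absent from the term map are skipped.
#'
#' @param peptides peptide evidence data.frame
#' @param peptide_to_terms named list: peptide sequence -> character vector
#'   of GO ids
#' @return Named numeric vector of BA values, sorted by GO id.
#' @export
compute_ba <- function(peptides, peptide_to_terms) {
  counts <- vapply(split(peptides$spectral_count, peptides$peptide), sum,
                   numeric(1))
  ba <- numeric(0)
  for (p in names(counts)) {
    terms <- peptide_to_terms[[p]]
    if (is.null(terms) || !length(terms)) next
    for (g in unique(terms)) {
      ba[g] <- (if (g %in% names(ba)) ba[[g]] else 0) + counts[[p]]
    }
  }
  ba[order(names(ba))]
}

#' Drop species with under 0.5% of taxon-specific peptides
#'
#' Species whose share of the species-level taxon-specific peptide count is
#' strictly below `fraction` are treated as false positives and removed;
#' a species sitting exactly at the threshold is retained.
#'
#' @param species_level_ta named numeric vector of species-level TA counts
#' @param fraction threshold fraction of the total (default 0.005)
#' @return Character vector of retained species ids.
#' @export
unipept_filter <- function(species_level_ta, fraction = 0.005) {
  total <- sum(species_level_ta)
  if (total == 0) return(character(0))
  sort(names(species_level_ta)[species_level_ta / total >= fraction])
}

#' Write LCA assignments
#' @param assignment data.frame from [assign_lca()]
#' @param path destination TSV (peptide, assigned_taxon_id, rank)
#' @return `path`, invisibly.
#' @export
write_lca_tsv <- function(assignment, path) {
  out <- data.frame(peptide = assignment$peptide,
                    assigned_taxon_id = assignment$assigned_taxon,
                    rank = assignment$rank, stringsAsFactors = FALSE)
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write NTA / BA vectors
#' @param x named numeric vector
#' @param path destination TSV
#' @param key column name for the identifier (e.g. `"taxon_id"`, `"go_id"`)
#' @param value column name for the value
#' @return `path`, invisibly.
#' @export
write_named_tsv <- function(x, path, key = "taxon_id", value = "value") {
  out <- data.frame(k = names(x), v = unname(x), stringsAsFactors = FALSE)
  names(out) <- c(key, value)
  fwrite(out, path, sep = "\t")
  invisible(path)
}
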