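# Fixtures built in code: tiny taxonomies, evidence-row builders, and random
# instances used across the unit and property tests.

# root -> genus G -> species A, B (the two-species/one-genus worked example)
tiny_tree <- function() {
  taxonomy_tree(data.frame(
    taxon_id = c("root", "G", "A", "B"),
    name = c("root", "Genus G", "Species A", "Species B"),
    rank = c("root", "genus", "species", "species"),
    parent_id = c("root", "root", "G", "G"),
    stringsAsFactors = FALSE))
}

# a single full seven-rank lineage root..species, with an optional strain
chain_tree <- function(strain = FALSE) {
  nodes <- data.frame(
    taxon_id = c("root", "p", "c", "o", "f", "g", "s"),
    name = c("root", "P", "C", "O", "F", "G", "S"),
    rank = canonical_ranks(),
    parent_id = c("root", "root", "p", "c", "o", "f", "g"),
    stringsAsFactors = FALSE)
  if (strain) {
    nodes <- rbind(nodes, data.frame(taxon_id = "st", name = "strain X",
                                     rank = "no-rank", parent_id = "s"))
  }
  taxonomy_tree(nodes)
}

# random rooted tree with n no-rank nodes under the root (shape-only; used
# for LCA oracle checks where ranks are irrelevant)
random_norank_tree <- function(n, seed) {
  set.seed(seed)
  ids <- c("root", paste0("n", seq_len(n)))
  parent <- c("root", vapply(seq_len(n), function(i)
    ids[sample.int(i, 1L)], character(1)))
  taxonomy_tree(data.frame(taxon_id = ids, name = ids,
                           rank = c("root", rep("no-rank", n)),
                           parent_id = parent, stringsAsFactors = FALSE))
}

make_peptides <- function(peptide, ms1_area = 1, spectral_count = 1L,
                          evalue = 1e-6, sample_id = "S1") {
  data.frame(peptide = peptide, evalue = evalue, ms1_area = ms1_area,
             spectral_count = as.integer(spectral_count),
             sample_id = sample_id, stringsAsFactors = FALSE)
}

make_proteins <- function(accession, taxon_id, evalue, peptides) {
  d <- data.frame(accession = accession, taxon_id = taxon_id,
                  evalue = evalue, stringsAsFactors = FALSE)
  d$peptides <- peptides
  d
}

make_annotations <- function(accession, go_id,
                             aspect = "biological_process") {
  data.frame(accession = accession, go_id = go_id, aspect = aspect,
             stringsAsFactors = FALSE)
}

# compatibility map assembled directly (bypasses protein plumbing) for
# EM-level tests: taxon_sets is a named list peptide -> taxa; terms is an
# optional named list peptide -> data.frame(taxon_id, go_id)
direct_compat <- function(taxon_sets, terms = NULL,
                          aspect = "biological_process") {
  pair_sets <- setNames(vector("list", 3),
                        c("biological_process", "molecular_function",
                          "cellular_component"))
  default_pairs <- lapply(taxon_sets, function(ts)
    data.frame(taxon_id = sort(ts), go_id = unannotated_term(),
               stringsAsFactors = FALSE))
  for (a in names(pair_sets)) pair_sets[[a]] <- default_pairs
  if (!is.null(terms)) pair_sets[[aspect]] <- terms
  structure(list(taxon_sets = lapply(taxon_sets, sort),
                 pair_sets = pair_sets),
            class = "compatibility_map")
}
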