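# Synthetic benchmark communities with known ground truth, emulating the
# mixture experiments the pipeline is evaluated on: 2-24 species combined at
# stated biomass ratios (defaults follow the 1:2:2:4 four-species mixture),
# peptides unique to a species plus peptides shared at higher ranks, and
# lognormal MS1 ion-area noise. Everything is deterministic given the seed.

#' Specification of a synthetic community
#'
#' @param biomass_ratios positive reals, one per species; normalized to the
#'   ground-truth biomass probabilities. Default `c(1, 2, 2, 4)`, the
#'   four-species benchmark mixture.
#' @param n_species number of species; defaults to
#'   `length(biomass_ratios)`.
#' @param proteins_per_species proteins simulated per species (default 10)
#' @param peptides_per_protein integer range `c(lo, hi)` of unique peptides
#'   per protein (default `c(5, 5)`, i.e. exactly 5)
#' @param terms_per_protein integer range of GO terms per protein per aspect
#'   (default `c(1, 3)`)
#' @param terms_pool_size per-aspect size of the GO-id pool (default 120)
#' @param sharing named numeric: fraction of the final peptide list shared
#'   at each rank (e.g. `c(genus = 0.2)`); fractions must sum to < 1, the
#'   remainder being species-unique peptides
#' @param noise_sigma lognormal sdlog of ion areas (default 0.5, a typical
#'   label-free intensity dispersion)
#' @param mu0 baseline meanlog of ion areas (default `log(1e6)`)
#' @param mean_extra_counts Poisson mean of spectral counts above 1
#'   (default 1)
#' @param seed integer seed controlling all randomness (default 1)
#' @return A `community_spec` list.
#' @export
community_spec <- function(biomass_ratios = c(1, 2, 2, 4),
                           n_species = length(biomass_ratios),
                           proteins_per_species = 10,
                           peptides_per_protein = c(5, 5),
                           terms_per_protein = c(1, 3),
                           terms_pool_size = 120,
                           sharing = c(genus = 0.2),
                           noise_sigma = 0.5,
                           mu0 = log(1e6),
                           mean_extra_counts = 1,
                           seed = 1) {
  stopifnot(all(biomass_ratios > 0), n_species == length(biomass_ratios),
            n_species >= 2, proteins_per_species >= 1,
            length(peptides_per_protein) == 2,
            peptides_per_protein[1] >= 1,
            peptides_per_protein[2] >= peptides_per_protein[1],
            noise_sigma >= 0, sum(sharing) < 1, all(sharing >= 0))
  if (length(sharing)) {
    stopifnot(all(names(sharing) %in% c("phylum", "class", "order",
                                        "family", "genus")))
  }
  structure(list(biomass_ratios = biomass_ratios, n_species = n_species,
                 proteins_per_species = proteins_per_species,
                 peptides_per_protein = peptides_per_protein,
                 terms_per_protein = terms_per_protein,
                 terms_pool_size = terms_pool_size,
                 sharing = sharing, noise_sigma = noise_sigma, mu0 = mu0,
                 mean_extra_counts = mean_extra_counts, seed = seed),
            class = "community_spec")
}

#' Default benchmark taxonomy for n species
#'
#' A seven-rank lineage: one phylum/class/order chain, genera holding two
#' species each, families holding two genera each, so that genus-, family-
#' and order-level peptide sharing are all expressible.
#'
#' @param n_species number of species (>= 2)
#' @return taxonomy_tree with species ids `s1..sn`.
#' @export
default_community_taxonomy <- function(n_species) {
  stopifnot(n_species >= 2)
  n_gen <- ceiling(n_species / 2)
  n_fam <- ceiling(n_gen / 2)
  rows <- list(
    data.frame(taxon_id = "root", name = "root", rank = "root",
               parent_id = "root"),
    data.frame(taxon_id = "p1", name = "Phylum 1", rank = "phylum",
               parent_id = "root"),
    data.frame(taxon_id = "c1", name = "Class 1", rank = "class",
               parent_id = "p1"),
    data.frame(taxon_id = "o1", name = "Order 1", rank = "order",
               parent_id = "c1"))
  for (f in seq_len(n_fam)) {
    rows[[length(rows) + 1L]] <- data.frame(
      taxon_id = paste0("f", f), name = paste("Family", f), rank = "family",
      parent_id = "o1")
  }
  for (g in seq_len(n_gen)) {
    rows[[length(rows) + 1L]] <- data.frame(
      taxon_id = paste0("g", g), name = paste("Genus", g), rank = "genus",
      parent_id = paste0("f", ceiling(g / 2)))
  }
  for (s in seq_len(n_species)) {
    rows[[length(rows) + 1L]] <- data.frame(
      taxon_id = paste0("s", s), name = paste("Species", s),
      rank = "species", parent_id = paste0("g", ceiling(s / 2)))
  }
  taxonomy_tree(do.call(rbind, rows))
}

# uniform integer in [lo, hi]; safe when lo == hi (sample() would otherwise
# treat a scalar as 1:n)
.rint <- function(lo, hi) {
  if (lo == hi) return(as.integer(lo))
  sample(seq.int(lo, hi), 1L)
}

.random_peptide <- function(n) {
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]
  body <- vapply(seq_len(n), function(i)
    paste(sample(aa, 11, replace = TRUE), collapse = ""), character(1))
  paste0(body, sample(c("K", "R"), n, replace = TRUE))
}

.unique_peptides <- function(n, existing = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    cand <- .random_peptide(n - length(out))
    cand <- setdiff(unique(cand), c(existing, out))
    out <- c(out, cand)
  }
  out
}

#' Generate a synthetic community
#'
#' Builds the taxonomy, protein records with synthetic tryptic-like peptide
#' tokens, per-aspect GO annotations, and the ground truth (normalized
#' biomass, per-taxon term sets, sharing structure). If the species-unique
#' peptide count is `U` and the sharing fractions sum to `f`, then
#' `round(f_r * U / (1 - f))` additional peptides are shared at rank `r`
#' (inserted into one protein of every species in a randomly chosen group at
#' that rank), so sharing fractions refer to the final peptide list.
#'
#' @param spec a `community_spec`
#' @return `synthetic_community`: list with `tree`, `proteins` (data.frame
#'   with list-column `peptides`), `annotations`, `peptide_table`
#'   (peptide -> source species and sharing rank), `ground_truth`, `spec`.
#' @export
generate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(spec$seed)
  n <- spec$n_species
  species <- paste0("s", seq_len(n))
  tree <- default_community_taxonomy(n)
  p_true <- spec$biomass_ratios / sum(spec$biomass_ratios)
  names(p_true) <- species

  # species-unique peptides, attached to proteins
  prot_rows <- list()
  pep_rows <- list()
  all_peps <- character(0)
  for (s in species) {
    for (j in seq_len(spec$proteins_per_species)) {
      k <- .rint(spec$peptides_per_protein[1], spec$peptides_per_protein[2])
      peps <- .unique_peptides(k, all_peps)
      all_peps <- c(all_peps, peps)
      acc <- sprintf("%s_P%03d", s, j)
      prot_rows[[acc]] <- data.frame(accession = acc, taxon_id = s,
                                     evalue = 10^runif(1, -12, -5),
                                     stringsAsFactors = FALSE)
      prot_rows[[acc]]$peptides <- list(peps)
      pep_rows[[length(pep_rows) + 1L]] <- data.frame(
        peptide = peps, shared_rank = "species", stringsAsFactors = FALSE)
      pep_rows[[length(pep_rows)]]$species <- rep(list(s), length(peps))
    }
  }
  proteins <- do.call(rbind, prot_rows)
  rownames(proteins) <- NULL
  peptide_table <- do.call(rbind, pep_rows)
  n_unique <- nrow(peptide_table)

  # peptides shared at higher ranks: each goes into one protein of every
  # species of a randomly chosen multi-species group at that rank
  f_total <- sum(spec$sharing)
  for (r in names(spec$sharing)) {
    n_r <- round(spec$sharing[[r]] * n_unique / (1 - f_total))
    if (n_r == 0) next
    anc <- lineage_at(tree, species, r)
    groups <- split(species, anc)
    groups <- groups[lengths(groups) >= 2L]
    if (!length(groups)) {
      stop("no group with >= 2 species at rank '", r,
           "'; cannot generate shared peptides")
    }
    peps <- .unique_peptides(n_r, peptide_table$peptide)
    pick <- sample(length(groups), n_r, replace = TRUE)
    for (i in seq_len(n_r)) {
      members <- groups[[pick[i]]]
      for (s in members) {
        cand <- which(proteins$taxon_id == s)
        j <- cand[sample.int(length(cand), 1L)]
        proteins$peptides[[j]] <- c(proteins$peptides[[j]], peps[i])
      }
      row <- data.frame(peptide = peps[i], shared_rank = r,
                        stringsAsFactors = FALSE)
      row$species <- list(members)
      peptide_table <- rbind(peptide_table, row)
    }
  }

  # per-aspect GO annotations from aspect-specific pools
  pool_base <- c(biological_process = 1000000L,
                 molecular_function = 3000000L,
                 cellular_component = 5000000L)
  ann <- list()
  for (aspect in GO_ASPECTS) {
    pool <- sprintf("GO:%07d", pool_base[[aspect]] +
                      seq_len(spec$terms_pool_size))
    for (j in seq_len(nrow(proteins))) {
      k <- .rint(spec$terms_per_protein[1], spec$terms_per_protein[2])
      ann[[length(ann) + 1L]] <- data.frame(
        accession = proteins$accession[j],
        go_id = sample(pool, k), aspect = aspect, stringsAsFactors = FALSE)
    }
  }
  annotations <- do.call(rbind, ann)
  rownames(annotations) <- NULL

  term_sets <- lapply(setNames(species, species), function(s) {
    accs <- proteins$accession[proteins$taxon_id == s]
    d <- unique(annotations[annotations$accession %in% accs,
                            c("go_id", "aspect")])
    d[order(d$aspect, d$go_id), , drop = FALSE]
  })
  shared_counts <- table(peptide_table$shared_rank)
  ground_truth <- list(
    biomass = as.list(p_true),
    term_sets = lapply(term_sets, function(d)
      split(d$go_id, d$aspect)),
    sharing = as.list(shared_counts))
  structure(list(tree = tree, proteins = proteins,
                 annotations = annotations, peptide_table = peptide_table,
                 ground_truth = ground_truth, spec = spec),
            class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat("<synthetic_community> ", x$spec$n_species, " species, ",
      nrow(x$proteins), " proteins, ", nrow(x$peptide_table),
      " peptides\n", sep = "")
  invisible(x)
}

#' Simulate one MS sample from a community
#'
#' Each peptide's MS1 ion area is lognormal around its source species'
#' biomass share, `LogNormal(mu0 + log p(s), sigma)`, summed over the
#' sharing species for shared peptides; at `sigma = 0` the per-species total
#' area of unique peptides is exactly proportional to the biomass ratios.
#' E-values are drawn at or below 1e-4 (all peptides are "true") and
#' spectral counts are `1 + Poisson(mean_extra_counts)`.
#'
#' @param community a `synthetic_community`
#' @param sample_id sample label (default `"S1"`)
#' @param seed integer seed for this sample; default `spec$seed + 1`
#' @return data.frame of peptide evidence (the `peptides.tsv` schema).
#' @export
generate_sample <- function(community, sample_id = "S1",
                            seed = community$spec$seed + 1L) {
  stopifnot(inherits(community, "synthetic_community"))
  set.seed(seed)
  spec <- community$spec
  pt <- community$peptide_table
  p_true <- unlist(community$ground_truth$biomass)
  area <- vapply(seq_len(nrow(pt)), function(i) {
    srcs <- pt$species[[i]]
    sum(vapply(srcs, function(s)
      rlnorm(1, meanlog = spec$mu0 + log(p_true[[s]]),
             sdlog = spec$noise_sigma), numeric(1)))
  }, numeric(1))
  data.frame(peptide = pt$peptide,
             evalue = 10^runif(nrow(pt), -10, -4),
             ms1_area = area,
             spectral_count = 1L + rpois(nrow(pt), spec$mean_extra_counts),
             sample_id = sample_id, stringsAsFactors = FALSE)
}

#' Write a community fixture directory
#'
#' Emits `lineage.tsv`, `proteins.tsv`, `annotations.tsv` and
#' `ground_truth.json` into `dir`.
#'
#' @param community a `synthetic_community`
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_lineage_tsv(community$tree, file.path(dir, "lineage.tsv"))
  write_proteins(community$proteins, file.path(dir, "proteins.tsv"))
  write_annotations(community$annotations, file.path(dir, "annotations.tsv"))
  jsonlite::write_json(community$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
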