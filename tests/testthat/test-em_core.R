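test_that("build_compatibility produces the documented T_i and A_i sets", {
  prot <- make_proteins(c("PA", "PB"), c("A", "B"), c(1e-8, 1e-7),
                        list(c("pep1", "pep2"), c("pep1")))
  ann <- make_annotations(c("PA", "PA"), c("GO:0000001", "GO:0000002"))
  compat <- build_compatibility(make_peptides(c("pep1", "pep2")), prot, ann,
                                c("A", "B"))
  expect_equal(compat$taxon_sets$pep1, c("A", "B"))
  expect_equal(compat$taxon_sets$pep2, "A")
  bp1 <- compat$pair_sets$biological_process$pep1
  expect_equal(bp1$go_id[bp1$taxon_id == "A"], c("GO:0000001", "GO:0000002"))
  expect_equal(bp1$go_id[bp1$taxon_id == "B"], unannotated_term())
  # unmapped peptides are dropped with a warning
  expect_warning(
    c2 <- build_compatibility(make_peptides(c("pep1", "ghost")), prot, ann,
                              c("A", "B")),
    "dropped")
  expect_false("ghost" %in% names(c2$taxon_sets))
})

test_that("build_compatibility matches a direct set-construction oracle", {
  set.seed(51)
  for (rep in 1:5) {
    npep <- 12
    peps <- sprintf("pep%02d", 1:npep)
    nprot <- 8
    prot <- make_proteins(sprintf("P%02d", 1:nprot),
                          sample(c("A", "B", "C"), nprot, replace = TRUE),
                          runif(nprot, 1e-9, 1e-3),
                          lapply(1:nprot, function(i)
                            sample(peps, sample(2:5, 1))))
    ann <- make_annotations(
      sample(prot$accession, 12, replace = TRUE),
      sprintf("GO:%07d", sample(1:6, 12, replace = TRUE)),
      "molecular_function")
    suppressWarnings(
      compat <- build_compatibility(make_peptides(peps), prot, ann,
                                    c("A", "B")))
    kept <- prot[prot$taxon_id %in% c("A", "B"), ]
    for (p in names(compat$taxon_sets)) {
      has <- vapply(kept$peptides, function(ps) p %in% ps, logical(1))
      expect_equal(compat$taxon_sets[[p]], sort(unique(kept$taxon_id[has])))
      d <- compat$pair_sets$molecular_function[[p]]
      for (t in unique(kept$taxon_id[has])) {
        accs <- kept$accession[has & kept$taxon_id == t]
        want <- sort(unique(ann$go_id[ann$accession %in% accs]))
        if (!length(want)) want <- unannotated_term()
        expect_equal(d$go_id[d$taxon_id == t], want)
      }
    }
  }
})

test_that("stage-1 EM handles degenerate and symmetric instances", {
  # single taxon: p = 1
  compat1 <- direct_compat(list(pep1 = "A", pep2 = "A"))
  bm <- estimate_biomass(make_peptides(c("pep1", "pep2"), ms1_area = c(3, 7)),
                         compat1)
  expect_equal(unname(bm$probabilities), 1)
  # all peptides shared, equal areas: symmetry gives 0.5 / 0.5
  compat2 <- direct_compat(list(pep1 = c("A", "B"), pep2 = c("A", "B")))
  bm2 <- estimate_biomass(make_peptides(c("pep1", "pep2")), compat2)
  expect_equal(unname(bm2$probabilities), c(0.5, 0.5))
  # all-zero areas ask for the spectral-count fallback
  expect_error(estimate_biomass(make_peptides("pep1", ms1_area = 0),
                                compat1), "count")
  bm3 <- estimate_biomass(make_peptides("pep1", ms1_area = 0), compat1,
                          weights = "count")
  expect_equal(unname(bm3$probabilities), 1)
})

test_that("stage-1 fixed point matches the grid-search likelihood oracle", {
  # unique-evidence areas 99 and 1 plus one shared peptide of area 1
  taxon_sets <- list(pepA = "A", pepB = "B", pepS = c("A", "B"))
  peps <- make_peptides(c("pepA", "pepB", "pepS"), ms1_area = c(99, 1, 1))
  bm <- estimate_biomass(peps, direct_compat(taxon_sets))
  want <- oracle_grid_stage1_2tax(taxon_sets, u = c(99, 1, 1),
                                  taxa = c("A", "B"))
  expect_equal(bm$probabilities, want, tolerance = 1e-4)
  # three-taxon instances against the nested-grid oracle
  set.seed(61)
  for (rep in 1:3) {
    sets <- lapply(1:8, function(i)
      sort(sample(c("A", "B", "C"), sample(1:3, 1))))
    names(sets) <- sprintf("pep%d", 1:8)
    u <- round(runif(8, 0.5, 20), 2)
    bm3 <- estimate_biomass(
      make_peptides(names(sets), ms1_area = u),
      direct_compat(sets))
    want3 <- oracle_grid_stage1_3tax(sets[sort(names(sets))],
                                     u[order(names(sets))],
                                     taxa = c("A", "B", "C"))
    expect_equal(bm3$probabilities[names(want3)], want3, tolerance = 1e-4)
  }
})

test_that("stage-1 log-likelihood is non-decreasing", {
  set.seed(71)
  for (rep in 1:10) {
    n <- sample(5:15, 1)
    sets <- lapply(1:n, function(i)
      sort(sample(c("A", "B", "C", "D"), sample(1:3, 1))))
    names(sets) <- sprintf("pep%02d", 1:n)
    bm <- estimate_biomass(make_peptides(names(sets),
                                         ms1_area = runif(n, 0.1, 10)),
                           direct_compat(sets))
    expect_true(all(diff(bm$loglik) >= -1e-9))
    expect_equal(sum(bm$probabilities), 1, tolerance = 1e-12)
  }
})

test_that("stage-2 reduces to direct proportions without sharing", {
  # one taxon, one term: joint = p = 1
  compat <- direct_compat(
    list(pep1 = "A"),
    terms = list(pep1 = data.frame(taxon_id = "A", go_id = "GO:0000001")))
  peps <- make_peptides("pep1")
  bm <- estimate_biomass(peps, compat)
  fa <- estimate_function_abundance(peps, compat, bm, "biological_process")
  expect_equal(fa$joint$abundance, 1)
  # two terms on disjoint peptides with areas 3 and 1: joint = 0.75 / 0.25
  compat2 <- direct_compat(
    list(pep1 = "A", pep2 = "A"),
    terms = list(
      pep1 = data.frame(taxon_id = "A", go_id = "GO:0000001"),
      pep2 = data.frame(taxon_id = "A", go_id = "GO:0000002")))
  peps2 <- make_peptides(c("pep1", "pep2"), ms1_area = c(3, 1))
  bm2 <- estimate_biomass(peps2, compat2)
  fa2 <- estimate_function_abundance(peps2, compat2, bm2,
                                     "biological_process")
  expect_equal(setNames(fa2$joint$abundance, fa2$joint$go_id),
               c("GO:0000001" = 0.75, "GO:0000002" = 0.25))
})

test_that("stage-2 fixed point matches the constrained grid oracle", {
  set.seed(81)
  for (rep in 1:3) {
    # 2 taxa x 2 terms with overlapping pair sets
    mk_pairs <- function(taxa, terms) {
      do.call(rbind, lapply(taxa, function(t)
        data.frame(taxon_id = t, go_id = terms, stringsAsFactors = FALSE)))
    }
    pair_sets <- list(
      pep1 = mk_pairs("t1", c("k1", "k2")),
      pep2 = mk_pairs(c("t1", "t2"), "k1"),
      pep3 = mk_pairs("t2", c("k1", "k2")),
      pep4 = mk_pairs(c("t1", "t2"), c("k1", "k2")))
    u <- round(runif(4, 0.5, 10), 2)
    taxon_sets <- lapply(pair_sets, function(d) unique(d$taxon_id))
    compat <- direct_compat(taxon_sets, terms = pair_sets)
    peps <- make_peptides(names(pair_sets), ms1_area = u)
    bm <- estimate_biomass(peps, compat)
    fa <- estimate_function_abundance(peps, compat, bm,
                                      "biological_process")
    p <- bm$probabilities
    names(p) <- c("t1", "t2")
    best <- oracle_grid_stage2(p, pair_sets, u)
    got <- setNames(fa$joint$abundance,
                    paste(fa$joint$taxon_id, fa$joint$go_id))
    expect_equal(unname(got["t1 k1"]), unname(p["t1"] * best["t1"]),
                 tolerance = 1e-4)
    expect_equal(unname(got["t2 k1"]), unname(p["t2"] * best["t2"]),
                 tolerance = 1e-4)
    # biomass constraint holds exactly
    sums <- vapply(split(fa$joint$abundance, fa$joint$taxon_id), sum,
                   numeric(1))
    expect_equal(sums, p[names(sums)], tolerance = 1e-9)
  }
})

test_that("taxa without peptides for an aspect sink to UNANNOTATED", {
  compat <- direct_compat(
    list(pep1 = "A"),
    terms = list(pep1 = data.frame(taxon_id = "A", go_id = "GO:0000001")))
  peps <- make_peptides("pep1")
  bm <- estimate_biomass(peps, compat)
  # molecular_function has only the default UNANNOTATED pairs
  fa <- estimate_function_abundance(peps, compat, bm, "molecular_function")
  expect_equal(fa$joint$go_id, unannotated_term())
  expect_equal(fa$joint$abundance, 1)
})

test_that("aggregation sums descendants and keeps GO ids constant", {
  tree <- tiny_tree()
  fa <- structure(list(
    aspect = "biological_process", level = "species",
    joint = data.frame(taxon_id = c("A", "A", "B"),
                       go_id = c("GO:0000001", "GO:0000002", "GO:0000001"),
                       abundance = c(0.3, 0.2, 0.5)),
    biomass = c(A = 0.5, B = 0.5), iterations = 1L, converged = TRUE),
    class = "function_abundance")
  gen <- aggregate_to_level(fa, tree, "genus")
  expect_equal(gen$joint$taxon_id, c("G", "G"))
  expect_equal(gen$joint$abundance[gen$joint$go_id == "GO:0000001"], 0.8)
  expect_equal(unname(gen$biomass), 1)
  # no genus/family/etc above: everything lands on the root
  rt <- aggregate_to_level(fa, tree, "family")
  expect_equal(unique(rt$joint$taxon_id), "root")
  expect_setequal(unique(rt$joint$go_id), unique(fa$joint$go_id))
})

test_that("aggregation matches a groupby-ancestor oracle on random tables", {
  set.seed(91)
  comm <- generate_community(community_spec(n_species = 6,
                                            biomass_ratios = rep(1, 6),
                                            proteins_per_species = 3,
                                            seed = 91))
  tree <- comm$tree
  species <- paste0("s", 1:6)
  for (rep in 1:5) {
    k <- 20
    jt <- data.frame(taxon_id = sample(species, k, replace = TRUE),
                     go_id = sprintf("GO:%07d", sample(1:8, k,
                                                       replace = TRUE)),
                     abundance = runif(k))
    bm <- runif(6)
    bm <- setNames(bm / sum(bm), species)
    fa <- structure(list(aspect = "molecular_function", level = "species",
                         joint = jt, biomass = bm, iterations = 1L,
                         converged = TRUE), class = "function_abundance")
    for (lv in canonical_ranks()) {
      ag <- aggregate_to_level(fa, tree, lv)
      anc <- lineage_at(tree, jt$taxon_id, lv)
      anc[is.na(anc)] <- tree$root
      want <- tapply(jt$abundance, paste(anc, jt$go_id, sep = "|"), sum)
      got <- setNames(ag$joint$abundance,
                      paste(ag$joint$taxon_id, ag$joint$go_id, sep = "|"))
      expect_setequal(names(got), names(want))
      expect_equal(unname(got[names(want)]), as.numeric(want))
      expect_equal(sum(ag$biomass), 1, tolerance = 1e-12)
      expect_setequal(unique(ag$joint$go_id), unique(jt$go_id))
    }
  }
})

test_that("shuffling peptide rows leaves all outputs bit-identical", {
  comm <- generate_community(community_spec(seed = 5))
  peps <- generate_sample(comm, seed = 6)
  compat <- build_compatibility(peps, comm$proteins, comm$annotations,
                                paste0("s", 1:4))
  bm1 <- estimate_biomass(peps, compat)
  set.seed(7)
  shuffled <- peps[sample(nrow(peps)), ]
  bm2 <- estimate_biomass(shuffled, compat)
  expect_identical(bm1$probabilities, bm2$probabilities)
  fa1 <- estimate_function_abundance(peps, compat, bm1,
                                     "molecular_function")
  fa2 <- estimate_function_abundance(shuffled, compat, bm2,
                                     "molecular_function")
  expect_identical(fa1$joint, fa2$joint)
})
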