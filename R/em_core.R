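# Two-stage biomass-constrained EM.
#
# Stage 1 estimates per-taxon relative biomass p(t) from the MS1
# extracted-ion-chromatogram areas of confidently identified peptides, a
# mixture model in which a peptide shared by several taxa has its evidence
# apportioned by the current weights. Stage 2, with p(t) held fixed,
# estimates the conditional term weights phi(k|t) so that the joint
# abundance p(k|t)p(t) of every GO term sums, per taxon, exactly to that
# taxon's biomass. Species-level output is then aggregated up the lineage.
#
# Both stages are deterministic: initialization is uniform and peptide rows
# are re-ordered canonically before any accumulation, so shuffling the input
# leaves all outputs bit-identical.

#' Reserved sink term for unannotated evidence
#'
#' Peptide-taxon pairs with no annotated GO term map to this reserved id so
#' that mass conservation (sum of joint abundances equals the taxon biomass)
#' holds even when proteins carry no annotation.
#'
#' @return The reserved term id, `"UNANNOTATED"`.
#' @export
unannotated_term <- function() "UNANNOTATED"

# canonical row order: makes every downstream accumulation independent of
# input row permutation
.canonical_peptide_order <- function(peptides) {
  order(peptides$peptide, peptides$sample_id, peptides$evalue,
        peptides$ms1_area, peptides$spectral_count)
}

#' Map peptides to compatible taxa and (taxon, GO-term) pairs
#'
#' For each confidently identified peptide sequence, `T_i` is the set of
#' identified taxa owning a retained protein that contains the peptide; per
#' GO aspect, `A_i` is the set of (taxon, term) pairs with the term annotated
#' to a retained protein of that taxon containing the peptide. A
#' peptide-taxon pair with no annotated term for an aspect maps to the
#' reserved `(taxon, UNANNOTATED)` pair. Peptides matching no retained
#' protein are dropped with a warning.
#'
#' @param peptides data.frame of peptide evidence (see [read_peptides()])
#' @param proteins data.frame of retained protein records (accession,
#'   taxon_id, evalue, list-column peptides)
#' @param annotations data.frame (accession, go_id, aspect)
#' @param identified_taxa character vector of identified taxon ids; proteins
#'   outside it are ignored
#' @return `compatibility_map`: list with `taxon_sets` (peptide ->
#'   sorted taxa) and `pair_sets` (aspect -> peptide -> data.frame(taxon_id,
#'   go_id)).
#' @export
build_compatibility <- function(peptides, proteins, annotations,
                                identified_taxa) {
  proteins <- proteins[proteins$taxon_id %in% as.character(identified_taxa), ,
                       drop = FALSE]
  seqs <- sort(unique(peptides$peptide))
  # peptide -> indices of retained proteins containing it
  prot_of <- vector("list", length(seqs))
  names(prot_of) <- seqs
  if (nrow(proteins)) {
    for (j in seq_len(nrow(proteins))) {
      for (p in intersect(unique(proteins$peptides[[j]]), seqs)) {
        prot_of[[p]] <- c(prot_of[[p]], j)
      }
    }
  }
  empty <- vapply(prot_of, is.null, logical(1))
  if (any(empty)) {
    warning(sum(empty), " peptide(s) matched no retained protein of an ",
            "identified taxon and were dropped")
  }
  seqs <- seqs[!empty]
  prot_of <- prot_of[!empty]
  ann_by_acc <- split(annotations[, c("go_id", "aspect")],
                      annotations$accession)
  taxon_sets <- lapply(prot_of, function(js)
    sort(unique(proteins$taxon_id[js])))
  pair_sets <- lapply(GO_ASPECTS, function(aspect) {
    per_pep <- lapply(seq_along(seqs), function(i) {
      js <- prot_of[[i]]
      rows <- lapply(sort(unique(proteins$taxon_id[js])), function(t) {
        accs <- proteins$accession[js][proteins$taxon_id[js] == t]
        terms <- unique(unlist(lapply(ann_by_acc[accs], function(a)
          a$go_id[a$aspect == aspect]), use.names = FALSE))
        if (is.null(terms) || !length(terms)) terms <- unannotated_term()
        data.frame(taxon_id = t, go_id = sort(terms),
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    names(per_pep) <- seqs
    per_pep
  })
  names(pair_sets) <- GO_ASPECTS
  structure(list(taxon_sets = taxon_sets, pair_sets = pair_sets),
            class = "compatibility_map")
}

#' @export
print.compatibility_map <- function(x, ...) {
  cat("<compatibility_map> ", length(x$taxon_sets), " peptides, ",
      length(unique(unlist(x$taxon_sets, use.names = FALSE))), " taxa\n",
      sep = "")
  invisible(x)
}

# aggregate evidence weight x_i * c_i per unique peptide sequence, in
# canonical order
.peptide_weights <- function(peptides, compat, weights) {
  keep <- peptides$peptide %in% names(compat$taxon_sets)
  if (!all(keep)) {
    warning(sum(!keep), " peptide row(s) absent from the compatibility map ",
            "were dropped")
    peptides <- peptides[keep, , drop = FALSE]
  }
  peptides <- peptides[.canonical_peptide_order(peptides), , drop = FALSE]
  u_row <- switch(weights,
                  area = peptides$ms1_area * peptides$spectral_count,
                  count = as.numeric(peptides$spectral_count))
  seqs <- sort(unique(peptides$peptide))
  u <- vapply(split(u_row, factor(peptides$peptide, levels = seqs)),
              sum, numeric(1))
  list(seqs = seqs, u = u)
}

#' Stage-1 EM: per-taxon relative biomass
#'
#' Mixture-weight EM over the identified taxa. With evidence weight
#' `u_i = ms1_area * spectral_count` for peptide `i` and compatibility sets
#' `T_i`, the E-step apportions `r_it = w_t / sum(w_t', t' in T_i)` and the
#' M-step sets `w_t <- sum_i u_i r_it / sum_i u_i`. The weighted
#' log-likelihood `sum_i u_i log(sum_{t in T_i} w_t)` is non-decreasing
#' across iterations; iteration stops when `max_t |delta w_t| < tol`.
#'
#' @param peptides peptide evidence data.frame
#' @param compat a `compatibility_map`
#' @param tol convergence tolerance on the weight change (default 1e-10)
#' @param max_iter iteration cap (default 2000)
#' @param init `"uniform"` (default) or `"area-weighted"` (weights seeded
#'   from equal-split evidence)
#' @param weights `"area"` (default, `ms1_area * spectral_count`) or
#'   `"count"` (spectral counts only, for area-free inputs)
#' @return `biomass_estimate`: list with `probabilities` (named, sums to 1),
#'   `iterations`, `converged`, and the `loglik` trace.
#' @export
estimate_biomass <- function(peptides, compat, tol = 1e-10, max_iter = 2000,
                             init = c("uniform", "area-weighted"),
                             weights = c("area", "count")) {
  init <- match.arg(init)
  weights <- match.arg(weights)
  if (weights == "area" && all(peptides$ms1_area == 0)) {
    stop("all MS1 areas are zero; rerun with weights = \"count\" to use ",
         "spectral counts as evidence")
  }
  pw <- .peptide_weights(peptides, compat, weights)
  seqs <- pw$seqs
  u <- pw$u
  if (!length(seqs)) stop("no peptides with compatible taxa")
  if (sum(u) <= 0) stop("total evidence weight is zero")
  taxa <- sort(unique(unlist(compat$taxon_sets[seqs], use.names = FALSE)))
  ti <- lapply(compat$taxon_sets[seqs], match, table = taxa)
  M <- Matrix::sparseMatrix(
    i = rep(seq_along(seqs), lengths(ti)),
    j = unlist(ti, use.names = FALSE),
    x = 1, dims = c(length(seqs), length(taxa)))
  w <- switch(init,
    uniform = rep(1 / length(taxa), length(taxa)),
    `area-weighted` = {
      w0 <- as.vector(Matrix::crossprod(M, u / Matrix::rowSums(M)))
      w0 / sum(w0)
    })
  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    denom <- as.vector(M %*% w)
    loglik <- c(loglik, sum(u * log(denom)))
    Z <- Matrix::Diagonal(x = 1 / denom) %*% M %*% Matrix::Diagonal(x = w)
    w_new <- as.vector(Matrix::crossprod(Z, u)) / sum(u)
    delta <- max(abs(w_new - w))
    w <- w_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("stage-1 EM did not converge in ", max_iter, " iterations")
  }
  structure(list(probabilities = setNames(w, taxa), iterations = iter,
                 converged = converged, loglik = loglik),
            class = "biomass_estimate")
}

#' @export
print.biomass_estimate <- function(x, ...) {
  cat("<biomass_estimate> ", length(x$probabilities), " taxa, ",
      x$iterations, " iterations, converged = ", x$converged, "\n", sep = "")
  print(round(x$probabilities, 6))
  invisible(x)
}

#' Stage-2 EM: joint GO-term abundances under the biomass constraint
#'
#' With the stage-1 biomass `p(t)` held fixed, estimates per-taxon
#' conditional term weights `phi(k|t)` by EM over the peptide pair sets
#' `A_i`: responsibilities `z_i(t,k) = p(t)phi(k|t) / sum over A_i`, then
#' `phi(k|t) <- S_tk / sum_k' S_tk'` with `S_tk = sum_i u_i z_i(t,k)`.
#' The returned joint abundance is `p(t) phi(k|t)`, so
#' `sum_k joint(t,k) = p(t)` holds by construction. A biomass taxon with no
#' compatible peptide for the aspect has its whole mass assigned to the
#' reserved `(t, UNANNOTATED)` pair.
#'
#' @param peptides peptide evidence data.frame
#' @param compat a `compatibility_map`
#' @param biomass a `biomass_estimate` covering all taxa in `compat`
#' @param aspect one of `"biological_process"`, `"molecular_function"`,
#'   `"cellular_component"`
#' @param tol convergence tolerance on the joint-abundance change
#' @param max_iter iteration cap
#' @param weights evidence weighting, as in [estimate_biomass()]
#' @return `function_abundance`: list with `aspect`, `level` (`"species"`),
#'   `joint` data.frame (taxon_id, go_id, abundance), `biomass` (named
#'   vector at this level), `iterations`, `converged`.
#' @export
estimate_function_abundance <- function(peptides, compat, biomass, aspect,
                                        tol = 1e-10, max_iter = 2000,
                                        weights = c("area", "count")) {
  aspect <- match.arg(aspect, GO_ASPECTS)
  weights <- match.arg(weights)
  stopifnot(inherits(biomass, "biomass_estimate"))
  p <- biomass$probabilities
  pw <- .peptide_weights(peptides, compat, weights)
  seqs <- pw$seqs
  u <- pw$u
  pairs_per_pep <- compat$pair_sets[[aspect]][seqs]
  all_pairs <- unique(do.call(rbind, unname(pairs_per_pep)))
  all_pairs <- all_pairs[order(all_pairs$taxon_id, all_pairs$go_id), ,
                         drop = FALSE]
  # taxa with biomass but no compatible peptide for this aspect: all mass
  # goes to the unannotated sink
  orphan_taxa <- setdiff(names(p), all_pairs$taxon_id)
  if (is.null(all_pairs) || !nrow(all_pairs)) {
    joint <- data.frame(taxon_id = names(p), go_id = unannotated_term(),
                        abundance = unname(p), stringsAsFactors = FALSE)
    return(structure(list(aspect = aspect, level = "species", joint = joint,
                          biomass = p, iterations = 0L, converged = TRUE),
                     class = "function_abundance"))
  }
  pair_key <- paste(all_pairs$taxon_id, all_pairs$go_id, sep = "\r")
  npair <- nrow(all_pairs)
  pair_tax <- match(all_pairs$taxon_id, names(p))
  if (anyNA(pair_tax)) {
    stop("compatibility map references taxa absent from the biomass estimate")
  }
  idx <- lapply(pairs_per_pep, function(d)
    match(paste(d$taxon_id, d$go_id, sep = "\r"), pair_key))
  M <- Matrix::sparseMatrix(
    i = rep(seq_along(seqs), lengths(idx)),
    j = unlist(idx, use.names = FALSE),
    x = 1, dims = c(length(seqs), npair))
  p_pair <- unname(p[pair_tax])
  tax_fac <- factor(pair_tax, levels = seq_along(p))
  n_terms <- as.vector(table(tax_fac))[pair_tax]
  phi <- 1 / n_terms                      # uniform over each taxon's terms
  theta <- p_pair * phi
  joint_prev <- theta
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    denom <- as.vector(M %*% theta)
    ok <- denom > 0
    Z <- Matrix::Diagonal(x = ifelse(ok, 1 / denom, 0)) %*% M %*%
      Matrix::Diagonal(x = theta)
    S <- as.vector(Matrix::crossprod(Z, u))
    tot <- vapply(split(S, tax_fac), sum, numeric(1))[pair_tax]
    phi <- ifelse(tot > 0, S / tot, phi)
    theta <- p_pair * phi
    delta <- max(abs(theta - joint_prev))
    joint_prev <- theta
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("stage-2 EM did not converge in ", max_iter, " iterations")
  }
  joint <- data.frame(taxon_id = all_pairs$taxon_id, go_id = all_pairs$go_id,
                      abundance = theta, stringsAsFactors = FALSE)
  if (length(orphan_taxa)) {
    joint <- rbind(joint,
                   data.frame(taxon_id = orphan_taxa,
                              go_id = unannotated_term(),
                              abundance = unname(p[orphan_taxa]),
                              stringsAsFactors = FALSE))
    joint <- joint[order(joint$taxon_id, joint$go_id), , drop = FALSE]
  }
  rownames(joint) <- NULL
  structure(list(aspect = aspect, level = "species", joint = joint,
                 biomass = p, iterations = iter, converged = converged),
            class = "function_abundance")
}

#' @export
print.function_abundance <- function(x, ...) {
  cat("<function_abundance> aspect = ", x$aspect, ", level = ", x$level,
      ", ", nrow(x$joint), " (taxon, term) rows\n", sep = "")
  invisible(x)
}

#' Aggregate a species-level abundance table to a taxonomic level
#'
#' Each species is projected to its ancestor at `level` via [lineage_at()]
#' (species lacking an ancestor at that rank aggregate to the root node);
#' joint abundances and biomass are summed within each ancestor. Aggregation
#' preserves the set of unique GO ids and total mass.
#'
#' @param table species-level `function_abundance`
#' @param tree taxonomy_tree
#' @param level target rank, one of [canonical_ranks()]
#' @return A `function_abundance` at the requested level.
#' @export
aggregate_to_level <- function(table, tree, level) {
  stopifnot(inherits(table, "function_abundance"))
  if (table$level != "species") {
    stop("aggregate_to_level expects a species-level table")
  }
  level <- match.arg(level, canonical_ranks())
  species <- sort(unique(c(table$joint$taxon_id, names(table$biomass))))
  anc <- lineage_at(tree, species, level)
  anc[is.na(anc)] <- tree$root
  anc_of <- setNames(anc, species)
  jt <- table$joint
  jt$taxon_id <- unname(anc_of[jt$taxon_id])
  agg <- aggregate(abundance ~ taxon_id + go_id, data = jt, FUN = sum)
  agg <- agg[order(agg$taxon_id, agg$go_id), c("taxon_id", "go_id",
                                               "abundance")]
  rownames(agg) <- NULL
  bm <- vapply(split(unname(table$biomass),
                     unname(anc_of[names(table$biomass)])), sum, numeric(1))
  structure(list(aspect = table$aspect, level = level, joint = agg,
                 biomass = bm[sort(names(bm))], iterations = table$iterations,
                 converged = table$converged),
            class = "function_abundance")
}

#' Aggregate a species-level table to every canonical level
#'
#' @param table species-level `function_abundance`
#' @param tree taxonomy_tree
#' @return Named list of `function_abundance` objects, one per rank in
#'   [canonical_ranks()].
#' @export
abundance_all_levels <- function(table, tree) {
  out <- lapply(canonical_ranks(), function(lv)
    aggregate_to_level(table, tree, lv))
  setNames(out, canonical_ranks())
}
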