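# Independent oracles: brute-force or enumeration implementations kept
# deliberately separate from the package's own code paths.

# LCA as the deepest element of the intersection of root-paths
oracle_lca <- function(tree, taxa) {
  paths <- lapply(taxa, function(t) ancestors(tree, t))  # self..root
  common <- Reduce(intersect, paths)
  # ancestors() returns deepest-first, and intersect keeps first-arg order
  common[[1L]]
}

# exhaustive scan over every rank r for the largest prefix with E_r/r <= t
oracle_pfd_prefix <- function(evalues, target) {
  e <- sort(evalues)
  best <- 0L
  for (r in seq_along(e)) {
    if (e[r] / r <= target) best <- r
  }
  if (best == 0L) numeric(0) else e[seq_len(best)]
}

# connected components of the pairwise overlap predicate via boolean
# transitive closure of the adjacency matrix
oracle_components <- function(pepsets, threshold) {
  n <- length(pepsets)
  adj <- diag(TRUE, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      ov <- length(intersect(pepsets[[a]], pepsets[[b]])) /
        min(length(pepsets[[a]]), length(pepsets[[b]]))
      if (ov >= threshold) adj[a, b] <- TRUE
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      k <- k + 1L
      comp[adj[i, ]] <- k
    }
  }
  comp
}

# stage-1 likelihood for weights w over taxa given peptide taxon sets and
# evidence weights u
stage1_loglik <- function(w, taxon_sets, u, taxa) {
  sum(u * log(vapply(taxon_sets, function(ts)
    sum(w[match(ts, taxa)]), numeric(1))))
}

# grid-search maximizer of the 2-taxon stage-1 likelihood, step 1e-5
oracle_grid_stage1_2tax <- function(taxon_sets, u, taxa) {
  stopifnot(length(taxa) == 2)
  grid <- seq(0, 1, by = 1e-5)
  ll <- vapply(grid, function(a)
    stage1_loglik(c(a, 1 - a), taxon_sets, u, taxa), numeric(1))
  a <- grid[which.max(ll)]
  setNames(c(a, 1 - a), taxa)
}

# nested-grid maximizer of the 3-taxon stage-1 likelihood (2 free params,
# coarse-to-fine refinement down to 1e-5)
oracle_grid_stage1_3tax <- function(taxon_sets, u, taxa) {
  stopifnot(length(taxa) == 3)
  eval_ll <- function(a, b) {
    w3 <- 1 - a - b
    if (w3 < 0) return(-Inf)
    stage1_loglik(c(a, b, w3), taxon_sets, u, taxa)
  }
  lo <- c(0, 0); hi <- c(1, 1); step <- 0.01
  best <- c(0.5, 0.25)
  repeat {
    as <- seq(max(0, lo[1]), min(1, hi[1]), by = step)
    bs <- seq(max(0, lo[2]), min(1, hi[2]), by = step)
    ll <- outer(as, bs, Vectorize(eval_ll))
    ix <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(as[ix[1]], bs[ix[2]])
    if (step <= 1e-5) break
    lo <- best - 2 * step
    hi <- best + 2 * step
    step <- step / 10
  }
  setNames(c(best, 1 - sum(best)), taxa)
}

# stage-2 likelihood with fixed p over 2 taxa x 2 terms: parameters a =
# phi(k1|t1), b = phi(k1|t2); pair_sets is peptide -> data.frame(taxon_id,
# go_id) with taxa in {t1, t2}, terms in {k1, k2}
stage2_loglik <- function(a, b, p, pair_sets, u) {
  phi <- matrix(c(a, 1 - a, b, 1 - b), nrow = 2, byrow = TRUE,
                dimnames = list(names(p), c("k1", "k2")))
  sum(u * vapply(pair_sets, function(d)
    log(sum(p[d$taxon_id] * phi[cbind(d$taxon_id, d$go_id)])), numeric(1)))
}

oracle_grid_stage2 <- function(p, pair_sets, u) {
  lo <- c(0, 0); hi <- c(1, 1); step <- 0.01
  best <- c(0.5, 0.5)
  repeat {
    as <- seq(max(0, lo[1]), min(1, hi[1]), by = step)
    bs <- seq(max(0, lo[2]), min(1, hi[2]), by = step)
    ll <- outer(as, bs, Vectorize(function(a, b)
      stage2_loglik(a, b, p, pair_sets, u)))
    ix <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(as[ix[1]], bs[ix[2]])
    if (step <= 1e-5) break
    lo <- best - 2 * step
    hi <- best + 2 * step
    step <- step / 10
  }
  setNames(best, names(p))
}
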