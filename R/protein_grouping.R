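# Protein clustering and per-taxon unclustering. Proteins sharing a
# significant fraction of identified peptides are grouped (overlap
# coefficient on peptide sets >= threshold, connected components); within
# each cluster one best protein per identified taxon is retained.

#' Cluster proteins by shared identified peptides
#'
#' Two proteins are linked when the overlap coefficient of their
#' identified-peptide sets, `|P_a & P_b| / min(|P_a|, |P_b|)`, is at least
#' `overlap_threshold`; clusters are the connected components of this graph.
#' Each cluster's head is its smallest-E-value member (ties broken by
#' lexicographically smallest accession).
#'
#' @param records data.frame of protein records with columns `accession`,
#'   `taxon_id`, `evalue` and list-column `peptides` (each nonempty).
#' @param overlap_threshold fraction in (0, 1]; default 0.8.
#' @return List of `protein_cluster` objects, each a list with `members`
#'   (rows of `records`), `head` (accession) and `retained` (named character,
#'   empty until [uncluster_by_taxon()]).
#' @export
cluster_proteins <- function(records, overlap_threshold = 0.8) {
  stopifnot(is.data.frame(records), overlap_threshold > 0,
            overlap_threshold <= 1)
  n <- nrow(records)
  if (!n) return(list())
  if (any(lengths(records$peptides) == 0L)) {
    stop("every protein record must have at least one identified peptide")
  }
  pepsets <- lapply(records$peptides, unique)
  # union-find over the pairwise overlap predicate
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1L) {
    for (a in seq_len(n - 1L)) {
      for (b in seq.int(a + 1L, n)) {
        ov <- length(intersect(pepsets[[a]], pepsets[[b]])) /
          min(length(pepsets[[a]]), length(pepsets[[b]]))
        if (ov >= overlap_threshold) parent[find(a)] <- find(b)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  # deterministic cluster order: by smallest member accession
  groups <- split(seq_len(n), comp)
  ord <- order(vapply(groups, function(ix) min(records$accession[ix]), ""))
  lapply(unname(groups[ord]), function(ix) {
    members <- records[ix, , drop = FALSE]
    best <- order(members$evalue, members$accession)[1L]
    structure(list(members = members,
                   head = members$accession[best],
                   retained = character(0)),
              class = "protein_cluster")
  })
}

#' @export
print.protein_cluster <- function(x, ...) {
  cat("<protein_cluster> head =", x$head, "| members =",
      nrow(x$members), "| retained =", length(x$retained), "\n")
  invisible(x)
}

#' Retain one best protein per identified taxon in a cluster
#'
#' For each identified taxon represented in the cluster, its
#' smallest-E-value member (ties by accession) is retained; members from
#' taxa outside `identified_taxa` are not retained.
#'
#' @param cluster a `protein_cluster`
#' @param identified_taxa nonempty character vector of taxon ids
#' @return The cluster with its `retained` map filled
#'   (taxon id -> accession).
#' @export
uncluster_by_taxon <- function(cluster, identified_taxa) {
  stopifnot(inherits(cluster, "protein_cluster"), length(identified_taxa) > 0)
  m <- cluster$members
  keep <- m$taxon_id %in% as.character(identified_taxa)
  m <- m[keep, , drop = FALSE]
  retained <- character(0)
  if (nrow(m)) {
    ord <- order(m$taxon_id, m$evalue, m$accession)
    m <- m[ord, , drop = FALSE]
    first <- !duplicated(m$taxon_id)
    retained <- setNames(m$accession[first], m$taxon_id[first])
  }
  cluster$retained <- retained
  cluster
}

#' Collect GO terms of retained proteins, per taxon
#'
#' Unions, over every cluster's retained proteins of each taxon, the GO
#' terms annotated to those proteins. Retained accessions absent from the
#' annotation table contribute an empty set with a warning.
#'
#' @param clusters list of unclustered `protein_cluster` objects
#' @param annotations data.frame (`accession`, `go_id`, `aspect`)
#' @return Named list: taxon id -> data.frame (`go_id`, `aspect`), unique
#'   rows, ordered.
#' @export
collect_go_terms <- function(clusters, annotations) {
  by_acc <- split(annotations[, c("go_id", "aspect")], annotations$accession)
  out <- list()
  missing_acc <- character(0)
  for (cl in clusters) {
    for (i in seq_along(cl$retained)) {
      taxon <- names(cl$retained)[i]
      acc <- cl$retained[[i]]
      terms <- by_acc[[acc]]
      if (is.null(terms)) {
        missing_acc <- c(missing_acc, acc)
        terms <- data.frame(go_id = character(0), aspect = character(0))
      }
      out[[taxon]] <- rbind(out[[taxon]], terms)
    }
  }
  if (length(missing_acc)) {
    warning("no annotations for retained accession(s): ",
            paste(unique(missing_acc), collapse = ", "))
  }
  out <- lapply(out, function(d) {
    d <- unique(d)
    d[order(d$aspect, d$go_id), , drop = FALSE]
  })
  out[order(names(out))]
}

#' Write a cluster table
#'
#' @param clusters list of `protein_cluster` objects
#' @param path destination TSV
#'   (cluster_id, accession, taxon_id, is_head, is_retained)
#' @return `path`, invisibly.
#' @export
write_clusters_tsv <- function(clusters, path) {
  rows <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(cluster_id = i,
               accession = cl$members$accession,
               taxon_id = cl$members$taxon_id,
               is_head = cl$members$accession == cl$head,
               is_retained = cl$members$accession %in% cl$retained,
               stringsAsFactors = FALSE)
  })
  fwrite(do.call(rbind, rows), path, sep = "\t")
  invisible(path)
}
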