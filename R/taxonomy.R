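#' @importFrom data.table fread fwrite
#' @importFrom stats setNames rlnorm runif rpois aggregate
#' @importFrom utils head tail packageVersion
NULL

#' Canonical taxonomic ranks
#'
#' The seven canonical levels used for lineage projection and reporting,
#' ordered from the root down to species. Nodes carrying any other rank
#' (strains, clades, "no rank" taxdump entries) are stored with rank
#' `"no-rank"` and are transparent to level projection.
#'
#' @return Character vector of the seven ranks, root first.
#' @export
canonical_ranks <- function() {
  c("root", "phylum", "class", "order", "family", "genus", "species")
}

.norm_rank <- function(rank) {
  rank <- tolower(trimws(rank))
  rank[rank %in% c("no rank", "norank", "no_rank", "clade", "strain",
                   "superkingdom", "kingdom", "domain", "subspecies",
                   "species group", "species subgroup", "suborder",
                   "subfamily", "subclass", "subphylum", "tribe")] <- "no-rank"
  bad <- !(rank %in% c(canonical_ranks(), "no-rank"))
  rank[bad] <- "no-rank"
  rank
}

#' Construct a taxonomy tree
#'
#' Builds and validates a rooted taxonomy from a node table. The root is the
#' unique node whose parent is itself (or empty). Every node must be reachable
#' from the root; duplicate ids and unresolvable parents are hard errors.
#'
#' @param nodes data.frame with columns `taxon_id`, `name`, `rank`,
#'   `parent_id` (all coercible to character; `rank` one of the canonical
#'   ranks or `"no-rank"`, unknown ranks are mapped to `"no-rank"`).
#' @return An object of class `taxonomy_tree`: list with `nodes` (the
#'   normalized table), `root`, and named lookup vectors `parent`, `rank`,
#'   `name`.
#' @export
taxonomy_tree <- function(nodes) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  req <- c("taxon_id", "name", "rank", "parent_id")
  if (!all(req %in% names(nodes))) {
    stop("taxonomy node table must have columns: ", paste(req, collapse = ", "))
  }
  nodes$taxon_id <- as.character(nodes$taxon_id)
  nodes$parent_id <- as.character(nodes$parent_id)
  nodes$name <- as.character(nodes$name)
  nodes$rank <- .norm_rank(nodes$rank)
  if (anyDuplicated(nodes$taxon_id)) {
    dup <- unique(nodes$taxon_id[duplicated(nodes$taxon_id)])
    stop("duplicate taxon id(s): ", paste(dup, collapse = ", "))
  }
  self_parent <- is.na(nodes$parent_id) | nodes$parent_id == "" |
    nodes$parent_id == nodes$taxon_id
  if (sum(self_parent) != 1L) {
    stop("taxonomy must have exactly one root (self-parent or empty parent); found ",
         sum(self_parent))
  }
  root <- nodes$taxon_id[self_parent]
  nodes$parent_id[self_parent] <- root
  nodes$rank[nodes$taxon_id == root] <- "root"
  missing_parent <- setdiff(nodes$parent_id, nodes$taxon_id)
  if (length(missing_parent)) {
    stop("orphan node(s): parent id(s) not in table: ",
         paste(missing_parent, collapse = ", "))
  }
  parent <- setNames(nodes$parent_id, nodes$taxon_id)
  # reachability / cycle check: walk each node to root
  for (id in nodes$taxon_id) {
    seen <- character(0)
    cur <- id
    while (cur != root) {
      if (cur %in% seen) stop("cycle detected involving taxon ", cur)
      seen <- c(seen, cur)
      cur <- parent[[cur]]
      if (length(seen) > nrow(nodes)) stop("cycle detected involving taxon ", id)
    }
  }
  tree <- structure(
    list(nodes = nodes, root = root,
         parent = parent,
         rank = setNames(nodes$rank, nodes$taxon_id),
         name = setNames(nodes$name, nodes$taxon_id)),
    class = "taxonomy_tree")
  .check_rank_order(tree)
  tree
}

# canonical ranks must appear in strictly descending order along every
# root-ward walk once no-rank nodes are dropped
.check_rank_order <- function(tree) {
  depth <- setNames(seq_along(canonical_ranks()), canonical_ranks())
  for (id in tree$nodes$taxon_id) {
    path <- ancestors(tree, id)  # self .. root
    rks <- tree$rank[path]
    rks <- rks[rks != "no-rank"]
    d <- depth[rks]
    if (any(diff(d) >= 0)) {
      stop("lineage of taxon ", id,
           " does not visit canonical ranks in strictly descending order")
    }
  }
  invisible(tree)
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("<taxonomy_tree> ", nrow(x$nodes), " nodes, root = ", x$root,
      " (", sum(x$rank == "species"), " species)\n", sep = "")
  invisible(x)
}

#' Path from a taxon to the root
#'
#' @param tree taxonomy_tree
#' @param taxon taxon id
#' @return Character vector of taxon ids, starting at `taxon`, ending at root.
#' @export
ancestors <- function(tree, taxon) {
  taxon <- as.character(taxon)
  if (!taxon %in% names(tree$parent)) stop("unknown taxon: ", taxon)
  path <- taxon
  cur <- taxon
  while (cur != tree$root) {
    cur <- tree$parent[[cur]]
    path <- c(path, cur)
  }
  path
}

#' Project a taxon to a canonical rank
#'
#' Returns the unique ancestor (or the taxon itself) carrying the requested
#' canonical rank, skipping no-rank nodes; `NA` if the lineage has no node of
#' that rank. Strain-like no-rank nodes below species therefore project to
#' their species ancestor.
#'
#' @param tree taxonomy_tree
#' @param taxon taxon id (vectorized)
#' @param level one of [canonical_ranks()]
#' @return Character vector of taxon ids (or `NA` where absent).
#' @export
lineage_at <- function(tree, taxon, level) {
  level <- match.arg(level, canonical_ranks())
  vapply(as.character(taxon), function(id) {
    path <- ancestors(tree, id)
    hit <- path[tree$rank[path] == level]
    if (length(hit)) hit[[1L]] else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node ancestral to (or equal to) every input taxon, computed on
#' the raw tree (no-rank nodes can be returned).
#'
#' @param tree taxonomy_tree
#' @param taxa nonempty character vector of taxon ids
#' @return A single taxon id.
#' @export
lca <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  if (!length(taxa)) stop("lca of an empty taxon set is undefined")
  # root-first paths; common prefix ends at the LCA
  paths <- lapply(taxa, function(t) rev(ancestors(tree, t)))
  common <- paths[[1L]]
  for (p in paths[-1L]) {
    n <- min(length(common), length(p))
    eq <- common[seq_len(n)] == p[seq_len(n)]
    k <- if (all(eq)) n else which(!eq)[1L] - 1L
    common <- common[seq_len(k)]
  }
  common[[length(common)]]
}

#' Read a flat lineage TSV
#'
#' Primary fixture format: UTF-8 TSV with header
#' `taxon_id  name  rank  parent_id`; the root row has `parent_id` equal to
#' its own id (or empty).
#'
#' @param path file path
#' @return taxonomy_tree
#' @export
read_lineage_tsv <- function(path) {
  tab <- fread(path, sep = "\t", colClasses = "character", data.table = FALSE)
  taxonomy_tree(tab)
}

#' Write a taxonomy as a flat lineage TSV
#'
#' @param tree taxonomy_tree
#' @param path destination
#' @return `path`, invisibly.
#' @export
write_lineage_tsv <- function(tree, path) {
  fwrite(tree$nodes[, c("taxon_id", "name", "rank", "parent_id")],
         path, sep = "\t")
  invisible(path)
}

#' Read an NCBI taxdump-dialect taxonomy
#'
#' Secondary reader for the `"|"`-delimited `nodes.dmp` / `names.dmp` format
#' (fields separated by `\t|\t`, lines terminated by `\t|`). Only scientific
#' names are taken from `names.dmp`; a missing names file leaves ids as names.
#'
#' @param nodes_path path to nodes.dmp-dialect file
#' @param names_path optional path to names.dmp-dialect file
#' @return taxonomy_tree
#' @export
read_taxdump <- function(nodes_path, names_path = NULL) {
  parse_dmp <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("\t\\|$", "", lines)
    strsplit(lines, "\t\\|\t")
  }
  rows <- parse_dmp(nodes_path)
  tab <- data.frame(
    taxon_id = vapply(rows, `[[`, "", 1L),
    parent_id = vapply(rows, `[[`, "", 2L),
    rank = vapply(rows, `[[`, "", 3L),
    stringsAsFactors = FALSE)
  tab$name <- tab$taxon_id
  if (!is.null(names_path)) {
    nrows <- parse_dmp(names_path)
    cls <- vapply(nrows, function(r) if (length(r) >= 4L) r[[4L]] else "", "")
    sci <- vapply(nrows[cls == "scientific name"], `[[`, "", 1L)
    nm <- vapply(nrows[cls == "scientific name"], `[[`, "", 2L)
    hit <- match(tab$taxon_id, sci)
    tab$name[!is.na(hit)] <- nm[hit[!is.na(hit)]]
  }
  taxonomy_tree(tab[, c("taxon_id", "name", "rank", "parent_id")])
}
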