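# Evaluation statistics: sensitivity and proportion of false discoveries
# (PFD) against a gold standard, overlap-coefficient matrices between
# methods, pairwise log2 fold changes, the three fold-change error metrics
# (expected error, expected mean absolute log2 fold-change error, and the
# percentage of errors within a threshold), and quasi-gold-standard
# construction from confidently identified proteins.

#' Sensitivity and PFD of a reported set against a gold standard
#'
#' `TP = |reported & gold|`, `FP = |reported \ gold|`,
#' `FN = |gold \ reported|`; sensitivity `TP/(TP+FN)`, PFD `FP/(TP+FP)`
#' (i.e. 1 - precision). An empty reported set has sensitivity 0 and an
#' undefined (`NA`) PFD.
#'
#' @param reported character vector (or set-like) of reported identifiers
#' @param gold nonempty character vector of gold-standard identifiers
#' @return list with `sensitivity`, `pfd` (raw fractions), `tp`, `fp`, `fn`.
#' @export
sensitivity_pfd <- function(reported, gold) {
  gold <- unique(as.character(gold))
  if (!length(gold)) stop("gold standard must be nonempty")
  reported <- unique(as.character(reported))
  tp <- length(intersect(reported, gold))
  fp <- length(setdiff(reported, gold))
  fn <- length(setdiff(gold, reported))
  list(sensitivity = tp / (tp + fn),
       pfd = if (tp + fp > 0) fp / (tp + fp) else NA_real_,
       tp = tp, fp = fp, fn = fn)
}

#' Format a fraction as a percentage string
#'
#' Reporting helper matching printed-precision conventions; raw fractions
#' are always retained in machine output, this only affects display.
#'
#' @param x fraction in \[0, 1\]
#' @param digits decimals to keep (default 1)
#' @param mode `"half-up"` (default) or `"truncate"`
#' @return Numeric percentage rounded per `mode`.
#' @export
format_percent <- function(x, digits = 1, mode = c("half-up", "truncate")) {
  mode <- match.arg(mode)
  scaled <- x * 100 * 10^digits
  v <- switch(mode,
              `half-up` = floor(scaled + 0.5),
              truncate = floor(scaled))
  v / 10^digits
}

#' Overlap-coefficient matrix between labeled sets
#'
#' `O[r, c] = |S_r & S_c| / |S_r|`: the fraction of the row method's
#' identifiers also reported by the column method. With a gold standard as
#' the first set, its row gives each method's sensitivity and one minus its
#' column gives each method's PFD. Rows for empty sets are `NA`.
#'
#' @param sets named list of >= 2 character vectors
#' @return Square numeric matrix with the sets' names as dimnames.
#' @export
overlap_matrix <- function(sets) {
  stopifnot(length(sets) >= 2, !is.null(names(sets)))
  sets <- lapply(sets, function(s) unique(as.character(s)))
  n <- length(sets)
  m <- matrix(NA_real_, n, n, dimnames = list(names(sets), names(sets)))
  for (r in seq_len(n)) {
    if (!length(sets[[r]])) next
    for (c in seq_len(n)) {
      m[r, c] <- length(intersect(sets[[r]], sets[[c]])) / length(sets[[r]])
    }
  }
  m
}

#' Pairwise log2 fold changes between two abundance tables
#'
#' For every identifier with strictly positive abundance in both tables,
#' computes `log2(a/b)` alongside its true value. Identifiers missing or
#' zero in either table are excluded (missing data, not errors) and counted.
#'
#' @param table_a,table_b named numeric abundance vectors
#' @param truth either a single number (the known true log2 fold change for
#'   all identifiers) or a named numeric vector
#' @return `fold_change_set`: list with `pairs` data.frame (`id`,
#'   `log2fc_computed`, `log2fc_true`), `m` (number of pairs) and
#'   `n_missing`.
#' @export
log2_fold_changes <- function(table_a, table_b, truth = 0) {
  ids <- intersect(names(table_a), names(table_b))
  pos <- ids[table_a[ids] > 0 & table_b[ids] > 0]
  n_missing <- length(union(names(table_a), names(table_b))) - length(pos)
  if (!length(pos)) warning("no shared identifiers with positive abundance")
  tr <- if (length(truth) == 1L && is.null(names(truth))) {
    rep(as.numeric(truth), length(pos))
  } else {
    unname(truth[pos])
  }
  pairs <- data.frame(id = sort(pos), stringsAsFactors = FALSE)
  ord <- match(pairs$id, pos)
  pairs$log2fc_computed <- unname(log2(table_a[pos] / table_b[pos]))[ord]
  pairs$log2fc_true <- tr[ord]
  structure(list(pairs = pairs, m = nrow(pairs), n_missing = n_missing),
            class = "fold_change_set")
}

#' Fold-change error metrics over pairwise comparisons
#'
#' Over `N` pairwise comparisons with `M_i` fold changes each and errors
#' `e_ij = log2FC_computed - log2FC_true`:
#' * `E[Error]   = (1/N) sum_i sum_j e_ij / M_i`
#' * `E[MALFCE]  = (1/N) sum_i sum_j |e_ij| / M_i`
#' * `%EV        = (1 / sum_i M_i) sum_i sum_j I(|e_ij| <= threshold)`
#'
#' Comparisons with `M_i = 0` are excluded with a warning and `N` reduced.
#'
#' @param fc_sets list of `fold_change_set` objects
#' @param ev_threshold absolute-error threshold for %EV (default 2)
#' @return list with `e_error`, `e_malfce`, `pct_ev`, `n_comparisons`.
#' @export
error_metrics <- function(fc_sets, ev_threshold = 2) {
  stopifnot(length(fc_sets) >= 1)
  m <- vapply(fc_sets, function(s) s$m, numeric(1))
  if (any(m == 0)) {
    warning(sum(m == 0), " comparison(s) with no fold changes excluded")
    fc_sets <- fc_sets[m > 0]
    m <- m[m > 0]
  }
  if (!length(fc_sets)) {
    return(list(e_error = NA_real_, e_malfce = NA_real_, pct_ev = NA_real_,
                n_comparisons = 0L))
  }
  n <- length(fc_sets)
  errs <- lapply(fc_sets, function(s)
    s$pairs$log2fc_computed - s$pairs$log2fc_true)
  e_error <- sum(vapply(errs, mean, numeric(1))) / n
  e_malfce <- sum(vapply(errs, function(e) mean(abs(e)), numeric(1))) / n
  all_err <- unlist(errs, use.names = FALSE)
  pct_ev <- sum(abs(all_err) <= ev_threshold) / length(all_err)
  list(e_error = e_error, e_malfce = e_malfce, pct_ev = pct_ev,
       n_comparisons = n)
}

#' Build a GO-term quasi-gold standard
#'
#' Emulates searching a database restricted to the true species: all
#' confidently identified proteins passing the expected-false-positive
#' cutoff (E-value at most `expected_fp`, i.e. the largest score at which
#' the expected number of false-positive proteins is `expected_fp`)
#' contribute their GO terms, without clustering.
#'
#' @param proteins data.frame with `accession` and `evalue`
#' @param annotations data.frame (`accession`, `go_id`, `aspect`)
#' @param expected_fp expected false-positive protein count (default 1)
#' @return data.frame (`go_id`, `aspect`), unique rows; empty with a warning
#'   if no protein passes.
#' @export
build_quasi_gold <- function(proteins, annotations, expected_fp = 1) {
  stopifnot(expected_fp > 0)
  kept <- proteins$accession[proteins$evalue <= expected_fp]
  if (!length(kept)) {
    warning("no protein passes the expected-false-positive cutoff")
    return(data.frame(go_id = character(0), aspect = character(0)))
  }
  terms <- annotations[annotations$accession %in% kept,
                       c("go_id", "aspect"), drop = FALSE]
  terms <- unique(terms)
  terms <- terms[order(terms$aspect, terms$go_id), , drop = FALSE]
  rownames(terms) <- NULL
  terms
}

#' Write a metrics report as JSON
#' @param metrics list of metric values
#' @param path destination .json
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a labeled matrix as TSV
#' @param m matrix with dimnames
#' @param path destination
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  out <- data.frame(label = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  fwrite(out, path, sep = "\t")
  invisible(path)
}
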