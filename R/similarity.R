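#' Shared-peak similarity score between two virtual spectra
#'
#' The score of a query ("inspected") spectrum against a reference is the
#' number of query peaks with a matching reference peak within `tol_da`
#' (boundary inclusive), divided by the total number of query peaks, as a
#' percentage. Matching is one-to-one: each reference peak certifies at
#' most one query peak, pairs being assigned greedily in order of
#' increasing |delta m/z| with ties broken toward the lower-m/z query peak.
#' The score is asymmetric — the denominator is the inspected spectrum —
#' and depends only on peak positions, not intensities.
#'
#' @param query,reference `icm_virtual_spectrum` objects (or any object
#'   with an `mz` field).
#' @param tol_da matching tolerance in Da (default 2).
#' @return percentage on \[0, 100\]; 0 when the query has no peaks.
#' @export
score <- function(query, reference, tol_da = 2) {
  stopifnot(tol_da > 0)
  q <- query$mz; r <- reference$mz
  nq <- length(q)
  if (nq == 0L) return(0)
  if (length(r) == 0L) return(0)
  100 * .greedy_match_count(q, r, tol_da) / nq
}

# Greedy one-to-one assignment by increasing |delta|, ties toward the
# lower-m/z query peak (then lower reference m/z, for determinism).
.greedy_match_count <- function(q, r, tol) {
  cand <- NULL
  for (i in seq_along(q)) {
    j <- which(abs(r - q[i]) <= tol)
    if (length(j) > 0)
      cand <- rbind(cand, cbind(i = i, j = j, d = abs(r[j] - q[i])))
  }
  if (is.null(cand)) return(0L)
  cand <- cand[order(cand[, "d"], q[cand[, "i"]], r[cand[, "j"]]), ,
               drop = FALSE]
  used_q <- logical(length(q)); used_r <- logical(length(r))
  matched <- 0L
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, "i"]; j <- cand[k, "j"]
    if (!used_q[i] && !used_r[j]) {
      used_q[i] <- TRUE; used_r[j] <- TRUE
      matched <- matched + 1L
    }
  }
  matched
}

#' All-pairs directed similarity matrix
#'
#' Entry (i, j) is the score of sample i's virtual spectrum inspected
#' against reference j; the matrix is generally asymmetric. The diagonal
#' is 100 for any sample with at least one consensus peak.
#'
#' @param library list of `icm_virtual_spectrum` with distinct sample ids.
#' @param tol_da matching tolerance in Da (default 2).
#' @return an `icm_similarity_matrix`: a numeric matrix with sample ids as
#'   dimnames and attribute `tol_da`.
#' @export
similarity_matrix <- function(library, tol_da = 2) {
  stopifnot(length(library) >= 2L)
  ids <- vapply(library, function(v) v$sample_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample_ids in library: ",
         paste(ids[duplicated(ids)], collapse = ", "))
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n))
    for (j in seq_len(n))
      m[i, j] <- score(library[[i]], library[[j]], tol_da)
  structure(m, tol_da = tol_da, class = c("icm_similarity_matrix", "matrix",
                                          "array"))
}

#' Write / read a similarity matrix as CSV
#'
#' First row and first column carry the sample ids; entries are written to
#' one decimal place.
#'
#' @param m an `icm_similarity_matrix`.
#' @param path CSV path.
#' @return `path` (write) or the matrix (read).
#' @export
write_similarity_csv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m),
                   round(unclass(m), 1), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_similarity_csv
#' @export
read_similarity_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  structure(m, class = c("icm_similarity_matrix", "matrix", "array"))
}

#' Color ramp for similarity heat maps
#'
#' Continuous ramp anchored at red (0) through dark orange, light orange,
#' yellow (50), light green and green to dark green (100).
#'
#' @param n number of colors.
#' @return character vector of colors.
#' @export
similarity_palette <- function(n = 101) {
  grDevices::colorRampPalette(
    c("red", "darkorange", "orange", "yellow",
      "lightgreen", "green3", "darkgreen"))(n)
}

#' Render a similarity matrix as a heat map image
#'
#' @param m an `icm_similarity_matrix`.
#' @param path output image path (.png or .pdf).
#' @param cluster reorder rows/columns by clustering (default FALSE: keep
#'   library order).
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(m, path, cluster = FALSE) {
  mm <- unclass(m)
  pheatmap::pheatmap(
    mm, cluster_rows = cluster, cluster_cols = cluster,
    color = similarity_palette(100), breaks = seq(0, 100, length.out = 101),
    display_numbers = ncol(mm) <= 12, number_format = "%.0f",
    filename = path, silent = TRUE)
  invisible(path)
}

#' Build a hierarchical similarity tree
#'
#' Symmetrizes the directed similarity matrix into distances
#' d(i, j) = 100 - (s(i,j) + s(j,i)) / 2 and clusters agglomeratively.
#' Samples are ordered lexicographically before clustering so ties are
#' broken deterministically toward the smallest leaf label. UPGMA (average
#' linkage) yields an ultrametric tree.
#'
#' @param m an `icm_similarity_matrix`.
#' @param linkage `"upgma"` (default), `"complete"` or `"single"`.
#' @return an `ape::phylo` tree with branch lengths in distance units
#'   (100 - percent similarity).
#' @export
build_tree <- function(m, linkage = c("upgma", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (nrow(m) < 2L) stop("need at least 2 samples to build a tree")
  mm <- unclass(m)
  d <- 100 - (mm + t(mm)) / 2
  diag(d) <- 0
  ord <- order(rownames(d))
  d <- d[ord, ord]
  method <- c(upgma = "average", complete = "complete", single = "single")[linkage]
  hc <- stats::hclust(stats::as.dist(d), method = method)
  ape::as.phylo(hc)
}

#' Export a similarity tree as Newick
#'
#' @param tree an `ape::phylo` as returned by [build_tree()].
#' @param path output path (.nwk).
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
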