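# ROC-AUC scoring of interaction rankings against ground truth.

#' Area under the ROC curve of an interaction ranking
#'
#' Mann--Whitney formulation with midrank tie handling:
#' `AUC = (rank sum of true-link scores - n1 (n1 + 1) / 2) / (n1 n0)`.
#' Equals 1 when every true link outscores every non-link, and exactly 1/2
#' when all scores are tied.
#'
#' @param scores numeric score vector (higher = more confident link).
#' @param labels logical (or 0/1) vector, `TRUE` for true links.
#' @return the AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: need at least one true link and one non-link in scope")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

truth_matrix <- function(truth) {
  if (inherits(truth, "network_spec")) {
    L <- (truth$J != 0) * 1L
    if (!is.null(truth$E)) {
      for (i in seq_len(truth$N)) {
        idx <- which(truth$E[[i]] != 0, arr.ind = TRUE)
        if (nrow(idx)) L[i, unique(as.vector(idx))] <- 1L
      }
    }
    L
  } else {
    (as.matrix(truth) != 0) * 1L
  }
}

#' AUC of a unit-level score matrix against a ground-truth network
#'
#' Scores all ordered off-diagonal pairs (self links are excluded); with
#' `observed` given, only pairs among the observed units are scored, making
#' no statement about links mediated by hidden units.
#'
#' @param scores unit-level score matrix, `scores[i, j]` for the candidate
#'   link j -> i.  Row/column names, when present, are unit ids.
#' @param truth a [network_spec] or adjacency matrix (`truth[i, j] != 0` iff
#'   j -> i exists).
#' @param observed optional vector of observed unit ids defining the scope.
#' @return the AUC.
#' @export
auc_network <- function(scores, truth, observed = NULL) {
  A <- truth_matrix(truth)
  units <- if (!is.null(rownames(scores))) as.integer(rownames(scores))
           else seq_len(nrow(scores))
  if (is.null(observed)) observed <- units
  keep <- match(intersect(observed, units), units)
  s <- scores[keep, keep, drop = FALSE]
  a <- A[units[keep], units[keep], drop = FALSE]
  off <- row(s) != col(s)
  auc_score(s[off], a[off] != 0)
}

#' AUC of hypernetwork pair rankings
#'
#' The candidate universe for each target `i` is every unordered pair
#' `{j, k}` of units with `j != k` (degenerate pairs containing `i` encode
#' pairwise links); unscored candidates share the tied minimal score.
#'
#' @param pair_scores tibble with columns `target`, `j`, `k`, `score`
#'   (e.g. the `pair_scores` element of an [infer_network()] result).
#' @param truth a hypernetwork [network_spec]; its `E` support defines the
#'   true pairs.
#' @return the AUC.
#' @export
auc_hypernetwork <- function(pair_scores, truth) {
  N <- truth$N
  prs <- utils::combn(N, 2L)
  uni <- tidyr::expand_grid(target = seq_len(N),
                            idx = seq_len(ncol(prs)))
  uni$j <- prs[1L, uni$idx]; uni$k <- prs[2L, uni$idx]
  tru <- tidy(truth)
  uni <- dplyr::left_join(uni, dplyr::select(tru, "target", "j", "k") |>
                            dplyr::mutate(true = TRUE),
                          by = c("target", "j", "k"))
  uni <- dplyr::left_join(uni,
                          dplyr::select(pair_scores, "target", "j", "k", "score"),
                          by = c("target", "j", "k"))
  auc_score(tidyr::replace_na(uni$score, 0),
            tidyr::replace_na(uni$true, FALSE))
}
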