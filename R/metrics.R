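# Evaluation statistics for alignments: ground-truth accuracy on duplicated
# slices, label contingency tables and F1 scores, Procrustes rotation
# recovery, and the (gameable) edge score.

#' Ground-truth accuracy of a duplicate-slice alignment
#'
#' In the duplicate setting, cell i's true partner is cell i; accuracy is the
#' fraction of cells whose best match (argmax cosine over the candidate set)
#' equals the truth.
#'
#' @param best integer vector, per-cell best-match index into slice 2.
#' @param truth integer vector of true partners (default the identity).
#' @return accuracy in `[0, 1]`.
#' @export
ground_truth_accuracy <- function(best, truth = seq_along(best)) {
  stopifnot(length(best) == length(truth))
  mean(best == truth)
}

#' Label-matching contingency report
#'
#' Per evaluated cell, flags whether the matched partner carries the same
#' cell type and the same spatial region; aggregates the four joint
#' proportions (which sum to 1) and per-class confusion matrices. Cells
#' unannotated in either partner (`"NA"`) are excluded.
#'
#' @param matches best-match table ([best_matches()]) or any table with one
#'   row per evaluated slice-1 cell (`source`, `target`).
#' @param type1,type2 cell-type labels of the two slices (optional).
#' @param region1,region2 region labels of the two slices (optional).
#' @return list of class `contingency_report`: `proportions` (2x2 table over
#'   type/region match), `type_accuracy`, `region_accuracy`,
#'   `joint_accuracy`, `n_evaluated`, and confusion matrices
#'   `type_confusion`, `region_confusion`.
#' @export
label_accuracy <- function(matches, type1 = NULL, type2 = NULL,
                           region1 = NULL, region2 = NULL) {
  i <- matches$source; j <- matches$target
  annotated <- rep(TRUE, length(i))
  is_ok <- function(x) !is.na(x) & x != "NA"
  if (!is.null(type1)) annotated <- annotated & is_ok(type1[i]) & is_ok(type2[j])
  if (!is.null(region1)) annotated <- annotated & is_ok(region1[i]) & is_ok(region2[j])
  i <- i[annotated]; j <- j[annotated]
  n <- length(i)
  type_ok <- if (is.null(type1)) rep(NA, n) else type1[i] == type2[j]
  region_ok <- if (is.null(region1)) rep(NA, n) else region1[i] == region2[j]
  prop <- matrix(NA_real_, 2, 2,
                 dimnames = list(type = c("match", "mismatch"),
                                 region = c("match", "mismatch")))
  if (!is.null(type1) && !is.null(region1)) {
    prop["match", "match"] <- mean(type_ok & region_ok)
    prop["match", "mismatch"] <- mean(type_ok & !region_ok)
    prop["mismatch", "match"] <- mean(!type_ok & region_ok)
    prop["mismatch", "mismatch"] <- mean(!type_ok & !region_ok)
  }
  conf <- function(a, b) if (is.null(a)) NULL else table(truth = a[i], matched = b[j])
  structure(
    list(proportions = prop,
         type_accuracy = if (is.null(type1)) NA_real_ else mean(type_ok),
         region_accuracy = if (is.null(region1)) NA_real_ else mean(region_ok),
         joint_accuracy = prop["match", "match"],
         n_evaluated = n,
         type_confusion = conf(type1, type2),
         region_confusion = conf(region1, region2)),
    class = "contingency_report"
  )
}

#' @exportS3Method base::print
print.contingency_report <- function(x, ...) {
  cat(sprintf("contingency_report over %d cells\n", x$n_evaluated))
  cat(sprintf("  type accuracy:   %s\n", format(x$type_accuracy, digits = 4)))
  cat(sprintf("  region accuracy: %s\n", format(x$region_accuracy, digits = 4)))
  cat(sprintf("  joint accuracy:  %s\n", format(x$joint_accuracy, digits = 4)))
  invisible(x)
}

# F1 of one class from a truth/prediction pair of label vectors.
class_f1 <- function(truth, pred, cls) {
  tp <- sum(truth == cls & pred == cls)
  fp <- sum(truth != cls & pred == cls)
  fn <- sum(truth == cls & pred != cls)
  if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
}

f1_pair <- function(truth, pred) {
  classes <- sort(unique(truth))  # macro over classes present in slice 1
  per_class <- vapply(classes, function(cl) class_f1(truth, pred, cl), 0)
  tp_total <- sum(truth == pred)
  # single-label multiclass micro-F1 equals accuracy
  list(micro = tp_total / length(truth), macro = mean(per_class),
       per_class = stats::setNames(per_class, classes))
}

#' Micro and macro F1 of label matching
#'
#' Treats the alignment as classifying each slice-1 cell into the label of
#' its matched slice-2 partner, and scores type, region, and joint
#' (type x region) labels. Macro-F1 averages over classes present in the
#' reference slice; classes never predicted contribute 0.
#'
#' @inheritParams label_accuracy
#' @return nested list `type`/`region`/`joint`, each with `micro`, `macro`
#'   and `per_class` (entries `NULL` when the labels are absent).
#' @export
f1_scores <- function(matches, type1 = NULL, type2 = NULL,
                      region1 = NULL, region2 = NULL) {
  i <- matches$source; j <- matches$target
  out <- list(type = NULL, region = NULL, joint = NULL)
  if (!is.null(type1)) out$type <- f1_pair(type1[i], type2[j])
  if (!is.null(region1)) out$region <- f1_pair(region1[i], region2[j])
  if (!is.null(type1) && !is.null(region1))
    out$joint <- f1_pair(paste(type1[i], region1[i], sep = "||"),
                         paste(type2[j], region2[j], sep = "||"))
  out
}

#' Rotation recovery by orthogonal Procrustes
#'
#' Given matched coordinate pairs, solves the Procrustes problem on centered
#' coordinates and returns the estimated rotation applied to the second
#' slice relative to the first (i.e. if `S2m` is `S1m` rotated by theta, the
#' estimate is theta). A determinant guard reports when the optimal
#' orthogonal map is a reflection.
#'
#' @param S1m,S2m matched coordinates (row i of each is one matched pair).
#' @return list with `angle_deg` in `(-180, 180]`, `residual` (mean distance
#'   after optimal rotation of the centered sets), and `reflection` flag.
#' @export
procrustes_rotation <- function(S1m, S2m) {
  S1m <- as.matrix(S1m); S2m <- as.matrix(S2m)
  stopifnot(nrow(S1m) == nrow(S2m), nrow(S1m) >= 2)
  A0 <- sweep(S1m, 2, colMeans(S1m))
  B0 <- sweep(S2m, 2, colMeans(S2m))
  if (min(svd(A0)$d) < 1e-12 * max(svd(A0)$d, 1))
    warning("near-collinear coordinates; rotation estimate may be unstable")
  # R rotating S1 (centered) onto S2: B0 ~ A0 %*% t(R)
  H <- crossprod(A0, B0)
  sv <- svd(H)
  refl <- det(tcrossprod(sv$v, sv$u)) < 0
  D <- diag(c(1, if (refl) -1 else 1))
  R <- sv$v %*% D %*% t(sv$u)
  ang <- atan2(R[2, 1], R[1, 1]) * 180 / pi
  resid <- mean(sqrt(rowSums((A0 %*% t(R) - B0)^2)))
  list(angle_deg = ang, residual = resid, reflection = refl)
}

#' Neighborhood-preservation edge score
#'
#' For each evaluated slice-1 cell n with matched partner n', every graph-1
#' neighbor m of n contributes +1 if the partners n', m' are adjacent in
#' graph 2 and -1 otherwise; the sum is divided by the number of evaluated
#' cells. Cells without a match are skipped and excluded from the
#' denominator. Note this score only measures matching continuity: locally
#' swapped pairings with preserved adjacency score identically to the
#' correct pairing.
#'
#' @param pairing integer vector mapping slice-1 cells to slice-2 partners
#'   (`NA` = unmatched).
#' @param g1,g2 `spatial_graph` objects.
#' @return the edge score (average signed preserved-neighbor count).
#' @export
edge_score <- function(pairing, g1, g2) {
  matched <- which(!is.na(pairing))
  if (length(matched) == 0L) return(NaN)
  A1 <- g1$A; A2 <- g2$A
  total <- 0
  for (n in matched) {
    nb <- which(A1[n, ] != 0)
    nb <- nb[!is.na(pairing[nb])]
    if (length(nb) == 0L) next
    adj <- as.numeric(A2[pairing[n], pairing[nb]])
    total <- total + sum(ifelse(adj != 0, 1, -1))
  }
  total / length(matched)
}

#' Aggregate metrics for an alignment
#'
#' Convenience wrapper computing ground-truth accuracy (when a truth pairing
#' exists), label accuracies/F1 (when labels exist) and rotation recovery,
#' suitable for JSON export.
#'
#' @param best best-match table.
#' @param s1,s2 the aligned slices.
#' @param truth optional integer truth pairing for duplicate-style tasks.
#' @return named list of scalar metrics and nested reports.
#' @export
alignment_metrics <- function(best, s1, s2, truth = NULL) {
  out <- list()
  if (!is.null(truth))
    out$ground_truth_accuracy <- ground_truth_accuracy(best$target[order(best$source)],
                                                       truth[sort(best$source)])
  rep_ <- label_accuracy(best, s1$cell_type, s2$cell_type, s1$region, s2$region)
  out$type_accuracy <- rep_$type_accuracy
  out$region_accuracy <- rep_$region_accuracy
  out$joint_accuracy <- rep_$joint_accuracy
  out$contingency <- rep_
  f1 <- f1_scores(best, s1$cell_type, s2$cell_type, s1$region, s2$region)
  out$f1 <- lapply(f1, function(x) if (is.null(x)) NULL else x[c("micro", "macro")])
  pr <- procrustes_rotation(s1$coords[best$source, , drop = FALSE],
                            s2$coords[best$target, , drop = FALSE])
  out$rotation_deg <- pr$angle_deg
  out$rotation_residual <- pr$residual
  out
}
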