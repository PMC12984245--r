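#' Segmentation and classification metrics
#'
#' Metrics used to evaluate brain-surface and cortical-vessel segmentation
#' masks and four-class tissue maps: Dice similarity coefficient (DSC),
#' average symmetric surface distance (ASSD), vessel hit rate (VHR), vessel
#' error rate (VER), per-class F1 and AUC, row-normalized confusion matrices,
#' and per-patient aggregation.
#'
#' Label codes used throughout the package: 0 unlabeled, 1 healthy, 2 tumor,
#' 3 vessel, 4 dura mater.  Fused class maps use 1 healthy, 2 tumor,
#' 3 vessel, 4 background.
#'
#' @name metrics
NULL

CLASS_UNLABELED <- 0L
CLASS_HEALTHY <- 1L
CLASS_TUMOR <- 2L
CLASS_VESSEL <- 3L
CLASS_DURA <- 4L
CLASS_BACKGROUND <- 4L  # fused maps reuse slot 4 for non-cortex

#' Dice similarity coefficient, in percent
#'
#' @param pred,ref binary masks of equal size.
#' @return DSC in `[0, 100]`; two empty masks score 100.
#' @export
dsc <- function(pred, ref) {
  a <- as_mask(pred); b <- as_mask(ref)
  stopifnot(all(dim(a) == dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L) return(100)
  200 * sum(a * b) / (sa + sb)
}

boundary_4 <- function(mask) {
  m <- as_mask(mask)
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0L, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  inner <- pad[2:(h + 1L), 2:(w + 1L)] == 1L &
    (pad[1:h, 2:(w + 1L)] == 0L | pad[3:(h + 2L), 2:(w + 1L)] == 0L |
       pad[2:(h + 1L), 1:w] == 0L | pad[2:(h + 1L), 3:(w + 2L)] == 0L)
  as_mask(inner)
}

#' Average symmetric surface distance, in pixels
#'
#' Boundaries are mask pixels with at least one 4-neighbour outside the mask
#' (image border counts as outside); distances are exact Euclidean.
#'
#' @param pred,ref non-empty binary masks of equal size.
#' @export
assd <- function(pred, ref) {
  a <- as_mask(pred); b <- as_mask(ref)
  stopifnot(all(dim(a) == dim(b)))
  if (sum(a) == 0L || sum(b) == 0L)
    stop("assd is undefined for empty masks")
  ba <- boundary_4(a); bb <- boundary_4(b)
  da <- dist_to_set(bb)[ba == 1L]   # pred boundary -> ref boundary
  db <- dist_to_set(ba)[bb == 1L]
  (mean(da) + mean(db)) / 2
}

#' Vessel hit rate (sensitivity of the vessel mask), in percent
#'
#' Fraction of ground-truth vessel-labeled pixels covered by the predicted
#' vessel mask.
#'
#' @param vessel_mask binary predicted vessel mask.
#' @param gt integer label mask (sparse ground truth).
#' @export
vhr <- function(vessel_mask, gt) {
  m <- as_mask(vessel_mask)
  av <- gt == CLASS_VESSEL
  if (sum(av) == 0L) stop("ground truth contains no vessel-labeled pixels")
  100 * sum(m[av]) / sum(av)
}

#' Vessel error rate, in percent
#'
#' Fraction of the predicted vessel mask falling on pixels annotated as
#' healthy or tumor tissue.
#'
#' @inheritParams vhr
#' @export
ver <- function(vessel_mask, gt) {
  m <- as_mask(vessel_mask)
  if (sum(m) == 0L) {
    warning("empty vessel mask; VER reported as 0")
    return(0)
  }
  aht <- gt == CLASS_HEALTHY | gt == CLASS_TUMOR
  100 * sum(m * aht) / sum(m)
}

#' Per-class F1 scores on labeled pixels
#'
#' One-vs-rest F1 (`2 TP / (2 TP + FP + FN)`) per class, restricted to
#' pixels carrying a ground-truth label.  Classes absent from the ground
#' truth are reported as `NA` and excluded from means.
#'
#' @param class_map integer predicted class map.
#' @param gt integer label mask; 0 marks unlabeled pixels.
#' @param classes integer class codes to evaluate.
#' @return list with per-class `f1` (percent) and `counts` (tp/fp/fn/tn).
#' @export
f1_per_class <- function(class_map, gt, classes = 1:4) {
  lab <- gt != CLASS_UNLABELED
  p <- class_map[lab]; g <- gt[lab]
  f1 <- counts <- list()
  for (cl in classes) {
    key <- as.character(cl)
    if (!any(g == cl)) {
      f1[[key]] <- NA_real_
      counts[[key]] <- c(tp = 0, fp = 0, fn = 0, tn = 0)
      next
    }
    tp <- sum(p == cl & g == cl); fp <- sum(p == cl & g != cl)
    fn <- sum(p != cl & g == cl); tn <- sum(p != cl & g != cl)
    f1[[key]] <- 100 * 2 * tp / (2 * tp + fp + fn)
    counts[[key]] <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  }
  list(f1 = unlist(f1), counts = counts)
}

#' Per-class ROC AUC on labeled pixels
#'
#' One-vs-rest AUC by the Mann-Whitney rank statistic with midranks for
#' ties, in percent.
#'
#' @param prob_map array `(h, w, n_classes)` of per-pixel class
#'   probabilities.
#' @inheritParams f1_per_class
#' @export
auc_per_class <- function(prob_map, gt, classes = 1:4) {
  lab <- which(gt != CLASS_UNLABELED)
  g <- gt[lab]
  out <- numeric(0)
  for (cl in classes) {
    key <- as.character(cl)
    pos <- g == cl
    if (!any(pos) || all(pos)) {
      out[key] <- NA_real_
      next
    }
    sc <- prob_map[, , cl][lab]
    r <- rank(sc)
    n1 <- sum(pos); n0 <- sum(!pos)
    out[key] <- 100 * (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  out
}

#' Confusion matrix over labeled pixels
#'
#' Rows are the true classes (healthy, tumor, vessel, other), columns the
#' predictions.  For fused maps dura-mater ground truth is mapped to the
#' "outside" row, matching the fused background class.
#'
#' @inheritParams f1_per_class
#' @param row_normalize if `TRUE`, rows are scaled to sum to 100.
#' @param dura_to_outside map dura labels/predictions into class 4
#'   ("outside") rather than treating dura as its own class.
#' @export
confusion_matrix <- function(class_map, gt, row_normalize = TRUE,
                             dura_to_outside = FALSE) {
  lab <- gt != CLASS_UNLABELED
  p <- class_map[lab]; g <- gt[lab]
  cm <- matrix(0, 4, 4,
               dimnames = list(true = c("H", "T", "V", "O"),
                               pred = c("H", "T", "V", "O")))
  for (i in 1:4) for (j in 1:4) cm[i, j] <- sum(g == i & p == j)
  if (row_normalize) {
    rs <- rowSums(cm)
    nz <- rs > 0
    cm[nz, ] <- 100 * cm[nz, , drop = FALSE] / rs[nz]
  }
  cm
}

#' Aggregate per-patient class metrics
#'
#' Averages metrics per class within each patient, then reports the mean and
#' sample standard deviation across patients.  `NA` class entries (classes
#' absent from that patient) are excluded from that patient's mean only.
#'
#' @param per_patient list of named numeric vectors (per-class metric
#'   values, e.g. F1 or AUC).
#' @return list with `mean`, `sd` and the per-patient means.
#' @export
aggregate_metrics <- function(per_patient) {
  stopifnot(length(per_patient) >= 1L)
  pm <- vapply(per_patient, function(v) mean(v, na.rm = TRUE), numeric(1))
  list(mean = mean(pm),
       sd = if (length(pm) > 1L) sd(pm) else 0,
       per_patient = pm)
}

#' Select percentile-ranked exemplar images
#'
#' Averages each image's DSC over models and returns the images closest to
#' the 5th, 50th and 95th percentiles of those averages (linear
#' interpolation), labelling them bad / intermediate / good.
#'
#' @param dsc_table numeric matrix, images in rows, models in columns.
#' @return named integer vector of row indices.
#' @export
percentile_rank <- function(dsc_table) {
  dsc_table <- as.matrix(dsc_table)
  if (nrow(dsc_table) < 3L) stop("need at least 3 images to rank")
  avg <- rowMeans(dsc_table)
  qs <- quantile(avg, c(0.05, 0.50, 0.95), type = 7, names = FALSE)
  sel <- vapply(qs, function(q) which.min(abs(avg - q)), integer(1))
  names(sel) <- c("bad", "intermediate", "good")
  sel
}
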