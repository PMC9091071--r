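# Independent brute-force oracles used to validate the fast implementations.
# They deliberately share no code with the package internals.

# IoU by explicit pixel-set counting on integer boxes
oracle_iou_pixels <- function(a, b) {
  cells <- function(bx) {
    xs <- seq(bx[["x0"]], bx[["x1"]] - 1)
    ys <- seq(bx[["y0"]], bx[["y1"]] - 1)
    paste(rep(xs, each = length(ys)), rep(ys, times = length(xs)))
  }
  ca <- cells(a); cb <- cells(b)
  length(intersect(ca, cb)) / length(union(ca, cb))
}

# greedy NMS by direct definition: repeatedly take the most confident
# remaining box (ties: lower x0, then y0) and drop overlapping ones
oracle_nms <- function(det, thr) {
  det$confidence <- pmax(det$s_benign, det$s_malignant)
  remaining <- seq_len(nrow(det))
  kept <- integer(0)
  while (length(remaining) > 0L) {
    best <- remaining[1L]
    for (i in remaining) {
      if (det$confidence[i] > det$confidence[best] ||
          (det$confidence[i] == det$confidence[best] &&
           (det$x0[i] < det$x0[best] ||
            (det$x0[i] == det$x0[best] && det$y0[i] < det$y0[best]))))
        best <- i
    }
    kept <- c(kept, best)
    remaining <- setdiff(remaining, best)
    ba <- c(x0 = det$x0[best], y0 = det$y0[best],
            x1 = det$x1[best], y1 = det$y1[best])
    drop <- c()
    for (i in remaining) {
      bi <- c(x0 = det$x0[i], y0 = det$y0[i], x1 = det$x1[i], y1 = det$y1[i])
      ix <- min(ba[["x1"]], bi[["x1"]]) - max(ba[["x0"]], bi[["x0"]])
      iy <- min(ba[["y1"]], bi[["y1"]]) - max(ba[["y0"]], bi[["y0"]])
      inter <- max(ix, 0) * max(iy, 0)
      un <- (ba[["x1"]] - ba[["x0"]]) * (ba[["y1"]] - ba[["y0"]]) +
        (bi[["x1"]] - bi[["x0"]]) * (bi[["y1"]] - bi[["y0"]]) - inter
      if (inter / un > thr) drop <- c(drop, i)
    }
    remaining <- setdiff(remaining, drop)
  }
  det[kept, , drop = FALSE]
}

# majority vote by explicit counting
oracle_majority <- function(categories) {
  n_m <- sum(categories == "malignant")
  n_b <- sum(categories == "benign")
  if (n_m >= n_b) "malignant" else "benign"
}

# AUC by O(P*N) pair counting with tie half-credit
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == "malignant"]
  neg <- scores[labels != "malignant"]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}
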