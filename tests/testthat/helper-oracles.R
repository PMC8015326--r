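# Independent oracles used to check the package's fast implementations.
# These deliberately use brute force / enumeration, never the code under test.

# IoU of two integer boxes by explicit pixel rasterisation.
oracle_iou <- function(a, b) {
  pix <- function(box) {
    as.vector(outer(seq(box[1], box[3] - 1), seq(box[2], box[4] - 1),
                    function(x, y) x * 1e6 + y))
  }
  pa <- pix(a)
  pb <- pix(b)
  inter <- length(intersect(pa, pb))
  inter / (length(pa) + length(pb) - inter)
}

# Globally optimal one-to-one matching (maximum number of pairs, ties broken
# by total IoU) by exhaustive enumeration; only usable for tiny instances.
oracle_optimal_match_count <- function(iou, threshold) {
  nd <- nrow(iou)
  na <- ncol(iou)
  best <- 0L
  recurse <- function(di, used) {
    if (di > nd) return(0L)
    top <- recurse(di + 1L, used)  # leave detection di unmatched
    for (ai in seq_len(na)) {
      if (!used[ai] && iou[di, ai] >= threshold) {
        used2 <- used
        used2[ai] <- TRUE
        top <- max(top, 1L + recurse(di + 1L, used2))
      }
    }
    top
  }
  if (nd == 0L || na == 0L) return(0L)
  recurse(1L, rep(FALSE, na))
}

# Average precision by an exhaustive threshold sweep: for each achieved
# recall level, take the best precision at any threshold reaching it.
oracle_ap_sweep <- function(conf, is_tp, n_pos) {
  if (n_pos == 0L) return(NA_real_)
  ord <- order(-conf, seq_along(conf))
  is_tp <- is_tp[ord]
  precisions <- cumsum(is_tp) / seq_along(is_tp)
  recalls <- cumsum(is_tp) / n_pos
  ap <- 0
  prev_r <- 0
  for (k in seq_len(n_pos)) {
    r <- k / n_pos
    reachable <- which(recalls >= r)
    if (!length(reachable)) break
    ap <- ap + (r - prev_r) * max(precisions[reachable])
    prev_r <- r
  }
  ap
}

# Two-sided paired signed-rank p-value by full enumeration of sign vectors.
oracle_wilcoxon_enum <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- apply(signs, 1, function(s) sum(r[s]))
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Random valid integer box within a square grid.
random_box <- function(grid = 200L, max_side = 60L) {
  w <- sample.int(max_side, 1L)
  h <- sample.int(max_side, 1L)
  x <- sample.int(grid - w, 1L) - 1L
  y <- sample.int(grid - h, 1L) - 1L
  c(x, y, x + w, y + h)
}

# Random annotation + random detections (not derived from the annotation),
# used for conservation property tests.
random_eval_case <- function(n_ann, n_det, width = 200L, height = 200L) {
  mk <- function(n) {
    if (n == 0L) return(NULL)
    t(replicate(n, random_box(min(width, height))))
  }
  ab <- mk(n_ann)
  ann <- worm_annotation(
    "case", width, height,
    if (is.null(ab)) wormscore:::empty_objects() else data.frame(
      x_min = ab[, 1], y_min = ab[, 2], x_max = ab[, 3], y_max = ab[, 4],
      class = sample(worm_classes(), n_ann, replace = TRUE)
    )
  )
  db <- mk(n_det)
  det <- worm_detections(
    "case",
    if (is.null(db)) wormscore:::empty_detections() else data.frame(
      class = sample(worm_classes(), n_det, replace = TRUE),
      x_min = db[, 1], y_min = db[, 2], x_max = db[, 3], y_max = db[, 4],
      confidence = round(runif(n_det), 3)
    )
  )
  list(ann = ann, det = det)
}

# Per-image class counts (internal helper surfaced for truth tables).
count_classes_public <- function(x) wormscore:::count_classes(x)
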