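#' Discrete intensity distribution of an image
#'
#' Bins all pixel/voxel intensities into `n_bins` equal-width bins over
#' `value_range` (values outside the range are clipped into the end
#' bins) and normalizes to probabilities. This is the `P(x)` used by the
#' histogram distribution distances.
#'
#' @param x numeric array.
#' @param n_bins number of bins (>= 2); default 256.
#' @param value_range `c(min, max)` intensity range covered by the bins.
#' @return An object of class `"intensity_histogram"`: list with
#'   `bin_edges` (length `n_bins + 1`), `p` (probabilities summing to
#'   1) and `n` (number of contributing values).
#' @export
intensity_histogram <- function(x, n_bins = 256, value_range = c(0, 1)) {
  if (length(x) == 0) stop("empty input", call. = FALSE)
  if (n_bins < 2) stop("need at least 2 bins", call. = FALSE)
  if (value_range[2] <= value_range[1]) stop("degenerate value_range", call. = FALSE)
  edges <- seq(value_range[1], value_range[2], length.out = n_bins + 1)
  v <- pmin(pmax(as.numeric(x), value_range[1]), value_range[2])
  bin <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  structure(list(bin_edges = edges, p = counts / length(v), n = length(v)),
            class = "intensity_histogram")
}

as_prob <- function(x) {
  p <- if (inherits(x, "intensity_histogram")) x$p else as.numeric(x)
  if (any(p < 0)) stop("negative probabilities", call. = FALSE)
  s <- sum(p)
  if (s <= 0) stop("empty distribution", call. = FALSE)
  p / s
}

check_aligned <- function(P, Q) {
  if (inherits(P, "intensity_histogram") && inherits(Q, "intensity_histogram") &&
      !isTRUE(all.equal(P$bin_edges, Q$bin_edges)))
    stop("histograms have different bins", call. = FALSE)
  if (length(as_prob(P)) != length(as_prob(Q)))
    stop("distributions have different numbers of bins", call. = FALSE)
  invisible(TRUE)
}

#' Bhattacharyya distance between two intensity distributions
#'
#' \eqn{D_B = -\ln \sum_i \sqrt{P_i Q_i}}: zero iff the distributions
#' are identical, symmetric in its arguments. When the supports are
#' truly disjoint the overlap is zero and `Inf` is returned.
#'
#' @param P,Q probability vectors or [intensity_histogram()] objects
#'   over aligned bins.
#' @return Non-negative real (possibly `Inf`).
#' @export
bhattacharyya <- function(P, Q) {
  check_aligned(P, Q)
  p <- as_prob(P); q <- as_prob(Q)
  bc <- sum(sqrt(p * q))
  if (bc == 0) return(Inf)
  max(0, -log(min(bc, 1)))
}

#' Kullback-Leibler divergence between two intensity distributions
#'
#' \eqn{D_{KL}(P\,\|\,Q) = \sum_i P_i \ln(P_i / Q_i)} in nats
#' (natural log). Not symmetric: `P` is the reference distribution.
#' Zero bins are smoothed by adding `eps` to every bin of both
#' distributions and renormalizing, which keeps small divergences
#' stable; if `Q` has no mass anywhere `P` does even before smoothing
#' (disjoint supports), `Inf` is returned.
#'
#' @param P,Q probability vectors or [intensity_histogram()] objects
#'   over aligned bins.
#' @param eps smoothing mass added per bin (default 1e-10).
#' @return Non-negative real (possibly `Inf`).
#' @export
kl_divergence <- function(P, Q, eps = 1e-10) {
  check_aligned(P, Q)
  p <- as_prob(P); q <- as_prob(Q)
  if (all(q[p > 0] == 0)) return(Inf)
  p <- (p + eps) / sum(p + eps)
  q <- (q + eps) / sum(q + eps)
  max(0, sum(p * log(p / q)))
}

#' Peak signal-to-noise ratio
#'
#' With intensities in `[0, 1]` (peak 1) and
#' \eqn{MSE = \frac1n \sum (x - \hat x)^2}, the `"paper"` convention
#' evaluates \eqn{20 \log_{10}(1/MSE)} and the `"standard"` convention
#' the usual \eqn{10 \log_{10}(1/MSE)}. Identical inputs give `Inf`.
#' Reports should always name the convention used.
#'
#' @param x,ref equally shaped arrays in `[0, 1]`.
#' @param convention `"paper"` (default) or `"standard"`.
#' @return PSNR in dB (`Inf` for identical inputs).
#' @export
psnr <- function(x, ref, convention = c("paper", "standard")) {
  convention <- match.arg(convention)
  stop_if_shape_mismatch(x, ref)
  mse <- mean((x - ref)^2)
  if (mse == 0) return(Inf)
  (if (convention == "paper") 20 else 10) * log10(1 / mse)
}

#' Zero-normalized cross-correlation
#'
#' \eqn{\frac1n \sum \frac{(a - \mu_a)}{\sigma_a} \cdot
#' \frac{(b - \mu_b)}{\sigma_b}} with population standard deviations:
#' 1 for inputs identical up to a positive affine rescale, -1 for
#' negated structure, 0 for uncorrelated content.
#'
#' @param a,b equally shaped non-constant arrays.
#' @return Real in `[-1, 1]`.
#' @export
zncc <- function(a, b) {
  stop_if_shape_mismatch(a, b)
  n <- length(a)
  sa <- sqrt(mean((a - mean(a))^2))
  sb <- sqrt(mean((b - mean(b))^2))
  if (sa == 0 || sb == 0)
    stop("zero-spread input: ZNCC undefined for constant images", call. = FALSE)
  v <- mean((a - mean(a)) / sa * (b - mean(b)) / sb)
  min(max(v, -1), 1)
}

#' Intersection over union of binary masks
#'
#' \eqn{|y_{pred} \cap y_{gt}| / |y_{pred} \cup y_{gt}|}. An empty
#' union (both masks empty) is defined as 0 and flagged with the
#' attribute `empty_union`.
#'
#' @param pred_mask,gt_mask equally shaped logical (or 0/1) arrays.
#' @return Real in `[0, 1]`.
#' @export
iou <- function(pred_mask, gt_mask) {
  stop_if_shape_mismatch(pred_mask, gt_mask)
  p <- pred_mask > 0; g <- gt_mask > 0
  u <- sum(p | g)
  if (u == 0) return(structure(0, empty_union = TRUE))
  sum(p & g) / u
}

#' Per-instance IoU with greedy overlap matching
#'
#' Matches each ground-truth label to a predicted label by maximal voxel
#' overlap (greedy, largest overlaps first, each predicted label used at
#' most once) and reports the IoU per ground-truth instance; unmatched
#' instances score 0.
#'
#' @param pred_labels,gt_labels equally shaped integer label arrays
#'   (0 = background).
#' @return Data frame with columns `gt_label`, `pred_label` (`NA` when
#'   unmatched) and `iou`.
#' @export
matched_instance_iou <- function(pred_labels, gt_labels) {
  stop_if_shape_mismatch(pred_labels, gt_labels)
  g <- as.integer(gt_labels); p <- as.integer(pred_labels)
  gt_ids <- setdiff(sort(unique(g)), 0L)
  if (!length(gt_ids))
    return(data.frame(gt_label = integer(0), pred_label = integer(0),
                      iou = numeric(0)))
  both <- g > 0L & p > 0L
  ov <- if (any(both)) as.data.frame(table(gt = g[both], pred = p[both]),
                                     stringsAsFactors = FALSE)
        else data.frame(gt = integer(0), pred = integer(0), Freq = integer(0))
  ov <- ov[ov$Freq > 0, , drop = FALSE]
  ov <- ov[order(-ov$Freq), , drop = FALSE]
  match_of <- stats::setNames(rep(NA_integer_, length(gt_ids)), gt_ids)
  used_pred <- integer(0)
  for (r in seq_len(nrow(ov))) {
    gi <- ov$gt[r]; pi_ <- as.integer(ov$pred[r])
    if (!is.na(match_of[gi]) || pi_ %in% used_pred) next
    match_of[gi] <- pi_
    used_pred <- c(used_pred, pi_)
  }
  res <- lapply(gt_ids, function(gi) {
    pm <- match_of[as.character(gi)]
    if (is.na(pm)) return(data.frame(gt_label = gi, pred_label = NA_integer_, iou = 0))
    inter <- sum(g == gi & p == pm)
    union <- sum(g == gi | p == pm)
    data.frame(gt_label = gi, pred_label = pm, iou = inter / union)
  })
  do.call(rbind, res)
}
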