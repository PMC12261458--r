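# Quality / privacy metrics for synthetic cohorts.
#
# All metrics operate on point sets: plain matrices (rows = samples) or
# gene_embedding objects, which are flattened to their live coefficient
# slots (the space the generator works in).

as_point_matrix <- function(x) {
  if (inherits(x, "gene_embedding")) {
    m <- flatten_batch(x$tensor)
    m[, as.vector(x$clamp_mask) == 1, drop = FALSE]
  } else if (inherits(x, "genotype_matrix")) {
    x$values
  } else {
    as.matrix(x)
  }
}

# full pairwise distance matrix between rows of A and rows of B
pairwise_distances <- function(A, B, metric = c("l2", "l1", "cosine")) {
  metric <- match.arg(metric)
  if (metric == "l2") {
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
    sqrt(pmax(d2, 0))
  } else if (metric == "l1") {
    D <- matrix(0, nrow(A), nrow(B))
    for (i in seq_len(nrow(A)))
      D[i, ] <- colSums(abs(t(B) - A[i, ]))
    D
  } else {
    na <- sqrt(rowSums(A^2))
    nb <- sqrt(rowSums(B^2))
    sim <- tcrossprod(A, B) / (na %o% nb)
    D <- 1 - sim
    # zero-norm rows have undefined angle; define distance 1
    D[na == 0, ] <- 1
    D[, nb == 0] <- 1
    D
  }
}

nn_cross <- function(A, B, metric) {
  apply(pairwise_distances(A, B, metric), 1, min)
}

nn_within <- function(A, metric) {
  D <- pairwise_distances(A, A, metric)
  diag(D) <- Inf          # leave-one-out: a point is not its own neighbour
  apply(D, 1, min)
}

#' Nearest-neighbour adversarial accuracy
#'
#' For every truth point, compare its nearest-neighbour distance into the
#' synthetic set against its nearest-neighbour distance within the truth set
#' (excluding itself); `AA_truth` is the fraction for which the cross-set
#' neighbour is strictly farther. `AA_syn` is the symmetric quantity.
#' Values near 0.5 mean the metric cannot tell the sets apart; values near 0
#' indicate copying/overfitting, values near 1 underfitting. When set sizes
#' differ, the larger set is subsampled without replacement to the smaller
#' (seeded), so neighbourhood densities are comparable.
#'
#' @param truth,syn point sets (matrix, [gene_embedding()], or
#'   [genotype_matrix()]), at least 2 points each, equal dimensionality.
#' @param metric `"l2"`, `"l1"` or `"cosine"`.
#' @param seed seed for the size-matching subsample.
#' @return an `nnaa_report` list with `AA_truth`, `AA_syn`, `metric`,
#'   `n_truth`, `n_syn`, `seed`.
#' @export
adversarial_accuracy <- function(truth, syn, metric = "l2", seed = 1L) {
  A <- as_point_matrix(truth)
  B <- as_point_matrix(syn)
  gd_assert(ncol(A) == ncol(B),
            "dimension mismatch: ", ncol(A), " vs ", ncol(B))
  gd_assert(nrow(A) >= 2 && nrow(B) >= 2, "each set needs at least 2 points")
  m <- min(nrow(A), nrow(B))
  with_local_seed(seed, {
    if (nrow(A) > m) A <- A[sample.int(nrow(A), m), , drop = FALSE]
    if (nrow(B) > m) B <- B[sample.int(nrow(B), m), , drop = FALSE]
  })
  d_ts <- nn_cross(A, B, metric)
  d_tt <- nn_within(A, metric)
  d_st <- nn_cross(B, A, metric)
  d_ss <- nn_within(B, metric)
  structure(list(AA_truth = mean(d_ts > d_tt),
                 AA_syn = mean(d_st > d_ss),
                 metric = metric, n_truth = m, n_syn = m,
                 seed = as.integer(seed)),
            class = "nnaa_report")
}

#' @exportS3Method base::print
print.nnaa_report <- function(x, ...) {
  cat(sprintf("NNAA (%s, n=%d): AA_truth = %.3f, AA_syn = %.3f\n",
              x$metric, x$n_truth, x$AA_truth, x$AA_syn))
  invisible(x)
}

#' Privacy loss of a synthetic set
#'
#' `AA_truth` computed against the generator's training split minus
#' `AA_truth` computed against a held-out split, sharing the same synthetic
#' set and seed. A strongly negative value signals memorisation (the
#' synthetic points sit suspiciously close to training points). The
#' mean-based variant, using `(AA_truth + AA_syn) / 2` per split, is
#' reported as a secondary diagnostic; it can mask models whose under- and
#' overfitting cancel.
#'
#' @param train_truth,test_truth,syn point sets of equal dimensionality.
#' @param metric distance name.
#' @param seed subsampling seed shared by both comparisons.
#' @return list with `privacy_loss`, `privacy_loss_mean_aa`, and the two
#'   underlying `nnaa_report`s.
#' @export
privacy_loss <- function(train_truth, test_truth, syn, metric = "l2",
                         seed = 1L) {
  r_tr <- adversarial_accuracy(train_truth, syn, metric, seed)
  r_te <- adversarial_accuracy(test_truth, syn, metric, seed)
  list(privacy_loss = r_tr$AA_truth - r_te$AA_truth,
       privacy_loss_mean_aa =
         (r_tr$AA_truth + r_tr$AA_syn) / 2 - (r_te$AA_truth + r_te$AA_syn) / 2,
       train = r_tr, test = r_te)
}

#' Recovery rate of a synthetically trained classifier
#'
#' The ratio `R = a_s / a_r` between the test accuracy of a classifier
#' trained on synthetic data and the test accuracy of the same classifier
#' trained on the real data the generator saw. Values near 1 mean the
#' synthetic data carries essentially all task-relevant signal; values
#' above 1 can only arise from artifacts or noise.
#'
#' @param a_r real-data test accuracy, must be positive.
#' @param a_s synthetic-data test accuracy.
#' @param percent return `100 * R` (the usual reporting scale).
#' @return recovery rate.
#' @export
recovery_rate <- function(a_r, a_s, percent = FALSE) {
  gd_assert(a_r > 0, "real-data accuracy must be positive")
  r <- a_s / a_r
  if (percent) 100 * r else r
}

#' Audit a synthetic set for duplicates of real points
#'
#' For each of the L1, L2 and cosine distances: the minimum cross-set
#' distance, the arg-min pair, and the number of pairs below tolerance.
#' A count of zero for every metric certifies that no synthetic point
#' reproduces a real one.
#'
#' @param real,syn point sets, non-empty, equal dimensionality.
#' @param tol named tolerances per metric.
#' @return a `duplicate_report`: per-metric list with `min`, `pair`
#'   (real index, syn index) and `n_below`, plus `n_duplicates`
#'   (the L2 count).
#' @export
duplicate_audit <- function(real, syn,
                            tol = c(l1 = 1e-6, l2 = 1e-6, cosine = 1e-8)) {
  A <- as_point_matrix(real)
  B <- as_point_matrix(syn)
  gd_assert(nrow(A) >= 1 && nrow(B) >= 1, "sets must be non-empty")
  gd_assert(ncol(A) == ncol(B), "dimension mismatch")
  out <- list()
  for (metric in c("l1", "l2", "cosine")) {
    D <- pairwise_distances(A, B, metric)
    k <- arrayInd(which.min(D), dim(D))
    out[[metric]] <- list(min = min(D),
                          pair = c(real = k[1], syn = k[2]),
                          n_below = sum(D < tol[[metric]]))
  }
  out$n_duplicates <- out$l2$n_below
  class(out) <- "duplicate_report"
  out
}

#' @exportS3Method base::print
print.duplicate_report <- function(x, ...) {
  for (m in c("l1", "l2", "cosine"))
    cat(sprintf("%-6s min = %.4g (real %d, syn %d), %d below tolerance\n",
                m, x[[m]]$min, x[[m]]$pair[1], x[[m]]$pair[2], x[[m]]$n_below))
  invisible(x)
}
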