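#' Derive a stage-specific sub-seed from a global seed
#'
#' All stochastic stages draw their RNG state from one global integer seed.
#' Each stage perturbs the seed with a deterministic hash of its stage name,
#' so that stages are mutually independent streams yet the whole run is
#' reproducible from a single integer. The hash is the sum of the UTF-8 code
#' points of the stage name weighted by position, folded with the seed by
#' `(seed * 7919 + hash) mod (2^31 - 1)`.
#'
#' @param seed integer global seed.
#' @param stage character scalar naming the stage (e.g. `"ibp"`).
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer(((as.numeric(seed) %% 2147483647) * 7919 + h) %% 2147483647)
}

#' Vectorize the upper triangle of a symmetric matrix
#'
#' Edges are taken in row-major upper-triangle order of the fixed ROI
#' ordering: (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n). This is the
#' bijection used for all length-`n(n-1)/2` fingerprints in the package.
#'
#' @param m symmetric numeric matrix with unit diagonal.
#' @return Numeric vector of length `n(n-1)/2`.
#' @seealso [devectorize()]
#' @export
vectorize_upper <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > 1e-8) stop("matrix is not symmetric")
  if (max(abs(diag(m) - 1)) > 1e-8) stop("matrix does not have a unit diagonal")
  t(m)[lower.tri(t(m))]
}

#' Rebuild a symmetric unit-diagonal matrix from its upper-triangle vector
#'
#' @param v numeric vector of length `n_rois * (n_rois - 1) / 2`.
#' @param n_rois number of ROIs (matrix dimension).
#' @return `n_rois x n_rois` symmetric matrix with unit diagonal.
#' @export
devectorize <- function(v, n_rois) {
  expect_len <- n_rois * (n_rois - 1) / 2
  if (length(v) != expect_len) {
    stop(sprintf("vector length %d is not the triangular number %d for %d ROIs",
                 length(v), expect_len, n_rois))
  }
  idx <- which(upper.tri(diag(n_rois)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  m2 <- diag(nrow = n_rois)
  m2[idx] <- v
  m2[idx[, c(2, 1), drop = FALSE]] <- v
  m2
}

#' Edge names for a fixed ROI ordering
#'
#' @param roi_names character vector of ROI identifiers.
#' @return Character vector `"ROIa__ROIb"` in upper-triangle order.
#' @export
edge_names <- function(roi_names) {
  n <- length(roi_names)
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  paste0(roi_names[idx[, 1]], "__", roi_names[idx[, 2]])
}

#' The 21-node DMN/DAN/SN network ROI ordering
#'
#' Fixed ordering of the 21 regions of interest spanning the default mode
#' network (four dmPFC and four PMC subregions, two subregions in each
#' temporoparietal junction), the dorsal attention network (bilateral dlPFC
#' and IPS) and the salience network (bilateral anterior insula, a single
#' midline midcingulate node, bilateral amygdala). 21 nodes give
#' `choose(21, 2) = 210` edges.
#'
#' @return Character vector of 21 ROI names.
#' @export
default_roi_names <- function() {
  c(paste0("dmPFC", 1:4), paste0("PMC", 1:4),
    paste0("L_TPJ", 1:2), paste0("R_TPJ", 1:2),
    "L_dlPFC", "R_dlPFC", "L_IPS", "R_IPS",
    "L_AI", "R_AI", "MCC", "L_AM", "R_AM")
}

#' Left-order a binary matrix
#'
#' Canonical column ordering of a binary feature matrix: columns sorted by
#' the binary number they encode reading rows top-to-bottom (most significant
#' bit = first row), descending; ties broken by the first active row. Removes
#' the column-permutation ambiguity of latent feature models.
#'
#' @param Z binary matrix (subjects x features).
#' @return `Z` with columns permuted into left-ordered form.
#' @export
left_order <- function(Z) {
  if (ncol(Z) <= 1L) return(Z)
  keys <- apply(Z, 2, function(col) paste(col, collapse = ""))
  first_active <- apply(Z, 2, function(col) {
    w <- which(col == 1); if (length(w)) w[1] else nrow(Z) + 1L
  })
  Z[, order(keys, first_active, decreasing = c(TRUE, FALSE), method = "radix"),
    drop = FALSE]
}

# Exact linear-assignment by permutation enumeration (k <= 8), minimizing
# total cost; greedy fallback for larger problems. Returns for each row the
# assigned column.
solve_assignment <- function(cost) {
  k <- nrow(cost)
  stopifnot(ncol(cost) == k)
  if (k <= 8L) {
    perms <- all_permutations(k)
    totals <- apply(perms, 1, function(p) sum(cost[cbind(seq_len(k), p)]))
    perms[which.min(totals), ]
  } else {
    assigned <- integer(k)
    free <- seq_len(k)
    for (i in order(apply(cost, 1, min))) {
      j <- free[which.min(cost[i, free])]
      assigned[i] <- j
      free <- setdiff(free, j)
    }
    assigned
  }
}

all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                            sub[, seq(pos, k - 1L)[seq_len(k - pos)],
                                drop = FALSE]))
  }
  storage.mode(out) <- "integer"
  out
}

#' Match factors between two models by correlation
#'
#' Resolves label switching: finds the permutation of the rows of `mat`
#' maximizing the summed Pearson correlation with the rows of `ref`
#' (exact assignment for k <= 8). Rows typically hold per-factor
#' distributions or edge-weight maps.
#'
#' @param mat,ref numeric matrices with the same shape, factors in rows.
#' @return Integer permutation `p` such that `mat[p, ]` aligns with `ref`.
#' @export
match_factors <- function(mat, ref) {
  stopifnot(nrow(mat) == nrow(ref), ncol(mat) == ncol(ref))
  k <- nrow(mat)
  cost <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      ci <- stats::sd(ref[i, ]); cj <- stats::sd(mat[j, ])
      cost[i, j] <- if (ci > 0 && cj > 0) -stats::cor(ref[i, ], mat[j, ]) else 0
    }
  }
  solve_assignment(cost)
}

# Optimal column matching of two binary matrices by Hamming distance.
# Pads the narrower matrix with all-zero columns. Returns the total number
# of mismatched cells under the best pairing and the normalizing cell count.
match_binary_columns <- function(Z, Z_ref) {
  n <- nrow(Z)
  stopifnot(nrow(Z_ref) == n)
  K <- max(ncol(Z), ncol(Z_ref))
  pad <- function(M) cbind(M, matrix(0, n, K - ncol(M)))
  A <- pad(Z); B <- pad(Z_ref)
  cost <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    cost[i, j] <- sum(B[, i] != A[, j])
  }
  p <- solve_assignment(cost)
  list(mismatches = sum(cost[cbind(seq_len(K), p)]),
       cells = n * K, permutation = p)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
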