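# Postural synergy analysis: PCA over average reaching postures (centered,
# unscaled — all seven dimensions are joint angles in degrees, hence
# directly comparable) and principal-angle distances between the subspaces
# spanned by the leading components of two groups.

#' PCA of average reaching postures
#'
#' Principal components analysis on the mean-centered, unscaled 7-D posture
#' rows; returns the seven components (orthonormal loadings) and the
#' explained-variance ratios.
#'
#' @param postures Data frame from [average_reaching_postures()] or a
#'   numeric matrix with the seven DoF columns.
#' @return A list of class `synergy_result`: `group`, `components` (7 x 7
#'   orthonormal matrix, columns sorted by decreasing variance),
#'   `ev_ratio` (length 7, sums to 1), `n`.
#' @export
run_pca <- function(postures) {
  if (is.data.frame(postures)) {
    group <- if ("group" %in% names(postures) && nrow(postures))
      as.character(postures$group[1]) else NA_character_
    M <- as.matrix(postures[, DOF_NAMES])
  } else {
    group <- NA_character_
    M <- as.matrix(postures)
  }
  if (nrow(M) < 2) stop("need at least 2 postures for PCA")
  if (nrow(M) < 8) {
    warning("fewer postures (", nrow(M), ") than dimensions; ",
            "trailing components are degenerate")
  }
  p <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  comps <- p$rotation
  if (ncol(comps) < 7) {  # pad degenerate case with an orthonormal completion
    comps <- qr.Q(qr(cbind(comps, diag(7))))[, 1:7]
    ev <- c(ev, rep(0, 7 - length(ev)))
  }
  structure(list(group = group, components = comps,
                 ev_ratio = ev / sum(ev), n = nrow(M)),
            class = "synergy_result")
}

#' Cumulated explained-variance ratio
#'
#' @param result A `synergy_result`.
#' @param n Number of leading components (1-7).
#' @return Sum of the first `n` explained-variance ratios.
#' @export
cumulative_ev <- function(result, n) {
  stopifnot(inherits(result, "synergy_result"))
  if (n < 1 || n > 7) stop("n must be between 1 and 7")
  sum(result$ev_ratio[seq_len(n)])
}

subspace_basis <- function(x, n) {
  B <- if (inherits(x, "synergy_result")) x$components else as.matrix(x)
  if (n > ncol(B)) stop("n exceeds the available components")
  B[, seq_len(n), drop = FALSE]
}

#' Angular distance between principal-component subspaces
#'
#' The minimal rotation angle separating the spans of the first `n`
#' components of two PCAs: the largest principal angle between the two
#' subspaces, computed as arccos of the smallest singular value of A'B for
#' orthonormal bases A and B. 0 degrees means identical spans, 90 degrees
#' mutually orthogonal subspaces; the value is symmetric in its arguments
#' and invariant to any orthonormal re-basis (including sign flips) of
#' either subspace.
#'
#' @param a,b `synergy_result` objects (or orthonormal basis matrices with
#'   at least `n` columns).
#' @param n Subspace dimension; the analysis focuses on 3-5 (values outside
#'   warn).
#' @return Angle in degrees, in `[0, 90]`.
#' @export
subspace_distance <- function(a, b, n = 3) {
  if (n < 3 || n > 5) {
    warning("subspace dimension outside the 3-5 analysis range")
  }
  A <- subspace_basis(a, n)
  B <- subspace_basis(b, n)
  s <- svd(crossprod(A, B))$d
  rad2deg(acos(pmin(1, pmax(0, min(s)))))
}
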