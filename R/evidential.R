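# Dirichlet evidential primitives.
#
# Per-pixel class evidence e_k >= 0 parameterizes a Dirichlet distribution
# with concentrations alpha_k = e_k + 1, so alpha_k >= 1 always. The total
# evidence S = sum_k alpha_k yields the epistemic uncertainty U = K/S
# (U = 1 at total ignorance, U -> 0 as evidence accumulates), and the
# expected class probability is the Dirichlet mean p_k = alpha_k / S.
# Equal probabilities do not imply equal uncertainty: p only fixes the
# ratios of alpha, while U depends on their sum.

#' Map evidence logits to Dirichlet concentrations
#'
#' `alpha = 1 + softplus(logits)`, guaranteeing `alpha >= 1` elementwise.
#' The softplus evidence activation keeps gradients smooth at small batch
#' sizes (exponential activations are prone to evidence explosion).
#'
#' @param logits Numeric array; the last dimension (or column) indexes the
#'   `K` classes.
#' @return Array of the same shape with all values `>= 1`.
#' @export
evidence_to_alpha <- function(logits) {
  if (!all(is.finite(logits))) stop("non-finite evidence logits")
  sp <- ifelse(logits > 30, logits, log1p(exp(pmin(logits, 30))))
  out <- 1 + sp
  attributes(out) <- attributes(logits)
  out
}

#' Total evidence strength and epistemic uncertainty
#'
#' Computes `S = sum_k alpha_k` and `U = K/S` per pixel. `U = 1` iff all
#' `alpha_k = 1` (zero evidence); `U -> 0` as `S >> K`.
#'
#' @param alpha Array `(H, W, K)` or matrix `(n, K)` of Dirichlet
#'   concentrations, all `>= 1`.
#' @return List with `S` and `U` (each `(H, W)` or length-`n`).
#' @export
dirichlet_uncertainty <- function(alpha) {
  m <- alpha_as_matrix(alpha)
  if (any(m < 1 - 1e-9)) stop("Dirichlet concentrations must all be >= 1")
  k <- ncol(m)
  s <- rowSums(m)
  u <- k / s
  d <- dim(alpha)
  if (!is.null(d) && length(d) == 3) {
    s <- matrix(s, d[1], d[2])
    u <- matrix(u, d[1], d[2])
  }
  list(S = s, U = u)
}

#' Expected class probabilities under the Dirichlet
#'
#' The Dirichlet mean `p_k = alpha_k / S`; rows sum to 1.
#'
#' @inheritParams dirichlet_uncertainty
#' @return Same shape as `alpha`.
#' @export
expected_probability <- function(alpha) {
  m <- alpha_as_matrix(alpha)
  if (any(m < 1 - 1e-9)) stop("Dirichlet concentrations must all be >= 1")
  p <- m / rowSums(m)
  out <- p
  d <- dim(alpha)
  if (!is.null(d) && length(d) == 3) out <- array(p, d)
  out
}

alpha_as_matrix <- function(alpha) {
  d <- dim(alpha)
  if (is.null(d)) return(matrix(alpha, nrow = 1))
  if (length(d) == 2) return(alpha)
  if (length(d) == 3) return(matrix(alpha, d[1] * d[2], d[3]))
  stop("alpha must be a vector, matrix, or (H, W, K) array")
}
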