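#' Discrete-time Laguerre basis
#'
#' Constructs `order` discrete-time Laguerre functions of scale `alpha` by
#' the standard recurrence
#' \deqn{b_0(0) = \sqrt{1-\alpha},\quad b_0(n) = \sqrt{\alpha}\, b_0(n-1),}
#' \deqn{b_j(n) = \sqrt{\alpha}\, b_j(n-1) + \sqrt{\alpha}\, b_{j-1}(n) - b_{j-1}(n-1),}
#' then re-orthonormalizes the columns on the finite window by a
#' sign-fixed thin QR decomposition. The QR step spans the same function
#' space (so fitted impulse responses are unchanged) while making the
#' basis exactly orthonormal on the truncated window, where the raw
#' recurrence functions are orthonormal only on an infinite horizon.
#'
#' Larger `alpha` stretches the basis to longer decay times. When `alpha`
#' is too large for the window the truncated functions become numerically
#' dependent; this is detected through the smallest singular value of the
#' raw basis and reported as an error.
#'
#' @param alpha Scale parameter in (0, 1).
#' @param order Number of basis functions (1..30).
#' @param length Samples per basis function; must be >= order.
#' @return A [LaguerreBasis-class] with orthonormal columns.
#' @examples
#' b <- laguerreBasis(0.95, 12, 562)
#' max(abs(crossprod(basisMatrix(b)) - diag(12)))   # ~1e-15
#' @export
laguerreBasis <- function(alpha, order, length) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (order < 1 || order > 30) stop("order must lie in 1..30")
  length <- as.integer(length)
  order <- as.integer(order)
  if (length < order) stop("length must be >= order")
  Braw <- .laguerreRecurrence(alpha, order, length)
  sv <- svd(Braw, nu = 0, nv = 0)$d
  if (min(sv) < 1e-7 * max(sv))
    stop("alpha = ", alpha, " is too large for a window of ", length,
         " samples: truncated basis is numerically rank-deficient; ",
         "use a smaller alpha or a longer window")
  qrd <- qr(Braw)
  Q <- qr.Q(qrd)
  s <- sign(diag(qr.R(qrd)))
  s[s == 0] <- 1
  B <- sweep(Q, 2, s, `*`)
  new("LaguerreBasis", alpha = alpha, order = order, length = length, B = B)
}

# raw recurrence, columns j = 0 .. order-1
.laguerreRecurrence <- function(alpha, order, length) {
  B <- matrix(0, length, order)
  sa <- sqrt(alpha)
  b <- numeric(length)
  b[1] <- sqrt(1 - alpha)
  for (n in 2:length) b[n] <- sa * b[n - 1]
  B[, 1] <- b
  if (order > 1) {
    for (j in 2:order) {
      prev <- B[, j - 1]
      b <- numeric(length)
      b[1] <- sa * prev[1]
      for (n in 2:length) b[n] <- sa * b[n - 1] + sa * prev[n] - prev[n - 1]
      B[, j] <- b
    }
  }
  B
}
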