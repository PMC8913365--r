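#' Non-negative least squares (active-set)
#'
#' Minimises `||y - X b||^2` subject to `b >= 0` with the Lawson-Hanson
#' active-set algorithm. With at most a dozen columns (the 11 lag terms of
#' the distributed-lag regression) the algorithm terminates exactly in a
#' handful of iterations and is fully deterministic.
#'
#' @param X design matrix.
#' @param y response vector.
#' @param tol dual-feasibility tolerance, scaled by the magnitude of
#'   `X'y` (default 1e-10).
#' @return list with `beta` (non-negative coefficients), `objective`
#'   (residual sum of squares) and `rankDeficient` (TRUE if a passive-set
#'   subproblem was rank deficient and the minimum-norm solution was used).
#' @examples
#' X <- matrix(rnorm(40), 20, 2)
#' y <- X %*% c(1, 0) + rnorm(20, sd = 0.1)
#' nnlsFit(X, y)$beta
#' @export
nnlsFit <- function(X, y, tol = 1e-10) {
  X <- as.matrix(X); y <- as.numeric(y)
  p <- ncol(X)
  beta <- numeric(p)
  passive <- logical(p)
  rankDeficient <- FALSE
  g0 <- drop(crossprod(X, y))
  eps <- tol * max(1, max(abs(g0)))

  solvePassive <- function(idx) {
    Xp <- X[, idx, drop = FALSE]
    qrX <- qr(Xp)
    if (qrX$rank < length(idx)) {
      rankDeficient <<- TRUE
      sv <- svd(Xp)
      pos <- sv$d > max(dim(Xp)) * max(sv$d) * 1e-12
      drop(sv$v[, pos, drop = FALSE] %*%
             ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos]))
    } else {
      qr.coef(qrX, y)
    }
  }

  maxOuter <- 10L * p + 10L
  for (iter in seq_len(maxOuter)) {
    w <- drop(crossprod(X, y - X %*% beta))
    candidates <- which(!passive & w > eps)
    if (!length(candidates)) break
    passive[candidates[which.max(w[candidates])]] <- TRUE
    repeat {
      idx <- which(passive)
      z <- solvePassive(idx)
      if (all(z > 0)) { beta[] <- 0; beta[idx] <- z; break }
      neg <- z <= 0
      alpha <- min(beta[idx][neg] / (beta[idx][neg] - z[neg]))
      beta[idx] <- beta[idx] + alpha * (z - beta[idx])
      drop0 <- idx[beta[idx] <= eps * max(1, max(abs(beta)))]
      beta[drop0] <- 0
      passive[drop0] <- FALSE
      if (!any(passive)) break
    }
  }
  beta[beta < 0] <- 0
  r <- y - X %*% beta
  list(beta = beta, objective = sum(r^2), rankDeficient = rankDeficient)
}
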