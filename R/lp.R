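## Linear-programming layer.
##
## All constraint-based problems here have the form
##   optimize  c'x   s.t.  A x = b,  extra inequality rows,  lb <= x <= ub.
## solve_lp() appends a nonnegative surplus column per >= row and hands the
## equality system to the bounded-variable simplex (R/simplex.R). The
## conventional +/-1000 proxy stands in for unbounded flux, and LP_BIG
## substitutes for explicit infinities so that "unbounded" problems
## surface as optima at the proxy (flagged when the objective magnitude
## exceeds LP_UNBOUNDED_AT).

LP_BIG <- 1e6
LP_UNBOUNDED_AT <- 1e5

#' Solve a bounded linear program
#'
#' Front end to the bounded-variable simplex for problems with equality
#' rows, optional extra \code{>=} rows, and box bounds.
#'
#' @param obj objective coefficient vector.
#' @param A equality constraint matrix (may have zero rows).
#' @param b equality right-hand side.
#' @param lb,ub variable bounds; infinities are replaced by \code{+/-1e6}.
#' @param sense \code{"max"} or \code{"min"}.
#' @param ge_rows optional list with matrix \code{A} and vector \code{b}
#'   giving additional \code{A x >= b} rows.
#' @return list with \code{status} (\code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"}), \code{x}, \code{objective}.
#' @keywords internal
solve_lp <- function(obj, A, b, lb, ub, sense = c("max", "min"),
                     ge_rows = NULL) {
  sense <- match.arg(sense)
  n <- length(obj)
  lb <- ifelse(is.finite(lb), lb, -LP_BIG)
  ub <- ifelse(is.finite(ub), ub, LP_BIG)
  A <- as.matrix(A)
  if (nrow(A) > 0L && ncol(A) != n) stop("LP dimension mismatch")

  Ae <- A; be <- b
  cc <- obj; lbe <- lb; ube <- ub
  if (!is.null(ge_rows) && nrow(ge_rows$A) > 0L) {
    k <- nrow(ge_rows$A)
    # a'x >= d  becomes  a'x - s = d with surplus s >= 0
    Ae <- rbind(cbind(Ae, matrix(0, nrow(Ae), k)),
                cbind(as.matrix(ge_rows$A), -diag(k)))
    be <- c(be, ge_rows$b)
    cc <- c(cc, rep(0, k))
    lbe <- c(lbe, rep(0, k))
    ube <- c(ube, rep(Inf, k))
  }

  res <- bounded_simplex(cc, Ae, be, lbe, ube, sense = sense)
  if (res$status != "optimal")
    return(list(status = res$status, x = rep(NA_real_, n),
                objective = NA_real_))
  x <- res$x[seq_len(n)]
  objective <- sum(obj * x)
  status <- if (abs(objective) >= LP_UNBOUNDED_AT &&
                any(obj != 0 & (x <= lb + 1e-6 & lb <= -LP_BIG + 1 |
                                x >= ub - 1e-6 & ub >= LP_BIG - 1)))
    "unbounded" else "optimal"
  list(status = status, x = x, objective = objective)
}

#' Enumerate all basic feasible points of a flux polytope
#'
#' Brute-force oracle support: enumerates candidate vertices of
#' \code{\{x : A x = b, lb <= x <= ub\}} by choosing, for every subset of
#' \code{n - rank(A)} variables, a nonbasic value from \code{lb}, \code{ub}
#' and optionally \code{0} (for variables straddling zero -- needed when an
#' absolute-value objective refines the polytope along coordinate
#' hyperplanes), then solving for the remaining variables and keeping
#' feasible solutions. Intended for tiny instances only.
#'
#' @param A equality matrix; \code{b} right-hand side.
#' @param lb,ub finite bounds.
#' @param include_zero logical: add 0 as a nonbasic candidate where
#'   \code{lb < 0 < ub}.
#' @param tol feasibility tolerance.
#' @return matrix with one row per feasible basic point (possibly with
#'   duplicates), or a 0-row matrix when the polytope is empty.
#' @keywords internal
enumerate_basic_points <- function(A, b, lb, ub, include_zero = FALSE,
                                   tol = 1e-8) {
  A <- as.matrix(A)
  n <- ncol(A)
  lb <- ifelse(is.finite(lb), lb, -LP_BIG)
  ub <- ifelse(is.finite(ub), ub, LP_BIG)
  r <- if (nrow(A) > 0L) qr(A)$rank else 0L
  k <- n - r
  pts <- list()

  cand <- lapply(seq_len(n), function(i) {
    v <- unique(c(lb[i], ub[i]))
    if (include_zero && lb[i] < 0 && ub[i] > 0) v <- c(v, 0)
    v
  })

  if (k == 0L) {
    nb_sets <- list(integer(0))
  } else {
    nb_sets <- utils::combn(n, k, simplify = FALSE)
  }

  for (nb in nb_sets) {
    basic <- setdiff(seq_len(n), nb)
    AB <- A[, basic, drop = FALSE]
    qrB <- qr(AB)
    if (qrB$rank < length(basic)) next
    grid <- if (length(nb) == 0L) list(numeric(0)) else {
      do.call(function(...) {
        g <- expand.grid(..., KEEP.OUT.ATTRS = FALSE)
        lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ]))
      }, cand[nb])
    }
    for (vals in grid) {
      rhs <- if (length(nb) > 0L) b - drop(A[, nb, drop = FALSE] %*% vals) else b
      xB <- qr.coef(qrB, rhs)
      if (anyNA(xB)) next
      x <- numeric(n)
      x[nb] <- vals
      x[basic] <- xB
      if (any(x < lb - tol) || any(x > ub + tol)) next
      if (nrow(A) > 0L && max(abs(drop(A %*% x) - b)) > tol) next
      pts[[length(pts) + 1L]] <- pmin(pmax(x, lb), ub)
    }
  }
  if (length(pts) == 0L) return(matrix(numeric(0), nrow = 0, ncol = n))
  do.call(rbind, pts)
}
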