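## Bounded-variable primal simplex.
##
## Solves   min/max c'x   s.t.  A x = b,  lb <= x <= ub
## with a two-phase revised simplex over bounded variables: phase 1 adds
## signed artificial columns and minimizes their sum from a bound-feasible
## starting point; phase 2 fixes the artificials at zero and optimizes the
## true objective. Entering and leaving variables are chosen by Bland's
## smallest-index rule, which guarantees termination on the degenerate
## problems metabolic networks produce (S v = 0 systems are rank-deficient
## and massively degenerate). Dense linear algebra throughout: the
## problems this package solves have at most a few dozen variables.

bounded_simplex <- function(cc, A, b, lb, ub, sense = c("min", "max"),
                            eps = 1e-9, max_iter = 20000L) {
  sense <- match.arg(sense)
  n <- length(cc)
  A <- as.matrix(A)
  m <- nrow(A)
  obj_sign <- if (sense == "max") -1 else 1
  cost0 <- obj_sign * cc

  if (any(lb > ub + eps)) return(list(status = "infeasible",
                                      x = rep(NA_real_, n),
                                      objective = NA_real_))
  if (m == 0L) {
    x <- ifelse(cost0 > 0, lb, ifelse(cost0 < 0, ub, lb))
    return(list(status = "optimal", x = x, objective = sum(cc * x)))
  }

  # start each structural variable at its bound nearest zero
  start_upper <- abs(ub) < abs(lb)
  x <- ifelse(start_upper, ub, lb)
  r <- b - drop(A %*% x)
  Dm <- matrix(0, m, m)
  Dm[cbind(seq_len(m), seq_len(m))] <- ifelse(r >= 0, 1, -1)

  Ae <- cbind(A, Dm)
  lbe <- c(lb, rep(0, m))
  ube <- c(ub, rep(Inf, m))
  xe <- c(x, abs(r))
  at_upper <- c(start_upper, rep(FALSE, m))
  basis <- n + seq_len(m)

  iterate <- function(cost) {
    for (it in seq_len(max_iter)) {
      B <- Ae[, basis, drop = FALSE]
      y <- tryCatch(solve(t(B), cost[basis]), error = function(e) NULL)
      if (is.null(y)) stop("simplex basis became singular")
      nb <- setdiff(seq_len(n + m), basis)
      nb <- nb[lbe[nb] < ube[nb]]  # fixed variables cannot move
      if (length(nb) == 0L) return("optimal")
      d <- cost[nb] - drop(crossprod(Ae[, nb, drop = FALSE], y))
      enter_ok <- (!at_upper[nb] & d < -eps) | (at_upper[nb] & d > eps)
      if (!any(enter_ok)) return("optimal")
      j <- min(nb[enter_ok])  # Bland
      dir <- if (at_upper[j]) -1 else 1
      w <- solve(B, Ae[, j])

      # ratio test: entering moves by t in direction dir, basics by -t*dir*w
      t_own <- ube[j] - lbe[j]
      t_best <- t_own
      leave_pos <- 0L  # 0 = bound-to-bound flip of the entering variable
      for (p in seq_len(m)) {
        g <- dir * w[p]
        bi <- basis[p]
        if (g > eps) {
          tp <- (xe[bi] - lbe[bi]) / g
        } else if (g < -eps) {
          tp <- (ube[bi] - xe[bi]) / (-g)
        } else next
        if (tp < t_best - eps ||
            (tp < t_best + eps && leave_pos > 0L && bi < basis[leave_pos])) {
          t_best <- tp
          leave_pos <- p
        }
      }
      if (!is.finite(t_best)) return("unbounded")
      t_best <- max(t_best, 0)

      xe[j] <<- xe[j] + dir * t_best
      xe[basis] <<- xe[basis] - dir * t_best * w
      if (leave_pos == 0L) {
        at_upper[j] <<- !at_upper[j]
        xe[j] <<- if (at_upper[j]) ube[j] else lbe[j]
      } else {
        out <- basis[leave_pos]
        g <- dir * w[leave_pos]
        at_upper[out] <<- g < 0
        xe[out] <<- if (at_upper[out]) ube[out] else lbe[out]
        basis[leave_pos] <<- j
        at_upper[j] <<- FALSE  # j is basic now; flag is irrelevant until it leaves
      }
    }
    stop("simplex iteration limit reached")
  }

  st1 <- iterate(c(rep(0, n), rep(1, m)))
  if (st1 != "optimal" || sum(xe[n + seq_len(m)]) > 1e-7 * (1 + max(abs(b))))
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objective = NA_real_))
  # pin artificials at zero and optimize the true objective
  ube[n + seq_len(m)] <- 0
  xe[n + seq_len(m)] <- pmax(pmin(xe[n + seq_len(m)], 0), 0)
  st2 <- iterate(c(cost0, rep(0, m)))
  if (st2 == "unbounded")
    return(list(status = "unbounded", x = rep(NA_real_, n),
                objective = if (sense == "max") Inf else -Inf))
  x <- xe[seq_len(n)]
  x <- pmin(pmax(x, lb), ub)
  list(status = "optimal", x = x, objective = sum(cc * x))
}
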