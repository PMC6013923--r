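# Linear programming core: a dense, bounded-variable, two-phase revised
# simplex. Flux-balance problems are small (a few hundred variables) but
# massively degenerate (the steady-state RHS is identically zero), so the
# implementation starts all nonbasic variables at the value nearest zero
# (which may be strictly inside their bounds; pricing is two-sided for such
# interior variables), uses Dantzig pricing with a Bland's-rule fallback
# once a degeneracy streak is detected, and refactorizes the basis by a
# fresh solve at every iteration — an O(m^3) step, cheap at this scale and
# immune to update drift.
#
# Problem form:  min/max c'x  s.t.  A x = b,  l <= x <= u  (l, u finite).

simplex_bounded <- function(c_vec, A, b, l, u,
                            maximize = FALSE,
                            tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(l) == n, length(u) == n,
            length(c_vec) == n, all(is.finite(l)), all(is.finite(u)))
  if (any(l > u + tol)) return(list(status = "infeasible"))
  if (maximize) c_vec <- -c_vec

  # nonbasic start values: as close to zero as the bounds allow
  x <- pmin(pmax(0, l), u)
  r <- b - as.vector(A %*% x)

  # artificial columns sign(r_i) e_i with start value |r_i| >= 0
  big <- sum(abs(b)) + sum(abs(r)) + 1
  Af <- cbind(A, diag(ifelse(r >= 0, 1, -1), m))
  lf <- c(l, rep(0, m)); uf <- c(u, rep(big, m))
  xf <- c(x, abs(r))
  nf <- n + m

  basis <- (n + 1L):nf
  in_basis <- logical(nf); in_basis[basis] <- TRUE

  phase <- 1L
  cost <- c(rep(0, n), rep(1, m))
  degen_streak <- 0L
  iter <- 0L

  recompute_basics <- function() {
    nb <- which(!in_basis)
    rhs <- b - as.vector(Af[, nb, drop = FALSE] %*% xf[nb])
    sol <- tryCatch(solve(Af[, basis, drop = FALSE], rhs),
                    error = function(e) NULL)
    if (!is.null(sol)) xf[basis] <<- sol
  }

  repeat {
    iter <- iter + 1L
    if (iter > max_iter) return(list(status = "iteration-limit"))

    B <- Af[, basis, drop = FALSE]
    y <- tryCatch(solve(t(B), cost[basis]), error = function(e) NULL)
    if (is.null(y)) return(list(status = "singular-basis"))
    d <- cost - as.vector(crossprod(Af, y))   # reduced costs

    nb <- which(!in_basis)
    movable <- nb[uf[nb] - lf[nb] > tol]
    at_lo <- xf[movable] <= lf[movable] + tol
    at_up <- xf[movable] >= uf[movable] - tol
    # improvement available: decrease cost by moving up (d<0) unless at
    # upper, or by moving down (d>0) unless at lower
    viol <- pmax(ifelse(at_up, 0, -d[movable]),
                 ifelse(at_lo, 0, d[movable]))

    if (!length(movable) || max(viol) <= tol) {
      if (phase == 1L) {
        if (sum(xf[(n + 1L):nf]) > 1e-7) return(list(status = "infeasible"))
        uf[(n + 1L):nf] <- 0
        cost <- c(c_vec, rep(0, m))
        phase <- 2L
        degen_streak <- 0L
        next
      }
      recompute_basics()
      xsol <- pmin(pmax(xf[seq_len(n)], l), u)
      obj <- sum(c_vec * xsol)
      return(list(status = "optimal",
                  x = xsol,
                  objective = if (maximize) -obj else obj))
    }

    # entering variable: Dantzig, or Bland after a degeneracy streak
    improving <- which(viol > tol)
    k_in <- if (degen_streak < 30L) improving[which.max(viol[improving])]
            else improving[which.min(movable[improving])]
    q <- movable[k_in]
    dir_sign <- if (at_up[k_in] || (!at_lo[k_in] && d[q] > 0)) -1 else 1

    w <- tryCatch(solve(B, Af[, q]), error = function(e) NULL)
    if (is.null(w)) return(list(status = "singular-basis"))

    # step t >= 0 moves x_q by dir_sign * t and x_B by t * delta
    delta <- -dir_sign * w
    t_own <- if (dir_sign > 0) uf[q] - xf[q] else xf[q] - lf[q]
    t_max <- t_own; leave <- 0L; leave_to <- NA_character_
    for (k in seq_len(m)) {
      j <- basis[k]
      if (delta[k] > tol) {
        tk <- (uf[j] - xf[j]) / delta[k]
        if (tk < t_max - 1e-12) { t_max <- tk; leave <- k; leave_to <- "upper" }
      } else if (delta[k] < -tol) {
        tk <- (lf[j] - xf[j]) / delta[k]
        if (tk < t_max - 1e-12) { t_max <- tk; leave <- k; leave_to <- "lower" }
      }
    }
    if (t_max < 0) t_max <- 0
    degen_streak <- if (t_max <= tol) degen_streak + 1L else 0L

    xf[q] <- xf[q] + dir_sign * t_max
    xf[basis] <- xf[basis] + t_max * delta

    if (leave == 0L) {
      # entering variable ran to its own bound; basis unchanged
      xf[q] <- if (dir_sign > 0) uf[q] else lf[q]
    } else {
      j_out <- basis[leave]
      basis[leave] <- q
      in_basis[q] <- TRUE
      in_basis[j_out] <- FALSE
      xf[j_out] <- if (identical(leave_to, "upper")) uf[j_out] else lf[j_out]
    }

    if (iter %% 200L == 0L) recompute_basics()
  }
}

# Solves  max/min  c'v  s.t.  S v = 0,  lb <= v <= ub,  [ineq_A v >= ineq_b].
# Inequalities are converted to equalities with bounded surplus variables.
solve_lp <- function(objective, S, lb, ub, maximize = TRUE,
                     ineq_A = NULL, ineq_b = NULL, tol = 1e-9) {
  n <- length(lb)
  stopifnot(length(ub) == n, length(objective) == n, ncol(S) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("LP requires finite flux bounds")
  }
  if (any(lb > ub)) {
    bad <- which(lb > ub)
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(if (!is.null(colnames(S))) colnames(S)[bad] else bad,
               collapse = ", "))
  }
  A <- as.matrix(S)
  b <- rep(0, nrow(A))
  cvec <- objective
  l <- lb; u <- ub
  if (!is.null(ineq_A)) {
    ineq_A <- matrix(ineq_A, ncol = n)
    k <- nrow(ineq_A)
    # A v - s = b with s in [0, span] encodes A v >= b
    span <- sum(abs(ineq_A) %*% pmax(abs(lb), abs(ub))) + sum(abs(ineq_b)) + 1
    A <- rbind(cbind(A, matrix(0, nrow(A), k)),
               cbind(ineq_A, -diag(1, k)))
    b <- c(b, ineq_b)
    cvec <- c(cvec, rep(0, k))
    l <- c(l, rep(0, k)); u <- c(u, rep(span, k))
  }
  res <- simplex_bounded(cvec, A, b, l, u, maximize = maximize, tol = tol)
  if (res$status != "optimal") {
    status <- if (res$status %in% c("infeasible", "iteration-limit"))
      res$status else "infeasible"
    return(list(status = status, objective = NA_real_,
                fluxes = stats::setNames(rep(NA_real_, n), colnames(S))))
  }
  v <- res$x[seq_len(n)]
  names(v) <- colnames(S)
  list(status = "optimal", objective = sum(objective * v), fluxes = v)
}
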