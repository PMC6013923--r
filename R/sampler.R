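#' Sampler configuration
#'
#' Defaults follow the reference study protocol: 2000 recorded points
#' with 500 hit-and-run iterations between consecutive records. By default
#' the ATP demand is constrained to at least 99% of its flux-balance maximum
#' before sampling, reconciling "maximal ATP production as objective" with
#' sampling of the steady-state space; set `optimality_fraction = 0` to
#' sample the unconstrained polytope.
#'
#' @param n_points Number of flux vectors to record.
#' @param steps_per_point ACHR iterations between recorded points.
#' @param n_warmup Number of warm-up points; default `2 *` the dimension of
#'   the sampled polytope, capped at 5000 (and never below dimension + 1).
#' @param seed Integer seed; the sampler is bit-reproducible given
#'   `(model, config)`.
#' @param tolerance Steady-state / bounds tolerance for validity checks.
#' @param optimality_fraction Fraction of the flux-balance optimum the
#'   objective is constrained to during sampling (0 disables).
#' @return A list of class `"sampler_config"`.
#' @export
sampler_config <- function(n_points = 2000, steps_per_point = 500,
                           n_warmup = NULL, seed = 1, tolerance = 1e-6,
                           optimality_fraction = 0.99) {
  for (field in c("n_points", "steps_per_point", "seed")) {
    v <- get(field)
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v != round(v)) {
      stop("sampler config: '", field, "' must be a positive integer")
    }
  }
  if (!is.null(n_warmup) &&
      (!is.numeric(n_warmup) || n_warmup <= 0 || n_warmup != round(n_warmup))) {
    stop("sampler config: 'n_warmup' must be a positive integer")
  }
  if (tolerance <= 0) stop("sampler config: 'tolerance' must be positive")
  if (optimality_fraction < 0 || optimality_fraction > 1) {
    stop("sampler config: 'optimality_fraction' must lie in [0, 1]")
  }
  structure(list(n_points = as.integer(n_points),
                 steps_per_point = as.integer(steps_per_point),
                 n_warmup = if (is.null(n_warmup)) NULL else as.integer(n_warmup),
                 seed = as.integer(seed), tolerance = tolerance,
                 optimality_fraction = optimality_fraction),
            class = "sampler_config")
}

# Structural bound propagation: a metabolite no reaction can produce (or
# consume) under the current bounds forces zero flux through all reactions
# touching it in the impossible direction. Iterated to a fixed point, this
# pins pathway chains that diet constraints shut (e.g. marine-FA chains
# under diets without EPA/DHA), so the sampled polytope becomes
# full-dimensional in the remaining directions.
propagate_forced_zero <- function(S, lb, ub) {
  repeat {
    changed <- FALSE
    produce <- (S > 0) & rep(ub > 0, each = nrow(S)) |
               (S < 0) & rep(lb < 0, each = nrow(S))
    consume <- (S < 0) & rep(ub > 0, each = nrow(S)) |
               (S > 0) & rep(lb < 0, each = nrow(S))
    no_prod <- !apply(produce, 1, any)
    no_cons <- !apply(consume, 1, any)
    for (i in which(no_prod)) {
      # consumption of metabolite i must vanish
      j_fwd <- which(S[i, ] < 0 & ub > 0)
      j_rev <- which(S[i, ] > 0 & lb < 0)
      if (length(j_fwd)) { ub[j_fwd] <- pmin(ub[j_fwd], 0); changed <- TRUE }
      if (length(j_rev)) { lb[j_rev] <- pmax(lb[j_rev], 0); changed <- TRUE }
    }
    for (i in which(no_cons)) {
      # production of metabolite i must vanish
      j_fwd <- which(S[i, ] > 0 & ub > 0)
      j_rev <- which(S[i, ] < 0 & lb < 0)
      if (length(j_fwd)) { ub[j_fwd] <- pmin(ub[j_fwd], 0); changed <- TRUE }
      if (length(j_rev)) { lb[j_rev] <- pmax(lb[j_rev], 0); changed <- TRUE }
    }
    if (!changed) break
  }
  list(lb = lb, ub = ub)
}

# Affine parameterization of the steady-state polytope:
#   v = v0 + N z on the non-fixed reactions, v fixed elsewhere,
#   with N an orthonormal null-space basis so S v = 0 holds to machine
#   precision along the whole chain, and the bounds (plus the optional
#   optimality face) expressed as A z <= b.
#
# After structural pruning an interior point is constructed from the
# flux-balance vertex plus random-objective vertices. Directions in which
# the trial point still touches a face are settled by targeted flux
# variability: reactions with zero range are pinned (implicit equalities
# that metabolite-level propagation cannot see, e.g. reversible-shuttle
# cycles), and the extreme vertices of the others are folded into the
# average until the point is strictly interior. Uses the RNG; callers seed.
polytope_setup <- function(model, optimality_fraction = 0, tolerance = 1e-6) {
  rxn_ids <- reaction_ids(model)
  lb <- lower_bounds(model); ub <- upper_bounds(model)
  S <- stoichiometric_matrix(model, sparse = FALSE)
  n <- length(rxn_ids)

  pr <- propagate_forced_zero(S, lb, ub)
  lb <- pr$lb; ub <- pr$ub

  obj <- as.numeric(rxn_ids == model$objective_reaction)
  ineq_A <- NULL; ineq_b <- NULL; target <- NULL
  if (optimality_fraction > 0) {
    sol <- fba_max_atp(model)
    if (sol$status != "optimal") {
      stop("cannot sample: flux balance problem is ", sol$status)
    }
    target <- optimality_fraction * sol$objective_value
    ineq_A <- matrix(obj, 1); ineq_b <- target
    v0 <- sol$fluxes
  } else {
    v0 <- NULL   # settled below once fixed reactions are known
  }

  geometry <- function() {
    fixed <- (ub - lb) <= tolerance * 1e-3
    v_fixed <- (lb + ub) / 2
    if (is.null(v0)) {
      v0 <- ifelse(fixed, v_fixed, pmin(pmax(0, lb), ub))
      if (max(abs(S %*% v0)) > 1e-9) {
        sol <- fba_max_atp(model)
        if (sol$status != "optimal") {
          stop("cannot sample: flux balance problem is ", sol$status)
        }
        v0 <- sol$fluxes
      }
    }
    free <- which(!fixed)
    S_free <- S[, free, drop = FALSE]
    sv <- svd(S_free, nu = 0, nv = ncol(S_free))
    rank <- sum(sv$d > max(dim(S_free)) * max(sv$d, 0) * 1e-12)
    d <- length(free) - rank
    N <- if (d > 0) sv$v[, seq(rank + 1, length(free)), drop = FALSE]
         else matrix(0, length(free), 0)
    A <- rbind(N, -N)
    b <- c(ub[free] - v0[free], v0[free] - lb[free])
    if (!is.null(target)) {
      A <- rbind(A, -matrix(obj[free], 1) %*% N)
      b <- c(b, sum(obj * v0) - target)
    }
    list(rxn_ids = rxn_ids, lb = lb, ub = ub, S = S,
         free = free, v_fixed = v_fixed, fixed = fixed,
         v0 = v0, N = N, dim = d, A = A, b = b,
         obj = obj, target = target,
         ineq_A = ineq_A, ineq_b = ineq_b, z0 = NULL)
  }

  extra_vs <- list()
  for (round in 1:6) {
    pt <- geometry()
    if (pt$dim == 0) return(pt)
    z0 <- interior_start(pt, extra_vs)
    slack <- pt$b - as.vector(pt$A %*% z0)
    nfree <- length(pt$free)
    tight <- which(slack[seq_len(2 * nfree)] < 1e-9)
    if (!length(tight)) {
      pt$z0 <- z0
      return(pt)
    }
    tight_rxns <- unique(pt$free[ifelse(tight > nfree, tight - nfree, tight)])
    pinned <- FALSE
    for (j in tight_rxns) {
      e <- as.numeric(seq_len(n) == j)
      lo <- solve_lp(e, S, lb, ub, maximize = FALSE,
                     ineq_A = ineq_A, ineq_b = ineq_b)
      hi <- solve_lp(e, S, lb, ub, maximize = TRUE,
                     ineq_A = ineq_A, ineq_b = ineq_b)
      if (lo$status != "optimal" || hi$status != "optimal") next
      if (hi$objective - lo$objective <= 1e-9) {
        lb[j] <- ub[j] <- (lo$objective + hi$objective) / 2
        pinned <- TRUE
      } else {
        extra_vs <- c(extra_vs, list(lo$fluxes), list(hi$fluxes))
      }
    }
    if (!pinned && round > 1 && !length(extra_vs)) break
  }
  pt <- geometry()
  if (pt$dim > 0) pt$z0 <- interior_start(pt, extra_vs)
  pt
}

# z -> full flux vector
polytope_v <- function(pt, z) {
  v <- pt$v0
  if (pt$dim > 0) v[pt$free] <- v[pt$free] + as.vector(pt$N %*% z)
  v[pt$fixed] <- pt$v_fixed[pt$fixed]
  v
}

# chord [a_min, a_max] through z along unit direction e (both in z space)
chord_interval <- function(pt, z, e, tol = 1e-12) {
  w <- as.vector(pt$A %*% e)
  t <- pt$b - as.vector(pt$A %*% z)
  t[t < 0] <- 0
  pos <- w > tol; neg <- w < -tol
  a_max <- if (any(pos)) min(t[pos] / w[pos]) else Inf
  a_min <- if (any(neg)) max(-t[neg] / -w[neg]) else -Inf
  c(a_min, a_max)
}

# interior starting point: average of the flux-balance vertex, any caller-
# supplied feasible vertices, and a few random-objective vertices of the
# same (optionally optimality-constrained) polytope, mapped to z coordinates
interior_start <- function(pt, extra_vs = list(), n_lp = 8) {
  vs <- c(list(pt$v0), extra_vs)
  for (k in seq_len(n_lp)) {
    o <- stats::rnorm(length(pt$rxn_ids))
    sol <- solve_lp(o, pt$S, pt$lb, pt$ub, maximize = TRUE,
                    ineq_A = pt$ineq_A, ineq_b = pt$ineq_b)
    if (sol$status == "optimal") vs <- c(vs, list(sol$fluxes))
  }
  v_bar <- Reduce(`+`, vs) / length(vs)
  as.vector(crossprod(pt$N, v_bar[pt$free] - pt$v0[pt$free]))
}

#' Generate hit-and-run warm-up points
#'
#' Starting from an interior feasible point (the average of the
#' flux-balance solution and a handful of random-objective vertices),
#' iterates a basic hit-and-run chain with uniform random directions in the
#' null space and records each step as a warm-up point. All points satisfy
#' steady state to machine precision and the flux bounds.
#'
#' @param model A feasible `"metabolic_model"`.
#' @param n_warmup Number of warm-up points; must exceed the dimension of
#'   the sampled polytope.
#' @param seed Integer seed.
#' @param optimality_fraction See [sampler_config()].
#' @return Matrix with one column per warm-up point (rows = reactions).
#' @export
generate_warmup <- function(model, n_warmup = NULL, seed = 1,
                            optimality_fraction = 0) {
  withr::with_seed(seed, {
    pt <- polytope_setup(model, optimality_fraction)
    if (is.null(n_warmup)) n_warmup <- max(pt$dim + 1L, min(2L * pt$dim, 5000L))
    if (n_warmup < pt$dim + 1) {
      stop("n_warmup (", n_warmup, ") must be at least the null-space ",
           "dimension + 1 (", pt$dim + 1, ")")
    }
    W <- warmup_z(pt, n_warmup)
    V <- matrix(0, length(pt$rxn_ids), n_warmup,
                dimnames = list(pt$rxn_ids, NULL))
    for (k in seq_len(n_warmup)) V[, k] <- polytope_v(pt, W[, k])
    V
  })
}

# warm-up chain in z coordinates (caller controls the RNG state)
warmup_z <- function(pt, n_warmup, inset = 1e-10) {
  d <- pt$dim
  if (d == 0) return(matrix(0, 0, n_warmup))
  z <- if (!is.null(pt$z0)) pt$z0 else interior_start(pt)
  W <- matrix(0, d, n_warmup)
  k <- 0L; stalls <- 0L
  while (k < n_warmup) {
    e <- stats::rnorm(d); e <- e / sqrt(sum(e * e))
    al <- chord_interval(pt, z, e)
    if (!all(is.finite(al)) || al[2] - al[1] <= 0) {
      stalls <- stalls + 1L
      if (stalls > 500L) {
        stop("warm-up chain is stalled: the flux polytope appears to be ",
             "lower-dimensional than its null space (", stalls,
             " zero-width chords); check for implicitly forced reactions")
      }
      next
    }
    stalls <- 0L
    pad <- inset * (al[2] - al[1])
    a <- stats::runif(1, al[1] + pad, al[2] - pad)
    z <- z + a * e
    k <- k + 1L
    W[, k] <- z
  }
  W
}

#' ACHR sampling of the steady-state flux polytope
#'
#' Artificial centering hit-and-run: warm-up points are stored as the
#' columns of a matrix `W` with running center `s`; each iteration draws a
#' random warm-up column `y`, takes the direction `u = (y - s) / |y - s|`,
#' computes the feasible chord through the current point along `u`, draws
#' the next point uniformly on the chord, substitutes it into `W` at a
#' random column (updating `s` incrementally), and records every
#' `steps_per_point`-th iterate until `n_points` flux vectors are collected.
#' Sampling is performed in an orthonormal null-space basis so the
#' steady-state equalities hold exactly along the chain; chord endpoints
#' are excluded by a relative inset of 1e-10 to avoid sticking to faces.
#'
#' @param model A feasible `"metabolic_model"` (typically the fixture after
#'   [apply_diet()]).
#' @param config A [sampler_config()].
#' @return An object of class `"flux_samples"`: `samples` (reactions x
#'   n_points matrix), `reaction_ids`, `diet` label (from the model, if
#'   any), `config`, and a `validity` list with the maximum steady-state
#'   residual and bound violation over all recorded points.
#' @export
achr_sample <- function(model, config = sampler_config()) {
  stopifnot(inherits(config, "sampler_config"))
  withr::with_seed(config$seed, {
    pt <- polytope_setup(model, config$optimality_fraction, config$tolerance)
    d <- pt$dim
    n_pts <- config$n_points

    if (d == 0) {
      warning("flux polytope has zero dimension; returning the single point")
      v <- polytope_v(pt, numeric(0))
      samples <- matrix(v, length(v), 1, dimnames = list(pt$rxn_ids, NULL))
      return(new_flux_samples(samples, model, config, pt))
    }

    n_warm <- config$n_warmup
    if (is.null(n_warm)) n_warm <- max(d + 1L, min(2L * d, 5000L))
    if (n_warm < d + 1) {
      stop("n_warmup (", n_warm, ") must be at least the null-space ",
           "dimension + 1 (", d + 1, ")")
    }

    W <- warmup_z(pt, n_warm)
    s <- rowMeans(W)
    z <- W[, ncol(W)]

    Z <- matrix(0, d, n_pts)
    inset <- 1e-10
    recorded <- 0L
    step_in_point <- 0L
    # pre-drawn randomness in blocks to keep the R loop lean
    block <- 10000L; bi <- block + 1L
    ycol <- integer(); jcol <- integer(); unif <- numeric()
    stalls <- 0L
    while (recorded < n_pts) {
      if (stalls > 5000L) {
        stop("ACHR chain is stalled (", stalls, " rejected steps in a row); ",
             "the flux polytope appears degenerate")
      }
      stalls <- stalls + 1L
      if (bi > block) {
        ycol <- sample.int(n_warm, block, replace = TRUE)
        jcol <- sample.int(n_warm, block, replace = TRUE)
        unif <- stats::runif(block)
        bi <- 1L
      }
      y <- W[, ycol[bi]]
      u <- y - s
      nrm <- sqrt(sum(u * u))
      if (nrm > 1e-12) {
        u <- u / nrm
        al <- chord_interval(pt, z, u)
        if (all(is.finite(al)) && al[2] - al[1] > 0) {
          stalls <- 0L
          pad <- inset * (al[2] - al[1])
          a <- al[1] + pad + (al[2] - al[1] - 2 * pad) * unif[bi]
          z_new <- z + a * u
          j <- jcol[bi]
          s <- s + (z_new - W[, j]) / n_warm
          W[, j] <- z_new
          z <- z_new
          step_in_point <- step_in_point + 1L
          if (step_in_point >= config$steps_per_point) {
            recorded <- recorded + 1L
            Z[, recorded] <- z
            step_in_point <- 0L
          }
        }
      }
      bi <- bi + 1L
    }

    samples <- matrix(0, length(pt$rxn_ids), n_pts,
                      dimnames = list(pt$rxn_ids, NULL))
    for (k in seq_len(n_pts)) samples[, k] <- polytope_v(pt, Z[, k])
    new_flux_samples(samples, model, config, pt)
  })
}

new_flux_samples <- function(samples, model, config, pt) {
  resid <- max(abs(pt$S %*% samples))
  lb_viol <- max(0, max(pt$lb - apply(samples, 1, min)))
  ub_viol <- max(0, max(apply(samples, 1, max) - pt$ub))
  bviol <- max(lb_viol, ub_viol)
  if (bviol > 1e-7) {
    # numerical escape beyond tolerance: re-project onto the box
    samples <- pmin(pmax(samples, pt$lb), pt$ub)
    bviol2 <- 0
    if (bviol > 1e-5) {
      stop("sampler escaped the flux bounds by ", format(bviol),
           "; persistent numerical failure")
    }
    bviol <- bviol2
  }
  structure(
    list(samples = samples,
         reaction_ids = rownames(samples),
         diet = model$diet,
         config = config,
         dim = pt$dim,
         validity = list(max_steady_state_residual = resid,
                         max_bound_violation = bviol)),
    class = "flux_samples")
}

#' @export
print.flux_samples <- function(x, ...) {
  cat("ACHR flux samples", if (!is.null(x$diet)) paste0(" [", x$diet, "]"),
      ": ", ncol(x$samples), " points x ", nrow(x$samples), " reactions",
      " (polytope dimension ", x$dim, ")\n", sep = "")
  cat("  max |S v| = ", format(x$validity$max_steady_state_residual, digits = 3),
      ", max bound violation = ",
      format(x$validity$max_bound_violation, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
summary.flux_samples <- function(object, reactions = NULL, ...) {
  if (is.null(reactions)) reactions <- object$reaction_ids
  summarize_fluxes(object, reactions)
}

#' Boxplot of sampled fluxes for selected reactions
#'
#' @param x A `"flux_samples"` object.
#' @param reactions Reaction ids to plot.
#' @param ... Passed to [graphics::boxplot()].
#' @return Invisibly, the boxplot statistics.
#' @export
plot.flux_samples <- function(x, reactions = x$reaction_ids[1:min(6, nrow(x$samples))],
                              ...) {
  dat <- t(x$samples[reactions, , drop = FALSE])
  bp <- graphics::boxplot(as.data.frame(dat),
                          ylab = "flux (mmol g-1 h-1)",
                          main = if (!is.null(x$diet)) x$diet else "", ...)
  invisible(bp)
}
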