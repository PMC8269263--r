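#' Solve a bounded linear program
#'
#' Maximizes (or minimizes) `obj'x` subject to `A x = b` and `lb <= x <= ub`
#' with a dense two-phase primal simplex that handles variable bounds
#' natively (no variable splitting). This is the linear-programming core
#' behind [fba()], [fva()] and the stoichiometric consistency check.
#'
#' Phase 1 starts from the bound vector closest to the origin, adds one
#' artificial variable per constraint row and minimizes their sum; phase 2
#' optimizes the user objective with the artificials pinned at zero. Entering
#' variables are chosen by the largest reduced cost (Dantzig); after a run of
#' degenerate pivots the rule switches to Bland's to guarantee termination.
#'
#' @param A constraint matrix (dense or sparse; coerced to dense).
#' @param b right-hand side vector.
#' @param obj objective coefficient vector.
#' @param lb,ub variable bounds; `-Inf`/`Inf` allowed.
#' @param maximize logical; maximize (default) or minimize.
#' @param tol feasibility/optimality tolerance.
#' @param max_iter pivot limit before giving up with an error.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `objective` and the primal solution `x` (length `ncol(A)`).
#' @export
solve_lp <- function(A, b, obj, lb, ub, maximize = TRUE,
                     tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(obj) == n, length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) stop("lower bound exceeds upper bound")
  if (!maximize) {
    res <- solve_lp(A, b, -obj, lb, ub, maximize = TRUE, tol = tol,
                    max_iter = max_iter)
    res$objective <- -res$objective
    return(res)
  }
  if (m == 0L) {
    x <- ifelse(obj > 0, ub, ifelse(obj < 0, lb, pmin(pmax(0, lb), ub)))
    if (any(!is.finite(x[obj != 0])))
      return(list(status = "unbounded", objective = Inf,
                  x = rep(NA_real_, n)))
    x[!is.finite(x)] <- 0
    return(list(status = "optimal", objective = sum(obj * x), x = x))
  }

  # start every structural variable on a finite bound (nearest to zero);
  # doubly unbounded variables are "free" nonbasic at 0
  x0 <- numeric(n); start_upper <- logical(n)
  for (j in seq_len(n)) {
    lf <- is.finite(lb[j]); uf <- is.finite(ub[j])
    if (lf && uf) {
      if (abs(ub[j]) < abs(lb[j])) { x0[j] <- ub[j]; start_upper[j] <- TRUE }
      else x0[j] <- lb[j]
    } else if (lf) x0[j] <- lb[j]
    else if (uf) { x0[j] <- ub[j]; start_upper[j] <- TRUE }
  }
  r <- b - drop(A %*% x0)
  sgn <- ifelse(r >= 0, 1, -1)

  Aa <- cbind(A, diag(sgn, m))         # structural vars + m artificials
  lba <- c(lb, rep(0, m))
  uba <- c(ub, rep(Inf, m))
  N <- n + m
  free_var <- !is.finite(lba) & !is.finite(uba)

  state <- list(
    x = c(x0, abs(r)),
    basis = (n + 1L):N,
    at_upper = c(start_upper, rep(FALSE, m))
  )

  run <- function(cvec, state) {
    x <- state$x; basis <- state$basis; at_upper <- state$at_upper
    is_basic <- rep(FALSE, N); is_basic[basis] <- TRUE
    stall <- 0L
    Bi <- NULL
    since_refac <- 0L
    for (iter in seq_len(max_iter)) {
      if (is.null(Bi) || since_refac >= 60L) {
        Bi <- tryCatch(solve(Aa[, basis, drop = FALSE]),
                       error = function(e) NULL)
        if (is.null(Bi)) stop("singular basis encountered in simplex")
        since_refac <- 0L
      }
      y <- drop(crossprod(Bi, cvec[basis]))
      dvec <- cvec - drop(crossprod(Aa, y))
      movable <- !is_basic & (lba < uba - tol)
      improving <- movable &
        (ifelse(free_var, abs(dvec) > tol,
                (!at_upper & dvec > tol) | (at_upper & dvec < -tol)))
      cand <- which(improving)
      if (!length(cand)) {
        return(list(x = x, basis = basis, at_upper = at_upper,
                    status = "optimal"))
      }
      e <- if (stall > 40L) cand[1L] else cand[which.max(abs(dvec[cand]))]
      s <- if (free_var[e]) sign(dvec[e]) else if (at_upper[e]) -1 else 1
      w <- drop(Bi %*% Aa[, e])
      dir <- -s * w                            # x_B changes by dir * t
      xb <- x[basis]
      lim <- rep(Inf, m)
      dn <- dir < -tol; up <- dir > tol
      lim[dn] <- (xb[dn] - lba[basis[dn]]) / (-dir[dn])
      lim[up] <- (uba[basis[up]] - xb[up]) / dir[up]
      lim[lim < 0] <- 0                        # degeneracy guard
      flip <- uba[e] - lba[e]                  # distance to opposite bound
      t_best <- min(flip, lim)
      if (!is.finite(t_best)) {
        return(list(x = x, basis = basis, at_upper = at_upper,
                    status = "unbounded"))
      }
      stall <- if (t_best <= tol) stall + 1L else 0L
      x[e] <- x[e] + s * t_best
      x[basis] <- xb + dir * t_best
      if (flip <= min(lim) + 1e-15 && is.finite(flip) && flip <= t_best + 1e-15) {
        at_upper[e] <- !at_upper[e]            # bound flip, basis unchanged
      } else {
        leave <- if (stall > 40L) {
          blockers <- which(lim <= t_best + 1e-12)
          blockers[which.min(basis[blockers])]
        } else which.min(lim)
        lv <- basis[leave]
        at_upper[lv] <- dir[leave] > 0
        x[lv] <- if (at_upper[lv]) uba[lv] else lba[lv]
        is_basic[lv] <- FALSE
        basis[leave] <- e
        is_basic[e] <- TRUE
        at_upper[e] <- FALSE
        # product-form update of the basis inverse
        piv <- w[leave]
        if (abs(piv) < 1e-11) { Bi <- NULL } else {
          brow <- Bi[leave, ] / piv
          Bi <- Bi - tcrossprod(w, brow)
          Bi[leave, ] <- brow
          since_refac <- since_refac + 1L
        }
      }
    }
    stop("simplex iteration limit reached (", max_iter, ")")
  }

  p1 <- run(c(rep(0, n), rep(-1, m)), state)
  if (p1$status != "optimal" || sum(p1$x[(n + 1L):N]) > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  uba <- c(ub, rep(0, m))                      # pin artificials at zero
  p1$x[(n + 1L):N] <- pmin(p1$x[(n + 1L):N], 0)
  p2 <- run(c(obj, rep(0, m)), p1)
  if (p2$status == "unbounded") {
    return(list(status = "unbounded", objective = Inf, x = rep(NA_real_, n)))
  }
  x <- p2$x[seq_len(n)]
  list(status = "optimal", objective = sum(obj * x), x = x)
}

#' Brute-force LP optimum by basic-solution enumeration
#'
#' Independent oracle for [solve_lp()]: enumerates candidate vertices of the
#' polytope `{A x = b, lb <= x <= ub}` by choosing, for every subset of
#' variables of size `rank(A)`, the remaining variables at each combination
#' of their finite bounds, solving the resulting square system and keeping
#' feasible points. Exponential in `ncol(A)`; intended for networks of at
#' most ~8 reactions.
#'
#' @inheritParams solve_lp
#' @return list with `status` (`"optimal"` or `"infeasible"`) and `objective`.
#' @export
enumerate_lp_optimum <- function(A, b, obj, lb, ub, maximize = TRUE,
                                 tol = 1e-7) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  sign <- if (maximize) 1 else -1
  k <- if (m > 0) qr(A)$rank else 0L
  best <- -Inf
  feasible <- FALSE
  consider <- function(x) {
    if (any(!is.finite(x))) return()
    if (any(x < lb - tol) || any(x > ub + tol)) return()
    if (m > 0 && max(abs(drop(A %*% x) - b)) > tol) return()
    feasible <<- TRUE
    v <- sign * sum(obj * x)
    if (v > best) best <<- v
  }
  if (k == 0L) {
    co <- sign * obj
    x <- ifelse(co > 0, ub, ifelse(co < 0, lb, pmin(pmax(0, lb), ub)))
    consider(x)
  } else {
    for (fs in utils::combn(n, k, simplify = FALSE)) {
      Af <- A[, fs, drop = FALSE]
      if (qr(Af)$rank < k) next
      nf <- setdiff(seq_len(n), fs)
      opts <- lapply(nf, function(j) {
        v <- unique(c(lb[j], ub[j]))
        v[is.finite(v)]
      })
      if (length(nf) && any(lengths(opts) == 0L)) next
      grid <- if (length(nf)) expand.grid(opts, KEEP.OUT.ATTRS = FALSE)
              else data.frame(row.names = "1")
      for (gi in seq_len(nrow(grid))) {
        x <- numeric(n)
        if (length(nf)) x[nf] <- as.numeric(grid[gi, ])
        rhs <- if (length(nf)) b - drop(A[, nf, drop = FALSE] %*% x[nf]) else b
        sol <- tryCatch(qr.solve(Af, rhs, tol = 1e-10),
                        error = function(e) NULL)
        if (is.null(sol)) next
        x[fs] <- sol
        consider(x)
      }
    }
  }
  if (!feasible) return(list(status = "infeasible", objective = NA_real_))
  list(status = "optimal", objective = sign * best)
}
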