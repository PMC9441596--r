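## Linear-programming layer.
##
## Every optimization in this package is of the form
##     min / max  c' x   s.t.  A x = b,  l <= x <= u
## (steady-state mass balances plus flux bounds). It is solved with a dense
## bounded-variable two-phase primal simplex using Bland's anti-cycling rule,
## which makes every solve deterministic and exact up to floating point --
## important because solutions are compared against analytic vertex oracles
## at tight tolerances. Problem sizes here are tiny (tens of rows), so a
## dense implementation is appropriate.

.LP_TOL <- 1e-9     # reduced-cost / feasibility tolerance
.LP_PIVOT_TOL <- 1e-11

## Solve min c'x s.t. A x = b, lb <= x <= ub.
## Returns list(status, x, objective) with status in
## optimal/infeasible/unbounded.
.simplexSolve <- function(cc, A, b, lb, ub, maximize = FALSE,
                          maxIter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(cc) == n, length(b) == m, length(lb) == n,
            length(ub) == n)
  if (any(lb > ub + .LP_TOL)) return(list(status = "infeasible"))
  if (maximize) cc <- -cc

  ## initial nonbasic values: finite bound closest to zero, else 0 (free)
  initVal <- function(l, u) {
    v <- numeric(length(l))
    both <- is.finite(l) & is.finite(u)
    v[both] <- ifelse(abs(l[both]) <= abs(u[both]), l[both], u[both])
    onlyL <- is.finite(l) & !is.finite(u)
    v[onlyL] <- l[onlyL]
    onlyU <- !is.finite(l) & is.finite(u)
    v[onlyU] <- u[onlyU]
    v
  }

  ## augment with artificials for phase 1
  x0 <- initVal(lb, ub)
  r <- b - as.vector(A %*% x0)
  sgn <- ifelse(r >= 0, 1, -1)
  Aa <- cbind(A, diag(sgn, nrow = m))
  lba <- c(lb, rep(0, m))
  uba <- c(ub, rep(Inf, m))
  x <- c(x0, abs(r))
  basis <- n + seq_len(m)
  nTot <- n + m

  runPhase <- function(cost, x, basis, lbv, ubv) {
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > maxIter)
        stop("simplex iteration limit reached", call. = FALSE)
      B <- Aa[, basis, drop = FALSE]
      luB <- tryCatch(solve(B), error = function(e) NULL)
      if (is.null(luB))
        stop("singular basis encountered", call. = FALSE)
      y <- as.vector(crossprod(luB, cost[basis]))  # B^-T c_B
      nonbasic <- setdiff(seq_len(nTot), basis)
      d <- cost[nonbasic] - as.vector(y %*% Aa[, nonbasic, drop = FALSE])

      atL <- is.finite(lbv[nonbasic]) &
        abs(x[nonbasic] - lbv[nonbasic]) <= .LP_TOL * (1 + abs(lbv[nonbasic]))
      atU <- is.finite(ubv[nonbasic]) &
        abs(x[nonbasic] - ubv[nonbasic]) <= .LP_TOL * (1 + abs(ubv[nonbasic]))
      fixed <- atL & atU
      ## admissible moves: +1 from lower (or free), -1 from upper (or free)
      up <- !fixed & d < -.LP_TOL & (atL | (!atL & !atU))
      dn <- !fixed & d >  .LP_TOL & (atU | (!atL & !atU))
      cand <- which(up | dn)
      if (!length(cand))
        return(list(x = x, basis = basis, status = "optimal"))
      j <- cand[which.min(nonbasic[cand])]        # Bland: smallest var index
      enter <- nonbasic[j]
      sj <- if (up[j]) 1 else -1

      w <- as.vector(luB %*% Aa[, enter])          # B^-1 a_enter
      ## ratio test
      tMax <- if (is.finite(ubv[enter]) && is.finite(lbv[enter]))
        ubv[enter] - lbv[enter] else Inf
      leave <- 0L                                  # 0 = bound flip
      xB <- x[basis]
      delta <- sj * w
      for (i in seq_len(m)) {
        if (delta[i] > .LP_PIVOT_TOL) {
          if (is.finite(lbv[basis[i]])) {
            ti <- (xB[i] - lbv[basis[i]]) / delta[i]
            if (ti < tMax - .LP_PIVOT_TOL ||
                (ti < tMax + .LP_PIVOT_TOL && leave > 0L &&
                 basis[i] < basis[leave])) {
              tMax <- max(ti, 0); leave <- i
            }
          }
        } else if (delta[i] < -.LP_PIVOT_TOL) {
          if (is.finite(ubv[basis[i]])) {
            ti <- (ubv[basis[i]] - xB[i]) / (-delta[i])
            if (ti < tMax - .LP_PIVOT_TOL ||
                (ti < tMax + .LP_PIVOT_TOL && leave > 0L &&
                 basis[i] < basis[leave])) {
              tMax <- max(ti, 0); leave <- i
            }
          }
        }
      }
      if (!is.finite(tMax))
        return(list(x = x, basis = basis, status = "unbounded"))

      x[enter] <- x[enter] + sj * tMax
      x[basis] <- x[basis] - tMax * delta
      if (leave > 0L) {
        out <- basis[leave]
        ## snap the leaving variable onto the bound it hit
        x[out] <- if (delta[leave] > 0) lbv[out] else ubv[out]
        basis[leave] <- enter
      }
      ## else: bound-to-bound flip, basis unchanged
    }
  }

  ## phase 1: minimize sum of artificials
  c1 <- c(rep(0, n), rep(1, m))
  p1 <- runPhase(c1, x, basis, lba, uba)
  art <- p1$x[(n + 1):nTot]
  if (sum(art) > 1e-7)
    return(list(status = "infeasible"))
  ## phase 2: artificials pinned to zero
  lba2 <- lba; uba2 <- uba
  lba2[(n + 1):nTot] <- 0; uba2[(n + 1):nTot] <- 0
  x2 <- p1$x
  x2[(n + 1):nTot] <- 0
  c2 <- c(cc, rep(0, m))
  p2 <- runPhase(c2, x2, p1$basis, lba2, uba2)
  if (p2$status == "unbounded")
    return(list(status = "unbounded"))

  ## clean final solution: recompute basic values from the bound-resident
  ## nonbasic part to undo accumulated update error
  xs <- p2$x
  nb <- setdiff(seq_len(nTot), p2$basis)
  rhs <- b - as.vector(Aa[, nb, drop = FALSE] %*% xs[nb])
  xB <- tryCatch(solve(Aa[, p2$basis, drop = FALSE], rhs),
                 error = function(e) NULL)
  if (!is.null(xB)) xs[p2$basis] <- xB
  xOut <- xs[seq_len(n)]
  obj <- sum(cc * xOut)
  list(status = "optimal", x = xOut,
       objective = if (maximize) -obj else obj)
}

## Solve an LP over a model's flux space with optional overrides.
## objective: named or full-length numeric cost vector over reactions.
.modelLP <- function(model, objective, maximize = TRUE,
                     lb = NULL, ub = NULL) {
  S <- model@S
  n <- ncol(S)
  rxns <- colnames(S)
  cc <- numeric(n)
  if (!is.null(names(objective))) {
    idx <- match(names(objective), rxns)
    if (anyNA(idx))
      stop("unknown reaction in objective: ",
           paste(names(objective)[is.na(idx)], collapse = ", "),
           call. = FALSE)
    cc[idx] <- objective
  } else {
    stopifnot(length(objective) == n)
    cc <- objective
  }
  lbv <- if (is.null(lb)) model@lb else lb
  ubv <- if (is.null(ub)) model@ub else ub
  res <- .simplexSolve(cc, S, rep(0, nrow(S)), lbv, ubv,
                       maximize = maximize)
  if (res$status != "optimal")
    return(.newSolution(res$status))
  .newSolution("optimal", objective = res$objective,
               fluxes = stats::setNames(res$x, rxns))
}
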