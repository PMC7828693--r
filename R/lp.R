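# A dense two-phase primal simplex for bounded linear programs
#
#   maximize c'v   subject to  A v = b,  lb <= v <= ub
#
# written for the small, dense LPs that flux balance analysis of the curated
# networks produces (tens of reactions). Variables are shifted to v = lb + x,
# upper bounds become slack rows, equality rows get phase-I artificials.
# Pivoting uses Dantzig's rule with lowest-index tie-breaks and falls back to
# Bland's rule after a fixed number of iterations, so solves are deterministic
# and finite. An exact rational simplex (see max_atp_exact()) certifies the
# optima this solver reports.

LP_TOL <- 1e-9

lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE) {
  n <- length(obj)
  stopifnot(ncol(A) == n, length(lb) == n, length(ub) == n, nrow(A) == length(b))
  if (any(lb > ub + LP_TOL)) {
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n),
                violated = "bounds: lb > ub"))
  }
  m <- nrow(A)
  d <- ub - lb
  b2 <- as.numeric(b - A %*% lb)

  # rows: m equalities then n upper-bound rows; columns: x (n), bound slacks
  # (n), artificials (m)
  M <- rbind(cbind(A, matrix(0, m, n)), cbind(diag(n), diag(n)))
  rhs <- c(b2, d)
  flip <- seq_len(m)[rhs[seq_len(m)] < 0]
  M[flip, ] <- -M[flip, , drop = FALSE]
  rhs[flip] <- -rhs[flip]
  nrow_t <- m + n
  art <- rbind(diag(m), matrix(0, n, m))
  Tab <- cbind(M, art)
  ncol_t <- ncol(Tab)
  art_cols <- 2 * n + seq_len(m)
  basis <- c(art_cols, n + seq_len(n))  # artificials for eq rows, slacks for bound rows

  pivot <- function(p, q) {
    piv <- Tab[p, q]
    Tab[p, ] <<- Tab[p, ] / piv
    rhs[p] <<- rhs[p] / piv
    col <- Tab[, q]
    col[p] <- 0
    Tab <<- Tab - outer(col, Tab[p, ])
    rhs <<- rhs - col * rhs[p]
    basis[p] <<- q
  }

  run_simplex <- function(cost, allowed) {
    # minimize cost'z over the tableau; returns status
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > 20000L) return("maxiter")
      # reduced costs: r_j = cost_j - cost_B' Tab_j
      cb <- cost[basis]
      r <- cost - as.numeric(crossprod(Tab, cb))
      r[!allowed] <- Inf
      r[basis] <- Inf
      if (iter <= 500L) {
        q <- which.min(r)
        if (r[q] >= -LP_TOL) return("optimal")
      } else {
        # Bland: first improving index
        cand <- which(r < -LP_TOL)
        if (!length(cand)) return("optimal")
        q <- cand[1]
      }
      colq <- Tab[, q]
      pos <- which(colq > LP_TOL)
      if (!length(pos)) return("unbounded")
      # deterministic tie-break: smallest ratio, then lowest row index
      ratio <- rhs[pos] / colq[pos]
      p <- pos[which(ratio <= min(ratio) + LP_TOL)][1]
      pivot(p, q)
    }
  }

  # phase I: drive artificials to zero
  cost1 <- c(rep(0, 2 * n), rep(1, m))
  allowed1 <- rep(TRUE, ncol_t)
  st1 <- run_simplex(cost1, allowed1)
  phase1_val <- sum(cost1[basis] * rhs)
  if (st1 != "optimal" || phase1_val > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n),
                violated = "equality constraints (steady state/bounds)"))
  }
  # pivot residual artificials out of the basis where possible
  for (p in which(basis %in% art_cols)) {
    row <- Tab[p, seq_len(2 * n)]
    q <- which(abs(row) > 1e-8)
    if (length(q)) pivot(p, q[1])
  }

  cost2 <- c(if (maximize) -obj else obj, rep(0, n), rep(0, m))
  allowed2 <- c(rep(TRUE, 2 * n), rep(FALSE, m))
  st2 <- run_simplex(cost2, allowed2)
  if (st2 == "unbounded") {
    return(list(status = "unbounded", objective = Inf, x = rep(NA_real_, n),
                violated = NULL))
  }
  if (st2 != "optimal") {
    return(list(status = "maxiter", objective = NA_real_, x = rep(NA_real_, n),
                violated = NULL))
  }
  x <- numeric(ncol_t)
  x[basis] <- rhs
  v <- x[seq_len(n)] + lb
  list(status = "optimal", objective = sum(obj * v), x = v, violated = NULL)
}

# Parsimonious second stage: minimize total flux at a fixed objective value.
# Splits v = p - q with p, q >= 0 so |v| is linear, adds the objective as an
# equality row, and reuses lp_solve. Returns the flux vector.
lp_parsimonious <- function(obj, A, b, lb, ub, z_opt) {
  n <- length(obj)
  A2 <- rbind(cbind(A, -A), c(obj, -obj))
  b2 <- c(b, z_opt)
  lb2 <- rep(0, 2 * n)
  ub2 <- c(pmax(ub, 0), pmax(-lb, 0))
  sol <- lp_solve(rep(-1, 2 * n), A2, b2, lb2, ub2, maximize = TRUE)
  if (sol$status != "optimal") return(NULL)
  sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
}
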