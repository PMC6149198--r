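# Bounded-variable two-phase primal simplex.
#
# Solves   maximize c'x   s.t.  A x = b,  l <= x <= u   (all bounds finite).
# General inequality rows are converted to equalities with slack variables
# whose bounds come from interval arithmetic over the box, so the problem
# stays bounded. Bland's smallest-index rule is used throughout, which
# guarantees termination on degenerate problems (FBA LPs are routinely
# degenerate). Dense solves are adequate at the problem sizes this package
# targets (toy and oracle models; a few hundred variables at most).

simplex_bvs <- function(cc, A, b, l, u, tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(cc) == n, length(b) == m, length(l) == n, length(u) == n)
  if (any(l > u + tol)) {
    return(list(status = "infeasible", value = NA_real_, x = NULL))
  }
  l <- pmin(l, u)

  # start with structural variables at the bound of smaller magnitude
  x <- ifelse(abs(l) <= abs(u), l, u)
  status <- ifelse(abs(l) <= abs(u), 1L, 2L)  # 1 lower, 2 upper, 0 basic
  r <- b - as.vector(A %*% x)

  # artificial variables, one per row, signed to make the residual feasible
  art_sign <- ifelse(r >= 0, 1, -1)
  Aall <- cbind(A, diag(art_sign, m, m))
  lall <- c(l, rep(0, m))
  uall <- c(u, abs(r) + 1)
  xall <- c(x, abs(r))
  status <- c(status, rep(0L, m))
  basis <- n + seq_len(m)
  nall <- n + m

  run_phase <- function(obj, xall, status, basis, iter_budget) {
    for (it in seq_len(iter_budget)) {
      AB <- Aall[, basis, drop = FALSE]
      lu <- tryCatch(solve(AB), error = function(e) NULL)
      if (is.null(lu)) {
        return(list(status = "singular", xall = xall, status_v = status,
                    basis = basis))
      }
      y <- as.vector(crossprod(lu, obj[basis]))  # y = AB^-T c_B
      entering <- 0L
      delta <- 0
      for (j in seq_len(nall)) {        # Bland: smallest index
        if (status[j] == 0L) next
        if (uall[j] - lall[j] < tol) next  # fixed variable cannot move
        dj <- obj[j] - sum(y * Aall[, j])
        if (status[j] == 1L && dj > tol) { entering <- j; delta <- 1; break }
        if (status[j] == 2L && dj < -tol) { entering <- j; delta <- -1; break }
      }
      if (entering == 0L) {
        return(list(status = "optimal", xall = xall, status_v = status,
                    basis = basis))
      }
      w <- as.vector(lu %*% Aall[, entering])  # basic change = -delta * w * t
      tmax <- uall[entering] - lall[entering]
      leave <- 0L  # 0 => bound flip of entering
      for (k in seq_len(m)) {
        chg <- -delta * w[k]
        if (chg > tol) {
          tk <- (uall[basis[k]] - xall[basis[k]]) / chg
        } else if (chg < -tol) {
          tk <- (lall[basis[k]] - xall[basis[k]]) / chg
        } else next
        tk <- max(tk, 0)
        if (tk < tmax - tol) {
          tmax <- tk; leave <- k
        } else if (tk <= tmax + tol) {   # tie: Bland smallest-index leaving
          if (leave == 0L || basis[k] < basis[leave]) {
            tmax <- min(tmax, tk); leave <- k
          }
        }
      }
      # apply step
      xall[entering] <- xall[entering] + delta * tmax
      if (m > 0) xall[basis] <- xall[basis] - delta * tmax * w
      if (leave == 0L) {
        status[entering] <- if (delta > 0) 2L else 1L  # bound flip
      } else {
        lv <- basis[leave]
        chg <- -delta * w[leave]
        status[lv] <- if (chg > 0) 2L else 1L
        xall[lv] <- if (chg > 0) uall[lv] else lall[lv]
        basis[leave] <- entering
        status[entering] <- 0L
      }
    }
    list(status = "iteration_limit", xall = xall, status_v = status,
         basis = basis)
  }

  # phase 1: drive artificials to zero
  obj1 <- c(rep(0, n), rep(-1, m))
  ph1 <- run_phase(obj1, xall, status, basis, max_iter)
  if (ph1$status != "optimal") {
    return(list(status = ph1$status, value = NA_real_, x = NULL))
  }
  if (sum(ph1$xall[n + seq_len(m)]) > 1e-7) {
    return(list(status = "infeasible", value = NA_real_, x = NULL))
  }
  # fix artificials at zero and optimize the true objective
  lall[n + seq_len(m)] <- 0
  uall[n + seq_len(m)] <- 0
  xall <- ph1$xall
  xall[n + seq_len(m)] <- 0
  obj2 <- c(cc, rep(0, m))
  ph2 <- run_phase(obj2, xall, ph1$status_v, ph1$basis, max_iter)
  if (ph2$status != "optimal") {
    return(list(status = ph2$status, value = NA_real_, x = NULL))
  }
  x <- ph2$xall[seq_len(n)]
  x <- pmin(pmax(x, l), u)
  list(status = "optimal", value = sum(cc * x), x = x)
}

# Maximize obj'v subject to l <= v <= u plus equality / >= / <= rows.
# Inequality rows get slack variables bounded by interval arithmetic over
# the box, keeping every variable finitely bounded.
lp_max <- function(obj, lb, ub, eq = NULL, ge = NULL, le = NULL) {
  n <- length(obj)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", value = NA_real_, solution = NULL))
  }
  A <- NULL; b <- numeric(0)
  slack_l <- numeric(0); slack_u <- numeric(0); slack_sign <- numeric(0)
  add_rows <- function(block, sign) {
    if (is.null(block) || length(block$b) == 0L) return()
    Ai <- matrix(block$A, ncol = n)
    A <<- rbind(A, Ai)
    b <<- c(b, as.numeric(block$b))
    if (is.na(sign)) {  # equality
      slack_sign <<- c(slack_sign, rep(0, nrow(Ai)))
      slack_l <<- c(slack_l, rep(0, nrow(Ai)))
      slack_u <<- c(slack_u, rep(0, nrow(Ai)))
    } else {
      # a'v - s = b (>=, s >= 0) or a'v + s = b (<=, s >= 0)
      for (k in seq_len(nrow(Ai))) {
        aa <- Ai[k, ]
        hi <- sum(pmax(aa, 0) * ub + pmin(aa, 0) * lb)
        lo <- sum(pmax(aa, 0) * lb + pmin(aa, 0) * ub)
        smax <- if (sign > 0) hi - block$b[k] else block$b[k] - lo
        slack_u <<- c(slack_u, max(smax, 0) + 1)
        slack_l <<- c(slack_l, 0)
        slack_sign <<- c(slack_sign, -sign)
      }
    }
  }
  add_rows(eq, NA)
  add_rows(ge, +1)
  add_rows(le, -1)
  if (is.null(A)) {
    v <- ifelse(obj > 0, ub, lb)
    return(list(status = "optimal", value = sum(obj * v), solution = v))
  }
  m <- nrow(A)
  ns <- sum(slack_sign != 0)
  if (ns > 0) {
    Sl <- matrix(0, m, ns)
    k <- 0L
    for (i in seq_len(m)) {
      if (slack_sign[i] != 0) { k <- k + 1L; Sl[i, k] <- slack_sign[i] }
    }
    Afull <- cbind(A, Sl)
    lfull <- c(lb, slack_l[slack_sign != 0])
    ufull <- c(ub, slack_u[slack_sign != 0])
  } else {
    Afull <- A; lfull <- lb; ufull <- ub
  }
  res <- simplex_bvs(c(obj, rep(0, ncol(Afull) - n)), Afull, b, lfull, ufull)
  if (res$status == "infeasible") {
    return(list(status = "infeasible", value = NA_real_, solution = NULL))
  }
  if (res$status != "optimal") {
    abort(sprintf("LP solver failed (%s)", res$status))
  }
  v <- res$x[seq_len(n)]
  list(status = "optimal", value = sum(obj * v), solution = v)
}
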