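# Dense two-phase primal simplex.
#
# Solves  min c'x  s.t.  Aeq x = beq,  Ale x <= ble,  lb <= x <= ub
# with finite lb (ub may be +Inf). Variables are shifted to y = x - lb and
# finite upper bounds become explicit rows, giving the standard form
# min c'y, A y (+ slacks) = b, y >= 0. Phase 1 minimises the sum of
# artificial variables; phase 2 optimises c. Pivoting uses Dantzig's rule
# with a switch to Bland's rule after an iteration budget, which guarantees
# termination on degenerate problems. Sizes here are small (toy networks),
# so a dense tableau is both simple and fast enough.

simplexCore <- function(tab, basis, cvec, n_real, tol = 1e-9,
                        bland_after = NULL, maxit = NULL) {
  m <- nrow(tab)
  N <- ncol(tab) - 1L
  if (is.null(bland_after)) bland_after <- 50L * (m + N)
  if (is.null(maxit)) maxit <- 400L * (m + N) + 5000L
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > maxit) stop("simplex iteration limit exceeded")
    cB <- cvec[basis]
    red <- cvec - as.vector(crossprod(tab[, seq_len(N), drop = FALSE], cB))
    cand <- which(red < -tol)
    if (!length(cand)) return(list(tab = tab, basis = basis, iters = it))
    j <- if (it > bland_after) cand[1] else cand[which.min(red[cand])]
    col <- tab[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(unbounded = TRUE, entering = j))
    ratio <- tab[pos, N + 1L] / col[pos]
    rmin <- min(ratio)
    ties <- pos[ratio <= rmin + tol]
    i <- ties[which.min(basis[ties])]  # Bland-compatible tie-break
    # pivot on (i, j)
    piv <- tab[i, ] / tab[i, j]
    tab <- tab - outer(tab[, j], piv)
    tab[i, ] <- piv
    basis[i] <- j
  }
}

#' Solve a linear program with the built-in simplex
#'
#' Minimises (or maximises) `c'x` subject to `Aeq x = beq`, `Ale x <= ble`
#' and box constraints `lb <= x <= ub`. All lower bounds must be finite;
#' upper bounds may be `Inf`. Intended for the small dense problems arising
#' from toy metabolic networks.
#'
#' @param cc objective coefficient vector.
#' @param Aeq,beq equality constraints (matrix/vector or `NULL`).
#' @param Ale,ble inequality (`<=`) constraints (matrix/vector or `NULL`).
#' @param lb,ub variable bounds (recycled).
#' @param maximize maximise instead of minimise.
#' @param tol numeric tolerance for pivoting and feasibility (default 1e-9).
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x` (solution) and `objective` (on the original scale).
#' @export
solveLP <- function(cc, Aeq = NULL, beq = NULL, Ale = NULL, ble = NULL,
                    lb = 0, ub = Inf, maximize = FALSE, tol = 1e-9) {
  n <- length(cc)
  lb <- rep_len(lb, n)
  ub <- rep_len(ub, n)
  if (any(!is.finite(lb))) stop("solveLP requires finite lower bounds")
  if (any(lb > ub)) return(list(status = "infeasible", x = NULL, objective = NA_real_))
  obj <- if (maximize) -cc else cc

  if (!is.null(Aeq)) Aeq <- matrix(as.numeric(Aeq), ncol = n)
  if (!is.null(Ale)) Ale <- matrix(as.numeric(Ale), ncol = n)
  beq2 <- if (is.null(Aeq)) numeric(0) else as.numeric(beq) - as.vector(Aeq %*% lb)
  ble2 <- if (is.null(Ale)) numeric(0) else as.numeric(ble) - as.vector(Ale %*% lb)
  ubp <- ub - lb
  fin <- which(is.finite(ubp))
  # explicit upper-bound rows y_i <= ubp_i
  if (length(fin)) {
    Ub <- matrix(0, length(fin), n)
    Ub[cbind(seq_along(fin), fin)] <- 1
    Ale <- rbind(Ale, Ub)
    ble2 <- c(ble2, ubp[fin])
  }
  me <- length(beq2)
  ml <- length(ble2)
  m <- me + ml
  if (m == 0L) {
    # pure box problem
    x <- ifelse(obj > 0, lb, ifelse(obj < 0, ub, lb))
    if (any(!is.finite(x[obj != 0])))
      return(list(status = "unbounded", x = NULL, objective = NA_real_))
    x[!is.finite(x)] <- lb[!is.finite(x)]
    val <- sum(obj * x)
    return(list(status = "optimal", x = x,
                objective = if (maximize) -val else val))
  }

  A <- rbind(if (me) Aeq else NULL, if (ml) Ale else NULL)
  b <- c(beq2, ble2)
  # slack columns for inequality rows
  Sl <- matrix(0, m, ml)
  if (ml) Sl[cbind(me + seq_len(ml), seq_len(ml))] <- 1
  A <- cbind(A, Sl)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  # rows needing artificials: all equality rows, plus negated inequality rows
  need_art <- c(rep(TRUE, me), neg[me + seq_len(ml)])
  na <- sum(need_art)
  Ar <- matrix(0, m, na)
  Ar[cbind(which(need_art), seq_len(na))] <- 1
  tab <- cbind(A, Ar, b)
  N <- ncol(tab) - 1L
  n_slack <- ml
  basis <- integer(m)
  basis[!need_art] <- n + which(!need_art[me + seq_len(ml)])  # their slack col
  basis[need_art] <- n + n_slack + seq_len(na)

  scale <- max(1, abs(b))
  # phase 1
  if (na) {
    c1 <- c(rep(0, n + n_slack), rep(1, na))
    res <- simplexCore(tab, basis, c1, n)
    if (!is.null(res$unbounded)) stop("phase-1 unbounded (internal error)")
    tab <- res$tab; basis <- res$basis
    p1 <- sum(c1[basis] * tab[, N + 1L])
    if (p1 > 1e-7 * scale)
      return(list(status = "infeasible", x = NULL, objective = NA_real_))
    # drive remaining artificials out of the basis
    art_cols <- n + n_slack + seq_len(na)
    for (i in which(basis %in% art_cols)) {
      row <- tab[i, seq_len(n + n_slack)]
      j <- which(abs(row) > 1e-7)
      if (length(j)) {
        j <- j[1]
        piv <- tab[i, ] / tab[i, j]
        tab <- tab - outer(tab[, j], piv)
        tab[i, ] <- piv
        basis[i] <- j
      }
      # else: redundant row; harmless to leave (artificial stays at zero)
    }
    # forbid artificials in phase 2 by dropping their columns
    keepc <- c(seq_len(n + n_slack), N + 1L)
    keep_basic_art <- intersect(basis, art_cols)
    if (length(keep_basic_art)) {
      # re-append columns for artificials still basic in redundant rows
      keepc <- c(seq_len(n + n_slack), keep_basic_art, N + 1L)
      remap <- stats::setNames(seq_along(keepc)[-length(keepc)],
                               keepc[-length(keepc)])
      basis <- as.integer(remap[as.character(basis)])
      tab <- tab[, keepc, drop = FALSE]
      N <- ncol(tab) - 1L
      c2 <- c(obj, rep(0, N - n))
    } else {
      tab <- tab[, keepc, drop = FALSE]
      N <- ncol(tab) - 1L
      c2 <- c(obj, rep(0, n_slack))
    }
  } else {
    c2 <- c(obj, rep(0, n_slack))
  }

  res <- simplexCore(tab, basis, c2, n)
  if (!is.null(res$unbounded))
    return(list(status = "unbounded", x = NULL, objective = NA_real_))
  tab <- res$tab; basis <- res$basis
  y <- numeric(N)
  y[basis] <- tab[, ncol(tab)]
  x <- y[seq_len(n)] + lb
  val <- sum(obj * x)
  list(status = "optimal", x = x, objective = if (maximize) -val else val)
}
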