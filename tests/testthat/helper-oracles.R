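# Independent oracles used to cross-check the package's implementations.
# Each deliberately takes a different computational route from the code
# under test.

# Number of 6-connected components among the 1-voxels of a 3-D array,
# by queue-based flood fill.
flood_fill_components <- function(grid) {
  d <- dim(grid)
  todo <- which(grid != 0)
  seen <- array(FALSE, dim = d)
  ncomp <- 0L
  for (start in todo) {
    if (seen[start]) next
    ncomp <- ncomp + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      i <- (v - 1L) %% d[1L] + 1L
      j <- ((v - 1L) %/% d[1L]) %% d[2L] + 1L
      k <- (v - 1L) %/% (d[1L] * d[2L]) + 1L
      for (step in list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                        c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))) {
        ii <- i + step[1L]; jj <- j + step[2L]; kk <- k + step[3L]
        if (ii < 1 || ii > d[1L] || jj < 1 || jj > d[2L] ||
            kk < 1 || kk > d[3L]) next
        w <- ii + (jj - 1L) * d[1L] + (kk - 1L) * d[1L] * d[2L]
        if (grid[w] != 0 && !seen[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
  }
  ncomp
}

# All permutations of 1..n via Heap's algorithm (iterative), distinct from
# the package's recursive first-element construction.
heap_permutations <- function(n) {
  a <- seq_len(n)
  out <- matrix(0L, factorial(n), n)
  out[1L, ] <- a
  c_vec <- rep(1L, n)
  row <- 1L
  i <- 1L
  while (i <= n) {
    if (c_vec[i] < i) {
      if (i %% 2L == 1L) {
        tmp <- a[1L]; a[1L] <- a[i]; a[i] <- tmp
      } else {
        tmp <- a[c_vec[i]]; a[c_vec[i]] <- a[i]; a[i] <- tmp
      }
      row <- row + 1L
      out[row, ] <- a
      c_vec[i] <- c_vec[i] + 1L
      i <- 1L
    } else {
      c_vec[i] <- 1L
      i <- i + 1L
    }
  }
  out
}

# Exhaustive permutation mapping oracle: slope t statistics from lm(),
# minimum over ROIs per permutation, (1 + count) / (1 + B) counting.
exhaustive_rlsm_oracle <- function(D, y) {
  n <- length(y)
  perms <- heap_permutations(n)
  B <- nrow(perms)
  stat_of <- function(yy) {
    vapply(seq_len(ncol(D)), function(k) {
      summary(stats::lm(yy ~ D[, k]))$coefficients[2L, 3L]
    }, numeric(1))
  }
  observed <- stat_of(y)
  mins <- vapply(seq_len(B), function(b) min(stat_of(y[perms[b, ]])),
                 numeric(1))
  p <- vapply(observed, function(s) (1 + sum(mins <= s)) / (B + 1),
              numeric(1))
  list(observed = observed, p = p, B = B)
}

# Linear epsilon-SVR oracle: solves the dual as an explicit QP
# (pracma::quadprog), then recovers the offset as the midpoint of the
# argmin interval of the piecewise-linear primal loss in the intercept.
svr_qp_oracle <- function(X, y, C = 1, eps = 0.1) {
  n <- nrow(X)
  K <- X %*% t(X)
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-10, 2 * n)
  f <- c(eps - y, eps + y)
  sol <- pracma::quadprog(H, f,
                          Aeq = matrix(c(rep(1, n), rep(-1, n)), 1),
                          beq = 0, lb = rep(0, 2 * n), ub = rep(C, 2 * n))
  w <- drop(t(X) %*% (sol$xmin[seq_len(n)] - sol$xmin[n + seq_len(n)]))
  r <- y - drop(X %*% w)
  bp <- sort(c(r - eps, r + eps))
  obj <- vapply(bp, function(b) sum(pmax(0, abs(r - b) - eps)), numeric(1))
  hit <- bp[obj <= min(obj) + 1e-12]
  list(beta = w, offset = (min(hit) + max(hit)) / 2)
}
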