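# Brute-force oracle for the dip statistic.
#
# dip(F_n) = min over unimodal G of sup |F_n - G|.  The minimiser can be
# taken piecewise linear with knots at the sample points and its mode --
# possibly an atom (jump) -- at a sample point: a mode inside a gap is
# always dominated by moving the jump to the knot at the basal end of the
# gap (the post-jump value stays within the band because the next knot
# value must).  For a candidate mode knot k and tolerance d, a unimodal G
# within sup-distance d exists iff the polytope below is non-empty, in
# variables g_1..g_n (knot values) and gminus (left limit at the mode):
#   i/n - d <= g_i <= (i-1)/n + d  for i != k   (bands encode the sup over
#   k/n - d <= g_k <= k/n + d                    open inter-knot intervals)
#   gminus <= (k-1)/n + d;  0 <= g <= 1;  g monotone;
#   g_{k-1} <= gminus <= g_k;
#   segment slopes nondecreasing up to the mode (segment into x_k ends at
#   gminus) and nonincreasing after it.
# Feasibility is checked exactly with quadprog (min ||x||^2 subject to the
# constraints errors out iff the polytope is empty); the dip is found by
# bisection on d, which is valid because feasibility is monotone in d.
dip_lp_oracle <- function(x, tol = 1e-11) {
  x <- sort(as.numeric(x))
  n <- length(x)
  stopifnot(n >= 2, !anyDuplicated(x))
  x <- (x - x[1]) / (x[n] - x[1])  # dip is affine-invariant; condition the LP

  # constraint rows (cons %*% vars >= rhs0 + d * rhsd), vars = (g_1..g_n, gminus)
  build <- function(k) {
    nv <- n + 1L
    rows <- list(); r0 <- numeric(); rd <- numeric()
    add <- function(row, c0, cd) {
      rows[[length(rows) + 1L]] <<- row; r0 <<- c(r0, c0); rd <<- c(rd, cd)
    }
    row0 <- rep(0, nv)
    for (i in seq_len(n)) {
      up <- if (i == k) i / n else (i - 1) / n
      r <- row0; r[i] <- -1; add(r, -up, -1)        # g_i <= up + d
      r <- row0; r[i] <- 1; add(r, i / n, -1)       # g_i >= i/n - d
      r <- row0; r[i] <- -1; add(r, -1, 0)          # g_i <= 1
      r <- row0; r[i] <- 1; add(r, 0, 0)            # g_i >= 0
    }
    r <- row0; r[n + 1] <- -1; add(r, -(k - 1) / n, -1)  # gminus <= (k-1)/n + d
    r <- row0; r[n + 1] <- 1; add(r, 0, 0)               # gminus >= 0
    for (i in seq_len(n - 1)) {
      r <- row0; r[i] <- -1; r[i + 1] <- 1; add(r, 0, 0) # monotone
    }
    if (k > 1) { r <- row0; r[k - 1] <- -1; r[n + 1] <- 1; add(r, 0, 0) }
    r <- row0; r[n + 1] <- -1; r[k] <- 1; add(r, 0, 0)
    slope <- function(i) { # slope of segment i -> i+1 as a linear form
      r <- row0
      to <- if (i + 1 == k) n + 1L else i + 1L
      r[to] <- 1 / (x[i + 1] - x[i]); r[i] <- r[i] - 1 / (x[i + 1] - x[i])
      r
    }
    if (k > 2) for (i in seq_len(k - 2))        # s_i <= s_{i+1}
      add(slope(i + 1) - slope(i), 0, 0)
    if (k < n - 1) for (i in k:(n - 2))         # s_i >= s_{i+1}
      add(slope(i) - slope(i + 1), 0, 0)
    list(A = do.call(rbind, rows), r0 = r0, rd = rd, nv = nv)
  }
  systems <- lapply(seq_len(n), build)

  feasible <- function(d) {
    for (sys in systems) {
      ok <- tryCatch({
        quadprog::solve.QP(Dmat = diag(sys$nv), dvec = rep(0, sys$nv),
                           Amat = t(sys$A), bvec = sys$r0 + d * sys$rd)
        TRUE
      }, error = function(e) FALSE)
      if (ok) return(TRUE)
    }
    FALSE
  }

  lo <- 1 / (2 * n); hi <- 0.25
  if (feasible(lo)) return(lo)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
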