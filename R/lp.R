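# Dense two-phase simplex for small linear programs.
#
#   minimize    c'x
#   subject to  A_le x <= b_le,  A_ge x >= b_ge,  x >= 0
#
# Ration problems have a handful of feeds and nutrients, so a dense tableau
# with Bland's anti-cycling rule is entirely adequate and exactly
# reproducible. Returns status "optimal" | "infeasible" | "unbounded".

solve_lp <- function(cost, A_le = NULL, b_le = NULL, A_ge = NULL,
                     b_ge = NULL, tol = 1e-9) {
  n <- length(cost)
  as_mat <- function(A) if (is.null(A)) matrix(0, 0, n) else
    matrix(as.numeric(A), ncol = n)
  A <- rbind(as_mat(A_le), as_mat(A_ge))
  b <- c(if (is.null(b_le)) numeric(0) else b_le,
         if (is.null(b_ge)) numeric(0) else b_ge)
  dir <- rep(c("le", "ge"), c(NROW(as_mat(A_le)), NROW(as_mat(A_ge))))
  m <- nrow(A)
  if (m == 0L) {   # only x >= 0: optimum at 0 unless some cost < 0
    if (any(cost < -tol)) return(list(status = "unbounded"))
    return(list(status = "optimal", x = numeric(n), value = 0))
  }
  # normalize to b >= 0 (flipping the inequality where needed)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  dir[neg] <- ifelse(dir[neg] == "le", "ge", "le")

  # columns: x (n) | slack/surplus (m) | artificials (for ge rows)
  slack <- diag(m) * ifelse(dir == "le", 1, -1)
  art_rows <- which(dir == "ge")
  n_art <- length(art_rows)
  art <- matrix(0, m, n_art)
  if (n_art) art[cbind(art_rows, seq_len(n_art))] <- 1
  Tab <- cbind(A, slack, art, b)
  n_tot <- n + m + n_art
  basis <- integer(m)
  basis[dir == "le"] <- n + which(dir == "le")
  basis[art_rows] <- n + m + seq_len(n_art)

  run_phase <- function(Tab, basis, phase_cost, allowed) {
    mm <- nrow(Tab)
    repeat {
      cb <- phase_cost[basis]
      red <- as.numeric(cb %*% Tab[, allowed, drop = FALSE]) -
        phase_cost[allowed]
      ent <- allowed[red > tol]
      if (!length(ent))
        return(list(Tab = Tab, basis = basis, status = "optimal"))
      j <- min(ent)                              # Bland's rule
      col <- Tab[, j]
      rows <- which(col > tol)
      if (!length(rows))
        return(list(Tab = Tab, basis = basis, status = "unbounded"))
      ratio <- Tab[rows, n_tot + 1L] / col[rows]
      cand <- rows[ratio <= min(ratio) + tol]
      r <- cand[which.min(basis[cand])]          # Bland tie-break
      Tab[r, ] <- Tab[r, ] / Tab[r, j]
      upd <- setdiff(seq_len(mm), r)
      Tab[upd, ] <- Tab[upd, , drop = FALSE] -
        outer(Tab[upd, j], Tab[r, ])
      basis[r] <- j
    }
  }

  if (n_art) {  # phase 1: drive artificials to zero
    c1 <- c(rep(0, n + m), rep(1, n_art))
    p1 <- run_phase(Tab, basis, c1, seq_len(n_tot))
    if (p1$status != "optimal") return(list(status = "infeasible"))
    Tab <- p1$Tab; basis <- p1$basis
    if (sum(Tab[basis > n + m, n_tot + 1L]) > 1e-7)
      return(list(status = "infeasible"))
    # pivot any zero-level artificial out of the basis where possible
    for (r in which(basis > n + m)) {
      piv <- which(abs(Tab[r, seq_len(n + m)]) > tol)
      if (length(piv)) {
        j <- piv[1]
        Tab[r, ] <- Tab[r, ] / Tab[r, j]
        upd <- setdiff(seq_len(m), r)
        Tab[upd, ] <- Tab[upd, , drop = FALSE] - outer(Tab[upd, j], Tab[r, ])
        basis[r] <- j
      }
    }
  }
  keep <- basis <= n + m   # rows still held by an artificial are redundant
  # artificials cannot re-enter: the allowed set excludes their columns
  c2 <- c(cost, rep(0, m + n_art))
  p2 <- run_phase(Tab[keep, , drop = FALSE], basis[keep], c2,
                  seq_len(n + m))
  if (p2$status == "unbounded") return(list(status = "unbounded"))
  x <- numeric(n)
  inx <- p2$basis <= n
  x[p2$basis[inx]] <- p2$Tab[inx, n_tot + 1L]
  list(status = "optimal", x = x, value = sum(cost * x))
}
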