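# Method of Moving Asymptotes (Svanberg), dense single-node implementation.
# Solves  min f0(x) s.t. fi(x) <= 0, xmin <= x <= xmax  through a sequence of
# separable convex subproblems built from first-order information at the
# current iterate, with adaptively moving lower/upper asymptotes.  The
# subproblem is solved by the standard primal-dual interior-point scheme.

#' One MMA design update
#'
#' @param iter Outer iteration number (asymptotes are initialised for
#'   `iter <= 2`).
#' @param xval Current design (length n).
#' @param xmin,xmax Box bounds (length n).
#' @param xold1,xold2 Previous two iterates.
#' @param f0val,df0dx Objective value and gradient.
#' @param fval,dfdx Constraint values (length m) and m x n gradient matrix.
#' @param low,upp Current asymptotes (updated and returned).
#' @param move Move limit (absolute, same units as x).
#' @param a0,a,c,d Scalars/vectors of the MMA subproblem (defaults give the
#'   common minimisation setup with heavily penalised constraint slack).
#' @return List with `x` (new design), `low`, `upp`, and subproblem slack
#'   diagnostics `y`, `z`.
#' @keywords internal
mma_update <- function(iter, xval, xmin, xmax, xold1, xold2,
                       f0val, df0dx, fval, dfdx, low, upp,
                       move = 0.2, a0 = 1,
                       a = rep(0, length(fval)),
                       c = rep(1000, length(fval)),
                       d = rep(1, length(fval))) {
  n <- length(xval)
  m <- length(fval)
  dfdx <- matrix(dfdx, nrow = m)
  raa0 <- 1e-5
  albefa <- 0.1
  asyinit <- 0.5
  asyincr <- 1.2
  asydecr <- 0.7
  xmami <- pmax(xmax - xmin, 1e-5)
  if (iter <= 2) {
    low <- xval - asyinit * xmami
    upp <- xval + asyinit * xmami
  } else {
    zzz <- (xval - xold1) * (xold1 - xold2)
    fac <- rep(1, n)
    fac[zzz > 0] <- asyincr
    fac[zzz < 0] <- asydecr
    low <- xval - fac * (xold1 - low)
    upp <- xval + fac * (upp - xold1)
    low <- pmin(pmax(low, xval - 10 * xmami), xval - 0.01 * xmami)
    upp <- pmax(pmin(upp, xval + 10 * xmami), xval + 0.01 * xmami)
  }
  alfa <- pmax(pmax(low + albefa * (xval - low), xval - move), xmin)
  beta <- pmin(pmin(upp - albefa * (upp - xval), xval + move), xmax)
  ux1 <- upp - xval
  xl1 <- xval - low
  ux2 <- ux1^2
  xl2 <- xl1^2
  p0 <- pmax(df0dx, 0)
  q0 <- pmax(-df0dx, 0)
  pq0 <- 0.001 * (p0 + q0) + raa0 / xmami
  p0 <- (p0 + pq0) * ux2
  q0 <- (q0 + pq0) * xl2
  P <- pmax(dfdx, 0)
  Q <- pmax(-dfdx, 0)
  PQ <- 0.001 * (P + Q) + raa0 * matrix(1 / xmami, m, n, byrow = TRUE)
  P <- (P + PQ) * matrix(ux2, m, n, byrow = TRUE)
  Q <- (Q + PQ) * matrix(xl2, m, n, byrow = TRUE)
  b <- as.numeric(P %*% (1 / ux1) + Q %*% (1 / xl1)) - fval
  sol <- mma_subsolve(m, n, low, upp, alfa, beta, p0, q0, P, Q, a0, a, b, c, d)
  list(x = sol$x, low = low, upp = upp, y = sol$y, z = sol$z)
}

# Primal-dual interior-point solver for the MMA subproblem.
mma_subsolve <- function(m, n, low, upp, alfa, beta, p0, q0, P, Q,
                         a0, a, b, c, d) {
  epsi <- 1
  x <- 0.5 * (alfa + beta)
  y <- rep(1, m)
  z <- 1
  lam <- rep(1, m)
  xsi <- pmax(1 / (x - alfa), 1)
  eta <- pmax(1 / (beta - x), 1)
  mu <- pmax(1, 0.5 * c)
  zet <- 1
  s <- rep(1, m)
  while (epsi > 1e-7) {
    ux1 <- upp - x; xl1 <- x - low
    plam <- p0 + as.numeric(crossprod(P, lam))
    qlam <- q0 + as.numeric(crossprod(Q, lam))
    gvec <- as.numeric(P %*% (1 / ux1) + Q %*% (1 / xl1))
    dpsidx <- plam / ux1^2 - qlam / xl1^2
    rex <- dpsidx - xsi + eta
    rey <- c + d * y - mu - lam
    rez <- a0 - zet - sum(a * lam)
    relam <- gvec - a * z - y + s - b
    rexsi <- xsi * (x - alfa) - epsi
    reeta <- eta * (beta - x) - epsi
    remu <- mu * y - epsi
    rezet <- zet * z - epsi
    res <- lam * s - epsi
    resid <- c(rex, rey, rez, relam, rexsi, reeta, remu, rezet, res)
    residunorm <- sqrt(sum(resid^2))
    residumax <- max(abs(resid))
    it <- 0
    while (residumax > 0.9 * epsi && it < 200) {
      it <- it + 1
      ux1 <- upp - x; xl1 <- x - low
      ux2 <- ux1^2; xl2 <- xl1^2
      ux3 <- ux1 * ux2; xl3 <- xl1 * xl2
      plam <- p0 + as.numeric(crossprod(P, lam))
      qlam <- q0 + as.numeric(crossprod(Q, lam))
      gvec <- as.numeric(P %*% (1 / ux1) + Q %*% (1 / xl1))
      GG <- P * matrix(1 / ux2, m, n, byrow = TRUE) -
            Q * matrix(1 / xl2, m, n, byrow = TRUE)
      dpsidx <- plam / ux2 - qlam / xl2
      delx <- dpsidx - epsi / (x - alfa) + epsi / (beta - x)
      dely <- c + d * y - lam - epsi / y
      delz <- a0 - sum(a * lam) - epsi / z
      dellam <- gvec - a * z - y - b + epsi / lam
      diagx <- 2 * (plam / ux3 + qlam / xl3) +
        xsi / (x - alfa) + eta / (beta - x)
      diagy <- d + mu / y
      diaglam <- s / lam
      diaglamyi <- diaglam + 1 / diagy
      # m << n: eliminate x, solve the m x m (plus z) system
      blam <- dellam + dely / diagy -
        as.numeric(GG %*% (delx / diagx))
      Alam <- diag(diaglamyi, m) +
        GG %*% (t(GG) / diagx)
      AA <- rbind(cbind(Alam, a), c(a, -zet / z))
      bb <- c(blam, delz)
      solut <- solve(AA, bb)
      dlam <- solut[1:m]
      dz <- solut[m + 1]
      dx <- -delx / diagx - as.numeric(crossprod(GG, dlam)) / diagx
      dy <- -dely / diagy + dlam / diagy
      dxsi <- -xsi + epsi / (x - alfa) - (xsi * dx) / (x - alfa)
      deta <- -eta + epsi / (beta - x) + (eta * dx) / (beta - x)
      dmu <- -mu + epsi / y - (mu * dy) / y
      dzet <- -zet + epsi / z - zet * dz / z
      ds <- -s + epsi / lam - (s * dlam) / lam
      xx <- c(y, z, lam, xsi, eta, mu, zet, s)
      dxx <- c(dy, dz, dlam, dxsi, deta, dmu, dzet, ds)
      stepxx <- -1.01 * dxx / xx
      stmxx <- max(stepxx)
      stepalfa <- -1.01 * dx / (x - alfa)
      stmalfa <- max(stepalfa)
      stepbeta <- 1.01 * dx / (beta - x)
      stmbeta <- max(stepbeta)
      stminv <- max(stmalfa, stmbeta, stmxx, 1)
      steg <- 1 / stminv
      xold <- x; yold <- y; zold <- z; lamold <- lam
      xsiold <- xsi; etaold <- eta; muold <- mu; zetold <- zet; sold <- s
      itto <- 0
      repeat {
        itto <- itto + 1
        x <- xold + steg * dx
        y <- yold + steg * dy
        z <- zold + steg * dz
        lam <- lamold + steg * dlam
        xsi <- xsiold + steg * dxsi
        eta <- etaold + steg * deta
        mu <- muold + steg * dmu
        zet <- zetold + steg * dzet
        s <- sold + steg * ds
        ux1 <- upp - x; xl1 <- x - low
        plam <- p0 + as.numeric(crossprod(P, lam))
        qlam <- q0 + as.numeric(crossprod(Q, lam))
        gvec <- as.numeric(P %*% (1 / ux1) + Q %*% (1 / xl1))
        dpsidx <- plam / ux1^2 - qlam / xl1^2
        resid <- c(dpsidx - xsi + eta,
                   c + d * y - mu - lam,
                   a0 - zet - sum(a * lam),
                   gvec - a * z - y + s - b,
                   xsi * (x - alfa) - epsi,
                   eta * (beta - x) - epsi,
                   mu * y - epsi,
                   zet * z - epsi,
                   lam * s - epsi)
        resinew <- sqrt(sum(resid^2))
        if (resinew <= residunorm || itto >= 50) break
        steg <- steg / 2
      }
      residunorm <- resinew
      residumax <- max(abs(resid))
    }
    epsi <- 0.1 * epsi
  }
  list(x = x, y = y, z = z, lam = lam)
}
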