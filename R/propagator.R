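# Pure-R Arnoldi exp(tau A) v for the density-matrix oracle. Kept fully
# independent of the compiled trajectory propagator so the two can serve
# as cross-checks of each other.

# complex dense matrix exponential, scaling-and-squaring + Pade(6,6)
expm_complex <- function(A) {
  stopifnot(nrow(A) == ncol(A))
  n <- nrow(A)
  nrmA <- max(colSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrmA, .Machine$double.xmin) / 0.5)))
  As <- A / 2^s
  b <- c(1, 1 / 2, 5 / 44, 1 / 66, 1 / 792, 1 / 15840, 1 / 665280)
  I <- diag(1 + 0i, n)
  A2 <- As %*% As
  A4 <- A2 %*% A2
  A6 <- A2 %*% A4
  U <- As %*% (b[2] * I + b[4] * A2 + b[6] * A4)
  V <- b[1] * I + b[3] * A2 + b[5] * A4 + b[7] * A6
  F <- solve(V - U, V + U)
  for (k in seq_len(s)) F <- F %*% F
  F
}

# exp(tau * A) v where A is given as a matvec closure; restarted Arnoldi
# with adaptive substeps (used at small dimension only).
expmv_arnoldi <- function(afun, v, tau, m = 30, tol = 1e-10) {
  if (tau <= 0) return(v)
  n <- length(v)
  m <- min(m, n)
  t_done <- 0
  dt <- tau
  while (t_done < tau * (1 - 1e-14)) {
    beta <- sqrt(sum(Mod(v)^2))
    if (beta == 0) return(v)
    V <- matrix(0i, n, m + 1)
    Hm <- matrix(0i, m + 1, m)
    V[, 1] <- v / beta
    meff <- m
    breakdown <- FALSE
    for (j in seq_len(m)) {
      w <- afun(V[, j])
      for (i in seq_len(j)) {
        h <- sum(Conj(V[, i]) * w)
        Hm[i, j] <- h
        w <- w - h * V[, i]
      }
      for (i in seq_len(j)) { # re-orthogonalize
        h <- sum(Conj(V[, i]) * w)
        Hm[i, j] <- Hm[i, j] + h
        w <- w - h * V[, i]
      }
      hn <- sqrt(sum(Mod(w)^2))
      Hm[j + 1, j] <- hn
      if (hn < 1e-12 * max(1, beta)) {
        meff <- j
        breakdown <- TRUE
        break
      }
      V[, j + 1] <- w / hn
    }
    dt <- min(dt, tau - t_done)
    repeat {
      F <- expm_complex(dt * Hm[seq_len(meff), seq_len(meff), drop = FALSE])
      err <- if (breakdown) 0 else
        beta * Mod(Hm[meff + 1, meff]) * Mod(F[meff, 1]) * dt
      if (err <= max(tol * max(1, beta), 1e-15) || dt < 1e-12) {
        v <- beta * (V[, seq_len(meff), drop = FALSE] %*% F[, 1])[, 1]
        t_done <- t_done + dt
        if (err < 0.05 * tol * max(1, beta)) dt <- 2 * dt
        break
      }
      dt <- dt / 2
    }
  }
  v
}

# Diagonal of sum_m gamma_m J_m^+ J_m over a mask basis: loss contributes
# gamma_l * (number of up spins), dephasing gamma_d * M (identity).
decay_diagonal <- function(spec, masks) {
  spec$gamma_loss * popcount(masks) +
    spec$gamma_dephase * spec$n_sites + 0 * masks
}

# thin wrapper so R code has one entry point into the compiled propagator
krylov_propagate <- function(H, d, psi, tau, m = 30, tol = 1e-9) {
  cpp_krylov_propagate(H, d, as.complex(psi), tau, as.integer(m), tol)
}

# ---- cached spectral decompositions --------------------------------------
# Closed dynamics reuse one Hamiltonian across hundreds of trajectories;
# for moderate dimensions a dense eigendecomposition H = U diag(lam) U^T,
# computed once and cached, turns every propagation into two BLAS-3
# products. Above `dense_limit` (or with dissipation) the Krylov
# propagator is used instead.

.eig_cache <- new.env(parent = emptyenv())

dense_limit <- function() 2048L

spec_key <- function(spec, extra = "") {
  paste(spec$n_sites, spec$connectivity, spec$J, spec$delta0,
        spec$sigma_int,
        paste(which(spec$adjacency == 1), collapse = ","),
        extra, sep = "|")
}

cached_hamiltonian <- function(spec) {
  key <- spec_key(spec, "H")
  hit <- .eig_cache[[key]]
  if (!is.null(hit)) return(hit)
  H <- build_hamiltonian(spec)
  .eig_cache[[key]] <- H
  H
}

get_eigen <- function(spec, H = NULL, key = spec_key(spec)) {
  hit <- .eig_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (is.null(H)) H <- build_hamiltonian(spec)
  e <- eigen(as.matrix(H), symmetric = TRUE)
  val <- list(U = e$vectors, lam = e$values)
  if (length(.eig_cache) > 8) rm(list = ls(.eig_cache), envir = .eig_cache)
  .eig_cache[[key]] <- val
  val
}

# psi(t0 + tau) = U exp(-i lam tau) U^T psi
dense_propagate <- function(eig, psi, tau) {
  if (tau <= 0) return(psi)
  c0 <- crossprod(eig$U, cbind(Re(psi), Im(psi)))
  cc <- (c0[, 1] + 1i * c0[, 2]) * exp(-1i * eig$lam * tau)
  out <- eig$U %*% cbind(Re(cc), Im(cc))
  out[, 1] + 1i * out[, 2]
}

# record magnetization at successive intervals `taus`; one BLAS-3 product
# maps all recorded states back to the site basis at once
dense_propagate_record <- function(eig, zs, psi, taus) {
  c0 <- crossprod(eig$U, cbind(Re(psi), Im(psi)))
  cc <- c0[, 1] + 1i * c0[, 2]
  tt <- cumsum(taus)
  C <- cc * exp(outer(-1i * eig$lam, tt))   # dim x n_times
  PsiR <- eig$U %*% Re(C)
  PsiI <- eig$U %*% Im(C)
  P2 <- PsiR^2 + PsiI^2
  tot <- colSums(P2)
  mag <- sweep(zs %*% P2, 2, tot, "/")
  psiT <- PsiR[, length(tt)] + 1i * PsiI[, length(tt)]
  list(mag = as.matrix(mag), psi = psiT, norm = sqrt(tot))
}
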