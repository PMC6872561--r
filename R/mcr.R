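#' Exact non-negative least squares for many right-hand sides
#'
#' Solves `min ||d_i - A c_i||^2, c_i >= 0` for every row `d_i` of `D`
#' against a common design `A`. For small numbers of components the
#' global optimum is found by enumerating support sets: the NNLS optimum
#' restricted to its own support is the unconstrained least-squares
#' solution there, so scanning all supports, keeping the feasible ones,
#' and taking the lowest residual is exact — and vectorizes over all rows
#' at once. Above 8 components it falls back to `pracma::lsqnonneg` per
#' row.
#'
#' @param D matrix (rows = problems, columns = observations).
#' @param A design matrix (observations x components).
#' @param ridge small non-negative diagonal loading for rank-deficient
#'   designs.
#' @return Matrix of non-negative coefficients (rows x components).
#' @keywords internal
nnls_rows <- function(D, A, ridge = 0) {
  k <- ncol(A)
  n <- nrow(D)
  if (k > 8L) {
    out <- t(apply(D, 1L, function(d) pracma::lsqnonneg(A, d)$x))
    return(matrix(out, nrow = n, ncol = k))
  }
  rss0 <- rowSums(D * D)
  best_res <- rss0                 # the all-zero solution
  best_C <- matrix(0, n, k)
  G_full <- crossprod(A) + diag(ridge, k)
  B_full <- D %*% A                # n x k
  for (mask in seq_len(2^k - 1L)) {
    s <- which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0L)
    G <- G_full[s, s, drop = FALSE]
    if (rcond(G) < 1e-12) next
    Cs <- B_full[, s, drop = FALSE] %*% solve(G)       # n x |s|
    feas <- rowSums(Cs < -1e-10) == 0L
    if (!any(feas)) next
    fit <- rowSums(Cs * B_full[, s, drop = FALSE])
    res <- rss0 - fit
    upd <- feas & (res < best_res - 1e-12)
    if (any(upd)) {
      best_res[upd] <- res[upd]
      best_C[upd, ] <- 0
      best_C[upd, s] <- pmax(Cs[upd, , drop = FALSE], 0)
    }
  }
  best_C
}

#' Initial pure-component spectra from reference cubes
#'
#' Mirrors the experimental initialization of the bianalyte unmixing:
#' normalized spectra obtained from isotopically pure samples. Per
#' reference cube (already denoised and baseline-corrected), the pixels in
#' the top intensity decile are averaged, negatives are clipped to zero,
#' and the spectrum is normalized to unit maximum.
#'
#' @param pure_cubes list of corrected [hyper_cube()]s, one per species.
#' @param top_fraction fraction of brightest pixels averaged (default 0.1).
#' @return Matrix `S0` (components x channels), rows named by list names.
#' @export
build_reference_spectra <- function(pure_cubes, top_fraction = 0.1) {
  if (inherits(pure_cubes, "hyper_cube")) pure_cubes <- list(pure_cubes)
  S0 <- t(vapply(pure_cubes, function(cb) {
    m <- cube_matrix(cb)
    mx <- apply(m, 1L, max)
    if (max(mx) <= 0) stop("reference cube has no pixel above noise floor")
    thr <- quantile(mx, 1 - top_fraction)
    sel <- mx >= thr
    s <- colMeans(m[sel, , drop = FALSE])
    s <- pmax(s, 0)
    if (max(s) <= 0) stop("reference cube has no pixel above noise floor")
    s / max(s)
  }, numeric(pure_cubes[[1]]$axis$n_channels)))
  if (nrow(S0) > 1L) {
    for (i in seq_len(nrow(S0) - 1L)) {
      for (j in (i + 1L):nrow(S0)) {
        if (max(abs(S0[i, ] - S0[j, ])) < 1e-8)
          warning("reference spectra ", i, " and ", j,
                  " are identical; unmixing will be degenerate")
      }
    }
  }
  if (!is.null(names(pure_cubes))) rownames(S0) <- names(pure_cubes)
  S0
}

#' Multivariate curve resolution by alternating least squares
#'
#' Bilinear factorization `D ~ C S` of pixel spectra into non-negative
#' concentration profiles `C` and non-negative component spectra `S`,
#' fitted by alternating exact NNLS updates: `C` given `S`, then `S` given
#' `C`, then each row of `S` renormalized to unit maximum with the scale
#' absorbed into `C`. Because every half-step solves its subproblem
#' exactly, the residual norm is non-increasing across iterations.
#' Convergence is declared when the relative change in lack of fit,
#' `lof = 100 * sqrt(sum((D - CS)^2) / sum(D^2))`, drops below `tol`.
#'
#' @param D matrix (pixels x channels), baseline-corrected.
#' @param S0 initial spectra estimate (components x channels), e.g. from
#'   [build_reference_spectra()].
#' @param max_iter maximum alternations (default 50).
#' @param tol relative lack-of-fit change tolerance (default 1e-4).
#' @return An object of class `mcr_result`: `C` (pixels x components),
#'   `S` (components x channels, unit-maximum rows), `lof_trace`,
#'   `iterations`, `converged`.
#' @export
mcr_als <- function(D, S0, max_iter = 50L, tol = 1e-4) {
  D <- as.matrix(D)
  S <- matrix(as.numeric(S0), nrow = NROW(S0), ncol = NCOL(S0))
  rownames(S) <- rownames(S0)
  if (ncol(S) != ncol(D)) stop("S0 channels do not match D")
  if (any(S < 0)) stop("S0 must be non-negative")
  ridge <- 0
  if (nrow(S) > 1L && rcond(tcrossprod(S)) < 1e-10) {
    warning("rank-deficient S0; using ridge-stabilized updates")
    ridge <- 1e-8 * max(rowSums(S^2))
  }
  if (mean(D < 0) > 0.5)
    warning("D is negative-dominated; was the baseline subtracted?")
  ssD <- sum(D^2)
  lof <- function(C, S) 100 * sqrt(sum((D - C %*% S)^2) / ssD)
  trace <- numeric(0)
  C <- NULL
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    C <- nnls_rows(D, t(S), ridge = ridge)
    S <- t(nnls_rows(t(D), C, ridge = ridge))
    rn <- apply(S, 1L, max)
    live <- rn > 0
    S[live, ] <- S[live, , drop = FALSE] / rn[live]
    C[, live] <- C[, live, drop = FALSE] *
      rep(rn[live], each = nrow(C))
    trace <- c(trace, lof(C, S))
    if (it >= 2L) {
      prev <- trace[it - 1L]
      if (abs(prev - trace[it]) <= tol * max(prev, .Machine$double.eps)) {
        converged <- TRUE
        break
      }
    }
  }
  if (any(colSums(C) == 0))
    warning("component(s) ", paste(which(colSums(C) == 0), collapse = ", "),
            " vanished during fitting")
  structure(list(C = C, S = S, lof_trace = trace, iterations = it,
                 converged = converged),
            class = "mcr_result")
}

#' @export
print.mcr_result <- function(x, ...) {
  cat(sprintf(
    "<mcr_result> %d pixels x %d components, lof %.3g%% after %d iterations (%sconverged)\n",
    nrow(x$C), ncol(x$C), tail(x$lof_trace, 1L), x$iterations,
    if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Unmix a corrected cube into per-component concentration images
#'
#' Thin wrapper around [mcr_als()] that flattens the cube to pixels x
#' channels and reshapes the recovered concentration columns back onto
#' the image grid.
#'
#' @param cube a corrected [hyper_cube()].
#' @param S0 initial spectra (components x channels).
#' @param max_iter,tol passed to [mcr_als()].
#' @return List with `result` (the `mcr_result`) and `maps` (list of
#'   concentration images aligned with the cube grid, one per component).
#' @export
unmix_cube <- function(cube, S0, max_iter = 50L, tol = 1e-4) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$data)
  res <- mcr_als(cube_matrix(cube), S0, max_iter = max_iter, tol = tol)
  maps <- lapply(seq_len(ncol(res$C)), function(i)
    matrix(res$C[, i], d[1], d[2]))
  names(maps) <- rownames(res$S)
  list(result = res, maps = maps)
}
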