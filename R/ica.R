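#' Independent component analysis of rank-reduced EEG
#'
#' Linearly decomposes multichannel data into maximally independent
#' sources.  Two algorithms are provided behind one contract: an
#' extended-Infomax-style natural-gradient ascent (the default), which
#' adapts per-component sub/super-Gaussian nonlinearities, and a
#' fixed-point negentropy (FastICA-style) iteration with symmetric
#' decorrelation.  Either way the returned decomposition satisfies
#' `unmixing %*% mixing = I` on the retained subspace and reconstructs the
#' rank-reduced input exactly.
#'
#' Components are returned in descending order of mean projected variance,
#' with each scalp topography scaled to unit norm and its sign fixed so
#' the largest-magnitude weight is positive -- a deterministic polarity
#' convention that the clustering and ERP stages rely on.
#'
#' @param x channels x samples matrix, or an `ica_ready` object from
#'   [prepare_for_ica()].
#' @param algorithm `"extended-infomax"` or `"fixed-point-negentropy"`.
#' @param seed integer seed for the random initial rotation (and block
#'   permutations).
#' @param max_iter maximum passes over the data (for the natural-gradient
#'   algorithm this bounds both the stochastic phase and the full-batch
#'   refinement phase that follows it).
#' @param tol convergence tolerance on the weight change.
#' @param rank number of components; defaults to the numerical rank of
#'   `x` (or the rank recorded by `prepare_for_ica`).
#' @param max_samples if the data has more samples than this, the
#'   unmixing matrix is estimated on an evenly spaced subsample of this
#'   size (activations are still computed on the full data).  `Inf`
#'   disables subsampling.
#' @return object of class `decomposition`: `unmixing` (rank x channels),
#'   `mixing` (channels x rank, unit-norm topographies as columns),
#'   `activations` (rank x samples), `rank`, `algorithm`, `seed`,
#'   `converged`, `n_iter`, and epoch bookkeeping when available.
#' @export
run_ica <- function(x, algorithm = c("extended-infomax", "fixed-point-negentropy"),
                    seed = 1L, max_iter = 200L, tol = 1e-6, rank = NULL,
                    max_samples = Inf) {
  algorithm <- match.arg(algorithm)
  meta <- NULL
  if (inherits(x, "ica_ready")) {
    meta <- x
    rank <- rank %||% x$rank
    x <- x$data
  }
  x <- as.matrix(x)
  n_ch <- nrow(x); n_s <- ncol(x)
  if (any(!is.finite(x))) stop_invalid("data must be finite")

  sv <- svd(x, nu = min(n_ch, 30L), nv = 0L)
  if (sv$d[1L] == 0) stop_invalid("zero-variance input")
  if (is.null(rank)) rank <- sum(sv$d > 1e-7 * sv$d[1L])
  if (n_s <= 20L * rank) {
    stop_invalid("need more than 20 x rank (= %d) samples, got %d",
                 20L * rank, n_s)
  }

  xf <- if (is.finite(max_samples) && n_s > max_samples) {
    x[, as.integer(seq(1L, n_s, length.out = max_samples)), drop = FALSE]
  } else x
  mu <- rowMeans(xf)
  xc <- xf - mu
  # whitening restricted to the top-`rank` subspace
  sv <- svd(xc, nu = rank, nv = 0L)
  d <- sv$d[seq_len(rank)] / sqrt(ncol(xf))
  U <- sv$u
  z <- crossprod(U, xc) / d  # rank x samples, identity covariance

  rng <- local_rng(derive_seed(seed, 3L))
  on.exit(rng$restore())
  W0 <- random_rotation(rank)

  res <- if (algorithm == "extended-infomax") {
    infomax_ext(z, W0, max_iter = max_iter, tol = tol)
  } else {
    fastica_sym(z, W0, max_iter = max_iter, tol = tol)
  }
  W <- res$W  # rank x rank, (near-)orthonormal in whitened space

  unmixing <- (W / d[col(W)]) %*% t(U)      # rank x channels
  mixing <- U %*% (t(W) * d)                # channels x rank
  acts <- unmixing %*% x

  # order by mean projected variance, unit-norm + sign-fixed topographies
  pvar <- colSums(mixing^2) * apply(acts, 1L, function(a) mean(a^2))
  ord <- order(pvar, decreasing = TRUE)
  mixing <- mixing[, ord, drop = FALSE]
  unmixing <- unmixing[ord, , drop = FALSE]
  acts <- acts[ord, , drop = FALSE]
  nrm <- sqrt(colSums(mixing^2))
  sgn <- vapply(seq_len(rank), function(i) {
    v <- mixing[, i]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  mixing <- sweep(mixing, 2L, nrm * sgn, "/")
  unmixing <- sweep(unmixing, 1L, nrm * sgn, "*")
  acts <- sweep(acts, 1L, nrm * sgn, "*")

  out <- list(unmixing = unmixing, mixing = mixing, activations = acts,
              rank = rank, algorithm = algorithm, seed = seed,
              converged = res$converged, n_iter = res$n_iter)
  if (!res$converged) {
    warning(sprintf("ICA did not reach tol %.1e in %d iterations", tol,
                    max_iter))
  }
  if (!is.null(meta)) {
    out$n_epochs <- meta$n_epochs
    out$samples_per_epoch <- meta$samples_per_epoch
    out$sampling_rate <- meta$sampling_rate
    out$epoch_stimulus <- meta$epoch_stimulus
  }
  structure(out, class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> %d components (%s, %s after %d iterations)\n",
              x$rank, x$algorithm,
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

random_rotation <- function(n) {
  qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
}

# Extended Infomax: natural-gradient ascent with per-component
# sub/super-Gaussian switching, block updates, annealed learning rate.
infomax_ext <- function(z, W, max_iter, tol, block = 512L) {
  n <- nrow(z); ns <- ncol(z)
  block <- min(block, ns)
  lr <- 0.015 / log(n + 2)
  signs <- rep(1, n)  # +1 super-Gaussian, -1 sub-Gaussian
  I_n <- diag(n)
  converged <- FALSE
  it <- 0L
  probe <- as.integer(seq(1L, ns, length.out = min(ns, 4096L)))
  old_change <- NULL
  for (it in seq_len(max_iter)) {
    W_old <- W
    perm <- sample.int(ns)
    for (s in seq(1L, ns - block + 1L, by = block)) {
      ix <- perm[s:(s + block - 1L)]
      u <- W %*% z[, ix, drop = FALSE]
      y <- tanh(u)
      grad <- I_n - (signs * y) %*% t(u) / block - u %*% t(u) / block
      W <- W + lr * grad %*% W
      if (!all(is.finite(W)) || max(abs(W)) > 1e6) {  # diverged: back off
        W <- W_old
        lr <- lr / 2
        break
      }
    }
    # re-estimate sub/super-Gaussian signs from the kurtosis sign
    u <- W %*% z[, probe, drop = FALSE]
    k <- rowMeans(u^4) / rowMeans(u^2)^2 - 3
    signs <- ifelse(k >= 0, 1, -1)
    change <- W - W_old
    if (max(abs(change)) < tol) { converged <- TRUE; break }
    # anneal only when successive update directions oscillate (> 60 deg),
    # so the step size stays large while progress is steady
    if (!is.null(old_change)) {
      denom <- sqrt(sum(change^2) * sum(old_change^2))
      if (denom > 0 && sum(change * old_change) / denom < 0.5) {
        lr <- lr * 0.9
      }
    }
    old_change <- change
  }
  # full-batch natural-gradient polish: removes the stochastic-update
  # noise floor so runs land on the empirical optimum deterministically
  lr_fb <- 0.2
  for (jt in seq_len(max_iter)) {
    u <- W %*% z
    y <- tanh(u)
    grad <- I_n - (signs * y) %*% t(u) / ns - u %*% t(u) / ns
    W_new <- W + lr_fb * grad %*% W
    if (!all(is.finite(W_new)) || max(abs(W_new)) > 1e6) {
      lr_fb <- lr_fb / 2
      next
    }
    delta <- max(abs(W_new - W))
    W <- W_new
    it <- it + 1L
    if (delta < tol * lr_fb) { converged <- TRUE; break }
    lr_fb <- min(1, lr_fb * 1.02)
  }
  # polish orthonormality in the whitened space
  s <- svd(W)
  list(W = s$u %*% t(s$v), converged = converged, n_iter = it)
}

# FastICA with tanh contrast and symmetric decorrelation.
fastica_sym <- function(z, W, max_iter, tol) {
  ns <- ncol(z)
  sym <- function(M) {
    s <- svd(M)
    s$u %*% t(s$v)
  }
  W <- sym(W)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    u <- W %*% z
    g <- tanh(u)
    gp <- rowMeans(1 - g^2)
    W_new <- sym(g %*% t(z) / ns - gp * W)
    d <- max(abs(abs(rowSums(W_new * W)) - 1))
    W <- W_new
    if (d < tol) { converged <- TRUE; break }
  }
  list(W = W, converged = converged, n_iter = it)
}

#' Amari separation index
#'
#' Permutation- and scale-invariant distance between an estimated
#' unmixing matrix and a true mixing matrix; 0 means perfect separation.
#'
#' @param unmixing estimated unmixing (k x channels).
#' @param mixing true mixing (channels x k).
#' @return non-negative scalar.
#' @export
amari_index <- function(unmixing, mixing) {
  P <- abs(unmixing %*% mixing)
  n <- nrow(P)
  r <- sum(rowSums(P / apply(P, 1L, max)) - 1)
  c <- sum(colSums(t(t(P) / apply(P, 2L, max))) - 1)
  (r + c) / (2 * n * (n - 1))
}

#' Match estimated components to reference signals
#'
#' Finds the one-to-one assignment maximizing the total absolute Pearson
#' correlation between rows of `est` and rows of `ref` (exhaustive over
#' permutations for up to 8 signals, greedy beyond).
#'
#' @param est,ref matrices with one signal per row.
#' @return list with `assignment` (for each ref row, the matched est row)
#'   and `correlations` (absolute correlation per matched pair).
#' @export
match_components <- function(est, ref) {
  C <- abs(stats::cor(t(ref), t(est)))
  k <- nrow(C)
  if (k <= 8L && ncol(C) == k) {
    perms <- all_permutations(k)
    scores <- vapply(perms, function(p) sum(C[cbind(seq_len(k), p)]),
                     numeric(1))
    best <- perms[[which.max(scores)]]
  } else {
    best <- integer(k)
    avail <- rep(TRUE, ncol(C))
    for (i in order(apply(C, 1L, max), decreasing = TRUE)) {
      j <- which.max(ifelse(avail, C[i, ], -1))
      best[i] <- j
      avail[j] <- FALSE
    }
  }
  list(assignment = best, correlations = C[cbind(seq_len(k), best)])
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 1L
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[i]] <- append(p, n, after = pos - 1L)
      i <- i + 1L
    }
  }
  out
}
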