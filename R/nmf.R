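# Nonnegative matrix factorization minimizing generalized Kullback-Leibler
# divergence, the standard model for Poisson-distributed mutation counts,
# with multiplicative updates and nonnegative-double-SVD initialization.

#' Bootstrap-resample a mutation catalog
#'
#' Redraws each sample's channel counts from a multinomial with that
#' sample's total and relative spectrum, conserving per-sample totals
#' exactly. Zero-total samples are preserved as zero rows.
#'
#' @param catalog A [mutation_catalog()].
#' @param seed Integer seed.
#' @return A resampled [mutation_catalog()] of the same shape.
#' @export
bootstrap_catalog <- function(catalog, seed) {
  counts <- unclass(catalog)
  out <- counts
  for (i in seq_len(nrow(counts))) {
    n <- sum(counts[i, ])
    if (n > 0) {
      # per-sample stream: resampling does not depend on sample order
      set.seed(stage_seed(seed, rownames(counts)[i]))
      out[i, ] <- as.vector(stats::rmultinom(1, n, counts[i, ] / n))
    }
  }
  mutation_catalog(out, catalog_schema(catalog))
}

# Generalized KL divergence D(V || WH); terms with V = 0 contribute WH.
kl_divergence <- function(V, WH) {
  pos <- V > 0
  sum(V[pos] * log(V[pos] / WH[pos])) - sum(V[pos]) + sum(WH)
}

# Nonnegative double SVD initialization (NNDSVDa variant: zeros replaced by
# the matrix mean, which suits multiplicative updates).
nndsvd_init <- function(V, k) {
  sv <- svd(V, nu = k, nv = k)
  W <- matrix(0, nrow(V), k); H <- matrix(0, k, ncol(V))
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k > 1) for (j in 2:k) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    n_up <- sqrt(sum(up^2)); n_vp <- sqrt(sum(vp^2))
    n_un <- sqrt(sum(un^2)); n_vn <- sqrt(sum(vn^2))
    if (n_up * n_vp >= n_un * n_vn) {
      sig <- n_up * n_vp
      if (sig > 0) {
        W[, j] <- sqrt(sv$d[j] * sig) * up / n_up
        H[j, ] <- sqrt(sv$d[j] * sig) * vp / n_vp
      }
    } else {
      sig <- n_un * n_vn
      W[, j] <- sqrt(sv$d[j] * sig) * un / n_un
      H[j, ] <- sqrt(sv$d[j] * sig) * vn / n_vn
    }
  }
  m <- mean(V)
  W[W <= 0] <- m; H[H <= 0] <- m
  list(W = W, H = H)
}

#' KL-divergence NMF by multiplicative updates
#'
#' Factorizes a nonnegative channels x samples matrix `V` as `W %*% H` with
#' `k` signatures, minimizing the generalized Kullback-Leibler divergence.
#' The multiplicative updates guarantee a non-increasing objective. On
#' return, columns of `W` are normalized to sum to one with the
#' compensating scale moved into `H`.
#'
#' @param V Nonnegative matrix, channels in rows, samples in columns.
#' @param k Number of signatures (1 <= k <= min(dim(V))).
#' @param seed Seed for the random initialization.
#' @param max_iter Maximum update iterations. Default 500.
#' @param tol Relative objective-change stopping tolerance (checked every 10
#'   iterations). Default 1e-6.
#' @param init `"nndsvd"` (deterministic SVD-based start) or `"random"`.
#' @return List with `W` (channels x k, columns sum to 1), `H`
#'   (k x samples), `objective` (final KL divergence), `objective_trace`,
#'   `iterations`, `converged`.
#' @export
nmf_kl <- function(V, k, seed = 1L, max_iter = 500L, tol = 1e-6,
                   init = c("nndsvd", "random")) {
  init <- match.arg(init)
  V <- as.matrix(V)
  if (any(V < 0)) stop("V must be nonnegative")
  if (k < 1 || k > min(dim(V)))
    stop("k must lie in 1..min(channels, samples)")
  if (any(colSums(V) == 0))
    stop("V has all-zero sample column(s); drop them before factorizing")
  eps <- .Machine$double.eps
  if (init == "nndsvd") {
    ini <- nndsvd_init(V, k)
    W <- ini$W; H <- ini$H
  } else {
    set.seed(seed)
    W <- matrix(stats::runif(nrow(V) * k, 0.1, 1), nrow(V), k)
    H <- matrix(stats::runif(k * ncol(V), 0.1, 1) * mean(V), k, ncol(V))
  }
  W <- pmax(W, eps); H <- pmax(H, eps)
  trace <- numeric(0)
  obj_prev <- Inf; converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    WH <- W %*% H
    H <- H * crossprod(W, V / pmax(WH, eps)) / colSums(W)
    WH <- W %*% H
    W <- W * ((V / pmax(WH, eps)) %*% t(H)) / rep(rowSums(H), each = nrow(W))
    W <- pmax(W, eps); H <- pmax(H, eps)
    if (it %% 10L == 0L || it == max_iter) {
      obj <- kl_divergence(V, W %*% H)
      trace <- c(trace, obj)
      if (is.finite(obj_prev) &&
          (obj_prev - obj) <= tol * max(abs(obj_prev), 1)) {
        converged <- TRUE
        break
      }
      obj_prev <- obj
    }
  }
  scale <- colSums(W)
  W <- sweep(W, 2, scale, "/")
  H <- H * scale
  rownames(W) <- rownames(V); colnames(H) <- colnames(V)
  colnames(W) <- rownames(H) <- paste0("SIG", seq_len(k))
  list(W = W, H = H, objective = kl_divergence(V, W %*% H),
       objective_trace = trace, iterations = it, converged = converged)
}
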