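#' Wasserstein-1 distance between discrete measures
#'
#' Computes the optimal-mass-transport distance
#' \deqn{W_1(\mu,\nu) = \min_{\gamma \in \Gamma(\mu,\nu)} \sum_{ij} \gamma_{ij} d_{ij}}
#' over couplings \eqn{\gamma} with marginals \eqn{\mu} and \eqn{\nu}, where
#' \eqn{d} is a ground metric on the common support. The exact method solves
#' the transportation linear program with a transportation-simplex routine;
#' the entropic method returns a Sinkhorn approximation, intended for very
#' large supports where the exact solve is too slow.
#'
#' @param mu,nu numeric probability vectors over the same support (each sums
#'   to 1 within `1e-9`). Zero-mass atoms are dropped before solving.
#' @param D ground metric matrix, `length(mu)` x `length(nu)`; symmetric with
#'   zero diagonal when square.
#' @param method `"exact"` (transportation simplex) or `"entropic"`
#'   (Sinkhorn with regularization `reg`).
#' @param reg entropic regularization; default `0.01 * median(D)` over the
#'   active cost submatrix.
#' @param check validate marginals and the metric (disable only in tight
#'   inner loops where inputs are constructed to be valid).
#' @return the transport cost, a nonnegative scalar.
#' @examples
#' D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3) # path metric 1-2-3
#' wasserstein1(c(1, 0, 0), c(0, 0, 1), D) # mass moved two hops -> 2
#' @export
wasserstein1 <- function(mu, nu, D, method = c("exact", "entropic"),
                         reg = NULL, check = TRUE) {
  method <- match.arg(method)
  mu <- as.numeric(mu)
  nu <- as.numeric(nu)
  if (length(mu) != nrow(D) || length(nu) != ncol(D))
    stop("measure lengths must match the ground metric dimensions")
  if (check) {
    if (abs(sum(mu) - 1) > 1e-9 || abs(sum(nu) - 1) > 1e-9)
      stop("unbalanced masses: mu and nu must each sum to 1 (tol 1e-9)")
    if (any(mu < 0) || any(nu < 0)) stop("measures must be nonnegative")
    if (nrow(D) == ncol(D)) {
      if (max(abs(D - t(D))) > 1e-12) stop("ground metric must be symmetric")
      if (any(diag(D) != 0)) stop("ground metric must have zero diagonal")
    }
  }
  si <- which(mu > 0)
  sj <- which(nu > 0)
  m <- mu[si] / sum(mu[si])
  n <- nu[sj] / sum(nu[sj])
  C <- D[si, sj, drop = FALSE]
  if (length(si) == 1L && length(sj) == 1L) return(C[1L, 1L])
  if (method == "exact") {
    .ot_exact_cpp(m, n, C, FALSE)$cost
  } else {
    sinkhorn_cost(m, n, C, reg = reg)
  }
}

#' Optimal transport plan between discrete measures
#'
#' As [wasserstein1()] with `method = "exact"`, but also returns the optimal
#' coupling on the full support.
#'
#' @inheritParams wasserstein1
#' @return list with elements `cost` and `plan` (a `length(mu)` x
#'   `length(nu)` coupling matrix).
#' @export
transport_plan <- function(mu, nu, D) {
  si <- which(mu > 0)
  sj <- which(nu > 0)
  m <- mu[si] / sum(mu[si])
  n <- nu[sj] / sum(nu[sj])
  C <- D[si, sj, drop = FALSE]
  res <- .ot_exact_cpp(m, n, C, TRUE)
  plan <- matrix(0, length(mu), length(nu))
  plan[si, sj] <- res$plan
  list(cost = res$cost, plan = plan)
}

# Sinkhorn iterations for entropically regularized transport.
# Approximation error grows with reg; used only for large supports.
sinkhorn_cost <- function(mu, nu, C, reg = NULL, max_iter = 10000L,
                          tol = 1e-9) {
  if (is.null(reg)) reg <- 0.01 * stats::median(C)
  if (!is.finite(reg) || reg <= 0) reg <- 1e-3
  # log-domain stabilized updates
  f <- numeric(length(mu))
  g <- numeric(length(nu))
  logmu <- log(mu)
  lognu <- log(nu)
  for (it in seq_len(max_iter)) {
    # f_i = reg * (logmu_i - logsumexp_j((g_j - C_ij)/reg))
    M <- sweep(-C / reg, 2L, g / reg, "+")
    mx <- apply(M, 1L, max)
    f <- reg * (logmu - (mx + log(rowSums(exp(M - mx)))))
    M <- sweep(-C / reg, 1L, f / reg, "+")
    mx <- apply(M, 2L, max)
    g <- reg * (lognu - (mx + log(colSums(exp(sweep(M, 2L, mx, "-"))))))
    # marginal violation of the row sums
    P <- exp(sweep(sweep(-C, 1L, f, "+"), 2L, g, "+") / reg)
    if (max(abs(rowSums(P) - mu)) < tol) break
  }
  sum(P * C)
}
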