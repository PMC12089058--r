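#' Fit a recursive least squares short-channel filter
#'
#' Runs the standard RLS recursion over the training samples, regressing each
#' long channel of one probe side on that side's short channel (plus an
#' intercept by default). At each sample \eqn{t} with regressor vector
#' \eqn{x_t}: gain \eqn{k_t = P_{t-1} x_t / (\lambda + x_t^T P_{t-1} x_t)},
#' coefficient update \eqn{w_t = w_{t-1} + k_t e_t} with prediction error
#' \eqn{e_t}, and \eqn{P_t = (P_{t-1} - k_t x_t^T P_{t-1}) / \lambda}.
#' \eqn{P_0 = \delta I}; with \eqn{\lambda = 1} and a weakly informative
#' initialisation (large \eqn{\delta}, or many samples) the final
#' coefficients converge to the batch least-squares solution.
#'
#' @param short Numeric vector: the short-channel (superficial) series.
#' @param long Numeric vector or n x m matrix: the long channel(s) to clean.
#' @param lambda Forgetting factor in (0, 1]; default 0.999.
#' @param delta Initial inverse-correlation scale, \eqn{P_0 = \delta I};
#'   default 100.
#' @param intercept Include an intercept regressor (default `TRUE`).
#' @return Object of class `nirs_rls`: list with coefficient matrix `w`
#'   (p x m), final `P`, `lambda`, `delta`, `intercept`, `n_train`,
#'   `targets`.
#' @examples
#' s <- sin(seq(0, 20, by = 0.1))
#' fit <- rls_fit(s, 2 * s, lambda = 1)
#' fit$w
#' @export
rls_fit <- function(short, long, lambda = 0.999, delta = 100,
                    intercept = TRUE) {
  long <- as.matrix(long)
  if (anyNA(short) || anyNA(long)) stop("NaN/NA in input series")
  if (!(lambda > 0 && lambda <= 1)) stop("lambda must be in (0, 1]")
  stopifnot(delta > 0, length(short) == nrow(long))
  n <- length(short)
  m <- ncol(long)
  p <- if (intercept) 2L else 1L
  w <- matrix(0, p, m)
  P <- diag(delta, p)
  for (t in seq_len(n)) {
    x <- if (intercept) c(short[t], 1) else short[t]
    Px <- P %*% x
    denom <- lambda + sum(x * Px)
    k <- Px / denom
    e <- long[t, ] - as.numeric(crossprod(w, x))
    w <- w + k %*% t(e)
    P <- (P - k %*% t(Px)) / lambda
    P <- (P + t(P)) / 2  # keep symmetric against roundoff
  }
  structure(
    list(w = w, P = P, lambda = lambda, delta = delta, intercept = intercept,
         n_train = n, targets = colnames(long)),
    class = "nirs_rls"
  )
}

#' Apply a frozen RLS filter
#'
#' Subtracts the short-channel prediction from each long channel using the
#' fitted coefficients. The coefficients are frozen: no update is performed,
#' so repeated application with the same state is identical.
#'
#' @param state A fitted `nirs_rls` object.
#' @param short Short-channel series.
#' @param long Long channel vector or matrix (same targets as at fit time).
#' @return Denoised matrix of the same shape as `long`.
#' @export
rls_apply <- function(state, short, long) {
  if (!inherits(state, "nirs_rls")) stop("state is not a fitted nirs_rls")
  long <- as.matrix(long)
  stopifnot(length(short) == nrow(long), ncol(long) == ncol(state$w))
  X <- if (state$intercept) cbind(short, 1) else cbind(short)
  out <- long - X %*% state$w
  dimnames(out) <- dimnames(long)
  out
}

#' @export
print.nirs_rls <- function(x, ...) {
  cat("RLS short-channel filter (lambda =", x$lambda, ", delta =", x$delta,
      ")\n")
  cat("  trained on", x$n_train, "samples,", ncol(x$w), "target channel(s)\n")
  rn <- if (x$intercept) c("slope", "intercept") else "slope"
  w <- x$w
  rownames(w) <- rn
  print(w)
  invisible(x)
}

## Fit one RLS filter per (side, chromophore) on the training samples of the
## given sessions, coupling each short channel to the 3 long channels of its
## side. `train_mask_fn(session)` returns the logical sample mask to train on.
fit_rls_set <- function(sessions, train_mask_fn, lambda = 0.999, delta = 100,
                        intercept = TRUE) {
  filters <- list()
  info <- sessions[[1]]$channel_info
  for (side in intersect(SIDE_LEVELS, unique(info$side))) {
    for (chrom in c("HbO", "HbR")) {
      short_ch <- info$channel[info$side == side & info$type == "short" &
                                 info$chromophore == chrom]
      long_ch <- info$channel[info$side == side & info$type == "long" &
                                info$chromophore == chrom]
      stopifnot(length(short_ch) == 1, length(long_ch) == 3)
      short <- numeric(0)
      long <- NULL
      for (s in sessions) {
        mask <- train_mask_fn(s)
        short <- c(short, s$channels[mask, short_ch])
        long <- rbind(long, s$channels[mask, long_ch, drop = FALSE])
      }
      filters[[paste(side, chrom, sep = "_")]] <-
        rls_fit(short, long, lambda = lambda, delta = delta,
                intercept = intercept)
    }
  }
  filters
}

## Replace each long channel with its RLS-denoised version (frozen filters).
apply_rls_set <- function(session, filters) {
  info <- session$channel_info
  for (name in names(filters)) {
    parts <- strsplit(name, "_")[[1]]
    side <- parts[1]
    chrom <- parts[2]
    short_ch <- info$channel[info$side == side & info$type == "short" &
                               info$chromophore == chrom]
    long_ch <- info$channel[info$side == side & info$type == "long" &
                              info$chromophore == chrom]
    session$channels[, long_ch] <- rls_apply(
      filters[[name]], session$channels[, short_ch],
      session$channels[, long_ch, drop = FALSE]
    )
  }
  session
}
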