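#' Adaptive step-up false discovery rate selection
#'
#' Shared FDR routine used both for auditory-responsive voxel selection and
#' for the pixelwise gradient-consistency test. The default `"tsbh"` method
#' is the two-stage adaptive step-up procedure: stage one applies the linear
#' (Benjamini-Hochberg) step-up at level `q` and estimates the number of true
#' nulls as `m0hat = m - r1`; stage two reapplies the step-up at level
#' `q * m / m0hat`. Because `m0hat <= m`, the stage-two level is never below
#' `q`, so the selection always contains the plain BH selection at the same
#' `q`. The `"bky"` method is the more conservative two-stage variant that
#' runs both stages at `q/(1+q)`; `"bh"` is the plain linear step-up.
#'
#' @param p Vector of p-values in [0, 1] (`NA` allowed, never selected).
#' @param q FDR level (default 0.05).
#' @param method One of `"tsbh"` (default), `"bky"`, `"bh"`.
#' @return Logical vector: `TRUE` where the hypothesis is rejected.
#' @export
fdr_select <- function(p, q = 0.05, method = c("tsbh", "bky", "bh")) {
  method <- match.arg(method)
  stopifnot(q > 0, q < 1)
  out <- rep(FALSE, length(p))
  ok <- !is.na(p)
  if (!any(ok)) {
    warning("fdr_select: no usable p-values; empty selection")
    return(out)
  }
  pv <- p[ok]
  if (any(pv < 0 | pv > 1)) stop("fdr_select: p-values must lie in [0, 1]")
  m <- length(pv)

  bh_reject <- function(pv, level) {
    o <- order(pv)
    thr <- level * seq_len(m) / m
    k <- which(pv[o] <= thr)
    rej <- rep(FALSE, m)
    if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
    rej
  }

  rej <- switch(method,
    bh = bh_reject(pv, q),
    tsbh = {
      r1 <- sum(bh_reject(pv, q))
      if (r1 == 0) rep(FALSE, m)
      else if (r1 == m) rep(TRUE, m)
      else bh_reject(pv, q * m / (m - r1))
    },
    bky = {
      q1 <- q / (1 + q)
      r1 <- sum(bh_reject(pv, q1))
      if (r1 == 0) rep(FALSE, m)
      else if (r1 == m) rep(TRUE, m)
      else bh_reject(pv, q1 * m / (m - r1))
    })
  out[ok] <- rej
  out
}
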