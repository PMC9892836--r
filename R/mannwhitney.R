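#' Mann-Whitney U test (tie-corrected asymptotic or exact permutation)
#'
#' Two-sided two-sample Mann-Whitney U test.  The default is the
#' tie-corrected normal approximation without continuity correction (the
#' common statistical-software default for ordinal data):
#' \deqn{z = (U - n_1 n_2 / 2) / \sqrt{\frac{n_1 n_2}{12}\left[(N+1) -
#'   \frac{\sum_j (t_j^3 - t_j)}{N(N-1)}\right]}}
#' where the \eqn{t_j} are the tie-group sizes.  `method = "exact"` instead
#' enumerates the full permutation distribution of U (all
#' \eqn{\binom{N}{n_1}} group assignments; limited to 12 observations per
#' group) and reports the two-sided permutation p-value.
#'
#' If every observation in both groups is identical the test is degenerate:
#' z is set to 0, p to 1, and `degenerate` is `TRUE`.
#'
#' @param a,b numeric vectors (group A and group B).
#' @param method `"asymptotic"` (default) or `"exact"`.
#' @return list with `U` (statistic for group A), `z`, `p`, `n1`, `n2`,
#'   `method`, `degenerate`.
#' @examples
#' mw_test(c(1, 2, 3, 4), c(1, 2, 3, 4))$p  # identical groups -> 1
#' @export
mw_test <- function(a, b, method = c("asymptotic", "exact")) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  x <- c(a, b)
  r <- rank(x)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tie <- table(x)
  degenerate <- length(tie) == 1L
  if (method == "asymptotic" || degenerate) {
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    if (degenerate || sig2 <= 0) {
      return(list(U = U, z = 0, p = 1, n1 = n1, n2 = n2,
                  method = "asymptotic", degenerate = TRUE))
    }
    z <- (U - n1 * n2 / 2) / sqrt(sig2)
    return(list(U = U, z = z, p = 2 * stats::pnorm(-abs(z)), n1 = n1,
                n2 = n2, method = "asymptotic", degenerate = FALSE))
  }
  if (min(n1, n2) > 12L) {
    stop("exact permutation enumeration is limited to 12 per group",
         call. = FALSE)
  }
  idx <- utils::combn(N, n1)
  offs <- n1 * (n1 + 1) / 2
  u_all <- apply(idx, 2L, function(i) sum(r[i])) - offs
  dev <- abs(u_all - n1 * n2 / 2)
  p <- mean(dev >= abs(U - n1 * n2 / 2) - 1e-12)
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
  z <- if (sig2 > 0) (U - n1 * n2 / 2) / sqrt(sig2) else 0
  list(U = U, z = z, p = p, n1 = n1, n2 = n2, method = "exact",
       degenerate = FALSE)
}
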