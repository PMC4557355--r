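#' Binomial labelling matrix B(N, m, p)
#'
#' Entry `[N, m]` is the probability that an N-mer carries exactly m
#' functional fluorophores when each subunit is labelled independently with
#' probability `p`: `B[N, m] = choose(N, m) p^m (1-p)^(N-m)` for `m <= N`,
#' zero otherwise. Rows are true sizes N = 1..n_max, columns observed labelled
#' counts m = 1..n_max (m = 0, the invisible class, is excluded, so row N
#' sums to `1 - (1-p)^N`).
#'
#' @param n_max Largest size considered (1..6).
#' @param p Labelling probability in (0, 1].
#' @return An `n_max x n_max` matrix with dimnames N (rows) and m (columns).
#' @examples
#' binomial_matrix(6, 0.8)[4, 3]  # 0.4096
#' @export
binomial_matrix <- function(n_max = 6, p = 0.8) {
  if (!(p > 0 && p <= 1)) stop("p must be in (0, 1]")
  if (n_max < 1 || n_max > 6) stop("n_max must be between 1 and 6")
  B <- matrix(0, n_max, n_max,
              dimnames = list(N = seq_len(n_max), m = seq_len(n_max)))
  for (N in seq_len(n_max))
    for (m in seq_len(N))
      B[N, m] <- stats::dbinom(m, N, p)
  B
}

#' Forward binomial thinning of a true size distribution
#'
#' Maps the true oligomer-size distribution S_N to the observed
#' labelled-count distribution L_m: `L_m` is proportional to
#' `sum_N B[N, m] S_N`, renormalized over m = 1..n_max because completely
#' unlabelled particles are dark and never enter the observed sample.
#'
#' @param S Numeric vector of true fractions over N = 1..n_max (sums to 1).
#' @param p Labelling probability.
#' @return Numeric vector `L` over m = 1..n_max, summing to 1.
#' @export
forward_label <- function(S, p = 0.8) {
  S <- as.numeric(S)
  if (any(S < -1e-12)) stop("S must be nonnegative")
  if (abs(sum(S) - 1) > 1e-9) stop("S must sum to 1")
  B <- binomial_matrix(length(S), p)
  L <- as.numeric(crossprod(B, S))  # L_m = sum_N B[N,m] S_N
  L / sum(L)
}

#' Correct an observed labelled-count distribution for partial labelling
#'
#' Inverts the binomial thinning: solves the square linear system
#' `L = t(B) S` for the true size distribution S (sizes and labelled counts
#' both 1..n_max). Measurement noise can push some solved fractions negative;
#' following the standard clip-and-renormalize rule these are set to zero and
#' the distribution renormalized to sum to 1, with the `clipped` attribute
#' flagging that this happened.
#'
#' Because the observed distribution is conditioned on seeing at least one
#' label, the system is solved up to a scale factor and renormalized; with
#' `condition_on_detection = TRUE` each row of B is explicitly divided by
#' `1 - (1-p)^N` before solving, which differs measurably for p at or below
#' about 0.7.
#'
#' @param L Observed fractions over m = 1..n_max (sums to 1), e.g. from
#'   [census_from_steps()] or `coef()` of a [stoich_fit()].
#' @param p Labelling probability.
#' @param condition_on_detection Condition each size's thinning row on the
#'   particle being visible (at least one label) before solving.
#' @return Numeric vector `S` over N = 1..n_max of class `true_distribution`
#'   with attribute `clipped` (logical).
#' @examples
#' S0 <- c(0, 0.45, 0, 0.35, 0, 0.20)
#' L <- forward_label(S0, 0.8)
#' correct_labelling(L, 0.8)  # recovers S0
#' @export
correct_labelling <- function(L, p = 0.8, condition_on_detection = FALSE) {
  L <- as.numeric(L)
  if (any(L < -1e-12)) stop("L must be nonnegative")
  if (abs(sum(L) - 1) > 1e-9) stop("L must sum to 1")
  n_max <- length(L)
  B <- binomial_matrix(n_max, p)
  if (condition_on_detection) B <- B / (1 - (1 - p)^seq_len(n_max))
  # t(B) is triangular with positive diagonal p^N for p in (0,1]: nonsingular
  S <- solve(t(B), L)
  clipped <- any(S < -1e-12)
  S[S < 0] <- 0
  if (sum(S) <= 0) stop("degenerate correction: all solved fractions clipped")
  S <- S / sum(S)
  structure(as.numeric(S), class = "true_distribution", clipped = clipped,
            p = p, names = paste0("S", seq_len(n_max)))
}

#' @export
print.true_distribution <- function(x, digits = 3, ...) {
  cat("Corrected oligomer-size distribution (labelling p =",
      attr(x, "p"), ")\n")
  print(round(unclass(x), digits))
  if (isTRUE(attr(x, "clipped")))
    cat("note: negative solved fractions were clipped to zero and renormalized\n")
  invisible(x)
}
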