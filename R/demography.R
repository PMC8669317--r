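#' Vital rates for a three-stage seabird projection model
#'
#' Bundles the demographic parameters of the single-sex (female) stage model:
#' survival of fledged chicks over their first winter (`s0`), annual survival
#' of sub-adults (`s1`), breeding adults (`s2`) and non-breeding adults
#' (`s3`), adult annual breeding probability (`b`), mean eggs per breeding
#' pair (`e`), hatching success (`h`), baseline fledging success (`f`), and
#' age of first reproduction in years (`AFR`).
#'
#' The model assumes a pre-breeding census: the youngest tracked class are
#' birds approaching one year of age, so `s0` enters only through the
#' fecundity element of the projection matrix.
#'
#' @param s0,s1,s2,s3 Stage survival probabilities in `[0, 1]`.
#' @param b Adult annual breeding probability in `[0, 1]`.
#' @param e Mean number of eggs per breeding pair (positive; typically 1-3).
#' @param h Hatching success probability in `[0, 1]`.
#' @param f Baseline fledging probability in `[0, 1]`.
#' @param AFR Age of first reproduction in whole years (`>= 1`).
#' @return An object of class `vital_rates` (a named list).
#' @examples
#' v <- vital_rates(s0 = 0.6, s1 = 0.8, s2 = 0.92, s3 = 0.9,
#'                  b = 0.85, e = 2, h = 0.75, f = 0.7, AFR = 4)
#' build_matrix(v)$lambda
#' @export
vital_rates <- function(s0, s1, s2, s3, b, e, h, f, AFR) {
  for (nm in c("s0", "s1", "s2", "s3", "b", "h", "f")) {
    check_prob(get(nm), nm)
  }
  check_positive(e, "e")
  if (!is.numeric(AFR) || AFR < 1 || AFR != round(AFR)) {
    stop_invalid("AFR must be an integer >= 1")
  }
  structure(list(s0 = s0, s1 = s1, s2 = s2, s3 = s3, b = b,
                 e = e, h = h, f = f, AFR = as.integer(AFR)),
            class = "vital_rates")
}

#' @export
print.vital_rates <- function(x, ...) {
  cat("Seabird vital rates (female, pre-breeding census)\n")
  cat(sprintf("  survival      s0=%.3f s1=%.3f s2=%.3f s3=%.3f\n",
              x$s0, x$s1, x$s2, x$s3))
  cat(sprintf("  reproduction  b=%.3f e=%.2f h=%.3f f=%.3f AFR=%d\n",
              x$b, x$e, x$h, x$f, x$AFR))
  invisible(x)
}

as_vitals_vector <- function(v) {
  c(v$s0, v$s1, v$s2, v$s3, v$b, v$e, v$h, v$f)
}

#' Sub-adult growth transition probability
#'
#' Probability that a sub-adult transitions to the breeding-adult stage in a
#' given year, under the standard fixed-duration age-class collapse:
#' \deqn{g = \frac{(s_1/\lambda)^T - (s_1/\lambda)^{T-1}}{(s_1/\lambda)^T - 1}}
#' where `T` is the number of years spent in the sub-adult stage and
#' `lambda` the asymptotic annual growth rate. At `s1/lambda = 1` the
#' formula has the analytic limit `1/T`, which is returned (and approached
#' continuously) near the singularity.
#'
#' @param s1 Sub-adult annual survival, in `(0, 1]`.
#' @param lam Annual growth rate `lambda` (positive).
#' @param T Sub-adult stage duration in years (integer `>= 1`).
#' @return Growth transition probability in `[0, 1]`.
#' @examples
#' growth_fraction(0.8, 1.0, 3)
#' @export
growth_fraction <- function(s1, lam, T) {
  check_prob(s1, "s1", allow_zero = FALSE)
  check_positive(lam, "lam")
  if (T < 1 || T != round(T)) stop_invalid("T must be an integer >= 1")
  r <- s1 / lam
  if (abs(r - 1) < 1e-9) return(1 / T)
  g <- (r^T - r^(T - 1)) / (r^T - 1)
  clamp(g, 0, 1)
}

#' Build the three-stage projection matrix
#'
#' Constructs the stage-structured female projection matrix with stages
#' (sub-adult, breeding adult, non-breeding adult):
#' \preformatted{
#'   | s1 (1 - g)   (e/2) h f s0     0        |
#'   | s1 g         s2 b             s3 b     |
#'   | 0            s2 (1 - b)       s3 (1-b) |
#' }
#' The fecundity element uses `e/2` because the model tracks females only
#' and `e` counts eggs per pair. The growth transition `g` depends on
#' `lambda` (see [growth_fraction()]), which in turn depends on the matrix,
#' so the pair is solved by fixed-point iteration: `lambda` starts at
#' `lambda0`, `g` is computed, `lambda` is recomputed as the dominant
#' eigenvalue, and the cycle repeats until successive `lambda` values differ
#' by less than `tol`.
#'
#' @param v A [vital_rates()] object.
#' @param T Sub-adult stage duration in years. Defaults to `AFR - 1`
#'   (recruitment at age one under the pre-breeding census, first breeding
#'   at age `AFR`). A value of zero (possible when `AFR = 1`) forces `g = 1`.
#' @param g Optional fixed growth transition; when supplied the fixed-point
#'   iteration is skipped and the matrix is built directly.
#' @param tol Convergence tolerance on successive `lambda` values. The
#'   default `1e-6` is tighter than the two-decimal stabilisation that
#'   motivates the iterative scheme; set `tol = 1e-2` to reproduce that
#'   looser behaviour.
#' @param max_iter Maximum fixed-point iterations.
#' @param lambda0 Starting value for `lambda`.
#' @return An object of class `projection_matrix`: a list with elements `A`
#'   (the 3x3 matrix), `lambda`, `g`, `T`, `converged` and `iterations`.
#' @examples
#' v <- vital_rates(0.6, 0.8, 0.92, 0.9, 0.85, 2, 0.75, 0.7, 4)
#' pm <- build_matrix(v)
#' pm$lambda
#' @export
build_matrix <- function(v, T = NULL, g = NULL, tol = 1e-6,
                         max_iter = 500, lambda0 = 1) {
  stopifnot(inherits(v, "vital_rates"))
  T <- T %||% (v$AFR - 1L)
  vv <- as_vitals_vector(v)
  if (!is.null(g)) {
    check_prob(g, "g")
    A <- stage_matrix_from_g(vv, g)
    lam <- .dominant_eig3_cpp(A)
    out <- list(A = A, lambda = lam, g = g, T = T,
                converged = TRUE, iterations = 0L)
  } else {
    sol <- .solve_stage_cpp(vv, as.numeric(T), tol, as.integer(max_iter),
                            lambda0)
    if (!sol$converged) {
      stop_invalid(sprintf(
        "lambda/g fixed point did not converge in %d iterations (last two lambda values: %.8f, %.8f)",
        max_iter, sol$lambda_prev, sol$lambda))
    }
    out <- list(A = sol$A, lambda = sol$lambda, g = sol$g, T = T,
                converged = sol$converged, iterations = sol$iterations)
  }
  dimnames(out$A) <- list(stage_names(), stage_names())
  out$vitals <- v
  class(out) <- "projection_matrix"
  out
}

stage_names <- function() c("subadult", "breeder", "nonbreeder")

stage_matrix_from_g <- function(vv, g) {
  s0 <- vv[1]; s1 <- vv[2]; s2 <- vv[3]; s3 <- vv[4]
  b <- vv[5]; e <- vv[6]; h <- vv[7]; f <- vv[8]
  matrix(c(s1 * (1 - g), (e / 2) * h * f * s0, 0,
           s1 * g,       s2 * b,               s3 * b,
           0,            s2 * (1 - b),         s3 * (1 - b)),
         nrow = 3, byrow = TRUE)
}

#' @export
print.projection_matrix <- function(x, ...) {
  cat(sprintf("Stage projection matrix (lambda = %.5f, g = %.5f, T = %g)\n",
              x$lambda, x$g, x$T))
  print(round(x$A, 5))
  invisible(x)
}

#' Stable stage distribution
#'
#' Dominant right eigenvector of a non-negative projection matrix,
#' normalised to sum to one: the long-run proportional composition of the
#' population across stages.
#'
#' @param A A `projection_matrix` object or a plain non-negative square
#'   matrix.
#' @param tol Tolerance used to decide whether the dominant eigenvalue is
#'   real and strictly dominant.
#' @return Numeric vector of stage proportions summing to 1.
#' @examples
#' stable_stage_distribution(matrix(c(0, 2, 0, 0.5, 0, 0, 0, 0, 0), 3,
#'                                  byrow = TRUE))
#' @export
stable_stage_distribution <- function(A, tol = 1e-8) {
  M <- if (inherits(A, "projection_matrix")) A$A else as.matrix(A)
  if (any(M < 0)) stop_invalid("matrix must be non-negative")
  ev <- eigen(M)
  mods <- Mod(ev$values)
  i <- which.max(mods)
  if (abs(Im(ev$values[i])) > tol * max(1, mods[i])) {
    stop_invalid("degenerate matrix: dominant eigenvalue is not real")
  }
  others <- mods[-i]
  if (length(others) && any(abs(others - mods[i]) < tol * max(1, mods[i]))) {
    # repeated dominant modulus: accept only if the candidate eigenvector
    # is already non-negative (e.g. reducible matrices with an unreachable
    # stage); otherwise refuse
    v <- Re(ev$vectors[, i])
    if (any(v > 0) && any(v < -tol)) {
      stop_invalid("degenerate matrix: dominant eigenvalue is not unique")
    }
  }
  v <- Re(ev$vectors[, i])
  if (sum(v) < 0) v <- -v
  v[abs(v) < tol] <- 0
  if (any(v < 0)) stop_invalid("degenerate matrix: dominant eigenvector changes sign")
  v / sum(v)
}

#' Density-dependent fledging success
#'
#' Scales baseline fledging success down as a colony approaches its
#' carrying capacity:
#' \deqn{f_{dd} = f / (1 + (N/K)^\theta)}
#' With `theta` in the 5-10 range the reduction is negligible below about
#' two-thirds of `K`, accelerates above it, and reaches exactly 50% at
#' `N = K`, which drives growth to zero near capacity.
#'
#' @param f Baseline fledging probability.
#' @param N Current female abundance (`>= 0`).
#' @param K Carrying capacity in females (positive).
#' @param theta Shape exponent (positive; default 7.5, the midpoint of the
#'   5-10 range over which the curve has the intended knee).
#' @return Adjusted fledging probability.
#' @examples
#' density_dependent_fledging(0.7, N = 500, K = 1000)
#' density_dependent_fledging(0.7, N = 1000, K = 1000)  # exactly 0.35
#' @export
density_dependent_fledging <- function(f, N, K, theta = 7.5) {
  check_prob(f, "f")
  if (!is.numeric(N) || anyNA(N) || any(N < 0)) stop_invalid("N must be >= 0")
  check_positive(K, "K")
  check_positive(theta, "theta")
  f / (1 + (N / K)^theta)
}
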