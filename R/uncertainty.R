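#' An uncertain scalar input
#'
#' Describes one input of an estimator as a distribution: `normal`
#' (Gaussian with the given mean and sd, optionally truncated to
#' `[lower, upper]` by resampling) or `fixed` (a constant; forced when
#' `sd = 0`). Truncation exists for physically bounded quantities such
#' as diet mass fractions, which must stay in `[0, 1]` no matter how
#' wide their reported uncertainty is.
#'
#' @param mean Central value (per mil, fraction, ...).
#' @param sd Standard deviation, `>= 0`.
#' @param distribution `"normal"` or `"fixed"`.
#' @param lower,upper Truncation bounds for `"normal"`.
#' @return Object of class `uncertain_input`.
#' @export
#' @examples
#' uncertain_input(0.88, 0.02, lower = 0, upper = 1)
uncertain_input <- function(mean, sd = 0,
                            distribution = c("normal", "fixed"),
                            lower = -Inf, upper = Inf) {
  distribution <- match.arg(distribution)
  stopifnot(is.finite(mean), is.numeric(sd), length(sd) == 1)
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (sd == 0) distribution <- "fixed"
  if (lower > upper) stop("lower must be <= upper", call. = FALSE)
  structure(list(mean = mean, sd = sd, distribution = distribution,
                 lower = lower, upper = upper),
            class = "uncertain_input")
}

draw_input <- function(input, n) {
  if (input$distribution == "fixed") return(rep(input$mean, n))
  x <- stats::rnorm(n, input$mean, input$sd)
  clipped <- 0L
  bad <- which(x < input$lower | x > input$upper)
  while (length(bad)) {
    clipped <- clipped + length(bad)
    x[bad] <- stats::rnorm(length(bad), input$mean, input$sd)
    bad <- bad[x[bad] < input$lower | x[bad] > input$upper]
  }
  attr(x, "clipped") <- clipped
  x
}

#' Monte-Carlo uncertainty propagation
#'
#' Propagates independent uncertain inputs through an arbitrary
#' estimator by simulation: each input is drawn `n_draws` times, the
#' estimator is evaluated per draw, and the mean and sample sd of the
#' results are returned. Fully reproducible for a fixed seed. Truncated
#' draws (resampled back into an input's bounds) are counted and
#' reported via a message, since truncation shifts the propagated mean.
#'
#' @param fn Function of `length(inputs)` numeric arguments returning a
#'   numeric scalar (vectorized functions are evaluated in one call).
#' @param inputs List of [uncertain_input()]s, in `fn`'s argument order.
#' @param n_draws Number of draws, `>= 1000`.
#' @param seed Integer RNG seed; recorded in the result.
#' @return Object of class `propagation_result`: list with `mean`,
#'   `sd`, `n_draws`, `seed`, `method = "monte_carlo"`, `n_clipped`.
#' @export
#' @examples
#' est <- function(f) tp_diet(diet_model(f, 2.38, 2.67))$tp
#' propagate(est, list(uncertain_input(0.88, 0.02, lower = 0, upper = 1)),
#'           n_draws = 1000, seed = 1)
propagate <- function(fn, inputs, n_draws = 1e5, seed = 1L) {
  stopifnot(is.function(fn), is.list(inputs), length(inputs) >= 1)
  if (!all(vapply(inputs, inherits, logical(1), "uncertain_input")))
    stop("inputs must be uncertain_input objects", call. = FALSE)
  if (n_draws < 1000)
    stop("n_draws must be at least 1000", call. = FALSE)
  draws <- with_seed(seed, lapply(inputs, draw_input, n = n_draws))
  n_clipped <- sum(vapply(draws, function(d) {
    cl <- attr(d, "clipped")
    if (is.null(cl)) 0L else cl
  }, integer(1)))
  if (n_clipped > 0)
    message("propagate: ", n_clipped,
            " draw(s) fell outside input bounds and were resampled")
  draws <- lapply(draws, as.vector)
  out <- tryCatch({
    v <- do.call(fn, draws)
    if (length(v) != n_draws) stop("not vectorized")
    v
  }, error = function(e) {
    vapply(seq_len(n_draws), function(i)
      do.call(fn, lapply(draws, `[[`, i)), numeric(1))
  })
  structure(list(mean = mean(out), sd = stats::sd(out), n_draws = n_draws,
                 seed = seed, method = "monte_carlo",
                 n_clipped = n_clipped),
            class = "propagation_result")
}

#' Exact propagation through an affine estimator
#'
#' For an estimator affine in its uncertain inputs (as every Glu/Phe TP
#' formula, size/bulk-offset correction and the diet mass balance are),
#' the output mean is the estimator at the input means and the sd is
#' `sqrt(sum((c_i * sd_i)^2))` with `c_i` the coefficient on input `i`,
#' assuming independence. Coefficients are obtained by unit
#' perturbation, and affinity is verified by a second-difference check:
#' a non-affine estimator raises an error rather than returning a wrong
#' answer.
#'
#' @inheritParams propagate
#' @param tol Curvature tolerance of the affinity check.
#' @return Object of class `propagation_result` with
#'   `method = "analytic_linear"`.
#' @export
#' @examples
#' est <- function(g, p) tp_single_tdf(g, p)$tp
#' propagate_analytic(est, list(uncertain_input(18, 0.5),
#'                              uncertain_input(3, 0.5)))
propagate_analytic <- function(fn, inputs, tol = 1e-8) {
  stopifnot(is.function(fn), is.list(inputs), length(inputs) >= 1)
  if (!all(vapply(inputs, inherits, logical(1), "uncertain_input")))
    stop("inputs must be uncertain_input objects", call. = FALSE)
  means <- lapply(inputs, `[[`, "mean")
  f0 <- do.call(fn, means)
  stopifnot(is.numeric(f0), length(f0) == 1)
  coef <- vapply(seq_along(inputs), function(i) {
    shift <- function(h) {
      a <- means; a[[i]] <- a[[i]] + h
      do.call(fn, a)
    }
    f1 <- shift(1); f2 <- shift(2)
    scale <- max(1, abs(f0), abs(f1), abs(f2))
    if (abs(f2 - 2 * f1 + f0) > tol * scale)
      stop("estimator is not affine in input ", i,
           "; use propagate() instead", call. = FALSE)
    f1 - f0
  }, numeric(1))
  sds <- vapply(inputs, `[[`, numeric(1), "sd")
  structure(list(mean = f0, sd = sqrt(sum((coef * sds)^2)),
                 n_draws = NA_integer_, seed = NA_integer_,
                 method = "analytic_linear", n_clipped = 0L),
            class = "propagation_result")
}

#' @export
print.propagation_result <- function(x, ...) {
  cat("<propagation_result>", x$method, "\n")
  cat("  mean =", format(x$mean, digits = 6),
      " sd =", format(x$sd, digits = 4), "\n")
  if (identical(x$method, "monte_carlo"))
    cat("  n_draws =", x$n_draws, " seed =", x$seed,
        " clipped draws =", x$n_clipped, "\n")
  invisible(x)
}

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}
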