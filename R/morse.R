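#' Fit a Morse potential to an energy curve
#'
#' Least-squares fit of the Morse form
#' \deqn{V(s) = C + D\,(1 - e^{-a (s - s_0)})^2}
#' to all points of an energy-versus-separation scan.  The fitted asymptote
#' `C + D` is the large-separation energy used as the reference when
#' computing an interaction energy.
#'
#' Starting values follow the curve itself: `s0` at the sampled minimum, `C`
#' at the minimum energy, `D` as plateau-minus-minimum and `a = 1` per
#' Angstrom; if the first fit does not converge, up to `restarts` bounded
#' refits are attempted with deterministic jitter on the start values.
#'
#' @param curve An [energy_curve()] or any data frame with `separation` and
#'   `energy` columns.
#' @param restarts Maximum number of jittered restarts after the initial
#'   attempt (default 10).
#' @return An object of class `morse_fit` with elements `D`, `a`, `s0`, `C`,
#'   `asymptote` (`C + D`), `rmse` and the fitted model.  Supports
#'   [predict()], [tidy()] and [glance()].
#' @export
#' @examples
#' curve <- gen_energy_curve(D = 1, a = 1.2, s0 = 2.5, C = -3)
#' fit <- fit_morse(curve)
#' glance(fit)
fit_morse <- function(curve, restarts = 10L) {
  pts <- curve_points(curve)
  if (nrow(pts) < 4L) {
    stop_porepass(
      sprintf("Morse fit needs at least 4 points (4 free parameters); got %d.",
              nrow(pts)),
      "porepass_input_error")
  }
  s <- pts$separation
  e <- pts$energy

  # plateau estimate: mean of the far-field samples (beyond 10 A when
  # available, else the last two points)
  far <- e[s > 10]
  plateau <- if (length(far)) mean(far) else mean(tail(e, 2))
  start0 <- list(D = max(plateau - min(e), 1e-3),
                 a = 1,
                 s0 = s[which.min(e)],
                 C = min(e))
  lower <- c(D = 1e-9, a = 1e-6, s0 = min(s) - 5, C = -Inf)
  upper <- c(D = Inf, a = 50, s0 = max(s), C = Inf)

  jitters <- morse_start_jitter(restarts)
  fit <- NULL
  for (k in seq_len(restarts + 1L)) {
    start <- start0
    if (k > 1L) {
      j <- jitters[k - 1L, ]
      start$D <- max(start0$D * j[["D"]], 1e-6)
      start$a <- start0$a * j[["a"]]
      start$s0 <- start0$s0 + j[["s0"]]
      start$C <- start0$C + j[["C"]] * max(abs(start0$D), 0.1)
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(
        energy ~ C + D * (1 - exp(-a * (separation - s0)))^2,
        data = pts, start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop_porepass(
      "Morse fit failed to converge after bounded restarts.",
      "porepass_fit_error",
      residuals = e - (start0$C + start0$D *
                         (1 - exp(-start0$a * (s - start0$s0)))^2))
  }
  cf <- coef(fit)
  res <- resid(fit)
  structure(
    list(D = unname(cf["D"]), a = unname(cf["a"]), s0 = unname(cf["s0"]),
         C = unname(cf["C"]), asymptote = unname(cf["C"] + cf["D"]),
         rmse = sqrt(mean(res^2)), residuals = as.numeric(res),
         n = nrow(pts), model = fit,
         residue_code = attr(curve, "residue_code") %||% NA_character_),
    class = "morse_fit")
}

# Deterministic start-value jitter for refits; fixed seed, global RNG state
# left untouched.
morse_start_jitter <- function(restarts) {
  if (restarts < 1L) return(matrix(numeric(0), 0, 4,
                                   dimnames = list(NULL, c("D", "a", "s0", "C"))))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(1221L)
  cbind(D = exp(runif(restarts, -1.5, 1.5)),
        a = exp(runif(restarts, -1.5, 1.5)),
        s0 = runif(restarts, -1, 1),
        C = runif(restarts, -0.5, 0.5))
}

curve_points <- function(curve) {
  if (inherits(curve, "energy_curve")) return(as_tibble(curve))
  if (!is.data.frame(curve)) {
    stop_porepass("`curve` must be an energy_curve or data frame.",
                  "porepass_input_error")
  }
  nm <- names(curve)
  sep_col <- intersect(c("separation", "separation_angstrom"), nm)[1]
  en_col <- intersect(c("energy", "energy_ev"), nm)[1]
  if (is.na(sep_col) || is.na(en_col)) {
    stop_porepass("`curve` needs `separation` and `energy` columns.",
                  "porepass_input_error")
  }
  tibble(separation = as.numeric(curve[[sep_col]]),
         energy = as.numeric(curve[[en_col]]))
}

#' @export
predict.morse_fit <- function(object, newdata = NULL, ...) {
  s <- if (is.null(newdata)) {
    stop_porepass("supply separations to predict at", "porepass_input_error")
  } else if (is.data.frame(newdata)) newdata$separation else as.numeric(newdata)
  object$C + object$D * (1 - exp(-object$a * (s - object$s0)))^2
}

#' @export
print.morse_fit <- function(x, ...) {
  cat(sprintf(
    "<morse_fit>%s D = %.4f eV, a = %.4f /A, s0 = %.3f A, C = %.4f eV\n",
    ifelse(is.na(x$residue_code), "", paste0(" ", x$residue_code, ":")),
    x$D, x$a, x$s0, x$C))
  cat(sprintf("  asymptote C + D = %.4f eV, rmse = %.2e eV (n = %d)\n",
              x$asymptote, x$rmse, x$n))
  invisible(x)
}

#' @rdname fit_morse
#' @param x A `morse_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.morse_fit <- function(x, ...) {
  tibble(term = c("D", "a", "s0", "C"),
         estimate = c(x$D, x$a, x$s0, x$C),
         unit = c("eV", "1/Angstrom", "Angstrom", "eV"))
}

#' @rdname fit_morse
#' @exportS3Method generics::glance
glance.morse_fit <- function(x, ...) {
  tibble(D = x$D, a = x$a, s0 = x$s0, C = x$C,
         asymptote = x$asymptote, rmse = x$rmse, n = x$n)
}
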