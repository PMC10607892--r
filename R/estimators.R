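# Component separation: conventional matrix inverse and the Wiener
# (linear MMSE) estimator.
#
# Conventional:  r = F^{-1} v              (ignores noise)
# Wiener:        r~ = G v,  G = Rrr F' (F Rrr F' + Rnn)^{-1}
#
# G minimizes the ensemble mean squared error <|r - r~|^2> over linear
# estimators given the second-order statistics of the pigments (Rrr, raw
# second moments) and of the noise (Rnn). With Rnn = 0 and F invertible,
# G reduces to F^{-1} and both estimators coincide.

#' 2x2 autocorrelation matrix container
#'
#' Symmetric positive semi-definite second-moment matrix with a role tag
#' (`pigment` for Rrr, `noise` for Rnn, `observation` for Rvv, `cross` for
#' Rrv) and a provenance record (`"analytic"` or `"sampled"`).
#'
#' @param entries 2x2 numeric matrix.
#' @param role one of `"pigment"`, `"noise"`, `"observation"`, `"cross"`.
#' @param provenance `"analytic"` or `"sampled"`.
#' @param n_samples,seed sampling metadata when `provenance = "sampled"`.
#' @param tol symmetry / PSD tolerance.
#' @return An object of class `autocorrelation_matrix`.
#' @export
autocorrelation_matrix <- function(entries,
                                   role = c("pigment", "noise", "observation",
                                            "cross"),
                                   provenance = c("analytic", "sampled"),
                                   n_samples = NULL, seed = NULL,
                                   tol = 1e-8) {
  role <- match.arg(role)
  provenance <- match.arg(provenance)
  entries <- as.matrix(entries)
  if (!identical(dim(entries), c(2L, 2L)) || any(!is.finite(entries))) {
    stop("autocorrelation entries must be a finite 2x2 matrix", call. = FALSE)
  }
  scale <- max(abs(entries), 1)
  if (role != "cross") {
    if (max(abs(entries - t(entries))) > tol * scale) {
      stop("autocorrelation matrix must be symmetric", call. = FALSE)
    }
    entries <- (entries + t(entries)) / 2
    ev <- eigen(entries, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -tol * scale) {
      stop(sprintf("autocorrelation matrix must be positive semi-definite (min eigenvalue %.3g)",
                   min(ev)), call. = FALSE)
    }
  }
  structure(entries, role = role, provenance = provenance,
            n_samples = n_samples, seed = seed,
            class = c("autocorrelation_matrix", "matrix"))
}

#' Conventional separation by matrix inverse
#'
#' Per frame, `r = F^{-1} v`. Noise in `v` is propagated (and, for
#' near-collinear `F`, amplified) into the pigment estimates.
#'
#' @param f a `system_matrix` (non-singular).
#' @param v a [density_series].
#' @return A [pigment_series] with `method_tag = "conventional"`.
#' @export
conventional_separate <- function(f, v) {
  stopifnot(inherits(f, "system_matrix"), inherits(v, "density_series"))
  fm <- matrix(as.numeric(f), 2, 2)
  check_nonsingular(fm, "system matrix F")
  r <- t(solve(fm, t(unclass(v))))
  pigment_series(r, attr(v, "frame_rate"), method_tag = "conventional")
}

#' Pigment autocorrelation Rrr from a hemoglobin-varied ensemble
#'
#' Draws `n_samples` pigment vectors `r = (h, shade_value)` with the
#' hemoglobin value varied over `hb_range` while the shade is held fixed —
#' hemoglobin fluctuates with the blood whereas shade does not — and returns
#' the raw second-moment matrix `Rrr = mean(r r')`. A degenerate range
#' (`min == max`) yields the exact deterministic moment matrix.
#'
#' @param hb_range length-2 closed interval of hemoglobin density values.
#' @param shade_value fixed shade density value.
#' @param n_samples ensemble size, >= 1 (default 50000).
#' @param seed optional integer seed.
#' @param distribution `"uniform"` (default; maximum-entropy choice on a
#'   bounded interval) or `"empirical"` to resample from `hb_samples`.
#' @param hb_samples numeric vector of observed hemoglobin values, required
#'   for `distribution = "empirical"`.
#' @return An `autocorrelation_matrix` with role `"pigment"`.
#' @export
build_pigment_autocorrelation <- function(hb_range, shade_value,
                                          n_samples = 50000, seed = NULL,
                                          distribution = c("uniform",
                                                           "empirical"),
                                          hb_samples = NULL) {
  distribution <- match.arg(distribution)
  if (length(hb_range) != 2L || any(!is.finite(hb_range))) {
    stop("`hb_range` must be a finite length-2 interval", call. = FALSE)
  }
  if (hb_range[1] > hb_range[2]) {
    stop("`hb_range` must satisfy min <= max", call. = FALSE)
  }
  stopifnot_scalar_number(shade_value, "shade_value")
  if (!is.numeric(n_samples) || n_samples < 1) {
    stop("`n_samples` must be >= 1", call. = FALSE)
  }
  n_samples <- as.integer(n_samples)
  if (distribution == "uniform" && hb_range[1] == hb_range[2]) {
    h2 <- hb_range[1]^2
    hs <- hb_range[1] * shade_value
    return(autocorrelation_matrix(matrix(c(h2, hs, hs, shade_value^2), 2, 2),
                                  role = "pigment", provenance = "analytic"))
  }
  h <- with_seed(seed, {
    if (distribution == "uniform") {
      stats::runif(n_samples, hb_range[1], hb_range[2])
    } else {
      if (is.null(hb_samples) || !length(hb_samples)) {
        stop("`hb_samples` required for the empirical distribution", call. = FALSE)
      }
      sample(hb_samples, n_samples, replace = TRUE)
    }
  })
  m11 <- mean(h^2)
  m12 <- mean(h) * shade_value
  m22 <- shade_value^2
  autocorrelation_matrix(matrix(c(m11, m12, m12, m22), 2, 2),
                         role = "pigment", provenance = "sampled",
                         n_samples = n_samples, seed = seed)
}

#' Wiener estimation matrix
#'
#' Builds `G = Rrr F' (F Rrr F' + Rnn)^{-1}` via a numerically stable solve
#' (never an explicit inverse) and retains all inputs for provenance.
#'
#' @param rrr pigment autocorrelation (`autocorrelation_matrix` or plain 2x2).
#' @param f a `system_matrix`.
#' @param rnn noise autocorrelation (`autocorrelation_matrix` or plain 2x2).
#' @return An object of class `wiener_estimator` with fields `G`, `F`,
#'   `Rrr`, `Rnn`.
#' @export
wiener_matrix <- function(rrr, f, rnn) {
  stopifnot(inherits(f, "system_matrix"))
  rrr_m <- matrix(as.numeric(rrr), 2, 2)
  rnn_m <- matrix(as.numeric(rnn), 2, 2)
  fm <- matrix(as.numeric(f), 2, 2)
  inner <- fm %*% rrr_m %*% t(fm) + rnn_m
  k <- kappa(inner, exact = TRUE)
  if (!is.finite(k) || k > 1e12) {
    stop(sprintf("F Rrr F' + Rnn is numerically singular (condition number %.3g)",
                 k), call. = FALSE)
  }
  # G = Rrr F' inner^{-1}  <=>  G' = solve(inner', (Rrr F')') ; inner symmetric
  g <- t(solve(inner, fm %*% rrr_m))
  structure(list(G = g, F = f, Rrr = rrr, Rnn = rnn),
            class = "wiener_estimator")
}

#' Wiener separation
#'
#' Per frame, `r~ = G v`.
#'
#' @param est a `wiener_estimator` from [wiener_matrix].
#' @param v a [density_series].
#' @return A [pigment_series] with `method_tag = "wiener"`.
#' @export
wiener_separate <- function(est, v) {
  stopifnot(inherits(est, "wiener_estimator"), inherits(v, "density_series"))
  r <- unclass(v) %*% t(est$G)
  pigment_series(r, attr(v, "frame_rate"), method_tag = "wiener")
}

#' Serialize estimator provenance to a JSON sidecar
#'
#' Writes F, Rrr, Rnn, G and any sampling metadata so a separation run can
#' be reproduced exactly.
#'
#' @param est a `wiener_estimator`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_estimator_sidecar <- function(est, path) {
  stopifnot(inherits(est, "wiener_estimator"))
  meta <- function(m) {
    list(entries = matrix(as.numeric(m), 2, 2),
         role = attr(m, "role") %||% NA_character_,
         provenance = attr(m, "provenance") %||% NA_character_,
         n_samples = attr(m, "n_samples") %||% NA,
         seed = attr(m, "seed") %||% NA)
  }
  obj <- list(G = est$G,
              F = matrix(as.numeric(est$F), 2, 2),
              band_ids = attr(est$F, "band_ids"),
              Rrr = meta(est$Rrr),
              Rnn = meta(est$Rnn))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.wiener_estimator <- function(x, ...) {
  cat("<wiener_estimator> G = Rrr F' (F Rrr F' + Rnn)^{-1}:\n")
  print(x$G)
  invisible(x)
}
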