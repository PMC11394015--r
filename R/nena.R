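#' Consecutive-frame nearest-neighbour distances
#'
#' For every localization in frame t, the Euclidean distance to its nearest
#' neighbour in frame t + 1, pooled over all adjacent frame pairs. Because a
#' blinking molecule is re-localized in consecutive frames, the small-distance
#' part of this sample reflects twice the localization precision.
#'
#' @param table A [loc_table()].
#' @return Numeric vector of distances (nm).
#' @export
consecutive_frame_nn_distances <- function(table) {
  if (nrow(table) < 2) stop("need at least 2 localizations")
  by_frame <- split(seq_len(nrow(table)), table$frame)
  fr <- as.integer(names(by_frame))
  out <- vector("list", length(fr))
  for (k in seq_along(fr)) {
    nxt <- match(fr[k] + 1L, fr)
    if (is.na(nxt)) next
    i <- by_frame[[k]]; j <- by_frame[[nxt]]
    q <- cbind(table$x[i], table$y[i])
    ref <- cbind(table$x[j], table$y[j])
    out[[k]] <- as.numeric(FNN::get.knnx(ref, q, k = 1)$nn.dist)
  }
  d <- unlist(out, use.names = FALSE)
  if (length(d) == 0) stop("no adjacent-frame localization pairs in table")
  d
}

#' Fit the NeNA localization-precision model
#'
#' The distance histogram is fit by least squares to the sum of a
#' same-molecule term, a Rayleigh density with scale `sqrt(2) * sigma`
#' (two independent localizations of one molecule, each with per-axis
#' precision sigma), and two empirical correction terms for mismatched
#' neighbours: a Gaussian bump and a linearly rising background,
#' \deqn{f(d) = A \frac{d}{2\sigma^2} e^{-d^2/(4\sigma^2)}
#'       + B \frac{1}{\sqrt{2\pi}\,\omega} e^{-(d-d_c)^2/(2\omega^2)} + C d.}
#'
#' @param distances Distance sample from
#'   [consecutive_frame_nn_distances()] (nm).
#' @param bin_width Histogram bin width (nm), default 1.
#' @param d_max Histogram upper range (nm), default 200.
#' @param min_sample Minimum usable sample size within range, default 100.
#' @return A `nena_fit` with elements `sigma` (nm), `coefficients`,
#'   `fitted`, `histogram` (data.frame mid, density), `n`, `convergence`.
#' @export
fit_nena <- function(distances, bin_width = 1, d_max = 200, min_sample = 100) {
  stopifnot(all(distances >= 0))
  d <- distances[distances <= d_max]
  if (length(d) < min_sample)
    stop("NeNA needs >= ", min_sample, " distances within [0, ", d_max, "] nm")
  if (stats::sd(d) == 0)
    stop("degenerate distance sample (no spread); cannot fit NeNA model")
  breaks <- seq(0, d_max, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  dens <- h$counts / (sum(h$counts) * bin_width)  # unit area on [0, d_max]
  mid <- h$mids

  sigma0 <- max(mid[which.max(dens)], bin_width) / sqrt(2)
  df <- data.frame(mid = mid, dens = dens)
  model <- function(p, d) {
    p["A"] * d / (2 * p["sigma"]^2) * exp(-d^2 / (4 * p["sigma"]^2)) +
      p["B"] / (sqrt(2 * pi) * p["w"]) *
        exp(-(d - p["dc"])^2 / (2 * p["w"]^2)) +
      p["C"] * d
  }
  # correction amplitudes start near (not at) zero: at exactly zero the
  # Gaussian term's dc/w gradient columns vanish and the Jacobian is singular
  start <- c(A = 1, sigma = sigma0, B = 0.01, dc = stats::median(d),
             w = 30, C = 1e-6)
  lower <- c(A = 0, sigma = 1e-3, B = 0, dc = 0, w = 1, C = 0)
  upper <- c(A = Inf, sigma = d_max, B = Inf, dc = d_max, w = d_max, C = Inf)
  fit <- try(minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper,
    fn = function(p) dens - model(p, mid),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error") || !fit$info %in% 1:4)
    stop("NeNA fit failed to converge; initial sigma = ", format(sigma0),
         if (!inherits(fit, "try-error"))
           paste0("; nls.lm status ", fit$info, " (", fit$message, ")"))
  co <- fit$par
  structure(list(sigma = unname(co["sigma"]), coefficients = co,
                 fitted = model(co, mid),
                 histogram = df, n = length(d),
                 bin_width = bin_width, d_max = d_max,
                 convergence = fit$info %in% 1:4),
            class = "nena_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.nena_fit <- function(x, ...) {
  cat(sprintf("NeNA localization precision: sigma = %.2f nm (n = %d distances)\n",
              x$sigma, x$n))
  invisible(x)
}

#' @export
coef.nena_fit <- function(object, ...) object$coefficients

#' @method plot nena_fit
#' @export
plot.nena_fit <- function(x, ...) {
  graphics::plot(x$histogram$mid, x$histogram$dens, type = "h", col = "grey",
                 xlab = "nearest-neighbour distance (nm)", ylab = "density",
                 main = sprintf("NeNA fit: sigma = %.1f nm", x$sigma), ...)
  graphics::lines(x$histogram$mid, x$fitted, col = "red", lwd = 2)
  invisible(x)
}

#' NeNA precision for one localization table
#'
#' Convenience wrapper chaining [consecutive_frame_nn_distances()] and
#' [fit_nena()].
#'
#' @param table A [loc_table()].
#' @param ... Passed to [fit_nena()].
#' @return A `nena_fit`.
#' @export
nena_precision <- function(table, ...) {
  fit_nena(consecutive_frame_nn_distances(table), ...)
}
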