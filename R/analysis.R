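# Odor-coding analyses: linear-kernel fitting of binned firing-rate
# responses, rectified two-odor prediction, the residual-over-noise score,
# respiration-phase and delta-rate correlations of sister cells, odor-morph
# model fitting, and scaled-pulse latency/similarity metrics.

#' Fit a linear odor kernel to binned responses
#'
#' Least-squares fit of a 2 s kernel discretised at the bin width (40 taps
#' at 50 ms) to one or more air-subtracted pulse-train responses, by
#' stacking the discrete convolution design matrices of all stimuli and
#' solving the joint normal equations via QR.  No regularisation.
#'
#' @param responses list of numeric vectors (trial-averaged binned rates,
#'   one per stimulus), or a single vector
#' @param concentrations list of matching binned concentration series
#' @param n_taps kernel length in bins (default 40)
#' @param baseline constant air baseline to subtract (default: mean of each
#'   response's first bin is NOT used; supply explicitly, default 0)
#' @return object of class \code{kernel_fit}: \code{kernel} (tibble
#'   \code{lag}, \code{value}), \code{baseline}, \code{fitted} (list),
#'   \code{rank_deficient} flag
#' @export
fit_linear_kernel <- function(responses, concentrations, n_taps = 40,
                              baseline = 0) {
  if (is.numeric(responses)) responses <- list(responses)
  if (is.numeric(concentrations)) concentrations <- list(concentrations)
  stopifnot(length(responses) == length(concentrations))
  Xs <- list(); ys <- list()
  for (i in seq_along(responses)) {
    y <- responses[[i]] - baseline
    cc <- concentrations[[i]]
    stopifnot(length(y) == length(cc))
    nb <- length(y)
    X <- matrix(0, nb, n_taps)
    for (k in seq_len(n_taps)) {
      idx <- seq_len(nb - k + 1)
      X[idx + k - 1, k] <- cc[idx]
    }
    Xs[[i]] <- X; ys[[i]] <- y
  }
  X <- do.call(rbind, Xs); y <- unlist(ys)
  qrX <- qr(X)
  rank_def <- qrX$rank < n_taps
  if (rank_def) {
    beta <- as.numeric(MASS_ginv(X) %*% y)
  } else {
    beta <- qr.coef(qrX, y)
  }
  fitted <- lapply(Xs, function(Xi) as.numeric(Xi %*% beta) + baseline)
  structure(list(kernel = tibble(lag = seq_len(n_taps) - 1L, value = beta),
                 baseline = baseline, fitted = fitted,
                 rank_deficient = rank_def),
            class = "kernel_fit")
}

# small pseudo-inverse (avoids a MASS dependency for this one fallback)
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*%
    ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat("<kernel_fit> ", nrow(x$kernel), " taps, baseline ", x$baseline,
      if (x$rank_deficient) " (rank-deficient: pseudo-inverse)", "\n",
      sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.kernel_fit <- function(x, ...) x$kernel

#' @exportS3Method generics::glance
glance.kernel_fit <- function(x, ...) {
  tibble(n_taps = nrow(x$kernel), baseline = x$baseline,
         rank_deficient = x$rank_deficient,
         peak = max(x$kernel$value), peak_lag = x$kernel$lag[
           which.max(x$kernel$value)])
}

#' Predict the response to a two-odor stimulus
#'
#' Rectified sum of the convolutions of each odor's fitted kernel with its
#' concentration series, plus the air baseline.
#'
#' @param fitA,fitB [fit_linear_kernel()] results on a common bin grid
#' @param concA,concB binned concentration series (equal length)
#' @return predicted rate vector, floored at zero
#' @export
predict_two_odor <- function(fitA, fitB, concA, concB) {
  if (length(concA) != length(concB))
    stop("concentration series must be on the same grid", call. = FALSE)
  if (nrow(fitA$kernel) != nrow(fitB$kernel))
    stop("kernel grids do not match", call. = FALSE)
  conv1 <- function(fit, cc) {
    k <- fit$kernel$value
    nb <- length(cc)
    out <- numeric(nb)
    for (j in seq_along(k)) {
      idx <- seq_len(nb - j + 1)
      out[idx + j - 1] <- out[idx + j - 1] + k[j] * cc[idx]
    }
    out
  }
  pmax(conv1(fitA, concA) + conv1(fitB, concB) +
         fitA$baseline + fitB$baseline - min(fitA$baseline, fitB$baseline),
       0)
}

#' Residual-over-noise goodness score
#'
#' residual = mean over bins of the squared deviation of the fit or
#' prediction from the trial-averaged data; noise = mean over bins of the
#' across-trial variance (SD-based, not SEM).  Scores below 1 are
#' conventionally acceptable.  With identical trials (zero variance) and a
#' non-zero residual the ratio is reported as \code{Inf} with a flag.
#'
#' @param prediction predicted/fitted series over bins
#' @param trials matrix of per-trial series (trials x bins)
#' @return tibble \code{residual}, \code{noise}, \code{ratio},
#'   \code{infinite}
#' @export
residual_over_noise <- function(prediction, trials) {
  trials <- as.matrix(trials)
  if (nrow(trials) < 2)
    stop("noise undefined with a single trial", call. = FALSE)
  m <- colMeans(trials)
  stopifnot(length(prediction) == length(m))
  residual <- mean((prediction - m)^2)
  noise <- mean(apply(trials, 2, var))
  ratio <- if (noise == 0) {
    if (residual == 0) 0 else Inf
  } else residual / noise
  tibble(residual = residual, noise = noise, ratio = ratio,
         infinite = is.infinite(ratio))
}

#' Phase correlation of two sister-cell cycle responses
#'
#' Pearson correlation over the respiration-cycle bins (conventionally 5)
#' of the two central sisters' mean single-cycle responses.  Pairs in which
#' either response is all-zero or has zero variance are excluded
#' (\code{NA} with an exclusion flag).
#'
#' @param sisterA,sisterB binned single-cycle responses
#' @return tibble \code{r}, \code{excluded}
#' @export
phase_correlation <- function(sisterA, sisterB) {
  stopifnot(length(sisterA) == length(sisterB))
  if (all(sisterA == 0) || all(sisterB == 0) ||
      sd(sisterA) == 0 || sd(sisterB) == 0)
    return(tibble(r = NA_real_, excluded = TRUE))
  tibble(r = cor(sisterA, sisterB), excluded = FALSE)
}

#' Delta-rate correlation across odors and network instances
#'
#' The delta-rate of a cell for one odor in one instance is its mean odor
#' rate minus its mean air rate.  Stringing the delta-rates of all
#' instance-odor combinations of one central sister into a vector, and the
#' other sister's into another, the Pearson correlation between the two
#' vectors measures how much the sisters co-vary in mean rate change.
#'
#' @param deltas tibble with columns \code{instance}, \code{odor},
#'   \code{sister} (1 or 2), \code{delta}
#' @return scalar correlation
#' @export
delta_rate_correlation <- function(deltas) {
  wide <- deltas %>%
    tidyr::pivot_wider(id_cols = c("instance", "odor"),
                       names_from = "sister", values_from = "delta",
                       names_prefix = "s")
  wide <- wide[complete.cases(wide), ]
  if (nrow(wide) < 2)
    stop("need at least 2 instance-odor combinations", call. = FALSE)
  cor(wide$s1, wide$s2)
}

#' Sigmoidal output non-linearity of the morph model
#' @param x input
#' @export
morph_sigmoid <- function(x) exp(4.39 * x) / (1 + exp(4.39 * x))

#' Fit the odor-morph response model
#'
#' Responses to air, two pure odors and binary mixtures (morphs) are fitted
#' as \code{R(t) = r_max f(w_A F_A(t) + w_B F_B(t) + F_air(t))} with
#' free-form per-bin internal representations F, a saturation rate r_max,
#' and weights w monotone in concentration (pure-odor and air responses use
#' the same equations with w = 1 or 0).  \code{mode} selects the printed
#' sigmoid \code{f(x) = exp(4.39x)/(1+exp(4.39x))} with free weights, or a
#' simple rectifier with weights fixed at the normalised concentrations.
#'
#' @param responses named list: \code{air}, \code{A}, \code{B} (binned
#'   vectors) and \code{morphs} (list of binned vectors)
#' @param conc tibble with \code{cA}, \code{cB} for each morph (normalised
#'   concentrations in [0,1])
#' @param mode \code{"free_weights_sigmoid"} or
#'   \code{"linear_weights_rectifier"}
#' @param n_starts random restarts for the optimiser
#' @param trials optional list of per-condition trial matrices for
#'   residual/noise
#' @return object of class \code{morph_fit}
#' @export
fit_morph_model <- function(responses, conc,
                            mode = c("free_weights_sigmoid",
                                     "linear_weights_rectifier"),
                            n_starts = 5, trials = NULL) {
  mode <- match.arg(mode)
  nb <- length(responses$air)
  nm <- length(responses$morphs)
  stopifnot(nrow(conc) == nm)
  rmax0 <- max(unlist(responses), 1e-6)
  f <- if (mode == "free_weights_sigmoid") morph_sigmoid else
    function(x) pmax(x, 0)
  finv_guess <- function(y, rmax) {
    p <- pmin(pmax(y / rmax, 0.01), 0.99)
    if (mode == "free_weights_sigmoid") log(p / (1 - p)) / 4.39 else p
  }

  # parameter vector: log(rmax), Fair, FA, FB, then (if free weights)
  # monotone weight increments for A and B levels
  lvA <- sort(unique(conc$cA[conc$cA > 0]))
  lvB <- sort(unique(conc$cB[conc$cB > 0]))
  free_w <- mode == "free_weights_sigmoid"
  unpack <- function(p) {
    rmax <- exp(p[1])
    Fair <- p[2:(1 + nb)]
    FA <- p[(2 + nb):(1 + 2 * nb)]
    FB <- p[(2 + 2 * nb):(1 + 3 * nb)]
    if (free_w) {
      iA <- p[(2 + 3 * nb):(1 + 3 * nb + length(lvA))]
      iB <- p[(2 + 3 * nb + length(lvA)):(1 + 3 * nb + length(lvA) +
                                            length(lvB))]
      wA <- cumsum(exp(iA)); wB <- cumsum(exp(iB))
    } else {
      wA <- lvA; wB <- lvB
    }
    list(rmax = rmax, Fair = Fair, FA = FA, FB = FB, wA = wA, wB = wB)
  }
  wfor <- function(cc, lv, w) if (cc == 0) 0 else w[match(cc, lv)]
  predict_all <- function(par) {
    pr <- list(air = par$rmax * f(par$Fair),
               A = par$rmax * f(par$FA),
               B = par$rmax * f(par$FB))
    pr$morphs <- lapply(seq_len(nm), function(i) {
      par$rmax * f(wfor(conc$cA[i], lvA, par$wA) * par$FA +
                     wfor(conc$cB[i], lvB, par$wB) * par$FB + par$Fair)
    })
    pr
  }
  objective <- function(p) {
    par <- unpack(p)
    pr <- predict_all(par)
    sum((pr$air - responses$air)^2) + sum((pr$A - responses$A)^2) +
      sum((pr$B - responses$B)^2) +
      sum(vapply(seq_len(nm), function(i)
        sum((pr$morphs[[i]] - responses$morphs[[i]])^2), 0))
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    rm0 <- rmax0 * runif(1, 1.0, 1.6)
    p0 <- c(log(rm0),
            finv_guess(responses$air, rm0) * runif(nb, 0.9, 1.1),
            finv_guess(responses$A, rm0) * runif(nb, 0.9, 1.1),
            finv_guess(responses$B, rm0) * runif(nb, 0.9, 1.1))
    if (free_w) {
      p0 <- c(p0, log(diff(c(0, lvA)) + 0.05 * runif(length(lvA))),
              log(diff(c(0, lvB)) + 0.05 * runif(length(lvB))))
    }
    fit <- optim(p0, objective, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  par <- unpack(best$par)
  pred <- predict_all(par)
  quality <- NULL
  if (!is.null(trials)) {
    qs <- list(
      air = residual_over_noise(pred$air, trials$air),
      A = residual_over_noise(pred$A, trials$A),
      B = residual_over_noise(pred$B, trials$B))
    qm <- purrr::map_dfr(seq_len(nm), function(i)
      residual_over_noise(pred$morphs[[i]], trials$morphs[[i]]))
    quality <- bind_rows(bind_rows(qs, .id = "condition"),
                         qm %>% mutate(condition = paste0("morph", row_number())))
  }
  structure(list(par = par, predictions = pred, sse = best$value,
                 converged = best$convergence == 0, mode = mode,
                 conc = conc, quality = quality),
            class = "morph_fit")
}

#' @export
print.morph_fit <- function(x, ...) {
  cat("<morph_fit> mode=", x$mode, " sse=", signif(x$sse, 4),
      if (!x$converged) " (optimizer not converged; best-so-far)",
      "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.morph_fit <- function(x, ...) {
  bind_rows(
    tibble(term = "r_max", level = NA_real_, value = x$par$rmax),
    tibble(term = "w_A", level = sort(unique(x$conc$cA[x$conc$cA > 0])),
           value = x$par$wA),
    tibble(term = "w_B", level = sort(unique(x$conc$cB[x$conc$cB > 0])),
           value = x$par$wB))
}

#' @exportS3Method generics::glance
glance.morph_fit <- function(x, ...) {
  tibble(mode = x$mode, sse = x$sse, converged = x$converged,
         r_max = x$par$rmax)
}

#' Latency and similarity metrics for scaled-pulse responses
#'
#' Per cell: the latency to first spike and to the peak of the rate
#' histogram after odor onset, normalised by that cell's mean across
#' concentrations; plus the Pearson correlation of each concentration's
#' histogram against the reference (1%) histogram, and response peaks.
#'
#' @param responses tibble with columns \code{cell}, \code{conc},
#'   \code{first_spike} (ms after onset, NA if none) and a list-column
#'   \code{hist} of binned air-subtracted histograms
#' @param ref_conc reference concentration (default 1)
#' @return tibble, one row per cell x concentration, with
#'   \code{norm_latency_spike}, \code{norm_latency_peak}, \code{r_vs_ref},
#'   \code{peak}
#' @export
scaled_pulse_metrics <- function(responses, ref_conc = 1) {
  responses %>%
    group_by(.data$cell) %>%
    mutate(
      peak = vapply(.data$hist, function(h) max(h), 0),
      lat_peak = vapply(.data$hist, function(h) which.max(h), 0),
      norm_latency_spike = .data$first_spike /
        mean(.data$first_spike, na.rm = TRUE),
      norm_latency_peak = .data$lat_peak / mean(.data$lat_peak),
      r_vs_ref = {
        ref <- .data$hist[.data$conc == ref_conc][[1]]
        vapply(.data$hist, function(h)
          if (sd(h) == 0 || sd(ref) == 0) NA_real_ else cor(h, ref), 0)
      }) %>%
    ungroup() %>%
    select("cell", "conc", "norm_latency_spike", "norm_latency_peak",
           "r_vs_ref", "peak")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
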