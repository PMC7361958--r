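# Elliptic IIR design in zero-pole-gain form.
#
# The analog low-pass prototype is computed from Jacobi elliptic functions
# (pracma::ellipke / ellipj), band-transformed and bilinear-mapped without
# ever expanding a high-order polynomial, then realized as a cascade of
# biquad sections. Direct transfer-function design (e.g. signal::ellip) is
# numerically unstable for a 0.1 Hz edge at EEG sampling rates because the
# expanded denominator pushes near-unit-circle poles outside the circle.

# analog elliptic low-pass prototype (passband edge 1 rad/s) as z/p/k
ellip_prototype <- function(n, rp, rs) {
  eps_sq <- 10^(0.1 * rp) - 1
  eps <- sqrt(eps_sq)
  if (n == 1) {
    p <- complex(real = -sqrt(1 / eps_sq))
    return(list(z = complex(0), p = p, k = -Re(p)))
  }
  ck1_sq <- eps_sq / (10^(0.1 * rs) - 1)
  K1 <- pracma::ellipke(ck1_sq)$k
  K1p <- pracma::ellipke(1 - ck1_sq)$k
  krat <- n * K1 / K1p
  # degree equation K(m)/K(1-m) = krat, solved for m on a logit scale
  f <- function(lg) {
    m <- stats::plogis(lg)
    pracma::ellipke(m)$k / pracma::ellipke(1 - m)$k - krat
  }
  m <- stats::plogis(stats::uniroot(f, c(-40, 40), tol = 1e-14)$root)
  capk <- pracma::ellipke(m)$k
  j <- seq(1 - n %% 2, n - 1, by = 2)
  ej <- pracma::ellipj(j * capk / n, rep(m, length(j)))
  s <- ej$sn; cn <- ej$cn; dn <- ej$dn
  snz <- s[abs(s) > 1e-14]
  z <- complex(imaginary = 1 / (sqrt(m) * snz))
  z <- c(z, Conj(z))
  # v0 from the inverse Jacobi sc at the complementary modulus
  mp <- 1 - ck1_sq
  Kp <- pracma::ellipke(mp)$k
  g <- function(u) { e <- pracma::ellipj(u, mp); e$sn / e$cn - 1 / eps }
  u <- stats::uniroot(g, c(1e-12, Kp * (1 - 1e-12)), tol = 1e-14)$root
  v0 <- capk * u / (n * K1)
  ev <- pracma::ellipj(v0, 1 - m)   # complementary parameter for the pole ordinate
  p <- -(cn * dn * ev$sn * ev$cn + 1i * s * ev$dn) / (1 - (dn * ev$sn)^2)
  if (n %% 2) {
    pc <- p[abs(Im(p)) > 1e-12 * sqrt(sum(Mod(p)^2))]
    p <- c(p, Conj(pc))
  } else {
    p <- c(p, Conj(p))
  }
  k <- Re(prod(-p) / prod(-z))
  if (n %% 2 == 0) k <- k / sqrt(1 + eps_sq)
  list(z = z, p = p, k = k)
}

lp2lp_zpk <- function(zpk, wo) {
  deg <- length(zpk$p) - length(zpk$z)
  list(z = zpk$z * wo, p = zpk$p * wo, k = zpk$k * wo^deg)
}

lp2hp_zpk <- function(zpk, wo) {
  deg <- length(zpk$p) - length(zpk$z)
  k <- zpk$k * Re(prod(-zpk$z) / prod(-zpk$p))
  list(z = c(wo / zpk$z, rep(0 + 0i, deg)), p = wo / zpk$p, k = k)
}

lp2bp_zpk <- function(zpk, wo, bw) {
  z <- zpk$z; p <- zpk$p
  deg <- length(p) - length(z)
  zl <- z * bw / 2; pl <- p * bw / 2
  zb <- c(zl + sqrt(as.complex(zl^2 - wo^2)), zl - sqrt(as.complex(zl^2 - wo^2)))
  pb <- c(pl + sqrt(as.complex(pl^2 - wo^2)), pl - sqrt(as.complex(pl^2 - wo^2)))
  list(z = c(zb, rep(0 + 0i, deg)), p = pb, k = zpk$k * bw^deg)
}

bilinear_zpk <- function(zpk, fs) {
  fs2 <- 2 * fs
  deg <- length(zpk$p) - length(zpk$z)
  list(z = c((fs2 + zpk$z) / (fs2 - zpk$z), rep(-1 + 0i, deg)),
       p = (fs2 + zpk$p) / (fs2 - zpk$p),
       k = zpk$k * Re(prod(fs2 - zpk$z) / prod(fs2 - zpk$p)))
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

# pair conjugate roots into biquads; poles closest to the unit circle are
# matched with their nearest zero pair to limit per-section gain spread
zpk_to_sos <- function(zpk) {
  pair_up <- function(r) {
    r <- r[order(Re(r), abs(Im(r)))]
    got <- rep(FALSE, length(r)); pairs <- list()
    for (i in seq_along(r)) {
      if (got[i]) next
      got[i] <- TRUE
      if (abs(Im(r[i])) > 1e-9) {
        j <- which(!got & abs(r - Conj(r[i])) < 1e-6)[1]
        if (is.na(j)) abort("unpaired complex root in filter design.",
                            class = "eegdx_design_error")
        got[j] <- TRUE
        pairs[[length(pairs) + 1]] <- c(r[i], r[j])
      } else {
        j <- which(!got & abs(Im(r)) <= 1e-9)
        if (length(j)) {
          got[j[1]] <- TRUE
          pairs[[length(pairs) + 1]] <- c(r[i], r[j[1]])
        } else {
          pairs[[length(pairs) + 1]] <- r[i]
        }
      }
    }
    pairs
  }
  pp <- pair_up(zpk$p)
  zz <- pair_up(zpk$z)
  pp <- pp[order(-vapply(pp, function(q) max(Mod(q)), numeric(1)))]
  sos <- matrix(0, nrow = length(pp), ncol = 6)
  used <- rep(FALSE, length(zz))
  for (i in seq_along(pp)) {
    pcen <- mean(pp[[i]])
    cand <- which(!used)
    if (length(cand)) {
      d <- vapply(cand, function(j) Mod(mean(zz[[j]]) - pcen), numeric(1))
      jz <- cand[which.min(d)]
      used[jz] <- TRUE
      zr <- zz[[jz]]
    } else {
      zr <- complex(0)
    }
    b <- Re(poly_from_roots(zr)); a <- Re(poly_from_roots(pp[[i]]))
    sos[i, ] <- c(c(b, rep(0, 3 - length(b))), c(a, rep(0, 3 - length(a))))
  }
  sos[1, 1:3] <- sos[1, 1:3] * zpk$k
  sos
}

new_filter_spec <- function(kind, sos, fs, params) {
  structure(c(list(kind = kind, sos = sos, fs = fs), params),
            class = "filter_spec")
}

#' Design an elliptic band-pass filter
#'
#' Designs a digital elliptic (Cauer) band-pass in zero-pole-gain form and
#' returns it as a cascade of second-order sections, which stays numerically
#' stable even for the standard 0.1-60 Hz EEG band whose low edge sits very
#' close to DC. `order` is the analog prototype order, so the realized
#' band-pass has `2 * order` poles.
#'
#' @param fs Sampling rate in Hz.
#' @param low_hz,high_hz Passband edges in Hz, `0 < low_hz < high_hz < fs/2`.
#' @param passband_ripple_db Peak-to-peak passband ripple in dB (> 0).
#' @param stopband_atten_db Minimum stopband attenuation in dB (> 0).
#' @param order Prototype order (default 8).
#' @return A `filter_spec` object holding the second-order sections.
#' @export
design_elliptic_bandpass <- function(fs, low_hz = 0.1, high_hz = 60,
                                     passband_ripple_db = 0.5,
                                     stopband_atten_db = 40, order = 8) {
  if (passband_ripple_db <= 0 || stopband_atten_db <= 0 || order < 1) {
    abort("ripple, attenuation and order must be positive.",
          class = "eegdx_parameter_error")
  }
  if (!(0 < low_hz && low_hz < high_hz)) {
    abort("need 0 < low_hz < high_hz.", class = "eegdx_parameter_error")
  }
  if (high_hz >= fs / 2) {
    abort(sprintf("design error: high edge %g Hz is at or above Nyquist (%g Hz).",
                  high_hz, fs / 2),
          class = "eegdx_design_error")
  }
  proto <- ellip_prototype(order, passband_ripple_db, stopband_atten_db)
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  w1 <- warp(low_hz); w2 <- warp(high_hz)
  dig <- bilinear_zpk(lp2bp_zpk(proto, sqrt(w1 * w2), w2 - w1), fs)
  if (max(Mod(dig$p)) >= 1) {
    abort("design error: realized filter is unstable; reduce the order.",
          class = "eegdx_design_error")
  }
  sos <- zpk_to_sos(dig)
  spec <- new_filter_spec("elliptic_bandpass", sos, fs,
                          list(low_hz = low_hz, high_hz = high_hz,
                               passband_ripple_db = passband_ripple_db,
                               stopband_atten_db = stopband_atten_db,
                               order = order))
  # pin the passband peak to exactly unity gain (special-function precision
  # can leave the realized response a few hundredths of a dB off)
  grid <- exp(seq(log(low_hz), log(high_hz), length.out = 512))
  peak <- max(Mod(filter_response(spec, grid)))
  spec$sos[1, 1:3] <- spec$sos[1, 1:3] / peak
  spec
}

#' Design a notch filter
#'
#' Standard constant-gain biquad notch, used optionally to suppress mains
#' interference (e.g. 60 Hz).
#'
#' @param fs Sampling rate in Hz.
#' @param freq_hz Notch center frequency (< fs/2).
#' @param q Quality factor (center / -3 dB width).
#' @return A `filter_spec` object.
#' @export
design_notch <- function(fs, freq_hz = 60, q = 30) {
  if (freq_hz <= 0 || freq_hz >= fs / 2) {
    abort("notch frequency must lie in (0, fs/2).", class = "eegdx_design_error")
  }
  w0 <- 2 * pi * freq_hz / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  new_filter_spec("notch", matrix(c(b / a[1], a / a[1]), nrow = 1), fs,
                  list(freq_hz = freq_hz, q = q))
}

#' Frequency response of a designed filter
#'
#' @param spec A `filter_spec`.
#' @param f Frequencies in Hz.
#' @return Complex response `H(f)`.
#' @export
filter_response <- function(spec, f) {
  z <- exp(2i * pi * f / spec$fs)
  h <- rep(1 + 0i, length(z))
  for (i in seq_len(nrow(spec$sos))) {
    s <- spec$sos[i, ]
    h <- h * (s[1] + s[2] / z + s[3] / z^2) / (s[4] + s[5] / z + s[6] / z^2)
  }
  h
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %s @ fs=%g Hz, %d biquad section(s)\n",
              x$kind, x$fs, nrow(x$sos)))
  if (x$kind == "elliptic_bandpass") {
    cat(sprintf("  band %g-%g Hz, ripple %g dB, attenuation %g dB, order %d\n",
                x$low_hz, x$high_hz, x$passband_ripple_db,
                x$stopband_atten_db, x$order))
  }
  invisible(x)
}

sos_filter_vec <- function(sos, x, zero_phase) {
  for (i in seq_len(nrow(sos))) {
    b <- sos[i, 1:3]; a <- sos[i, 4:6]
    x <- if (zero_phase) {
      signal::filtfilt(b, a, x)
    } else {
      as.numeric(signal::filter(b, a, x))
    }
  }
  x
}

#' Apply a designed filter to a segment
#'
#' Each channel is filtered independently through the biquad cascade.
#' `zero_phase` (default) runs each section forward and backward so the
#' output has no group delay; `causal` is a single forward pass.
#'
#' @param seg An [eeg_segment] or [eeg_recording].
#' @param spec A `filter_spec` whose `fs` matches the segment's.
#' @param mode `"zero_phase"` or `"causal"`.
#' @return The filtered segment, metadata unchanged.
#' @export
apply_filter <- function(seg, spec, mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "filter_spec"))
  if (!isTRUE(all.equal(spec$fs, seg$fs))) {
    abort(sprintf("filter fs (%g) does not match segment fs (%g).",
                  spec$fs, seg$fs),
          class = "eegdx_contract_error")
  }
  out <- seg
  for (ci in seq_len(n_channels(seg))) {
    out$samples[, ci] <- sos_filter_vec(spec$sos, seg$samples[, ci],
                                        mode == "zero_phase")
  }
  out
}
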