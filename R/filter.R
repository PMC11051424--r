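# Minimal IIR filtering support: closed-form second-order Butterworth sections
# applied forward-backward (zero phase). Only what the trough detector needs.

# coefficients of a 2nd-order Butterworth section via the bilinear transform;
# returns list(b, a) with a[1] = 1
.butter2 <- function(fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  K <- tan(pi * fc / fs)
  norm <- 1 / (1 + sqrt(2) * K + K^2)
  a <- c(1, 2 * (K^2 - 1) * norm, (1 - sqrt(2) * K + K^2) * norm)
  b <- if (type == "low") c(K^2, 2 * K^2, K^2) * norm
       else c(1, -2, 1) * norm
  list(b = b, a = a)
}

# direct-form IIR: y[n] = b0 x[n] + b1 x[n-1] + b2 x[n-2] - a1 y[n-1] - a2 y[n-2]
.iir2 <- function(x, coef) {
  xf <- coef$b[1] * x +
    coef$b[2] * c(0, x[-length(x)]) +
    coef$b[3] * c(0, 0, x[-c(length(x) - 1L, length(x))])
  as.numeric(stats::filter(xf, -coef$a[2:3], method = "recursive"))
}

# zero-phase (forward-backward) application with reflective edge padding
.filtfilt2 <- function(x, coef, pad = min(length(x) - 1L, 256L)) {
  n <- length(x)
  xp <- c(2 * x[1] - x[pad:2], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- .iir2(xp, coef)
  y <- rev(.iir2(rev(y), coef))
  y[(pad + 1L):(pad + n)]
}

# zero-phase band-pass as cascaded high- and low-pass Butterworth sections
bandpass_zerophase <- function(x, fs, low = 0.5, high = 8) {
  if (length(x) < 16L) return(x - mean(x))
  y <- .filtfilt2(x, .butter2(low, fs, "high"))
  if (high < fs / 2) y <- .filtfilt2(y, .butter2(high, fs, "low"))
  y
}
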