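#' Global auto-threshold methods
#'
#' Sixteen classical global thresholding algorithms operating on a 256-bin
#' intensity histogram, following their published definitions as implemented
#' in the ImageJ ecosystem's auto-threshold collection. Every method returns
#' an integer level `t` in 0..255 such that pixels with value `> t` are
#' foreground (bright objects on a dark background); the result is
#' deterministic for a given histogram.
#'
#' Method notes:
#' * `Default` is the original ImageJ iterative intermeans (an IsoData
#'   variant); `IsoData` is the Ridler-Calvard iteration.
#' * `Otsu` maximizes between-class variance; `Yen`, `MaxEntropy`,
#'   `RenyiEntropy` and `Shanbhag` are entropy criteria; `Huang` minimizes
#'   fuzzy-membership entropy; `Li` iterates minimum cross entropy;
#'   `MinError(I)` is the iterative Kittler-Illingworth fit (started at the
#'   histogram mean; iteration `T <- floor(temp + 0.5)` until fixpoint, and
#'   the current level is returned if the discriminant turns negative).
#' * `Intermodes` and `Minimum` smooth the histogram with a 3-bin running
#'   mean until exactly two local maxima remain; they fail on histograms
#'   that never become bimodal.
#' * `Mean`, `Percentile`, `Moments` and `Triangle` are their classical
#'   closed-form / geometric constructions.
#'
#' @param histogram Integer vector of 256 bin counts (bins 0..255), e.g. from
#'   [channel_histogram()].
#' @param method One of `threshold_methods()`.
#' @return Integer threshold in 0..255 (foreground is strictly above it).
#' @examples
#' h <- integer(256); h[11] <- 100; h[201] <- 100   # spikes at 10 and 200
#' auto_threshold(h, "Otsu")
#' @export
auto_threshold <- function(histogram, method = "Default") {
  h <- check_histogram(histogram)
  method <- normalize_method(method)
  t <- switch(method,
    "Default"      = th_default(h),
    "Huang"        = th_huang(h),
    "Intermodes"   = th_intermodes(h, minimum = FALSE),
    "IsoData"      = th_isodata(h),
    "Li"           = th_li(h),
    "MaxEntropy"   = th_maxentropy(h),
    "Mean"         = th_mean(h),
    "MinError(I)"  = th_minerror(h),
    "Minimum"      = th_intermodes(h, minimum = TRUE),
    "Moments"      = th_moments(h),
    "Otsu"         = th_otsu(h),
    "Percentile"   = th_percentile(h),
    "RenyiEntropy" = th_renyi(h),
    "Shanbhag"     = th_shanbhag(h),
    "Triangle"     = th_triangle(h),
    "Yen"          = th_yen(h))
  as.integer(t)
}

#' @rdname auto_threshold
#' @export
threshold_methods <- function() {
  c("Default", "Huang", "Intermodes", "IsoData", "Li", "MaxEntropy", "Mean",
    "MinError(I)", "Minimum", "Moments", "Otsu", "Percentile", "RenyiEntropy",
    "Shanbhag", "Triangle", "Yen")
}

normalize_method <- function(method) {
  if (identical(method, "MinError")) method <- "MinError(I)"
  if (!method %in% threshold_methods())
    stop("unknown threshold method '", method, "'; valid methods: ",
         paste(threshold_methods(), collapse = ", "))
  method
}

check_histogram <- function(h) {
  if (length(h) != 256 || any(h < 0)) stop("histogram must be 256 nonnegative counts")
  if (sum(h) <= 0) stop("histogram is empty")
  if (sum(h > 0) < 2)
    stop("no threshold separates foreground: all mass in one bin (constant image)")
  as.numeric(h)
}

# bins are 0-based throughout: h[i + 1] is the count of intensity i
bins <- 0:255

th_mean <- function(h) floor(sum(bins * h) / sum(h))

th_otsu <- function(h) {
  p <- h / sum(h)
  w0 <- cumsum(p)
  mu <- cumsum(bins * p)
  muT <- mu[256]
  t_cand <- 0:254
  w <- w0[t_cand + 1]
  bcv <- ifelse(w > 0 & w < 1, (muT * w - mu[t_cand + 1])^2 / (w * (1 - w)), -Inf)
  t_cand[which.max(bcv)]
}

th_default <- function(h) {
  nz <- which(h > 0) - 1L
  lo <- nz[1]; hi <- nz[length(nz)]
  moving <- lo
  repeat {
    i1 <- lo:moving; i2 <- if (moving < 255) (moving + 1):hi else integer(0)
    s2 <- sum(h[i1 + 1]); s4 <- sum(h[i2 + 1])
    result <- (sum(i1 * h[i1 + 1]) / s2 + sum(i2 * h[i2 + 1]) / s4) / 2
    moving <- moving + 1
    if (!((moving + 1) <= result && moving < hi - 1)) break
  }
  round(result)
}

th_isodata <- function(h) {
  g <- which(h[2:256] > 0)[1] + 1L  # first nonzero bin above 0, plus one
  if (is.na(g)) g <- 1L
  repeat {
    below <- 0:(g - 1); above <- if (g < 255) (g + 1):255 else integer(0)
    totl <- sum(h[below + 1]); toth <- sum(h[above + 1])
    if (totl > 0 && toth > 0) {
      l <- sum(below * h[below + 1]) %/% totl
      hh <- sum(above * h[above + 1]) %/% toth
      if (g == round((l + hh) / 2)) return(g)
    }
    g <- g + 1L
    if (g > 254) stop("IsoData threshold not found")
  }
}

th_li <- function(h) {
  tot <- sum(h)
  new_thresh <- sum(bins * h) / tot
  threshold <- NA_integer_
  for (iter in 1:1000) {
    old_thresh <- new_thresh
    threshold <- as.integer(old_thresh + 0.5)
    back <- 0:threshold
    obj <- if (threshold < 255) (threshold + 1):255 else integer(0)
    nb <- sum(h[back + 1]); no <- sum(h[obj + 1])
    mean_back <- if (nb == 0) 0 else sum(back * h[back + 1]) / nb
    mean_obj <- if (no == 0) 0 else sum(obj * h[obj + 1]) / no
    temp <- (mean_back - mean_obj) / (log(mean_back) - log(mean_obj))
    new_thresh <- if (temp < -.Machine$double.eps) as.integer(temp - 0.5)
                  else as.integer(temp + 0.5)
    if (abs(new_thresh - old_thresh) <= 0.5) break
  }
  threshold
}

th_huang <- function(h) {
  nz <- which(h > 0) - 1L
  first <- nz[1]; last <- nz[length(nz)]
  C <- last - first
  S <- cumsum(h); W <- cumsum(bins * h)
  Stot <- S[last + 1]; Wtot <- W[last + 1]
  best_t <- first; best_ent <- Inf
  for (t in first:last) {
    mu0 <- W[t + 1] / S[t + 1]
    n1 <- Stot - S[t + 1]
    mu1 <- if (n1 > 0) (Wtot - W[t + 1]) / n1 else 0
    i0 <- first:t
    mux0 <- 1 / (1 + abs(i0 - mu0) / C)
    ent <- sum(h[i0 + 1] * fuzzy_ent(mux0))
    if (t < last) {
      i1 <- (t + 1):last
      mux1 <- 1 / (1 + abs(i1 - mu1) / C)
      ent <- ent + sum(h[i1 + 1] * fuzzy_ent(mux1))
    }
    if (ent < best_ent) { best_ent <- ent; best_t <- t }
  }
  best_t
}

fuzzy_ent <- function(mu) {
  out <- numeric(length(mu))
  ok <- mu > 1e-6 & mu < 1 - 1e-6
  m <- mu[ok]
  out[ok] <- -m * log(m) - (1 - m) * log(1 - m)
  out
}

# 3-bin running-mean smoothing (replicated edges) until exactly two maxima
smooth_until_bimodal <- function(h, max_iter = 10000) {
  y <- h
  for (k in seq_len(max_iter)) {
    if (n_modes(y) == 2) return(y)
    y <- (c(y[1], y[-256]) + y + c(y[-1], y[256])) / 3
  }
  stop("histogram did not become bimodal after ", max_iter,
       " smoothing passes (Intermodes/Minimum require a bimodal histogram)")
}

n_modes <- function(y) {
  sum(y[2:255] > y[1:254] & y[2:255] > y[3:256])
}

th_intermodes <- function(h, minimum = FALSE) {
  y <- smooth_until_bimodal(h)
  peaks <- which(y[2:255] > y[1:254] & y[2:255] > y[3:256])  # 0-based bins
  if (minimum) {
    for (i in 1:254) {
      if (y[i] > y[i + 1] && y[i + 2] >= y[i + 1]) return(i)  # bin i (0-based)
    }
    stop("Minimum threshold not found")
  }
  floor(sum(peaks) / 2)
}

th_maxentropy <- function(h) {
  p <- h / sum(h)
  P1 <- cumsum(p)
  best_t <- 0; best_ent <- -Inf
  for (t in 0:254) {
    w0 <- P1[t + 1]; w1 <- 1 - w0
    if (w0 < 1e-12 || w1 < 1e-12) next
    p0 <- p[1:(t + 1)]; p0 <- p0[p0 > 0]
    p1 <- p[(t + 2):256]; p1 <- p1[p1 > 0]
    ent <- -sum((p0 / w0) * log(p0 / w0)) - sum((p1 / w1) * log(p1 / w1))
    if (ent > best_ent) { best_ent <- ent; best_t <- t }
  }
  best_t
}

th_minerror <- function(h) {
  A <- cumsum(h); B <- cumsum(bins * h); C <- cumsum(bins^2 * h)
  At <- A[256]; Bt <- B[256]; Ct <- C[256]
  threshold <- th_mean(h)
  prev <- -2L
  for (iter in 1:1000) {
    if (threshold == prev) break
    i <- threshold + 1
    if (A[i] <= 0 || At - A[i] <= 0) break
    mu <- B[i] / A[i]
    nu <- (Bt - B[i]) / (At - A[i])
    p <- A[i] / At; q <- 1 - p
    sigma2 <- C[i] / A[i] - mu^2
    tau2 <- (Ct - C[i]) / (At - A[i]) - nu^2
    if (sigma2 <= 0 || tau2 <= 0) break
    w0 <- 1 / sigma2 - 1 / tau2
    w1 <- mu / sigma2 - nu / tau2
    w2 <- mu^2 / sigma2 - nu^2 / tau2 + log10((sigma2 * q^2) / (tau2 * p^2))
    sqterm <- w1^2 - w0 * w2
    if (sqterm < 0) break
    temp <- (w1 + sqrt(sqterm)) / w0
    if (is.nan(temp)) break
    prev <- threshold
    threshold <- as.integer(floor(temp + 0.5))
    threshold <- min(max(threshold, 0L), 254L)
  }
  threshold
}

th_moments <- function(h) {
  p <- h / sum(h)
  m1 <- sum(bins * p); m2 <- sum(bins^2 * p); m3 <- sum(bins^3 * p)
  cd <- m2 - m1^2
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (-m3 + m2 * m1) / cd
  disc <- c1^2 - 4 * c0
  if (disc < 0) disc <- 0
  z0 <- 0.5 * (-c1 - sqrt(disc))
  z1 <- 0.5 * (-c1 + sqrt(disc))
  pd <- (z1 - m1) / (z1 - z0)  # fraction of pixels below the threshold
  csum <- cumsum(p)
  t <- which(csum > pd)[1] - 1L
  if (is.na(t)) t <- 255L
  t
}

th_percentile <- function(h) {
  frac <- cumsum(h) / sum(h)
  which.min(abs(frac - 0.5)) - 1L
}

renyi_entropy_threshold <- function(p, P1, alpha) {
  best_t <- 0; best <- -Inf
  for (t in 0:254) {
    w0 <- P1[t + 1]; w1 <- 1 - w0
    if (w0 < 1e-12 || w1 < 1e-12) next
    p0 <- p[1:(t + 1)]; p1 <- p[(t + 2):256]
    phi <- (log(sum((p0 / w0)^alpha)) + log(sum((p1 / w1)^alpha))) / (1 - alpha)
    if (phi > best) { best <- phi; best_t <- t }
  }
  best_t
}

th_renyi <- function(h) {
  p <- h / sum(h)
  P1 <- cumsum(p)
  t1 <- renyi_entropy_threshold(p, P1, 0.5)
  t2 <- th_maxentropy(h)                  # Shannon limit, alpha -> 1
  t3 <- renyi_entropy_threshold(p, P1, 2)
  ts <- sort(c(t1, t2, t3))
  t1 <- ts[1]; t2 <- ts[2]; t3 <- ts[3]
  if (abs(t1 - t2) <= 5) {
    if (abs(t2 - t3) <= 5) { b1 <- 1; b2 <- 2; b3 <- 1 }
    else { b1 <- 0; b2 <- 1; b3 <- 3 }
  } else {
    if (abs(t2 - t3) <= 5) { b1 <- 3; b2 <- 1; b3 <- 0 }
    else { b1 <- 1; b2 <- 2; b3 <- 1 }
  }
  omega <- P1[t3 + 1] - P1[t1 + 1]
  round(t1 * (P1[t1 + 1] + 0.25 * omega * b1) +
        0.25 * t2 * omega * b2 +
        t3 * (1 - P1[t3 + 1] + 0.25 * omega * b3))
}

th_shanbhag <- function(h) {
  p <- h / sum(h)
  P1 <- cumsum(p); P2 <- 1 - P1
  eps <- .Machine$double.eps
  first <- which(P1 >= eps)[1] - 1L
  last <- max(which(P2 >= eps)) - 1L
  if (is.na(first)) first <- 0L
  best_t <- first; best <- Inf
  for (t in first:last) {
    term_b <- 0.5 / P1[t + 1]
    ent_back <- 0
    if (t >= 1) {
      i <- 1:t
      ent_back <- -sum(p[i + 1] * log(1 - term_b * P1[i])) * term_b
    }
    term_o <- 0.5 / P2[t + 1]
    ent_obj <- 0
    if (t < 255) {
      i <- (t + 1):255
      ent_obj <- -sum(p[i + 1] * log(1 - term_o * P2[i + 1])) * term_o
    }
    tot <- abs(ent_back - ent_obj)
    if (tot < best) { best <- tot; best_t <- t }
  }
  best_t
}

th_triangle <- function(h) {
  nz <- which(h > 0) - 1L
  lo <- max(nz[1] - 1L, 0L)
  hi <- min(nz[length(nz)] + 1L, 255L)
  peak <- which.max(h) - 1L
  inverted <- (peak - lo) < (hi - peak)  # long tail on the right: mirror it left
  if (inverted) {
    h <- rev(h)
    lo2 <- 255L - hi
    peak <- 255L - peak
    lo <- lo2
  }
  if (lo == peak) return(if (inverted) 255L - lo else lo)
  # signed distance below the line from (lo, h[lo]) to (peak, h[peak])
  nx <- h[peak + 1] - h[lo + 1]; ny <- lo - peak
  d <- sqrt(nx^2 + ny^2); nx <- nx / d; ny <- ny / d
  d0 <- nx * lo + ny * h[lo + 1]
  split <- lo; split_dist <- 0
  for (i in (lo + 1):peak) {
    nd <- nx * i + ny * h[i + 1] - d0
    if (nd > split_dist) { split <- i; split_dist <- nd }
  }
  split <- split - 1L
  if (inverted) 255L - split else split
}

th_yen <- function(h) {
  p <- h / sum(h)
  P1 <- cumsum(p)
  P1sq <- cumsum(p^2)
  P2sq <- P1sq[256] - P1sq
  best_t <- 0; best <- -Inf
  for (t in 0:254) {
    a <- P1sq[t + 1] * P2sq[t + 1]
    b <- P1[t + 1] * (1 - P1[t + 1])
    crit <- -(if (a > 0) log(a) else 0) + 2 * (if (b > 0) log(b) else 0)
    if (crit > best) { best <- crit; best_t <- t }
  }
  best_t
}
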