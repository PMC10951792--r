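# Independent reference implementations used as oracles. These are written
# deliberately as plain, loop-based transcriptions of each method's published
# definition (exhaustive search where the criterion permits), separate from
# the package's vectorized implementations.

oracle_threshold <- function(h, method) {
  switch(method,
    "Mean" = {
      s <- 0; n <- 0
      for (i in 0:255) { s <- s + i * h[i + 1]; n <- n + h[i + 1] }
      floor(s / n)
    },
    "Otsu" = {
      n <- sum(h)
      best <- -1; bt <- 0
      for (t in 0:254) {
        w0 <- 0; w1 <- 0; s0 <- 0; s1 <- 0
        for (i in 0:t) { w0 <- w0 + h[i + 1]; s0 <- s0 + i * h[i + 1] }
        for (i in (t + 1):255) { w1 <- w1 + h[i + 1]; s1 <- s1 + i * h[i + 1] }
        if (w0 == 0 || w1 == 0) next
        crit <- (w0 / n) * (w1 / n) * (s0 / w0 - s1 / w1)^2
        if (crit > best) { best <- crit; bt <- t }
      }
      bt
    },
    "Default" = {
      nz <- which(h > 0) - 1
      mn <- nz[1]; mx <- nz[length(nz)]
      moving <- mn
      repeat {
        s1 <- s2 <- s3 <- s4 <- 0
        for (i in mn:moving) { s1 <- s1 + i * h[i + 1]; s2 <- s2 + h[i + 1] }
        for (i in (moving + 1):mx) { s3 <- s3 + i * h[i + 1]; s4 <- s4 + h[i + 1] }
        result <- (s1 / s2 + s3 / s4) / 2
        moving <- moving + 1
        if (!((moving + 1) <= result && moving < mx - 1)) break
      }
      round(result)
    },
    "IsoData" = {
      g <- 0
      for (i in 1:255) if (h[i + 1] > 0) { g <- i + 1; break }
      repeat {
        totl <- l <- toth <- hh <- 0
        for (i in 0:(g - 1)) { totl <- totl + h[i + 1]; l <- l + i * h[i + 1] }
        if (g < 255) for (i in (g + 1):255) { toth <- toth + h[i + 1]; hh <- hh + i * h[i + 1] }
        if (totl > 0 && toth > 0) {
          l <- l %/% totl; hh <- hh %/% toth
          if (g == round((l + hh) / 2)) return(g)
        }
        g <- g + 1
        if (g > 254) stop("no threshold")
      }
    },
    "Li" = {
      new_t <- sum((0:255) * h) / sum(h)
      thr <- 0
      repeat {
        old_t <- new_t
        thr <- as.integer(old_t + 0.5)
        sb <- nb <- so <- no <- 0
        for (i in 0:thr) { sb <- sb + i * h[i + 1]; nb <- nb + h[i + 1] }
        if (thr < 255) for (i in (thr + 1):255) { so <- so + i * h[i + 1]; no <- no + h[i + 1] }
        mb <- if (nb == 0) 0 else sb / nb
        mo <- if (no == 0) 0 else so / no
        temp <- (mb - mo) / (log(mb) - log(mo))
        new_t <- if (temp < -.Machine$double.eps) as.integer(temp - 0.5) else as.integer(temp + 0.5)
        if (abs(new_t - old_t) <= 0.5) break
      }
      thr
    },
    "Huang" = {
      nz <- which(h > 0) - 1
      first <- nz[1]; last <- nz[length(nz)]
      C <- last - first
      best <- Inf; bt <- first
      for (t in first:last) {
        s0 <- n0 <- s1 <- n1 <- 0
        for (i in first:t) { s0 <- s0 + i * h[i + 1]; n0 <- n0 + h[i + 1] }
        if (t < last) for (i in (t + 1):last) { s1 <- s1 + i * h[i + 1]; n1 <- n1 + h[i + 1] }
        mu0 <- s0 / n0
        mu1 <- if (n1 > 0) s1 / n1 else 0
        ent <- 0
        for (i in first:last) {
          mu <- if (i <= t) 1 / (1 + abs(i - mu0) / C) else 1 / (1 + abs(i - mu1) / C)
          if (mu > 1e-6 && mu < 1 - 1e-6)
            ent <- ent + h[i + 1] * (-mu * log(mu) - (1 - mu) * log(1 - mu))
        }
        if (ent < best) { best <- ent; bt <- t }
      }
      bt
    },
    "Intermodes" = ,
    "Minimum" = {
      y <- as.numeric(h)
      for (k in 1:10000) {
        peaks <- 0
        for (i in 1:254) if (y[i + 1] > y[i] && y[i + 1] > y[i + 2]) peaks <- peaks + 1
        if (peaks == 2) break
        y2 <- y
        for (i in 0:255) {
          lo <- if (i == 0) y[1] else y[i]
          hi <- if (i == 255) y[256] else y[i + 2]
          y2[i + 1] <- (lo + y[i + 1] + hi) / 3
        }
        y <- y2
        if (k == 10000) stop("not bimodal")
      }
      if (method == "Minimum") {
        for (i in 1:254) if (y[i] > y[i + 1] && y[i + 2] >= y[i + 1]) return(i)
        stop("no minimum")
      }
      tt <- 0
      for (i in 1:254) if (y[i + 1] > y[i] && y[i + 1] > y[i + 2]) tt <- tt + i
      floor(tt / 2)
    },
    "MaxEntropy" = {
      p <- h / sum(h)
      best <- -Inf; bt <- 0
      for (t in 0:254) {
        P1 <- sum(p[1:(t + 1)]); P2 <- 1 - P1
        if (P1 < 1e-12 || P2 < 1e-12) next
        hb <- hw <- 0
        for (i in 0:t) if (p[i + 1] > 0) hb <- hb - (p[i + 1] / P1) * log(p[i + 1] / P1)
        for (i in (t + 1):255) if (p[i + 1] > 0) hw <- hw - (p[i + 1] / P2) * log(p[i + 1] / P2)
        if (hb + hw > best) { best <- hb + hw; bt <- t }
      }
      bt
    },
    "MinError(I)" = {
      A_ <- function(j) sum(h[1:(j + 1)])
      B_ <- function(j) sum((0:j) * h[1:(j + 1)])
      C_ <- function(j) sum((0:j)^2 * h[1:(j + 1)])
      thr <- oracle_threshold(h, "Mean")
      prev <- -2
      for (k in 1:1000) {
        if (thr == prev) break
        if (A_(thr) <= 0 || A_(255) - A_(thr) <= 0) break
        mu <- B_(thr) / A_(thr)
        nu <- (B_(255) - B_(thr)) / (A_(255) - A_(thr))
        p <- A_(thr) / A_(255); q <- 1 - p
        s2 <- C_(thr) / A_(thr) - mu^2
        t2 <- (C_(255) - C_(thr)) / (A_(255) - A_(thr)) - nu^2
        if (s2 <= 0 || t2 <= 0) break
        w0 <- 1 / s2 - 1 / t2
        w1 <- mu / s2 - nu / t2
        w2 <- mu^2 / s2 - nu^2 / t2 + log10((s2 * q^2) / (t2 * p^2))
        sq <- w1^2 - w0 * w2
        if (sq < 0) break
        tmp <- (w1 + sqrt(sq)) / w0
        if (is.nan(tmp)) break
        prev <- thr
        thr <- min(max(as.integer(floor(tmp + 0.5)), 0), 254)
      }
      thr
    },
    "Moments" = {
      p <- h / sum(h)
      m1 <- m2 <- m3 <- 0
      for (i in 0:255) {
        m1 <- m1 + i * p[i + 1]; m2 <- m2 + i^2 * p[i + 1]; m3 <- m3 + i^3 * p[i + 1]
      }
      cd <- m2 - m1^2
      c0 <- (-m2^2 + m1 * m3) / cd
      c1 <- (-m3 + m2 * m1) / cd
      z0 <- 0.5 * (-c1 - sqrt(max(c1^2 - 4 * c0, 0)))
      z1 <- 0.5 * (-c1 + sqrt(max(c1^2 - 4 * c0, 0)))
      pd <- (z1 - m1) / (z1 - z0)
      s <- 0
      for (i in 0:255) { s <- s + p[i + 1]; if (s > pd) return(i) }
      255
    },
    "Percentile" = {
      n <- sum(h)
      best <- Inf; bt <- 0; cum <- 0
      for (i in 0:255) {
        cum <- cum + h[i + 1]
        d <- abs(cum / n - 0.5)
        if (d < best) { best <- d; bt <- i }
      }
      bt
    },
    "RenyiEntropy" = {
      p <- h / sum(h)
      ent_t <- function(alpha) {
        best <- -Inf; bt <- 0
        for (t in 0:254) {
          P1 <- sum(p[1:(t + 1)]); P2 <- 1 - P1
          if (P1 < 1e-12 || P2 < 1e-12) next
          if (alpha == 1) {
            hb <- hw <- 0
            for (i in 0:t) if (p[i + 1] > 0) hb <- hb - (p[i + 1] / P1) * log(p[i + 1] / P1)
            for (i in (t + 1):255) if (p[i + 1] > 0) hw <- hw - (p[i + 1] / P2) * log(p[i + 1] / P2)
            phi <- hb + hw
          } else {
            sb <- sw <- 0
            for (i in 0:t) sb <- sb + (p[i + 1] / P1)^alpha
            for (i in (t + 1):255) sw <- sw + (p[i + 1] / P2)^alpha
            phi <- (log(sb) + log(sw)) / (1 - alpha)
          }
          if (phi > best) { best <- phi; bt <- t }
        }
        bt
      }
      ts <- sort(c(ent_t(0.5), ent_t(1), ent_t(2)))
      t1 <- ts[1]; t2 <- ts[2]; t3 <- ts[3]
      if (abs(t1 - t2) <= 5) {
        if (abs(t2 - t3) <= 5) { b <- c(1, 2, 1) } else { b <- c(0, 1, 3) }
      } else {
        if (abs(t2 - t3) <= 5) { b <- c(3, 1, 0) } else { b <- c(1, 2, 1) }
      }
      P1 <- cumsum(p)
      om <- P1[t3 + 1] - P1[t1 + 1]
      round(t1 * (P1[t1 + 1] + 0.25 * om * b[1]) + 0.25 * t2 * om * b[2] +
            t3 * (1 - P1[t3 + 1] + 0.25 * om * b[3]))
    },
    "Shanbhag" = {
      p <- h / sum(h)
      P1 <- cumsum(p); P2 <- 1 - P1
      eps <- .Machine$double.eps
      first <- 0; while (P1[first + 1] < eps) first <- first + 1
      last <- 255; while (last > 0 && P2[last + 1] < eps) last <- last - 1
      best <- Inf; bt <- first
      for (t in first:last) {
        eb <- 0; term <- 0.5 / P1[t + 1]
        if (t >= 1) for (i in 1:t) eb <- eb - p[i + 1] * log(1 - term * P1[i])
        eb <- eb * term
        eo <- 0; term <- 0.5 / P2[t + 1]
        if (t < 255) for (i in (t + 1):255) eo <- eo - p[i + 1] * log(1 - term * P2[i + 1])
        eo <- eo * term
        if (abs(eb - eo) < best) { best <- abs(eb - eo); bt <- t }
      }
      bt
    },
    "Triangle" = {
      nz <- which(h > 0) - 1
      lo <- max(nz[1] - 1, 0)
      hi <- min(nz[length(nz)] + 1, 255)
      peak <- 0; dmax <- -1
      for (i in 0:255) if (h[i + 1] > dmax) { dmax <- h[i + 1]; peak <- i }
      inverted <- (peak - lo) < (hi - peak)
      hh <- h
      if (inverted) { hh <- rev(h); lo <- 255 - hi; peak <- 255 - peak }
      if (lo == peak) return(if (inverted) 255 - lo else lo)
      # signed sag of (i, hh[i]) below the chord from (lo, hh[lo]) to (peak, hh[peak])
      x1 <- lo; y1 <- hh[lo + 1]; x2 <- peak; y2 <- hh[peak + 1]
      best <- 0; split <- lo
      for (i in (lo + 1):peak) {
        d <- ((y2 - y1) * (i - x1) - (x2 - x1) * (hh[i + 1] - y1)) /
          sqrt((y2 - y1)^2 + (x2 - x1)^2)
        if (d > best) { best <- d; split <- i }
      }
      split <- split - 1
      if (inverted) 255 - split else split
    },
    "Yen" = {
      p <- h / sum(h)
      best <- -Inf; bt <- 0
      for (t in 0:254) {
        P1 <- sum(p[1:(t + 1)])
        P1sq <- sum(p[1:(t + 1)]^2)
        P2sq <- sum(p[(t + 2):256]^2)
        a <- P1sq * P2sq; b <- P1 * (1 - P1)
        crit <- -(if (a > 0) log(a) else 0) + 2 * (if (b > 0) log(b) else 0)
        if (crit > best) { best <- crit; bt <- t }
      }
      bt
    },
    stop("no oracle for ", method))
}

# random well-behaved bimodal histogram (two Gaussian bumps plus floor noise)
random_histogram <- function() {
  mu1 <- runif(1, 30, 90); mu2 <- runif(1, 150, 230)
  s1 <- runif(1, 6, 18); s2 <- runif(1, 8, 25)
  n1 <- runif(1, 2000, 12000); n2 <- runif(1, 1000, 9000)
  hh <- round(n1 * dnorm(0:255, mu1, s1) + n2 * dnorm(0:255, mu2, s2) +
              rpois(256, 1))
  as.integer(hh)
}

# brute-force prominence maxima count (matrix-shift flood, no shared code);
# the local-threshold condition references the median of the region (whole
# window when region is NULL)
oracle_foci_count <- function(w, tolerance, region = NULL) {
  med <- stats::median(if (is.null(region)) w else w[region])
  nr <- nrow(w); nc <- ncol(w)
  shift_max <- function(m) {
    out <- matrix(-Inf, nr, nc)
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      rs <- (1 + max(0, dy)):(nr + min(0, dy))
      cs <- (1 + max(0, dx)):(nc + min(0, dx))
      out[rs, cs] <- pmax(out[rs, cs], m[rs - dy, cs - dx])
    }
    out
  }
  nbmax <- shift_max(w)
  is_peak <- w >= nbmax & is.finite(nbmax) & w > apply_min_neighbor(w)
  # plateau grouping by repeated dilation of equal-valued peak pixels
  visited <- matrix(FALSE, nr, nc)
  peaks <- which(is_peak)
  vals <- w[peaks]
  ord <- order(-vals, peaks)
  accepted <- matrix(FALSE, nr, nc)
  count <- 0
  kept <- list()
  for (k in ord) {
    p <- peaks[k]
    if (visited[p]) next
    v <- w[p]
    # flood the component of {w > v - tolerance} containing p
    comp <- matrix(FALSE, nr, nc); comp[p] <- TRUE
    ok <- w > v - tolerance
    repeat {
      grown <- (comp | (shift_logical(comp, nr, nc))) & ok
      if (identical(grown, comp)) break
      comp <- grown
    }
    plateau <- comp & (w == v) & is_peak
    visited[plateau] <- TRUE
    if (any(w[comp] > v)) next
    if (any(accepted[comp] & w[comp] == v)) next
    accepted[plateau] <- TRUE
    pos <- which(plateau)
    cx <- mean((pos - 1) %/% nr); cy <- mean((pos - 1) %% nr)
    if (!is.null(region) && !region[cbind(round(cy) + 1, round(cx) + 1)]) next
    if (v < med + tolerance) next
    count <- count + 1
  }
  count
}

apply_min_neighbor <- function(w) {
  nr <- nrow(w); nc <- ncol(w)
  out <- matrix(Inf, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    rs <- (1 + max(0, dy)):(nr + min(0, dy))
    cs <- (1 + max(0, dx)):(nc + min(0, dx))
    out[rs, cs] <- pmin(out[rs, cs], w[rs - dy, cs - dx])
  }
  out
}

shift_logical <- function(m, nr, nc) {
  out <- matrix(FALSE, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    rs <- (1 + max(0, dy)):(nr + min(0, dy))
    cs <- (1 + max(0, dx)):(nc + min(0, dx))
    out[rs, cs] <- out[rs, cs] | m[rs - dy, cs - dx]
  }
  out
}

# naive classifier: explicit loops over cells x types x constraints
oracle_classify <- function(table, types) {
  out <- character(nrow(table))
  for (i in seq_len(nrow(table))) {
    if (!table$relevant[i]) { out[i] <- "excluded"; next }
    label <- "unknown"
    for (ty in types) {
      all_ok <- TRUE
      for (cs in ty$constraints) {
        if (cs$form == "interval") {
          v <- table[[cs$feature]][i]
          lo <- if (is.character(cs$min)) celltyper::quartile_thresholds(table, cs$feature)[[cs$min]] else cs$min
          hi <- if (is.character(cs$max)) celltyper::quartile_thresholds(table, cs$feature)[[cs$max]] else cs$max
          ok <- !is.na(v) && v >= lo && v <= hi
        } else {
          l <- table[[cs$left]][i]; r <- table[[cs$right]][i]
          ok <- !is.na(l) && !is.na(r) && switch(cs$relation,
            "<" = l < r, "<=" = l <= r, ">" = l > r, ">=" = l >= r)
        }
        if (!ok) { all_ok <- FALSE; break }
      }
      if (all_ok) { label <- ty$name; break }
    }
    out[i] <- label
  }
  out
}

# random feature table + random type definitions for classifier fuzzing
random_table_and_types <- function(n_cells = NULL) {
  n <- if (is.null(n_cells)) sample(4:40, 1) else n_cells
  tbl <- tibble::tibble(
    cell_id = seq_len(n),
    M1.area = runif(n, 1, 100),
    M1.circularity = runif(n),
    M1.mean = runif(n, 0, 255),
    M2.mean = runif(n, 0, 255),
    M2.foci_count = sample(0:12, n, replace = TRUE),
    relevant = runif(n) > 0.2,
    cell_type = NA_character_)
  tbl$relevant[1:4] <- TRUE   # quartile-bound constraints need >= 4 relevant
  feats <- c("M1.area", "M1.circularity", "M1.mean", "M2.mean", "M2.foci_count")
  rand_constraint <- function() {
    if (runif(1) < 0.6) {
      f <- sample(feats, 1)
      if (runif(1) < 0.25) {
        celltyper::constraint(f, min = sample(c("Q1", "Q2", "Q3"), 1))
      } else {
        b <- sort(runif(2, 0, if (f == "M1.circularity") 1 else 150))
        celltyper::constraint(f, min = b[1], max = b[2])
      }
    } else {
      lr <- sample(feats, 2)
      celltyper::constraint(left = lr[1], right = lr[2],
                            relation = sample(c("<", "<=", ">", ">="), 1))
    }
  }
  n_types <- sample(0:4, 1)
  types <- lapply(seq_len(n_types), function(k)
    celltyper::cell_type(paste0("T", k), "#112233",
                         lapply(seq_len(sample(1:3, 1)),
                                function(z) rand_constraint())))
  list(table = tbl, types = types)
}

# random valid analysis configuration for round-trip fuzzing
random_config <- function() {
  n_ch <- sample(1:3, 1)
  roles <- c("MarkerI", "MarkerII", "MarkerIII")[seq_len(n_ch)]
  channels <- stats::setNames(as.list(sample(0:2, n_ch)), roles)
  steps <- list()
  if (runif(1) < 0.5) steps <- c(steps, list(celltyper::preprocess_step("gaussian_blur", sigma = round(runif(1, 0.5, 4), 3))))
  if (runif(1) < 0.3) steps <- c(steps, list(celltyper::preprocess_step("median_filter", radius = sample(1:3, 1))))
  if (runif(1) < 0.2) steps <- c(steps, list(celltyper::preprocess_step("invert")))
  filters <- list()
  if (runif(1) < 0.7)
    filters <- list(celltyper::relevance_filter("M1.area", min = round(runif(1, 0, 20), 2)))
  types <- list()
  if (n_ch >= 2 && runif(1) < 0.7) {
    types <- list(celltyper::cell_type("tA", "#ff0000", list(
      celltyper::constraint("M2.mean", min = round(runif(1, 10, 100), 2)))))
    if (runif(1) < 0.5)
      types <- c(types, list(celltyper::cell_type("tB", "#00ff00", list(
        celltyper::constraint(left = "M2.mean", relation = ">", right = "M1.mean"),
        celltyper::constraint("M1.circularity", min = "Q3")))))
  }
  roi <- NULL
  if (runif(1) < 0.4)
    roi <- list(type = "rectangle", x = sample(0:20, 1), y = sample(0:20, 1),
                width = sample(50:150, 1), height = sample(50:150, 1))
  celltyper::analysis_config(
    channels = channels,
    calibration = if (runif(1) < 0.5) celltyper::calibration() else
      celltyper::calibration(round(runif(1, 0.1, 2), 4), round(runif(1, 0.1, 2), 4), "um"),
    roi = roi,
    preprocess = steps,
    segment = list(method = sample(celltyper::threshold_methods(), 1),
                   watershed = runif(1) < 0.5, fill_holes = runif(1) < 0.3,
                   dark_background = TRUE),
    markerII = if (n_ch >= 2) list(
      resize = celltyper::resize_spec(sample(c("none", "erode", "dilate"), 1),
                                      sample(1:3, 1)),
      foci = list(enabled = runif(1) < 0.5, tolerance = sample(10:50, 1))) else list(),
    filters = filters, cell_types = types)
}
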