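# Independent oracles, deliberately coded differently from the package paths
# they check.

# Weighted least squares via explicit normal equations (two-pass sums).
wls_oracle <- function(x, y, w) {
  sw <- sum(w)
  xbar <- sum(w * x) / sw
  ybar <- sum(w * y) / sw
  slope <- sum(w * (x - xbar) * (y - ybar)) / sum(w * (x - xbar)^2)
  intercept <- ybar - slope * xbar
  fitted <- intercept + slope * x
  r2 <- 1 - sum(w * (y - fitted)^2) / sum(w * (y - ybar)^2)
  list(intercept = intercept, slope = slope, r_squared = r2)
}

# Benjamini-Hochberg step-up, literal definition.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running_min <- 1
  for (i in m:1) {
    running_min <- min(running_min, m * p[ord[i]] / i)
    adj[ord[i]] <- running_min
  }
  pmin(adj, 1)
}

# Exhaustive linear-range scan: try every contiguous run of levels of length
# >= min_points, refit with 1/x weights via wls_oracle, accept the run if
# every level's back-calculated mean response is within the band; prefer
# more levels, then wider span, then lower start.
range_oracle <- function(concentration, ratio, min_points, band = c(0.8, 1.2)) {
  lv <- sort(unique(concentration))
  candidates <- list()
  for (i in seq_along(lv)) {
    for (j in seq_along(lv)) {
      n_run <- j - i + 1
      if (n_run < min_points) next
      run <- lv[i:j]
      sel <- concentration %in% run
      fit <- wls_oracle(concentration[sel], ratio[sel], 1 / concentration[sel])
      ok <- TRUE
      for (l in run) {
        mr <- mean(ratio[concentration == l])
        acc <- ((mr - fit$intercept) / fit$slope) / l
        if (acc < band[1] || acc > band[2]) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        candidates[[length(candidates) + 1]] <-
          c(n = n_run, span = lv[j] / lv[i], start = i, lloq = lv[i], uloq = lv[j])
      }
    }
  }
  if (!length(candidates)) return(NULL)
  cand <- do.call(rbind, candidates)
  cand <- cand[order(-cand[, "n"], -cand[, "span"], cand[, "start"]), ,
               drop = FALSE]
  as.list(cand[1, ])
}

# Two-pass Pearson correlation.
pearson_oracle <- function(x, y) {
  xm <- x - mean(x)
  ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# %RSD, direct two-pass formula.
rsd_oracle <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  100 * sqrt(sum((x - m)^2) / (n - 1)) / m
}
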