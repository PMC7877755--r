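# Independent oracles and small fixture builders shared across test files.
# The dense weighted-least-squares oracle deliberately builds the full
# observation-level design matrix and calls lm.wfit, sharing no code with the
# package's sufficient-statistics solver.

# uniform tiny fragment map: n fragments of equal length
tiny_map <- function(n, len = 400, bait = ceiling(n / 2)) {
  fragment_map("chrS", (seq_len(n) - 1) * len, seq_len(n) * len,
               bait_index = bait)
}

# random small LWMR instance: counts ~ Poisson, Y = log10(frac * p + 1)
random_lwmr_instance <- function(n_frag, n_cond, n_rep, seed) {
  set.seed(seed)
  map <- tiny_map(n_frag)
  cond <- factor(rep(sprintf("c%02d", seq_len(n_cond)), each = n_rep))
  counts <- matrix(rpois(n_frag * n_cond * n_rep, lambda = 5),
                   n_frag, n_cond * n_rep)
  frac <- sweep(counts, 2, pmax(colSums(counts), 1), "/")
  Y <- log10(frac * 500 + 1)
  position <- runif(1, 0, max(map$end))
  sigma <- runif(1, 800, 3000)
  list(map = map, cond = cond, counts = counts, Y = Y,
       position = position, scheme = weight_scheme(sigma))
}

# dense WLS solve of the same local objective; constraint chosen by `coding`
# ("sum" reproduces the package parametrization, "treatment" pins b_1 = 0)
lwmr_dense_oracle <- function(Y, counts, map, cond, position, scheme,
                              coding = c("sum", "treatment")) {
  coding <- match.arg(coding)
  mid <- (map$start + map$end) / 2
  d <- abs(mid - position)
  win <- which(d <= scheme$truncation_radius)
  wg <- exp(-d[win]^2 / (2 * scheme$sigma^2))
  lev <- levels(cond)
  J <- length(lev)
  ws <- sapply(lev, function(l)
    rowMeans(counts[win, cond == l, drop = FALSE] > 0))
  rows <- expand.grid(r = seq_len(sum(cond == lev[1])), j = seq_len(J),
                      i = seq_along(win))
  y <- mapply(function(i, j, r) Y[win[i], which(cond == lev[j])[r]],
              rows$i, rows$j, rows$r)
  w <- wg[rows$i] * ws[cbind(rows$i, rows$j)]
  Xa <- model.matrix(~ 0 + factor(rows$i, levels = seq_along(win)))
  Xb <- if (coding == "sum") stats::contr.sum(J)[rows$j, , drop = FALSE]
        else stats::contr.treatment(J)[rows$j, , drop = FALSE]
  fit <- lm.wfit(cbind(Xa, Xb), y, w)
  th <- fit$coefficients[seq_len(J - 1) + ncol(Xa)]
  b <- if (coding == "sum") drop(stats::contr.sum(J) %*% th)
       else c(0, th)
  names(b) <- lev
  list(a = unname(fit$coefficients[seq_len(ncol(Xa))]), b = b, window = win)
}

# median of ZT hours on the 24-h circle, unwrapped around a reference phase
circular_median <- function(zt, ref) {
  ((stats::median((zt - ref + 12) %% 24) - 12) + ref) %% 24
}
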