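# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# row-wise Pearson correlation between matrix rows and paired matrix rows;
# returns NA where either row has zero variance
.row_cor <- function(x, y) {
  stopifnot(identical(dim(x), dim(y)))
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  sx <- sqrt(rowSums(xc^2))
  sy <- sqrt(rowSums(yc^2))
  r <- rowSums(xc * yc) / (sx * sy)
  r[sx == 0 | sy == 0] <- NA_real_
  r
}

.row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  rowSums((x - rowMeans(x))^2) / (n - 1)
}

# z-score rows; rows with zero variance come back as NA
.row_zscore <- function(x) {
  m <- rowMeans(x)
  s <- sqrt(.row_vars(x))
  out <- (x - m) / s
  out[s == 0, ] <- NA_real_
  out
}

.assert_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1))
    stop(sprintf("'%s' must be in [0, 1]", name), call. = FALSE)
  invisible(x)
}

# derive a child RNG seed from a base seed, keeping it a valid 32-bit integer
.child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 104729 * offset) %% 2147483647L)
}
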