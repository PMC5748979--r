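# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(sprintf("'%s' must be a positive number", name), call. = FALSE)
  invisible(x)
}

.check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop(sprintf("'%s' must be a non-negative number", name), call. = FALSE)
  invisible(x)
}

.set_seed <- function(seed) {
  if (!is.null(seed) && !is.na(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# euclidean distance between rows of two matrices (n x 3)
.row_dist <- function(a, b) sqrt(rowSums((a - b)^2))

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

# rolling SD over windows [s, min(s + w - 1, n)] for every start s;
# windows with fewer than 2 samples report 0 (trivially stable)
.rolling_sd_from <- function(x, w) {
  n <- length(x)
  vapply(seq_len(n), function(s) {
    e <- min(s + w - 1L, n)
    if (e - s < 1L) 0 else stats::sd(x[s:e])
  }, numeric(1))
}
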