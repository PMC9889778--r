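# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never clobbers user seeds.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x > 0 && x == round(x)

# Fold change on the linear scale reconstructed from mean log-normalized
# values: log2((expm1(a) + eps) / (expm1(b) + eps)).
log2fc_expm1 <- function(mean_ln_a, mean_ln_b, eps = 1e-9) {
  log2((expm1(mean_ln_a) + eps) / (expm1(mean_ln_b) + eps))
}

# Row-wise two-sided Wilcoxon rank-sum test with normal approximation,
# tie correction and continuity correction; for genome-wide scans over
# thousands of cells where per-gene wilcox.test() calls are too slow.
# Returns a two-column matrix (statistic W, p).
row_ranksum <- function(mat, idx_a, idx_b) {
  na <- length(idx_a); nb <- length(idx_b)
  n <- na + nb
  sub <- mat[, c(idx_a, idx_b), drop = FALSE]
  p <- numeric(nrow(sub)); W <- numeric(nrow(sub))
  for (i in seq_len(nrow(sub))) {
    x <- sub[i, ]
    r <- rank(x)
    Wi <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    nt <- table(x)
    tie_term <- sum(nt^3 - nt)
    sigma2 <- (na * nb / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      p[i] <- 1
    } else {
      z <- Wi - na * nb / 2
      corr <- sign(z) * 0.5
      p[i] <- min(1, 2 * stats::pnorm(-abs((z - corr) / sqrt(sigma2))))
    }
    W[i] <- Wi
  }
  cbind(statistic = W, p = p)
}

# Adjusted Rand index between two labelings (used by callers validating
# module/cluster recovery against planted truth).
#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items.
#' 1 means identical partitions, 0 is the expectation under random labeling.
#'
#' @param a,b label vectors of equal length.
#' @return A single numeric value.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
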