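# internal helpers shared across modules

# logit2 / inverse on the M-value scale: M = log2(beta / (1 - beta))
.logit2 <- function(beta) log2(beta / (1 - beta))

.ilogit2 <- function(m) {
  e <- 2^m
  e / (1 + e)
}

# clip into the open interval (eps, 1 - eps); keeps logits finite
.clip01 <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

.is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Newton solve of trigamma(y) = x, vectorised; used by the method-of-moments
# hyperprior fit for variance shrinkage
.trigammaInverse <- function(x) {
  if (length(x) == 0L) return(numeric(0))
  y <- numeric(length(x))
  hi <- x > 1e7
  lo <- x < 1e-6
  mid <- !hi & !lo & !is.na(x)
  y[hi] <- 1 / sqrt(x[hi])
  y[lo] <- 1 / x[lo]
  y[is.na(x)] <- NA_real_
  if (any(mid)) {
    z <- 0.5 + 1 / x[mid]
    for (i in seq_len(50)) {
      tri <- trigamma(z)
      dif <- tri * (1 - tri / x[mid]) / psigamma(z, deriv = 2L)
      z <- z + dif
      if (max(-dif / z) < 1e-8) break
    }
    y[mid] <- z
  }
  y
}

# canonical key for a set of leaf indices (cluster identity across bootstrap
# trees); a power-of-two sum is exact up to 53 leaves, larger trees fall back
# to a string key
.leaf_keys <- function(sets, n_leaves) {
  if (n_leaves <= 53L) {
    pow <- 2^(seq_len(n_leaves) - 1L)
    vapply(sets, function(ix) sum(pow[ix]), numeric(1L))
  } else {
    vapply(sets, function(ix) paste(sort(ix), collapse = ","), character(1L))
  }
}

# leaf sets of every internal node of an hclust tree, as canonical keys
.node_leaf_sets <- function(tree) {
  merge <- tree$merge
  n_nodes <- nrow(merge)
  sets <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) {
    left <- merge[i, 1L]
    right <- merge[i, 2L]
    l <- if (left < 0) -left else sets[[left]]
    r <- if (right < 0) -right else sets[[right]]
    sets[[i]] <- c(l, r)
  }
  sets
}
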