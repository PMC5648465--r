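# Independent naive oracles: deliberately unoptimized double-loop
# implementations, kept free of any code path they are used to check.

# random quantized image (levels 1..ng, optional background zeros)
random_quantized <- function(nr = 20, nc = 20, ng = 10, bg_frac = 0, seed = 1) {
  set.seed(seed)
  lev <- matrix(sample.int(ng, nr * nc, replace = TRUE), nr, nc)
  if (bg_frac > 0)
    lev[sample(nr * nc, round(bg_frac * nr * nc))] <- 0L
  structure(list(levels = lev, n_grey = as.integer(ng)),
            class = "quantized_image")
}

oracle_glcm <- function(L, ng, distance = 1L,
                        directions = c(0, 45, 90, 135)) {
  offs <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
               `135` = c(-1, -1))
  counts <- matrix(0, ng, ng)
  for (d in as.character(directions)) {
    o <- offs[[d]] * distance
    for (r in seq_len(nrow(L))) for (c in seq_len(ncol(L))) {
      r2 <- r + o[1]; c2 <- c + o[2]
      if (r2 < 1 || r2 > nrow(L) || c2 < 1 || c2 > ncol(L)) next
      a <- L[r, c]; b <- L[r2, c2]
      if (a == 0 || b == 0) next
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  counts / sum(counts)
}

oracle_glcm_features <- function(p) {
  ng <- nrow(p)
  contrast <- dissim <- energy <- homog <- entropy <- 0
  for (i in 1:ng) for (j in 1:ng) {
    contrast <- contrast + (i - j)^2 * p[i, j]
    dissim <- dissim + abs(i - j) * p[i, j]
    energy <- energy + p[i, j]^2
    homog <- homog + p[i, j] / (1 + (i - j)^2)
    if (p[i, j] > 0) entropy <- entropy - p[i, j] * log(p[i, j])
  }
  px <- rowSums(p)
  mu <- sum((1:ng) * px)
  s2 <- sum(((1:ng) - mu)^2 * px)
  corr <- if (s2 > 0) {
    acc <- 0
    for (i in 1:ng) for (j in 1:ng)
      acc <- acc + (i - mu) * (j - mu) * p[i, j]
    acc / s2
  } else NA_real_
  sa <- se <- 0
  for (k in 2:(2 * ng)) {
    pk <- 0
    for (i in 1:ng) for (j in 1:ng) if (i + j == k) pk <- pk + p[i, j]
    sa <- sa + k * pk
    if (pk > 0) se <- se - pk * log(pk)
  }
  de <- 0
  for (k in 0:(ng - 1)) {
    pk <- 0
    for (i in 1:ng) for (j in 1:ng) if (abs(i - j) == k) pk <- pk + p[i, j]
    if (pk > 0) de <- de - pk * log(pk)
  }
  c(contrast = contrast, dissimilarity = dissim, energy = energy,
    homogeneity = homog, correlation = corr, entropy = entropy,
    sum_average = sa, sum_entropy = se, difference_entropy = de)
}

oracle_ngtdm_features <- function(L, ng, eps = 1e-12) {
  nr <- nrow(L); nc <- ncol(L)
  s <- numeric(ng); n <- numeric(ng)
  for (r in 2:(nr - 1)) for (c in 2:(nc - 1)) {
    if (L[r, c] == 0) next
    nb <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      if (L[r + dr, c + dc] > 0) nb <- c(nb, L[r + dr, c + dc])
    }
    if (length(nb) == 0) next
    i <- L[r, c]
    s[i] <- s[i] + abs(i - mean(nb))
    n[i] <- n[i] + 1
  }
  N <- sum(n)
  p <- n / N
  nz <- which(p > 0)
  coarse <- min(1 / (eps + sum(p * s)), 1e12)
  if (length(nz) < 2)
    return(c(coarseness = coarse, contrast = 0, busyness = 0,
             complexity = 0, strength = 0))
  ctr <- 0; bden <- 0; cx <- 0; stg <- 0
  for (i in nz) for (j in nz) {
    ctr <- ctr + p[i] * p[j] * (i - j)^2
    bden <- bden + abs(i * p[i] - j * p[j])
    cx <- cx + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
    stg <- stg + (p[i] + p[j]) * (i - j)^2
  }
  ngp <- length(nz)
  c(coarseness = coarse,
    contrast = ctr / (ngp * (ngp - 1)) * sum(s) / N,
    busyness = if (bden > 0) sum(p * s) / bden else 0,
    complexity = cx / N,
    strength = stg / (eps + sum(s)))
}

oracle_rlm <- function(L, ng) {
  counts <- matrix(0, ng, max(dim(L)))
  scan_line <- function(v) {
    run_val <- 0L; run_len <- 0L
    for (x in c(v, 0L)) { # sentinel flushes the last run
      if (x == run_val) {
        run_len <- run_len + 1L
      } else {
        if (run_val > 0L) counts[run_val, run_len] <<- counts[run_val, run_len] + 1
        run_val <- x; run_len <- 1L
      }
    }
  }
  for (r in seq_len(nrow(L))) scan_line(L[r, ])
  for (c in seq_len(ncol(L))) scan_line(L[, c])
  for (k in unique(c(row(L) + col(L)))) scan_line(L[row(L) + col(L) == k])
  for (k in unique(c(row(L) - col(L)))) scan_line(L[row(L) - col(L) == k])
  counts
}

oracle_glszm <- function(L, ng) {
  nr <- nrow(L); nc <- ncol(L)
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (seen[r0, c0] || L[r0, c0] == 0) next
    val <- L[r0, c0]
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE; size <- 0
    while (length(stack)) {
      pt <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        r <- pt[1] + dr; c <- pt[2] + dc
        if (r < 1 || r > nr || c < 1 || c > nc) next
        if (!seen[r, c] && L[r, c] == val) {
          seen[r, c] <- TRUE
          stack[[length(stack) + 1]] <- c(r, c)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(val, size)
  }
  zm <- do.call(rbind, zones)
  counts <- matrix(0, ng, max(zm[, 2]))
  for (k in seq_len(nrow(zm)))
    counts[zm[k, 1], zm[k, 2]] <- counts[zm[k, 1], zm[k, 2]] + 1
  counts
}

# direct evaluation of the separable Keys (a = -0.5) kernel at sample points
oracle_bicubic <- function(x, d) {
  keys <- function(t) {
    t <- abs(t)
    if (t <= 1) 1.5 * t^3 - 2.5 * t^2 + 1
    else if (t < 2) -0.5 * (t^3 - 5 * t^2 + 8 * t - 4)
    else 0
  }
  n_out <- ceiling(dim(x) / d)
  out <- matrix(0, n_out[1], n_out[2])
  for (i in seq_len(n_out[1])) for (j in seq_len(n_out[2])) {
    u <- (i - 0.5) * d + 0.5; v <- (j - 0.5) * d + 0.5
    acc <- 0
    for (a in -1:2) for (b in -1:2) {
      r <- floor(u) + a; c <- floor(v) + b
      w <- keys(u - r) * keys(v - c)
      r <- min(nrow(x), max(1, r)); c <- min(ncol(x), max(1, c))
      acc <- acc + w * x[r, c]
    }
    out[i, j] <- acc
  }
  out
}

# unpenalized logistic regression by straight Newton-Raphson
oracle_newton_logistic <- function(X, y, maxit = 50, tol = 1e-12) {
  X1 <- cbind(1, X)
  beta <- numeric(ncol(X1))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X1 %*% beta)
    p <- plogis(eta)
    w <- p * (1 - p)
    g <- crossprod(X1, y - p)
    H <- crossprod(X1 * w, X1)
    step <- solve(H, g)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# 1:1 conditional logistic == logistic regression on within-pair differences
oracle_paired_clogit <- function(cohort, predictor) {
  d <- vapply(split(seq_len(nrow(cohort)), cohort$stratum), function(idx) {
    cohort[[predictor]][idx][cohort$case[idx] == 1] -
      cohort[[predictor]][idx][cohort$case[idx] == 0]
  }, numeric(1))
  fit <- glm(rep(1, length(d)) ~ d - 1, family = binomial)
  unname(coef(fit))
}

# tiny helper: quantized image wrapper around a bare level matrix
as_quantized <- function(L, ng) {
  storage.mode(L) <- "integer"
  structure(list(levels = L, n_grey = as.integer(ng)),
            class = "quantized_image")
}

# windowed_image wrapper around a bare [0,1] matrix
as_windowed <- function(v, bg = NULL, spacing = 1 / mammotex::REFERENCE_PX_PER_MM) {
  if (is.null(bg)) bg <- matrix(FALSE, nrow(v), ncol(v))
  v[bg] <- 0
  structure(list(values = v, background = bg, lower_bound = 0,
                 upper_bound = 1, pixel_spacing = spacing),
            class = "windowed_image")
}
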